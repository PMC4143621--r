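# thin wrappers over the package's sib-pair machinery for direct
# correlation checks
sib_pairs <- linksim:::sib_pairs
age_adjusted <- linksim:::age_adjusted

sib_correlation <- function(resid, pairs) {
  x <- as.vector(resid[pairs$a, , drop = FALSE])
  y <- as.vector(resid[pairs$b, , drop = FALSE])
  cor(c(x, y), c(y, x))
}
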