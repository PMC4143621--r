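#' Estimate minor-allele frequencies from founders only
#'
#' Per marker, the estimate is the minor-allele count among genotyped
#' founders divided by twice the number of founders with a non-missing
#' genotype. Markers with no observed minor allele in founders —
#' including markers where no founder is genotyped at all — are floored
#' at 0.0001 so that every marker can still be scored. If the computed
#' frequency exceeds 0.5 the allele labels are swapped (`swapped = TRUE`)
#' so the reported frequency is always a *minor*-allele frequency;
#' downstream dosages are flipped accordingly by [analysis_dosages()].
#'
#' Nonfounders never contribute, even when many founders are masked;
#' the estimate is therefore more accurate for common than for rare
#' variants when founders are missing.
#'
#' @param geno a `geno_matrix`.
#' @param peds the matching `ped_set`.
#' @param floor frequency assigned when no minor allele is observed
#'   (default 0.0001).
#' @return The marker table (attribute `markers` of `geno`) with
#'   `estimated_maf`, `swapped`, `n_founders_genotyped` and
#'   `minor_count` filled in.
#' @export
estimate_founder_maf <- function(geno, peds, floor = 1e-4) {
  markers <- attr(geno, "markers")
  df <- ped_df(peds)
  fk <- pheno_key(df$family, df$id)[is.na(df$fid)]
  fg <- geno[rownames(geno) %in% fk, , drop = FALSE]
  obs <- !is.na(fg)
  n_obs <- colSums(obs)
  count <- colSums(fg, na.rm = TRUE)
  freq <- ifelse(n_obs > 0L, count / (2 * n_obs), 0)
  swapped <- freq > 0.5
  freq[swapped] <- 1 - freq[swapped]
  # count of the allele reported as minor after any swap
  minor_count <- ifelse(swapped, 2L * n_obs - count, count)
  floored <- minor_count == 0L
  freq[floored] <- floor
  if (any(floored))
    message(sprintf("estimate_founder_maf: %d marker(s) with no minor allele in founders set to %g",
                    sum(floored), floor))
  markers$estimated_maf <- as.numeric(freq)
  markers$swapped <- swapped
  markers$n_founders_genotyped <- as.integer(n_obs)
  markers$minor_count <- as.integer(minor_count)
  markers
}

#' Dosages on the analysis (post-swap) minor allele
#'
#' Returns the genotype matrix with dosages flipped (`2 - d`) for
#' markers whose allele labels were swapped by
#' [estimate_founder_maf()], so that dosage always counts the allele
#' whose frequency is `estimated_maf`.
#'
#' @param geno a `geno_matrix`.
#' @param markers marker table with a `swapped` column.
#' @return An integer matrix of the same shape.
#' @export
analysis_dosages <- function(geno, markers) {
  sw <- which(markers$swapped)
  if (length(sw) > 0L)
    geno[, sw] <- 2L - geno[, sw, drop = FALSE]
  geno
}

#' Write a founder allele-frequency table
#'
#' Tab-separated, PLINK-frequency-report compatible columns:
#' `marker_id`, `n_founders_genotyped`, `minor_count`, `estimated_maf`.
#'
#' @param markers marker table filled by [estimate_founder_maf()].
#' @param path output path.
#' @export
write_freq_table <- function(markers, path) {
  utils::write.table(
    markers[, c("marker_id", "n_founders_genotyped", "minor_count",
                "estimated_maf")],
    path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
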