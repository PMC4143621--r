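#' Simulate the polygenic null quantitative trait
#'
#' Draws, per pedigree and replicate, a multivariate normal trait with
#' mean `trait_mean + age_mean_slope * age` and covariance
#' `trait_sd^2 * (h2 * 2 * Phi + (1 - h2) * I)`, where `Phi` is the
#' kinship matrix of the family. This is the additive polygenic model:
#' relatives are correlated (full sibs by `h2 / 2`) but the trait is
#' independent of every genotyped marker by construction, so any
#' significant linkage to it is a false positive. Replicates are
#' mutually independent; replicate `r` depends only on
#' `(config$seed, r)`.
#'
#' @param peds a `ped_set`.
#' @param config a [sim_config()]; uses `heritability`,
#'   `age_mean_slope`, `trait_mean`, `trait_sd`, `n_replicates`, `seed`.
#' @return A `trait_replicates` object: numeric matrix (individuals x
#'   replicates) with `family:id` rownames and the generating parameters
#'   in attribute `params`.
#' @export
simulate_polygenic_trait <- function(peds, config) {
  stopifnot(inherits(config, "sim_config"))
  h2 <- config$heritability
  df <- ped_df(peds)
  n_all <- nrow(df)
  R <- config$n_replicates
  # Per-family Cholesky factors of the trait covariance, computed once.
  chols <- lapply(peds, function(p) {
    phi <- kinship_matrix(p)
    sigma <- config$trait_sd^2 * (h2 * 2 * phi + (1 - h2) * diag(nrow(phi)))
    ch <- tryCatch(chol(sigma), error = function(e)
      stop("trait covariance not positive definite in family ", family_id(p)))
    ch
  })
  mu <- config$trait_mean + config$age_mean_slope * df$age
  out <- matrix(NA_real_, n_all, R,
                dimnames = list(pheno_key(df$family, df$id),
                                sprintf("rep%03d", seq_len(R))))
  sizes <- vapply(peds, nrow, integer(1))
  offsets <- cumsum(c(0L, sizes))
  for (r in seq_len(R)) {
    set.seed(stage_seed(config$seed, "trait", r))
    for (f in seq_along(peds)) {
      n <- sizes[f]
      ix <- offsets[f] + seq_len(n)
      out[ix, r] <- mu[ix] + drop(crossprod(chols[[f]], stats::rnorm(n)))
    }
  }
  structure(out,
            params = list(heritability = h2,
                          age_mean_slope = config$age_mean_slope,
                          trait_mean = config$trait_mean,
                          trait_sd = config$trait_sd),
            class = c("trait_replicates", "matrix", "array"))
}

#' @export
print.trait_replicates <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "Quantitative trait replicates: %d individuals x %d replicates (h2 = %g, age slope = %g)\n",
    nrow(x), ncol(x), p$heritability, p$age_mean_slope))
  invisible(x)
}

#' Dichotomize a quantitative trait at a founder quantile
#'
#' Estimates a single cutoff as the `founder_quantile` quantile
#' (linear-interpolation estimator, [stats::quantile()] type 7) of the
#' founder trait values pooled across *all* available replicates, then
#' classifies, within each replicate, every individual with a value
#' strictly smaller than the cutoff as affected and all others as
#' unaffected; individuals with no trait value are unknown.
#'
#' @param traits a `trait_replicates` matrix.
#' @param peds the matching `ped_set`.
#' @param config a [sim_config()]; uses `founder_quantile`.
#' @return An `affection_replicates` object: integer matrix
#'   (individuals x replicates, codes 0/1/2) with the cutoff in
#'   attribute `cutoff`.
#' @export
dichotomize_by_founder_quantile <- function(traits, peds, config) {
  stopifnot(inherits(config, "sim_config"))
  df <- ped_df(peds)
  key <- pheno_key(df$family, df$id)
  founder_keys <- key[is.na(df$fid)]
  fv <- as.vector(traits[rownames(traits) %in% founder_keys, , drop = FALSE])
  fv <- fv[!is.na(fv)]
  if (length(fv) == 0L) stop("no founder trait values to estimate the cutoff")
  cutoff <- unname(stats::quantile(fv, probs = config$founder_quantile, type = 7))
  message(sprintf("dichotomization cutoff: %.6g (quantile %.2f of %d pooled founder values)",
                  cutoff, config$founder_quantile, length(fv)))
  aff <- matrix(0L, nrow(traits), ncol(traits), dimnames = dimnames(traits))
  aff[!is.na(traits) & traits < cutoff] <- 2L
  aff[!is.na(traits) & traits >= cutoff] <- 1L
  structure(aff, cutoff = cutoff,
            class = c("affection_replicates", "matrix", "array"))
}

#' Assign a complete-null random affection status
#'
#' Each phenotyped individual is independently affected with probability
#' `prevalence`, per replicate, independent of genotypes and of the
#' pedigree — the complete null for a linkage scan.
#'
#' @param peds a `ped_set`.
#' @param config a [sim_config()]; uses `prevalence`, `n_replicates`,
#'   `seed`.
#' @return An `affection_replicates` matrix (codes 1/2).
#' @export
assign_random_affection <- function(peds, config) {
  stopifnot(inherits(config, "sim_config"))
  df <- ped_df(peds)
  n <- nrow(df)
  R <- config$n_replicates
  aff <- matrix(NA_integer_, n, R,
                dimnames = list(pheno_key(df$family, df$id),
                                sprintf("rep%03d", seq_len(R))))
  for (r in seq_len(R)) {
    set.seed(stage_seed(config$seed, "affection", r))
    aff[, r] <- ifelse(stats::runif(n) < config$prevalence, 2L, 1L)
  }
  structure(aff, class = c("affection_replicates", "matrix", "array"))
}

#' @export
print.affection_replicates <- function(x, ...) {
  cat(sprintf(
    "Affection replicates: %d individuals x %d replicates (%.1f%% affected)",
    nrow(x), ncol(x), 100 * mean(x == 2L, na.rm = TRUE)))
  if (!is.null(attr(x, "cutoff")))
    cat(sprintf("; dichotomization cutoff %.4g", attr(x, "cutoff")))
  cat("\n")
  invisible(x)
}

#' Write a phenotype table
#'
#' Tab-separated long table: family, individual, replicate,
#' quantitative value (`NA` if none), affection code.
#'
#' @param path output path.
#' @param peds a `ped_set`.
#' @param affection an `affection_replicates` matrix.
#' @param traits optional `trait_replicates` matrix.
#' @export
write_phenotypes <- function(path, peds, affection, traits = NULL) {
  df <- ped_df(peds)
  key <- pheno_key(df$family, df$id)
  R <- ncol(affection)
  out <- data.frame(
    family = rep(df$family, R),
    individual = rep(df$id, R),
    replicate = rep(seq_len(R), each = nrow(df)),
    value = if (is.null(traits)) NA_real_ else
      as.vector(traits[match(key, rownames(traits)), , drop = FALSE]),
    affection = as.vector(affection[match(key, rownames(affection)), , drop = FALSE]))
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Recover heritability from simulated sib pairs
#'
#' Moment estimator of narrow-sense heritability: under the additive
#' polygenic model full sibs have trait correlation `h2 / 2`, so twice
#' the age-adjusted full-sib correlation estimates `h2`. Trait values
#' are first residualized on age by least squares (pooling replicates),
#' then the correlation is computed over all full-sib pairs in all
#' replicates, each pair entered in both orders so the estimate is
#' symmetric.
#'
#' @param traits a `trait_replicates` matrix.
#' @param peds the matching `ped_set`.
#' @return A list with `h2` (the estimate), `r` (sib correlation),
#'   `n_pairs` (sib pair-replicate observations) and `ci95` (Fisher-z
#'   interval for `h2`).
#' @export
estimate_h2_sib <- function(traits, peds) {
  pairs <- sib_pairs(peds)
  if (length(pairs$a) == 0L) stop("no full-sib pairs in the pedigree set")
  resid <- age_adjusted(traits, peds)
  x <- as.vector(resid[pairs$a, , drop = FALSE])
  y <- as.vector(resid[pairs$b, , drop = FALSE])
  r <- stats::cor(c(x, y), c(y, x))
  n <- length(x)
  z <- atanh(r) + c(-1.96, 1.96) / sqrt(n)
  list(h2 = 2 * r, r = r, n_pairs = n, ci95 = 2 * tanh(z))
}

# all unordered full-sib pairs, as row indices into the trait matrix
sib_pairs <- function(peds) {
  df <- ped_df(peds)
  key <- pheno_key(df$family, df$id)
  a <- integer(0)
  b <- integer(0)
  par <- paste(df$family, df$fid, df$mid)
  for (grp in split(seq_len(nrow(df))[!is.na(df$fid)],
                    par[!is.na(df$fid)])) {
    if (length(grp) < 2L) next
    cmb <- utils::combn(grp, 2L)
    a <- c(a, cmb[1L, ])
    b <- c(b, cmb[2L, ])
  }
  list(a = a, b = b, keys = key)
}

# least-squares age adjustment, pooled across replicates
age_adjusted <- function(traits, peds) {
  df <- ped_df(peds)
  age <- df$age[match(rownames(traits), pheno_key(df$family, df$id))]
  fit <- stats::lm(as.vector(traits) ~ rep(age, ncol(traits)))
  matrix(stats::residuals(fit), nrow(traits), ncol(traits),
         dimnames = dimnames(traits))
}
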