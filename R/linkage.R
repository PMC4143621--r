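#' Parametric trait model
#'
#' The single-locus disease model plugged into the linkage likelihood:
#' disease allele frequency and the penetrance vector
#' `(f_dd, f_Dd, f_DD)`, i.e. the probability of being affected given
#' 0, 1 or 2 copies of the disease allele D. The default is the
#' rare-dominant reduced-penetrance model used throughout the
#' simulation study: `p_D = 0.01`, penetrances 0.05 for dd and 0.5 for
#' both Dd and DD.
#'
#' @param disease_allele_freq frequency of D, in (0, 1).
#' @param penetrances numeric length 3, each in `[0, 1]`.
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(disease_allele_freq = 0.01,
                        penetrances = c(0.05, 0.5, 0.5)) {
  stopifnot(disease_allele_freq > 0, disease_allele_freq < 1,
            length(penetrances) == 3L,
            all(penetrances >= 0), all(penetrances <= 1))
  structure(list(disease_allele_freq = disease_allele_freq,
                 penetrances = as.numeric(penetrances)),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf(
    "Trait model: p(D) = %g, penetrances dd/Dd/DD = %g/%g/%g%s\n",
    x$disease_allele_freq, x$penetrances[1L], x$penetrances[2L],
    x$penetrances[3L],
    if (x$penetrances[2L] == x$penetrances[3L]) " (dominant)" else ""))
  invisible(x)
}

#' Pedigree log-likelihood of joint trait and marker data
#'
#' Exact likelihood of the observed affection statuses and marker
#' genotypes of one loop-free family under the two-locus model
#' (trait locus from `model`, biallelic marker with minor-allele
#' frequency `marker_maf`, recombination fraction `theta`), computed by
#' Elston-Stewart peeling over the 16 ordered two-locus diplotypes.
#' Unknown affection and missing marker genotypes contribute factors of
#' one. Returns `-Inf` when the likelihood is exactly zero.
#'
#' @param ped a loop-free `pedigree`.
#' @param marker_dosages named integer vector (names = member ids) of
#'   minor-allele dosages 0/1/2, `NA` for missing; members absent from
#'   the vector are treated as missing.
#' @param marker_maf minor-allele frequency, in (0, 1).
#' @param model a [trait_model()].
#' @param theta recombination fraction in `[0, 0.5]`.
#' @param affection optional integer vector (0/1/2) along members
#'   overriding `ped$aff`.
#' @return Natural-log likelihood (scalar).
#' @export
pedigree_log_likelihood <- function(ped, marker_dosages, marker_maf, model,
                                    theta = 0, affection = NULL) {
  stopifnot(inherits(model, "trait_model"),
            marker_maf > 0, marker_maf < 1)
  if (theta < 0 || theta > 0.5) stop("theta must be in [0, 0.5]")
  plan <- peel_plan(ped)
  aff <- if (is.null(affection)) ped$aff else as.integer(affection)
  d <- matrix(NA_integer_, nrow(ped), 1L)
  hit <- match(ped$id, names(marker_dosages))
  d[!is.na(hit), 1L] <- as.integer(marker_dosages[hit[!is.na(hit)]])
  log(10) * peel_loglik10(plan, aff, d, marker_maf, model, theta)
}

#' Brute-force likelihood by exhaustive enumeration
#'
#' Independent ground-truth oracle for [pedigree_log_likelihood()]:
#' sums founder priors x transmissions x penetrances over every joint
#' assignment of ordered two-locus diplotypes to all members. Only
#' states consistent with each member's observed marker dosage are
#' enumerated (4, 8 or 16 states per member); the total number of
#' joint assignments must not exceed `max_combos`.
#'
#' @inheritParams pedigree_log_likelihood
#' @param max_combos enumeration bound (default `2^22`).
#' @return Natural-log likelihood (scalar); `-Inf` for likelihood zero.
#' @export
brute_force_log_likelihood <- function(ped, marker_dosages, marker_maf, model,
                                       theta = 0, affection = NULL,
                                       max_combos = 2^22) {
  stopifnot(inherits(model, "trait_model"),
            marker_maf > 0, marker_maf < 1, theta >= 0, theta <= 0.5)
  n <- nrow(ped)
  aff <- if (is.null(affection)) ped$aff else as.integer(affection)
  d <- rep(NA_integer_, n)
  hit <- match(ped$id, names(marker_dosages))
  d[!is.na(hit)] <- as.integer(marker_dosages[hit[!is.na(hit)]])
  f <- model$penetrances
  pD <- model$disease_allele_freq
  founder <- is_founder(ped)
  prior <- pD^.st_nD * (1 - pD)^(2 - .st_nD) *
    marker_maf^.st_nminor * (1 - marker_maf)^(2 - .st_nminor)
  weight <- lapply(seq_len(n), function(i) {
    pen <- switch(aff[i] + 1L, rep(1, 16L), 1 - f[.st_nD + 1L], f[.st_nD + 1L])
    if (founder[i]) pen <- pen * prior
    pen
  })
  allowed <- lapply(seq_len(n), function(i) {
    if (is.na(d[i])) 1:16 else which(.st_nminor == d[i])
  })
  sizes <- lengths(allowed)
  N <- prod(sizes)
  if (N > max_combos)
    stop(sprintf("pedigree too large for enumeration: %.3g consistent joint states (cap %.3g)",
                 N, max_combos))
  G <- gamete_matrix(theta)
  # transmission lookup T[c, f, m] flattened
  Tarr <- array(0, c(16L, 16L, 16L))
  for (sc in 1:16)
    Tarr[sc, , ] <- outer(G[.st_hp[sc], ], G[.st_hm[sc], ])
  fi <- match(ped$fid, ped$id)
  mi <- match(ped$mid, ped$id)
  base <- cumprod(c(1, sizes[-n]))
  total <- 0
  chunk <- 2^16
  for (start in seq(0, N - 1, by = chunk)) {
    idx <- start:min(start + chunk - 1, N - 1)
    st <- matrix(0L, length(idx), n)
    prob <- rep(1, length(idx))
    for (i in seq_len(n)) {
      digit <- (idx %/% base[i]) %% sizes[i]
      st[, i] <- allowed[[i]][digit + 1L]
      prob <- prob * weight[[i]][st[, i]]
    }
    for (i in which(!founder)) {
      prob <- prob * Tarr[cbind(st[, i], st[, fi[i]], st[, mi[i]])]
    }
    total <- total + sum(prob)
  }
  if (total <= 0) -Inf else log(total)
}

# ---- two-point LOD scans -------------------------------------------------

# Per-family cached quantities reused across replicates and theta
# values: peeling plan, analysis dosage submatrix, per-marker MAFs and
# the marker-only log10 likelihood (theta-free denominator part).
new_scan_cache <- function(peds, geno, markers, model) {
  maf <- markers$estimated_maf
  if (anyNA(maf)) stop("markers lack estimated_maf; run estimate_founder_maf()")
  dos_all <- analysis_dosages(geno, markers)
  fams <- lapply(peds, function(p) {
    plan <- peel_plan(p)
    key <- pheno_key(family_id(p), p$id)
    dmat <- matrix(NA_integer_, nrow(p), nrow(markers))
    hit <- match(key, rownames(dos_all))
    dmat[!is.na(hit), ] <- dos_all[hit[!is.na(hit)], , drop = FALSE]
    marker_only <- peel_loglik10(plan, rep(0L, nrow(p)), dmat, maf, model, 0.5)
    if (any(marker_only == -Inf))
      stop("Mendelian-inconsistent marker data in family ", family_id(p),
           ": marker(s) ",
           paste(utils::head(markers$marker_id[marker_only == -Inf], 5L),
                 collapse = ", "),
           " have zero likelihood under any recombination fraction")
    list(plan = plan, dmat = dmat, marker_only = marker_only,
         key = key, n = nrow(p))
  })
  list(fams = fams, maf = maf, markers = markers, model = model)
}

# affection codes per family member for replicate input: named vector on
# family:id keys, or NULL to use ped$aff
fam_affection <- function(cache_fam, ped, affection) {
  if (is.null(affection)) return(ped$aff)
  a <- affection[cache_fam$key]
  a[is.na(a)] <- 0L
  as.integer(a)
}

#' Two-point LOD scan
#'
#' Computes, for every marker, the two-point parametric LOD score
#' `log10 L(theta) - log10 L(0.5)` per family and their sum, under a
#' given trait model. The denominator factorizes at free recombination
#' into the trait-only times the marker-only likelihood, which are
#' cached per family. A family LOD of `-Inf` (zero likelihood at the
#' evaluated theta, e.g. an obligate recombinant under full penetrance)
#' propagates to the total and is reported as a sentinel; such markers
#' are excluded from significance counting downstream.
#'
#' @param peds a `ped_set` of loop-free pedigrees.
#' @param geno a `geno_matrix`.
#' @param markers marker table with `estimated_maf` filled (see
#'   [estimate_founder_maf()]).
#' @param model a [trait_model()].
#' @param theta recombination fraction (default 0, the scan used in the
#'   false-positive study).
#' @param affection optional named integer vector (`family:id` keys,
#'   codes 0/1/2) overriding the affection column, e.g. one replicate
#'   column of an `affection_replicates` matrix.
#' @param cache optional precomputed cache from `new_scan_cache()`
#'   (internal; reused across replicates by [run_experiment()]).
#' @return A `lod_scan`: list with `table` (data frame marker_id,
#'   chrom, pos_bp, estimated_maf, theta, total_lod), `family_lods`
#'   (families x markers matrix), `theta`, `model`.
#' @export
twopoint_lod <- function(peds, geno, markers, model = trait_model(),
                         theta = 0, affection = NULL, cache = NULL) {
  if (theta < 0 || theta > 0.5) stop("theta must be in [0, 0.5]")
  if (is.null(cache)) cache <- new_scan_cache(peds, geno, markers, model)
  M <- nrow(cache$markers)
  fl <- matrix(0, length(peds), M,
               dimnames = list(names(peds), cache$markers$marker_id))
  if (theta < 0.5) {
    for (f in seq_along(peds)) {
      cf <- cache$fams[[f]]
      aff <- fam_affection(cf, peds[[f]], affection)
      joint <- peel_loglik10(cf$plan, aff, cf$dmat, cache$maf, model, theta)
      trait_only <- peel_loglik10(cf$plan, aff,
                                  matrix(NA_integer_, cf$n, 1L), 0.5,
                                  model, 0.5)
      fl[f, ] <- joint - drop(trait_only) - cf$marker_only
    }
  }
  total <- colSums(fl)
  structure(list(
    table = data.frame(marker_id = cache$markers$marker_id,
                       chrom = cache$markers$chrom,
                       pos_bp = cache$markers$pos_bp,
                       estimated_maf = cache$maf,
                       theta = theta,
                       total_lod = total,
                       stringsAsFactors = FALSE),
    family_lods = fl, theta = theta, model = model),
    class = "lod_scan")
}

#' @export
print.lod_scan <- function(x, ...) {
  finite <- is.finite(x$table$total_lod)
  cat(sprintf(
    "Two-point LOD scan: %d markers x %d families at theta = %g\n",
    nrow(x$table), nrow(x$family_lods), x$theta))
  if (any(finite))
    cat(sprintf("  max total LOD %.4f at %s\n",
                max(x$table$total_lod[finite]),
                x$table$marker_id[finite][which.max(x$table$total_lod[finite])]))
  if (any(!finite))
    cat(sprintf("  %d marker(s) with -Inf LOD sentinel\n", sum(!finite)))
  invisible(x)
}

#' @export
summary.lod_scan <- function(object, thresholds = lod_thresholds(), ...) {
  summarize_replicate(object, thresholds)
}

#' @export
plot.lod_scan <- function(x, thresholds = lod_thresholds(), ...) {
  ok <- is.finite(x$table$total_lod)
  plot(x$table$pos_bp[ok] / 1e6, x$table$total_lod[ok],
       xlab = "position (Mb)", ylab = "total LOD",
       main = sprintf("Two-point LOD at theta = %g", x$theta),
       pch = 16, cex = 0.4, ...)
  graphics::abline(h = c(thresholds$gws_lod, thresholds$suggestive_lod),
                   lty = c(1, 2), col = "grey40")
  invisible(x)
}

#' Maximize the LOD over a recombination-fraction grid
#'
#' Evaluates the total two-point LOD on a grid of theta values and
#' returns, per marker, the maximizing theta and the maximum LOD, ties
#' broken toward smaller theta. The default grid is
#' `{0, 0.001, 0.01, 0.02, ..., 0.5}`.
#'
#' @inheritParams twopoint_lod
#' @param grid theta values in `[0, 0.5]`; must contain 0 and 0.5.
#' @return A `lod_scan` whose table gains `theta_hat` and `max_lod`;
#'   `family_lods` and `total_lod` refer to theta = 0.
#' @export
maximize_theta <- function(peds, geno, markers, model = trait_model(),
                           grid = c(0, 0.001, seq(0.01, 0.5, by = 0.01)),
                           affection = NULL) {
  if (length(grid) == 0L) stop("empty theta grid")
  if (!any(grid == 0) || !any(grid == 0.5))
    stop("theta grid must contain 0 and 0.5")
  grid <- sort(unique(grid))
  cache <- new_scan_cache(peds, geno, markers, model)
  totals <- matrix(NA_real_, length(grid), nrow(markers))
  base <- NULL
  for (k in seq_along(grid)) {
    sc <- twopoint_lod(peds, geno, markers, model, theta = grid[k],
                       affection = affection, cache = cache)
    totals[k, ] <- sc$table$total_lod
    if (grid[k] == 0) base <- sc
  }
  totals[!is.finite(totals)] <- -Inf
  # ties (within numerical tolerance) break toward the smallest theta
  best <- apply(totals, 2L, function(v)
    which(v >= max(v) - 1e-9)[1L])
  base$table$theta_hat <- grid[best]
  base$table$max_lod <- totals[cbind(best, seq_len(ncol(totals)))]
  base
}

#' Stream per-marker LOD results to a file
#'
#' Tab-separated: marker_id, chrom, pos, estimated_maf, theta,
#' total_lod, then one column per family LOD.
#'
#' @param scan a `lod_scan`.
#' @param path output path.
#' @param append append without header (for streaming replicates).
#' @export
write_lod_table <- function(scan, path, append = FALSE) {
  out <- cbind(scan$table, as.data.frame(t(scan$family_lods)))
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     sep = "\t", append = append, col.names = !append)
  invisible(path)
}
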