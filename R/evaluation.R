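#' LOD thresholds
#'
#' The classic genome-wide-significance (3.3) and suggestive (1.9)
#' two-point LOD thresholds, plus the per-family minor thresholds (1.0,
#' 0.5) used to profile which families drive a significant marker.
#'
#' @param gws_lod,suggestive_lod,family_minor_lod_mid,family_minor_lod_low
#'   log10-unit thresholds; must satisfy gws > suggestive > mid > low > 0.
#' @return A list of class `lod_thresholds`.
#' @export
lod_thresholds <- function(gws_lod = 3.3, suggestive_lod = 1.9,
                           family_minor_lod_mid = 1.0,
                           family_minor_lod_low = 0.5) {
  stopifnot(gws_lod > suggestive_lod,
            suggestive_lod > family_minor_lod_mid,
            family_minor_lod_mid > family_minor_lod_low,
            family_minor_lod_low > 0)
  structure(list(gws_lod = gws_lod, suggestive_lod = suggestive_lod,
                 family_minor_lod_mid = family_minor_lod_mid,
                 family_minor_lod_low = family_minor_lod_low),
            class = "lod_thresholds")
}

#' Summarize one replicate of a genome scan
#'
#' Counts markers whose total LOD meets or exceeds the
#' genome-wide-significance threshold (the boundary is inclusive:
#' a LOD equal to the threshold is significant). `-Inf` and `NaN`
#' sentinel LODs are excluded; `max_lod` is taken over finite values.
#'
#' @param scan a `lod_scan`.
#' @param thresholds a [lod_thresholds()].
#' @param replicate_id optional identifier echoed in the summary.
#' @return A `replicate_summary`: list with `replicate_id`,
#'   `n_significant_markers`, `max_lod`, and `significant` (data frame
#'   of significant markers with estimated MAF, total and per-family
#'   LODs and the family-contribution profile label).
#' @export
summarize_replicate <- function(scan, thresholds = lod_thresholds(),
                                replicate_id = NA_integer_) {
  stopifnot(inherits(scan, "lod_scan"))
  lod <- scan$table$total_lod
  if (length(lod) == 0L) stop("empty LOD stream")
  finite <- is.finite(lod)
  sig <- finite & lod >= thresholds$gws_lod
  sig_df <- scan$table[sig, , drop = FALSE]
  if (nrow(sig_df) > 0L) {
    fls <- scan$family_lods[, sig, drop = FALSE]
    sig_df$profile <- vapply(seq_len(ncol(fls)), function(j)
      family_contribution_profile(fls[, j], thresholds), "")
    sig_df$family_lods <- I(lapply(seq_len(ncol(fls)), function(j) fls[, j]))
  } else {
    sig_df$profile <- character(0)
    sig_df$family_lods <- I(list())
  }
  structure(list(replicate_id = replicate_id,
                 n_significant_markers = sum(sig),
                 max_lod = if (any(finite)) max(lod[finite]) else -Inf,
                 significant = sig_df),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf(
    "Replicate %s: %d significant marker(s), max LOD %.4f\n",
    ifelse(is.na(x$replicate_id), "?", as.character(x$replicate_id)),
    x$n_significant_markers, x$max_lod))
  invisible(x)
}

#' Family-contribution profile of a significant marker
#'
#' Labels a significant marker by which families drive it:
#' `driver_1_2_suggestive` when one or two families individually exceed
#' the suggestive threshold (1.9), `diffuse` when no family exceeds 1.0
#' but two to five families exceed 0.5, and `other` otherwise.
#'
#' @param family_lods numeric vector of per-family LOD scores.
#' @param thresholds a [lod_thresholds()].
#' @return A single label string.
#' @export
family_contribution_profile <- function(family_lods,
                                        thresholds = lod_thresholds()) {
  fl <- family_lods[is.finite(family_lods)]
  n_sugg <- sum(fl > thresholds$suggestive_lod)
  n_mid <- sum(fl > thresholds$family_minor_lod_mid)
  n_low <- sum(fl > thresholds$family_minor_lod_low)
  if (n_sugg >= 1L && n_sugg <= 2L) return("driver_1_2_suggestive")
  if (n_mid == 0L && n_low >= 2L && n_low <= 5L) return("diffuse")
  "other"
}

#' Summarize an experiment across replicates
#'
#' Aggregates per-replicate summaries into the experiment-level view:
#' how many replicates produced at least one genome-wide-significant
#' marker (the family-wise error estimate, with an exact
#' Clopper-Pearson 95% interval), per-replicate significant-marker
#' counts, nested MAF strata of significant markers (`< 0.05`,
#' `< 0.01`, and exactly at the 0.0001 floor), family-contribution
#' profile counts, and a cross-replicate overlap report (how many
#' distinct markers were significant in exactly one replicate).
#'
#' @param reps list of `replicate_summary` objects.
#' @param thresholds a [lod_thresholds()].
#' @param maf_floor the monomorphic floor matched by exact equality.
#' @return An `experiment_summary` list.
#' @export
summarize_experiment <- function(reps, thresholds = lod_thresholds(),
                                 maf_floor = 1e-4) {
  stopifnot(length(reps) >= 1L)
  n_rep <- length(reps)
  n_sig <- vapply(reps, function(r) r$n_significant_markers, integer(1))
  with_gws <- sum(n_sig >= 1L)
  ci <- stats::binom.test(with_gws, n_rep)$conf.int
  sig_all <- do.call(rbind, lapply(reps, function(r)
    r$significant[, c("marker_id", "estimated_maf", "total_lod", "profile")]))
  if (is.null(sig_all))
    sig_all <- data.frame(marker_id = character(0), estimated_maf = numeric(0),
                          total_lod = numeric(0), profile = character(0))
  maf <- sig_all$estimated_maf
  marker_reps <- table(sig_all$marker_id)
  structure(list(
    n_replicates = n_rep,
    n_replicates_with_gws = with_gws,
    fwer_estimate = with_gws / n_rep,
    fwer_ci95 = as.numeric(ci),
    mean_significant = mean(n_sig),
    min_significant = min(n_sig),
    max_significant = max(n_sig),
    n_significant_total = nrow(sig_all),
    maf_strata = c(lt_0.05 = sum(maf < 0.05),
                   lt_0.01 = sum(maf < 0.01),
                   at_floor = sum(maf == maf_floor)),
    profile_counts = c(
      driver_1_2_suggestive = sum(sig_all$profile == "driver_1_2_suggestive"),
      diffuse = sum(sig_all$profile == "diffuse"),
      other = sum(sig_all$profile == "other")),
    n_markers_in_one_replicate = sum(marker_reps == 1L),
    max_lod = max(c(-Inf, vapply(reps, function(r) r$max_lod, numeric(1)))),
    thresholds = thresholds),
    class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("Experiment summary over %d replicates:\n", x$n_replicates))
  cat(sprintf(
    "  replicates with >= 1 GWS marker (LOD >= %.2f): %d  (FWER estimate %.3f, exact 95%% CI %.3f-%.3f)\n",
    x$thresholds$gws_lod, x$n_replicates_with_gws, x$fwer_estimate,
    x$fwer_ci95[1L], x$fwer_ci95[2L]))
  cat(sprintf(
    "  significant markers per replicate: mean %.1f (range %d-%d); max LOD %.4f\n",
    x$mean_significant, x$min_significant, x$max_significant, x$max_lod))
  cat(sprintf(
    "  MAF strata of %d significant markers (nested): %d with MAF < 0.05, %d with MAF < 0.01, %d at the 0.0001 floor\n",
    x$n_significant_total, x$maf_strata["lt_0.05"], x$maf_strata["lt_0.01"],
    x$maf_strata["at_floor"]))
  cat(sprintf(
    "  family profiles: %d driven by 1-2 suggestive families, %d diffuse, %d other; %d marker(s) significant in exactly one replicate\n",
    x$profile_counts["driver_1_2_suggestive"], x$profile_counts["diffuse"],
    x$profile_counts["other"], x$n_markers_in_one_replicate))
  invisible(x)
}
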