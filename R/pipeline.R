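#' Experiment specification
#'
#' Bundles everything one end-to-end false-positive experiment needs:
#' the trait mode (`dichotomized_polygenic` — the polygenic null
#' quantitative trait cut at a founder quantile — or `complete_null` —
#' random affection at the configured prevalence), the simulation
#' configuration, the parametric trait model, the LOD thresholds, the
#' theta policy (`zero_only` evaluates the scan at theta = 0, the
#' study's default; `grid_max` also maximizes over a theta grid), and
#' the output directory for artifact files.
#'
#' @param trait_mode `"dichotomized_polygenic"` or `"complete_null"`.
#' @param config a [sim_config()].
#' @param model a [trait_model()].
#' @param thresholds a [lod_thresholds()].
#' @param theta_policy `"zero_only"` or `"grid_max"`.
#' @param output_dir directory for artifacts; `NULL` disables writing.
#' @return A list of class `experiment_spec`.
#' @export
experiment_spec <- function(trait_mode = c("dichotomized_polygenic",
                                           "complete_null"),
                            config = sim_config(),
                            model = trait_model(),
                            thresholds = lod_thresholds(),
                            theta_policy = c("zero_only", "grid_max"),
                            output_dir = NULL) {
  structure(list(trait_mode = match.arg(trait_mode),
                 config = config, model = model, thresholds = thresholds,
                 theta_policy = match.arg(theta_policy),
                 output_dir = output_dir),
            class = "experiment_spec")
}

#' Run a false-positive linkage experiment end to end
#'
#' Stages, in order: generate pedigrees, verify they are loop-free,
#' gene-drop markers and mask ungenotyped individuals, simulate the
#' configured null trait (`n_replicates` replicates), estimate founder
#' minor-allele frequencies (0.0001 floor), run the two-point LOD scan
#' at theta = 0 for every replicate (plus a grid maximization when the
#' theta policy asks for it), and summarize false positives per
#' replicate and across the experiment. Deterministic for a fixed
#' config (including its seed). When `output_dir` is set, intermediate
#' artifacts (pedigrees, .ped/.map genotypes, phenotype table,
#' frequency table, per-replicate LOD tables, reports) are written
#' there; partial outputs are retained if a stage fails.
#'
#' @param spec an [experiment_spec()].
#' @param shared optional list of precomputed inputs `(peds, geno,
#'   markers)` so paired experiments can reuse identical genotypes.
#' @param progress print per-replicate progress.
#' @return An `experiment_summary` (see [summarize_experiment()]) with
#'   the per-replicate summaries in attribute `replicates` and the
#'   shared inputs in attribute `inputs`.
#' @export
run_experiment <- function(spec, shared = NULL, progress = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  cfg <- spec$config
  out <- spec$output_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.null(shared)) {
    peds <- stage("generate_pedigrees", generate_pedigree_set(cfg))
    stage("check_loops", {
      for (p in peds)
        if (length(detect_loops(p)) > 0L)
          stop("generated pedigree ", family_id(p), " has loops")
    })
    markers <- stage("simulate_markers", simulate_markers(cfg))
    geno <- stage("gene_drop", gene_drop_genotypes(peds, markers, cfg))
    masked <- stage("mask", mask_ungenotyped(geno, peds, cfg))
    geno <- masked$geno
    peds <- masked$peds
  } else {
    peds <- shared$peds
    geno <- shared$geno
    markers <- attr(geno, "markers")
  }
  traits <- NULL
  if (spec$trait_mode == "dichotomized_polygenic") {
    traits <- stage("simulate_trait", simulate_polygenic_trait(peds, cfg))
    affection <- stage("dichotomize", suppressMessages(
      dichotomize_by_founder_quantile(traits, peds, cfg)))
  } else {
    affection <- stage("assign_affection", assign_random_affection(peds, cfg))
  }
  markers <- stage("estimate_maf", suppressMessages(
    estimate_founder_maf(geno, peds)))
  if (!is.null(out)) {
    write_pedigrees(peds, file.path(out, "pedigrees.ped"))
    write_plink(geno, peds, file.path(out, "genotypes"))
    write_phenotypes(file.path(out, "phenotypes.tsv"), peds, affection, traits)
    write_freq_table(markers, file.path(out, "founder_freq.tsv"))
  }
  cache <- stage("scan_cache", new_scan_cache(peds, geno, markers, spec$model))
  reps <- vector("list", cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    scan <- stage(sprintf("linkage replicate %d", r),
                  twopoint_lod(peds, geno, markers, spec$model, theta = 0,
                               affection = affection[, r], cache = cache))
    if (spec$theta_policy == "grid_max") {
      mx <- stage(sprintf("theta maximization replicate %d", r),
                  maximize_theta(peds, geno, markers, spec$model,
                                 affection = affection[, r]))
      scan$table$theta_hat <- mx$table$theta_hat
      scan$table$max_lod <- mx$table$max_lod
    }
    reps[[r]] <- summarize_replicate(scan, spec$thresholds, replicate_id = r)
    if (!is.null(out))
      write_lod_table(scan, file.path(out, sprintf("lod_rep%03d.tsv", r)))
    if (progress)
      message(sprintf("replicate %d/%d: %d significant, max LOD %.3f",
                      r, cfg$n_replicates, reps[[r]]$n_significant_markers,
                      reps[[r]]$max_lod))
  }
  summary <- summarize_experiment(reps, spec$thresholds)
  attr(summary, "replicates") <- reps
  attr(summary, "inputs") <- list(peds = peds, geno = geno, markers = markers,
                                  affection = affection, traits = traits)
  if (!is.null(out)) write_report(summary, spec)
  summary
}

#' Write experiment reports
#'
#' Emits a machine-readable tab-separated summary
#' (`experiment_summary.tsv`: one `field<TAB>value` row per quantity), a
#' human-readable text report with a provenance block (trait mode,
#' seed, package version, config echo), and a per-replicate
#' significant-marker table (`significant_markers.tsv`: replicate,
#' marker, position, LOD).
#'
#' @param summary an `experiment_summary` from [run_experiment()].
#' @param spec the [experiment_spec()] that produced it.
#' @param dir output directory; defaults to `spec$output_dir`.
#' @return The directory, invisibly.
#' @export
write_report <- function(summary, spec, dir = spec$output_dir) {
  stopifnot(!is.null(dir))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fields <- c(n_replicates = summary$n_replicates,
              n_replicates_with_gws = summary$n_replicates_with_gws,
              fwer_estimate = summary$fwer_estimate,
              fwer_ci_low = summary$fwer_ci95[1L],
              fwer_ci_high = summary$fwer_ci95[2L],
              mean_significant = summary$mean_significant,
              min_significant = summary$min_significant,
              max_significant = summary$max_significant,
              n_significant_total = summary$n_significant_total,
              maf_lt_0.05 = unname(summary$maf_strata["lt_0.05"]),
              maf_lt_0.01 = unname(summary$maf_strata["lt_0.01"]),
              maf_at_floor = unname(summary$maf_strata["at_floor"]),
              profile_driver = unname(summary$profile_counts["driver_1_2_suggestive"]),
              profile_diffuse = unname(summary$profile_counts["diffuse"]),
              profile_other = unname(summary$profile_counts["other"]),
              n_markers_in_one_replicate = summary$n_markers_in_one_replicate,
              max_lod = summary$max_lod)
  utils::write.table(
    # full double precision so numeric fields re-parse exactly
    data.frame(field = names(fields),
               value = sprintf("%.17g", unname(fields))),
    file.path(dir, "experiment_summary.tsv"),
    quote = FALSE, row.names = FALSE, sep = "\t")
  reps <- attr(summary, "replicates")
  sig <- do.call(rbind, lapply(reps, function(r) {
    if (nrow(r$significant) == 0L) return(NULL)
    data.frame(replicate = r$replicate_id,
               marker_id = r$significant$marker_id,
               chrom = r$significant$chrom,
               pos_bp = r$significant$pos_bp,
               total_lod = r$significant$total_lod,
               estimated_maf = r$significant$estimated_maf,
               profile = r$significant$profile)
  }))
  if (is.null(sig))
    sig <- data.frame(replicate = integer(0), marker_id = character(0),
                      chrom = character(0), pos_bp = integer(0),
                      total_lod = numeric(0), estimated_maf = numeric(0),
                      profile = character(0))
  utils::write.table(sig, file.path(dir, "significant_markers.tsv"),
                     quote = FALSE, row.names = FALSE, sep = "\t")
  txt <- c(
    "Two-point linkage false-positive experiment",
    sprintf("trait mode: %s | theta policy: %s | seed: %d | linksim %s",
            spec$trait_mode, spec$theta_policy, spec$config$seed,
            as.character(utils::packageVersion("linksim"))),
    sprintf("model: p(D) = %g, penetrances %s; GWS LOD >= %g (inclusive), suggestive > %g",
            spec$model$disease_allele_freq,
            paste(spec$model$penetrances, collapse = "/"),
            spec$thresholds$gws_lod, spec$thresholds$suggestive_lod),
    "",
    utils::capture.output(print(summary)),
    "",
    "config:",
    utils::capture.output(print(spec$config))[-1L])
  writeLines(txt, file.path(dir, "report.txt"))
  write_sim_config(spec$config, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Read back a machine-readable experiment summary
#'
#' @param path the `experiment_summary.tsv` written by [write_report()].
#' @return A named numeric vector of the summary fields.
#' @export
read_experiment_summary <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$value), df$field)
}
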