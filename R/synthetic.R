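#' Simulation configuration
#'
#' Collects every tunable of the synthetic study in one validated list.
#' The defaults emulate the study system: ~20 multi-generation pedigrees
#' of 30-90 members, a rare-variant-heavy biallelic marker panel with
#' optional founder-haplotype LD, about a third of individuals without
#' genotypes (founders over-represented), a polygenic null quantitative
#' trait with heritability 0.68 whose mean decreases with age, a 20%
#' founder-quantile dichotomization, a 10% random-affection prevalence,
#' and 50 phenotype replicates.
#'
#' @param n_pedigrees number of families.
#' @param pedigree_size_range integer pair, accepted family sizes.
#' @param n_generations generations per family (founders are generation 1).
#' @param n_markers number of biallelic markers.
#' @param marker_maf_spectrum list with `rare_prop` (proportion of
#'   markers in the rare class), `rare_range` and `common_range`
#'   (uniform minor-allele-frequency ranges for the two classes).
#' @param founder_haplotype_pool distinct founder haplotypes per LD
#'   block; 0 means independent markers (no LD).
#' @param ld_block_markers consecutive markers per LD block when a
#'   haplotype pool is used.
#' @param intermarker_spacing centimorgans between adjacent markers.
#' @param ungenotyped_fraction proportion of individuals with all
#'   genotypes masked.
#' @param founder_mask_weight sampling weight of founders relative to
#'   nonfounders when choosing who is masked.
#' @param heritability narrow-sense h-squared of the polygenic trait.
#' @param age_mean_slope trait units per year of age (negative: the
#'   trait mean decreases with age).
#' @param trait_mean baseline trait mean (trait units at age 0).
#' @param trait_sd total trait standard deviation (trait units).
#' @param prevalence probability of affection under the complete-null
#'   random trait.
#' @param founder_quantile founder-distribution quantile used as the
#'   dichotomization cutoff.
#' @param n_replicates number of phenotype replicates.
#' @param seed master integer seed; every stage derives its stream from
#'   it, so a fixed config is fully reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_pedigrees = 20L,
                       pedigree_size_range = c(30L, 90L),
                       n_generations = 4L,
                       n_markers = 10000L,
                       marker_maf_spectrum = list(rare_prop = 0.7,
                                                  rare_range = c(0.0005, 0.01),
                                                  common_range = c(0.01, 0.5)),
                       founder_haplotype_pool = 0L,
                       ld_block_markers = 10L,
                       intermarker_spacing = 0.05,
                       ungenotyped_fraction = 0.3,
                       founder_mask_weight = 3,
                       heritability = 0.68,
                       age_mean_slope = -0.5,
                       trait_mean = 100,
                       trait_sd = 15,
                       prevalence = 0.10,
                       founder_quantile = 0.20,
                       n_replicates = 50L,
                       seed = 1L) {
  cfg <- list(n_pedigrees = as.integer(n_pedigrees),
              pedigree_size_range = as.integer(pedigree_size_range),
              n_generations = as.integer(n_generations),
              n_markers = as.integer(n_markers),
              marker_maf_spectrum = marker_maf_spectrum,
              founder_haplotype_pool = as.integer(founder_haplotype_pool),
              ld_block_markers = as.integer(ld_block_markers),
              intermarker_spacing = as.numeric(intermarker_spacing),
              ungenotyped_fraction = as.numeric(ungenotyped_fraction),
              founder_mask_weight = as.numeric(founder_mask_weight),
              heritability = as.numeric(heritability),
              age_mean_slope = as.numeric(age_mean_slope),
              trait_mean = as.numeric(trait_mean),
              trait_sd = as.numeric(trait_sd),
              prevalence = as.numeric(prevalence),
              founder_quantile = as.numeric(founder_quantile),
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed))
  stopifnot(cfg$n_pedigrees >= 0L,
            length(cfg$pedigree_size_range) == 2L,
            cfg$pedigree_size_range[1L] >= 3L,
            diff(cfg$pedigree_size_range) >= 0L,
            cfg$n_generations >= 2L,
            cfg$n_markers >= 0L,
            cfg$marker_maf_spectrum$rare_prop >= 0,
            cfg$marker_maf_spectrum$rare_prop <= 1,
            cfg$founder_haplotype_pool >= 0L,
            cfg$intermarker_spacing >= 0,
            cfg$ungenotyped_fraction >= 0, cfg$ungenotyped_fraction <= 1,
            cfg$heritability >= 0, cfg$heritability <= 1,
            cfg$trait_sd > 0,
            cfg$prevalence >= 0, cfg$prevalence <= 1,
            cfg$founder_quantile >= 0, cfg$founder_quantile <= 1,
            cfg$n_replicates >= 1L)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration:\n")
  for (k in names(x)) {
    v <- x[[k]]
    if (is.list(v)) v <- paste(names(v), vapply(v, paste, "", collapse = "/"),
                               sep = "=", collapse = " ")
    cat(sprintf("  %-24s %s\n", k, paste(v, collapse = ", ")))
  }
  invisible(x)
}

# Deterministic per-stage seed splitting: every stage (and, where
# relevant, replicate or family index) draws from its own stream derived
# only from (master seed, stage, index). Kept below 2^31.
stage_seed <- function(seed, stage, index = 0L) {
  code <- match(stage, c("pedigrees", "markers", "genedrop", "mask",
                         "trait", "affection", "misc"))
  if (is.na(code)) stop("unknown seed stage: ", stage)
  as.integer((as.numeric(seed) * 69069 + code * 1000003 + index * 7919) %%
               2147483629)
}

#' Generate a synthetic pedigree set
#'
#' Builds `n_pedigrees` loop-free multi-generation families by forward
#' simulation: one founding couple, 2-5 children per couple, and a
#' fraction of children in non-terminal generations marrying in a new
#' founder spouse. Draws are repeated until the family size falls in
#' `pedigree_size_range`. Ages decrease by about 25 years per
#' generation, founders (top generation) being 60-90 years old.
#' Affection is initialized to unknown; traits are simulated separately.
#'
#' @param config a [sim_config()].
#' @return A `ped_set`.
#' @export
generate_pedigree_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  peds <- vector("list", config$n_pedigrees)
  for (i in seq_len(config$n_pedigrees)) {
    set.seed(stage_seed(config$seed, "pedigrees", i))
    peds[[i]] <- simulate_one_pedigree(sprintf("fam%02d", i), config)
  }
  new_ped_set(peds)
}

simulate_one_pedigree <- function(fam, config, max_attempts = 500L) {
  lo <- config$pedigree_size_range[1L]
  hi <- config$pedigree_size_range[2L]
  G <- config$n_generations
  for (attempt in seq_len(max_attempts)) {
    nid <- 0L
    new_id <- function() {
      nid <<- nid + 1L
      as.character(nid)
    }
    rows <- list()
    add <- function(id, fid, mid, sex, gen) {
      age <- max(1, round(stats::runif(1, 60, 90) - 25 * (gen - 1) +
                            stats::rnorm(1, 0, 2)))
      rows[[length(rows) + 1L]] <<- data.frame(
        id = id, fid = fid, mid = mid, sex = sex, aff = 0L, age = age,
        genotyped = TRUE, stringsAsFactors = FALSE)
    }
    f0 <- new_id(); m0 <- new_id()
    add(f0, NA_character_, NA_character_, 1L, 1L)
    add(m0, NA_character_, NA_character_, 2L, 1L)
    couples <- list(c(f0, m0))
    for (g in seq_len(G - 1L)) {
      nxt <- list()
      for (cp in couples) {
        nkids <- sample(2:5, 1L)
        for (k in seq_len(nkids)) {
          kid <- new_id()
          sex <- sample(1:2, 1L)
          add(kid, cp[1L], cp[2L], sex, g + 1L)
          if (g + 1L < G && stats::runif(1) < 0.75) {
            sp <- new_id()
            add(sp, NA_character_, NA_character_, 3L - sex, g + 1L)
            nxt[[length(nxt) + 1L]] <-
              if (sex == 1L) c(kid, sp) else c(sp, kid)
          }
        }
      }
      couples <- nxt
      if (length(rows) > hi) break
    }
    n <- length(rows)
    if (n >= lo && n <= hi) {
      ped <- new_pedigree(fam, do.call(rbind, rows))
      return(validate_pedigree(ped))
    }
  }
  stop(sprintf(
    "could not generate a pedigree of %d-%d members with %d generations in %d attempts",
    lo, hi, G, max_attempts))
}

#' Simulate the marker panel
#'
#' Draws `n_markers` biallelic markers on one chromosome at uniform
#' genetic spacing, with true minor-allele frequencies from the
#' configured rare/common mixture (default 70% of markers uniform on
#' the rare range, 30% on the common range, emulating the
#' rare-variant-heavy spectrum of sequencing panels). Physical
#' positions use 1 cM ~ 1 Mb.
#'
#' @param config a [sim_config()].
#' @return A `marker_info` data frame with columns `marker_id`, `chrom`,
#'   `pos_bp`, `pos_cM`, `minor`, `major`, `true_maf`, `estimated_maf`
#'   (`NA` until [estimate_founder_maf()]), `swapped`.
#' @export
simulate_markers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "markers"))
  M <- config$n_markers
  sp <- config$marker_maf_spectrum
  rare <- stats::runif(M) < sp$rare_prop
  maf <- numeric(M)
  maf[rare] <- stats::runif(sum(rare), sp$rare_range[1L], sp$rare_range[2L])
  maf[!rare] <- stats::runif(sum(!rare), sp$common_range[1L], sp$common_range[2L])
  cm <- seq_len(M) * config$intermarker_spacing
  data.frame(marker_id = sprintf("m%06d", seq_len(M)),
             chrom = "1",
             pos_bp = round(cm * 1e6) + 1,
             pos_cM = cm,
             minor = "A", major = "G",
             true_maf = maf,
             estimated_maf = NA_real_,
             swapped = FALSE,
             stringsAsFactors = FALSE)
}

# Haldane map function: cM distance -> recombination fraction.
haldane_theta <- function(d_cm) 0.5 * (1 - exp(-2 * d_cm / 100))

#' Gene-drop genotypes through a pedigree set
#'
#' Founder haplotypes are drawn from population frequencies (allele-wise
#' Bernoulli draws, or from a finite per-block haplotype pool when
#' `founder_haplotype_pool > 0`, which induces strong local LD), and
#' each nonfounder receives one recombinant gamete per parent with
#' intermarker recombination fractions obtained from the cM map via
#' Haldane's map function. The result records minor-allele dosages.
#'
#' @param peds a `ped_set`.
#' @param markers a `marker_info` data frame sorted by map position.
#' @param config a [sim_config()].
#' @return A `geno_matrix`: integer matrix (individuals x markers,
#'   dosage 0/1/2) with `family:id` rownames and the marker table in
#'   attribute `markers`.
#' @export
gene_drop_genotypes <- function(peds, markers, config) {
  stopifnot(inherits(config, "sim_config"))
  M <- nrow(markers)
  if (is.unsorted(markers$pos_cM)) stop("markers must be sorted by map position")
  theta <- if (M > 1L) haldane_theta(diff(markers$pos_cM)) else numeric(0)
  if (M > 1L) theta[diff(as.integer(factor(markers$chrom))) != 0] <- 0.5
  # population-level founder haplotype pool, shared by all families so
  # LD block orientation is consistent study-wide
  pools <- NULL
  if (config$founder_haplotype_pool > 0L) {
    set.seed(stage_seed(config$seed, "genedrop", 0L))
    blk <- ceiling(seq_len(M) / config$ld_block_markers)
    pool_n <- config$founder_haplotype_pool
    pools <- lapply(split(seq_len(M), blk), function(ix)
      matrix(as.integer(stats::runif(pool_n * length(ix)) <
                          rep(markers$true_maf[ix], each = pool_n)),
             nrow = pool_n))
    attr(pools, "blk") <- blk
  }
  rows <- list()
  fam_i <- 0L
  for (p in peds) {
    fam_i <- fam_i + 1L
    set.seed(stage_seed(config$seed, "genedrop", fam_i))
    hap <- gene_drop_family(p, markers$true_maf, theta, config, pools)
    dos <- hap$pat + hap$mat
    rownames(dos) <- pheno_key(family_id(p), p$id)
    rows[[fam_i]] <- dos
  }
  geno <- do.call(rbind, rows)
  if (is.null(geno)) geno <- matrix(0L, 0L, M)
  colnames(geno) <- markers$marker_id
  structure(geno, markers = markers, class = c("geno_matrix", class(geno)))
}

# One family: returns list(pat, mat) of 0/1 minor-allele haplotype
# matrices, members x markers.
gene_drop_family <- function(ped, maf, theta, config, pools = NULL) {
  n <- nrow(ped)
  M <- length(maf)
  pat <- matrix(0L, n, M)
  mat <- matrix(0L, n, M)
  draw_founder_hap <- if (!is.null(pools)) {
    blk <- attr(pools, "blk")
    pool_n <- config$founder_haplotype_pool
    function() {
      h <- integer(M)
      for (b in seq_along(pools)) {
        ix <- which(blk == b)
        h[ix] <- pools[[b]][sample.int(pool_n, 1L), ]
      }
      h
    }
  } else {
    function() as.integer(stats::runif(M) < maf)
  }
  gamete <- function(h1, h2) {
    if (M == 1L) {
      if (stats::runif(1) < 0.5) h1 else h2
    } else {
      swaps <- stats::runif(M - 1L) < theta
      use2 <- cumsum(c(stats::runif(1) < 0.5, swaps)) %% 2L == 1L
      ifelse(use2, h2, h1)
    }
  }
  fi <- match(ped$fid, ped$id)
  mi <- match(ped$mid, ped$id)
  for (i in topological_order(ped)) {
    if (is.na(fi[i])) {
      pat[i, ] <- draw_founder_hap()
      mat[i, ] <- draw_founder_hap()
    } else {
      pat[i, ] <- gamete(pat[fi[i], ], mat[fi[i], ])
      mat[i, ] <- gamete(pat[mi[i], ], mat[mi[i], ])
    }
  }
  list(pat = pat, mat = mat)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d markers (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Mask ungenotyped individuals
#'
#' Sets all genotypes of `round(fraction * N)` individuals to missing,
#' sampling founders with `founder_mask_weight` times the weight of
#' nonfounders (the emulated study added many ungenotyped founders to
#' complete its pedigrees), and updates the `genotyped` flags.
#'
#' @param geno a `geno_matrix`.
#' @param peds the matching `ped_set`.
#' @param config a [sim_config()]; uses `ungenotyped_fraction` and
#'   `founder_mask_weight`.
#' @return A list with elements `geno` (masked matrix) and `peds`
#'   (flags updated).
#' @export
mask_ungenotyped <- function(geno, peds, config) {
  stopifnot(inherits(config, "sim_config"))
  N <- nrow(geno)
  n_mask <- round(config$ungenotyped_fraction * N)
  if (n_mask > 0L) {
    set.seed(stage_seed(config$seed, "mask"))
    df <- ped_df(peds)
    key <- pheno_key(df$family, df$id)
    fo <- is.na(df$fid)
    w <- ifelse(fo, config$founder_mask_weight, 1)[match(rownames(geno), key)]
    masked <- sample.int(N, n_mask, prob = w)
    geno[masked, ] <- NA_integer_
    masked_keys <- rownames(geno)[masked]
    peds <- new_ped_set(lapply(peds, function(p) {
      p$genotyped <- !(pheno_key(family_id(p), p$id) %in% masked_keys)
      p
    }))
  }
  list(geno = geno, peds = peds)
}

# ---- file formats --------------------------------------------------------

#' Write and read PLINK-style .ped/.map files
#'
#' `write_plink()` emits a pre-makeped pedigree + genotype file
#' (`<prefix>.ped`: family, id, father, mother, sex, affection, then two
#' allele columns per marker, `0 0` for missing) and the matching
#' 4-column `.map` (chromosome, marker id, cM, bp).
#'
#' @param geno a `geno_matrix`.
#' @param peds the matching `ped_set`.
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(geno, peds, prefix) {
  markers <- attr(geno, "markers")
  df <- ped_df(peds)
  key <- pheno_key(df$family, df$id)
  g <- geno[match(key, rownames(geno)), , drop = FALSE]
  minor <- markers$minor
  major <- markers$major
  al <- matrix("0", nrow(g), 2L * ncol(g))
  for (j in seq_len(ncol(g))) {
    d <- g[, j]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, minor[j], major[j]))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2L, minor[j], major[j]))
    al[, 2L * j - 1L] <- a1
    al[, 2L * j] <- a2
  }
  lead <- cbind(df$family, df$id, ifelse(is.na(df$fid), "0", df$fid),
                ifelse(is.na(df$mid), "0", df$mid), df$sex, df$aff)
  utils::write.table(cbind(lead, al), paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  utils::write.table(markers[, c("chrom", "marker_id", "pos_cM", "pos_bp")],
                     paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' @rdname write_plink
#' @description `read_genotypes_ped()` reads the pair back; allele
#'   columns are converted to minor-allele dosages using the allele
#'   labels in `markers` (default: minor `A`, major `G`).
#' @param markers optional `marker_info`; reconstructed from the `.map`
#'   when absent.
#' @export
read_genotypes_ped <- function(prefix, markers = NULL) {
  map <- utils::read.table(paste0(prefix, ".map"), stringsAsFactors = FALSE,
                           col.names = c("chrom", "marker_id", "pos_cM", "pos_bp"))
  if (is.null(markers)) {
    markers <- data.frame(marker_id = as.character(map$marker_id),
                          chrom = as.character(map$chrom),
                          pos_bp = map$pos_bp, pos_cM = map$pos_cM,
                          minor = "A", major = "G", true_maf = NA_real_,
                          estimated_maf = NA_real_, swapped = FALSE,
                          stringsAsFactors = FALSE)
  }
  ped <- utils::read.table(paste0(prefix, ".ped"), stringsAsFactors = FALSE,
                           colClasses = "character")
  M <- nrow(map)
  if (ncol(ped) != 6L + 2L * M)
    stop("ped/map mismatch: ", ncol(ped) - 6L, " allele columns for ", M,
         " markers")
  geno <- matrix(NA_integer_, nrow(ped), M)
  for (j in seq_len(M)) {
    a1 <- ped[[6L + 2L * j - 1L]]
    a2 <- ped[[6L + 2L * j]]
    d <- (a1 == markers$minor[j]) + (a2 == markers$minor[j])
    d[a1 == "0" | a2 == "0"] <- NA_integer_
    geno[, j] <- as.integer(d)
  }
  rownames(geno) <- pheno_key(ped[[1L]], ped[[2L]])
  colnames(geno) <- markers$marker_id
  structure(geno, markers = markers, class = c("geno_matrix", "matrix", "array"))
}

#' Write and read a minimal VCF
#'
#' `write_vcf()` emits a plain-text VCFv4.2 with a GT-only FORMAT, the
#' minor allele as ALT, and one sample column per individual
#' (`family:id`). `read_genotypes_vcf()` parses it back (via the vcfR
#' package) into a `geno_matrix` of ALT-allele dosages.
#'
#' @param geno a `geno_matrix`.
#' @param path output `.vcf` path.
#' @return `write_vcf()` the path; `read_genotypes_vcf()` a `geno_matrix`.
#' @export
write_vcf <- function(geno, path) {
  markers <- attr(geno, "markers")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=linksim",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(geno)), collapse = "\t")),
             con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(geno))) {
    d <- geno[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    writeLines(paste(c(markers$chrom[j], markers$pos_bp[j], markers$marker_id[j],
                       markers$major[j], markers$minor[j], ".", ".", ".", "GT",
                       gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L
  fix <- vcfR::getFIX(v)
  markers <- data.frame(marker_id = fix[, "ID"], chrom = fix[, "CHROM"],
                        pos_bp = as.numeric(fix[, "POS"]),
                        pos_cM = as.numeric(fix[, "POS"]) / 1e6,
                        minor = fix[, "ALT"], major = fix[, "REF"],
                        true_maf = NA_real_, estimated_maf = NA_real_,
                        swapped = FALSE, stringsAsFactors = FALSE)
  geno <- t(dos)
  colnames(geno) <- markers$marker_id
  structure(geno, markers = markers, class = c("geno_matrix", "matrix", "array"))
}

#' Write and read a flat key-value configuration file
#'
#' Mirrors the [sim_config()] fields one per line as `key = value`
#' (vectors comma-separated; the MAF spectrum flattened to
#' `rare_prop`, `rare_range`, `common_range`).
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @export
write_sim_config <- function(config, path) {
  flat <- config
  sp <- flat$marker_maf_spectrum
  flat$marker_maf_spectrum <- NULL
  flat$rare_prop <- sp$rare_prop
  flat$rare_range <- sp$rare_range
  flat$common_range <- sp$common_range
  writeLines(vapply(names(flat), function(k)
    paste0(k, " = ", paste(flat[[k]], collapse = ",")), ""), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- lapply(kv, function(x) as.numeric(strsplit(trimws(x[2L]), ",")[[1L]]))
  names(vals) <- keys
  spectrum <- list(rare_prop = vals$rare_prop, rare_range = vals$rare_range,
                   common_range = vals$common_range)
  vals <- vals[setdiff(keys, c("rare_prop", "rare_range", "common_range"))]
  do.call(sim_config, c(vals, list(marker_maf_spectrum = spectrum)))
}
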