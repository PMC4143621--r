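test_that("h2 = 0 gives relatives no trait correlation", {
  cfg <- sim_config(n_pedigrees = 3L, pedigree_size_range = c(10L, 25L),
                    n_generations = 3L, heritability = 0,
                    n_replicates = 200L, seed = 8L)
  peds <- generate_pedigree_set(cfg)
  tr <- simulate_polygenic_trait(peds, cfg)
  pairs <- sib_pairs(peds)
  resid <- age_adjusted(tr, peds)
  r <- sib_correlation(resid, pairs)
  n_eff <- length(pairs$a) * ncol(tr)
  expect_lt(abs(atanh(r)), 3 / sqrt(n_eff))
})

test_that("h2 = 0.68 gives an age-adjusted full-sib correlation near h2/2", {
  cfg <- sim_config(n_pedigrees = 10L, pedigree_size_range = c(20L, 40L),
                    n_generations = 3L, heritability = 0.68,
                    n_replicates = 20L, seed = 8L)
  peds <- generate_pedigree_set(cfg)
  tr <- simulate_polygenic_trait(peds, cfg)
  pairs <- sib_pairs(peds)
  n_pairs <- length(pairs$a) * ncol(tr)
  expect_gte(n_pairs, 2000L)
  # the replicate-pooled correlation is centered on h2/2 = 0.34 (the
  # per-replicate correlation is biased low with few families, since
  # grand-mean centering over a handful of correlated clusters eats
  # between-family variance; pooling replicates removes that)
  est <- estimate_h2_sib(tr, peds)
  expect_lt(abs(est$r - 0.34), 0.05)
  # doubling recovers the generative heritability
  expect_lt(abs(est$h2 - 0.68), 0.1)
  expect_equal(est$n_pairs, n_pairs)
})

test_that("regression on age recovers the configured (negative) slope", {
  cfg <- sim_config(n_pedigrees = 8L, pedigree_size_range = c(20L, 40L),
                    n_generations = 3L, age_mean_slope = -0.5,
                    n_replicates = 20L, seed = 9L)
  peds <- generate_pedigree_set(cfg)
  tr <- simulate_polygenic_trait(peds, cfg)
  df <- ped_df(peds)
  age <- df$age[match(rownames(tr), pheno_key(df$family, df$id))]
  fit <- lm(as.vector(tr) ~ rep(age, ncol(tr)))
  est <- coef(summary(fit))[2L, ]
  expect_lt(est["Estimate"], 0)
  expect_lt(abs(est["Estimate"] - (-0.5)), 3 * est["Std. Error"])
})

test_that("trait replicates are deterministic and replicate-indexed", {
  cfg <- small_config()
  peds <- generate_pedigree_set(cfg)
  t1 <- simulate_polygenic_trait(peds, cfg)
  t2 <- simulate_polygenic_trait(peds, cfg)
  expect_identical(unclass(t1), unclass(t2))
})

test_that("founder-quantile dichotomization uses the linear-interpolation quantile", {
  # founders with values 1..10 in a single replicate: the 20% quantile
  # is 2.8, so exactly the individuals valued 1 and 2 are affected
  ped <- new_pedigree("q", data.frame(
    id = as.character(1:10), fid = NA_character_, mid = NA_character_,
    sex = rep(c(1L, 2L), 5L), aff = 0L))
  peds <- new_ped_set(list(ped))
  tr <- structure(matrix(as.numeric(1:10), 10L, 1L,
                         dimnames = list(pheno_key("q", ped$id), "rep001")),
                  class = c("trait_replicates", "matrix", "array"))
  cfg <- sim_config(founder_quantile = 0.20, seed = 1L)
  aff <- suppressMessages(dichotomize_by_founder_quantile(tr, peds, cfg))
  expect_equal(attr(aff, "cutoff"), 2.8)
  expect_equal(unname(aff[, 1L]), c(2L, 2L, rep(1L, 8L)))
})

test_that("identical trait values yield zero affected (strict inequality)", {
  ped <- new_pedigree("q", data.frame(
    id = as.character(1:5), fid = NA_character_, mid = NA_character_,
    sex = c(1L, 2L, 1L, 2L, 1L), aff = 0L))
  tr <- structure(matrix(7, 5L, 2L,
                         dimnames = list(pheno_key("q", ped$id), NULL)),
                  class = c("trait_replicates", "matrix", "array"))
  aff <- suppressMessages(dichotomize_by_founder_quantile(
    tr, new_ped_set(list(ped)), sim_config(seed = 1L)))
  expect_true(all(aff == 1L))
})

test_that("missing trait values become unknown affection", {
  ped <- new_pedigree("q", data.frame(
    id = as.character(1:4), fid = NA_character_, mid = NA_character_,
    sex = c(1L, 2L, 1L, 2L), aff = 0L))
  tr <- structure(matrix(c(1, 2, NA, 4), 4L, 1L,
                         dimnames = list(pheno_key("q", ped$id), NULL)),
                  class = c("trait_replicates", "matrix", "array"))
  aff <- suppressMessages(dichotomize_by_founder_quantile(
    tr, new_ped_set(list(ped)), sim_config(founder_quantile = 0.5, seed = 1L)))
  expect_equal(unname(aff[, 1L]), c(2L, 1L, 0L, 1L))
})

test_that("pooled founder affected fraction matches the configured quantile", {
  cfg <- sim_config(n_pedigrees = 8L, pedigree_size_range = c(20L, 40L),
                    n_generations = 3L, founder_quantile = 0.20,
                    n_replicates = 50L, seed = 10L)
  peds <- generate_pedigree_set(cfg)
  tr <- simulate_polygenic_trait(peds, cfg)
  aff <- suppressMessages(dichotomize_by_founder_quantile(tr, peds, cfg))
  df <- ped_df(peds)
  fo <- rownames(aff) %in% pheno_key(df$family, df$id)[is.na(df$fid)]
  frac <- mean(aff[fo, ] == 2L)
  n <- sum(fo) * ncol(aff)
  expect_lt(abs(frac - 0.20), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("lowering the quantile weakly shrinks the affected set", {
  cfg <- sim_config(n_pedigrees = 3L, pedigree_size_range = c(10L, 25L),
                    n_generations = 3L, n_replicates = 5L, seed = 12L)
  peds <- generate_pedigree_set(cfg)
  tr <- simulate_polygenic_trait(peds, cfg)
  prev <- NULL
  for (q in c(0.5, 0.3, 0.2, 0.1, 0.0)) {
    cfg$founder_quantile <- q
    aff <- suppressMessages(dichotomize_by_founder_quantile(tr, peds, cfg))
    cur <- which(aff == 2L)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("random affection hits prevalence bounds and the binomial band", {
  cfg <- sim_config(n_pedigrees = 6L, pedigree_size_range = c(20L, 40L),
                    n_generations = 3L, prevalence = 0, n_replicates = 3L,
                    seed = 14L)
  peds <- generate_pedigree_set(cfg)
  expect_true(all(assign_random_affection(peds, cfg) == 1L))
  cfg$prevalence <- 1
  expect_true(all(assign_random_affection(peds, cfg) == 2L))
  cfg$prevalence <- 0.10
  cfg$n_replicates <- 50L
  aff <- assign_random_affection(peds, cfg)
  n <- length(aff)
  expect_gte(n, 50L * 120L)
  expect_lt(abs(mean(aff == 2L) - 0.10), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("traits are independent of marker genotypes across replicates", {
  cfg <- sim_config(n_pedigrees = 4L, pedigree_size_range = c(15L, 30L),
                    n_generations = 3L, n_markers = 40L,
                    ungenotyped_fraction = 0, n_replicates = 100L, seed = 15L)
  peds <- generate_pedigree_set(cfg)
  mk <- simulate_markers(cfg)
  mk$true_maf <- pmax(mk$true_maf, 0.2)  # keep markers polymorphic
  g <- gene_drop_genotypes(peds, mk, cfg)
  tr <- simulate_polygenic_trait(peds, cfg)
  resid <- age_adjusted(tr, peds)  # remove the shared age trend
  g <- g[rownames(tr), ]
  # per-replicate correlation between a marker dosage and the trait,
  # averaged over replicates, for a handful of markers
  for (j in c(1L, 10L, 25L)) {
    if (sd(g[, j]) == 0) next
    rs <- apply(resid, 2L, function(y) cor(g[, j], y))
    expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)))
  }
})

test_that("phenotype table round-trips values and affection codes", {
  cfg <- small_config()
  peds <- generate_pedigree_set(cfg)
  tr <- simulate_polygenic_trait(peds, cfg)
  aff <- suppressMessages(dichotomize_by_founder_quantile(tr, peds, cfg))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(f, peds, aff, tr)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(tr) * ncol(tr))
  k <- pheno_key(back$family, back$individual)
  expect_equal(back$value,
               tr[cbind(match(k, rownames(tr)), back$replicate)])
  expect_equal(back$affection,
               unname(aff[cbind(match(k, rownames(aff)), back$replicate)]))
})
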