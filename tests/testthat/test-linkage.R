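test_that("a single untyped founder with unknown affection has likelihood 1", {
  ped <- new_pedigree("s", data.frame(id = "1", fid = NA_character_,
                                      mid = NA_character_, sex = 1L, aff = 0L))
  m <- trait_model()
  expect_equal(pedigree_log_likelihood(ped, c(), 0.3, m, 0), 0)
  expect_equal(brute_force_log_likelihood(ped, c(), 0.3, m, 0), 0)
})

test_that("peeling equals enumeration on hand-built pedigrees at several theta", {
  m <- trait_model()
  trio <- make_trio()
  tg <- make_three_gen()
  d_trio <- c("1" = 1L, "2" = 0L, "3" = 1L)
  d_tg <- c("1" = 1L, "2" = 0L, "4" = 1L, "6" = 0L, "7" = 1L, "8" = 0L)
  for (th in c(0, 0.1, 0.25, 0.5)) {
    for (maf in c(0.01, 0.2)) {
      a <- pedigree_log_likelihood(trio, d_trio, maf, m, th)
      b <- brute_force_log_likelihood(trio, d_trio, maf, m, th)
      expect_lt(abs(a - b) / abs(b), 1e-12)
      a <- pedigree_log_likelihood(tg, d_tg, maf, m, th)
      b <- brute_force_log_likelihood(tg, d_tg, maf, m, th,
                                      max_combos = 2^24)
      expect_lt(abs(a - b) / abs(b), 1e-12)
    }
  }
})

test_that("peeling equals enumeration on fuzzed pedigrees", {
  set.seed(2024)
  m_list <- list(trait_model(), full_penetrance_model(),
                 trait_model(0.1, c(0.02, 0.3, 0.9)))
  for (k in 1:120) {
    ped <- random_pedigree(sample(3:7, 1L))
    maf <- runif(1, 0.05, 0.45)
    d <- random_dosages(ped, maf)
    th <- sample(c(0, 0.01, 0.1, 0.3, 0.5), 1L)
    m <- m_list[[sample.int(3L, 1L)]]
    a <- pedigree_log_likelihood(ped, d, maf, m, th)
    b <- brute_force_log_likelihood(ped, d, maf, m, th)
    if (is.finite(b)) {
      expect_lt(abs(a - b) / abs(b), 1e-10)
    } else {
      expect_identical(a, -Inf)
    }
  }
})

test_that("at theta = 0.5 the joint likelihood factorizes into trait x marker", {
  m <- trait_model()
  ped <- make_three_gen()
  d <- c("1" = 1L, "2" = 0L, "4" = 1L, "6" = 0L, "7" = 1L, "8" = 0L)
  joint <- pedigree_log_likelihood(ped, d, 0.2, m, 0.5)
  trait_only <- pedigree_log_likelihood(ped, c(), 0.2, m, 0.5)
  marker_only <- pedigree_log_likelihood(ped, d, 0.2, m, 0.5,
                                         affection = rep(0L, nrow(ped)))
  expect_equal(joint, trait_only + marker_only, tolerance = 1e-9)
})

test_that("likelihood is invariant under member reordering", {
  m <- trait_model()
  ped <- make_three_gen()
  d <- c("1" = 1L, "2" = 0L, "4" = 1L, "6" = 0L, "7" = 1L, "8" = 0L)
  perm <- c(3L, 8L, 1L, 5L, 2L, 7L, 4L, 6L)
  ped2 <- new_pedigree("tg", as.data.frame(ped)[perm, ])
  expect_equal(pedigree_log_likelihood(ped2, d, 0.2, m, 0.1),
               pedigree_log_likelihood(ped, d, 0.2, m, 0.1),
               tolerance = 1e-12)
  expect_equal(brute_force_log_likelihood(ped2, d, 0.2, m, 0.1,
                                          max_combos = 2^24),
               brute_force_log_likelihood(ped, d, 0.2, m, 0.1,
                                          max_combos = 2^24),
               tolerance = 1e-12)
})

test_that("likelihood computation refuses looped pedigrees and bad theta", {
  m <- trait_model()
  expect_error(pedigree_log_likelihood(make_two_brothers_loop(), c(), 0.2, m, 0),
               "loops")
  expect_error(pedigree_log_likelihood(make_trio(), c(), 0.2, m, 0.7),
               "theta")
})

# scan over a tiny simulated panel, reused below
make_scan_fixture <- function(seed = 51L, n_markers = 30L) {
  cfg <- sim_config(n_pedigrees = 3L, pedigree_size_range = c(10L, 20L),
                    n_generations = 3L, n_markers = n_markers,
                    ungenotyped_fraction = 0.15, n_replicates = 2L,
                    seed = seed)
  peds <- generate_pedigree_set(cfg)
  mk <- simulate_markers(cfg)
  g <- mask_ungenotyped(gene_drop_genotypes(peds, mk, cfg), peds, cfg)
  mk <- suppressMessages(estimate_founder_maf(g$geno, g$peds))
  aff <- assign_random_affection(g$peds, cfg)
  list(peds = g$peds, geno = g$geno, mk = mk, aff = aff, cfg = cfg)
}

test_that("at theta = 0.5 every LOD is exactly zero", {
  fx <- make_scan_fixture()
  sc <- twopoint_lod(fx$peds, fx$geno, fx$mk, trait_model(), theta = 0.5,
                     affection = fx$aff[, 1L])
  expect_true(all(sc$table$total_lod == 0))
  expect_true(all(sc$family_lods == 0))
})

test_that("total LOD is the sum of family LODs and matches direct computation", {
  fx <- make_scan_fixture()
  m <- trait_model()
  sc <- twopoint_lod(fx$peds, fx$geno, fx$mk, m, theta = 0,
                     affection = fx$aff[, 1L])
  expect_equal(sc$table$total_lod, unname(colSums(sc$family_lods)),
               tolerance = 1e-9)
  # spot-check one family x marker against single-marker likelihoods
  p <- fx$peds[[2L]]
  key <- pheno_key(family_id(p), p$id)
  aff <- as.integer(fx$aff[key, 1L])
  for (j in c(1L, 17L)) {
    d <- analysis_dosages(fx$geno, fx$mk)[key, j]
    names(d) <- p$id
    maf <- fx$mk$estimated_maf[j]
    lod <- (pedigree_log_likelihood(p, d, maf, m, 0, affection = aff) -
              pedigree_log_likelihood(p, d, maf, m, 0.5, affection = aff)) /
      log(10)
    expect_equal(unname(sc$family_lods[2L, j]), lod, tolerance = 1e-9)
  }
})

test_that("phase-known fully informative meioses give LOD(0) = n log10 2", {
  m <- full_penetrance_model()
  for (n_kids in c(2L, 4L)) {
    fx <- make_phase_known_family(n_kids)
    lod0 <- (pedigree_log_likelihood(fx$ped, fx$dosages, 0.2, m, 0) -
               pedigree_log_likelihood(fx$ped, fx$dosages, 0.2, m, 0.5)) / log(10)
    expect_equal(lod0, n_kids * log10(2), tolerance = 1e-10)
    # cross-checked against the enumeration oracle
    b0 <- brute_force_log_likelihood(fx$ped, fx$dosages, 0.2, m, 0)
    b5 <- brute_force_log_likelihood(fx$ped, fx$dosages, 0.2, m, 0.5)
    expect_equal((b0 - b5) / log(10), n_kids * log10(2), tolerance = 1e-10)
  }
})

test_that("an obligate recombinant under full penetrance gives -Inf at theta 0", {
  m <- full_penetrance_model()
  fx <- make_phase_known_family(4L, recombinant = 1L)
  expect_identical(pedigree_log_likelihood(fx$ped, fx$dosages, 0.2, m, 0), -Inf)
  expect_identical(brute_force_log_likelihood(fx$ped, fx$dosages, 0.2, m, 0),
                   -Inf)
  # but finite away from theta = 0
  expect_true(is.finite(pedigree_log_likelihood(fx$ped, fx$dosages, 0.2, m,
                                                0.1)))
})

test_that("theta maximization: flat profiles tie-break to 0, max >= LOD(0)", {
  fx <- make_scan_fixture()
  mx <- maximize_theta(fx$peds, fx$geno, fx$mk, trait_model(),
                       affection = fx$aff[, 1L])
  expect_true(all(mx$table$max_lod >= mx$table$total_lod - 1e-9))
  # the grid contains 0.5 where the LOD is 0 by definition
  expect_true(all(mx$table$max_lod >= -1e-9))
  expect_error(maximize_theta(fx$peds, fx$geno, fx$mk, grid = c(0.1, 0.5)),
               "contain 0")
  # a marker observed homozygous in every (fully genotyped) member is
  # uninformative: flat profile, tie-break to theta_hat = 0
  ped <- make_trio()
  mk <- data.frame(marker_id = "m1", chrom = "1", pos_bp = 1, pos_cM = 0.001,
                   minor = "A", major = "G", true_maf = 0,
                   estimated_maf = 1e-4, swapped = FALSE, minor_count = 0L,
                   n_founders_genotyped = 2L, stringsAsFactors = FALSE)
  g <- structure(matrix(0L, 3L, 1L,
                        dimnames = list(pheno_key("trio", ped$id), "m1")),
                 markers = mk, class = c("geno_matrix", "matrix", "array"))
  flat <- maximize_theta(new_ped_set(list(ped)), g, mk, trait_model())
  expect_equal(flat$table$theta_hat, 0)
  expect_equal(flat$table$max_lod, 0, tolerance = 1e-9)
})

test_that("a coarse theta grid reproduces the dense-grid maximum within 0.01 LOD", {
  fx <- make_scan_fixture(seed = 77L, n_markers = 20L)
  m <- trait_model()
  coarse <- maximize_theta(fx$peds, fx$geno, fx$mk, m,
                           grid = c(0, 0.001, seq(0.01, 0.5, 0.01)),
                           affection = fx$aff[, 2L])
  dense <- maximize_theta(fx$peds, fx$geno, fx$mk, m,
                          grid = seq(0, 0.5, 0.001),
                          affection = fx$aff[, 2L])
  expect_true(all(abs(coarse$table$max_lod - dense$table$max_lod) < 0.01))
})

test_that("masking a genotype does not increase |LOD| on average", {
  set.seed(99)
  m <- trait_model()
  diffs <- replicate(150, {
    ped <- random_pedigree(sample(5:7, 1L))
    ped$aff <- sample(1:2, nrow(ped), replace = TRUE, prob = c(0.6, 0.4))
    maf <- runif(1, 0.1, 0.4)
    d <- random_dosages(ped, maf, mask_prob = 0)
    lod_full <- (pedigree_log_likelihood(ped, d, maf, m, 0) -
                   pedigree_log_likelihood(ped, d, maf, m, 0.5)) / log(10)
    d[sample.int(length(d), 1L)] <- NA_integer_
    lod_masked <- (pedigree_log_likelihood(ped, d, maf, m, 0) -
                     pedigree_log_likelihood(ped, d, maf, m, 0.5)) / log(10)
    abs(lod_masked) - abs(lod_full)
  })
  expect_lt(mean(diffs), 2 * sd(diffs) / sqrt(length(diffs)))
})

test_that("a 90-member pedigree at MAF 1e-4 stays finite", {
  cfg <- sim_config(n_pedigrees = 1L, pedigree_size_range = c(90L, 90L),
                    n_generations = 5L, n_markers = 3L,
                    ungenotyped_fraction = 0, seed = 41L)
  peds <- generate_pedigree_set(cfg)
  mk <- simulate_markers(cfg)
  mk$true_maf <- c(0, 0.3, 0.001)
  g <- gene_drop_genotypes(peds, mk, cfg)
  mk <- suppressMessages(estimate_founder_maf(g, peds))
  expect_identical(mk$estimated_maf[1L], 1e-4)
  p <- peds[[1L]]
  p$aff <- rep(c(1L, 2L), length.out = nrow(p))
  key <- pheno_key(family_id(p), p$id)
  for (j in 1:3) {
    d <- g[key, j]
    names(d) <- p$id
    ll <- pedigree_log_likelihood(p, d, mk$estimated_maf[j], trait_model(), 0)
    expect_true(is.finite(ll))
    expect_lte(ll, 0)
  }
})

test_that("Mendelian-inconsistent marker data raise a family-naming error", {
  ped <- make_trio()
  peds <- new_ped_set(list(ped))
  mk <- data.frame(marker_id = "m1", chrom = "1", pos_bp = 1, pos_cM = 0.001,
                   minor = "A", major = "G", true_maf = 0.2,
                   estimated_maf = 0.2, swapped = FALSE,
                   stringsAsFactors = FALSE)
  g <- structure(matrix(c(0L, 0L, 2L), ncol = 1L,
                        dimnames = list(pheno_key("trio", ped$id), "m1")),
                 markers = mk, class = c("geno_matrix", "matrix", "array"))
  expect_error(twopoint_lod(peds, g, mk, trait_model()),
               "Mendelian-inconsistent.*trio")
})

test_that("likelihoods are probabilities: log never positive", {
  set.seed(7)
  m <- trait_model()
  for (k in 1:25) {
    ped <- random_pedigree(sample(3:7, 1L))
    maf <- runif(1, 0.05, 0.45)
    d <- random_dosages(ped, maf)
    ll <- pedigree_log_likelihood(ped, d, maf, m, runif(1, 0, 0.5))
    expect_lte(ll, 1e-12)
  }
})
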