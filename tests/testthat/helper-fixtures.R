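# Pedigree fixtures and fuzzers shared across the suite.

make_trio <- function(aff = c(2L, 1L, 2L)) {
  new_pedigree("trio", data.frame(
    id = c("1", "2", "3"), fid = c(NA, NA, "1"), mid = c(NA, NA, "2"),
    sex = c(1L, 2L, 1L), aff = aff))
}

# three generations, 8 members, no loops; founders 1,2,3,6
make_three_gen <- function() {
  new_pedigree("tg", data.frame(
    id = as.character(1:8),
    fid = c(NA, NA, NA, "1", "1", NA, "4", "4"),
    mid = c(NA, NA, NA, "2", "2", NA, "6", "6"),
    sex = c(1L, 2L, 2L, 1L, 2L, 2L, 1L, 2L),
    aff = c(2L, 1L, 1L, 2L, 0L, 1L, 2L, 1L)))
}

# one woman (5) with children from two brothers (3, 4): a marriage loop
make_two_brothers_loop <- function() {
  new_pedigree("tb", data.frame(
    id = as.character(1:7),
    fid = c(NA, NA, "1", "1", NA, "3", "4"),
    mid = c(NA, NA, "2", "2", NA, "5", "5"),
    sex = c(1L, 2L, 1L, 1L, 2L, 1L, 2L),
    aff = c(1L, 1L, 1L, 1L, 1L, 2L, 2L)))
}

# first-cousin mating with offspring: an inbreeding loop
make_first_cousin_loop <- function() {
  new_pedigree("fc", data.frame(
    id = as.character(1:9),
    fid = c(NA, NA, "1", "1", NA, NA, "3", "4", "7"),
    mid = c(NA, NA, "2", "2", NA, NA, "5", "6", "8"),
    sex = c(1L, 2L, 1L, 1L, 2L, 2L, 1L, 2L, 1L),
    aff = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L)))
}

# 8-member first-cousin pedigree without the inbred child (loop-free),
# for kinship checks: 7 and 8 are first cousins
make_first_cousins <- function() {
  new_pedigree("fc8", data.frame(
    id = as.character(1:8),
    fid = c(NA, NA, "1", "1", NA, NA, "3", "4"),
    mid = c(NA, NA, "2", "2", NA, NA, "5", "6"),
    sex = c(1L, 2L, 1L, 1L, 2L, 2L, 1L, 2L),
    aff = 1L))
}

# Random loop-free pedigree of exactly n members: grow by giving a
# random existing spouse-less individual a new founder spouse and a
# child. Every spouse is a fresh founder, so no marriage or
# consanguinity loop can arise.
random_pedigree <- function(n, fam = "rnd") {
  stopifnot(n >= 3L)
  df <- data.frame(id = c("1", "2"), fid = NA_character_, mid = NA_character_,
                   sex = c(1L, 2L), aff = 1L, stringsAsFactors = FALSE)
  spouse_of <- c("2", "1")
  nid <- 2L
  while (nrow(df) < n) {
    # members that can still have children without a new spouse
    coupled <- which(spouse_of != "")
    if (n - nrow(df) >= 2L && runif(1) < 0.4) {
      # marry a spouse-less member to a new founder, then give a child
      single <- which(spouse_of == "")
      if (length(single) > 0L) {
        i <- single[sample.int(length(single), 1L)]
        nid <- nid + 1L
        sp <- as.character(nid)
        df <- rbind(df, data.frame(id = sp, fid = NA_character_,
                                   mid = NA_character_, sex = 3L - df$sex[i],
                                   aff = 1L))
        spouse_of[i] <- sp
        spouse_of <- c(spouse_of, df$id[i])
        next
      }
    }
    i <- coupled[sample.int(length(coupled), 1L)]
    pa <- if (df$sex[i] == 1L) df$id[i] else spouse_of[i]
    ma <- if (df$sex[i] == 1L) spouse_of[i] else df$id[i]
    nid <- nid + 1L
    df <- rbind(df, data.frame(id = as.character(nid), fid = pa, mid = ma,
                               sex = sample(1:2, 1L), aff = 1L))
    spouse_of <- c(spouse_of, "")
  }
  df$aff <- sample(0:2, nrow(df), replace = TRUE, prob = c(0.15, 0.5, 0.35))
  new_pedigree(fam, df)
}

# Mendelian-consistent single-marker dosages for a pedigree (a 1-marker
# gene drop), with optional masking, constrained so the brute-force
# enumeration stays below `max_combos` consistent joint states.
random_dosages <- function(ped, maf, mask_prob = 0.15, max_combos = 2^20) {
  n <- nrow(ped)
  fi <- match(ped$fid, ped$id)
  mi <- match(ped$mid, ped$id)
  ord <- linksim_topo(ped)
  for (try in 1:50) {
    hap <- matrix(0L, n, 2L)
    for (i in ord) {
      if (is.na(fi[i])) {
        hap[i, ] <- as.integer(runif(2) < maf)
      } else {
        hap[i, 1L] <- hap[fi[i], sample(1:2, 1L)]
        hap[i, 2L] <- hap[mi[i], sample(1:2, 1L)]
      }
    }
    d <- rowSums(hap)
    d[runif(n) < mask_prob] <- NA_integer_
    sizes <- ifelse(is.na(d), 16L, ifelse(d == 1L, 8L, 4L))
    if (prod(sizes) <= max_combos) {
      names(d) <- ped$id
      return(d)
    }
    mask_prob <- mask_prob / 2
  }
  stop("could not draw dosages under the enumeration cap")
}

linksim_topo <- function(ped) {
  ord <- integer(0)
  placed <- rep(FALSE, nrow(ped))
  fi <- match(ped$fid, ped$id)
  mi <- match(ped$mid, ped$id)
  while (length(ord) < nrow(ped)) {
    ready <- which(!placed & (is.na(fi) | placed[replace(fi, is.na(fi), 1L)]) &
                     (is.na(mi) | placed[replace(mi, is.na(mi), 1L)]))
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  ord
}

full_penetrance_model <- function() trait_model(0.01, c(0, 1, 1))

# phase-known fully informative nuclear family: grandparents force the
# father's phase; his n affected children are all nonrecombinant
make_phase_known_family <- function(n_children = 4L, recombinant = 0L) {
  kids <- data.frame(
    id = as.character(4L + seq_len(n_children)),
    fid = "3", mid = "4", sex = 1L, aff = 2L)
  ped <- new_pedigree("pk", rbind(
    data.frame(id = c("1", "2", "3", "4"),
               fid = c(NA, NA, "1", NA), mid = c(NA, NA, "2", NA),
               sex = c(1L, 2L, 1L, 2L), aff = c(2L, 1L, 2L, 1L)),
    kids))
  d <- c("1" = 2L, "2" = 0L, "3" = 1L, "4" = 0L,
         stats::setNames(rep(1L, n_children), kids$id))
  if (recombinant > 0L)
    d[4L + seq_len(recombinant)] <- 0L  # affected child without the minor allele
  list(ped = ped, dosages = d)
}

# tiny study config used by several suites
small_config <- function(...) {
  sim_config(n_pedigrees = 4L, pedigree_size_range = c(10L, 25L),
             n_generations = 3L, n_markers = 50L,
             ungenotyped_fraction = 0.2, n_replicates = 5L, seed = 424242L, ...)
}
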