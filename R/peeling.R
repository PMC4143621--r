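# Elston-Stewart peeling over joint trait-marker diplotypes.
#
# State space: 4 two-locus haplotypes (trait allele d/D x marker allele
# major/minor), phase explicit, so an individual has 16 ordered
# diplotypes (paternal haplotype, maternal haplotype). Founder priors
# are products of haplotype frequencies under linkage equilibrium;
# transmission passes each parental haplotype intact with probability
# (1 - theta)/2 and each recombinant with probability theta/2. The
# pedigree likelihood is computed by sum-product message passing on the
# (loop-free) marriage graph: one factor per mating connecting father,
# mother and their children. Messages are 16 x M matrices, columns are
# markers, so a whole marker panel is peeled in one vectorized pass;
# per-message rescaling keeps everything finite at any pedigree size.

# haplotype index h in 1:4 -> trait allele a (1 = D), marker allele b
# (1 = minor); state s in 1:16 -> (paternal h, maternal h)
.hap_a <- (0:3) %/% 2L
.hap_b <- (0:3) %% 2L
.st_hp <- (0:15) %/% 4L + 1L
.st_hm <- (0:15) %% 4L + 1L
.st_nD <- .hap_a[.st_hp] + .hap_a[.st_hm]
.st_nminor <- .hap_b[.st_hp] + .hap_b[.st_hm]

# 4 x 16 gamete matrix: P(transmitted haplotype | parent state)
gamete_matrix <- function(theta) {
  G <- matrix(0, 4L, 16L)
  for (s in 1:16) {
    h1 <- .st_hp[s]
    h2 <- .st_hm[s]
    r1 <- 2L * .hap_a[h1] + .hap_b[h2] + 1L
    r2 <- 2L * .hap_a[h2] + .hap_b[h1] + 1L
    G[h1, s] <- G[h1, s] + (1 - theta) / 2
    G[h2, s] <- G[h2, s] + (1 - theta) / 2
    G[r1, s] <- G[r1, s] + theta / 2
    G[r2, s] <- G[r2, s] + theta / 2
  }
  G
}

# 256 x 16 transmission: rows (father state, mother state) father-major,
# columns child state
transmission_matrix <- function(theta) {
  G <- gamete_matrix(theta)
  sf <- rep(1:16, each = 16L)
  sm <- rep(1:16, times = 16L)
  TT <- matrix(0, 256L, 16L)
  for (sc in 1:16)
    TT[, sc] <- G[.st_hp[sc], sf] * G[.st_hm[sc], sm]
  TT
}

# Factor-tree peeling plan for one family; errors on loops.
peel_plan <- function(ped) {
  n <- nrow(ped)
  nonf <- which(!is_founder(ped))
  fkey <- paste(ped$fid[nonf], ped$mid[nonf], sep = "\r")
  uk <- unique(fkey)
  K <- length(uk)
  fac <- vector("list", K)
  for (u in seq_len(K)) {
    kids <- nonf[fkey == uk[u]]
    pr <- strsplit(uk[u], "\r", fixed = TRUE)[[1L]]
    fac[[u]] <- list(f = match(pr[1L], ped$id), m = match(pr[2L], ped$id),
                     children = kids)
  }
  adj_var <- rep(list(integer(0)), n)
  for (u in seq_len(K)) {
    for (v in c(fac[[u]]$f, fac[[u]]$m, fac[[u]]$children))
      adj_var[[v]] <- c(adj_var[[v]], u)
  }
  # BFS over the bipartite graph; nodes 1..n are individuals, n+1..n+K
  # are mating factors
  total <- n + K
  parent <- rep(NA_integer_, total)
  visited <- rep(FALSE, total)
  order <- integer(0)
  roots <- integer(0)
  n_edges_seen <- 0L
  for (start in seq_len(n)) {
    if (visited[start]) next
    roots <- c(roots, start)
    visited[start] <- TRUE
    queue <- start
    while (length(queue) > 0L) {
      x <- queue[1L]
      queue <- queue[-1L]
      order <- c(order, x)
      nb <- if (x <= n) n + adj_var[[x]]
            else with(fac[[x - n]], c(f, m, children))
      for (y in nb) {
        n_edges_seen <- n_edges_seen + 1L
        if (!visited[y]) {
          visited[y] <- TRUE
          parent[y] <- x
          queue <- c(queue, y)
        }
      }
    }
  }
  E <- sum(vapply(fac, function(u) 2L + length(u$children), integer(1)))
  if (E != total - length(roots))
    stop("pedigree ", family_id(ped),
         " contains loops; break them before likelihood computation")
  list(n = n, fac = fac, adj_var = adj_var, parent = parent,
       order = order, roots = roots,
       founder = is_founder(ped))
}

# Unary potentials: list of 16 x M matrices (penetrance x marker
# indicator x founder prior). aff: integer 0/1/2 per member; dosage:
# n x M integer (NA = missing); maf: length-M frequency of the minor
# allele at each marker.
peel_unaries <- function(plan, aff, dosage, maf, model) {
  M <- length(maf)
  f <- model$penetrances
  pD <- model$disease_allele_freq
  trait_prior <- pD^.st_nD * (1 - pD)^(2 - .st_nD)
  marker_prior <- t(vapply(1:16, function(s)
    maf^.st_nminor[s] * (1 - maf)^(2 - .st_nminor[s]), numeric(M)))
  if (M == 1L) marker_prior <- matrix(marker_prior, 16L, 1L)
  lapply(seq_len(plan$n), function(i) {
    pen <- switch(aff[i] + 1L, rep(1, 16L), 1 - f[.st_nD + 1L], f[.st_nD + 1L])
    ind <- outer(.st_nminor, dosage[i, ], "==")
    ind[is.na(ind)] <- TRUE
    U <- pen * ind
    if (plan$founder[i]) U <- U * (trait_prior * marker_prior)
    U
  })
}

# log10 likelihood per marker for one family. Returns -Inf where the
# likelihood is exactly zero.
peel_loglik10 <- function(plan, aff, dosage, maf, model, theta) {
  stopifnot(theta >= 0, theta <= 0.5)
  M <- length(maf)
  U <- peel_unaries(plan, aff, dosage, maf, model)
  TT <- transmission_matrix(theta)
  sf_of_r <- rep(1:16, each = 16L)
  sm_of_r <- rep(1:16, times = 16L)
  n <- plan$n
  msg <- vector("list", n + length(plan$fac))
  log10scale <- numeric(M)
  rescale <- function(m) {
    sc <- colSums(m)
    ok <- sc > 0
    log10scale <<- log10scale + ifelse(ok, log10(ifelse(ok, sc, 1)), 0)
    m / rep(ifelse(ok, sc, 1), each = 16L)
  }
  for (x in rev(plan$order)) {
    p <- plan$parent[x]
    if (is.na(p)) next
    if (x <= n) {
      # individual -> mating factor: unary times messages from the
      # individual's other adjacent factors (its tree children)
      m <- U[[x]]
      for (u in plan$adj_var[[x]]) {
        if (n + u != p) m <- m * msg[[n + u]]
      }
      msg[[x]] <- rescale(m)
    } else {
      u <- plan$fac[[x - n]]
      mf <- msg[[u$f]]
      mm <- msg[[u$m]]
      # inner sums over each non-target child
      prodS <- NULL
      for (ch in u$children) {
        if (ch == p) next
        S <- TT %*% msg[[ch]]
        prodS <- if (is.null(prodS)) S else prodS * S
      }
      if (p %in% u$children) {
        W <- mf[sf_of_r, , drop = FALSE] * mm[sm_of_r, , drop = FALSE]
        if (!is.null(prodS)) W <- W * prodS
        m <- crossprod(TT, W)
      } else if (p == u$f) {
        P <- mm[sm_of_r, , drop = FALSE]
        if (!is.null(prodS)) P <- P * prodS
        m <- rowsum(P, sf_of_r)
      } else {
        P <- mf[sf_of_r, , drop = FALSE]
        if (!is.null(prodS)) P <- P * prodS
        m <- rowsum(P, sm_of_r)
      }
      msg[[x]] <- rescale(m)
    }
  }
  total <- numeric(M)
  for (r in plan$roots) {
    b <- U[[r]]
    for (u in plan$adj_var[[r]]) b <- b * msg[[n + u]]
    L <- colSums(b)
    total <- total + ifelse(L > 0, log10(ifelse(L > 0, L, 1)), -Inf)
  }
  total + log10scale
}
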