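#' Pedigree objects
#'
#' A `pedigree` is a data frame with one row per individual and columns
#' `id`, `fid`, `mid` (father/mother id, `NA` for founders), `sex`
#' (1 = male, 2 = female), `aff` (affection status: 0 = unknown,
#' 1 = unaffected, 2 = affected, the LINKAGE convention), `age` (years,
#' `NA` if unknown) and `genotyped` (logical). The family identifier is
#' stored in the `family_id` attribute. A `ped_set` is a named list of
#' pedigrees.
#'
#' Invariants enforced by [new_pedigree()]: member ids are unique, both
#' parents are either present or absent (both absent defines a founder),
#' named parents are members with the correct sex, and the parent
#' relation is acyclic.
#'
#' @param family_id single string identifying the family.
#' @param df data frame with columns `id`, `fid`, `mid`, `sex`, `aff`,
#'   and optionally `age` and `genotyped`.
#' @return An object of class `pedigree`.
#' @export
new_pedigree <- function(family_id, df) {
  stopifnot(is.character(family_id), length(family_id) == 1L)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("id", "fid", "mid", "sex", "aff")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("pedigree is missing columns: ", paste(missing_cols, collapse = ", "))
  df$id <- as.character(df$id)
  df$fid <- as.character(df$fid)
  df$mid <- as.character(df$mid)
  df$sex <- as.integer(df$sex)
  df$aff <- as.integer(df$aff)
  if (is.null(df$age)) df$age <- NA_real_ else df$age <- as.numeric(df$age)
  if (is.null(df$genotyped)) df$genotyped <- TRUE
  df$genotyped <- as.logical(df$genotyped)
  rownames(df) <- NULL
  structure(df, family_id = family_id,
            class = c("pedigree", "data.frame"))
}

#' @rdname new_pedigree
#' @param x object to test or print.
#' @export
is.pedigree <- function(x) inherits(x, "pedigree")

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree %s: %d members (%d founders, %d affected)\n",
              family_id(x), nrow(x), sum(is_founder(x)), sum(x$aff == 2L)))
  print.data.frame(x, ...)
  invisible(x)
}

#' @rdname new_pedigree
#' @export
family_id <- function(x) attr(x, "family_id")

#' Founder identification
#'
#' Founders are members with no parents in the pedigree; all other
#' members have both parents present.
#'
#' @param ped a `pedigree`.
#' @return `is_founder()` a logical vector along members; `founders()`
#'   the founder ids.
#' @export
is_founder <- function(ped) is.na(ped$fid) & is.na(ped$mid)

#' @rdname is_founder
#' @export
founders <- function(ped) ped$id[is_founder(ped)]

# Validate structural invariants; errors mention `where` (e.g. file lines).
validate_pedigree <- function(ped, where = NULL) {
  loc <- function(i) {
    if (is.null(where)) sprintf("family %s, individual %s", family_id(ped), ped$id[i])
    else sprintf("line %d (family %s, individual %s)", where[i], family_id(ped), ped$id[i])
  }
  if (anyDuplicated(ped$id)) {
    i <- which(duplicated(ped$id))[1L]
    stop("duplicate individual id at ", loc(i), call. = FALSE)
  }
  half <- xor(is.na(ped$fid), is.na(ped$mid))
  if (any(half))
    stop("exactly one parent named at ", loc(which(half)[1L]),
         "; parents must be both present or both absent", call. = FALSE)
  if (!all(ped$sex %in% c(1L, 2L))) {
    i <- which(!(ped$sex %in% c(1L, 2L)))[1L]
    stop("invalid sex code at ", loc(i), call. = FALSE)
  }
  idx <- match(ped$fid, ped$id)
  bad <- !is.na(ped$fid) & is.na(idx)
  if (any(bad))
    stop("father id not found at ", loc(which(bad)[1L]), call. = FALSE)
  bad <- !is.na(idx) & ped$sex[idx] != 1L
  if (any(bad))
    stop("named father is not male at ", loc(which(bad)[1L]), call. = FALSE)
  idx <- match(ped$mid, ped$id)
  bad <- !is.na(ped$mid) & is.na(idx)
  if (any(bad))
    stop("mother id not found at ", loc(which(bad)[1L]), call. = FALSE)
  bad <- !is.na(idx) & ped$sex[idx] != 2L
  if (any(bad))
    stop("named mother is not female at ", loc(which(bad)[1L]), call. = FALSE)
  if (is.null(topological_order(ped))) {
    stop("cyclic parentage in family ", family_id(ped),
         if (!is.null(where)) sprintf(" (records around line %d)", where[1L]),
         call. = FALSE)
  }
  invisible(ped)
}

# Members ordered so that parents precede children; NULL if the parent
# relation is cyclic (an individual its own ancestor).
topological_order <- function(ped) {
  n <- nrow(ped)
  fi <- match(ped$fid, ped$id)
  mi <- match(ped$mid, ped$id)
  placed <- rep(FALSE, n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(fi) | placed[pmax(fi, 1L)] & !is.na(fi)) &
      (is.na(mi) | placed[pmax(mi, 1L)] & !is.na(mi))
    ready[is.na(ready)] <- FALSE
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (all(placed)) ord else NULL
}

#' Pedigree sets
#'
#' @param peds list of `pedigree` objects.
#' @return A `ped_set`, a named list of pedigrees.
#' @export
new_ped_set <- function(peds) {
  stopifnot(all(vapply(peds, is.pedigree, logical(1))))
  names(peds) <- vapply(peds, family_id, character(1))
  if (anyDuplicated(names(peds)))
    stop("duplicate family ids in pedigree set")
  structure(peds, class = "ped_set")
}

#' @export
print.ped_set <- function(x, ...) {
  sizes <- vapply(x, nrow, integer(1))
  cat(sprintf("Pedigree set: %d families, %d individuals\n",
              length(x), sum(sizes)))
  for (p in x)
    cat(sprintf("  %s: %d members, %d founders\n", family_id(p), nrow(p),
                sum(is_founder(p))))
  invisible(x)
}

#' @export
`[.ped_set` <- function(x, i) new_ped_set(unclass(x)[i])

# All members of a set as one data frame with a leading `family` column.
ped_df <- function(peds) {
  do.call(rbind, lapply(unname(peds), function(p)
    cbind(family = family_id(p), as.data.frame(p), stringsAsFactors = FALSE)))
}

#' Read pedigree files
#'
#' Reads whitespace-delimited pedigree files in the pre-makeped LINKAGE
#' dialect (columns family, individual, father, mother, sex, affection)
#' or the PLINK `.fam`/`.ped` leading-column dialect (same six columns,
#' with `-9` or `0` in the phenotype column meaning unknown). Genotype
#' columns after the sixth are ignored here; see [read_genotypes_ped()].
#'
#' @param path file path.
#' @param dialect `"linkage"` or `"plink"`.
#' @param missing_parent token denoting a missing parent (default `"0"`).
#' @return A `ped_set`.
#' @export
read_pedigrees <- function(path, dialect = c("linkage", "plink"),
                           missing_parent = "0") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) stop("no pedigree records in ", path)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop(sprintf("malformed record at line %d: expected >= 6 columns, got %d",
                 keep[which(nf < 6L)[1L]], nf[which(nf < 6L)[1L]]), call. = FALSE)
  rec <- data.frame(
    family = vapply(fields, `[`, "", 1L),
    id     = vapply(fields, `[`, "", 2L),
    fid    = vapply(fields, `[`, "", 3L),
    mid    = vapply(fields, `[`, "", 4L),
    sex    = vapply(fields, `[`, "", 5L),
    aff    = vapply(fields, `[`, "", 6L),
    line   = keep, stringsAsFactors = FALSE)
  rec$fid[rec$fid == missing_parent] <- NA_character_
  rec$mid[rec$mid == missing_parent] <- NA_character_
  sex <- suppressWarnings(as.integer(rec$sex))
  if (anyNA(sex))
    stop(sprintf("malformed sex code at line %d", rec$line[which(is.na(sex))[1L]]),
         call. = FALSE)
  aff_raw <- rec$aff
  aff <- suppressWarnings(as.integer(aff_raw))
  if (dialect == "plink") aff[!is.na(aff) & aff == -9L] <- 0L
  # unknown affection tokens map to unknown (0)
  aff[is.na(aff) | !(aff %in% c(0L, 1L, 2L))] <- 0L
  peds <- lapply(split(seq_len(nrow(rec)), rec$family), function(ix) {
    p <- new_pedigree(rec$family[ix[1L]], data.frame(
      id = rec$id[ix], fid = rec$fid[ix], mid = rec$mid[ix],
      sex = sex[ix], aff = aff[ix], stringsAsFactors = FALSE))
    validate_pedigree(p, where = rec$line[ix])
  })
  new_ped_set(peds[unique(rec$family)])
}

#' Write pedigree files
#'
#' Writes a `ped_set` in the pre-makeped LINKAGE dialect (six
#' whitespace-delimited columns). An alternative affection coding per
#' individual can be supplied, e.g. one replicate of a simulated trait.
#'
#' @param peds a `ped_set`.
#' @param path output file path.
#' @param affection optional named integer vector (names are
#'   `family:id` keys as produced by [pheno_key()]) overriding the
#'   stored affection column.
#' @export
write_pedigrees <- function(peds, path, affection = NULL) {
  df <- ped_df(peds)
  aff <- df$aff
  if (!is.null(affection)) {
    k <- pheno_key(df$family, df$id)
    hit <- k %in% names(affection)
    aff[hit] <- affection[k[hit]]
  }
  out <- data.frame(df$family, df$id,
                    ifelse(is.na(df$fid), "0", df$fid),
                    ifelse(is.na(df$mid), "0", df$mid),
                    df$sex, aff)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' @rdname write_pedigrees
#' @param family,id character vectors.
#' @export
pheno_key <- function(family, id) paste(family, id, sep = ":")

# ---- marriage graph and loops -------------------------------------------

# Bipartite graph: individual nodes and one union node per mating pair,
# with spouse-union and union-child edges. Peeling is possible without
# loop handling iff this graph is acyclic.
marriage_graph <- function(ped) {
  nonf <- which(!is_founder(ped))
  if (length(nonf) == 0L) {
    return(igraph::make_empty_graph(directed = FALSE) +
             igraph::vertices(paste0("I:", ped$id)))
  }
  union_key <- paste(ped$fid[nonf], ped$mid[nonf], sep = "\r")
  uk <- unique(union_key)
  umap <- match(union_key, uk)
  unions <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
  edges <- rbind(
    cbind(paste0("I:", unions[, 1L]), paste0("U:", seq_along(uk))),
    cbind(paste0("I:", unions[, 2L]), paste0("U:", seq_along(uk))),
    cbind(paste0("U:", umap), paste0("I:", ped$id[nonf])))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  iso <- setdiff(paste0("I:", ped$id), igraph::V(g)$name)
  if (length(iso) > 0L) g <- g + igraph::vertices(iso)
  igraph::set_graph_attr(g, "unions", unions)
}

#' Detect pedigree loops
#'
#' Finds every independent cycle of the marriage-node graph (individuals
#' plus one union node per mating, with spouse-union and union-child
#' edges). A pedigree with no such cycle can be peeled directly. Loops
#' are classified as `inbreeding` when some union on the cycle joins two
#' spouses sharing a pedigree ancestor (consanguinity), else `marriage`
#' (e.g. one person with children from two members of connected
#' sibships).
#'
#' @param ped a `pedigree`.
#' @return A list of loops, each a list with elements `kind` and
#'   `member_ids` (individual ids along the cycle); empty if the
#'   pedigree is loop-free.
#' @export
detect_loops <- function(ped) {
  g <- marriage_graph(ped)
  n_cycles <- igraph::ecount(g) - igraph::vcount(g) +
    igraph::components(g)$no
  if (n_cycles <= 0L) return(list())
  forest <- igraph::mst(g)
  extra <- igraph::difference(g, forest)
  anc <- ancestor_sets(ped)
  lapply(seq_len(igraph::ecount(extra)), function(k) {
    ends <- igraph::ends(extra, k)
    path <- igraph::shortest_paths(forest, from = ends[1L], to = ends[2L])$vpath[[1L]]
    cyc <- igraph::V(forest)$name[as.integer(path)]
    inds <- sub("^I:", "", cyc[startsWith(cyc, "I:")])
    kind <- "marriage"
    for (u in cyc[startsWith(cyc, "U:")]) {
      ui <- as.integer(sub("^U:", "", u))
      sp <- igraph::graph_attr(g, "unions")[ui, ]
      if (length(intersect(anc[[sp[1L]]], anc[[sp[2L]]])) > 0L) {
        kind <- "inbreeding"
        break
      }
    }
    list(kind = kind, member_ids = inds)
  })
}

# id -> character vector of strict ancestors, per member
ancestor_sets <- function(ped) {
  ord <- topological_order(ped)
  anc <- stats::setNames(vector("list", nrow(ped)), ped$id)
  for (i in ord) {
    a <- character(0)
    if (!is.na(ped$fid[i])) a <- c(ped$fid[i], anc[[ped$fid[i]]])
    if (!is.na(ped$mid[i])) a <- c(a, ped$mid[i], anc[[ped$mid[i]]])
    anc[[ped$id[i]]] <- unique(a)
  }
  anc
}

#' Break a pedigree loop
#'
#' Applies one of two simple loop-breaking strategies.
#' `remove_individual` deletes the target (and, by default, all of its
#' descendants, since removing a connecting individual only opens the
#' loop if the connecting line is pruned). `duplicate_individual`
#' requires the target to have both parents and at least one child in
#' the pedigree: the original keeps its parents and loses its children,
#' and a duplicate founder with id `<id>__dup<N>` carrying the same
#' sex, affection, age and genotype flag receives the children.
#'
#' @param ped a `pedigree`.
#' @param strategy `"remove_individual"` or `"duplicate_individual"`.
#' @param target_id id of the individual to remove or duplicate.
#' @param cascade with `remove_individual`, also remove all descendants
#'   of the target (default `TRUE`; with `FALSE` the target must be
#'   childless).
#' @return The modified `pedigree`; an error if the result does not have
#'   strictly fewer loops than the input (the caller may then exclude
#'   the family instead). A loop-free input is returned unchanged with a
#'   warning.
#' @export
break_loops <- function(ped, strategy = c("remove_individual",
                                          "duplicate_individual"),
                        target_id, cascade = TRUE) {
  strategy <- match.arg(strategy)
  if (!target_id %in% ped$id)
    stop("target individual ", target_id, " is not in family ", family_id(ped))
  before <- detect_loops(ped)
  if (length(before) == 0L) {
    warning("pedigree ", family_id(ped), " has no loops; returned unchanged")
    return(ped)
  }
  if (strategy == "remove_individual") {
    drop <- target_id
    if (cascade) {
      repeat {
        kids <- ped$id[(ped$fid %in% drop) | (ped$mid %in% drop)]
        add <- setdiff(kids, drop)
        if (length(add) == 0L) break
        drop <- c(drop, add)
      }
      if (length(drop) > 1L)
        message(sprintf("break_loops: cascading removal of %d descendants of %s",
                        length(drop) - 1L, target_id))
    } else {
      kids <- ped$id[(!is.na(ped$fid) & ped$fid == target_id) |
                       (!is.na(ped$mid) & ped$mid == target_id)]
      if (length(kids) > 0L)
        stop("remove_individual without cascade requires a childless target; ",
             target_id, " has children")
    }
    out <- new_pedigree(family_id(ped), ped[!(ped$id %in% drop), , drop = FALSE])
  } else {
    has_parents <- !is.na(ped$fid[match(target_id, ped$id)])
    kids <- which((!is.na(ped$fid) & ped$fid == target_id) |
                    (!is.na(ped$mid) & ped$mid == target_id))
    if (!has_parents || length(kids) == 0L)
      stop("duplicate_individual requires both parents and at least one child ",
           "in the pedigree for target ", target_id)
    n <- 1L
    while (paste0(target_id, "__dup", n) %in% ped$id) n <- n + 1L
    dup_id <- paste0(target_id, "__dup", n)
    t <- match(target_id, ped$id)
    dup <- ped[t, , drop = FALSE]
    dup$id <- dup_id
    dup$fid <- NA_character_
    dup$mid <- NA_character_
    out <- as.data.frame(ped, stringsAsFactors = FALSE)
    out$fid[kids][out$fid[kids] == target_id] <- dup_id
    out$mid[kids][out$mid[kids] == target_id] <- dup_id
    out <- new_pedigree(family_id(ped), rbind(out, as.data.frame(dup)))
  }
  validate_pedigree(out)
  after <- detect_loops(out)
  if (length(after) >= length(before))
    stop("loop breaking with strategy '", strategy, "' on ", target_id,
         " did not reduce the number of loops in family ", family_id(ped),
         "; consider excluding this family")
  out
}

#' Write a loop report
#'
#' @param peds a `ped_set`.
#' @param path output path for a tab-separated report with columns
#'   `family_id`, `loop_kind`, `member_ids` (comma-joined).
#' @export
write_loop_report <- function(peds, path) {
  rows <- list()
  for (p in peds) {
    for (lp in detect_loops(p)) {
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = family_id(p), loop_kind = lp$kind,
        member_ids = paste(lp$member_ids, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_id = character(0), loop_kind = character(0),
               member_ids = character(0))
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(out)
}

#' Kinship matrix
#'
#' Recursive kinship coefficients phi for all pairs of members:
#' `phi(i,i) = 0.5 * (1 + phi(f_i, m_i))` and, taking `i` not an
#' ancestor of `j`, `phi(i,j) = 0.5 * (phi(f_i, j) + phi(m_i, j))`,
#' with founders pairwise unrelated. The additive genetic covariance
#' between relatives is proportional to `2 * phi`.
#'
#' @param ped a `pedigree`.
#' @return A symmetric numeric matrix with individual ids as dimnames.
#' @export
kinship_matrix <- function(ped) {
  ord <- topological_order(ped)
  if (is.null(ord)) stop("cyclic parentage in family ", family_id(ped))
  n <- nrow(ped)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  fi <- match(ped$fid, ped$id)
  mi <- match(ped$mid, ped$id)
  for (i in ord) {
    if (is.na(fi[i])) {
      phi[i, i] <- 0.5
    } else {
      phi[i, i] <- 0.5 * (1 + phi[fi[i], mi[i]])
      prev <- ord[seq_len(match(i, ord) - 1L)]
      phi[i, prev] <- 0.5 * (phi[fi[i], prev] + phi[mi[i], prev])
      phi[prev, i] <- phi[i, prev]
    }
  }
  phi
}
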