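# Branch B step 3 and shared alignment machinery: progressive multiple
# alignment, alignment trimming, conserved-block curation, protein
# distances with Kimura correction, neighbour-joining with bootstrap, and
# clade-based genus assignment.
#
# An MSA is a named character vector of equal-length gapped sequences.

msa_matrix <- function(msa) {
  stopifnot(length(msa) >= 1, length(unique(nchar(msa))) == 1)
  do.call(rbind, strsplit(unname(msa), "", fixed = TRUE))
}

matrix_msa <- function(M, ids) setNames(apply(M, 1, paste, collapse = ""), ids)

degap <- function(x) gsub("-", "", x, fixed = TRUE)

# 3-mer count distance between unaligned proteins: 1 - shared fraction
kmer_distance <- function(seqs, k = 3L) {
  n <- length(seqs)
  counts <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(table(character(0)))
    table(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  })
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    a <- counts[[i]]; b <- counts[[j]]
    shared <- sum(pmin(a[names(a) %in% names(b)],
                       b[names(a)[names(a) %in% names(b)]]))
    denom <- max(1, min(sum(a), sum(b)))
    D[i, j] <- D[j, i] <- 1 - shared / denom
  }
  D
}

profile_of <- function(rows, letters) {
  M <- msa_matrix(rows)
  P <- matrix(0, nrow = length(letters), ncol = ncol(M),
              dimnames = list(letters, NULL))
  for (j in seq_len(ncol(M))) {
    col <- M[, j]
    col <- col[col != "-"]
    if (length(col)) {
      tab <- table(factor(col, levels = letters))
      P[, j] <- as.numeric(tab) / length(col)
    }
  }
  P
}

apply_ops <- function(rows, ops, side) {
  # side 1: keep on op 0/1 (gap on 2); side 2: keep on op 0/2
  M <- msa_matrix(rows)
  L <- length(ops)
  out <- matrix("-", nrow = nrow(M), ncol = L)
  keep_op <- if (side == 1) c(0L, 1L) else c(0L, 2L)
  src <- 0L
  for (c0 in seq_len(L)) {
    if (ops[c0] %in% keep_op) {
      src <- src + 1L
      out[, c0] <- M[, src]
    }
  }
  matrix_msa(out, names(rows))
}

#' Progressive multiple protein alignment
#'
#' Guide order from 3-mer count distances agglomerated by
#' neighbour-joining; profiles are merged in join order by global
#' profile-profile alignment with BLOSUM62 and affine gaps (open -10,
#' extend -1). Deterministic for a given input set.
#'
#' @param proteins protein sequence set (>= 2 sequences)
#' @param gap_open,gap_ext positive gap penalties
#' @return MSA (named character vector, equal lengths)
#' @export
progressive_align <- function(proteins, gap_open = 10, gap_ext = 1) {
  n <- length(proteins)
  if (n < 2) stop("progressive_align: need at least 2 sequences")
  proteins <- setNames(as.character(proteins), names(proteins))
  bl <- blosum62()
  letters <- rownames(bl)
  if (n == 2) {
    ops <- cpp_profile_align(profile_of(proteins[1], letters),
                             profile_of(proteins[2], letters), bl, gap_open, gap_ext)
    a1 <- apply_ops(proteins[1], ops, 1)
    a2 <- apply_ops(proteins[2], ops, 2)
    return(c(a1, a2))
  }
  D <- kmer_distance(proteins)
  merges <- nj_join_order(D)
  clusters <- lapply(seq_len(n), function(i) proteins[i])
  for (m in seq_len(nrow(merges))) {
    i <- merges[m, 1]; j <- merges[m, 2]
    A <- clusters[[i]]; B <- clusters[[j]]
    ops <- cpp_profile_align(profile_of(A, letters), profile_of(B, letters),
                             bl, gap_open, gap_ext)
    AB <- c(apply_ops(A, ops, 1), apply_ops(B, ops, 2))
    clusters[[i]] <- AB
    clusters[[j]] <- NA  # consumed
  }
  sizes <- vapply(clusters, length, integer(1))
  msa <- clusters[[which.max(sizes)]]
  msa[names(proteins)]
}

# Neighbour-joining join order on a distance matrix: returns an (n-2) x 2
# matrix of cluster indices (into the evolving cluster list, where the
# merged cluster replaces index min(i, j)). Deterministic tie-breaking.
nj_join_order <- function(D) {
  n <- nrow(D)
  active <- seq_len(n)
  idx <- seq_len(n)  # position of cluster in original numbering
  out <- matrix(0L, nrow = 0, ncol = 2)
  Dm <- D
  while (length(active) > 2) {
    m <- length(active)
    r <- rowSums(Dm[active, active, drop = FALSE])
    best <- c(NA, NA); bestq <- Inf
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      i <- active[a]; j <- active[b]
      q <- (m - 2) * Dm[i, j] - r[a] - r[b]
      if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    for (k in active) {
      if (k == i || k == j) next
      Dm[i, k] <- Dm[k, i] <- 0.5 * (Dm[i, k] + Dm[j, k] - Dm[i, j])
    }
    out <- rbind(out, c(i, j))
    active <- setdiff(active, j)
  }
  if (length(active) == 2) out <- rbind(out, active)
  out
}

#' Trim a multiple alignment
#'
#' Columns with gap fraction above `col_gap_max` are removed first; then
#' sequences whose residues occupy less than `seq_occupancy_min` of the
#' remaining columns are removed (except protected ids, e.g. the
#' reference panel).
#'
#' @param msa MSA (named character vector)
#' @param col_gap_max maximum column gap fraction (default 0.8)
#' @param seq_occupancy_min minimum per-sequence occupancy (default 0.5)
#' @param protected ids never removed
#' @return list(msa, removed)
#' @export
trim_msa <- function(msa, col_gap_max = 0.8, seq_occupancy_min = 0.5,
                     protected = character(0)) {
  M <- msa_matrix(msa)
  gapfrac <- colMeans(M == "-")
  M2 <- M[, gapfrac <= col_gap_max, drop = FALSE]
  occ <- rowMeans(M2 != "-")
  if (ncol(M2) == 0) occ <- rep(0, nrow(M2))
  drop <- occ < seq_occupancy_min & !(names(msa) %in% protected)
  if (all(drop)) stop("trim_msa: all sequences removed")
  list(msa = matrix_msa(M2[!drop, , drop = FALSE], names(msa)[!drop]),
       removed = names(msa)[drop])
}

#' Iterative align/trim sequence selection
#'
#' Initial alignment and trim, followed by `rounds` repetitions of
#' realigning the survivors and trimming again; stops early at a fixed
#' point. Survivors are returned unaligned.
#'
#' @param proteins protein sequence set
#' @param rounds number of additional rounds (2 in the mining stage,
#'   4 before the final phylogeny)
#' @param protected ids exempt from removal
#' @param ... forwarded to [trim_msa()]
#' @return list(survivors, removed, msa) where `msa` is the final alignment
#' @export
iterative_align_trim <- function(proteins, rounds = 2L, protected = character(0), ...) {
  removed_all <- character(0)
  cur <- proteins
  msa <- progressive_align(cur)
  tr <- trim_msa(msa, protected = protected, ...)
  removed_all <- c(removed_all, tr$removed)
  cur <- cur[!names(cur) %in% tr$removed]
  last_msa <- tr$msa
  for (r in seq_len(rounds)) {
    if (length(cur) < 2) break
    msa <- progressive_align(cur)
    tr <- trim_msa(msa, protected = protected, ...)
    last_msa <- tr$msa
    if (length(tr$removed) == 0) break
    removed_all <- c(removed_all, tr$removed)
    cur <- cur[!names(cur) %in% tr$removed]
  }
  list(survivors = cur, removed = removed_all, msa = last_msa)
}

#' Select conserved alignment blocks
#'
#' A column is good when its gap fraction is at most `col_gap_max` and
#' its modal residue frequency (among residues) is at least
#' `col_conservation_min`; maximal runs of at least `min_block`
#' consecutive good columns are kept and concatenated.
#'
#' @param msa MSA
#' @param min_block minimum run length (default 5)
#' @param col_gap_max maximum gap fraction (default 0.5)
#' @param col_conservation_min minimum modal residue frequency (default 0.5)
#' @return curated MSA
#' @export
select_blocks <- function(msa, min_block = 5L, col_gap_max = 0.5,
                          col_conservation_min = 0.5) {
  M <- msa_matrix(msa)
  good <- vapply(seq_len(ncol(M)), function(j) {
    col <- M[, j]
    gf <- mean(col == "-")
    if (gf > col_gap_max) return(FALSE)
    res <- col[col != "-"]
    max(table(res)) / length(res) >= col_conservation_min
  }, logical(1))
  r <- rle(good)
  ends <- cumsum(r$lengths)
  keep <- logical(ncol(M))
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && r$lengths[i] >= min_block)
      keep[(ends[i] - r$lengths[i] + 1):ends[i]] <- TRUE
  }
  if (!any(keep)) stop("select_blocks: no conserved block survives")
  matrix_msa(M[, keep, drop = FALSE], names(msa))
}

#' Protein distance matrix with Kimura correction
#'
#' p-distance over mutually non-gap columns per pair, corrected as
#' d = -ln(1 - p - p^2/5); p >= 0.85 is capped at d = 10.
#'
#' @param msa MSA (ideally after [select_blocks()])
#' @return symmetric numeric matrix with zero diagonal
#' @export
msa_distance_matrix <- function(msa) {
  M <- msa_matrix(msa)
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- M[i, ] != "-" & M[j, ] != "-"
    if (!any(ok)) stop(sprintf("msa_distance_matrix: no shared columns between %s and %s",
                               names(msa)[i], names(msa)[j]))
    p <- mean(M[i, ok] != M[j, ok])
    d <- if (p >= 0.85) 10 else -log(1 - p - p^2 / 5)
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbour-joining tree
#'
#' Standard neighbour-joining agglomeration with deterministic
#' tie-breaking; negative branch lengths are clamped to zero. The result
#' is an unrooted `ape::phylo` tree.
#'
#' @param D symmetric distance matrix with at least 3 taxa
#' @return `phylo` object
#' @export
nj_tree <- function(D) {
  n <- nrow(D)
  if (n < 3) stop("nj_tree: need at least 3 taxa")
  labs <- rownames(D)
  if (any(grepl("[():,;'\"\\s]", labs, perl = TRUE)))
    stop("nj_tree: taxon labels must not contain Newick metacharacters")
  nodes <- as.list(labs)  # newick fragments
  active <- seq_len(n)
  Dm <- D
  while (length(active) > 3) {
    m <- length(active)
    r <- setNames(rowSums(Dm[active, active, drop = FALSE]), active)
    best <- c(NA, NA); bestq <- Inf
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      i <- active[a]; j <- active[b]
      q <- (m - 2) * Dm[i, j] - r[as.character(i)] - r[as.character(j)]
      if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- 0.5 * Dm[i, j] + (r[as.character(i)] - r[as.character(j)]) / (2 * (m - 2))
    lj <- Dm[i, j] - li
    li <- max(0, li); lj <- max(0, lj)
    for (k in active) {
      if (k == i || k == j) next
      Dm[i, k] <- Dm[k, i] <- max(0, 0.5 * (Dm[i, k] + Dm[j, k] - Dm[i, j]))
    }
    nodes[[i]] <- sprintf("(%s:%.8f,%s:%.8f)", nodes[[i]], li, nodes[[j]], lj)
    active <- setdiff(active, j)
  }
  i <- active[1]; j <- active[2]; k <- active[3]
  li <- max(0, 0.5 * (Dm[i, j] + Dm[i, k] - Dm[j, k]))
  lj <- max(0, 0.5 * (Dm[i, j] + Dm[j, k] - Dm[i, k]))
  lk <- max(0, 0.5 * (Dm[i, k] + Dm[j, k] - Dm[i, j]))
  txt <- sprintf("(%s:%.8f,%s:%.8f,%s:%.8f);", nodes[[i]], li, nodes[[j]], lj, nodes[[k]], lk)
  ape::read.tree(text = txt)
}

#' Bootstrap support for the neighbour-joining tree
#'
#' Columns are resampled with replacement per replicate; the support of
#' each internal bipartition of the point-estimate tree is the percentage
#' of replicate trees containing it. Node labels of the returned tree
#' hold the supports.
#'
#' @param msa MSA (after block selection)
#' @param replicates number of bootstrap replicates (default 100)
#' @param seed RNG seed
#' @return `phylo` tree with numeric node labels (support 0-100)
#' @export
bootstrap_support <- function(msa, replicates = 100L, seed = 1L) {
  point <- nj_tree(msa_distance_matrix(msa))
  M <- msa_matrix(msa)
  set.seed(seed)
  reps <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
    rep_msa <- matrix_msa(M[, cols, drop = FALSE], names(msa))
    reps[[r]] <- tryCatch(nj_tree(msa_distance_matrix(rep_msa)), error = function(e) NULL)
  }
  reps <- Filter(Negate(is.null), reps)
  cl <- ape::prop.clades(point, reps, rooted = FALSE)
  cl[is.na(cl)] <- 0L
  support <- round(100 * cl / length(reps))
  point$node.label <- as.character(support)
  point
}

#' Clade-based genus assignment of candidate leaves
#'
#' The tree is rooted on the outgroup references; for each candidate the
#' smallest clade containing it together with at least one reference at
#' support >= `min_support` provides the assignment, and only when that
#' clade's references carry a single genus. Otherwise the candidate is
#' "unclassified".
#'
#' @param tree `phylo` tree with support node labels (see
#'   [bootstrap_support()])
#' @param reference_labels named character vector: reference leaf ->
#'   genus; outgroup references must have genus "outgroup"
#' @param min_support minimum clade support (default 70)
#' @return data.frame (candidate_id, genus, support)
#' @export
classify_leaves <- function(tree, reference_labels, min_support = 70) {
  refs <- names(reference_labels)
  if (!all(refs %in% tree$tip.label))
    refs <- intersect(refs, tree$tip.label)
  candidates <- setdiff(tree$tip.label, refs)
  og <- sort(refs[reference_labels[refs] == "outgroup"])
  if (length(og) == 0) stop("classify_leaves: no outgroup reference in tree")
  # root on a single outgroup leaf: always valid even when the outgroups
  # are not monophyletic in the estimate
  tr <- ape::root(tree, outgroup = og[1], resolve.root = TRUE, edgelabel = TRUE)
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  # leaf sets per internal node by post-order accumulation
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  leafset <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) leafset[[i]] <- tr$tip.label[i]
  ord <- rev(ape::reorder.phylo(tr, "cladewise")$edge[, 2])
  for (v in c(ord, ntip + 1L)) {
    if (v <= ntip || !is.null(leafset[[v]])) next
    leafset[[v]] <- unlist(lapply(kids[[as.character(v)]], function(u) leafset[[u]]))
  }
  supports <- suppressWarnings(as.numeric(tr$node.label))
  out <- data.frame(candidate_id = character(0), genus = character(0),
                    support = numeric(0), stringsAsFactors = FALSE)
  for (cand in candidates) {
    best_sz <- Inf; best_gen <- "unclassified"; best_sup <- NA_real_
    for (v in (ntip + 1L):(ntip + nnode)) {
      ls <- leafset[[v]]
      if (!(cand %in% ls)) next
      rr <- intersect(ls, refs)
      if (length(rr) == 0) next
      sup <- supports[v - ntip]
      if (v == ntip + 1L) sup <- 100  # root contains everything by definition
      if (is.na(sup) || sup < min_support) next
      if (length(ls) < best_sz) {
        best_sz <- length(ls)
        gen <- unique(reference_labels[rr])
        best_gen <- if (length(gen) == 1) unname(gen) else "unclassified"
        best_sup <- sup
      }
    }
    out <- rbind(out, data.frame(candidate_id = cand, genus = best_gen,
                                 support = best_sup, stringsAsFactors = FALSE))
  }
  out
}

#' Write a tree in Newick format (supports as internal node labels)
#'
#' @param tree `phylo` object
#' @param path output file
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
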