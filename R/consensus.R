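# Branch A step 2: group repetitive sub-genome sequences and build
# consensus sequences.
#
# The de novo repeat-discovery stage is a defined single-linkage
# span-graph grouping: all-vs-all nucleotide HSPs above the identity
# threshold contribute their two end spans as graph nodes, near-identical
# spans on the same segment are fused, and connected components with at
# least `hsp_min` member spans become groups. Up to `group_cap` members
# (longest first) are star-aligned to the longest member and a
# majority-rule consensus is called per backbone column.

IUPAC_NT <- c(A = "A", C = "C", G = "G", T = "T",
              AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
              CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N")

iupac_code <- function(residues) {
  key <- paste(sort(unique(residues)), collapse = "")
  unname(IUPAC_NT[key] %||% "N")
}

#' All-vs-all sub-genome HSP search
#'
#' Nucleotide search of every segment against every other, excluding the
#' trivial self identity hit and mirror duplicates. Only hits at or above
#' the identity threshold and at least `min_len` alignment columns are
#' kept; off-diagonal self hits (internal tandem structure) are retained.
#'
#' @param segments sub-genome sequence set
#' @param min_identity identity threshold in percent (default 85)
#' @param min_len minimum alignment length (default 100)
#' @param params nucleotide search overrides
#' @return hit data.frame
#' @export
find_subgenome_hsps <- function(segments, min_identity = 85, min_len = 100L,
                                params = list()) {
  if (length(segments) < 2) return(empty_hits())
  p <- params
  p$min_identity <- min_identity
  # upper-triangle passes only: the mirror half is redundant by symmetry
  hits <- do.call(rbind, lapply(seq_along(segments), function(j)
    search_homology(segments[seq_len(j)], segments[j], mode = "nt_nt", params = p)))
  if (nrow(hits) == 0) return(hits)
  trivial <- hits$query_id == hits$subject_id & hits$q_start == hits$s_start &
    hits$q_end == hits$s_end & hits$strand == "+"
  hits <- hits[!trivial, , drop = FALSE]
  # mirror duplicates: A-vs-B and B-vs-A describe the same alignment
  key <- ifelse(hits$query_id < hits$subject_id |
                  (hits$query_id == hits$subject_id & hits$q_start <= hits$s_start),
                paste(hits$query_id, hits$subject_id, hits$q_start, hits$q_end,
                      hits$s_start, hits$s_end),
                paste(hits$subject_id, hits$query_id, hits$s_start, hits$s_end,
                      hits$q_start, hits$q_end))
  hits <- hits[!duplicated(key), , drop = FALSE]
  hits <- hits[hits$identity_pct >= min_identity & hits$aln_len >= min_len, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Group HSP spans into repeat families
#'
#' Every hit contributes its query-side and subject-side span as a node.
#' Nodes on the same segment sharing at least `fuse_overlap` mutual
#' overlap are fused; hits connect their two (fused) spans, and connected
#' components with at least `min_members` distinct member spans of at
#' least 100 bp become groups.
#'
#' @param hits data.frame from [find_subgenome_hsps()]
#' @param min_members minimum member spans per emitted group (default 5)
#' @param fuse_overlap mutual-overlap fraction for span fusion (default 0.8)
#' @return data.frame (group_id, segment_id, start, end) of member spans
#' @export
group_hsps <- function(hits, min_members = 5L, fuse_overlap = 0.8) {
  empty <- data.frame(group_id = character(0), segment_id = character(0),
                      start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  spans <- rbind(
    data.frame(seg = hits$query_id, start = hits$q_start, end = hits$q_end,
               stringsAsFactors = FALSE),
    data.frame(seg = hits$subject_id, start = hits$s_start, end = hits$s_end,
               stringsAsFactors = FALSE))
  hit_nodes <- matrix(seq_len(nrow(spans)), ncol = 2)  # row i of hits -> nodes i, i+n
  dup_key <- paste(spans$seg, spans$start, spans$end)
  first_idx <- match(dup_key, dup_key)
  n <- nrow(spans)
  parent <- seq_len(n)
  union2 <- function(a, b) {
    ra <- uf_find(parent, a); rb <- uf_find(parent, b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    invisible(NULL)
  }
  for (i in seq_len(n)) if (first_idx[i] != i) union2(first_idx[i], i)
  # fuse near-identical spans on the same segment
  for (seg in unique(spans$seg)) {
    idx <- which(spans$seg == seg & first_idx == seq_len(n))
    if (length(idx) < 2) next
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1):length(idx)) {
        i <- idx[a]; j <- idx[b]
        ov <- min(spans$end[i], spans$end[j]) - max(spans$start[i], spans$start[j])
        if (ov <= 0) next
        if (ov / (spans$end[i] - spans$start[i]) >= fuse_overlap &&
            ov / (spans$end[j] - spans$start[j]) >= fuse_overlap) union2(i, j)
      }
    }
  }
  # hits connect their two fused nodes
  for (i in seq_len(nrow(hits))) union2(hit_nodes[i, 1], hit_nodes[i, 2])
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  # fused member span = union interval of the spans collapsed into a node
  # (node identity = fused spans pre hit-edges); recompute fusion-only roots
  parent2 <- seq_len(n)
  union2b <- function(a, b) {
    ra <- uf_find(parent2, a); rb <- uf_find(parent2, b)
    if (ra != rb) parent2[max(ra, rb)] <<- min(ra, rb)
    invisible(NULL)
  }
  for (i in seq_len(n)) if (first_idx[i] != i) union2b(first_idx[i], i)
  for (seg in unique(spans$seg)) {
    idx <- which(spans$seg == seg & first_idx == seq_len(n))
    if (length(idx) < 2) next
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1):length(idx)) {
        i <- idx[a]; j <- idx[b]
        ov <- min(spans$end[i], spans$end[j]) - max(spans$start[i], spans$start[j])
        if (ov <= 0) next
        if (ov / (spans$end[i] - spans$start[i]) >= fuse_overlap &&
            ov / (spans$end[j] - spans$start[j]) >= fuse_overlap) union2b(i, j)
      }
    }
  }
  node_root <- vapply(seq_len(n), function(i) uf_find(parent2, i), integer(1))
  members <- do.call(rbind, lapply(split(seq_len(n), node_root), function(ix) {
    data.frame(node = ix[1], seg = spans$seg[ix[1]],
               start = min(spans$start[ix]), end = max(spans$end[ix]),
               comp = roots[ix[1]], stringsAsFactors = FALSE)
  }))
  members <- members[members$end - members$start >= 100L, , drop = FALSE]
  if (nrow(members) == 0) return(empty)
  keep <- names(which(table(members$comp) >= min_members))
  members <- members[members$comp %in% keep, , drop = FALSE]
  if (nrow(members) == 0) return(empty)
  members <- members[order(members$comp, members$seg, members$start), , drop = FALSE]
  gid <- match(members$comp, unique(members$comp))
  data.frame(group_id = sprintf("G%03d", gid), segment_id = members$seg,
             start = members$start, end = members$end, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Build a majority-rule consensus for one group
#'
#' Up to `cap` member spans (longest first) are extracted and star-aligned
#' to the longest member with free end gaps. Per backbone column the
#' modal residue is called over the members whose aligned span covers the
#' column; columns where fewer than half of the covering members have a
#' residue are dropped, and ties emit the IUPAC ambiguity code.
#' Insertions relative to the backbone are not added.
#'
#' @param members data.frame (segment_id, start, end) for one group
#' @param segments sub-genome sequence set
#' @param cap maximum members aligned (default 20)
#' @return list with `residues`, `n_members`, `backbone`
#' @export
build_group_consensus <- function(members, segments, cap = 20L) {
  seqs <- substr(as.character(segments[members$segment_id]), members$start + 1L, members$end)
  names(seqs) <- NULL
  len <- nchar(seqs)
  ok <- len >= 100L
  members <- members[ok, , drop = FALSE]; seqs <- seqs[ok]; len <- len[ok]
  if (length(seqs) < 2) stop("build_group_consensus: fewer than 2 usable members")
  ord <- order(-len, members$segment_id, members$start)
  take <- ord[seq_len(min(cap, length(ord)))]
  seqs <- unname(seqs[take])
  bb <- seqs[1]
  L <- nchar(bb)
  nm <- length(seqs)
  M <- matrix(NA_character_, nrow = nm, ncol = L)
  M[1, ] <- strsplit(bb, "", fixed = TRUE)[[1]]
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2, baseOnly = FALSE)
  for (i in seq_len(nm)[-1]) {
    # members may derive from either strand: align both orientations to
    # the backbone and keep the better one
    fwd <- Biostrings::pairwiseAlignment(Biostrings::DNAString(seqs[i]), Biostrings::DNAString(bb),
                                         substitutionMatrix = sm, gapOpening = 5,
                                         gapExtension = 2, type = "overlap")
    rcs <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqs[i])))
    rev <- Biostrings::pairwiseAlignment(Biostrings::DNAString(rcs), Biostrings::DNAString(bb),
                                         substitutionMatrix = sm, gapOpening = 5,
                                         gapExtension = 2, type = "overlap")
    pa <- if (Biostrings::score(fwd) >= Biostrings::score(rev)) fwd else rev
    al_p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "", fixed = TRUE)[[1]]
    al_s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "", fixed = TRUE)[[1]]
    off <- Biostrings::start(Biostrings::subject(pa)) - 1L  # 0-based backbone offset
    pos <- off
    for (c0 in seq_along(al_s)) {
      if (al_s[c0] != "-") {
        pos <- pos + 1L
        M[i, pos] <- al_p[c0]
      }
    }
  }
  cons <- character(L)
  keep <- logical(L)
  for (j in seq_len(L)) {
    col <- M[, j]
    covering <- !is.na(col)
    votes <- col[covering & col != "-"]
    if (length(votes) / sum(covering) < 0.5) next
    tab <- table(votes)
    top <- names(tab)[tab == max(tab)]
    keep[j] <- TRUE
    cons[j] <- if (length(top) == 1) top else iupac_code(top)
  }
  list(residues = paste(cons[keep], collapse = ""), n_members = nm, backbone = bb)
}

#' Build consensus library from sub-genome segments
#'
#' Runs the HSP search, grouping and per-group consensus steps and
#' returns the consensus records.
#'
#' @param segments sub-genome sequence set
#' @param config see [eve_config()]
#' @return list with `consensi` (nt sequence set), `meta` (data.frame id,
#'   group_id, length, n_members) and `members` (group membership table)
#' @export
build_consensus_library <- function(segments, config = eve_config()) {
  hits <- find_subgenome_hsps(segments, min_identity = config$subgenome_identity_pct,
                              min_len = config$min_hsp_len, params = config$search_nt)
  members <- group_hsps(hits, min_members = config$hsp_min)
  if (nrow(members) == 0) {
    return(list(consensi = seq_set(character(0), "nt"),
                meta = data.frame(id = character(0), group_id = character(0),
                                  length = integer(0), n_members = integer(0)),
                members = members))
  }
  out <- lapply(split(members, members$group_id), function(mm) {
    cc <- build_group_consensus(mm, segments, cap = config$group_cap)
    data.frame(group_id = mm$group_id[1], residues = cc$residues,
               n_members = cc$n_members, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[nchar(out$residues) >= 100L, , drop = FALSE]
  ids <- sprintf("cons_%s", out$group_id)
  consensi <- seq_set(setNames(out$residues, ids), "nt")
  meta <- data.frame(id = ids, group_id = out$group_id,
                     length = nchar(out$residues), n_members = out$n_members,
                     stringsAsFactors = FALSE, row.names = NULL)
  list(consensi = consensi, meta = meta, members = members)
}
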