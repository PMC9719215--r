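# Branch B steps 1-2: mine, translate, filter and dereplicate
# caulimovirid RT protein sequences from a genome.

#' Find RT-like loci in a genome
#'
#' Protein-vs-translated-genome search with the RT reference probes; each
#' hit is extended by `flank` bp on both sides (to bridge alignment
#' breaks), clamped, and overlapping extended spans are merged per
#' subject. The dominant frame of a locus is the frame of its
#' highest-scoring source hit.
#'
#' @param genome nucleotide sequence set
#' @param rt_refs protein RT probe set
#' @param flank extension in bp (default 120)
#' @param params protein search overrides
#' @return locus data.frame (subject_id, start, end, n_hits, frame)
#' @export
find_rt_loci <- function(genome, rt_refs, flank = 120L, params = list()) {
  hits <- search_homology(rt_refs, genome, mode = "aa_vs_txnt", params = params)
  if (nrow(hits) == 0) {
    out <- empty_loci(); out$frame <- integer(0); return(out)
  }
  ext <- data.frame(subject_id = hits$subject_id,
                    start = pmax(0L, hits$s_start - as.integer(flank)),
                    end = pmin(nchar(genome)[hits$subject_id], hits$s_end + as.integer(flank)),
                    stringsAsFactors = FALSE)
  loci <- reduce_spans(ext, max_gap = 0L)
  # dominant frame per locus
  loci$frame <- NA_integer_
  for (i in seq_len(nrow(loci))) {
    hh <- hits[hits$subject_id == loci$subject_id[i] &
                 hits$s_end + flank > loci$start[i] &
                 hits$s_start - flank < loci$end[i], , drop = FALSE]
    if (nrow(hh)) loci$frame[i] <- hh$frame_s[which.max(hh$score)]
  }
  loci
}

# translation frame offset of a genome slice [a, b) for genome frame f
# (slice taken forward for f > 0, reverse-complemented for f < 0)
slice_frame_offset <- function(f, a, b, L) {
  k <- abs(f) - 1L
  if (f > 0) (k - a) %% 3L else (k - (L - b)) %% 3L
}

#' Extract candidate RT proteins from loci
#'
#' Each locus is translated in its dominant frame, split at stop codons,
#' and maximal stop-free segments of at least `min_aa` residues become
#' candidates. Candidate coordinates are the nucleotide span of the
#' translated segment on the genome forward strand.
#'
#' @param genome nucleotide sequence set
#' @param loci data.frame from [find_rt_loci()]
#' @param min_aa minimum protein length (default 200)
#' @return data.frame (candidate_id, subject_id, start, end, frame, protein)
#' @export
extract_rt_proteins <- function(genome, loci, min_aa = 200L) {
  out <- data.frame(candidate_id = character(0), subject_id = character(0),
                    start = integer(0), end = integer(0), frame = integer(0),
                    protein = character(0), stringsAsFactors = FALSE)
  cnt <- 0L
  for (i in seq_len(nrow(loci))) {
    f <- loci$frame[i]
    if (is.na(f)) next
    a <- loci$start[i]; b <- loci$end[i]
    L <- nchar(genome[[loci$subject_id[i]]])
    slice <- substr(genome[[loci$subject_id[i]]], a + 1L, b)
    src <- if (f > 0) slice else as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(slice)))
    off <- slice_frame_offset(f, a, b, L)
    n <- nchar(src) - off
    n <- n - (n %% 3L)
    if (n < 3L) next
    prot <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(src, off + 1L, off + n)), if.fuzzy.codon = "solve",
      no.init.codon = TRUE))
    # maximal stop-free runs
    pieces <- gregexpr("[^*]+", prot)[[1]]
    if (pieces[1] == -1) next
    for (pi in seq_along(pieces)) {
      ps <- pieces[pi]
      pl <- attr(pieces, "match.length")[pi]
      if (pl < min_aa) next
      aa0 <- ps - 1L  # 0-based aa start within translation
      nt0 <- off + 3L * aa0          # within src
      nt1 <- off + 3L * (aa0 + pl)
      slice_len <- nchar(slice)
      if (f > 0) { g0 <- a + nt0; g1 <- a + nt1 }
      else { g0 <- a + (slice_len - nt1); g1 <- a + (slice_len - nt0) }
      cnt <- cnt + 1L
      # ids stay free of Newick/GFF metacharacters (used as tree leaves)
      out <- rbind(out, data.frame(
        candidate_id = sprintf("%s_%d_%d_%s%d", loci$subject_id[i], g0, g1,
                               if (f > 0) "p" else "m", abs(f)),
        subject_id = loci$subject_id[i], start = g0, end = g1, frame = f,
        protein = substr(prot, ps, ps + pl - 1L), stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Competitive best-hit filtering of RT candidates
#'
#' Protein-protein comparison of each candidate against the mixed RT
#' library (caulimovirid plus Copia/Gypsy retroelements); candidates are
#' kept only when their top-scoring library hit is caulimovirid. Ties are
#' broken as in [bait_filter()]; candidates with no hit are discarded.
#'
#' @param candidates data.frame from [extract_rt_proteins()]
#' @param rt_library protein sequence set with class/genus tags
#' @param params protein search overrides
#' @return kept candidates with best_hit_class/genus/score columns
#' @export
rt_best_hit_filter <- function(candidates, rt_library, params = list()) {
  if (nrow(candidates) == 0) {
    candidates$best_hit_class <- character(0)
    candidates$best_hit_genus <- character(0)
    candidates$best_hit_score <- numeric(0)
    return(candidates)
  }
  tags <- bait_tags(rt_library)
  prots <- seq_set(setNames(candidates$protein, candidates$candidate_id), "aa")
  hits <- search_homology(rt_library, prots, mode = "aa_aa", params = params)
  best <- best_bait_per_segment(hits, tags)
  m <- match(candidates$candidate_id, best$subject_id)
  candidates$best_hit_class <- ifelse(is.na(m), "none", best$bait_class[m])
  candidates$best_hit_genus <- ifelse(is.na(m), NA_character_, best$bait_genus[m])
  candidates$best_hit_score <- ifelse(is.na(m), NA_real_, best$score[m])
  kept <- candidates[candidates$best_hit_class == "caulimovirid", , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Greedy centroid clustering of proteins
#'
#' Sequences are sorted longest first; each joins the first centroid with
#' global-alignment identity at or above the threshold, otherwise founds
#' a new cluster. The centroid is the cluster representative, so any two
#' final centroids are below the threshold.
#'
#' @param proteins protein sequence set
#' @param identity threshold in percent (default 80)
#' @return data.frame (id, cluster_id, representative)
#' @export
cluster_greedy_centroid <- function(proteins, identity = 80) {
  ids <- names(proteins)
  if (length(ids) == 0)
    return(data.frame(id = character(0), cluster_id = character(0),
                      representative = logical(0)))
  ord <- order(-nchar(proteins), ids)
  centroids <- integer(0)
  assign <- integer(length(ids))
  for (i in ord) {
    placed <- FALSE
    for (ci in centroids) {
      al <- align_pair(proteins[[ci]], proteins[[i]], alphabet = "aa")
      if (al$identity_pct >= identity) { assign[i] <- ci; placed <- TRUE; break }
    }
    if (!placed) { centroids <- c(centroids, i); assign[i] <- i }
  }
  lab <- setNames(sprintf("RTC%03d", seq_along(centroids)), centroids)
  data.frame(id = ids, cluster_id = unname(lab[as.character(assign)]),
             representative = seq_along(ids) %in% centroids, stringsAsFactors = FALSE)
}

#' Mine representative caulimovirid RT proteins (Branch B steps 1-2)
#'
#' @param genome nucleotide sequence set
#' @param rt_refs RT probe proteins (search queries)
#' @param rt_library mixed filtering library with class/genus tags
#' @param config see [eve_config()]
#' @return list with `loci`, `candidates` (post-filter), `clusters`,
#'   `representatives` (protein sequence set)
#' @export
mine_rt_proteins <- function(genome, rt_refs, rt_library, config = eve_config()) {
  loci <- find_rt_loci(genome, rt_refs, flank = config$rt_flank_bp,
                       params = config$search_aa)
  cands <- extract_rt_proteins(genome, loci, min_aa = config$min_protein_aa)
  kept <- rt_best_hit_filter(cands, rt_library, params = config$search_aa)
  if (nrow(kept) == 0) {
    return(list(loci = loci, candidates = kept,
                clusters = data.frame(id = character(0), cluster_id = character(0),
                                      representative = logical(0)),
                representatives = seq_set(character(0), "aa")))
  }
  prots <- seq_set(setNames(kept$protein, kept$candidate_id), "aa")
  cl <- cluster_greedy_centroid(prots, identity = config$rt_cluster_identity_pct)
  reps <- prots[cl$id[cl$representative]]
  list(loci = loci, candidates = kept, clusters = cl,
       representatives = seq_set(reps, "aa"))
}
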