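# Branch A step 1: build the caulimovirid-enriched sub-genome.
#
# A translated (six-frame vs six-frame) search of the genome with the
# viral genome library yields hits whose genome-side spans are merged into
# candidate loci. Extracted loci are classified by competitive best hit
# against the mixed "baits" protein library (caulimovirid proteins plus
# Copia/Gypsy RT+RNaseH); loci whose best bait is a retroelement protein,
# or that hit no bait at all, are discarded. Survivors within 5 kbp are
# merged (one presumed integration event) and extended by the -X value
# before extraction.

LOCUS_COLS <- c("subject_id", "start", "end", "n_hits")

empty_loci <- function() {
  data.frame(subject_id = character(0), start = integer(0), end = integer(0),
             n_hits = integer(0), stringsAsFactors = FALSE)
}

# reduce 0-based half-open spans per subject; spans touching end-to-start
# are merged; gap <= max_gap merges when max_gap > 0
reduce_spans <- function(df, max_gap = 0L) {
  if (nrow(df) == 0) return(empty_loci())
  out <- lapply(split(df, df$subject_id), function(d) {
    ir <- IRanges::IRanges(start = d$start + 1L, end = d$end)
    red <- IRanges::reduce(ir, min.gapwidth = max_gap + 1L)
    ov <- IRanges::findOverlaps(ir, red, maxgap = max_gap)
    nh <- tabulate(S4Vectors::subjectHits(ov), nbins = length(red))
    w <- if ("n_hits" %in% names(d)) d$n_hits else rep(1L, nrow(d))
    agg <- vapply(seq_along(red), function(i)
      sum(w[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == i]]), integer(1))
    data.frame(subject_id = d$subject_id[1],
               start = IRanges::start(red) - 1L, end = IRanges::end(red),
               n_hits = agg, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$subject_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge overlapping hits into candidate loci
#'
#' The union of hit spans on each subject is partitioned into maximal
#' connected components; strand is ignored and spans that merely touch
#' (end == next start, half-open) are merged as contiguous sequence.
#'
#' @param hits data.frame from [search_homology()] (subject side is the genome)
#' @return locus data.frame (subject_id, start, end, n_hits), disjoint and
#'   sorted per subject
#' @export
merge_overlapping_hits <- function(hits) {
  if (nrow(hits) == 0) return(empty_loci())
  df <- data.frame(subject_id = hits$subject_id, start = hits$s_start,
                   end = hits$s_end, stringsAsFactors = FALSE)
  reduce_spans(df, max_gap = 0L)
}

#' Merge loci separated by small gaps
#'
#' Consecutive loci on the same subject with gap (next start minus
#' previous end) less than or equal to `max_gap` are merged; the
#' threshold is inclusive and the operation is idempotent.
#'
#' @param loci locus data.frame, disjoint and sorted
#' @param max_gap maximum gap in bp (default 5000)
#' @return merged locus data.frame
#' @export
merge_nearby <- function(loci, max_gap = 5000L) {
  if (nrow(loci) == 0) return(loci)
  keep_cols <- setdiff(names(loci), LOCUS_COLS)
  merged <- reduce_spans(loci[, LOCUS_COLS], max_gap = as.integer(max_gap))
  if (length(keep_cols)) {
    # carry classification of the best-scoring constituent locus
    for (cc in keep_cols) merged[[cc]] <- NA
    if ("best_bait_score" %in% names(loci)) {
      for (i in seq_len(nrow(merged))) {
        sel <- loci$subject_id == merged$subject_id[i] &
          loci$start >= merged$start[i] & loci$end <= merged$end[i]
        if (any(sel)) {
          j <- which(sel)[which.max(loci$best_bait_score[sel])]
          for (cc in keep_cols) merged[[cc]][i] <- loci[[cc]][j]
        }
      }
    }
  }
  merged
}

segment_id <- function(subject_id, start, end) sprintf("%s:%d-%d", subject_id, start, end)

#' Extract locus sequences from a genome
#'
#' @param genome nucleotide sequence set
#' @param loci locus data.frame
#' @return nucleotide sequence set of segments; ids encode
#'   `subject:start-end` (0-based half-open) and the origin table is
#'   attached as attribute "origin"
#' @export
extract_segments <- function(genome, loci) {
  if (nrow(loci) == 0) {
    out <- seq_set(character(0), "nt")
    attr(out, "origin") <- data.frame(segment_id = character(0), subject_id = character(0),
                                      start = integer(0), end = integer(0))
    return(out)
  }
  stopifnot(all(loci$subject_id %in% names(genome)))
  stopifnot(all(loci$end <= nchar(genome)[loci$subject_id]))
  ids <- segment_id(loci$subject_id, loci$start, loci$end)
  res <- substr(genome[loci$subject_id], loci$start + 1L, loci$end)
  out <- seq_set(setNames(res, ids), "nt")
  attr(out, "origin") <- data.frame(segment_id = ids, subject_id = loci$subject_id,
                                    start = loci$start, end = loci$end,
                                    stringsAsFactors = FALSE)
  out
}

#' Parse class/genus tags from bait headers
#'
#' Bait and RT-panel records carry `class=` (caulimovirid or retroelement)
#' and optional `genus=` tags in their FASTA descriptions.
#'
#' @param seqs protein sequence set
#' @return data.frame (id, class, genus)
#' @export
bait_tags <- function(seqs) {
  desc <- seq_desc(seqs)
  cls <- ifelse(grepl("class=(\\S+)", desc), sub(".*class=(\\S+).*", "\\1", desc), NA_character_)
  gen <- ifelse(grepl("genus=(\\S+)", desc), sub(".*genus=(\\S+).*", "\\1", desc), NA_character_)
  if (any(is.na(cls))) stop("bait records without class= tag: ",
                            paste(head(names(seqs)[is.na(cls)], 3), collapse = ", "))
  data.frame(id = names(seqs), class = cls, genus = gen, stringsAsFactors = FALSE)
}

# best bait hit per segment with deterministic tie-breaking:
# higher score, then longer alignment, then caulimovirid class, then
# lexicographic bait id
best_bait_per_segment <- function(hits, tags) {
  if (nrow(hits) == 0) return(hits)
  cls <- tags$class[match(hits$query_id, tags$id)]
  gen <- tags$genus[match(hits$query_id, tags$id)]
  ord <- order(hits$subject_id, -hits$score, -hits$aln_len,
               cls != "caulimovirid", hits$query_id)
  h <- hits[ord, , drop = FALSE]
  h$bait_class <- cls[ord]; h$bait_genus <- gen[ord]
  h[!duplicated(h$subject_id), , drop = FALSE]
}

#' Competitive bait filtering of extracted segments
#'
#' Each segment is compared in six-frame translation against the mixed
#' bait protein library; a segment is kept if and only if its single
#' highest-scoring bait is tagged caulimovirid. Segments with no bait hit
#' are discarded as unclassifiable.
#'
#' @param segments nucleotide sequence set (see [extract_segments()])
#' @param baits protein sequence set with class/genus header tags
#' @param params search parameter overrides (protein mode)
#' @return the surviving subset of `segments`; the attached "origin" table
#'   gains best-bait columns
#' @export
bait_filter <- function(segments, baits, params = list()) {
  if (length(baits) == 0) stop("bait_filter: empty bait library cannot classify")
  origin <- attr(segments, "origin")
  if (length(segments) == 0) return(segments)
  tags <- bait_tags(baits)
  hits <- search_homology(baits, segments, mode = "aa_vs_txnt", params = params)
  best <- best_bait_per_segment(hits, tags)
  keep_ids <- best$subject_id[best$bait_class == "caulimovirid"]
  kept <- segments[names(segments) %in% keep_ids]
  kept <- seq_set(kept, "nt")
  o <- origin[origin$segment_id %in% keep_ids, , drop = FALSE]
  m <- match(o$segment_id, best$subject_id)
  o$best_bait_id <- best$query_id[m]
  o$best_bait_class <- best$bait_class[m]
  o$best_bait_genus <- best$bait_genus[m]
  o$best_bait_score <- best$score[m]
  rownames(o) <- NULL
  attr(kept, "origin") <- o
  kept
}

#' Extend loci and extract the sub-genome segments
#'
#' Each locus is grown by `X` bp on both sides, clamped to the sequence;
#' loci that come to overlap (or touch) after extension are re-merged
#' before extraction.
#'
#' @param genome nucleotide sequence set
#' @param loci locus data.frame (disjoint, sorted)
#' @param X extension in bp (default 2000)
#' @return sub-genome segments (see [extract_segments()])
#' @export
extend_and_extract <- function(genome, loci, X = 2000L) {
  if (nrow(loci) == 0) return(extract_segments(genome, loci))
  loci$start <- pmax(0L, as.integer(loci$start - X))
  loci$end <- pmin(nchar(genome)[loci$subject_id], as.integer(loci$end + X))
  merged <- merge_nearby(loci, max_gap = 0L)
  extract_segments(genome, merged)
}

#' Build the caulimovirid-enriched sub-genome (Branch A step 1)
#'
#' Composition: translated search of the genome with the viral genome
#' library, hit merging, extraction, competitive bait filtering, merging
#' of nearby loci, extension and final extraction.
#'
#' @param genome nucleotide sequence set
#' @param virus_refs nucleotide viral genome library (queries)
#' @param baits mixed protein bait library with class tags
#' @param config see [eve_config()]
#' @return list with `segments` (sub-genome sequence set), `loci`
#'   (post-filter merged loci) and `raw_loci` (pre-filter)
#' @export
build_subgenome <- function(genome, virus_refs, baits, config = eve_config()) {
  hits <- search_homology(virus_refs, genome, mode = "txnt_vs_txnt",
                          params = config$search_aa)
  raw_loci <- merge_overlapping_hits(hits)
  segs <- extract_segments(genome, raw_loci)
  kept <- bait_filter(segs, baits, params = config$search_aa)
  o <- attr(kept, "origin")
  if (nrow(o) == 0) {
    empty <- extract_segments(genome, empty_loci())
    return(list(segments = empty, loci = empty_loci(), raw_loci = raw_loci))
  }
  loci <- data.frame(subject_id = o$subject_id, start = o$start, end = o$end,
                     n_hits = raw_loci$n_hits[match(segment_id(o$subject_id, o$start, o$end),
                                                    segment_id(raw_loci$subject_id, raw_loci$start, raw_loci$end))],
                     best_bait_id = o$best_bait_id, best_bait_class = o$best_bait_class,
                     best_bait_genus = o$best_bait_genus, best_bait_score = o$best_bait_score,
                     stringsAsFactors = FALSE)
  loci <- loci[order(loci$subject_id, loci$start), , drop = FALSE]
  merged <- merge_nearby(loci, max_gap = config$merge_gap_bp)
  segments <- extend_and_extract(genome, merged, X = config$extension_bp)
  list(segments = segments, loci = merged, raw_loci = raw_loci)
}
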