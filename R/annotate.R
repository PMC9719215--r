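# Branch A step 4: genome-wide annotation with the selected consensus
# library and coverage estimation.

ANN_COLS <- c("subject_id", "start", "end", "strand", "library_id",
              "identity_pct", "score")

empty_annotations <- function() {
  data.frame(subject_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), library_id = character(0),
             identity_pct = numeric(0), score = numeric(0), stringsAsFactors = FALSE)
}

#' Annotate a genome with a repeat library
#'
#' Nucleotide search of every library sequence against the genome.
#' Overlapping hits of the same library sequence on a genome region are
#' merged into one annotation (reporting the best identity and the summed
#' span); overlaps between different library sequences stay separate.
#'
#' @param genome nucleotide sequence set
#' @param library selected consensus sequence set
#' @param min_identity minimum hit identity in percent (default 70)
#' @param min_len minimum hit length in bp (default 80)
#' @param params nucleotide search overrides
#' @return annotation data.frame (subject_id, start, end, strand,
#'   library_id, identity_pct, score)
#' @export
mask_genome <- function(genome, library, min_identity = 70, min_len = 80L,
                        params = list()) {
  if (length(library) == 0) {
    warning("mask_genome: empty library, no annotations")
    return(empty_annotations())
  }
  p <- params
  p$min_identity <- min_identity
  p$min_alnlen <- as.integer(min_len)
  hits <- search_homology(library, genome, mode = "nt_nt", params = p)
  if (nrow(hits) == 0) return(empty_annotations())
  grp <- split(hits, paste(hits$subject_id, hits$query_id, sep = "\r"))
  out <- lapply(grp, function(h) {
    ir <- IRanges::IRanges(start = h$s_start + 1L, end = h$s_end)
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    data.frame(subject_id = h$subject_id[1],
               start = IRanges::start(red) - 1L, end = IRanges::end(red),
               strand = vapply(seq_along(red), function(i) {
                 hh <- h[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == i], , drop = FALSE]
                 hh$strand[which.max(hh$score)]
               }, character(1)),
               library_id = h$query_id[1],
               identity_pct = vapply(seq_along(red), function(i)
                 max(h$identity_pct[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == i]]),
                 numeric(1)),
               score = vapply(seq_along(red), function(i)
                 max(h$score[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == i]]),
                 numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$subject_id, out$start, out$library_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome fraction covered by annotations
#'
#' 100 times the union of annotated positions over the total genome
#' length; bases covered by several annotations count once, so the value
#' is invariant under splitting annotations into adjacent pieces.
#'
#' @param annotations annotation data.frame
#' @param genome nucleotide sequence set
#' @return percentage in `[0, 100]`
#' @export
coverage_percent <- function(annotations, genome) {
  total <- sum(nchar(genome))
  if (total == 0) return(0)
  if (nrow(annotations) == 0) return(0)
  covered <- sum(vapply(split(annotations, annotations$subject_id), function(a) {
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start = a$start + 1L, end = a$end))))
  }, numeric(1)))
  100 * covered / total
}

#' Per-library coverage summary
#'
#' @param annotations annotation data.frame
#' @param genome nucleotide sequence set
#' @return data.frame (library_id, n, bases, coverage_pct) plus a "total" row
#' @export
coverage_summary <- function(annotations, genome) {
  total <- sum(nchar(genome))
  per <- lapply(split(annotations, annotations$library_id), function(a) {
    data.frame(library_id = a$library_id[1], n = nrow(a),
               bases = sum(a$end - a$start),
               coverage_pct = coverage_percent(a, genome), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  if (is.null(per)) per <- data.frame(library_id = character(0), n = integer(0),
                                      bases = integer(0), coverage_pct = numeric(0))
  rbind(per, data.frame(library_id = "total", n = nrow(annotations),
                        bases = sum(annotations$end - annotations$start),
                        coverage_pct = coverage_percent(annotations, genome)))
}

#' Write annotations as GFF3
#'
#' Source "eve-hunter", type "dispersed_repeat", 1-based inclusive
#' coordinates, attributes `Target` and `identity`.
#'
#' @param annotations annotation data.frame
#' @param path output file
#' @export
write_gff3 <- function(annotations, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(annotations)) {
    lines <- sprintf("%s\teve-hunter\tdispersed_repeat\t%d\t%d\t%.1f\t%s\t.\tTarget=%s;identity=%.2f",
                     annotations$subject_id, annotations$start + 1L, annotations$end,
                     annotations$score, annotations$strand, annotations$library_id,
                     annotations$identity_pct)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param df data.frame with subject_id, start, end and optionally a name
#'   column (`library_id` or `name`) and strand
#' @param path output file
#' @export
write_bed <- function(df, path) {
  name <- df$library_id %||% df$name %||% rep(".", nrow(df))
  score <- df$score %||% rep(0, nrow(df))
  strand <- df$strand %||% rep(".", nrow(df))
  lines <- sprintf("%s\t%d\t%d\t%s\t%.0f\t%s", df$subject_id, df$start, df$end,
                   name, score, strand)
  writeLines(lines, path)
  invisible(path)
}
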