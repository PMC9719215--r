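# Built-in seed-and-extend local homology search (the BLAST-family
# stand-in) and global pairwise alignment utilities.
#
# Four comparison modes are provided: nt_nt, aa_aa, aa_vs_txnt (protein
# queries against a six-frame-translated nucleotide subject) and
# txnt_vs_txnt (six-frame against six-frame). Translated modes report
# nucleotide coordinates on the untranslated sequences. Significance is a
# raw score + identity threshold, not an E-value, so results are
# deterministic and independent of database size.

HIT_COLS <- c("query_id", "subject_id", "q_start", "q_end", "s_start", "s_end",
              "strand", "frame_q", "frame_s", "identity_pct", "score",
              "matches", "aln_len")

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             strand = character(0), frame_q = integer(0), frame_s = integer(0),
             identity_pct = numeric(0), score = numeric(0),
             matches = integer(0), aln_len = integer(0),
             stringsAsFactors = FALSE)
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

nt_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      letters <- c("A", "C", "G", "T", "N")
      m <- matrix(-2L, 5, 5, dimnames = list(letters, letters))
      diag(m) <- 1L
      m["N", ] <- -1L
      m[, "N"] <- -1L
      cache <<- m
    }
    cache
  }
})

#' Default scoring and threshold bundle for the search engine
#'
#' Nucleotide searches use exact 11-mer seeds with match +1 / mismatch -2 /
#' gap open -5 / extend -2 and require score >= 40 and identity >= 60%.
#' Protein searches use 4-mer seeds expanded to a BLOSUM62 neighbourhood
#' with score >= 12, two-hit triggering, gap open -11 / extend -1, and
#' require score >= 50 and identity >= 30%. All values can be overridden.
#'
#' @param alphabet "nt" or "aa"
#' @param ... named overrides of individual parameters
#' @return a parameter list consumed by [search_homology()]
#' @export
search_params <- function(alphabet = c("nt", "aa"), ...) {
  alphabet <- match.arg(alphabet)
  p <- if (alphabet == "nt") {
    list(letters = paste(rownames(nt_submat()), collapse = ""),
         submat = nt_submat(), fallback = "N",
         index_letters = 4L, seed_k = 11L,
         neighbor_min = 0L, max_neighbors = 0L,
         two_hit = FALSE, two_hit_window = 0L,
         ungapped_xdrop = 20L, gapped_xdrop = 60L, ungapped_trigger = 30L,
         gap_open = 5L, gap_ext = 2L, max_band = 192L,
         min_score = 40, min_identity = 60, min_alnlen = 1L,
         max_candidates = 50000L)
  } else {
    bl <- blosum62()
    list(letters = paste(rownames(bl), collapse = ""),
         submat = bl, fallback = "X",
         index_letters = 20L, seed_k = 4L,
         neighbor_min = 12L, max_neighbors = 64L,
         two_hit = TRUE, two_hit_window = 40L,
         ungapped_xdrop = 16L, gapped_xdrop = 30L, ungapped_trigger = 40L,
         gap_open = 11L, gap_ext = 1L, max_band = 128L,
         min_score = 50, min_identity = 30, min_alnlen = 1L,
         max_candidates = 50000L)
  }
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over))) over <- over[[1]]
  for (nm in names(over)) {
    if (!nm %in% names(p)) stop("unknown search parameter: ", nm)
    p[[nm]] <- over[[nm]]
  }
  p
}

raw_search <- function(qseqs, sseqs, p) {
  df <- cpp_search(unname(qseqs), unname(sseqs), p)
  df$query_id <- names(qseqs)[df$qi]
  df$subject_id <- names(sseqs)[df$si]
  df
}

# Search many small subject strings as one pooled subject separated by
# 64 X residues (the separator is strongly negative under BLOSUM62 and
# longer than the gapped X-drop allows to cross, so no hit bridges two
# blocks). Amortizes the per-subject index build and the per-query seed
# enumeration; hit coordinates are mapped back to the original blocks.
raw_search_pooled <- function(qseqs, sseqs, p, sep = 64L) {
  lens <- nchar(sseqs)
  starts <- cumsum(c(0L, head(lens + sep, -1L)))
  pooled <- setNames(paste(sseqs, collapse = strrep("X", sep)), "pool")
  df <- cpp_search(unname(qseqs), unname(pooled), p)
  df$query_id <- names(qseqs)[df$qi]
  if (nrow(df)) {
    b <- findInterval(df$s_start, starts)
    ok <- df$s_end <= starts[b] + lens[b]
    df <- df[ok, , drop = FALSE]; b <- b[ok]
    df$s_start <- df$s_start - starts[b]
    df$s_end <- df$s_end - starts[b]
    df$si <- b
    df$subject_id <- names(sseqs)[b]
  } else {
    df$subject_id <- character(0)
  }
  df
}

#' Local homology search
#'
#' Seed-and-extend local alignment of every query against every subject.
#' Hits report 0-based half-open coordinates on the forward strands of the
#' untranslated sequences; `strand` is the subject strand of the match and
#' `frame_q`/`frame_s` give translation frames for translated modes.
#'
#' @param queries,subjects sequence sets (see [seq_set()])
#' @param mode one of "nt_nt", "aa_aa", "aa_vs_txnt", "txnt_vs_txnt"
#' @param params overrides merged onto [search_params()] for the mode's
#'   comparison alphabet
#' @return data.frame of hits sorted by (subject_id, s_start)
#' @export
search_homology <- function(queries, subjects,
                            mode = c("nt_nt", "aa_aa", "aa_vs_txnt", "txnt_vs_txnt"),
                            params = list()) {
  mode <- match.arg(mode)
  qa <- seq_alphabet(queries); sa <- seq_alphabet(subjects)
  want <- switch(mode,
                 nt_nt = c("nt", "nt"), aa_aa = c("aa", "aa"),
                 aa_vs_txnt = c("aa", "nt"), txnt_vs_txnt = c("nt", "nt"))
  if (!identical(c(qa, sa), want))
    stop(sprintf("mode %s expects query=%s subject=%s, got query=%s subject=%s",
                 mode, want[1], want[2], qa, sa))
  if (length(queries) == 0 || length(subjects) == 0) return(empty_hits())
  comparison_alphabet <- if (mode == "nt_nt") "nt" else "aa"
  p <- search_params(comparison_alphabet, params)

  hits <- switch(mode,
    nt_nt = {
      # forward and reverse-complement query passes share one subject index
      nq <- length(queries)
      qrc <- setNames(reverse_complement(queries), paste0(names(queries), "\rrc"))
      both <- c(as.character(queries), qrc)
      names(both) <- c(names(queries), names(qrc))
      out <- raw_search(both, subjects, p)
      isrc <- out$qi > nq
      out$strand <- ifelse(isrc, "-", "+")
      out$query_id <- names(queries)[ifelse(isrc, out$qi - nq, out$qi)]
      if (any(isrc)) {
        qlen <- nchar(queries)[out$query_id[isrc]]
        qs <- qlen - out$q_end[isrc]
        qe <- qlen - out$q_start[isrc]
        out$q_start[isrc] <- qs; out$q_end[isrc] <- qe
      }
      out$frame_q <- rep(NA_integer_, nrow(out))
      out$frame_s <- rep(NA_integer_, nrow(out))
      out
    },
    aa_aa = {
      out <- raw_search(queries, subjects, p)
      out$strand <- rep("+", nrow(out))
      out$frame_q <- rep(NA_integer_, nrow(out))
      out$frame_s <- rep(NA_integer_, nrow(out))
      out
    },
    aa_vs_txnt = {
      sf <- translate_all_frames(subjects)
      sseqs <- setNames(sf$protein, paste0(sf$seq_id, "|", sf$frame))
      keep <- nchar(sseqs) >= p$seed_k
      sf <- sf[keep, , drop = FALSE]; sseqs <- sseqs[keep]
      if (!length(sseqs)) return(empty_hits())
      out <- raw_search_pooled(queries, sseqs, p)
      if (nrow(out)) {
        frame_s <- sf$frame[out$si]
        sid <- sf$seq_id[out$si]
        L <- nchar(subjects)[sid]
        mapped <- mapply(aa_to_nt, frame_s, out$s_start, out$s_end, L)
        out$s_start <- mapped[1, ]; out$s_end <- mapped[2, ]
        out$subject_id <- sid
        out$strand <- ifelse(frame_s > 0, "+", "-")
        out$frame_s <- frame_s
        out$frame_q <- rep(NA_integer_, nrow(out))
      } else { out$strand <- character(0); out$frame_q <- integer(0); out$frame_s <- integer(0) }
      out
    },
    txnt_vs_txnt = {
      qf <- translate_all_frames(queries)
      qseqs <- setNames(qf$protein, paste0(qf$seq_id, "|", qf$frame))
      keepq <- nchar(qseqs) >= p$seed_k
      qf <- qf[keepq, , drop = FALSE]; qseqs <- qseqs[keepq]
      sf <- translate_all_frames(subjects)
      sseqs <- setNames(sf$protein, paste0(sf$seq_id, "|", sf$frame))
      keeps <- nchar(sseqs) >= p$seed_k
      sf <- sf[keeps, , drop = FALSE]; sseqs <- sseqs[keeps]
      if (!length(qseqs) || !length(sseqs)) return(empty_hits())
      out <- raw_search_pooled(qseqs, sseqs, p)
      if (nrow(out)) {
        frame_q <- qf$frame[out$qi]
        qid <- qf$seq_id[out$qi]
        Lq <- nchar(queries)[qid]
        mq <- mapply(aa_to_nt, frame_q, out$q_start, out$q_end, Lq)
        out$q_start <- mq[1, ]; out$q_end <- mq[2, ]
        out$query_id <- qid
        frame_s <- sf$frame[out$si]
        sid <- sf$seq_id[out$si]
        Ls <- nchar(subjects)[sid]
        ms <- mapply(aa_to_nt, frame_s, out$s_start, out$s_end, Ls)
        out$s_start <- ms[1, ]; out$s_end <- ms[2, ]
        out$subject_id <- sid
        out$strand <- ifelse(frame_s > 0, "+", "-")
        out$frame_q <- frame_q; out$frame_s <- frame_s
      } else { out$strand <- character(0); out$frame_q <- integer(0); out$frame_s <- integer(0) }
      out
    })
  hits$strand <- as.character(hits$strand)
  hits <- hits[, HIT_COLS, drop = FALSE]
  hits <- hits[order(hits$subject_id, hits$s_start, hits$query_id, hits$q_start,
                     -hits$score), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Export hits as a 12-column tab-separated table
#'
#' Mirrors the common tabular homology-search layout (query, subject,
#' identity, length, mismatches, gap placeholder, 1-based coordinates,
#' strand, score). Intended for debugging.
#'
#' @param hits data.frame from [search_homology()]
#' @param path output file
#' @export
write_hit_table <- function(hits, path) {
  tab <- data.frame(hits$query_id, hits$subject_id,
                    sprintf("%.2f", hits$identity_pct), hits$aln_len,
                    hits$aln_len - hits$matches, 0L,
                    hits$q_start + 1L, hits$q_end,
                    hits$s_start + 1L, hits$s_end,
                    hits$strand, hits$score)
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Global pairwise alignment with identity and mutual coverage
#'
#' Needleman-Wunsch alignment (BLOSUM62 for proteins; +1/-2 with affine
#' gaps for nucleotides). Identity is matches over alignment columns
#' (pairwise alignments have no dual-gap columns); coverage of a sequence
#' is the fraction of its residues sitting in columns where both
#' sequences have a residue.
#'
#' @param a,b character scalars (or length-1 sequence sets)
#' @param alphabet "nt" or "aa"; defaults to the alphabet attribute of `a`
#' @param type "global" or "overlap" (free end gaps)
#' @return list with identity_pct, coverage_a, coverage_b, score, aln_a, aln_b
#' @export
align_pair <- function(a, b, alphabet = NULL, type = c("global", "overlap")) {
  type <- match.arg(type)
  alphabet <- alphabet %||% seq_alphabet(a)
  a <- as.character(a)[1L]; b <- as.character(b)[1L]
  if (!nzchar(a) || !nzchar(b)) stop("align_pair: empty sequence")
  if (alphabet == "aa") {
    pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(a), Biostrings::AAString(b),
                                        substitutionMatrix = "BLOSUM62",
                                        gapOpening = 11, gapExtension = 1, type = type)
  } else {
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2, baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a), Biostrings::DNAString(b),
                                        substitutionMatrix = sm,
                                        gapOpening = 5, gapExtension = 2, type = type)
  }
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  A <- strsplit(al_a, "", fixed = TRUE)[[1L]]
  B <- strsplit(al_b, "", fixed = TRUE)[[1L]]
  both <- A != "-" & B != "-"
  cols <- sum(A != "-" | B != "-")
  matches <- sum(A == B & both)
  list(identity_pct = if (cols) 100 * matches / cols else 0,
       coverage_a = sum(both) / nchar(a),
       coverage_b = sum(both) / nchar(b),
       score = Biostrings::score(pa),
       aln_a = al_a, aln_b = al_b)
}
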