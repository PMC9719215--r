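# Sequence IO and nucleotide/protein primitives.
#
# Sequences are plain named character vectors (names = record ids, no
# whitespace) carrying an "alphabet" attribute ("nt" or "aa") and an
# optional "desc" attribute with per-record free-text descriptions.
# Coordinates everywhere in the package are 0-based half-open on the
# forward strand; they are converted to 1-based inclusive only when
# writing GFF3.

NT_LETTERS <- "ACGTNRYSWKMBDHV-"   # "-" permitted for aligned FASTA IO
AA_LETTERS <- "ACDEFGHIKLMNPQRSTVWYX*-"

#' Construct a sequence set
#'
#' @param x named character vector of residues (names are record ids)
#' @param alphabet "nt" or "aa"
#' @param desc optional character vector of descriptions (recycled names)
#' @return a validated sequence set (named character vector with attributes)
#' @export
seq_set <- function(x, alphabet = c("nt", "aa"), desc = NULL) {
  alphabet <- match.arg(alphabet)
  if (length(x) && is.null(names(x))) stop("sequence set must be named")
  keep_origin <- attr(x, "origin")
  if (is.null(desc)) desc <- attr(x, "desc")
  nm <- names(x)
  x <- toupper(as.character(x))
  names(x) <- nm
  attr(x, "alphabet") <- alphabet
  if (!is.null(desc)) {
    if (is.null(names(desc))) names(desc) <- nm
    attr(x, "desc") <- as.character(desc[nm])
    names(attr(x, "desc")) <- nm
  }
  if (!is.null(keep_origin)) attr(x, "origin") <- keep_origin
  class(x) <- c("eve_seqs", "character")
  validate_seqs(x)
  x
}

#' @export
`[.eve_seqs` <- function(x, i, ...) {
  out <- NextMethod()
  attr(out, "alphabet") <- attr(x, "alphabet")
  d <- attr(x, "desc")
  if (!is.null(d)) attr(out, "desc") <- d[names(out)]
  class(out) <- class(x)
  out
}

#' @export
print.eve_seqs <- function(x, ...) {
  cat(sprintf("<%s sequence set: %d records>\n", seq_alphabet(x), length(x)))
  n <- min(6L, length(x))
  for (i in seq_len(n)) {
    s <- x[[i]]
    cat(sprintf("  %s (%d): %s%s\n", names(x)[i], nchar(s),
                substr(s, 1, 40), if (nchar(s) > 40) "..." else ""))
  }
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

#' Alphabet and descriptions of a sequence set
#' @param x sequence set
#' @return `seq_alphabet`: "nt" or "aa"; `seq_desc`: named character of
#'   per-record descriptions
#' @export
seq_alphabet <- function(x) attr(x, "alphabet") %||% "nt"

#' @rdname seq_alphabet
#' @export
seq_desc <- function(x) attr(x, "desc") %||% setNames(rep("", length(x)), names(x))

validate_seqs <- function(x) {
  alphabet <- seq_alphabet(x)
  allowed <- if (alphabet == "nt") NT_LETTERS else AA_LETTERS
  if (length(x) == 0) return(invisible(x))
  if (anyDuplicated(names(x))) stop("duplicate sequence ids: ",
                                    paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  if (any(grepl("\\s", names(x)))) stop("sequence ids must not contain whitespace")
  bad <- !grepl(paste0("^[", gsub("\\*", "\\\\*", allowed), "]*$"), x)
  if (any(bad)) {
    i <- which(bad)[1L]
    pos <- regexpr(paste0("[^", gsub("\\*", "\\\\*", allowed), "]"), x[i])
    stop(sprintf("illegal %s residue '%s' in record '%s' at position %d",
                 alphabet, substr(x[i], pos, pos), names(x)[i], as.integer(pos)))
  }
  invisible(x)
}

#' Read a FASTA file
#'
#' Residues are upper-cased and checked against the declared alphabet.
#' Record ids are the first whitespace-delimited token of each header;
#' the remainder is kept as the record description.
#'
#' @param path FASTA file
#' @param alphabet "nt" or "aa"
#' @return sequence set (see [seq_set()])
#' @export
parse_fasta <- function(path, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(seq_set(character(0), alphabet))
  }
  ss <- Biostrings::readBStringSet(path)
  full <- names(ss)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  x <- setNames(toupper(as.character(ss)), ids)
  seq_set(x, alphabet, desc = desc)
}

#' Write a FASTA file
#'
#' @param seqs sequence set
#' @param path output file
#' @param width line wrap width
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  desc <- seq_desc(seqs)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    hdr <- names(seqs)[i]
    if (nzchar(desc[i])) hdr <- paste(hdr, desc[i])
    writeLines(paste0(">", hdr), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0) next
    starts <- seq.int(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Reverse complement of nucleotide sequences
#'
#' IUPAC ambiguity codes are complemented. Applying twice is the identity.
#'
#' @param s character vector of nucleotide sequences (or a sequence set)
#' @return character vector of the same length
#' @export
reverse_complement <- function(s) {
  if (identical(seq_alphabet(s), "aa")) stop("reverse_complement requires nucleotide input")
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(as.character(s))))
  names(out) <- names(s)
  out
}

#' Translate a nucleotide sequence in selected frames
#'
#' Uses the standard genetic code. The trailing partial codon is dropped,
#' stop codons are rendered `*`, and codons containing ambiguity codes are
#' rendered `X` unless all resolutions agree. Minus frames translate the
#' reverse complement.
#'
#' @param s a single nucleotide sequence (character scalar)
#' @param frames subset of c(1, 2, 3, -1, -2, -3)
#' @return named character vector of protein sequences, names "+1".."-3"
#' @export
translate_frames <- function(s, frames = c(1L, 2L, 3L, -1L, -2L, -3L)) {
  if (identical(seq_alphabet(s), "aa")) stop("translate_frames requires nucleotide input")
  s <- as.character(s)[1L]
  stopifnot(all(frames %in% c(1L, 2L, 3L, -1L, -2L, -3L)))
  out <- setNames(character(length(frames)),
                  ifelse(frames > 0, paste0("+", frames), as.character(frames)))
  rc <- if (any(frames < 0))
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))) else NULL
  subs <- character(0); which_f <- integer(0)
  for (i in seq_along(frames)) {
    f <- frames[i]
    src <- if (f > 0) s else rc
    off <- abs(f) - 1L
    n <- nchar(src) - off
    n <- n - (n %% 3L)
    if (n < 3L) next
    subs <- c(subs, substr(src, off + 1L, off + n))
    which_f <- c(which_f, i)
  }
  if (length(subs)) {
    tr <- as.character(Biostrings::translate(Biostrings::DNAStringSet(subs),
                                             if.fuzzy.codon = "solve",
                                             no.init.codon = TRUE))
    out[which_f] <- tr
  }
  out
}

# Translate every sequence of a set in all six frames; returns a data.frame
# (seq_id, frame, protein) used by the translated search modes. Works on
# whole DNAStringSet objects so the per-call S4 overhead is paid six
# times, not six times per record.
translate_all_frames <- function(seqs) {
  fwd <- Biostrings::DNAStringSet(as.character(seqs))
  rev <- Biostrings::reverseComplement(fwd)
  res <- vector("list", 6)
  k <- 0
  for (f in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    src <- if (f > 0) fwd else rev
    off <- abs(f) - 1L
    w <- pmax(Biostrings::width(src) - off, 0L)
    w <- w - (w %% 3L)
    prot <- rep("", length(seqs))
    ok <- w >= 3L
    if (any(ok)) {
      sub <- Biostrings::subseq(src[ok], start = off + 1L, width = w[ok])
      prot[ok] <- as.character(Biostrings::translate(sub, if.fuzzy.codon = "solve",
                                                     no.init.codon = TRUE))
    }
    k <- k + 1
    res[[k]] <- data.frame(seq_id = names(seqs), frame = f, protein = prot,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out[order(match(out$seq_id, names(seqs)), abs(out$frame), -sign(out$frame)), ,
      drop = FALSE]
}

# Map an amino-acid interval [aa_start, aa_end) on a translation frame back
# to 0-based half-open nucleotide coordinates on the forward strand of the
# untranslated sequence of length L.
aa_to_nt <- function(frame, aa_start, aa_end, L) {
  off <- abs(frame) - 1L
  ntb <- off + 3L * aa_start
  nte <- off + 3L * aa_end
  if (frame > 0) c(ntb, nte) else c(L - nte, L - ntb)
}
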