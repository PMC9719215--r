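# Branch A step 3: characterize, filter, classify and cluster consensus
# sequences.
#
# Conserved protein domains are detected with bundled consensus-pattern
# profiles (simplified position-specific models scored with BLOSUM62 by
# local alignment of the profile consensus against all six frames).
# Consensi carrying a TE-specific domain (integrase, transposase) are
# chimera-filtered; best-hit comparison against the baits library gives a
# preliminary genus classification; identity/coverage single-linkage
# clustering groups redundant records and bipartite genome components.

#' Bundled domain profile set
#'
#' Simplified consensus-pattern models for the domains relevant to
#' caulimovirid/TE discrimination: RT core (with the YxDD motif), RNase H,
#' aspartyl protease, movement protein, Gag-like zinc finger (CCHC),
#' integrase and transposase. Each profile carries a class
#' (caulimovirid_associated, te_specific or shared) and a score cutoff
#' calibrated so that random sequence rarely fires.
#'
#' @return list with `seqs` (protein sequence set) and `meta`
#'   (data.frame name, klass, cutoff)
#' @export
domain_profiles <- function() {
  faa <- system.file("extdata", "domain_profiles.faa", package = "evehunter")
  tsv <- system.file("extdata", "domain_classes.tsv", package = "evehunter")
  seqs <- parse_fasta(faa, "aa")
  meta <- read.table(tsv, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(names(seqs) %in% meta$name))
  list(seqs = seqs, meta = meta)
}

#' Scan a nucleotide record for conserved protein domains
#'
#' All six frames are compared against every profile; hits above the
#' per-profile cutoff are kept and made non-overlapping per frame by
#' greedy best-score selection. Coordinates are amino-acid positions on
#' the reported frame.
#'
#' @param record single nucleotide sequence (named character of length 1)
#' @param profiles see [domain_profiles()]
#' @param params protein search overrides
#' @return data.frame (name, start, end, frame, score, klass)
#' @export
scan_domains <- function(record, profiles = domain_profiles(), params = list()) {
  if (length(profiles$seqs) == 0) stop("scan_domains: empty profile set")
  if (is.null(names(record))) names(record) <- "record"
  rec <- seq_set(setNames(as.character(record), names(record)), "nt")
  p <- params
  p$min_score <- min(profiles$meta$cutoff)
  hits <- search_homology(profiles$seqs, rec, mode = "aa_vs_txnt", params = p)
  out <- data.frame(name = character(0), start = integer(0), end = integer(0),
                    frame = integer(0), score = numeric(0), klass = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(out)
  cut <- profiles$meta$cutoff[match(hits$query_id, profiles$meta$name)]
  hits <- hits[hits$score >= cut, , drop = FALSE]
  if (nrow(hits) == 0) return(out)
  # back to aa coordinates on the frame
  L <- nchar(rec[[1]])
  f <- hits$frame_s
  off <- abs(f) - 1L
  aa_start <- ifelse(f > 0, (hits$s_start - off) / 3, (L - hits$s_end - off) / 3)
  aa_end <- ifelse(f > 0, (hits$s_end - off) / 3, (L - hits$s_start - off) / 3)
  dom <- data.frame(name = hits$query_id, start = as.integer(aa_start),
                    end = as.integer(aa_end), frame = f, score = hits$score,
                    stringsAsFactors = FALSE)
  dom$klass <- profiles$meta$klass[match(dom$name, profiles$meta$name)]
  # greedy non-overlapping per frame
  dom <- dom[order(-dom$score, dom$name, dom$frame, dom$start), , drop = FALSE]
  kept <- rep(FALSE, nrow(dom))
  for (i in seq_len(nrow(dom))) {
    sel <- which(kept & dom$frame == dom$frame[i])
    clash <- any(dom$start[sel] < dom$end[i] & dom$end[sel] > dom$start[i])
    if (!clash) kept[i] <- TRUE
  }
  dom <- dom[kept, , drop = FALSE]
  dom <- dom[order(dom$frame, dom$start), , drop = FALSE]
  rownames(dom) <- NULL
  dom
}

#' Scan a whole consensus library for domains
#'
#' @param consensi nucleotide sequence set
#' @param profiles see [domain_profiles()]
#' @param params protein search overrides
#' @return data.frame with a `record_id` column prepended to the
#'   [scan_domains()] output
#' @export
scan_domains_all <- function(consensi, profiles = domain_profiles(), params = list()) {
  res <- lapply(names(consensi), function(id) {
    d <- scan_domains(consensi[id], profiles, params)
    if (nrow(d)) cbind(record_id = id, d, stringsAsFactors = FALSE) else NULL
  })
  res <- do.call(rbind, res)
  if (is.null(res)) res <- data.frame(record_id = character(0), name = character(0),
                                      start = integer(0), end = integer(0),
                                      frame = integer(0), score = numeric(0),
                                      klass = character(0), stringsAsFactors = FALSE)
  res
}

#' Remove chimeric consensi carrying TE-specific domains
#'
#' @param consensi nucleotide sequence set
#' @param domains data.frame from [scan_domains_all()]
#' @param enabled when FALSE, pass-through (option `-ch`)
#' @return the surviving subset of `consensi`
#' @export
filter_chimeras <- function(consensi, domains, enabled = TRUE) {
  if (!enabled || length(consensi) == 0) return(consensi)
  bad <- unique(domains$record_id[domains$klass == "te_specific"])
  seq_set(consensi[!names(consensi) %in% bad], "nt")
}

#' Best-hit classification of consensi against the baits library
#'
#' Six-frame comparison of each consensus against the bait proteins; the
#' highest-scoring bait (ties broken as in [bait_filter()]) provides a
#' preliminary class and genus. Records whose best hit is a retroelement
#' protein, or with no hit, are flagged non-caulimovirid.
#'
#' @param consensi nucleotide sequence set
#' @param baits protein sequence set with class/genus tags
#' @param params protein search overrides
#' @return data.frame (id, best_bait_id, class, genus, score); class is
#'   "none" for records without any bait hit
#' @export
classify_best_hit <- function(consensi, baits, params = list()) {
  out <- data.frame(id = names(consensi), best_bait_id = NA_character_,
                    class = "none", genus = NA_character_, score = NA_real_,
                    stringsAsFactors = FALSE)
  if (length(consensi) == 0 || length(baits) == 0) return(out)
  tags <- bait_tags(baits)
  hits <- search_homology(baits, consensi, mode = "aa_vs_txnt", params = params)
  best <- best_bait_per_segment(hits, tags)
  m <- match(out$id, best$subject_id)
  hit <- !is.na(m)
  out$best_bait_id[hit] <- best$query_id[m[hit]]
  out$class[hit] <- best$bait_class[m[hit]]
  out$genus[hit] <- best$bait_genus[m[hit]]
  out$score[hit] <- best$score[m[hit]]
  out
}

#' Identity/coverage single-linkage clustering
#'
#' Two sequences are linked if a global pairwise alignment reaches
#' identity >= S and coverage >= L (of both sequences by default, or of
#' either/the shorter one); clusters are the connected components of the
#' link relation, so the partition is independent of input order.
#'
#' @param seqs nucleotide (or protein) sequence set
#' @param S identity threshold in percent (default 90)
#' @param L coverage threshold as a fraction (default 0.9)
#' @param coverage_rule "both" (default), "either" or "shorter"
#' @return data.frame (id, cluster_id); cluster ids are assigned by the
#'   lexicographically smallest member id
#' @export
cluster_identity_coverage <- function(seqs, S = 90, L = 0.9,
                                      coverage_rule = c("both", "either", "shorter")) {
  coverage_rule <- match.arg(coverage_rule)
  ids <- names(seqs)
  n <- length(seqs)
  if (n == 0) return(data.frame(id = character(0), cluster_id = character(0)))
  parent <- seq_len(n)
  union2 <- function(a, b) {
    ra <- uf_find(parent, a); rb <- uf_find(parent, b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    invisible(NULL)
  }
  len <- nchar(seqs)
  alphabet <- seq_alphabet(seqs)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ratio <- min(len[i], len[j]) / max(len[i], len[j])
        if (coverage_rule == "both" && ratio < L) next  # longer one cannot reach L
        # the shorter-sequence rule mirrors local-alignment clustering
        # (an embedded sequence must be able to link its container), so
        # end gaps are free there; the both-sequence rule is end-to-end
        aln_type <- if (coverage_rule == "shorter") "overlap" else "global"
        al <- align_pair(seqs[[i]], seqs[[j]], alphabet = alphabet, type = aln_type)
        if (alphabet == "nt") {
          # strand-agnostic linking: consensus orientation is arbitrary
          rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(seqs[[j]])))
          al2 <- align_pair(seqs[[i]], rc, alphabet = "nt", type = aln_type)
          if (al2$identity_pct * min(al2$coverage_a, al2$coverage_b) >
                al$identity_pct * min(al$coverage_a, al$coverage_b)) al <- al2
        }
        covs <- c(al$coverage_a, al$coverage_b)
        cov_ok <- switch(coverage_rule,
                         both = all(covs >= L),
                         either = any(covs >= L),
                         shorter = covs[which.min(c(len[i], len[j]))] >= L)
        if (al$identity_pct >= S && cov_ok) union2(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  rep_id <- vapply(split(ids, roots), function(v) min(v), character(1))
  cluster_of <- rep_id[as.character(roots)]
  uniq <- sort(unique(cluster_of))
  lab <- setNames(sprintf("CL%03d", seq_along(uniq)), uniq)
  data.frame(id = ids, cluster_id = unname(lab[cluster_of]), stringsAsFactors = FALSE)
}

#' Select the output consensus library
#'
#' By default, records whose best bait hit is caulimovirid are selected.
#' With supplementation, all members of any cluster containing at least
#' one such record are selected as well. Redundant records are
#' intentionally kept (structural variants and bipartite components).
#'
#' @param clusters data.frame from [cluster_identity_coverage()]
#' @param classification data.frame from [classify_best_hit()]
#' @param supplementation option `-bl` (default FALSE)
#' @return character vector of selected record ids
#' @export
select_library <- function(clusters, classification, supplementation = FALSE) {
  caul <- classification$id[classification$class == "caulimovirid"]
  if (!supplementation) return(sort(caul))
  cl <- clusters$cluster_id[match(caul, clusters$id)]
  sort(unique(clusters$id[clusters$cluster_id %in% cl]))
}

#' Flag concatemeric consensi
#'
#' Self-comparison of a record; an off-main-diagonal hit of at least
#' `min_hit` bp at `min_identity` or better implies two or more tandem
#' copies of a unit. The monomer length is the diagonal offset of the
#' best such hit.
#'
#' @param record single nucleotide sequence
#' @param min_len records shorter than this are never flagged (default 2000)
#' @param min_hit minimum off-diagonal hit length (default 1000)
#' @param min_identity minimum off-diagonal hit identity (default 90)
#' @param params nucleotide search overrides
#' @return list(concatemer = flag, monomer_length, monomer_span)
#' @export
flag_concatemers <- function(record, min_len = 2000L, min_hit = 1000L,
                             min_identity = 90, params = list()) {
  res <- list(concatemer = FALSE, monomer_length = NA_integer_, monomer_span = NULL)
  if (nchar(record[[1]]) < min_len) return(res)
  if (is.null(names(record))) names(record) <- "record"
  rec <- seq_set(setNames(as.character(record), names(record)[1]), "nt")
  hits <- search_homology(rec, rec, mode = "nt_nt", params = params)
  if (nrow(hits) == 0) return(res)
  off <- abs(hits$s_start - hits$q_start)
  cand <- hits$strand == "+" & off >= 200 & hits$aln_len >= min_hit &
    hits$identity_pct >= min_identity
  if (!any(cand)) return(res)
  h <- hits[cand, , drop = FALSE]
  h <- h[order(-h$score, h$q_start), , drop = FALSE][1, ]
  unit <- abs(h$s_start - h$q_start)
  a <- min(h$q_start, h$s_start)
  res$concatemer <- TRUE
  res$monomer_length <- as.integer(unit)
  res$monomer_span <- c(a, a + unit)
  res
}
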