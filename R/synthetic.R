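# Synthetic fixture generator and evaluator: ancestral caulimovirid-like
# genomes and Gypsy-like decoys built from the bundled domain profiles,
# planting of mutationally decayed copies into an i.i.d. background, the
# 85/85 benchmark clustering, and recovery scoring against ground truth.

random_nt <- function(n, gc = 0.36) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)), collapse = "")
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

mutate_aa <- function(s, d) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < d)
  for (i in hit) v[i] <- sample(setdiff(AA20, v[i]), 1)
  paste(v, collapse = "")
}

#' Mutate a nucleotide sequence
#'
#' Per-site substitutions at the given rate plus indels at 10% of the
#' substitution rate with geometric lengths (mean 2).
#'
#' @param s nucleotide string
#' @param divergence substitution rate (fraction, e.g. 0.1)
#' @param indel_frac indel rate as a fraction of the substitution rate
#' @return mutated string
#' @export
mutate_nt <- function(s, divergence, indel_frac = 0.1) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < divergence)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  pos <- which(runif(length(v)) < divergence * indel_frac)
  for (p in rev(pos)) {
    L <- rgeom(1, 0.5) + 1L
    if (runif(1) < 0.5) {
      v <- v[-(p:min(length(v), p + L - 1L))]
    } else {
      v <- append(v, sample(c("A", "C", "G", "T"), L, replace = TRUE), after = p)
    }
  }
  paste(v, collapse = "")
}

codon_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc), unname(gc))
    }
    cache
  }
})

reverse_translate <- function(aa) {
  tab <- codon_table()
  v <- strsplit(aa, "", fixed = TRUE)[[1]]
  paste(vapply(v, function(x) {
    cods <- tab[[x]]
    if (is.null(cods)) cods <- tab[["X"]] %||% "NNN"
    if (length(cods) == 1) cods else sample(cods, 1)
  }, character(1)), collapse = "")
}

#' Default ancestor specifications
#'
#' Viral ancestors are 7.5 kb with a Gag-Pol-like polyprotein ORF
#' (MP-AP-RT_core-RNaseH-zf_CCHC plus genus-specific filler); the Gypsy
#' decoy is 5 kb with RT_core-RNaseH-integrase. Bipartite components
#' carry the full cassette (A) or only the terminal MP/zinc-finger region
#' (B) and share a configurable region.
#'
#' @param n_viral number of viral genera (default 3)
#' @param decoy include the Gypsy-like decoy (default TRUE)
#' @param bipartite include a bipartite A/B pair (default FALSE)
#' @return list of specification lists
#' @export
default_ancestor_specs <- function(n_viral = 3L, decoy = TRUE, bipartite = FALSE) {
  specs <- lapply(seq_len(n_viral), function(i) {
    list(id = sprintf("virus_G%d", i), kind = "caulimovirid",
         genus = sprintf("G%d", i), length = 7500L,
         orf_layout = c("MP", "AP", "RT_core", "RNaseH", "zf_CCHC"),
         filler_aa = 1200L, divergence_from_profile = 0.18)
  })
  if (bipartite) {
    specs <- c(specs, list(
      list(id = "bipartite_A", kind = "bipartite_A", genus = "GB", length = 7500L,
           orf_layout = c("MP", "AP", "RT_core", "RNaseH"), filler_aa = 1000L,
           divergence_from_profile = 0.18),
      list(id = "bipartite_B", kind = "bipartite_B", genus = "GB", length = 7500L,
           orf_layout = c("MP", "zf_CCHC"), filler_aa = 0L,
           divergence_from_profile = 0.18, partner = "bipartite_A",
           shared_region = 500L)))
  }
  if (decoy) {
    specs <- c(specs, list(
      list(id = "gypsy_decoy", kind = "gypsy_decoy", genus = "gypsy", length = 5000L,
           orf_layout = c("RT_core", "RNaseH", "integrase"), filler_aa = 600L,
           divergence_from_profile = 0.18)))
  }
  specs
}

#' Generate ancestral genomes, bait library and RT reference panel
#'
#' Each ancestor embeds a readable ORF whose domain segments are mutated
#' copies of the bundled profile consensus sequences (so they score on
#' their assigned profiles); viral ancestors never carry a TE-specific
#' token. The matching protein bait library (class/genus-tagged), the RT
#' reference panel (one RT per genus plus retroelement outgroups) and the
#' viral genome library are emitted alongside.
#'
#' @param specs see [default_ancestor_specs()]
#' @param seed RNG seed
#' @return list with `genomes`, `baits`, `rt_panel`, `rt_probes`,
#'   `proteins` (per-ancestor domain proteins), `specs`
#' @export
make_ancestors <- function(specs = default_ancestor_specs(), seed = 1L) {
  profs <- domain_profiles()
  te_tokens <- profs$meta$name[profs$meta$klass == "te_specific"]
  for (sp in specs) {
    if (sp$kind %in% c("caulimovirid", "bipartite_A", "bipartite_B") &&
        any(sp$orf_layout %in% te_tokens))
      stop("viral ancestor spec ", sp$id, " requests a TE-specific domain token")
  }
  set.seed(seed)
  genomes <- character(0); gdesc <- character(0)
  baits <- character(0); bdesc <- character(0)
  panel <- character(0); pdesc <- character(0)
  proteins <- list()
  for (sp in specs) {
    div <- sp$divergence_from_profile %||% 0.18
    viral <- sp$kind != "gypsy_decoy"
    cls <- if (viral) "caulimovirid" else "retroelement"
    doms <- lapply(sp$orf_layout, function(tok) mutate_aa(profs$seqs[[tok]], div))
    names(doms) <- sp$orf_layout
    # genus-specific filler is distributed BETWEEN the conserved domains,
    # mirroring real caulimovirid organisation (movement protein near the
    # 5' end, Gag-like and Pol domains spread across the genome)
    nf <- max(1L, length(doms) - 1L)
    per_gap <- as.integer((sp$filler_aa %||% 0L) / nf)
    pieces <- character(0)
    for (di in seq_along(doms)) {
      pieces <- c(pieces, doms[[di]], random_aa(10))
      if (di < length(doms) && per_gap > 0) pieces <- c(pieces, random_aa(per_gap))
    }
    poly <- paste0("M", paste(pieces, collapse = ""))
    orf_nt <- paste0(reverse_translate(poly), "TAA")
    pre <- 400L
    post <- sp$length - pre - nchar(orf_nt)
    if (post < 0) stop("ancestor ", sp$id, " too short for its ORF")
    genome <- paste0(random_nt(pre), orf_nt, random_nt(post))
    genomes <- c(genomes, setNames(genome, sp$id))
    gdesc <- c(gdesc, sprintf("kind=%s genus=%s", sp$kind, sp$genus))
    # baits: full polyprotein + each domain protein
    ids <- c(sprintf("%s_poly", sp$id), sprintf("%s_%s", sp$id, names(doms)))
    sqs <- c(poly, unlist(doms))
    baits <- c(baits, setNames(sqs, ids))
    bdesc <- c(bdesc, rep(sprintf("class=%s genus=%s", cls, sp$genus), length(ids)))
    proteins[[sp$id]] <- setNames(unlist(doms), names(doms))
    if ("RT_core" %in% names(doms)) {
      pid <- sprintf("REF_%s_RT", sp$genus)
      if (!pid %in% names(panel)) {
        panel <- c(panel, setNames(doms[["RT_core"]], pid))
        pdesc <- c(pdesc, sprintf("class=%s genus=%s", cls,
                                  if (viral) sp$genus else "outgroup"))
      }
    }
  }
  # additional independent retroelement-like outgroup RT
  panel <- c(panel, setNames(mutate_aa(profs$seqs[["RT_core"]], 0.30), "REF_retro_RT"))
  pdesc <- c(pdesc, "class=retroelement genus=outgroup")
  # bipartite shared regions
  ids <- names(genomes)
  for (sp in specs) {
    if (!is.null(sp$partner)) {
      sh <- sp$shared_region %||% 500L
      src <- genomes[[sp$partner]]
      piece <- substr(src, nchar(src) - sh + 1L, nchar(src))
      g <- genomes[[sp$id]]
      genomes[[sp$id]] <- paste0(substr(g, 1, nchar(g) - sh), piece)
    }
  }
  gset <- seq_set(genomes, "nt", desc = gdesc)
  bset <- seq_set(baits, "aa", desc = bdesc)
  pset <- seq_set(panel, "aa", desc = pdesc)
  probes <- pset[grepl("^REF_G", names(pset))]
  list(genomes = gset, baits = bset, rt_panel = pset,
       rt_probes = seq_set(probes, "aa",
                           desc = seq_desc(pset)[names(probes)]),
       proteins = proteins, specs = specs)
}

#' Default copy plan for the standard synthetic benchmark genome
#'
#' For each viral ancestor: ten full copies spanning 5-15% divergence with
#' a burst-plus-tail age structure (a recent integration cohort at 5-7.5%
#' and an older tail at 10-15%, the standard demography of an EVE family
#' and the only structure under which at least `hsp_min` copies stay
#' mutually linkable at the 85% repeat-discovery threshold), plus five
#' fragments at 8%; the first viral ancestor additionally gets one triple
#' tandem at 5%. The Gypsy decoy gets thirty full copies at 10%. One row
#' per planted element.
#'
#' @param ancestors ancestor sequence set (viral ids start with "virus_")
#' @return copy plan data.frame for [plant_elements()]
#' @export
default_copy_plan <- function(ancestors) {
  viral <- names(ancestors)[grepl("^virus_", names(ancestors))]
  decoy <- names(ancestors)[grepl("decoy", names(ancestors))]
  rows <- list()
  for (v in viral) {
    rows[[length(rows) + 1L]] <- data.frame(
      ancestor_id = v, n_full = 1L, n_fragment = 0L, n_tandem = 0L,
      tandem_k = 3L, divergence = c(5, 5.5, 6, 6.5, 7, 7.5, 10, 12, 14, 15))
    rows[[length(rows) + 1L]] <- data.frame(
      ancestor_id = v, n_full = 0L, n_fragment = 1L, n_tandem = 0L,
      tandem_k = 3L, divergence = rep(8, 5))
  }
  if (length(viral)) {
    rows[[length(rows) + 1L]] <- data.frame(
      ancestor_id = viral[1], n_full = 0L, n_fragment = 0L, n_tandem = 1L,
      tandem_k = 3L, divergence = 5)
  }
  for (d in decoy) {
    rows[[length(rows) + 1L]] <- data.frame(
      ancestor_id = d, n_full = 1L, n_fragment = 0L, n_tandem = 0L,
      tandem_k = 3L, divergence = rep(10, 30))
  }
  do.call(rbind, rows)
}

#' Plant decayed element copies into a synthetic background genome
#'
#' The background is i.i.d. nucleotide sequence at the requested GC.
#' Copies are substituted/indel-mutated ([mutate_nt()]); fragments are
#' uniform random sub-spans of 20-60% length; tandems are `tandem_k`
#' concatenated copies mutated as one element. Both strands are used and
#' insertions never overlap. The returned truth table is exact.
#'
#' @param background_len background length in bp
#' @param gc background GC fraction (default 0.36)
#' @param ancestors nucleotide sequence set of ancestor genomes
#' @param copy_plan data.frame with columns ancestor_id, n_full,
#'   n_fragment, n_tandem, tandem_k, divergence (percent)
#' @param seed RNG seed
#' @return list(genome, truth); truth columns: element_id, ancestor_id,
#'   start, end, strand, form, divergence
#' @export
plant_elements <- function(background_len, gc = 0.36, ancestors, copy_plan, seed = 1L) {
  set.seed(seed)
  elems <- character(0)
  meta <- list()
  k <- 0L
  for (r in seq_len(nrow(copy_plan))) {
    aid <- copy_plan$ancestor_id[r]
    anc <- ancestors[[aid]]
    d <- copy_plan$divergence[r] / 100
    tk <- copy_plan$tandem_k[r] %||% 3L
    if (is.na(tk)) tk <- 3L
    mk <- function(form) {
      k <<- k + 1L
      base <- switch(form,
                     full = anc,
                     fragment = {
                       flen <- round(nchar(anc) * runif(1, 0.2, 0.6))
                       a0 <- sample.int(nchar(anc) - flen + 1L, 1)
                       substr(anc, a0, a0 + flen - 1L)
                     },
                     tandem = paste(rep(anc, tk), collapse = ""))
      s <- mutate_nt(base, d)
      strand <- if (runif(1) < 0.5) "+" else "-"
      if (strand == "-") s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      elems[[length(elems) + 1L]] <<- s
      meta[[length(meta) + 1L]] <<- data.frame(
        element_id = sprintf("elem_%03d", k), ancestor_id = aid,
        strand = strand, form = if (form == "tandem") sprintf("tandem_%d", tk) else form,
        divergence = copy_plan$divergence[r], stringsAsFactors = FALSE)
      invisible(NULL)
    }
    for (i in seq_len(copy_plan$n_full[r] %||% 0)) mk("full")
    for (i in seq_len(copy_plan$n_fragment[r] %||% 0)) mk("fragment")
    for (i in seq_len(copy_plan$n_tandem[r] %||% 0)) mk("tandem")
  }
  total <- sum(nchar(elems))
  if (total >= background_len / 2)
    stop("plant_elements: planted length must stay below half the background")
  bg <- random_nt(background_len, gc)
  n <- length(elems)
  if (n == 0) {
    empty <- data.frame(element_id = character(0), ancestor_id = character(0),
                        start = integer(0), end = integer(0), strand = character(0),
                        form = character(0), divergence = numeric(0))
    return(list(genome = seq_set(c(chr1 = bg), "nt"), truth = empty))
  }
  # distinct insertion points with a minimal separation
  ok <- FALSE
  for (try in seq_len(50)) {
    pts <- sort(sample.int(background_len - 1L, n))
    if (n < 2 || min(diff(pts)) >= 100L) { ok <- TRUE; break }
  }
  if (!ok) stop("plant_elements: could not place elements without overlap")
  pieces <- character(2 * n + 1)
  truth <- do.call(rbind, meta)
  starts <- integer(n); prev <- 0L; off <- 0L
  for (i in seq_len(n)) {
    pieces[2 * i - 1] <- substr(bg, prev + 1L, pts[i])
    pieces[2 * i] <- elems[[i]]
    starts[i] <- pts[i] + off
    off <- off + nchar(elems[[i]])
    prev <- pts[i]
  }
  pieces[2 * n + 1] <- substr(bg, prev + 1L, background_len)
  genome <- paste(pieces, collapse = "")
  truth$start <- starts
  truth$end <- starts + nchar(unlist(elems))
  truth <- truth[, c("element_id", "ancestor_id", "start", "end", "strand",
                     "form", "divergence")]
  list(genome = seq_set(c(chr1 = genome), "nt"), truth = truth)
}

#' Benchmark clustering of pipeline output against reference sequences
#'
#' Combines output and reference sequences and clusters them at the
#' benchmark settings (85% identity, 85% coverage of the target/shorter
#' sequence). Reports, per reference, whether its cluster contains at
#' least one output sequence, plus the singleton list.
#'
#' @param output_seqs,reference_seqs nucleotide sequence sets
#' @param identity identity threshold (default 85)
#' @param coverage coverage threshold on the shorter sequence (default 0.85)
#' @return list(assignments, per_reference, singletons)
#' @export
benchmark_cluster <- function(output_seqs, reference_seqs, identity = 85,
                              coverage = 0.85) {
  combined <- seq_set(c(unclass(output_seqs), unclass(reference_seqs))[
    unique(c(names(output_seqs), names(reference_seqs)))], "nt")
  cl <- cluster_identity_coverage(combined, S = identity, L = coverage,
                                  coverage_rule = "shorter")
  per_ref <- do.call(rbind, lapply(names(reference_seqs), function(rid) {
    cid <- cl$cluster_id[cl$id == rid]
    mates <- cl$id[cl$cluster_id == cid & cl$id != rid]
    data.frame(reference = rid, cluster_id = cid,
               co_clustered = any(mates %in% names(output_seqs)),
               stringsAsFactors = FALSE)
  }))
  sizes <- table(cl$cluster_id)
  singletons <- cl$id[cl$cluster_id %in% names(sizes)[sizes == 1]]
  list(assignments = cl, per_reference = per_ref, singletons = singletons)
}

#' Score pipeline recovery against the planted truth
#'
#' A planted element is recovered when a single annotation overlaps at
#' least half of its span. When consensi and ancestors are supplied, the
#' best consensus per ancestor is reported with its identity to the
#' ancestor and the fraction of the ancestor covered (free-end-gap
#' alignment).
#'
#' @param truth truth table from [plant_elements()]
#' @param annotations annotation data.frame (optional)
#' @param consensi consensus sequence set (optional)
#' @param ancestors ancestor sequence set (required with `consensi`)
#' @return list with `sensitivity`, `per_element`, and optionally
#'   `per_ancestor`
#' @export
score_recovery <- function(truth, annotations = NULL, consensi = NULL,
                           ancestors = NULL) {
  out <- list()
  if (!is.null(annotations)) {
    rec <- vapply(seq_len(nrow(truth)), function(i) {
      if (nrow(annotations) == 0) return(0)
      ov <- pmin(annotations$end, truth$end[i]) - pmax(annotations$start, truth$start[i])
      max(0, max(ov)) / (truth$end[i] - truth$start[i])
    }, numeric(1))
    out$per_element <- data.frame(element_id = truth$element_id,
                                  best_overlap = rec,
                                  recovered = rec >= 0.5, stringsAsFactors = FALSE)
    out$sensitivity <- mean(rec >= 0.5)
  }
  if (!is.null(consensi) && length(consensi) && !is.null(ancestors)) {
    out$per_ancestor <- do.call(rbind, lapply(names(ancestors), function(aid) {
      best <- NULL
      for (cid in names(consensi)) {
        # consensus orientation is arbitrary: score both strands
        al1 <- align_pair(consensi[[cid]], ancestors[[aid]], alphabet = "nt",
                          type = "overlap")
        rc <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(consensi[[cid]])))
        al2 <- align_pair(rc, ancestors[[aid]], alphabet = "nt", type = "overlap")
        al <- if (al1$identity_pct * al1$coverage_b >= al2$identity_pct * al2$coverage_b)
          al1 else al2
        cand <- data.frame(ancestor_id = aid, consensus_id = cid,
                           identity_pct = al$identity_pct,
                           ancestor_coverage = al$coverage_b, stringsAsFactors = FALSE)
        if (is.null(best) || cand$identity_pct * cand$ancestor_coverage >
              best$identity_pct * best$ancestor_coverage)
          best <- cand
      }
      best
    }))
  }
  out
}
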