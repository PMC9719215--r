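# Stage orchestration for both branches: compose the module operations,
# write every declared output file and a run manifest with per-stage
# record counts, and terminate cleanly on empty intermediate results.

manifest_new <- function(command, config, inputs, seed) {
  digests <- lapply(inputs, function(p)
    if (is.character(p) && length(p) == 1 && file.exists(p))
      unname(tools::md5sum(p)) else NA_character_)
  list(command = command, config = config[order(names(config))],
       inputs = digests, seed = seed, stages = list(), outputs = character(0))
}

manifest_stage <- function(man, name, n_in, n_out) {
  man$stages[[name]] <- list(n_in = n_in, n_out = n_out)
  man
}

manifest_write <- function(man, outdir) {
  path <- file.path(outdir, "manifest.json")
  man$outputs <- sort(man$outputs)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

as_input <- function(x, alphabet) {
  if (is.character(x) && length(x) == 1 && file.exists(x) && is.null(attr(x, "alphabet")))
    parse_fasta(x, alphabet) else x
}

#' Run Branch A: locate, reconstruct, classify, annotate
#'
#' Executes the four-step workflow and writes the sub-genome FASTA,
#' consensus library FASTA, selected library FASTA, per-consensus summary
#' TSV, GFF3/BED annotation, coverage report and a run manifest to
#' `outdir`. Empty intermediate results terminate cleanly with a
#' "no candidate loci" status and empty outputs.
#'
#' @param genome genome FASTA path or nucleotide sequence set
#' @param virus_refs viral genome library (path or sequence set)
#' @param baits mixed protein bait library with class/genus tags
#' @param outdir output directory (created)
#' @param config see [eve_config()]
#' @return invisibly, a list with all intermediate results and `status`
#' @export
run_branch_a <- function(genome, virus_refs, baits, outdir,
                         config = eve_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  man <- manifest_new("branch-a", config,
                      list(genome = if (is.character(genome) && length(genome) == 1) genome else NA,
                           virus_refs = if (is.character(virus_refs) && length(virus_refs) == 1) virus_refs else NA,
                           baits = if (is.character(baits) && length(baits) == 1) baits else NA),
                      config$seed)
  genome <- as_input(genome, "nt")
  virus_refs <- as_input(virus_refs, "nt")
  baits <- as_input(baits, "aa")
  set.seed(config$seed)

  sg <- build_subgenome(genome, virus_refs, baits, config)
  man <- manifest_stage(man, "locate", length(virus_refs), length(sg$segments))
  write_fasta(sg$segments, file.path(outdir, "subgenome.fasta"))
  if (nrow(sg$loci)) write_bed(data.frame(subject_id = sg$loci$subject_id,
                                          start = sg$loci$start, end = sg$loci$end,
                                          name = "candidate_locus"),
                               file.path(outdir, "loci.bed"))
  else writeLines(character(0), file.path(outdir, "loci.bed"))
  origin <- attr(sg$segments, "origin")
  write.table(origin, file.path(outdir, "segments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  man$outputs <- c(man$outputs, "subgenome.fasta", "loci.bed", "segments.tsv")
  empty_finish <- function(status) {
    write_fasta(seq_set(character(0), "nt"), file.path(outdir, "consensus_library.fasta"))
    write_fasta(seq_set(character(0), "nt"), file.path(outdir, "selected_library.fasta"))
    write.table(data.frame(), file.path(outdir, "consensus_summary.tsv"))
    write_gff3(empty_annotations(), file.path(outdir, "annotations.gff3"))
    writeLines(character(0), file.path(outdir, "annotations.bed"))
    write.table(coverage_summary(empty_annotations(), genome),
                file.path(outdir, "coverage.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    man$outputs <- c(man$outputs, "consensus_library.fasta", "selected_library.fasta",
                     "consensus_summary.tsv", "annotations.gff3", "annotations.bed",
                     "coverage.tsv")
    man$status <- status
    manifest_write(man, outdir)
    invisible(list(status = status, subgenome = sg,
                   annotations = empty_annotations(),
                   coverage_pct = 0, selected = seq_set(character(0), "nt")))
  }
  if (length(sg$segments) == 0) return(empty_finish("no candidate loci"))

  cons <- build_consensus_library(sg$segments, config)
  man <- manifest_stage(man, "consensus", length(sg$segments), length(cons$consensi))
  write_fasta(cons$consensi, file.path(outdir, "consensus_library.fasta"))
  write.table(cons$members, file.path(outdir, "group_members.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  man$outputs <- c(man$outputs, "consensus_library.fasta", "group_members.tsv")
  if (length(cons$consensi) == 0) return(empty_finish("no repeat groups"))

  profiles <- domain_profiles()
  domains <- scan_domains_all(cons$consensi, profiles, params = config$search_aa)
  kept <- filter_chimeras(cons$consensi, domains, enabled = config$filter_chimeras)
  man <- manifest_stage(man, "chimera_filter", length(cons$consensi), length(kept))
  classification <- classify_best_hit(kept, baits, params = config$search_aa)
  clusters <- cluster_identity_coverage(kept, S = config$cluster_S_pct,
                                        L = config$cluster_L_frac,
                                        coverage_rule = config$coverage_rule)
  selected_ids <- select_library(clusters, classification,
                                 supplementation = config$blastclust_supplementation)
  selected <- seq_set(kept[selected_ids], "nt")
  man <- manifest_stage(man, "select", length(kept), length(selected))
  conc <- lapply(names(kept), function(id)
    flag_concatemers(kept[id], min_len = config$concatemer_min_len,
                     min_hit = config$concatemer_min_hit,
                     min_identity = config$concatemer_min_identity,
                     params = config$search_nt))
  names(conc) <- names(kept)
  summary <- data.frame(
    id = names(kept),
    length = nchar(kept),
    group_id = cons$meta$group_id[match(names(kept), cons$meta$id)],
    domains = vapply(names(kept), function(id)
      paste(domains$name[domains$record_id == id], collapse = ","), character(1)),
    best_bait_class = classification$class[match(names(kept), classification$id)],
    best_bait_genus = classification$genus[match(names(kept), classification$id)],
    cluster_id = clusters$cluster_id[match(names(kept), clusters$id)],
    concatemer = vapply(conc, `[[`, logical(1), "concatemer"),
    monomer_length = vapply(conc, `[[`, integer(1), "monomer_length"),
    selected = names(kept) %in% selected_ids,
    stringsAsFactors = FALSE)
  write_fasta(selected, file.path(outdir, "selected_library.fasta"))
  write.table(summary, file.path(outdir, "consensus_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  man$outputs <- c(man$outputs, "selected_library.fasta", "consensus_summary.tsv")

  annotations <- mask_genome(genome, selected,
                             min_identity = config$mask_min_identity_pct,
                             min_len = config$mask_min_len_bp,
                             params = config$search_nt)
  man <- manifest_stage(man, "annotate", length(selected), nrow(annotations))
  cov <- coverage_summary(annotations, genome)
  write_gff3(annotations, file.path(outdir, "annotations.gff3"))
  if (nrow(annotations)) write_bed(annotations, file.path(outdir, "annotations.bed"))
  else writeLines(character(0), file.path(outdir, "annotations.bed"))
  write.table(cov, file.path(outdir, "coverage.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  man$outputs <- c(man$outputs, "annotations.gff3", "annotations.bed", "coverage.tsv")
  man$status <- "ok"
  manifest_write(man, outdir)
  invisible(list(status = "ok", subgenome = sg, consensus = cons,
                 domains = domains, classification = classification,
                 clusters = clusters, summary = summary, selected = selected,
                 annotations = annotations,
                 coverage_pct = coverage_percent(annotations, genome)))
}

#' Run Branch B: RT mining, dereplication and phylogeny
#'
#' Executes RT locus mining, translation and best-hit filtering, greedy
#' clustering with representative selection, the two iterative align/trim
#' stages, conserved-block curation, neighbour-joining with bootstrap and
#' clade-based genus assignment. Writes the representative RT FASTA, the
#' final MSA, the Newick tree, the classification TSV and a manifest.
#' A run with zero surviving candidates exits cleanly with empty outputs.
#'
#' @param genome genome FASTA path or nucleotide sequence set
#' @param rt_refs RT probe proteins (queries)
#' @param rt_library mixed RT filtering library with class/genus tags
#' @param reference_panel genus-labelled reference RT panel including
#'   outgroups (used for the final phylogeny)
#' @param outdir output directory
#' @param config see [eve_config()]
#' @return invisibly, a list with intermediate results and `status`
#' @export
run_branch_b <- function(genome, rt_refs, rt_library, reference_panel, outdir,
                         config = eve_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  man <- manifest_new("branch-b", config, list(), config$seed)
  genome <- as_input(genome, "nt")
  rt_refs <- as_input(rt_refs, "aa")
  rt_library <- as_input(rt_library, "aa")
  reference_panel <- as_input(reference_panel, "aa")
  set.seed(config$seed)

  mined <- mine_rt_proteins(genome, rt_refs, rt_library, config)
  man <- manifest_stage(man, "rt_loci", length(rt_refs), nrow(mined$loci))
  man <- manifest_stage(man, "rt_candidates", nrow(mined$loci), nrow(mined$candidates))
  write.table(mined$candidates, file.path(outdir, "rt_candidates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  man$outputs <- c(man$outputs, "rt_candidates.tsv")
  empty_finish <- function(status) {
    write_fasta(seq_set(character(0), "aa"), file.path(outdir, "rt_representatives.fasta"))
    writeLines(character(0), file.path(outdir, "rt_alignment.fasta"))
    writeLines(character(0), file.path(outdir, "rt_tree.nwk"))
    write.table(data.frame(candidate_id = character(0), genus = character(0),
                           support = numeric(0)),
                file.path(outdir, "classification.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    man$outputs <- c(man$outputs, "rt_representatives.fasta", "rt_alignment.fasta",
                     "rt_tree.nwk", "classification.tsv")
    man$status <- status
    manifest_write(man, outdir)
    invisible(list(status = status, mined = mined,
                   representatives = seq_set(character(0), "aa"),
                   classification = data.frame(candidate_id = character(0),
                                               genus = character(0),
                                               support = numeric(0))))
  }
  if (length(mined$representatives) == 0) return(empty_finish("no RT candidates"))

  # stage 2: initial + 2 rounds of align/trim on the representatives
  reps <- mined$representatives
  if (length(reps) >= 2) {
    it2 <- iterative_align_trim(reps, rounds = config$trim_rounds_initial)
    reps <- seq_set(reps[names(it2$survivors)], "aa")
  }
  man <- manifest_stage(man, "representatives", length(mined$representatives), length(reps))
  write_fasta(reps, file.path(outdir, "rt_representatives.fasta"))
  man$outputs <- c(man$outputs, "rt_representatives.fasta")
  if (length(reps) == 0) return(empty_finish("no RT representatives"))

  # stage 3: merge with the reference panel, 4 more align/trim rounds
  # (references are exempt from removal), block curation, NJ + bootstrap
  combined <- seq_set(c(unclass(reference_panel), unclass(reps)), "aa",
                      desc = c(seq_desc(reference_panel),
                               setNames(rep("", length(reps)), names(reps))))
  it3 <- iterative_align_trim(combined, rounds = config$trim_rounds_final,
                              protected = names(reference_panel))
  msa <- it3$msa
  blocks <- select_blocks(msa)
  write_fasta(seq_set(blocks, "aa"), file.path(outdir, "rt_alignment.fasta"))
  man <- manifest_stage(man, "alignment", length(combined), length(blocks))
  tree <- bootstrap_support(blocks, replicates = config$bootstrap_replicates,
                            seed = config$seed)
  write_newick(tree, file.path(outdir, "rt_tree.nwk"))
  tags <- bait_tags(reference_panel)
  ref_labels <- setNames(ifelse(tags$class == "caulimovirid", tags$genus, "outgroup"),
                         tags$id)
  classification <- classify_leaves(tree, ref_labels,
                                    min_support = config$support_threshold)
  write.table(classification, file.path(outdir, "classification.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  man$outputs <- c(man$outputs, "rt_alignment.fasta", "rt_tree.nwk", "classification.tsv")
  man$status <- "ok"
  manifest_write(man, outdir)
  invisible(list(status = "ok", mined = mined, representatives = reps,
                 msa = blocks, tree = tree, classification = classification))
}
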