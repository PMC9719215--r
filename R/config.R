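# Pipeline configuration: every tunable ships with the documented default
# and can be overridden from a YAML file or per-call arguments.

#' Pipeline configuration
#'
#' Returns the full configuration list with shipped defaults:
#' \itemize{
#'   \item `extension_bp` (2000): extension of merged loci in both
#'     directions when building the sub-genome (option `-X`).
#'   \item `merge_gap_bp` (5000): loci separated by this many bp or less
#'     are merged as one presumed integration event.
#'   \item `hsp_min` (5): minimum high-scoring-pair group size for
#'     consensus building (option `-hsp`).
#'   \item `group_cap` (20): maximum sequences aligned per group.
#'   \item `subgenome_identity_pct` (85): all-by-all identity threshold
#'     for sub-genome HSP admission.
#'   \item `cluster_S_pct` (90) / `cluster_L_frac` (0.9): identity and
#'     coverage thresholds for consensus clustering (options `-S`, `-L`).
#'   \item `filter_chimeras` (TRUE): discard consensi carrying a
#'     TE-specific domain (option `-ch`).
#'   \item `blastclust_supplementation` (FALSE): also select cluster
#'     co-members of caulimovirid-classified consensi (option `-bl`).
#'   \item `rt_flank_bp` (120): RT locus extension to bridge alignment
#'     breaks.
#'   \item `min_protein_aa` (200): minimum translated protein length.
#'   \item `rt_cluster_identity_pct` (80): greedy-centroid protein
#'     clustering threshold.
#'   \item `trim_rounds_initial` (2) / `trim_rounds_final` (4): additional
#'     align/trim rounds in the two phylogeny preparation stages.
#'   \item `support_threshold` (70): bootstrap support required for
#'     clade-based genus assignment.
#'   \item `bootstrap_replicates` (100).
#'   \item `mask_min_identity_pct` (70) / `mask_min_len_bp` (80):
#'     genome annotation thresholds.
#'   \item `coverage_rule` ("both"): whether the `-L` coverage condition
#'     applies to both sequences or either one.
#'   \item `search_nt` / `search_aa`: overrides forwarded to
#'     [search_params()].
#'   \item `seed` (1): global RNG seed.
#' }
#'
#' @param ... named overrides
#' @param file optional YAML file of overrides (applied before `...`)
#' @return configuration list
#' @export
eve_config <- function(..., file = NULL) {
  cfg <- list(
    extension_bp = 2000L,
    merge_gap_bp = 5000L,
    hsp_min = 5L,
    group_cap = 20L,
    subgenome_identity_pct = 85,
    cluster_S_pct = 90,
    cluster_L_frac = 0.9,
    filter_chimeras = TRUE,
    blastclust_supplementation = FALSE,
    rt_flank_bp = 120L,
    min_protein_aa = 200L,
    rt_cluster_identity_pct = 80,
    trim_rounds_initial = 2L,
    trim_rounds_final = 4L,
    support_threshold = 70,
    bootstrap_replicates = 100L,
    mask_min_identity_pct = 70,
    mask_min_len_bp = 80L,
    min_hsp_len = 100L,
    coverage_rule = "both",
    concatemer_min_len = 2000L,
    concatemer_min_hit = 1000L,
    concatemer_min_identity = 90,
    search_nt = list(),
    # genome-scale runs use a raw-score floor of 80 for protein-level
    # comparisons: with score-only significance (no E-value), the generic
    # engine default of 50 admits spurious hits at megabase search-space
    # sizes, polluting the sub-genome with background loci
    search_aa = list(min_score = 80),
    seed = 1L
  )
  if (!is.null(file)) {
    over <- yaml::read_yaml(file)
    for (nm in names(over)) {
      if (!nm %in% names(cfg)) stop("unknown config key in ", file, ": ", nm)
      cfg[[nm]] <- over[[nm]]
    }
  }
  dots <- list(...)
  if (length(dots) == 1 && is.list(dots[[1]]) && is.null(names(dots))) dots <- dots[[1]]
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config key: ", nm)
    cfg[[nm]] <- dots[[nm]]
  }
  cfg
}
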