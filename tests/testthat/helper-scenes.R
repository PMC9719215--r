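# Expensive end-to-end fixtures used by the acceptance tests, built once
# per session. The benchmark scene follows the standard study conditions:
# a 2 Mb background at GC 0.36, three viral ancestors with ten full
# copies each spanning 5-15% divergence plus fragments, one triple
# tandem, and thirty Gypsy-like decoy copies.

benchmark_scene <- function() cached_fixture("benchmark_scene", function() {
  anc <- make_ancestors(seed = 1)
  viral <- names(anc$genomes)[grepl("^virus", names(anc$genomes))]
  plan <- default_copy_plan(anc$genomes)
  sim <- plant_elements(2e6, 0.36, anc$genomes, plan, seed = 1)
  outdir <- file.path(tempdir(), "benchmark_branch_a")
  res <- run_branch_a(sim$genome, anc$genomes[viral], anc$baits, outdir,
                      eve_config(seed = 1L))
  list(anc = anc, sim = sim, viral = viral, res = res, outdir = outdir)
})
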