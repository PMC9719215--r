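test_that("ancestor generation is deterministic and self-consistent", {
  a1 <- make_ancestors(seed = 77)
  a2 <- make_ancestors(seed = 77)
  expect_identical(as.character(a1$genomes), as.character(a2$genomes))
  expect_identical(as.character(a1$baits), as.character(a2$baits))
  a3 <- make_ancestors(seed = 78)
  expect_false(identical(as.character(a1$genomes), as.character(a3$genomes)))
  # viral ancestors carry their assigned domains, never TE-specific ones
  d <- scan_domains(a1$genomes["virus_G2"])
  expect_true(all(c("MP", "AP", "RT_core", "RNaseH", "zf_CCHC") %in% d$name))
  expect_false(any(d$klass == "te_specific"))
  dd <- scan_domains(a1$genomes["gypsy_decoy"])
  expect_true("integrase" %in% dd$name)
  # a viral spec with a TE token is rejected
  bad <- default_ancestor_specs(n_viral = 1, decoy = FALSE)
  bad[[1]]$orf_layout <- c("MP", "integrase")
  expect_error(make_ancestors(bad, seed = 1), "TE-specific")
})

test_that("planting with an empty plan returns pure background", {
  anc <- small_scene()$anc
  plan <- data.frame(ancestor_id = "virus_G1", n_full = 0L, n_fragment = 0L,
                     n_tandem = 0L, tandem_k = 3L, divergence = 5)
  sim <- plant_elements(5000, 0.36, anc$genomes, plan, seed = 3)
  expect_equal(nrow(sim$truth), 0)
  expect_equal(nchar(sim$genome[[1]]), 5000)
})

test_that("a zero-divergence copy appears verbatim at the truth span", {
  anc <- small_scene()$anc
  plan <- data.frame(ancestor_id = "virus_G1", n_full = 1L, n_fragment = 0L,
                     n_tandem = 0L, tandem_k = 3L, divergence = 0)
  sim <- plant_elements(40000, 0.36, anc$genomes, plan, seed = 5)
  tr <- sim$truth
  expect_equal(nrow(tr), 1)
  got <- substr(sim$genome[[1]], tr$start + 1, tr$end)
  want <- anc$genomes[["virus_G1"]]
  if (tr$strand == "-") want <- unname(reverse_complement(seq_set(c(x = want), "nt")))
  expect_equal(got, want)
})

test_that("realized divergence tracks the requested rate within 3 points", {
  anc <- small_scene()$anc
  plan <- data.frame(ancestor_id = "virus_G1", n_full = 1L, n_fragment = 0L,
                     n_tandem = 0L, tandem_k = 3L,
                     divergence = c(5, 10, 15, 20))
  sim <- plant_elements(100000, 0.36, anc$genomes, plan, seed = 6)
  tr <- sim$truth
  for (i in seq_len(nrow(tr))) {
    copy <- substr(sim$genome[[1]], tr$start[i] + 1, tr$end[i])
    if (tr$strand[i] == "-") copy <- unname(reverse_complement(seq_set(c(x = copy), "nt")))
    al <- align_pair(seq_set(c(a = copy), "nt"),
                     seq_set(c(b = anc$genomes[["virus_G1"]]), "nt"))
    expect_lt(abs((100 - al$identity_pct) - tr$divergence[i]), 3.5,
              label = sprintf("copy at %g%%: realized %.1f", tr$divergence[i],
                              100 - al$identity_pct))
  }
})

test_that("tandem and fragment forms have consistent spans", {
  anc <- small_scene()$anc
  plan <- data.frame(ancestor_id = "virus_G1",
                     n_full = c(0L, 0L), n_fragment = c(1L, 0L), n_tandem = c(0L, 1L),
                     tandem_k = 3L, divergence = 5)
  sim <- plant_elements(120000, 0.36, anc$genomes, plan, seed = 8)
  tr <- sim$truth
  L <- nchar(anc$genomes[["virus_G1"]])
  frag <- tr[tr$form == "fragment", ]
  expect_true(frag$end - frag$start >= 0.15 * L && frag$end - frag$start <= 0.65 * L)
  tand <- tr[grepl("tandem", tr$form), ]
  expect_equal(tand$form, "tandem_3")
  expect_lt(abs((tand$end - tand$start) - 3 * L) / (3 * L), 0.05)
  # infeasible plans are rejected
  plan2 <- data.frame(ancestor_id = "virus_G1", n_full = 10L, n_fragment = 0L,
                      n_tandem = 0L, tandem_k = 3L, divergence = 5)
  expect_error(plant_elements(20000, 0.36, anc$genomes, plan2, seed = 1),
               "below half")
})

test_that("same seed reproduces the genome and truth byte-identically", {
  anc <- small_scene()$anc
  plan <- default_copy_plan(anc$genomes)
  plan <- plan[plan$divergence <= 8 & plan$n_full > 0, ][1:6, ]
  s1 <- plant_elements(150000, 0.36, anc$genomes, plan, seed = 99)
  s2 <- plant_elements(150000, 0.36, anc$genomes, plan, seed = 99)
  expect_identical(s1$genome[[1]], s2$genome[[1]])
  expect_identical(s1$truth, s2$truth)
})

test_that("benchmark clustering co-clusters outputs with their references", {
  set.seed(91)
  refs <- seq_set(setNames(vapply(1:3, function(i) rand_nt(600), character(1)),
                           sprintf("ref%d", 1:3)), "nt")
  outs <- seq_set(setNames(as.character(refs), sprintf("out%d", 1:3)), "nt")
  bc <- benchmark_cluster(outs, refs)
  expect_true(all(bc$per_reference$co_clustered))
  # disjoint random sequences are all singletons
  r2 <- seq_set(setNames(vapply(1:3, function(i) rand_nt(500), character(1)),
                         sprintf("r%d", 1:3)), "nt")
  o2 <- seq_set(setNames(vapply(1:2, function(i) rand_nt(500), character(1)),
                         sprintf("o%d", 1:2)), "nt")
  bc2 <- benchmark_cluster(o2, r2)
  expect_false(any(bc2$per_reference$co_clustered))
  expect_setequal(bc2$singletons, c(names(r2), names(o2)))
  # coverage is evaluated on the shorter sequence: a long output containing
  # a reference still co-clusters
  long_out <- seq_set(c(big = paste0(rand_nt(400), refs[[1]], rand_nt(400))), "nt")
  bc3 <- benchmark_cluster(long_out, refs[1])
  expect_true(bc3$per_reference$co_clustered[1])
})

test_that("recovery scoring matches a per-base overlap computation", {
  truth <- data.frame(element_id = c("e1", "e2"), ancestor_id = "a",
                      start = c(100L, 500L), end = c(200L, 700L),
                      strand = "+", form = "full", divergence = 5)
  ann_perfect <- data.frame(subject_id = "chr", start = c(100L, 500L),
                            end = c(200L, 700L))
  expect_equal(score_recovery(truth, annotations = ann_perfect)$sensitivity, 1)
  expect_equal(score_recovery(truth, annotations = ann_perfect[0, ])$sensitivity, 0)
  ann_half <- data.frame(subject_id = "chr", start = 100L, end = 149L)
  sc <- score_recovery(truth, annotations = ann_half)
  expect_equal(sc$per_element$best_overlap[1], 49 / 100)
  expect_equal(sc$sensitivity, 0)
})
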