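mk_hits <- function(starts, ends, subject = "chr") {
  data.frame(query_id = "q", subject_id = subject, q_start = 0L, q_end = 1L,
             s_start = as.integer(starts), s_end = as.integer(ends),
             strand = "+", frame_q = NA_integer_, frame_s = NA_integer_,
             identity_pct = 100, score = 100, matches = 1L, aln_len = 1L,
             stringsAsFactors = FALSE)
}

test_that("overlapping and touching hit spans merge into maximal loci", {
  expect_equal(merge_overlapping_hits(mk_hits(c(10, 40), c(50, 90)))[, c("start", "end")],
               data.frame(start = 10L, end = 90L))
  # half-open spans that merely touch are contiguous sequence
  expect_equal(merge_overlapping_hits(mk_hits(c(10, 50), c(50, 90)))[, c("start", "end")],
               data.frame(start = 10L, end = 90L))
  two <- merge_overlapping_hits(mk_hits(c(10, 52), c(50, 90)))
  expect_equal(nrow(two), 2)
})

test_that("hit merging matches a per-base bitmap oracle on random span sets", {
  set.seed(21)
  for (i in 1:1000) {
    n <- sample(1:12, 1)
    st <- sample(0:400, n, replace = TRUE)
    en <- st + sample(1:80, n, replace = TRUE)
    got <- merge_overlapping_hits(mk_hits(st, en))
    want <- bitmap_merge(st, en)
    expect_equal(got$start, want$start, info = sprintf("iter %d", i))
    expect_equal(got$end, want$end, info = sprintf("iter %d", i))
  }
})

test_that("merge_nearby is inclusive at the gap threshold and idempotent", {
  loci <- data.frame(subject_id = "chr", start = c(0L, 6000L), end = c(1000L, 7000L),
                     n_hits = 1L)
  m <- merge_nearby(loci, 5000)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0L, 7000L))
  loci2 <- data.frame(subject_id = "chr", start = c(0L, 6001L), end = c(1000L, 7000L),
                      n_hits = 1L)
  expect_equal(nrow(merge_nearby(loci2, 5000)), 2)
  expect_equal(merge_nearby(m, 5000)[, c("start", "end")], m[, c("start", "end")])
})

test_that("merge_nearby equals brute-force closure of the gap relation", {
  set.seed(22)
  for (i in 1:300) {
    n <- sample(1:8, 1)
    st <- sort(sample(seq(0, 5000, 10), n))
    en <- st + sample(1:200, n, replace = TRUE)
    base <- merge_overlapping_hits(mk_hits(st, en))
    gap <- sample(c(0, 50, 300), 1)
    got <- merge_nearby(base, gap)
    want <- bitmap_merge(base$start, base$end, max_gap = gap)
    expect_equal(got$start, want$start, info = sprintf("iter %d", i))
    expect_equal(got$end, want$end, info = sprintf("iter %d", i))
  }
})

test_that("extension clamps to sequence bounds and re-merges overlaps", {
  set.seed(23)
  g <- seq_set(c(chr = rand_nt(10000)), "nt")
  loci <- data.frame(subject_id = "chr", start = 500L, end = 1500L, n_hits = 1L)
  seg <- extend_and_extract(g, loci, X = 2000)
  o <- attr(seg, "origin")
  expect_equal(c(o$start, o$end), c(0L, 3500L))
  loci2 <- data.frame(subject_id = "chr", start = c(0L, 4000L), end = c(1000L, 5000L),
                      n_hits = 1L)
  seg2 <- extend_and_extract(g, loci2, X = 2000)
  expect_equal(nrow(attr(seg2, "origin")), 1)
  expect_equal(attr(seg2, "origin")$end, 7000L)
})

test_that("extracted segment residues equal the genome slice exactly", {
  set.seed(24)
  g <- seq_set(c(chr = rand_nt(8000)), "nt")
  loci <- data.frame(subject_id = "chr", start = c(100L, 3000L), end = c(900L, 4200L),
                     n_hits = 1L)
  segs <- extract_segments(g, loci)
  o <- attr(segs, "origin")
  for (i in seq_len(nrow(o))) {
    expect_equal(segs[[i]], substr(g[[1]], o$start[i] + 1, o$end[i]))
  }
})

test_that("bait filtering routes by competitive best hit", {
  sc <- small_scene()
  anc <- sc$anc
  # segments = one viral ancestor slice, one decoy slice
  g <- seq_set(c(v = anc$genomes[["virus_G1"]], d = anc$genomes[["gypsy_decoy"]]), "nt")
  loci <- data.frame(subject_id = c("v", "d"), start = 0L,
                     end = nchar(g), n_hits = 1L)
  segs <- extract_segments(g, loci)
  kept <- bait_filter(segs, anc$baits)
  o <- attr(kept, "origin")
  expect_equal(o$subject_id, "v")
  expect_equal(o$best_bait_class, "caulimovirid")
  expect_equal(o$best_bait_genus, "G1")
  expect_error(bait_filter(segs, seq_set(character(0), "aa")), "empty bait")
})

test_that("planted viral and decoy segments are routed correctly at 10% divergence", {
  set.seed(25)
  sc <- small_scene()
  anc <- sc$anc
  n_each <- 12
  segs <- character(0)
  for (i in seq_len(n_each)) {
    segs[sprintf("vir%02d", i)] <- substitute_nt(anc$genomes[["virus_G2"]], 0.10)
    segs[sprintf("dec%02d", i)] <- substitute_nt(anc$genomes[["gypsy_decoy"]], 0.10)
  }
  g <- seq_set(segs, "nt")
  loci <- data.frame(subject_id = names(segs), start = 0L, end = nchar(segs), n_hits = 1L)
  kept <- bait_filter(extract_segments(g, loci), anc$baits)
  ids <- attr(kept, "origin")$subject_id
  expect_gte(sum(grepl("^vir", ids)), 11)
  expect_lte(sum(grepl("^dec", ids)), 1)
})

test_that("a background-only genome yields an empty sub-genome", {
  sc <- small_scene()
  set.seed(26)
  ok <- 0
  for (i in 1:3) {
    g <- seq_set(c(chr = rand_nt(60000)), "nt")
    viral <- sc$anc$genomes[sc$viral]
    sg <- build_subgenome(g, viral, sc$anc$baits)
    if (length(sg$segments) == 0) ok <- ok + 1
  }
  expect_gte(ok, 3)
})
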