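# aa-level fixture: reverse-translate a protein with random codons
orf_of <- function(prot) {
  paste(vapply(strsplit(prot, "")[[1]], function(a) {
    cods <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a]
    sample(cods, 1)
  }, character(1)), collapse = "")
}

mutate_aa_frac <- function(p, d) {
  v <- strsplit(p, "", fixed = TRUE)[[1]]
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  i <- which(runif(length(v)) < d)
  for (j in i) v[j] <- sample(setdiff(aa, v[j]), 1)
  paste(v, collapse = "")
}

test_that("RT hit extension arithmetic and merging follow the flank rule", {
  set.seed(61)
  sc <- small_scene()
  rt <- sc$anc$rt_panel[["REF_G1_RT"]]
  g <- seq_set(c(chr = paste0(rand_nt(1000), orf_of(rt), rand_nt(1000))), "nt")
  loci <- find_rt_loci(g, seq_set(c(p = rt), "aa"), flank = 120)
  expect_equal(nrow(loci), 1)
  # flank arithmetic: hit span +/- 120 bp (local ends may shift by a codon
  # or two when flanking residues happen to score positively)
  expect_lte(abs(loci$start - (1000L - 120L)), 9L)
  expect_lte(abs(loci$end - (1000L + 3L * nchar(rt) + 120L)), 9L)
  expect_equal(loci$frame, 2L)
})

test_that("nearby RT hits merge after flank extension", {
  set.seed(62)
  sc <- small_scene()
  rt <- sc$anc$rt_panel[["REF_G1_RT"]]
  half1 <- substr(rt, 1, 85)
  half2 <- substr(rt, 86, nchar(rt))
  # two hit islands separated by 150 bp < 2 * 120
  g <- seq_set(c(chr = paste0(rand_nt(999), orf_of(half1), rand_nt(150),
                              orf_of(half2), rand_nt(800))), "nt")
  loci <- find_rt_loci(g, seq_set(c(p = rt), "aa"), flank = 120)
  expect_equal(nrow(loci), 1)
})

test_that("planted diverged RT ORFs are recovered as loci", {
  set.seed(63)
  sc <- small_scene()
  rt <- sc$anc$rt_panel[["REF_G2_RT"]]
  n <- 10
  found <- 0
  for (i in seq_len(n)) {
    prot <- mutate_aa_frac(rt, 0.25)
    pos <- sample(500:3000, 1)
    g <- seq_set(c(chr = paste0(rand_nt(pos), orf_of(prot), rand_nt(1500))), "nt")
    loci <- find_rt_loci(g, seq_set(c(p = rt), "aa"))
    hit <- any(loci$start <= pos + 200 & loci$end >= pos + 3 * nchar(prot) - 200)
    if (hit) found <- found + 1
  }
  expect_gte(found, 9)
})

test_that("translation splits at stops and enforces the length floor", {
  set.seed(64)
  # 250 aa stop-free ORF -> one candidate of 250
  prot <- rand_aa(250)
  g <- seq_set(c(chr = paste0(rand_nt(300), orf_of(prot), rand_nt(300))), "nt")
  loci <- data.frame(subject_id = "chr", start = 300L, end = 300L + 750L,
                     n_hits = 1L, frame = ((300L) %% 3L) + 1L)
  cands <- extract_rt_proteins(g, loci, min_aa = 200)
  expect_equal(nrow(cands), 1)
  expect_equal(nchar(cands$protein), 250)
  expect_equal(cands$protein, prot)
  # 300 aa with a stop at position 150 -> two short halves -> nothing
  prot2 <- paste0(rand_aa(149), "*", rand_aa(150))
  orf2 <- orf_of(sub("\\*", "", prot2))
  orf2 <- paste0(substr(orf2, 1, 149 * 3), "TAA", substr(orf2, 149 * 3 + 1, nchar(orf2)))
  g2 <- seq_set(c(chr = paste0(rand_nt(300), orf2, rand_nt(300))), "nt")
  loci2 <- data.frame(subject_id = "chr", start = 300L, end = 300L + 900L,
                      n_hits = 1L, frame = 1L)
  expect_equal(nrow(extract_rt_proteins(g2, loci2, min_aa = 200)), 0)
  # 280 aa, a stop, then a 190 aa tail below the floor -> one candidate
  orf3 <- paste0(orf_of(rand_aa(280)), "TGA", orf_of(rand_aa(190)))
  g3 <- seq_set(c(chr = paste0(rand_nt(99), orf3, rand_nt(300))), "nt")
  loci3 <- data.frame(subject_id = "chr", start = 99L, end = 99L + 1413L,
                      n_hits = 1L, frame = 1L)
  c3 <- extract_rt_proteins(g3, loci3, min_aa = 200)
  expect_equal(nrow(c3), 1)
  expect_equal(nchar(c3$protein), 280)
})

test_that("minus-frame candidates report forward-strand coordinates", {
  set.seed(65)
  prot <- rand_aa(220)
  orf <- orf_of(prot)
  rc <- unname(reverse_complement(seq_set(c(x = orf), "nt")))
  g <- seq_set(c(chr = paste0(rand_nt(400), rc, rand_nt(200))), "nt")
  # ORF on minus strand; locus covering it, frame -1 relative to slice end
  L <- nchar(g[[1]])
  loci <- data.frame(subject_id = "chr", start = 400L, end = 400L + 660L,
                     n_hits = 1L, frame = -(((L - (400L + 660L)) %% 3L) + 1L))
  cands <- extract_rt_proteins(g, loci, min_aa = 200)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$protein, prot)
  expect_equal(c(cands$start, cands$end), c(400L, 1060L))
})

test_that("best-hit filtering keeps caulimovirid RTs and drops decoys", {
  set.seed(66)
  sc <- small_scene()
  anc <- sc$anc
  cands <- data.frame(
    candidate_id = c("v", "d", "junk"),
    subject_id = "chr", start = 0L, end = 1L, frame = 1L,
    protein = c(mutate_aa_frac(anc$rt_panel[["REF_G1_RT"]], 0.10),
                mutate_aa_frac(anc$rt_panel[["REF_gypsy_RT"]], 0.10),
                rand_aa(250)),
    stringsAsFactors = FALSE)
  kept <- rt_best_hit_filter(cands, anc$rt_panel)
  expect_equal(kept$candidate_id, "v")
  expect_equal(kept$best_hit_genus, "G1")
})

test_that("mixed planted RT sets are routed correctly per class", {
  set.seed(67)
  sc <- small_scene()
  anc <- sc$anc
  n <- 15
  cands <- do.call(rbind, lapply(seq_len(2 * n), function(i) {
    viral <- i <= n
    src <- if (viral) anc$rt_panel[["REF_G3_RT"]] else anc$rt_panel[["REF_gypsy_RT"]]
    data.frame(candidate_id = sprintf("%s%02d", if (viral) "v" else "d", i),
               subject_id = "chr", start = 0L, end = 1L, frame = 1L,
               protein = mutate_aa_frac(src, 0.10), stringsAsFactors = FALSE)
  }))
  kept <- rt_best_hit_filter(cands, anc$rt_panel)
  expect_gte(sum(grepl("^v", kept$candidate_id)), 14)
  expect_lte(sum(grepl("^d", kept$candidate_id)), 1)
})

test_that("greedy centroid clustering keeps all centroid pairs below threshold", {
  set.seed(68)
  base1 <- rand_aa(260); base2 <- rand_aa(260)
  prots <- seq_set(c(
    setNames(vapply(1:4, function(i) mutate_aa_frac(base1, 0.05), character(1)),
             sprintf("a%d", 1:4)),
    setNames(vapply(1:3, function(i) mutate_aa_frac(base2, 0.05), character(1)),
             sprintf("b%d", 1:3))), "aa")
  cl <- cluster_greedy_centroid(prots, identity = 80)
  expect_equal(length(unique(cl$cluster_id)), 2)
  expect_equal(sum(cl$representative), 2)
  reps <- cl$id[cl$representative]
  al <- align_pair(prots[[reps[1]]], prots[[reps[2]]], alphabet = "aa")
  expect_lt(al$identity_pct, 80)
  # every representative belongs to its own cluster
  expect_true(all(tapply(cl$representative, cl$cluster_id, sum) == 1))
  one <- cluster_greedy_centroid(prots[1], identity = 80)
  expect_true(one$representative)
})
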