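test_that("domain scan finds planted domains and nothing TE-specific in viral records", {
  sc <- small_scene()
  d <- scan_domains(sc$anc$genomes["virus_G1"])
  expect_true(all(c("MP", "AP", "RT_core", "RNaseH", "zf_CCHC") %in% d$name))
  expect_false(any(d$klass == "te_specific"))
  d2 <- scan_domains(sc$anc$genomes["gypsy_decoy"])
  expect_true("integrase" %in% d2$name)
  expect_equal(d2$klass[d2$name == "integrase"], "te_specific")
  expect_error(scan_domains(sc$anc$genomes["virus_G1"],
                            profiles = list(seqs = seq_set(character(0), "aa"),
                                            meta = data.frame())),
               "empty profile")
})

test_that("random sequence rarely fires any domain profile", {
  set.seed(41)
  fires <- 0
  n <- 20
  for (i in seq_len(n)) {
    d <- scan_domains(seq_set(c(r = rand_nt(7000)), "nt"))
    if (nrow(d) > 0) fires <- fires + 1
  }
  expect_lte(fires / n, 0.05)
})

test_that("chimera filtering removes TE-domain records only when enabled", {
  doms <- data.frame(record_id = c("a", "b"), name = c("integrase", "RT_core"),
                     start = 1L, end = 10L, frame = 1L, score = 100,
                     klass = c("te_specific", "shared"), stringsAsFactors = FALSE)
  cons <- seq_set(c(a = strrep("ACGT", 50), b = strrep("ACGT", 50)), "nt")
  expect_equal(names(filter_chimeras(cons, doms, enabled = TRUE)), "b")
  expect_equal(names(filter_chimeras(cons, doms, enabled = FALSE)), c("a", "b"))
})

test_that("best-hit classification assigns the generating genus", {
  set.seed(42)
  sc <- small_scene()
  anc <- sc$anc
  cons <- seq_set(c(c1 = substitute_nt(anc$genomes[["virus_G2"]], 0.05),
                    c2 = substitute_nt(anc$genomes[["gypsy_decoy"]], 0.05),
                    c3 = rand_nt(2000)), "nt")
  cl <- classify_best_hit(cons, anc$baits)
  expect_equal(cl$class[cl$id == "c1"], "caulimovirid")
  expect_equal(cl$genus[cl$id == "c1"], "G2")
  expect_equal(cl$class[cl$id == "c2"], "retroelement")
  expect_equal(cl$class[cl$id == "c3"], "none")
})

test_that("identity/coverage clustering follows the link definition", {
  set.seed(43)
  s <- rand_nt(1000)
  seqs <- seq_set(c(a = s, b = s, half = substr(s, 1, 500), other = rand_nt(1000)), "nt")
  cl <- cluster_identity_coverage(seqs, S = 90, L = 0.9)
  expect_equal(cl$cluster_id[cl$id == "a"], cl$cluster_id[cl$id == "b"])
  # the half-length fragment fails the both-sequence coverage rule
  expect_false(cl$cluster_id[cl$id == "half"] == cl$cluster_id[cl$id == "a"])
  expect_false(cl$cluster_id[cl$id == "other"] == cl$cluster_id[cl$id == "a"])
  # under the shorter-sequence rule the fragment joins
  cl2 <- cluster_identity_coverage(seqs, S = 90, L = 0.9, coverage_rule = "shorter")
  expect_equal(cl2$cluster_id[cl2$id == "half"], cl2$cluster_id[cl2$id == "a"])
})

test_that("clustering equals brute-force transitive closure and ignores input order", {
  set.seed(44)
  for (i in 1:12) {
    k <- sample(3:7, 1)
    fams <- sample(1:3, k, replace = TRUE)
    bases <- lapply(1:3, function(j) rand_nt(300))
    seqs <- setNames(vapply(seq_len(k), function(j)
      substitute_nt(bases[[fams[j]]], 0.02), character(1)), sprintf("s%d", seq_len(k)))
    ss <- seq_set(seqs, "nt")
    got <- cluster_identity_coverage(ss, S = 90, L = 0.9)
    # oracle: explicit link relation + closure
    links <- matrix(0L, 0, 2)
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      al <- align_pair(ss[[a]], ss[[b]], alphabet = "nt")
      if (al$identity_pct >= 90 && al$coverage_a >= 0.9 && al$coverage_b >= 0.9)
        links <- rbind(links, c(a, b))
    }
    want <- closure_components(k, links)
    got_comp <- match(got$cluster_id, unique(got$cluster_id[order(got$id)]))
    expect_equal(length(unique(got$cluster_id)), length(unique(want)),
                 info = sprintf("iter %d", i))
    same_got <- outer(got$cluster_id, got$cluster_id, "==")
    same_want <- outer(want, want, "==")
    expect_equal(same_got, same_want, info = sprintf("iter %d partition", i))
    # permutation invariance
    perm <- sample(k)
    got2 <- cluster_identity_coverage(ss[perm], S = 90, L = 0.9)
    got2 <- got2[match(got$id, got2$id), ]
    expect_equal(outer(got2$cluster_id, got2$cluster_id, "=="), same_got)
  }
})

test_that("library selection honours best hits and supplementation", {
  clusters <- data.frame(id = c("a", "b", "c", "d"),
                         cluster_id = c("CL1", "CL1", "CL2", "CL3"))
  classification <- data.frame(id = c("a", "b", "c", "d"),
                               class = c("caulimovirid", "none", "caulimovirid", "retroelement"))
  expect_equal(select_library(clusters, classification, FALSE), c("a", "c"))
  expect_equal(select_library(clusters, classification, TRUE), c("a", "b", "c"))
  # supplementation is always a superset
  expect_true(all(select_library(clusters, classification, FALSE) %in%
                    select_library(clusters, classification, TRUE)))
  # redundant caulimovirid records in one cluster are both kept
  cls2 <- data.frame(id = c("x", "y"), cluster_id = "CL1")
  cf2 <- data.frame(id = c("x", "y"), class = "caulimovirid")
  expect_equal(select_library(cls2, cf2, FALSE), c("x", "y"))
})

test_that("tandem doubling is flagged as a concatemer with the right monomer", {
  set.seed(45)
  unit <- rand_nt(3000)
  rec <- seq_set(c(t = paste0(unit, unit)), "nt")
  fl <- flag_concatemers(rec)
  expect_true(fl$concatemer)
  expect_lt(abs(fl$monomer_length - 3000) / 3000, 0.05)
  # single-copy sequence is not flagged
  expect_false(flag_concatemers(seq_set(c(s = rand_nt(7000)), "nt"))$concatemer)
  # short records are never flagged
  expect_false(flag_concatemers(seq_set(c(s = strrep("ACGT", 200)), "nt"),
                                min_len = 2000)$concatemer)
})

test_that("diverged triple tandems are flagged with monomer within 10%", {
  set.seed(46)
  unit <- rand_nt(2500)
  tri <- paste0(substitute_nt(unit, 0.05), substitute_nt(unit, 0.05),
                substitute_nt(unit, 0.05))
  fl <- flag_concatemers(seq_set(c(t = tri), "nt"))
  expect_true(fl$concatemer)
  expect_lt(abs(fl$monomer_length - 2500) / 2500, 0.10)
})
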