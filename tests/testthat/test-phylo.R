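mutate_prot <- function(p, d) {
  v <- strsplit(p, "", fixed = TRUE)[[1]]
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  i <- which(runif(length(v)) < d)
  for (j in i) v[j] <- sample(setdiff(aa, v[j]), 1)
  paste(v, collapse = "")
}

test_that("progressive alignment handles identical and near-trivial inputs", {
  p <- seq_set(c(a = "MKVLWALLVT", b = "MKVLWALLVT"), "aa")
  msa <- progressive_align(p)
  expect_false(any(grepl("-", msa, fixed = TRUE)))
  expect_equal(unname(msa["a"]), "MKVLWALLVT")
  msa2 <- progressive_align(seq_set(c(a = "MKV", b = "MV"), "aa"))
  expect_equal(nchar(msa2[["a"]]), 3)
  expect_equal(unname(msa2["a"]), "MKV")
  expect_equal(sum(strsplit(msa2[["b"]], "")[[1]] == "-"), 1)
  expect_error(progressive_align(seq_set(c(a = "MKV"), "aa")), "at least 2")
})

test_that("progressive alignment dominates a naive star alignment on families", {
  set.seed(71)
  bl <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e); e$BLOSUM62
  })
  sp_score <- function(msa) {
    M <- do.call(rbind, strsplit(unname(msa), ""))
    total <- 0
    for (a in seq_len(nrow(M) - 1)) for (b in (a + 1):nrow(M)) {
      ok <- M[a, ] != "-" & M[b, ] != "-"
      if (any(ok)) total <- total + sum(bl[cbind(M[a, ok], M[b, ok])])
    }
    total
  }
  wins <- 0
  for (i in 1:10) {
    anc <- rand_aa(80)
    fam <- setNames(vapply(1:5, function(j) mutate_prot(anc, 0.2), character(1)),
                    sprintf("s%d", 1:5))
    fam[2] <- paste0(substr(fam[2], 1, 30), substr(fam[2], 36, 80))  # one deletion
    ss <- seq_set(fam, "aa")
    msa <- progressive_align(ss)
    # naive star: pad to longest without alignment
    L <- max(nchar(fam))
    star <- setNames(vapply(fam, function(s)
      paste0(s, strrep("-", L - nchar(s))), character(1)), names(fam))
    if (sp_score(msa) >= sp_score(star)) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("trim_msa equals the direct column-then-row filter", {
  set.seed(72)
  for (i in 1:100) {
    nr <- sample(3:8, 1); nc <- sample(10:40, 1)
    M <- matrix(sample(c("A", "C", "D", "-"), nr * nc, TRUE, prob = c(.3, .3, .2, .2)),
                nr, nc)
    msa <- setNames(apply(M, 1, paste, collapse = ""), sprintf("r%d", 1:nr))
    got <- tryCatch(trim_msa(msa, 0.8, 0.5), error = function(e) "allgone")
    gapfrac <- colMeans(M == "-")
    M2 <- M[, gapfrac <= 0.8, drop = FALSE]
    occ <- if (ncol(M2)) rowMeans(M2 != "-") else rep(0, nr)
    if (all(occ < 0.5)) {
      expect_identical(got, "allgone", info = sprintf("iter %d", i))
    } else {
      keep <- occ >= 0.5
      want <- setNames(apply(M2[keep, , drop = FALSE], 1, paste, collapse = ""),
                       sprintf("r%d", 1:nr)[keep])
      expect_equal(got$msa, want, info = sprintf("iter %d", i))
      expect_equal(got$removed, sprintf("r%d", 1:nr)[!keep])
    }
  }
})

test_that("gap-free alignments trim to themselves and sparse rows are removed", {
  msa <- setNames(c("MKVL", "MKVL", "MKVL"), c("a", "b", "c"))
  tr <- trim_msa(msa)
  expect_equal(tr$msa, msa)
  expect_length(tr$removed, 0)
  msa2 <- c(msa, d = "M---")
  tr2 <- trim_msa(msa2, col_gap_max = 0.8, seq_occupancy_min = 0.5)
  expect_true("d" %in% tr2$removed)
  # protected rows survive
  tr3 <- trim_msa(msa2, protected = "d")
  expect_false("d" %in% tr3$removed)
})

test_that("select_blocks equals a brute-force run scan", {
  set.seed(73)
  for (i in 1:100) {
    nr <- sample(3:6, 1); nc <- sample(15:50, 1)
    M <- matrix(sample(c("A", "A", "C", "-"), nr * nc, TRUE), nr, nc)
    msa <- setNames(apply(M, 1, paste, collapse = ""), sprintf("r%d", 1:nr))
    good <- vapply(seq_len(nc), function(j) {
      col <- M[, j]
      if (mean(col == "-") > 0.5) return(FALSE)
      res <- col[col != "-"]
      max(table(res)) / length(res) >= 0.5
    }, logical(1))
    keep <- logical(nc)
    r <- rle(good); ends <- cumsum(r$lengths)
    for (k in seq_along(r$lengths))
      if (r$values[k] && r$lengths[k] >= 5)
        keep[(ends[k] - r$lengths[k] + 1):ends[k]] <- TRUE
    got <- tryCatch(select_blocks(msa), error = function(e) "none")
    if (!any(keep)) {
      expect_identical(got, "none", info = sprintf("iter %d", i))
    } else {
      want <- setNames(apply(M[, keep, drop = FALSE], 1, paste, collapse = ""),
                       names(msa))
      expect_equal(got, want, info = sprintf("iter %d", i))
    }
  }
})

test_that("protein distances follow the capped Kimura formula", {
  msa <- setNames(c("MKVLW", "MKVLW"), c("a", "b"))
  D <- msa_distance_matrix(msa)
  expect_equal(D["a", "b"], 0)
  set.seed(74)
  for (i in 1:50) {
    p <- runif(1, 0, 0.99)
    n <- 200
    k <- round(p * n); p_real <- k / n
    a <- strrep("A", n)
    b <- paste0(strrep("C", k), strrep("A", n - k))
    D2 <- msa_distance_matrix(setNames(c(a, b), c("x", "y")))
    want <- if (p_real >= 0.85) 10 else -log(1 - p_real - p_real^2 / 5)
    expect_equal(D2["x", "y"], want, tolerance = 1e-12)
  }
  expect_error(msa_distance_matrix(setNames(c("A-", "-C"), c("x", "y"))), "shared")
})

test_that("neighbour joining is exact on additive matrices", {
  # fixed 4-taxon additive matrix from tree ((A:1,B:2):1,(C:3,D:4))
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                                   c("A", "B", "C", "D")))
  tr <- nj_tree(D)
  split_ok <- ape::is.monophyletic(ape::root(tr, "D"), c("A", "B"))
  expect_true(split_ok)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
  # random additive 6-taxon matrices: topology recovered exactly
  set.seed(75)
  for (i in 1:100) {
    rt <- ape::rtree(6, br = function(n) runif(n, 0.5, 2))
    D6 <- cophenetic(rt)
    got <- nj_tree(D6)
    expect_equal(ape::dist.topo(ape::unroot(rt), ape::unroot(got)), structure(0, names = "PH85"),
                 ignore_attr = TRUE, info = sprintf("iter %d", i))
  }
})

test_that("nj_tree agrees with an independent implementation on random matrices", {
  set.seed(76)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    M <- matrix(runif(n * n, 0.1, 2), n, n)
    D <- (M + t(M)) / 2; diag(D) <- 0
    dimnames(D) <- list(letters[1:n], letters[1:n])
    got <- nj_tree(D)
    ref <- ape::nj(as.dist(D))
    expect_equal(ape::dist.topo(ape::unroot(got), ape::unroot(ref)),
                 structure(0, names = "PH85"), ignore_attr = TRUE,
                 info = sprintf("iter %d", i))
  }
})

test_that("bootstrap support is deterministic and bounded", {
  set.seed(77)
  ancA <- rand_aa(120); ancB <- rand_aa(120)
  fam <- c(setNames(vapply(1:4, function(i) mutate_prot(ancA, 0.08), character(1)),
                    sprintf("A%d", 1:4)),
           setNames(vapply(1:4, function(i) mutate_prot(ancB, 0.08), character(1)),
                    sprintf("B%d", 1:4)))
  msa <- progressive_align(seq_set(fam, "aa"))
  t1 <- bootstrap_support(msa, replicates = 50, seed = 9)
  t2 <- bootstrap_support(msa, replicates = 50, seed = 9)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  # the deep A|B split is strongly supported
  rooted <- ape::root(t1, "B1", resolve.root = TRUE, edgelabel = TRUE)
  expect_true(ape::is.monophyletic(rooted, sprintf("A%d", 1:4)))
  t3 <- bootstrap_support(msa, replicates = 1, seed = 3)
  s3 <- suppressWarnings(as.numeric(t3$node.label))
  expect_true(all(s3[!is.na(s3)] %in% c(0, 100)))
})

test_that("clade-based genus assignment follows the smallest supported clade", {
  set.seed(78)
  # genera are homologous RT variants of one ancestral domain, as in real
  # caulimovirid/retroelement panels (saturated unrelated sequences are
  # not the use case)
  base <- rand_aa(150)
  ancs <- setNames(lapply(1:3, function(i) mutate_prot(base, 0.20)), c("G1", "G2", "G3"))
  og <- mutate_prot(base, 0.35)
  seqs <- c(setNames(vapply(names(ancs), function(g) mutate_prot(ancs[[g]], 0.05),
                            character(1)), sprintf("REF_%s", names(ancs))),
            OG_ref = og)
  cands <- character(0)
  truthg <- character(0)
  for (i in 1:9) {
    g <- sprintf("G%d", ((i - 1) %% 3) + 1)
    cands[sprintf("cand%02d", i)] <- mutate_prot(ancs[[g]], 0.10)
    truthg[sprintf("cand%02d", i)] <- g
  }
  msa <- progressive_align(seq_set(c(seqs, cands), "aa"))
  tree <- bootstrap_support(msa, replicates = 100, seed = 4)
  labels <- setNames(c("G1", "G2", "G3", "outgroup"), names(seqs))
  cl <- classify_leaves(tree, labels, min_support = 70)
  acc <- mean(cl$genus == truthg[cl$candidate_id])
  expect_gte(acc, 0.9)
  expect_error(classify_leaves(tree, setNames("G1", "REF_G1")), "outgroup")
})

test_that("Newick output round-trips topology and supports", {
  set.seed(79)
  fam <- setNames(vapply(1:5, function(i) mutate_prot(rand_aa(100), 0), character(1)),
                  sprintf("s%d", 1:5))
  fam <- setNames(vapply(seq_along(fam), function(i) mutate_prot(fam[[1]], 0.1 * i),
                         character(1)), names(fam))
  msa <- progressive_align(seq_set(fam, "aa"))
  tr <- bootstrap_support(msa, replicates = 20, seed = 2)
  tf <- withr::local_tempfile()
  write_newick(tr, tf)
  back <- ape::read.tree(tf)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(tr)),
               structure(0, names = "PH85"), ignore_attr = TRUE)
  expect_equal(back$node.label, tr$node.label)
})
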