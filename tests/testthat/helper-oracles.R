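# Independent brute-force oracles and small fixture builders shared by
# the test files. Everything here is deliberately naive (per-base
# bitmaps, quadratic DP, table lookups) and independent of the package's
# implementation paths.

rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
rand_aa <- function(n) paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n, replace = TRUE),
                             collapse = "")

substitute_nt <- function(s, rate) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  i <- which(runif(length(v)) < rate)
  for (j in i) v[j] <- sample(setdiff(c("A", "C", "G", "T"), v[j]), 1)
  paste(v, collapse = "")
}

# per-base bitmap union of 0-based half-open spans; returns merged spans
bitmap_merge <- function(starts, ends, max_gap = 0L) {
  if (length(starts) == 0) return(data.frame(start = integer(0), end = integer(0)))
  lim <- max(ends) + max_gap + 2L
  hit <- logical(lim)
  for (i in seq_along(starts)) if (ends[i] > starts[i]) hit[(starts[i] + 1L):ends[i]] <- TRUE
  if (max_gap > 0) {
    # close gaps of size <= max_gap between covered runs
    r <- rle(hit)
    pos <- cumsum(r$lengths)
    for (i in seq_along(r$lengths)) {
      if (!r$values[i] && r$lengths[i] <= max_gap &&
          i > 1 && i < length(r$lengths)) {
        hit[(pos[i] - r$lengths[i] + 1L):pos[i]] <- TRUE
      }
    }
  }
  r <- rle(hit)
  ends2 <- cumsum(r$lengths)
  starts2 <- ends2 - r$lengths
  data.frame(start = starts2[r$values], end = ends2[r$values])
}

# quadratic Needleman-Wunsch with affine gaps matching align_pair's
# nucleotide scoring; returns identity over alignment columns
dp_global_identity <- function(a, b, match = 1, mismatch = -2, go = 5, ge = 2) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1); Y <- matrix(NEG, n + 1, m + 1)
  ptr <- array(0L, c(n + 1, m + 1, 3))
  # gap of length L costs go + ge * L, matching pairwiseAlignment
  M[1, 1] <- 0
  for (i in 2:(n + 1)) { X[i, 1] <- -go - ge * (i - 1); ptr[i, 1, 2] <- if (i == 2) 1L else 2L }
  for (j in 2:(m + 1)) { Y[1, j] <- -go - ge * (j - 1); ptr[1, j, 3] <- if (j == 2) 1L else 3L }
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (A[i - 1] == B[j - 1]) match else mismatch
    prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
    M[i, j] <- max(prev) + s
    ptr[i, j, 1] <- which.max(prev)
    vx <- c(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
    X[i, j] <- max(vx); ptr[i, j, 2] <- c(1L, 2L)[which.max(vx)]
    vy <- c(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
    Y[i, j] <- max(vy); ptr[i, j, 3] <- c(1L, 3L)[which.max(vy)]
  }
  # traceback for matches / columns
  fin <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  st <- which.max(fin)
  i <- n + 1; j <- m + 1
  matches <- 0L; cols <- 0L
  while (i > 1 || j > 1) {
    if (st == 1) {
      matches <- matches + (A[i - 1] == B[j - 1])
      cols <- cols + 1L
      st <- ptr[i, j, 1]; i <- i - 1; j <- j - 1
    } else if (st == 2) {
      cols <- cols + 1L
      st <- ptr[i, j, 2]; i <- i - 1
    } else {
      cols <- cols + 1L
      st <- ptr[i, j, 3]; j <- j - 1
    }
    if (i == 1 && st == 1 && j > 1) st <- 3
    if (j == 1 && st == 1 && i > 1) st <- 2
  }
  list(score = max(fin), identity_pct = 100 * matches / cols, cols = cols)
}

# independent per-codon translation using Biostrings' genetic code table
codon_translate <- function(nt) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(nt) - nchar(nt) %% 3
  if (n < 3) return("")
  cods <- substring(nt, seq(1, n, 3), seq(3, n, 3))
  paste(vapply(cods, function(cd) {
    if (grepl("[^ACGT]", cd)) {
      hits <- unique(gc[grepl(glob2rx(gsub("N", "*", cd)), names(gc))])
      # expand IUPAC crudely: translate all resolutions
      expand <- function(x) {
        opts <- list(A = "A", C = "C", G = "G", T = "T", N = c("A", "C", "G", "T"),
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                     K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                     D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"))
        do.call(paste0, expand.grid(opts[[substr(x, 1, 1)]], opts[[substr(x, 2, 2)]],
                                    opts[[substr(x, 3, 3)]]))
      }
      aa <- unique(gc[expand(cd)])
      if (length(aa) == 1) aa else "X"
    } else gc[[cd]]
  }, character(1)), collapse = "")
}

# brute-force transitive closure of an explicit link relation
closure_components <- function(n, links) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(links))) {
      i <- links[k, 1]; j <- links[k, 2]
      if (comp[i] != comp[j]) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# cached expensive fixtures (built once per test session)
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# standard small synthetic scene: 1 viral ancestor family + decoys
small_scene <- function() cached_fixture("small_scene", function() {
  anc <- make_ancestors(seed = 101)
  viral <- names(anc$genomes)[grepl("^virus", names(anc$genomes))]
  plan <- data.frame(ancestor_id = c("virus_G1", "gypsy_decoy"),
                     n_full = c(7L, 6L), n_fragment = 0L, n_tandem = 0L,
                     tandem_k = 3L, divergence = c(6, 10))
  sim <- plant_elements(250000, 0.36, anc$genomes, plan, seed = 202)
  list(anc = anc, sim = sim, viral = viral)
})
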