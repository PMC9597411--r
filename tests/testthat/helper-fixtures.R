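# Small in-code fixtures shared across test files.

# a minimal 2-genome, 2-pillar set with all tracks filled
toy_pillar_genes <- function() {
  rows <- list()
  for (p in 1:2) for (g in c("gA", "gB")) for (t in 1:3) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      pillar_id = p, genome = g, track = t,
      gene_id = sprintf("%s_p%d_t%d", g, p, t),
      chrom = sprintf("%s_chr%d", g, t),
      start = (p - 1) * 1000, end = (p - 1) * 1000 + 500, strand = "+"
    )
  }
  dplyr::bind_rows(rows)
}

toy_pillars <- function() pillar_set(toy_pillar_genes())

two_genome_tree <- function(u_a = 0.3, u_b = 0.35, u_root = 0.2) {
  tr <- ape::read.tree(text = sprintf("(gA:%g,gB:%g):%g;", u_a, u_b, u_root))
  tr
}

# brute-force forward likelihood by exhaustive path enumeration (<= 3 genomes,
# small pillar counts); independent of the C++ implementation
enumerate_loglik <- function(pillars, model, tree, theta) {
  enc <- hexfrac:::encode_dataset(pillars, tree)
  emis <- hexfrac:::emission_matrix(model, enc)   # S x nPat
  S <- enc$S
  G <- enc$G
  n <- length(enc$pat_of)
  A1 <- matrix(theta / 5, 6, 6)
  diag(A1) <- 1 - theta
  Tm <- matrix(1, S, S)
  for (s1 in 1:S) for (s2 in 1:S) {
    d1 <- hexfrac:::decode_state(s1 - 1L, G)
    d2 <- hexfrac:::decode_state(s2 - 1L, G)
    for (g in 1:G) Tm[s1, s2] <- Tm[s1, s2] * A1[d1[g], d2[g]]
  }
  paths <- as.matrix(expand.grid(rep(list(1:S), n)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    pr <- 1 / S * emis[s[1], enc$pat_of[1] + 1]
    for (t in seq_len(n - 1)) {
      step <- if (enc$new_block[t + 1]) 1 / S else Tm[s[t], s[t + 1]]
      pr <- pr * step * emis[s[t + 1], enc$pat_of[t + 1] + 1]
    }
    tot <- tot + pr
  }
  log(tot)
}

# truncated-series matrix exponential (independent oracle)
series_expm <- function(Q, u, terms = 60) {
  P <- diag(nrow(Q))
  term <- diag(nrow(Q))
  for (k in 1:terms) {
    term <- term %*% (Q * u) / k
    P <- P + term
  }
  P
}

# quadratic-space Smith-Waterman with affine gaps (independent oracle);
# returns the best local score and alignment length in columns
sw_oracle <- function(q, t, match = 4, mismatch = -5, open = 8, ext = 4) {
  qv <- strsplit(q, "")[[1]]
  tv <- strsplit(t, "")[[1]]
  n <- length(qv); m <- length(tv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)     # ending in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # gap in target (consume query)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in query (consume target)
  Lm <- matrix(0L, n + 1, m + 1); Lx <- matrix(0L, n + 1, m + 1)
  Ly <- matrix(0L, n + 1, m + 1)
  best <- 0; bestlen <- 0L
  for (i in 1:n) for (j in 1:m) {
    s <- if (qv[i] == tv[j] && qv[i] != "N") match else mismatch
    prev <- c(M[i, j], X[i, j], Y[i, j], 0)
    w <- which.max(prev)
    M[i + 1, j + 1] <- prev[w] + s
    Lm[i + 1, j + 1] <- (c(Lm[i, j], Lx[i, j], Ly[i, j], 0L))[w] + 1L
    cx <- c(M[i, j + 1] - open, X[i, j + 1] - ext)
    wx <- which.max(cx)
    X[i + 1, j + 1] <- cx[wx]
    Lx[i + 1, j + 1] <- (c(Lm[i, j + 1], Lx[i, j + 1]))[wx] + 1L
    cy <- c(M[i + 1, j] - open, Y[i + 1, j] - ext)
    wy <- which.max(cy)
    Y[i + 1, j + 1] <- cy[wy]
    Ly[i + 1, j + 1] <- (c(Lm[i + 1, j], Ly[i + 1, j]))[wy] + 1L
    if (M[i + 1, j + 1] > best) {
      best <- M[i + 1, j + 1]; bestlen <- Lm[i + 1, j + 1]
    }
  }
  list(score = best, length = bestlen)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
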