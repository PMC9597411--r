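test_that("leaf states encode surviving subgenome sets", {
  expect_equal(unname(leaf_state(c(TRUE, TRUE, TRUE), 1)),
               c(1, 0, 0, 0, 0, 0, 0))
  # tracks 1 and 3 present under (LF, IF, MF) -> D_LF.MF
  v <- leaf_state(c(TRUE, FALSE, TRUE), c("LF", "IF", "MF"))
  expect_equal(names(v)[v == 1], "D_LF.MF")
  expect_equal(unname(leaf_state(c(FALSE, FALSE, FALSE), 4)), rep(1, 7))
})

test_that("emission likelihood equals brute-force summation on 2-leaf trees", {
  tr <- two_genome_tree()
  rates <- as.list(setNames(c(0.7, 0.4, 1.2, 0.5, 0.9, 0.3, 1.1, 0.6),
                            hexfrac:::rho_names()[-1]))
  m <- build_model("arb", rates)
  P_root <- transition_matrix(m, 0.2)
  P_a <- transition_matrix(m, 0.3)
  P_b <- transition_matrix(m, 0.35)
  rd <- root_distribution(m)
  pres <- list(gA = c(TRUE, FALSE, FALSE), gB = c(TRUE, TRUE, FALSE))
  for (pa in 1:6) for (pb in c(1, 4, 6)) {
    got <- emission_likelihood(pres, c(gA = pa, gB = pb), m, tr)
    la <- leaf_state(pres$gA, pa)
    lb <- leaf_state(pres$gB, pb)
    # direct summation over the internal (root) node state
    at_root <- as.numeric(rd %*% P_root)
    want <- sum(at_root * as.numeric(P_a %*% la) * as.numeric(P_b %*% lb))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("fully retained pillars have state-independent emissions", {
  tr <- two_genome_tree()
  m <- build_model("arb", as.list(setNames(runif(8, 0.3, 1.5),
                                           hexfrac:::rho_names()[-1])))
  pres <- list(gA = rep(TRUE, 3), gB = rep(TRUE, 3))
  vals <- sapply(1:6, function(pa) {
    emission_likelihood(pres, c(gA = pa, gB = 3), m, tr)
  })
  expect_lt(diff(range(vals)), 1e-14)
})

test_that("single-genome emission reduces to one transition probability", {
  # one leaf, branch u: retaining only the LF-mapped track is P(T -> S_LF)(u)
  tip <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = "gA",
              Nnode = 1L, edge.length = 0.6, root.edge = 0)
  class(tip) <- "phylo"
  m <- build_model("arb", as.list(setNames(runif(8, 0.3, 1.5),
                                           hexfrac:::rho_names()[-1])))
  got <- emission_likelihood(list(gA = c(TRUE, FALSE, FALSE)),
                             c(gA = 1), m, tip)
  expect_equal(got, transition_matrix(m, 0.6)["T", "S_LF"],
               tolerance = 1e-12)
})

test_that("forward likelihood equals exhaustive path enumeration", {
  cfg <- sim_config(genomes = c("gA", "gB"), n_pillars = 3, theta = 0.25,
                    arrival = NULL, seed = 9, mean_block_length = 50)
  sim <- simulate_pillars(cfg)
  m <- sim$truth$model
  ll <- forward_loglik(sim$pillars, m, cfg$tree, 0.25)
  expect_equal(ll, enumerate_loglik(sim$pillars, m, cfg$tree, 0.25),
               tolerance = 1e-9)
  # arrival variant exercises the non-trivial root distribution
  cfg2 <- sim_config(genomes = c("gA", "gB"), n_pillars = 3, theta = 0.1,
                     arrival = list(last = "MF", tau = 0.3, kappa = 1.2),
                     seed = 10, mean_block_length = 50)
  sim2 <- simulate_pillars(cfg2)
  m2 <- sim2$truth$model
  ll2 <- forward_loglik(sim2$pillars, m2, cfg2$tree, 0.1)
  expect_equal(ll2, enumerate_loglik(sim2$pillars, m2, cfg2$tree, 0.1),
               tolerance = 1e-9)
})

test_that("forward and backward recursions agree", {
  cfg <- sim_config(n_pillars = 60, seed = 12, theta = 0.15)
  sim <- simulate_pillars(cfg)
  enc <- hexfrac:::encode_dataset(sim$pillars, cfg$tree)
  emis <- hexfrac:::emission_matrix(sim$truth$model, enc)
  fwd <- hexfrac:::cpp_forward_loglik(emis, enc$pat_of, enc$new_block,
                                      0.15, enc$G)
  bwd <- hexfrac:::cpp_backward_loglik(emis, enc$pat_of, enc$new_block,
                                       0.15, enc$G)
  expect_equal(fwd, bwd, tolerance = 1e-8)
})

test_that("posteriors are proper and match enumeration on small instances", {
  cfg <- sim_config(genomes = c("gA", "gB"), n_pillars = 3, theta = 0.2,
                    arrival = NULL, seed = 14, mean_block_length = 50)
  sim <- simulate_pillars(cfg)
  m <- sim$truth$model
  pd <- posterior_decode(sim$pillars, m, cfg$tree, 0.2)
  expect_true(all(abs(rowSums(pd$joint) - 1) < 1e-8))
  # marginals are consistent with the joint
  sums <- pd$marginals |>
    dplyr::summarise(s = sum(prob),
                     .by = c(pillar_id, genome, track))
  expect_true(all(abs(sums$s - 1) < 1e-8))
  # MAP has maximal posterior
  expect_true(all(pd$map$prob >= apply(pd$joint, 1, max) - 1e-12))

  # independent enumeration of the joint posterior at pillar 1
  enc <- hexfrac:::encode_dataset(sim$pillars, cfg$tree)
  emis <- hexfrac:::emission_matrix(m, enc)
  S <- enc$S
  theta <- 0.2
  A1 <- matrix(theta / 5, 6, 6); diag(A1) <- 1 - theta
  Tm <- matrix(1, S, S)
  for (s1 in 1:S) for (s2 in 1:S) {
    d1 <- hexfrac:::decode_state(s1 - 1L, 2)
    d2 <- hexfrac:::decode_state(s2 - 1L, 2)
    Tm[s1, s2] <- A1[d1[1], d2[1]] * A1[d1[2], d2[2]]
  }
  marg1 <- numeric(S)
  nb <- enc$new_block
  for (s1 in 1:S) {
    tot <- 0
    for (s2 in 1:S) for (s3 in 1:S) {
      pr <- emis[s1, enc$pat_of[1] + 1] / S *
        (if (nb[2]) 1 / S else Tm[s1, s2]) * emis[s2, enc$pat_of[2] + 1] *
        (if (nb[3]) 1 / S else Tm[s2, s3]) * emis[s3, enc$pat_of[3] + 1]
      tot <- tot + pr
    }
    marg1[s1] <- tot
  }
  marg1 <- marg1 / sum(marg1)
  expect_equal(unname(pd$joint[1, ]), marg1, tolerance = 1e-9)
})

test_that("uniform symmetry: all-retained pillars give uniform posteriors", {
  genes <- toy_pillar_genes()
  ps <- pillar_set(genes)
  tr <- two_genome_tree()
  m <- build_model("null", list(sigma = 0.7))
  pd <- posterior_decode(ps, m, tr, 0.1)
  expect_true(all(abs(pd$joint - 1 / 36) < 1e-10))
  # and the forward lnL is theta-independent (emissions state-independent)
  expect_equal(forward_loglik(ps, m, tr, 0.05),
               forward_loglik(ps, m, tr, 0.6), tolerance = 1e-9)
})

test_that("likelihood is invariant under consistent subgenome relabelling", {
  cfg <- sim_config(genomes = c("gA", "gB"), n_pillars = 40, theta = 0.1,
                    arrival = NULL, seed = 16)
  sim <- simulate_pillars(cfg)
  m <- sim$truth$model
  ll <- forward_loglik(sim$pillars, m, cfg$tree, 0.1)
  map <- c(LF = "MF", IF = "LF", MF = "IF")
  pr <- hexfrac:::permute_rho(m$rho, map)
  m2 <- m; m2$rho <- pr$rho
  tr2 <- hexfrac:::set_branch_lengths(
    cfg$tree, c(cfg$tree$root.edge, cfg$tree$edge.length) * pr$u_scale)
  ll2 <- forward_loglik(sim$pillars, m2, tr2, 0.1)
  expect_equal(ll, ll2, tolerance = 1e-8)
})

test_that("a frozen chain (theta = 0) forbids permutation changes in a block", {
  # two pillars in one block, consistent only with different permutations
  genes <- dplyr::bind_rows(
    tibble::tibble(pillar_id = 1, genome = "gA", track = 1,
                   gene_id = "a1", chrom = "c1", start = 0, end = 10,
                   strand = "+"),
    tibble::tibble(pillar_id = 2, genome = "gA", track = 2,
                   gene_id = "a2", chrom = "c2", start = 0, end = 10,
                   strand = "+")
  )
  ps <- pillar_set(genes, genomes = "gA")
  tip <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = "gA",
              Nnode = 1L, edge.length = 3, root.edge = 0)
  class(tip) <- "phylo"
  # rates that make S_LF overwhelmingly likely: only the permutation mapping
  # the occupied track to LF is plausible at each pillar, but the occupied
  # track changes between the pillars
  rates <- setNames(c(1e-4, 1e-4, 4, 1e-4, 4, 1e-4, 1e-4, 1e-4),
                    hexfrac:::rho_names()[-1])
  m <- build_model("arb", as.list(rates))
  ll0 <- forward_loglik(ps, m, tip, 0)
  llsmall <- forward_loglik(ps, m, tip, 0.05)
  expect_lt(ll0, llsmall)  # freezing the chain can only lose likelihood here
  expect_error(forward_loglik(ps, m, tip, 1), "theta")
})
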