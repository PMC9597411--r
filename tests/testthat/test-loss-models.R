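test_that("family definitions materialise the expected rate structure", {
  m <- build_model("null", list(sigma = 0.5))
  expect_equal(unname(m$rho), c(1, 1, 1, rep(0.5, 6)))
  # 1d with unit modifiers collapses onto null
  m1 <- build_model("1d", list(sigma = 0.5, f_t = 1, f_d = 1))
  expect_equal(m1$rho, m$rho)
  # arb materialises free rates verbatim
  r <- c(td_lf_mf = 0.7, td_if_mf = 0.2, ds_lfif_lf = 1.2, ds_lfif_if = 0.4,
         ds_lfmf_lf = 0.9, ds_lfmf_mf = 0.3, ds_ifmf_if = 1.1,
         ds_ifmf_mf = 0.6)
  ma <- build_model("arb", as.list(r))
  expect_equal(ma$rho[-1], r)
  expect_equal(unname(ma$rho[1]), 1)
})

test_that("free-parameter counts reproduce the nested-test degrees of freedom", {
  counts <- vapply(c("null", "1d", "3g", "arb"),
                   function(f) count_free_parameters(build_model(f)),
                   integer(1))
  expect_equal(unname(counts), c(1L, 3L, 5L, 8L))
  expect_equal(unname(diff(counts)), c(2L, 2L, 3L))
  arr <- build_model("arb", arrival = list(last = "MF", tau = 0.2))
  expect_equal(count_free_parameters(arr) -
                 count_free_parameters(build_model("arb")), 2L)
  rv <- build_model("arb", root_params = list(td_lf_if = 1, td_lf_mf = 1.3,
                                              td_if_mf = 0.7))
  expect_equal(count_free_parameters(rv) -
                 count_free_parameters(build_model("arb")), 3L)
  # root branch keeps the shared D -> S rates, swaps only the T -> D rates
  expect_equal(rv$root_rho[4:9], rv$rho[4:9])
  expect_equal(unname(rv$root_rho[2]), 1.3)
})

test_that("every family nests in the next richer one with identical matrices", {
  set.seed(71)
  for (rep in 1:5) {
    s <- runif(1, 0.2, 2); ft <- runif(1, 0.2, 2); fd <- runif(1, 0.2, 2)
    gt <- runif(1, 0.2, 2); gd <- runif(1, 0.2, 2)
    m1 <- build_model("1d", list(sigma = s, f_t = ft, f_d = fd))
    m3 <- build_model("3g", list(sigma = s, f_t = ft, f_d = fd,
                                 g_t = 1, g_d = 1))
    expect_equal(m1$rho, m3$rho)
    m3b <- build_model("3g", list(sigma = s, f_t = ft, f_d = fd,
                                  g_t = gt, g_d = gd))
    ma <- build_model("arb", as.list(m3b$rho[-1]))
    expect_equal(m3b$rho, ma$rho)
    u <- runif(1, 0, 2)
    expect_equal(transition_matrix(m3b, u), transition_matrix(ma, u))
  }
})

test_that("transition matrices match closed form and a series oracle", {
  m <- build_model("null", list(sigma = 0.5))
  for (u in c(0.1, 0.5, 2)) {
    P <- transition_matrix(m, u)
    expect_equal(P["T", "T"], exp(-3 * u), tolerance = 1e-10)
    expect_lt(max(abs(P - series_expm(hexfrac:::rate_matrix(m$rho), u))),
              1e-10)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    expect_true(all(P >= 0 & P <= 1 + 1e-12))
  }
  expect_equal(transition_matrix(m, 0), diag(7), ignore_attr = TRUE)
  # deep time drives all mass into the absorbing single-copy states
  ma <- build_model("arb", as.list(setNames(runif(8, 0.3, 1.5),
                                            hexfrac:::rho_names()[-1])))
  P50 <- transition_matrix(ma, 50)
  expect_gte(min(rowSums(P50[, c("S_LF", "S_IF", "S_MF")])[1:4]), 1 - 1e-6)
  expect_error(transition_matrix(m, -0.1), "u must")
})

test_that("Chapman-Kolmogorov holds for random parameter draws", {
  set.seed(42)
  for (rep in 1:5) {
    m <- build_model("arb", as.list(setNames(runif(8, 0.1, 2),
                                             hexfrac:::rho_names()[-1])))
    u1 <- runif(1, 0, 1.5); u2 <- runif(1, 0, 1.5)
    lhs <- transition_matrix(m, u1) %*% transition_matrix(m, u2)
    rhs <- transition_matrix(m, u1 + u2)
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})

test_that("root distribution handles arrival scenarios", {
  m <- build_model("arb")
  expect_equal(unname(root_distribution(m)), c(1, rep(0, 6)))
  m0 <- build_model("arb", arrival = list(last = "LF", tau = 0))
  expect_equal(unname(root_distribution(m0)), c(1, rep(0, 6)))
  # MF last: founders LF and IF evolve as a 3-state chain for tau, then the
  # hexaploidy maps D_LF.IF -> T, S_LF -> D_LF.MF, S_IF -> D_IF.MF
  rates <- as.list(setNames(c(0.8, 0.6, 1.2, 0.5, 0.9, 0.4, 1.1, 0.7),
                            hexfrac:::rho_names()[-1]))
  tau <- 0.2; kap <- 1.3
  m2 <- build_model("arb", rates, arrival = list(last = "MF", tau = tau,
                                                 kappa = kap))
  a <- m2$rho[["ds_lfif_lf"]]; b <- m2$rho[["ds_lfif_if"]]
  r <- kap * (a + b)
  expected <- setNames(rep(0, 7), loss_states())
  expected["T"] <- exp(-r * tau)
  expected["D_LF.MF"] <- a / (a + b) * (1 - exp(-r * tau))
  expected["D_IF.MF"] <- b / (a + b) * (1 - exp(-r * tau))
  expect_equal(root_distribution(m2), expected, tolerance = 1e-12)
  expect_equal(sum(root_distribution(m2)), 1, tolerance = 1e-12)
})

test_that("build_model rejects invalid configurations", {
  expect_error(build_model("null", list(sigma = -1)), "non-negative")
  expect_error(build_model("arb", arrival = list(tau = 0.1)), "last")
  expect_error(build_model("1d", root_params = list(a = 1)), "arb")
  expect_error(build_model("arb", list(td_lf_mf = 1)), "missing parameters")
})

test_that("subgenome relabelling permutes rates consistently", {
  rates <- as.list(setNames(runif(8, 0.2, 2), hexfrac:::rho_names()[-1]))
  m <- build_model("arb", rates)
  map <- c(LF = "IF", IF = "MF", MF = "LF")
  pr <- hexfrac:::permute_rho(m$rho, map)
  expect_equal(unname(pr$rho[1]), 1)
  # losing MF from T: old td_lf_if; new labels: losing map[MF]=LF is the
  # transition to the pair {map[LF], map[IF]} = {IF, MF}
  expect_equal(unname(pr$rho[["td_if_mf"]] * pr$u_scale),
               unname(m$rho[["td_lf_if"]]))
  # applying the inverse map recovers the original rates
  inv <- setNames(names(map), unname(map))
  back <- hexfrac:::permute_rho(pr$rho, inv)
  expect_equal(back$rho, m$rho / m$rho[1], tolerance = 1e-12)
})
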