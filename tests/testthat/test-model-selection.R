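fake_fit <- function(family, loglik, n_pillars = 100, arrival = NULL) {
  model <- build_model(family, arrival = arrival)
  structure(list(model = model, loglik = loglik, family = family,
                 theta = 0.1, n_free = count_free_parameters(model),
                 data = list(n_pillars = n_pillars, genomes = c("a", "b")),
                 diagnostics = list(converged = TRUE)),
            class = "wgt_fit")
}

test_that("LRT arithmetic, degrees of freedom and chi-square tail", {
  r <- lrt(fake_fit("null", -1000), fake_fit("1d", -1000))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 2L)
  r2 <- lrt(fake_fit("3g", -1000), fake_fit("arb", -993.1))
  expect_equal(r2$df, 3L)
  expect_equal(r2$statistic, 13.8, tolerance = 1e-9)
  # chi-square upper tail oracle: 2 d.f. tail is exp(-x/2)
  r3 <- lrt(fake_fit("null", -1006.9), fake_fit("1d", -1000))
  expect_equal(r3$p_value, exp(-13.8 / 2), tolerance = 1e-9)
  expect_equal(r3$p_value, 1.0e-3, tolerance = 2e-2)
  expect_error(lrt(fake_fit("arb", -1), fake_fit("null", -1)), "not nested")
  expect_warning(lrt(fake_fit("null", -999), fake_fit("1d", -999.5)),
                 "negative")
})

test_that("p-values decrease monotonically in the statistic", {
  stats <- seq(0, 30, by = 3)
  ps <- pchisq(stats, df = 2, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
})

test_that("topology comparison ranks the generating topology first", {
  cfg <- sim_config(genomes = c("gA", "gB", "gC"), n_pillars = 1200,
                    theta = 0.1, arrival = NULL, seed = 401)
  sim <- simulate_pillars(cfg)
  topos <- list(
    truth = ape::read.tree(text = "((gA,gB),gC);"),
    alt1 = ape::read.tree(text = "((gA,gC),gB);"),
    alt2 = ape::read.tree(text = "((gB,gC),gA);")
  )
  tab <- compare_topologies(sim$pillars, topos, family = "arb",
                            n_starts = 1, seed = 5,
                            control = list(factr = 1e9))
  expect_equal(tab$topology[1], "truth")
  # input order invariance (same fits, same ranking)
  tab2 <- compare_topologies(sim$pillars, rev(topos), family = "arb",
                             n_starts = 1, seed = 5,
                             control = list(factr = 1e9))
  expect_equal(tab2$topology[1], "truth")
  expect_equal(sort(tab$loglik), sort(tab2$loglik), tolerance = 1e-6)
  # duplicated topologies tie within optimiser tolerance
  tab3 <- compare_topologies(sim$pillars,
                             list(a = topos$truth, b = topos$truth),
                             family = "3g", n_starts = 1, seed = 5,
                             control = list(factr = 1e9))
  expect_lt(abs(diff(tab3$loglik)), 0.5)
  expect_error(compare_topologies(sim$pillars, list(
    topos$truth, ape::read.tree(text = "((gA,gB),gD);"))), "leaf set")
})

test_that("arrival comparison flags structural collapse at tau = 0", {
  cfg <- sim_config(genomes = c("gA", "gB"), n_pillars = 500, theta = 0.1,
                    arrival = NULL, seed = 402)
  sim <- simulate_pillars(cfg)
  topo <- ape::read.tree(text = "(gA,gB);")
  arb <- fit_loss_model(sim$pillars, topo, family = "arb", n_starts = 1,
                        seed = 6, control = list(factr = 1e9))
  cmp <- compare_arrival_models(sim$pillars, topo, arb_fit = arb,
                                n_starts = 1, seed = 6,
                                control = list(factr = 1e9))
  expect_equal(nrow(cmp$table), 3)
  expect_true(all(cmp$table$df == 2))
  # data without a tetraploid phase: no arrival model may fall below arb
  expect_true(all(cmp$table$delta_lnl > -0.5))
  # at least one candidate collapses (tau fitted to ~0 reproduces arb)
  expect_true(any(cmp$table$collapsed))
})

test_that("root-branch contrast reports reversals and ties", {
  rates <- setNames(rep(1, 8), hexfrac:::rho_names()[-1])
  same <- fake_fit("arb", -10)
  same$model$root_rho <- same$model$rho
  rc <- root_branch_contrast(same)
  expect_true(all(rc$favoured == "tied"))
  expect_false(rc$reversed[1])
  rev_fit <- fake_fit("arb", -10)
  rev_fit$model$rho[["td_lf_mf"]] <- 0.5    # later branches favour D_LF.IF
  rev_fit$model$root_rho <- rev_fit$model$rho
  rev_fit$model$root_rho[["td_lf_mf"]] <- 1.6  # root favours D_LF.MF
  rc2 <- root_branch_contrast(rev_fit)
  expect_true(rc2$reversed[1])
  expect_equal(rc2$favoured, c("D_LF.MF", "D_LF.IF"))
  expect_error(root_branch_contrast(fake_fit("arb", -1)), "root")
})
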