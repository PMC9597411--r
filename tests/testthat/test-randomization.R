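sym_sairs <- function(n_per = 6, len = 1000) {
  tibble::tibble(
    sair_id = sprintf("s%02d", seq_len(2 * n_per)),
    subgenome = rep(c("A", "B"), each = n_per),
    start = 0, end = len)
}

test_that("identical subgenomes with a zero observed difference give p near 1", {
  sairs <- sym_sairs()
  hits <- tibble::tibble(sair_id = c("s01", "s07"), start = 0, end = 100)
  rt <- randomization_test(hits, sairs, c("A", "B"), replicates = 300,
                           seed = 1)
  expect_equal(rt$observed_diff, 0)
  expect_gt(rt$p_value, 0.9)
})

test_that("the same seed reproduces identical results", {
  sairs <- sym_sairs(8, 1500)
  hits <- tibble::tibble(sair_id = c("s01", "s02", "s09", "s10", "s11"),
                         start = 0, end = c(100, 200, 150, 120, 90))
  r1 <- randomization_test(hits, sairs, c("A", "B"), replicates = 200,
                           seed = 42)
  r2 <- randomization_test(hits, sairs, c("A", "B"), replicates = 200,
                           seed = 42)
  expect_identical(r1, r2)
})

test_that("one hit across two equal SAIRs matches exact enumeration", {
  # a single hit lands in A or B with probability 1/2 each; the two-sided
  # p-value is then 1 for either outcome (|null diff| = |observed| always)
  sairs <- tibble::tibble(sair_id = c("sA", "sB"),
                          subgenome = c("A", "B"), start = 0, end = 500)
  hits <- tibble::tibble(sair_id = "sA", start = 0, end = 100)
  rt <- randomization_test(hits, sairs, c("A", "B"), replicates = 400,
                           seed = 7)
  expect_equal(rt$p_value, 1, tolerance = 1e-12)
  # one-sided: P(null >= observed) = P(hit lands in A) = 1/2
  rt1 <- randomization_test(hits, sairs, c("A", "B"), replicates = 2000,
                            seed = 8, alternative = "greater")
  expect_lt(abs(rt1$p_value - 0.5), 3 * sqrt(0.25 / 2000) + 1e-3)
})

test_that("strong planted enrichment reaches the add-one floor", {
  set.seed(11)
  sairs <- tibble::tibble(
    sair_id = sprintf("s%03d", 1:120),
    subgenome = rep(c("A", "B"), each = 60),
    start = 0, end = round(runif(120, 1500, 2500)))
  # ~10x density in A: 50 hits in A, 5 in B
  hits <- tibble::tibble(
    sair_id = c(sample(sairs$sair_id[1:60], 50),
                sample(sairs$sair_id[61:120], 5)),
    start = 0, end = round(runif(55, 80, 300)))
  rt <- randomization_test(hits, sairs, c("A", "B"), replicates = 999,
                           seed = 12)
  expect_equal(rt$p_value, 1 / 1000)
})

test_that("placement never reuses a SAIR and errors when it cannot place", {
  sairs <- sym_sairs(2, 300)
  hits <- tibble::tibble(sair_id = c("s01", "s02", "s03", "s04", "s01"),
                         start = 0, end = 50)
  expect_error(randomization_test(hits, sairs, c("A", "B"),
                                  replicates = 100),
               "more hits")
  # a hit longer than every SAIR cannot be placed
  sairs2 <- sym_sairs(3, 200)
  hits2 <- tibble::tibble(sair_id = "s01", start = 0, end = 250)
  expect_error(randomization_test(hits2, sairs2, c("A", "B"),
                                  replicates = 100, seed = 2),
               "no remaining SAIR|no hits")
})

test_that("randomized-tie p-values are uniform under the null", {
  # observed data generated by the placement procedure itself
  set.seed(13)
  sairs <- tibble::tibble(
    sair_id = sprintf("s%03d", 1:40),
    subgenome = rep(c("A", "B"), each = 20),
    start = 0, end = round(runif(40, 800, 2000)))
  lens <- sairs$end
  place_null <- function() {
    hl <- round(runif(8, 60, 200))
    used <- logical(40)
    ids <- character(8)
    for (h in seq_along(hl)) {
      w <- lens - hl[h]; w[used | w <= 0] <- 0
      pos <- runif(1) * sum(w)
      k <- which(cumsum(w) >= pos)[1]
      used[k] <- TRUE
      ids[h] <- sairs$sair_id[k]
    }
    tibble::tibble(sair_id = ids, start = 0, end = hl)
  }
  ps <- vapply(1:120, function(i) {
    randomization_test(place_null(), sairs, c("A", "B"), replicates = 150,
                       ties = "random")$p_value
  }, numeric(1))
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
  # the conservative variant is super-uniform at the 5% level
  ps2 <- vapply(1:120, function(i) {
    randomization_test(place_null(), sairs, c("A", "B"),
                       replicates = 150)$p_value
  }, numeric(1))
  expect_lte(mean(ps2 <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
})
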