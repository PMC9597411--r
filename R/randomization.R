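#' Randomization test for repeat-density differences between subgenomes
#'
#' Tests whether the observed difference in repeat density (hits/kB) between
#' two subgenomes could arise by chance placement. Each replicate shuffles
#' the order of the observed hits and places them uniformly at random into
#' the pooled SAIRs of both subgenomes: for a hit of length `L`, the number
#' of available positions is the sum over eligible SAIRs of
#' `SAIR length - L` (SAIRs shorter than the hit are omitted), a uniform
#' draw picks the position, and the receiving SAIR is removed from the pool
#' for all later hits of that replicate - so placed hits can never overlap.
#' The replicate's density difference is recomputed from the randomized
#' placements and compared to the observed difference.
#'
#' The p-value uses the add-one rule `p = (exceedances + 1)/(replicates + 1)`.
#' Because hit counts are integers the null statistic has atoms; with
#' `ties = "conservative"` (default) tied replicates count as exceedances,
#' giving a valid but super-uniform p-value. `ties = "random"` breaks ties
#' uniformly, which makes the null p-value distribution exactly uniform (the
#' calibration diagnostic used in the package's tests).
#'
#' @param hits Hit tibble (`sair_id`, `start`, `end`; one row per hit) for
#'   one genome.
#' @param sairs SAIR tibble for the same genome (`sair_id`, `subgenome`,
#'   `start`, `end`).
#' @param pair Character vector of the two subgenomes compared (difference is
#'   `pair[1] - pair[2]`).
#' @param replicates Number of randomization replicates (default 10000).
#' @param seed Optional RNG seed.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param ties `"conservative"` or `"random"` (see Details).
#' @return A one-row tibble: `subgenome_a`, `subgenome_b`, `observed_diff`,
#'   `density_a`, `density_b`, `replicates`, `exceedances`, `p_value`,
#'   `alternative`.
#' @export
randomization_test <- function(hits, sairs, pair, replicates = 10000,
                               seed = NULL,
                               alternative = c("two.sided", "greater", "less"),
                               ties = c("conservative", "random")) {
  alternative <- match.arg(alternative)
  ties <- match.arg(ties)
  stopifnot(length(pair) == 2, replicates >= 100)
  if (!is.null(seed)) set.seed(seed)
  pool <- sairs |>
    dplyr::filter(.data$subgenome %in% pair) |>
    dplyr::mutate(length = .data$end - .data$start)
  if (nrow(pool) == 0) stop("no SAIRs for subgenomes ",
                            paste(pair, collapse = ", "))
  hits <- dplyr::semi_join(hits, pool, by = "sair_id")
  hl <- hits$end - hits$start
  H <- length(hl)
  if (H == 0) stop("no hits fall in the SAIRs of the tested subgenomes")
  if (H > nrow(pool)) {
    stop("more hits (", H, ") than SAIRs (", nrow(pool),
         "); placement without SAIR reuse is impossible")
  }
  lens <- pool$length
  sg <- pool$subgenome
  tot_len <- c(sum(lens[sg == pair[1]]), sum(lens[sg == pair[2]]))
  if (any(tot_len <= 0)) stop("zero total SAIR length in one subgenome")
  obs_n <- c(sum(hits$sair_id %in% pool$sair_id[sg == pair[1]]),
             sum(hits$sair_id %in% pool$sair_id[sg == pair[2]]))
  dens <- 1000 * obs_n / tot_len
  obs <- dens[1] - dens[2]

  is_a <- sg == pair[1]
  null_diff <- numeric(replicates)
  for (r in seq_len(replicates)) {
    ord <- sample.int(H)
    used <- logical(length(lens))
    n_a <- 0L; n_b <- 0L
    for (h in ord) {
      L <- hl[h]
      w <- lens - L
      w[used | w <= 0] <- 0
      t_total <- sum(w)
      if (t_total <= 0) {
        stop("no remaining SAIR can host a hit of length ", L,
             " in replicate ", r)
      }
      pos <- runif(1) * t_total
      k <- which(cumsum(w) >= pos)[1]
      used[k] <- TRUE
      if (is_a[k]) n_a <- n_a + 1L else n_b <- n_b + 1L
    }
    null_diff[r] <- 1000 * (n_a / tot_len[1] - n_b / tot_len[2])
  }

  stat <- switch(alternative,
                 two.sided = abs(null_diff),
                 greater = null_diff,
                 less = -null_diff)
  obs_stat <- switch(alternative,
                     two.sided = abs(obs), greater = obs, less = -obs)
  eps <- 1e-9
  n_gt <- sum(stat > obs_stat + eps)
  n_eq <- sum(abs(stat - obs_stat) <= eps)
  exceed <- n_gt + n_eq
  p <- if (ties == "conservative") {
    (exceed + 1) / (replicates + 1)
  } else {
    (n_gt + runif(1) * (n_eq + 1)) / (replicates + 1)
  }
  tibble::tibble(
    subgenome_a = pair[1], subgenome_b = pair[2],
    observed_diff = obs, density_a = dens[1], density_b = dens[2],
    replicates = replicates, exceedances = exceed, p_value = p,
    alternative = alternative
  )
}
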