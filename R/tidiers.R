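#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted gene-loss model
#'
#' One row per estimated parameter: the materialised relative rates, the
#' branch lengths (root edge first, then the tree's edge order), `theta`,
#' and any arrival / root-branch parameters.
#'
#' @param x A `wgt_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `block`.
#' @export
tidy.wgt_fit <- function(x, ...) {
  rows <- list(
    tibble::tibble(term = names(x$model$rho), estimate = unname(x$model$rho),
                   block = "rate"),
    tibble::tibble(term = c("u_root", paste0("u_", branch_labels(x$tree))),
                   estimate = c(x$tree$root.edge, x$tree$edge.length),
                   block = "branch_length"),
    tibble::tibble(term = "theta", estimate = x$theta, block = "hmm")
  )
  if (!is.null(x$model$arrival)) {
    rows <- c(rows, list(tibble::tibble(
      term = c("tau", "kappa"),
      estimate = c(x$model$arrival$tau, x$model$arrival$kappa),
      block = "arrival"
    )))
  }
  if (!is.null(x$model$root_rho)) {
    rows <- c(rows, list(tibble::tibble(
      term = paste0("root_", names(x$model$root_rho)),
      estimate = unname(x$model$root_rho), block = "root_rate"
    )))
  }
  dplyr::bind_rows(rows)
}

branch_labels <- function(tree) {
  n <- length(tree$tip.label)
  vapply(tree$edge[, 2], function(node) {
    if (node <= n) tree$tip.label[node] else paste0("node", node)
  }, character(1))
}

#' One-line summary of a fitted gene-loss model
#'
#' @param x A `wgt_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `family`, `arrival`, `root_variant`, `loglik`,
#'   `n_free_rates`, `n_branches`, `theta`, `converged`, `n_pillars`.
#' @export
glance.wgt_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    arrival = if (is.null(x$model$arrival)) NA_character_ else
      x$model$arrival$last,
    root_variant = !is.null(x$model$root_rho),
    loglik = x$loglik,
    n_free_rates = x$n_free,
    n_branches = nrow(x$tree$edge) + 1L,
    theta = x$theta,
    converged = x$diagnostics$converged,
    n_pillars = x$data$n_pillars
  )
}
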