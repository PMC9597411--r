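family_rank <- function(family) match(family, model_families())

# is fit_a nested within fit_b?
is_nested <- function(fit_null, fit_alt) {
  fam_ok <- family_rank(fit_null$family) <= family_rank(fit_alt$family)
  null_extras <- (!is.null(fit_null$model$arrival)) +
    (!is.null(fit_null$model$root_rho))
  # an arrival or root-variant null can only nest in an alt with the same extra
  arr_ok <- is.null(fit_null$model$arrival) ||
    (!is.null(fit_alt$model$arrival) &&
       fit_null$model$arrival$last == fit_alt$model$arrival$last)
  root_ok <- is.null(fit_null$model$root_rho) || !is.null(fit_alt$model$root_rho)
  fam_ok && arr_ok && root_ok && null_extras <= 2
}

#' Likelihood-ratio test between nested fitted models
#'
#' Computes `2 * (lnL_alt - lnL_null)` with degrees of freedom equal to the
#' difference in free rate parameters ([count_free_parameters()]) and a
#' p-value from the upper chi-square tail. A slightly negative statistic
#' (optimiser tolerance) is clipped to 0 with a warning. For arrival models,
#' `tau` sits on the boundary of its range under the null; the chi-square
#' reference is still used (see the `boundary` flag in the output).
#'
#' @param fit_null,fit_alt `wgt_fit` objects on the same data, with
#'   `fit_null`'s family nested in `fit_alt`'s.
#' @return A one-row tibble: `lnl_null`, `lnl_alt`, `statistic`, `df`,
#'   `p_value`, `boundary`.
#' @export
lrt <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "wgt_fit"), inherits(fit_alt, "wgt_fit"))
  if (!is_nested(fit_null, fit_alt)) {
    stop("fit_null ('", fit_null$family, "') is not nested in fit_alt ('",
         fit_alt$family, "')")
  }
  if (!identical(fit_null$data$n_pillars, fit_alt$data$n_pillars)) {
    stop("fits are not on the same data")
  }
  df <- count_free_parameters(fit_alt$model) -
    count_free_parameters(fit_null$model)
  if (df < 1) stop("alternative model adds no free parameters")
  stat <- 2 * (fit_alt$loglik - fit_null$loglik)
  if (stat < 0) {
    warning("negative LRT statistic (", format(stat), ") clipped to 0; ",
            "check optimiser convergence")
    stat <- 0
  }
  tibble::tibble(
    lnl_null = fit_null$loglik, lnl_alt = fit_alt$loglik,
    statistic = stat, df = df,
    p_value = pchisq(stat, df = df, lower.tail = FALSE),
    boundary = !is.null(fit_alt$model$arrival) &&
      is.null(fit_null$model$arrival)
  )
}

#' Compare rooted topologies under one model family
#'
#' Fits the same loss-model family independently on each candidate rooted
#' topology and ranks them by maximised ln-likelihood.
#'
#' @param pillars A [pillar_set()].
#' @param topologies A (preferably named) list of [ape::phylo] trees over the
#'   same leaf set.
#' @param family Model family to fit (default `"arb"`).
#' @param ... Passed to [fit_loss_model()].
#' @return A tibble sorted by `loglik` descending: `topology`, `newick`,
#'   `loglik`, `rank`, and a list-column `fit`.
#' @export
compare_topologies <- function(pillars, topologies, family = "arb", ...) {
  stopifnot(length(topologies) >= 2)
  leafsets <- lapply(topologies, function(t) sort(t$tip.label))
  if (!all(vapply(leafsets, identical, logical(1), y = leafsets[[1]]))) {
    stop("all topologies must share the same leaf set")
  }
  nm <- names(topologies)
  if (is.null(nm)) nm <- paste0("topology_", seq_along(topologies))
  fits <- purrr::map(topologies, function(tr) {
    fit_loss_model(pillars, tr, family = family, ...)
  })
  out <- tibble::tibble(
    topology = nm,
    newick = vapply(topologies, function(t) ape::write.tree(t), character(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    fit = fits
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$loglik))
  out$rank <- seq_len(nrow(out))
  out
}

#' Compare last-arriving-subgenome models
#'
#' Fits the three arrival variants of the `arb` model (each proposing a
#' different last-arriving subgenome, i.e. a tetraploid phase for the other
#' two) and tests each against the plain `arb` fit with a 2-d.f. LRT. An
#' arrival model whose extra likelihood is below `collapse_tol` has collapsed
#' back into the `arb` model (its tetraploid phase fits at zero length).
#' Candidates of equal complexity are compared by raw ln-likelihood.
#'
#' With every rate free, the three candidates are images of one another under
#' subgenome relabelling, so they are only meaningful as *local* refinements
#' of the plain `arb` optimum: each candidate is warm-started at the `arb`
#' solution (which anchors the subgenome labels to the data) and optimised
#' locally, without the composite warm-up stage that could hop between
#' labelling basins.
#'
#' @param pillars A [pillar_set()].
#' @param tree Species tree topology.
#' @param arb_fit Optional pre-computed `arb` fit (computed if missing).
#' @param collapse_tol Collapse tolerance on the lnL difference (default
#'   `1e-3`).
#' @param control Optimiser control for the candidate fits (see
#'   [fit_loss_model()]); `stage1` is forced off.
#' @param ... Passed to [fit_loss_model()].
#' @return List with `arb_fit`, and `table`: a tibble (one row per candidate,
#'   ranked by lnL) with `last`, `loglik`, `delta_lnl`, `statistic`, `df`,
#'   `p_value`, `collapsed`, and list-column `fit`.
#' @export
compare_arrival_models <- function(pillars, tree, arb_fit = NULL,
                                   collapse_tol = 1e-3, control = list(),
                                   ...) {
  if (is.null(arb_fit)) {
    arb_fit <- fit_loss_model(pillars, tree, family = "arb",
                              control = control, ...)
  }
  ctrl <- utils::modifyList(control, list(stage1 = FALSE))
  warm <- list(rates = unlist(arb_fit$model$params),
               u = c(arb_fit$tree$root.edge, arb_fit$tree$edge.length),
               theta = arb_fit$theta, tau = 0.05, kappa = 1)
  rows <- purrr::map(subgenomes(), function(last) {
    f <- fit_loss_model(pillars, tree, family = "arb", arrival_last = last,
                        init = warm, canonical = FALSE, control = ctrl, ...)
    lr <- suppressWarnings(lrt(arb_fit, f))
    tibble::tibble(last = last, loglik = f$loglik,
                   delta_lnl = f$loglik - arb_fit$loglik,
                   statistic = lr$statistic, df = lr$df,
                   p_value = lr$p_value,
                   collapsed = (f$loglik - arb_fit$loglik) < collapse_tol,
                   fit = list(f))
  })
  tab <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$loglik))
  tab$rank <- seq_len(nrow(tab))
  list(arb_fit = arb_fit, table = tab)
}

#' Root-branch versus later-branch rate contrast
#'
#' For a root-branch-variant `arb` fit, compares the two T-to-D transition
#' rates that discriminate a late-arriving MF subgenome: losses of the IF
#' copy (into `D_LF.MF`) versus losses of the MF copy (into `D_LF.IF`). If MF
#' arrived last it had less time to lose genes on the root branch, so
#' transitions preserving MF should be relatively favoured there, with the
#' preference reversing on the later branches.
#'
#' @param fit A converged `wgt_fit` with a root-branch rate set.
#' @param tol Rates closer than this are reported as tied (default `1e-6`).
#' @return A tibble with one row per branch class: `branch`,
#'   `rate_to_d_lf_mf`, `rate_to_d_lf_if`, `favoured`; plus attribute-free
#'   column `reversed` (same value in both rows).
#' @export
root_branch_contrast <- function(fit, tol = 1e-6) {
  stopifnot(inherits(fit, "wgt_fit"))
  if (is.null(fit$model$root_rho)) {
    stop("fit has no root-branch rate set; refit with root_variant = TRUE")
  }
  cmp <- function(rho) {
    a <- rho[["td_lf_mf"]]  # loses IF, preserves MF
    b <- rho[["td_lf_if"]]  # loses MF, preserves IF
    fav <- if (abs(a - b) <= tol) "tied" else if (a > b) "D_LF.MF" else "D_LF.IF"
    c(a = a, b = b, fav = fav)
  }
  root <- cmp(fit$model$root_rho)
  later <- cmp(fit$model$rho)
  reversed <- root[["fav"]] != "tied" && later[["fav"]] != "tied" &&
    root[["fav"]] != later[["fav"]]
  tibble::tibble(
    branch = c("root", "later"),
    rate_to_d_lf_mf = as.numeric(c(root[["a"]], later[["a"]])),
    rate_to_d_lf_if = as.numeric(c(root[["b"]], later[["b"]])),
    favoured = c(root[["fav"]], later[["fav"]]),
    reversed = reversed
  )
}
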