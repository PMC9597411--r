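# Parameter layout for the joint optimisation. Rates, branch lengths, tau and
# kappa are log-transformed; theta is logit-transformed. u[1] is the root edge.
par_layout <- function(family, arrival_last, root_variant, n_branches) {
  rate_names <- free_param_names(family)
  layout <- tibble::tibble(
    name = c(paste0("rate.", rate_names),
             paste0("u.", seq_len(n_branches)),
             "theta",
             if (!is.null(arrival_last)) c("tau", "kappa"),
             if (root_variant) paste0("root.", rho_names()[1:3])),
    block = c(rep("rate", length(rate_names)),
              rep("u", n_branches),
              "theta",
              if (!is.null(arrival_last)) c("arrival", "arrival"),
              if (root_variant) rep("root", 3))
  )
  layout$lower <- ifelse(layout$block == "theta", stats::qlogis(1e-4),
                  ifelse(layout$name == "tau", log(1e-6),
                  ifelse(layout$block == "u", log(1e-5), log(1e-4))))
  layout$upper <- ifelse(layout$block == "theta", stats::qlogis(0.98),
                  ifelse(layout$block == "u", log(20), log(60)))
  layout
}

unpack_par <- function(par, layout, family, arrival_last, root_variant) {
  v <- setNames(par, layout$name)
  rates <- exp(v[layout$block == "rate"])
  names(rates) <- sub("^rate\\.", "", names(rates))
  u <- exp(v[layout$block == "u"])
  theta <- stats::plogis(v[["theta"]])
  arrival <- NULL
  if (!is.null(arrival_last)) {
    arrival <- list(last = arrival_last, tau = exp(v[["tau"]]),
                    kappa = exp(v[["kappa"]]))
  }
  root_params <- NULL
  if (root_variant) {
    root_params <- exp(v[layout$block == "root"])
    names(root_params) <- sub("^root\\.", "", names(root_params))
  }
  model <- build_model(family, as.list(rates), arrival = arrival,
                       root_params = root_params)
  list(model = model, u = unname(u), theta = theta)
}

# crude branch-length initialisation from per-genome mean copy number
init_branch_lengths <- function(enc) {
  masks <- enc$pat_masks[enc$pat_of + 1L, , drop = FALSE]
  bits <- function(m) (m %% 2) + (m %/% 2 %% 2) + (m %/% 4 %% 2)
  mcopies <- colMeans(bits(masks))
  tdepth <- -log(pmax(mcopies, 0.15) / 3)
  plan <- enc$plan
  nbr <- plan$n_edges + 1L
  u <- rep(max(0.05, mean(tdepth) * 0.15), nbr)
  tipedge <- match(seq_along(plan$tree$tip.label), plan$tree$edge[, 2])
  u[tipedge + 1L] <- pmax(0.05, tdepth[match(plan$tree$tip.label,
                                             plan$leaf_seq)] * 0.6)
  u
}

#' Fit a gene-loss model by maximum likelihood
#'
#' Jointly maximises the forward log-likelihood (see [forward_loglik()]) over
#' the family's relative rates, all branch lengths (including the root edge),
#' the synteny-break probability `theta`, and, for arrival models, the
#' tetraploid-phase parameters `tau` and `kappa`. Optimisation uses bounded
#' quasi-Newton (L-BFGS-B) on log/logit-transformed parameters, warmed up on
#' the pillar-marginal composite likelihood (the HMM coupling is switched off
#' for the warm-up, which gives fast, consistent starting values), with
#' optional random restarts.
#'
#' For the `arb` family the fitted subgenome labels are canonicalised so that
#' LF is the subgenome with the highest model-implied survival at the tips and
#' MF the lowest (`canonical = FALSE` disables this).
#'
#' @param pillars A [pillar_set()].
#' @param tree Species tree topology ([ape::phylo]); branch lengths, if
#'   present, seed the optimiser.
#' @param family Model family (see [build_model()]).
#' @param arrival_last `NULL`, or the last-arriving subgenome (`"LF"`,
#'   `"IF"`, `"MF"`) for an arrival model.
#' @param root_variant Give the root branch its own rate set (`arb` only).
#' @param n_starts Number of optimisation starts (the first is deterministic,
#'   the rest jittered).
#' @param seed Optional seed for the restart jitter.
#' @param init Optional named list with any of `rates`, `u`, `theta`, `tau`,
#'   `kappa`, `root_params` to seed the first start (used for warm starts
#'   along the nested-family ladder).
#' @param control List: `maxit` (default 500), `factr` (L-BFGS-B tolerance,
#'   default `4.5e7`, i.e. relative lnL change about 1e-8), `stage1`
#'   (composite warm-up, default `TRUE`).
#' @param canonical Canonicalise subgenome labels after fitting (`arb` only).
#' @return A `wgt_fit` object: `model`, `tree` (fitted lengths), `theta`,
#'   `loglik`, `diagnostics`.
#' @export
fit_loss_model <- function(pillars, tree, family = c("arb", "null", "1d", "3g"),
                           arrival_last = NULL, root_variant = FALSE,
                           n_starts = 2, seed = NULL, init = NULL,
                           control = list(), canonical = TRUE) {
  family <- match.arg(family)
  if (root_variant && family != "arb") {
    stop("root_variant requires the 'arb' family")
  }
  if (!is.null(arrival_last)) arrival_last <- match.arg(arrival_last,
                                                        subgenomes())
  ctrl <- utils::modifyList(list(maxit = 500, factr = 4.5e7, stage1 = TRUE),
                            control)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  }
  enc <- encode_dataset(pillars, tree)
  nbr <- enc$plan$n_edges + 1L
  layout <- par_layout(family, arrival_last, root_variant, nbr)
  counts <- tabulate(enc$pat_of + 1L, nbins = nrow(enc$pat_masks))

  neg_full <- function(par) {
    up <- unpack_par(par, layout, family, arrival_last, root_variant)
    emis <- emission_matrix(up$model, enc, up$u)
    ll <- cpp_forward_loglik(emis, enc$pat_of, enc$new_block, up$theta, enc$G)
    if (!is.finite(ll)) return(1e10)  # keep the line search in bounds
    -ll
  }
  # composite warm-up: product over pillars of the uniform-mixture marginal
  idx_nontheta <- which(layout$name != "theta")
  neg_comp <- function(par_sub, par_full) {
    par_full[idx_nontheta] <- par_sub
    up <- unpack_par(par_full, layout, family, arrival_last, root_variant)
    emis <- emission_matrix(up$model, enc, up$u)
    m <- colMeans(emis)
    if (any(m <= 0)) return(1e10)
    -sum(counts * log(m))
  }
  # forward-difference gradient reusing the last objective value (halves the
  # per-iteration cost relative to optim's internal central differences)
  fd_grad <- function(fn, ...) {
    cache <- new.env(parent = emptyenv())
    list(
      fn = function(par, ...) {
        v <- fn(par, ...)
        cache$par <- par; cache$val <- v
        v
      },
      gr = function(par, ...) {
        f0 <- if (!is.null(cache$par) && identical(cache$par, par)) cache$val
              else fn(par, ...)
        h <- 1e-5
        vapply(seq_along(par), function(i) {
          p <- par; p[i] <- p[i] + h
          (fn(p, ...) - f0) / h
        }, numeric(1))
      }
    )
  }
  obj_full <- fd_grad(neg_full)
  obj_comp <- fd_grad(neg_comp)

  # deterministic asymmetric tilt: an exactly label-symmetric start sits on a
  # saddle of the label-switching symmetry and gradient methods cannot leave it
  default_rate_init <- function() {
    nm <- free_param_names(family)
    tilt <- c(sigma = 1, f_t = 0.85, f_d = 0.85, g_t = 0.95, g_d = 0.95,
              td_lf_mf = 0.9, td_if_mf = 0.75,
              ds_lfif_lf = 1.1, ds_lfif_if = 0.8,
              ds_lfmf_lf = 1.2, ds_lfmf_mf = 0.7,
              ds_ifmf_if = 1.05, ds_ifmf_mf = 0.9)
    setNames(tilt[nm], nm)
  }
  base_par <- function(neutral = FALSE) {
    rates <- default_rate_init()
    if (neutral) rates[] <- 1
    u <- init_branch_lengths(enc)
    if (!is.null(enc$plan$edge_lengths) &&
        all(is.finite(c(enc$plan$root_edge, enc$plan$edge_lengths))) &&
        all(c(enc$plan$root_edge, enc$plan$edge_lengths) > 0)) {
      u <- c(enc$plan$root_edge, enc$plan$edge_lengths)
    }
    theta <- 0.1
    tau <- 0.1; kappa <- 1
    root_params <- c(td_lf_if = 1, td_lf_mf = 0.9, td_if_mf = 0.75)
    if (neutral) root_params[] <- 1
    if (!is.null(init)) {
      if (!is.null(init$rates)) {
        keep <- intersect(names(init$rates), names(rates))
        rates[keep] <- init$rates[keep]
      }
      if (!is.null(init$u)) u <- init$u
      if (!is.null(init$theta)) theta <- init$theta
      if (!is.null(init$tau)) tau <- init$tau
      if (!is.null(init$kappa)) kappa <- init$kappa
      if (!is.null(init$root_params)) {
        keep <- intersect(names(init$root_params), names(root_params))
        root_params[keep] <- unlist(init$root_params)[keep]
      }
    }
    par <- c(log(pmax(rates, 1e-4)), log(pmax(u, 1e-5)), stats::qlogis(theta),
             if (!is.null(arrival_last)) c(log(tau), log(kappa)),
             if (root_variant) log(pmax(root_params, 1e-4)))
    pmin(pmax(unname(par), layout$lower), layout$upper)
  }

  best <- NULL
  start_lls <- numeric(0)
  errors <- character(0)
  for (s in seq_len(max(1, n_starts))) {
    # start 1: tilted defaults (or the supplied init); start 2: the neutral
    # nesting point (rates not supplied by `init` at exactly 1), guaranteeing
    # a warm-started richer fit never falls below the simpler optimum;
    # further starts jitter the tilted start.
    par0 <- base_par(neutral = (s == 2))
    if (s > 2) {
      jit <- stats::rnorm(length(par0), sd = 0.4)
      jit[layout$block == "theta"] <- stats::rnorm(1, sd = 0.8)
      par0 <- pmin(pmax(par0 + jit, layout$lower), layout$upper)
    }
    use_stage1 <- ctrl$stage1 && !(s == 2 && !is.null(init))
    if (use_stage1) {
      o1 <- try(optim(par0[idx_nontheta], obj_comp$fn, gr = obj_comp$gr,
                      par_full = par0,
                      method = "L-BFGS-B",
                      lower = layout$lower[idx_nontheta],
                      upper = layout$upper[idx_nontheta],
                      control = list(maxit = ctrl$maxit, factr = 1e10)),
                silent = TRUE)
      if (!inherits(o1, "try-error")) par0[idx_nontheta] <- o1$par
    }
    o2 <- try(optim(par0, obj_full$fn, gr = obj_full$gr,
                    method = "L-BFGS-B",
                    lower = layout$lower, upper = layout$upper,
                    control = list(maxit = ctrl$maxit, factr = ctrl$factr)),
              silent = TRUE)
    if (inherits(o2, "try-error")) {
      errors <- c(errors, attr(o2, "condition")$message)
      next
    }
    start_lls <- c(start_lls, -o2$value)
    if (is.null(best) || -o2$value > best$loglik) {
      best <- list(par = o2$par, loglik = -o2$value,
                   converged = o2$convergence == 0,
                   counts = o2$counts)
    }
  }
  if (is.null(best)) {
    stop("all optimisation starts failed: ",
         paste(unique(errors), collapse = "; "))
  }
  up <- unpack_par(best$par, layout, family, arrival_last, root_variant)
  fit <- structure(
    list(model = up$model, theta = up$theta,
         tree = set_branch_lengths(enc$plan$tree, up$u),
         loglik = best$loglik,
         family = family,
         n_free = count_free_parameters(up$model),
         data = list(n_pillars = n_pillars(pillars),
                     genomes = pillars$genomes),
         diagnostics = list(converged = best$converged,
                            n_starts = max(1, n_starts),
                            start_logliks = start_lls,
                            fn_evals = best$counts)),
    class = "wgt_fit"
  )
  if (canonical && family == "arb") fit <- canonicalize_fit(fit)
  fit
}

# Relabel subgenomes of a fitted arb model so that model-implied survival at
# the tips orders LF >= IF >= MF. The relative-rate normalisation (first
# T -> D rate = 1) is restored by rescaling branch lengths and tau.
canonicalize_fit <- function(fit) {
  surv <- colMeans(model_tip_survival(fit$model, fit$tree))
  ord <- order(surv, decreasing = TRUE)
  if (identical(ord, 1:3)) return(fit)
  map <- setNames(subgenomes(), subgenomes()[ord])  # old label -> new label
  pr <- permute_rho(fit$model$rho, map)
  model <- fit$model
  model$rho <- pr$rho
  model$params <- as.list(pr$rho[-1])
  if (!is.null(model$arrival)) {
    model$arrival$last <- unname(map[[model$arrival$last]])
    model$arrival$tau <- model$arrival$tau * pr$u_scale
  }
  u <- c(fit$tree$root.edge, fit$tree$edge.length)
  if (!is.null(model$root_rho)) {
    # root rates share the global alpha scale: permute, then rescale like rho
    prr <- permute_rho(model$root_rho, map, normalize = FALSE)
    model$root_rho <- prr$rho / pr$u_scale
  }
  fit$model <- model
  fit$tree <- set_branch_lengths(fit$tree, u * pr$u_scale)
  fit$relabelled <- map
  fit
}

#' @export
print.wgt_fit <- function(x, ...) {
  cat(sprintf("<wgt_fit> family %s%s%s | lnL = %.3f | theta = %.4f | %s\n",
              x$family,
              if (!is.null(x$model$arrival))
                paste0(", ", x$model$arrival$last, "-last arrival") else "",
              if (!is.null(x$model$root_rho)) ", root-branch variant" else "",
              x$loglik, x$theta,
              if (x$diagnostics$converged) "converged" else "NOT converged"))
  print(x$model)
  invisible(x)
}

#' Fit the nested model ladder
#'
#' Fits a sequence of families with warm starts along the nesting
#' (`null` into `1d` into `3g` into `arb`), so that each richer fit starts
#' from (at least) the simpler optimum and the likelihoods are monotone.
#'
#' @inheritParams fit_loss_model
#' @param families Families to fit, in nesting order.
#' @return Named list of `wgt_fit` objects.
#' @export
fit_model_ladder <- function(pillars, tree,
                             families = c("null", "1d", "3g", "arb"),
                             n_starts = 2, seed = NULL, control = list()) {
  fits <- list()
  prev <- NULL
  for (fam in families) {
    init <- NULL
    if (!is.null(prev)) {
      init <- list(u = c(prev$tree$root.edge, prev$tree$edge.length),
                   theta = prev$theta,
                   rates = ladder_init_rates(prev, fam))
    }
    fits[[fam]] <- fit_loss_model(pillars, tree, family = fam,
                                  n_starts = n_starts, seed = seed,
                                  init = init, control = control)
    prev <- fits[[fam]]
  }
  fits
}

# warm-start rates for `fam` from a simpler fitted model; parameters the
# simpler family lacks are left to the tilted defaults (an exactly symmetric
# value would start the richer fit on a label-symmetry saddle)
ladder_init_rates <- function(prev_fit, fam) {
  if (fam == "arb") {
    prev_rho <- prev_fit$model$rho
    tilt <- c(1, 0.97, 0.94, 1.03, 0.96, 1.05, 0.95, 1.02, 0.98)
    r <- (prev_rho * tilt)[-1]
    names(r) <- rho_names()[-1]
    return(r)
  }
  have <- unlist(prev_fit$model$params)
  have[intersect(names(have), free_param_names(fam))]
}
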