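# Names of the 9 allowed transitions, in Q-matrix (upper-triangular) order:
# three T -> D losses followed by six D -> S losses. All rates are relative to
# the base loss rate alpha, which is absorbed into the branch lengths u = alpha*t.
rho_names <- function() {
  c("td_lf_if", "td_lf_mf", "td_if_mf",
    "ds_lfif_lf", "ds_lfif_if",
    "ds_lfmf_lf", "ds_lfmf_mf",
    "ds_ifmf_if", "ds_ifmf_mf")
}

# (from state, to state) index pairs for the 9 transitions, matching rho_names()
rho_edges <- function() {
  cbind(from = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L),
        to   = c(2L, 3L, 4L, 5L, 6L, 5L, 7L, 6L, 7L))
}

model_families <- function() c("null", "1d", "3g", "arb")

free_param_names <- function(family) {
  switch(family,
    null = "sigma",
    "1d" = c("sigma", "f_t", "f_d"),
    "3g" = c("sigma", "f_t", "f_d", "g_t", "g_d"),
    arb  = rho_names()[-1],
    stop("unknown model family: ", family)
  )
}

# Materialise the full 9-entry relative-rate vector from a family's free
# parameters. Conventions:
#   * rho(T -> D_LF.IF) == 1 fixes the overall scale (time is measured in
#     expected-loss units u = alpha*t).
#   * "1d" singles out LF: f_t scales the T -> D transition that loses the LF
#     copy, f_d multiplies the two D -> S transitions that lose the LF copy.
#   * "3g" adds the analogous (g_t, g_d) pair for transitions losing the IF
#     copy, so that all three subgenomes can differ.
#   * "arb" frees all nine rates (first fixed to 1).
materialize_rho <- function(family, params) {
  p <- as.list(params)
  need <- free_param_names(family)
  missing <- setdiff(need, names(p))
  if (length(missing) > 0) {
    stop("missing parameters for family '", family, "': ",
         paste(missing, collapse = ", "))
  }
  vals <- unlist(p[need])
  if (any(vals < 0)) stop("rates must be non-negative")
  rho <- switch(family,
    null = {
      s <- p$sigma
      c(1, 1, 1, s, s, s, s, s, s)
    },
    "1d" = {
      s <- p$sigma
      c(1, 1, p$f_t,
        s, s * p$f_d,          # D_LF.IF -> S_LF (loses IF), -> S_IF (loses LF)
        s, s * p$f_d,          # D_LF.MF -> S_LF (loses MF), -> S_MF (loses LF)
        s, s)                  # D_IF.MF -> S_IF, -> S_MF
    },
    "3g" = {
      s <- p$sigma
      c(1, p$g_t, p$f_t,
        s * p$g_d, s * p$f_d,  # D_LF.IF: lose IF, lose LF
        s, s * p$f_d,          # D_LF.MF: lose MF, lose LF
        s, s * p$g_d)          # D_IF.MF: lose MF, lose IF
    },
    arb = c(1, vals)
  )
  names(rho) <- rho_names()
  rho
}

#' Build a gene-loss model
#'
#' Constructs one of the nested continuous-time Markov models of homoeologue
#' loss after whole-genome triplication. The state space is the 7 states of
#' [loss_states()]; the 9 allowed transitions carry rates relative to the base
#' loss rate, which is absorbed into branch lengths (`u = alpha * t`).
#'
#' Families, from simplest to richest:
#' \describe{
#'   \item{`null`}{all subgenomes equivalent; one free rate `sigma` for the
#'     duplicate-to-singleton losses (1 free parameter).}
#'   \item{`1d`}{one subgenome (LF) may lose fewer genes; adds `f_t`, `f_d`
#'     (3 free parameters).}
#'   \item{`3g`}{all three subgenomes may differ; adds `g_t`, `g_d`
#'     (5 free parameters).}
#'   \item{`arb`}{every transition has its own rate, the first fixed to 1
#'     (8 free parameters).}
#' }
#'
#' An *arrival* variant models hexaploid formation through a tetraploid
#' intermediate: the two founder subgenomes evolve as a duplicated pair for a
#' phase of length `tau` (in `u` units, loss rates scaled by `kappa`) before
#' the last subgenome arrives; see [root_distribution()]. A *root-branch*
#' variant (only for `arb`) gives the root branch its own full rate set.
#'
#' @param family One of `"null"`, `"1d"`, `"3g"`, `"arb"`.
#' @param params Named list/vector of the family's free parameters (see
#'   Details). Defaults to all rates 1.
#' @param arrival `NULL`, or a list with `last` (one of `"LF"`, `"IF"`,
#'   `"MF"`), `tau` (tetraploid-phase length, `u` units) and `kappa`
#'   (tetraploid-phase rate modifier, default 1).
#' @param root_params `NULL`, or (family `"arb"` only) a named vector/list of
#'   the three `T -> D` rates (`td_lf_if`, `td_lf_mf`, `td_if_mf`) used on the
#'   root branch; the `D -> S` rates stay shared with the other branches.
#'   Only the initial-loss rates are freed because the tip likelihood sees the
#'   root branch solely through its 6-dimensional exit distribution: a full
#'   independent rate set (plus the free root-edge length) would be an
#'   unidentifiable ridge, whereas the three initial-loss rates - the
#'   quantities the arrival hypothesis makes predictions about - are
#'   identified once the downstream rates are pinned.
#' @return A `wgt_model` object.
#' @examples
#' m <- build_model("null", list(sigma = 0.5))
#' transition_matrix(m, u = 0.3)["T", "T"]  # exp(-3 * 0.3)
#' @export
build_model <- function(family = c("null", "1d", "3g", "arb"),
                        params = NULL, arrival = NULL, root_params = NULL) {
  family <- match.arg(family)
  if (is.null(params)) {
    params <- setNames(as.list(rep(1, length(free_param_names(family)))),
                       free_param_names(family))
  }
  rho <- materialize_rho(family, params)
  if (!is.null(arrival)) {
    if (is.null(arrival$last) || !arrival$last %in% subgenomes()) {
      stop("arrival$last must be one of ", paste(subgenomes(), collapse = ", "))
    }
    if (is.null(arrival$tau) || arrival$tau < 0) {
      stop("arrival$tau must be a non-negative tetraploid-phase length")
    }
    if (is.null(arrival$kappa)) arrival$kappa <- 1
    if (arrival$kappa < 0) stop("arrival$kappa must be non-negative")
    arrival <- list(last = arrival$last, tau = arrival$tau,
                    kappa = arrival$kappa)
  }
  root_rho <- NULL
  if (!is.null(root_params)) {
    if (family != "arb") {
      stop("a root-branch rate set is only supported for the 'arb' family")
    }
    rp <- unlist(root_params)
    need <- rho_names()[1:3]
    if (!all(need %in% names(rp))) {
      stop("root_params must name the three T -> D rates: ",
           paste(need, collapse = ", "))
    }
    if (any(rp[need] < 0)) stop("rates must be non-negative")
    root_rho <- rho
    root_rho[need] <- rp[need]
  }
  structure(
    list(family = family, params = params, rho = rho,
         arrival = arrival, root_rho = root_rho),
    class = "wgt_model"
  )
}

#' @export
print.wgt_model <- function(x, ...) {
  cat("<wgt_model> family:", x$family)
  if (!is.null(x$arrival)) {
    cat(sprintf(" | arrival: %s last (tau = %.4g, kappa = %.4g)",
                x$arrival$last, x$arrival$tau, x$arrival$kappa))
  }
  if (!is.null(x$root_rho)) cat(" | root-branch rate set")
  cat("\n")
  cat("relative rates (alpha units):\n")
  print(round(x$rho, 4))
  invisible(x)
}

#' Count independently estimable rate parameters
#'
#' Counts the free rate parameters of a loss model, excluding branch lengths
#' and the HMM synteny-break parameter, under the normalisation that one
#' T-to-D rate is fixed to 1. These counts give the degrees of freedom of the
#' nested likelihood-ratio tests: 1 (null), 3 (1d), 5 (3g), 8 (arb), plus 2
#' for an arrival variant and 3 for a root-branch variant (its three free
#' root T-to-D rates; see [build_model()]).
#'
#' @param model A `wgt_model`.
#' @return Integer parameter count.
#' @export
count_free_parameters <- function(model) {
  stopifnot(inherits(model, "wgt_model"))
  base <- c(null = 1L, "1d" = 3L, "3g" = 5L, arb = 8L)[[model$family]]
  base + (!is.null(model$arrival)) * 2L + (!is.null(model$root_rho)) * 3L
}

# 7x7 generator matrix from a 9-entry relative-rate vector
rate_matrix <- function(rho) {
  Q <- matrix(0, 7, 7, dimnames = list(loss_states(), loss_states()))
  e <- rho_edges()
  Q[e] <- rho
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probability matrix over a branch
#'
#' Computes `P(u) = exp(Q u)` for the 7-state loss process, with `u` the
#' branch length in expected-loss units (`alpha * t`).
#'
#' @param model A `wgt_model`.
#' @param u Non-negative branch length.
#' @param branch `"internal"` (default) or `"root"`; with a root-branch
#'   variant model, `"root"` uses the root-specific rate set.
#' @return A 7 x 7 row-stochastic matrix with dimnames [loss_states()].
#' @export
transition_matrix <- function(model, u, branch = c("internal", "root")) {
  stopifnot(inherits(model, "wgt_model"))
  branch <- match.arg(branch)
  if (length(u) != 1 || is.na(u) || u < 0) stop("u must be a single value >= 0")
  rho <- if (branch == "root" && !is.null(model$root_rho)) model$root_rho else model$rho
  Q <- rate_matrix(rho)
  P <- as.matrix(Matrix::expm(Q * u))
  # guard tiny negative round-off
  P[P < 0] <- 0
  dimnames(P) <- list(loss_states(), loss_states())
  P
}

#' Loss-state distribution at the hexaploidy event
#'
#' For the instantaneous (non-arrival) models, every pillar starts triplicated:
#' a point mass on `T`. For arrival models, the two founder subgenomes first
#' evolve as a duplicated pair for the tetraploid phase (length `tau`, their
#' two loss rates scaled by `kappa`); at the second hybridization the
#' surviving founder states map into the triplicated state space:
#' both founders surviving becomes `T`, a single surviving founder `Y`
#' becomes the duplicated state pairing `Y` with the last-arriving subgenome.
#'
#' @param model A `wgt_model`.
#' @return Probability vector of length 7, named by [loss_states()].
#' @export
root_distribution <- function(model) {
  stopifnot(inherits(model, "wgt_model"))
  out <- setNames(numeric(7), loss_states())
  if (is.null(model$arrival)) {
    out["T"] <- 1
    return(out)
  }
  last <- model$arrival$last
  founders <- setdiff(subgenomes(), last)
  dstate <- pair_state_name(founders[1], founders[2])
  # tetraploid-phase loss rates: the D_founders -> S_founder rates of the
  # base model, scaled by kappa
  a <- model$rho[ds_rate_name(dstate, founders[1])]
  b <- model$rho[ds_rate_name(dstate, founders[2])]
  r <- model$arrival$kappa * (a + b)
  tau <- model$arrival$tau
  pT <- exp(-r * tau)
  out["T"] <- pT
  if (r > 0) {
    out[pair_state_name(founders[1], last)] <- a / (a + b) * (1 - pT)
    out[pair_state_name(founders[2], last)] <- b / (a + b) * (1 - pT)
  }
  out
}

# canonical D-state name for an unordered subgenome pair
pair_state_name <- function(x, y) {
  ord <- subgenomes()
  pair <- ord[sort(match(c(x, y), ord))]
  paste0("D_", pair[1], ".", pair[2])
}

# rho entry name for a D -> S transition
ds_rate_name <- function(dstate, survivor) {
  pair <- strsplit(sub("^D_", "", dstate), ".", fixed = TRUE)[[1]]
  paste0("ds_", tolower(pair[1]), tolower(pair[2]), "_", tolower(survivor))
}

# Apply a subgenome relabelling to a rho vector. `map` is a named character
# vector, map[old_label] = new_label. Returns the permuted, re-normalised rho
# and the scale factor by which branch lengths must be multiplied to preserve
# the process (rho[1] is re-fixed to 1); `normalize = FALSE` skips the
# rescaling (u_scale 1).
permute_rho <- function(rho, map, normalize = TRUE) {
  stopifnot(setequal(names(map), subgenomes()), setequal(map, subgenomes()))
  new_rho <- setNames(numeric(9), rho_names())
  e <- rho_edges()
  states <- loss_states()
  relabel_state <- function(s) {
    if (s == "T") return("T")
    if (startsWith(s, "D_")) {
      pair <- strsplit(sub("^D_", "", s), ".", fixed = TRUE)[[1]]
      return(pair_state_name(map[[pair[1]]], map[[pair[2]]]))
    }
    paste0("S_", map[[sub("^S_", "", s)]])
  }
  for (k in 1:9) {
    from_new <- relabel_state(states[e[k, "from"]])
    to_new <- relabel_state(states[e[k, "to"]])
    key <- transition_key(from_new, to_new)
    new_rho[key] <- rho[k]
  }
  if (!normalize) return(list(rho = new_rho, u_scale = 1))
  scale <- new_rho[[1]]
  list(rho = new_rho / scale, u_scale = scale)
}

# rho_names() key for a (from, to) state pair
transition_key <- function(from, to) {
  if (from == "T") {
    pair <- tolower(strsplit(sub("^D_", "", to), ".", fixed = TRUE)[[1]])
    paste0("td_", pair[1], "_", pair[2])
  } else {
    ds_rate_name(from, sub("^S_", "", to))
  }
}

# Model-implied probability that each subgenome retains a copy at the end of a
# root-to-tip path of matrices; used to rank subgenomes by fractionation.
subgenome_survival <- function(tip_dist) {
  states <- loss_states()
  vapply(subgenomes(), function(sg) {
    keep <- grepl(sg, states) | states == "T"
    sum(tip_dist[keep])
  }, numeric(1))
}
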