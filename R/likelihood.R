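# Precompute everything about a (pillars, tree) pair that does not depend on
# model parameters: the tree program, presence masks (deduplicated into
# patterns) and block structure.
encode_dataset <- function(pillars, tree) {
  stopifnot(inherits(pillars, "pillar_set"))
  tree <- validate_tree(tree, genomes = pillars$genomes,
                        lengths_required = FALSE)
  plan <- tree_plan(tree)
  masks <- pillar_masks(pillars, genome_order = plan$leaf_seq)
  G <- ncol(masks)
  key <- as.vector(masks %*% 8^(seq_len(G) - 1))
  upat <- !duplicated(key)
  pat_masks <- masks[upat, , drop = FALSE]
  pat_of <- match(key, key[upat]) - 1L
  list(plan = plan, G = G, S = n_orthology_states(G),
       pat_masks = pat_masks, pat_of = pat_of,
       new_block = pillars$index$new_block,
       leafstate = leafstate_table() - 1L)  # 0-based states, -1 = missing
}

# Transition matrices for every edge (plan edge order) plus the root
# distribution propagated through the root edge.
model_matrices <- function(model, enc, u = NULL) {
  plan <- enc$plan
  lens <- if (is.null(u)) c(plan$root_edge, plan$edge_lengths) else u
  if (anyNA(lens)) stop("tree has no branch lengths and none were supplied")
  ne <- plan$n_edges
  Pcube <- array(0, dim = c(7, 7, ne))
  for (e in seq_len(ne)) {
    Pcube[, , e] <- transition_matrix(model, lens[e + 1])
  }
  Proot <- transition_matrix(model, lens[1], branch = "root")
  rvec <- as.numeric(root_distribution(model) %*% Proot)
  list(Pcube = Pcube, rvec = rvec)
}

emission_matrix <- function(model, enc, u = NULL) {
  mm <- model_matrices(model, enc, u)
  cpp_emissions(enc$pat_masks, enc$leafstate, as.numeric(mm$Pcube),
                enc$plan$ops, mm$rvec, enc$S)
}

#' Leaf partial-likelihood vector for one genome at one pillar
#'
#' Given a genome's presence pattern at a pillar and a track-to-subgenome
#' permutation, the observation is the unique loss state whose surviving
#' subgenome set equals the subgenomes mapped to the occupied tracks; the
#' result is its indicator vector over [loss_states()]. A genome with no gene
#' at the pillar is treated as missing data (all-ones vector).
#'
#' @param present Logical (or 0/1) vector of length 3: which tracks hold a
#'   gene.
#' @param permutation Integer 1..6 (row of [track_permutations()]) or a
#'   character vector of 3 subgenome labels.
#' @return Numeric vector of length 7 named by [loss_states()].
#' @export
leaf_state <- function(present, permutation) {
  stopifnot(length(present) == 3)
  if (is.character(permutation)) {
    pm <- perm_index_matrix()
    permutation <- which(apply(pm, 1, function(r) {
      all(subgenomes()[r] == permutation)
    }))
    if (length(permutation) != 1) stop("not a permutation of the subgenomes")
  }
  mask <- sum(bitwShiftL(1L, which(as.logical(present)) - 1L))
  st <- leafstate_table()[mask + 1L, permutation]
  v <- setNames(rep(1, 7), loss_states())
  if (st > 0L) {
    v[] <- 0
    v[st] <- 1
  }
  v
}

#' Emission likelihood of one pillar under one orthology state
#'
#' Felsenstein pruning over the 7 loss states: each genome's leaf vector is
#' the [leaf_state()] indicator under that genome's permutation, branch
#' transitions come from [transition_matrix()], and the root carries
#' [root_distribution()] propagated through the root edge.
#'
#' @param pillar One pillar's gene rows (a data frame with `genome` and
#'   `track`), or a named list mapping genome to a logical presence triple.
#' @param state Integer vector of per-genome permutation indices (1..6), named
#'   by genome.
#' @param model A `wgt_model`.
#' @param tree Species tree ([ape::phylo]) whose leaves are the genomes.
#' @return The emission probability (a value in \[0, 1\]).
#' @export
emission_likelihood <- function(pillar, state, model, tree) {
  tree <- validate_tree(tree, lengths_required = TRUE)
  plan <- tree_plan(tree)
  genomes <- plan$leaf_seq
  if (is.data.frame(pillar)) {
    pres <- lapply(genomes, function(g) {
      tr <- pillar$track[pillar$genome == g]
      seq_len(3) %in% tr
    })
    names(pres) <- genomes
  } else {
    pres <- pillar
  }
  masks <- matrix(0L, nrow = 1, ncol = length(genomes))
  for (k in seq_along(genomes)) {
    p <- pres[[genomes[k]]]
    masks[1, k] <- sum(bitwShiftL(1L, which(as.logical(p)) - 1L))
  }
  enc <- list(plan = plan, G = length(genomes),
              S = n_orthology_states(length(genomes)),
              pat_masks = masks, leafstate = leafstate_table() - 1L)
  emis <- emission_matrix(model, enc)
  st <- state[genomes]
  idx0 <- sum((as.integer(st) - 1L) * 6^(seq_along(st) - 1L))
  emis[idx0 + 1L, 1]
}

#' Forward log-likelihood of a pillar set
#'
#' Runs the hidden Markov model over the `6^n` joint orthology states: the
#' emission at each pillar comes from Felsenstein pruning over the species
#' tree, and between adjacent pillars each genome keeps its permutation with
#' probability `1 - theta` or switches to each of the 5 alternatives with
#' probability `theta/5`, independently across genomes. The chain starts from
#' the uniform distribution and is re-initialised at contiguity breaks.
#'
#' @param pillars A [pillar_set()].
#' @param model A `wgt_model`.
#' @param tree Species tree with branch lengths in `u = alpha*t` units (a
#'   `root.edge` gives the shared branch between hexaploidy and first
#'   speciation).
#' @param theta Synteny-break probability per adjacent pillar pair, in
#'   `[0, 1)`.
#' @return The total natural-log likelihood (may be `-Inf` for impossible
#'   configurations, e.g. `theta = 0` with conflicting blocks).
#' @export
forward_loglik <- function(pillars, model, tree, theta) {
  if (length(theta) != 1 || is.na(theta) || theta < 0 || theta >= 1) {
    stop("theta must lie in [0, 1)")
  }
  enc <- encode_dataset(pillars, tree)
  emis <- emission_matrix(model, enc)
  cpp_forward_loglik(emis, enc$pat_of, enc$new_block, theta, enc$G)
}

#' Posterior decoding of orthology states
#'
#' Forward-backward smoothing of the orthology HMM (see [forward_loglik()]).
#' Returns per-pillar posteriors over the joint states, the MAP state (ties
#' broken towards the lexicographically first state), and per-genome marginal
#' posteriors of each track-to-subgenome assignment.
#'
#' @inheritParams forward_loglik
#' @param return_joint Keep the full per-pillar joint posterior matrix
#'   (`n_pillars` x `6^n`). Defaults to `TRUE` when that matrix has at most
#'   `2e6` entries.
#' @return An `orthology_posterior` object with elements `loglik`,
#'   `marginals` (tibble: `pillar_id`, `genome`, `track`, `subgenome`,
#'   `prob`), `map` (tibble: `pillar_id`, `state`, `prob`), `states` (the
#'   state lookup from [orthology_states()]), and `joint` (matrix or `NULL`).
#' @export
posterior_decode <- function(pillars, model, tree, theta,
                             return_joint = NULL) {
  if (length(theta) != 1 || is.na(theta) || theta < 0 || theta >= 1) {
    stop("theta must lie in [0, 1)")
  }
  enc <- encode_dataset(pillars, tree)
  if (is.null(return_joint)) {
    return_joint <- (as.double(n_pillars(pillars)) * enc$S) <= 2e6
  }
  emis <- emission_matrix(model, enc)
  fb <- cpp_forward_backward(emis, enc$pat_of, enc$new_block, theta, enc$G,
                             return_joint)
  genomes <- enc$plan$leaf_seq
  n <- n_pillars(pillars)
  perms <- perm_index_matrix()
  # per-genome permutation marginals -> track x subgenome marginals
  marg_rows <- vector("list", length(genomes))
  for (k in seq_along(genomes)) {
    pm <- fb$marg[, (k - 1) * 6 + (1:6), drop = FALSE]  # n x 6
    # track t -> subgenome s marginal: sum over perms with perms[p, t] == s
    tmat <- matrix(0, nrow = n, ncol = 9)
    for (t in 1:3) for (s in 1:3) {
      sel <- which(perms[, t] == s)
      tmat[, (t - 1) * 3 + s] <- rowSums(pm[, sel, drop = FALSE])
    }
    marg_rows[[k]] <- tidyr::expand_grid(
      track = 1:3, subgenome = subgenomes()
    ) |>
      dplyr::mutate(col = dplyr::row_number()) |>
      tidyr::expand_grid(pillar_id = pillars$index$pillar_id) |>
      dplyr::arrange(.data$col) |>
      dplyr::mutate(prob = as.vector(tmat),
                    genome = genomes[k]) |>
      dplyr::select("pillar_id", "genome", "track", "subgenome", "prob")
  }
  marginals <- dplyr::bind_rows(marg_rows) |>
    dplyr::arrange(.data$pillar_id, .data$genome, .data$track)
  map <- tibble::tibble(pillar_id = pillars$index$pillar_id,
                        state = fb$map_idx + 1L,
                        prob = fb$map_prob)
  structure(
    list(loglik = fb$loglik, marginals = marginals, map = map,
         genomes = genomes,
         perm_marginals = fb$marg,
         states = orthology_states(genomes),
         joint = if (return_joint) fb$joint else NULL,
         theta = theta),
    class = "orthology_posterior"
  )
}

#' @export
print.orthology_posterior <- function(x, ...) {
  cat(sprintf("<orthology_posterior> %d pillars, %d genomes, lnL = %.3f\n",
              nrow(x$map), length(x$genomes), x$loglik))
  invisible(x)
}
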