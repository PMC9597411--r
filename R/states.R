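#' The three subgenome labels
#'
#' Subgenomes of a paleohexaploid are conventionally named by how much gene
#' loss (fractionation) each has suffered: least- (`LF`), intermediate- (`IF`)
#' and most-fractionated (`MF`).
#'
#' @return Character vector `c("LF", "IF", "MF")`.
#' @export
subgenomes <- function() c("LF", "IF", "MF")

#' The seven gene-loss states of a triplicated locus
#'
#' A locus triplicated by hexaploidy starts with copies on all three
#' subgenomes (`T`), loses one copy to reach a duplicated state (`D_X.Y`,
#' named for the two subgenomes still carrying a copy) and finally a second
#' copy to reach a single-copy state (`S_X`). Single-copy states are
#' absorbing: the model has no gain transitions and total loss of a pillar is
#' not modelled.
#'
#' @return Character vector of the 7 state names, in the canonical order used
#'   throughout the package (`T`, then the three `D` states, then the three
#'   `S` states).
#' @export
loss_states <- function() {
  c("T", "D_LF.IF", "D_LF.MF", "D_IF.MF", "S_LF", "S_IF", "S_MF")
}

#' Track-to-subgenome permutations for one genome
#'
#' Each genome carries up to three syntenic "tracks" at every pillar; an
#' orthology state assigns each track to a subgenome via one of the 3! = 6
#' permutations. The rows are in lexicographic order, which is also the
#' tie-break order used for MAP decoding.
#'
#' @return A 6 x 3 character matrix; row `p`, column `t` is the subgenome
#'   assigned to track `t` under permutation `p`.
#' @export
track_permutations <- function() {
  idx <- matrix(c(1L, 2L, 3L,
                  1L, 3L, 2L,
                  2L, 1L, 3L,
                  2L, 3L, 1L,
                  3L, 1L, 2L,
                  3L, 2L, 1L), ncol = 3, byrow = TRUE)
  m <- matrix(subgenomes()[idx], ncol = 3)
  colnames(m) <- paste0("track", 1:3)
  m
}

# integer version, 1 = LF, 2 = IF, 3 = MF
perm_index_matrix <- function() {
  matrix(c(1L, 2L, 3L,
           1L, 3L, 2L,
           2L, 1L, 3L,
           2L, 3L, 1L,
           3L, 1L, 2L,
           3L, 2L, 1L), ncol = 3, byrow = TRUE)
}

#' Number of joint orthology states
#'
#' With 6 track-to-subgenome arrangements per genome, `n` genomes give
#' `6^n` joint orthology states per pillar (1296 for the four-genome case).
#'
#' @param n_genomes Number of polyploid genomes.
#' @return Integer count `6^n_genomes`.
#' @export
n_orthology_states <- function(n_genomes) {
  stopifnot(n_genomes >= 1)
  as.integer(6^n_genomes)
}

# Map a surviving-subgenome set (as a bitmask over LF=1, IF=2, MF=4) to the
# loss-state index 1..7; 0 (empty set) has no state.
surviving_set_state <- function(key) {
  # key: 1..7
  c(5L, 6L, 2L, 7L, 3L, 4L, 1L)[key]
}

# 8 x 6 lookup: [presence mask + 1, permutation] -> loss-state index 1..7, or
# 0L for the all-empty mask (missing data, all-ones leaf vector).
# Presence mask bit t (1,2,4) set means track t occupied.
leafstate_table <- function() {
  perms <- perm_index_matrix()
  out <- matrix(0L, nrow = 8, ncol = 6)
  for (mask in 1:7) {
    tracks <- which(bitwAnd(mask, c(1L, 2L, 4L)) > 0L)
    for (p in 1:6) {
      sg <- unique(perms[p, tracks])
      key <- sum(2L^(sg - 1L))
      out[mask + 1L, p] <- surviving_set_state(key)
    }
  }
  out
}

# Decode a 0-based joint-state index into per-genome permutation indices
# (1..6), genomes ordered as the digits (first genome fastest).
decode_state <- function(idx0, n_genomes) {
  out <- integer(n_genomes)
  for (g in seq_len(n_genomes)) {
    out[g] <- (idx0 %% 6L) + 1L
    idx0 <- idx0 %/% 6L
  }
  out
}

#' Enumerate joint orthology states
#'
#' @param genomes Character vector of genome names (digit order: the first
#'   genome varies fastest in the state index).
#' @return A tibble with one row per (state, genome): `state` (1-based index),
#'   `genome`, `perm` (1..6) and the three `track*` subgenome columns.
#' @export
orthology_states <- function(genomes) {
  n <- length(genomes)
  S <- n_orthology_states(n)
  perms <- track_permutations()
  grid <- tibble::tibble(
    state = rep(seq_len(S), each = n),
    genome = rep(genomes, times = S)
  )
  pidx <- t(vapply(seq_len(S) - 1L, decode_state, integer(n), n_genomes = n))
  grid$perm <- as.vector(t(pidx))
  grid$track1 <- perms[grid$perm, 1]
  grid$track2 <- perms[grid$perm, 2]
  grid$track3 <- perms[grid$perm, 3]
  grid
}
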