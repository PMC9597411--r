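#' Assign genes to subgenomes from HMM posteriors
#'
#' Each gene present at a pillar is assigned to the subgenome its track maps
#' to under that genome's marginal track-to-subgenome posterior; the
#' confidence is that marginal probability. Genes whose confidence is below
#' `threshold` are flagged rather than dropped, so the full assignment table
#' is returned with a `high_confidence` column (the `>= threshold` rule; a
#' marginal of exactly the threshold passes).
#'
#' @param posterior An `orthology_posterior` from [posterior_decode()].
#' @param pillars The [pillar_set()] the posterior was computed on.
#' @param threshold Confidence threshold (default 0.95).
#' @return A tibble: `gene_id`, `genome`, `pillar_id`, `track`, `subgenome`,
#'   `confidence`, `high_confidence`.
#' @export
assign_genes <- function(posterior, pillars, threshold = 0.95) {
  stopifnot(inherits(posterior, "orthology_posterior"))
  best <- posterior$marginals |>
    dplyr::group_by(.data$pillar_id, .data$genome, .data$track) |>
    dplyr::slice_max(.data$prob, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  pillars$genes |>
    dplyr::select("gene_id", "genome", "pillar_id", "track") |>
    dplyr::left_join(best, by = c("pillar_id", "genome", "track")) |>
    dplyr::mutate(confidence = .data$prob,
                  high_confidence = .data$confidence >= threshold) |>
    dplyr::select("gene_id", "genome", "pillar_id", "track", "subgenome",
                  "confidence", "high_confidence")
}

#' Expected surviving-gene counts per genome and subgenome
#'
#' Sums, over pillars and occupied tracks, the marginal posterior that the
#' track maps to each subgenome ("expected" counts), or counts tracks under
#' the MAP state ("map" hard counts). Because each genome's permutation is a
#' bijection, the three per-genome counts always sum to that genome's total
#' gene count in the pillar set.
#'
#' @inheritParams assign_genes
#' @param method `"expected"` (posterior-weighted, default) or `"map"`.
#' @return A tibble: `genome`, `subgenome`, `count`.
#' @export
count_surviving <- function(posterior, pillars, method = c("expected", "map")) {
  method <- match.arg(method)
  stopifnot(inherits(posterior, "orthology_posterior"))
  occupied <- dplyr::select(pillars$genes, "pillar_id", "genome", "track")
  if (method == "expected") {
    out <- occupied |>
      dplyr::inner_join(posterior$marginals,
                        by = c("pillar_id", "genome", "track")) |>
      dplyr::group_by(.data$genome, .data$subgenome) |>
      dplyr::summarise(count = sum(.data$prob), .groups = "drop")
  } else {
    perms <- track_permutations()
    map_perm <- posterior$map |>
      dplyr::select("pillar_id", "state") |>
      dplyr::inner_join(posterior$states, by = "state",
                        relationship = "many-to-many") |>
      dplyr::select("pillar_id", "genome", "perm")
    out <- occupied |>
      dplyr::inner_join(map_perm, by = c("pillar_id", "genome")) |>
      dplyr::mutate(subgenome = perms[cbind(.data$perm, .data$track)]) |>
      dplyr::count(.data$genome, .data$subgenome, name = "count") |>
      dplyr::mutate(count = as.numeric(.data$count))
  }
  tidyr::complete(out, genome = pillars$genomes, subgenome = subgenomes(),
                  fill = list(count = 0)) |>
    dplyr::mutate(subgenome = factor(.data$subgenome, levels = subgenomes())) |>
    dplyr::arrange(.data$genome, .data$subgenome) |>
    dplyr::mutate(subgenome = as.character(.data$subgenome))
}
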