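#' Find subgenome-assigned intergenic regions (SAIRs)
#'
#' A SAIR group is the set of orthologous intergenic intervals between two
#' neighbouring pillars, for one subgenome, such that (i) that subgenome has a
#' gene present in every genome at both pillars (under each pillar's MAP
#' orthology state), (ii) the two genes are syntenic neighbours in every
#' genome, and (iii) the joint orthology-state posterior is at least
#' `threshold` at both pillars. The interval in each genome is the gap
#' between the two flanking gene bodies; abutting or overlapping flanks drop
#' the group.
#'
#' @param pillars A [pillar_set()].
#' @param posterior An `orthology_posterior` for `pillars`.
#' @param annotation Optional annotation tibble (as from [read_annotation()])
#'   used to look up flanking gene bodies; by default the coordinates carried
#'   in the pillar set are used.
#' @param threshold Joint-state confidence threshold, default 0.95 (the
#'   `>= 95\%` rule).
#' @param max_gap Number of intervening pillars tolerated between the two
#'   pillars of a pair (default 0: strict adjacency in the ancestral order).
#' @return A tibble with one row per genome per SAIR: `sair_id`, `subgenome`,
#'   `pillar_left`, `pillar_right`, `confidence` (min of the two joint
#'   posteriors), `genome`, `chrom`, `start`, `end`, `flank_left`,
#'   `flank_right`. Groups dropped for abutting flanks are reported in the
#'   `dropped` attribute.
#' @export
find_sairs <- function(pillars, posterior, annotation = NULL,
                       threshold = 0.95, max_gap = 0) {
  stopifnot(inherits(pillars, "pillar_set"),
            inherits(posterior, "orthology_posterior"))
  genomes <- pillars$genomes
  perms <- track_permutations()
  idx <- pillars$index
  n <- nrow(idx)
  map <- posterior$map
  # per pillar per genome: MAP permutation
  map_perm <- map |>
    dplyr::select("pillar_id", "state") |>
    dplyr::inner_join(posterior$states, by = "state",
                      relationship = "many-to-many") |>
    dplyr::select("pillar_id", "genome", "perm")

  genes <- pillars$genes
  if (!is.null(annotation)) {
    genes <- genes |>
      dplyr::select(-"start", -"end", -"chrom") |>
      dplyr::inner_join(
        dplyr::select(annotation, "genome", "gene_id", "chrom", "start",
                      "end"),
        by = c("genome", "gene_id")
      )
  }
  # coordinate rank over pillar genes, for the syntenic-neighbour predicate
  genes <- genes |>
    dplyr::group_by(.data$genome, .data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(.rank = dplyr::row_number()) |>
    dplyr::ungroup()

  gene_at <- genes |>
    dplyr::inner_join(map_perm, by = c("pillar_id", "genome")) |>
    dplyr::mutate(subgenome = perms[cbind(.data$perm, .data$track)])

  conf <- map$prob  # map rows are in pillar (ancestral) order
  by_pos <- split(gene_at, match(gene_at$pillar_id, idx$pillar_id))
  rows <- list()
  dropped <- list()
  for (i in seq_len(max(0, n - 1))) {
    jmax <- min(n, i + 1 + max_gap)
    for (j in (i + 1):jmax) {
      # pairs must lie in one contiguity block
      if (any(idx$new_block[(i + 1):j])) break
      pid_l <- idx$pillar_id[i]; pid_r <- idx$pillar_id[j]
      c_l <- conf[i]; c_r <- conf[j]
      if (min(c_l, c_r) < threshold) next
      gl <- by_pos[[as.character(i)]]
      gr <- by_pos[[as.character(j)]]
      if (is.null(gl) || is.null(gr)) next
      for (sg in subgenomes()) {
        fl <- gl[gl$subgenome == sg, ]
        fr <- gr[gr$subgenome == sg, ]
        if (nrow(fl) < length(genomes) || nrow(fr) < length(genomes)) next
        pair <- dplyr::inner_join(
          dplyr::select(fl, "genome", l_gene = "gene_id", l_chrom = "chrom",
                        l_start = "start", l_end = "end", l_rank = ".rank"),
          dplyr::select(fr, "genome", r_gene = "gene_id", r_chrom = "chrom",
                        r_start = "start", r_end = "end", r_rank = ".rank"),
          by = "genome"
        )
        syntenic <- pair$l_chrom == pair$r_chrom &
          abs(pair$l_rank - pair$r_rank) == 1
        if (!all(syntenic)) next
        left_first <- pair$l_start <= pair$r_start
        out <- tibble::tibble(
          subgenome = sg, pillar_left = pid_l, pillar_right = pid_r,
          confidence = min(c_l, c_r),
          genome = pair$genome,
          chrom = pair$l_chrom,
          start = ifelse(left_first, pair$l_end, pair$r_end),
          end = ifelse(left_first, pair$r_start, pair$l_start),
          flank_left = ifelse(left_first, pair$l_gene, pair$r_gene),
          flank_right = ifelse(left_first, pair$r_gene, pair$l_gene)
        )
        if (any(out$start >= out$end)) {
          dropped[[length(dropped) + 1]] <- tibble::tibble(
            subgenome = sg, pillar_left = pid_l, pillar_right = pid_r,
            reason = "abutting or overlapping flanking genes"
          )
          next
        }
        rows[[length(rows) + 1]] <- out
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out <- dplyr::mutate(
      out,
      sair_id = sprintf("SAIR_%s_p%d_p%d", .data$subgenome,
                        .data$pillar_left, .data$pillar_right),
      .before = 1
    )
  } else {
    out <- tibble::tibble(sair_id = character(), subgenome = character(),
                          pillar_left = integer(), pillar_right = integer(),
                          confidence = numeric(), genome = character(),
                          chrom = character(), start = numeric(),
                          end = numeric(), flank_left = character(),
                          flank_right = character())
  }
  attr(out, "dropped") <- dplyr::bind_rows(dropped)
  out
}

#' Attach sequences to SAIR intervals
#'
#' Slices each genome's chromosome sequence by the SAIR's 0-based half-open
#' interval. Strand is ignored throughout (no reverse complement): repeat
#' searches and alignments are strand-agnostic.
#'
#' @param sairs A SAIR tibble from [find_sairs()].
#' @param sequences A named list (by genome) of [Biostrings::DNAStringSet]
#'   objects or paths to FASTA files with the chromosome sequences.
#' @return `sairs` with a `sequence` character column added.
#' @export
extract_sequences <- function(sairs, sequences) {
  getset <- function(x) {
    if (inherits(x, "DNAStringSet")) x else Biostrings::readDNAStringSet(x)
  }
  seqs <- lapply(sequences, getset)
  missing <- setdiff(unique(sairs$genome), names(seqs))
  if (length(missing) > 0) {
    stop("no sequences supplied for genome(s): ",
         paste(missing, collapse = ", "))
  }
  out <- character(nrow(sairs))
  for (k in seq_len(nrow(sairs))) {
    ss <- seqs[[sairs$genome[k]]]
    chrom <- sairs$chrom[k]
    if (!chrom %in% names(ss)) {
      stop("chromosome ", chrom, " not found in sequences for ",
           sairs$genome[k])
    }
    len <- Biostrings::width(ss[chrom])
    if (sairs$end[k] > len) {
      stop("SAIR interval [", sairs$start[k], ",", sairs$end[k],
           ") exceeds length of ", chrom, " (", len, ")")
    }
    out[k] <- as.character(Biostrings::subseq(ss[[chrom]],
                                              start = sairs$start[k] + 1,
                                              end = sairs$end[k]))
  }
  sairs$sequence <- out
  sairs
}
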