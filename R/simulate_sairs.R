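# 12 synthetic repeat elements, lengths 60-400 b, generated deterministically
# from an internal seed so every build ships the same toy library.
toy_re_library <- function() {
  path <- system.file("extdata", "toy_re_library.fa", package = "hexfrac")
  if (nzchar(path) && file.exists(path)) {
    ss <- Biostrings::readDNAStringSet(path)
    return(setNames(as.character(ss), names(ss)))
  }
  generate_toy_re_library()
}

generate_toy_re_library <- function() {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(607001)
  lens <- round(seq(60, 400, length.out = 12))
  setNames(
    vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1)),
    sprintf("toyRE%02d_len%d", seq_along(lens), lens)
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute a fraction d of sites with a different base
mutate_seq <- function(seq, d) {
  if (d <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < d)
  if (length(hit) > 0) {
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    v[hit] <- vapply(v[hit], function(b) {
      j <- sample.int(3, 1)
      substr(alt[[b]], j, j)
    }, character(1))
  }
  paste(v, collapse = "")
}

# apply random indels: per-base probability `rate`, geometric lengths
apply_indels <- function(seq, rate, mean_len) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  for (i in seq_len(k)) {
    L <- 1 + stats::rgeom(1, 1 / mean_len)
    pos <- sample.int(max(1, length(v)), 1)
    if (runif(1) < 0.5) {
      v <- v[-(pos:min(length(v), pos + L - 1))]  # deletion
    } else {
      ins <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      v <- append(v, ins, after = pos)
    }
  }
  if (length(v) < 10) return(paste(c(v, rep("A", 10 - length(v))),
                                   collapse = ""))
  paste(v, collapse = "")
}

#' Simulate SAIR sequences with planted repeats and known truth
#'
#' Draws ancestral intergenic sequences for a requested number of SAIRs per
#' subgenome, plants copies of a bundled toy repeat library at per-subgenome
#' Poisson densities (non-overlapping; planted-at-root copies are the
#' ancestral truth), and evolves each genome's copy along the species tree by
#' substitutions (per-tip divergence scaled by root-to-tip path length) and
#' random indels. Emits per-genome sequences, a perfect-knowledge hit table
#' (each planted copy's interval per genome, E-value 0) so downstream stages
#' can be tested without running an external search, and the truth table.
#'
#' @param config A [sim_config()] (uses `re_density`, SAIR length and
#'   divergence parameters, and the seed).
#' @param n_per_subgenome Named or unnamed counts of SAIRs per subgenome
#'   (default 100 each).
#' @return A list: `sairs` (tibble with `sair_id`, `subgenome`, `genome`,
#'   `start`, `end`, `sequence` - coordinates span the whole simulated
#'   interval), `hits` (per-genome planted-repeat hit table), `truth`
#'   (planted elements with ancestral flags and intervals).
#' @export
simulate_sairs <- function(config, n_per_subgenome = c(LF = 100, IF = 100,
                                                       MF = 100)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  if (is.null(names(n_per_subgenome))) {
    n_per_subgenome <- setNames(rep(n_per_subgenome, length.out = 3),
                                subgenomes())
  }
  lib <- toy_re_library()
  lib_len <- nchar(lib)
  genomes <- config$genomes
  # per-tip divergence: substitutions proportional to root-to-tip u
  depths <- tip_depths(config$tree)
  tipdiv <- config$divergence * depths / max(depths)

  sair_rows <- list(); hit_rows <- list(); truth_rows <- list()
  for (sg in subgenomes()) {
    nsg <- n_per_subgenome[[sg]]
    if (nsg == 0) next
    dens <- config$re_density[[sg]]
    for (i in seq_len(nsg)) {
      sid <- sprintf("SIM_%s_%04d", sg, i)
      len <- max(200, round(stats::rlnorm(1, config$sair_length_meanlog,
                                          config$sair_length_sdlog)))
      anc <- random_dna(len)
      n_re <- rpois(1, dens * len / 1000)
      placed <- IRanges::IRanges()
      for (k in seq_len(n_re)) {
        el <- sample(length(lib), 1)
        L <- lib_len[el]
        if (L + 2 >= len) next
        for (try in 1:20) {
          s0 <- sample.int(len - L, 1)  # 0-based start
          cand <- IRanges::IRanges(s0 + 1, s0 + L)
          if (length(placed) == 0 ||
              !any(IRanges::overlapsAny(cand, placed))) {
            placed <- c(placed, cand)
            substr(anc, s0 + 1, s0 + L) <- lib[[el]]
            truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
              sair_id = sid, subgenome = sg, element_id = names(lib)[el],
              start = s0, end = s0 + L, ancestral = TRUE
            )
            break
          }
        }
      }
      for (g in genomes) {
        d <- tipdiv[[g]]
        gseq <- mutate_seq(anc, d)
        gseq <- apply_indels(gseq, config$indel_rate, config$indel_mean)
        sair_rows[[length(sair_rows) + 1]] <- tibble::tibble(
          sair_id = sid, subgenome = sg, genome = g,
          chrom = paste0(sid, "|", g),
          start = 0, end = nchar(gseq), sequence = gseq
        )
      }
    }
  }
  sairs <- dplyr::bind_rows(sair_rows)
  truth <- dplyr::bind_rows(truth_rows)
  # perfect-knowledge hit table: planted intervals, adjusted only by clipping
  # to each genome's (possibly indel-shortened) sequence length
  if (nrow(truth) > 0) {
    hits <- tidyr::expand_grid(truth, genome = genomes) |>
      dplyr::inner_join(
        dplyr::select(sairs, "sair_id", "genome", seq_len_g = "end"),
        by = c("sair_id", "genome")
      ) |>
      dplyr::mutate(end = pmin(.data$end, .data$seq_len_g)) |>
      dplyr::filter(.data$end - .data$start >= 20) |>
      dplyr::transmute(
        element_id = .data$element_id, sair_id = .data$sair_id,
        genome = .data$genome, start = .data$start, end = .data$end,
        score = (.data$end - .data$start) * 2, evalue = 0
      )
  } else {
    hits <- tibble::tibble(element_id = character(), sair_id = character(),
                           genome = character(), start = numeric(),
                           end = numeric(), score = numeric(),
                           evalue = numeric())
  }
  list(sairs = sairs, hits = hits, truth = truth)
}

# root-to-tip path lengths (u units), named by tip
tip_depths <- function(tree) {
  tree <- validate_tree(tree)
  n <- length(tree$tip.label)
  depth <- numeric(n + tree$Nnode)
  depth[n + 1L] <- tree$root.edge
  edges <- tree$edge
  walk <- function(node) {
    for (r in which(edges[, 1] == node)) {
      child <- edges[r, 2]
      depth[child] <<- depth[node] + tree$edge.length[r]
      if (child > n) walk(child)
    }
  }
  walk(n + 1L)
  setNames(depth[seq_len(n)], tree$tip.label)
}
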