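#' Construct a pillar set
#'
#' A *pillar* is one ancestral locus triplicated by the hexaploidy; for each
#' polyploid genome it carries up to three syntenic gene slots ("tracks").
#' A `pillar_set` holds the ordered pillars, the per-track gene records, the
#' per-track adjacency flags (is this track's gene the syntenic neighbour of
#' the same track's gene in the previous pillar?) and the contiguity breaks at
#' which the ancestral order is interrupted.
#'
#' Adjacency is computed from coordinates: two genes are syntenic neighbours
#' when they lie on the same chromosome with no other pillar gene of that
#' genome between them. Contiguity breaks (where the hidden orthology chain is
#' re-initialised) are the explicitly declared ones (`#BREAK` rows in the
#' TSV); with `detect_breaks = TRUE`, junctions across which no genome has any
#' adjacent track pair are additionally declared. Detection is off by default:
#' a junction that merely lacks adjacency evidence is uninformative about
#' synteny switching, and forcing a chain reset there conditions on the local
#' loss pattern and measurably biases the fitted loss rates. Use detection
#' only for pillar files that carry no block annotation at all.
#'
#' @param genes A data frame with one row per occupied track: `pillar_id`,
#'   `genome`, `track` (1-3), `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`, `"-"` or `"."`; carried but ignored by all
#'   likelihood computations).
#' @param genomes Character vector of genome names (defines column order in
#'   the TSV); defaults to the genomes present.
#' @param index Optional tibble with `pillar_id` and `reference_gene`
#'   (outgroup anchor, `NA` allowed); defaults to the pillar ids present.
#' @param explicit_breaks Integer vector of pillar *positions* (1-based, in
#'   ancestral order) that start a new contiguity block.
#' @param detect_breaks Also declare breaks at junctions with no adjacent
#'   track pair in any genome (default `FALSE`; see Details).
#' @return A `pillar_set` object.
#' @export
pillar_set <- function(genes, genomes = NULL, index = NULL,
                       explicit_breaks = integer(), detect_breaks = FALSE) {
  genes <- tibble::as_tibble(genes)
  need <- c("pillar_id", "genome", "track", "gene_id", "chrom", "start",
            "end", "strand")
  missing <- setdiff(need, names(genes))
  if (length(missing) > 0) {
    stop("genes is missing columns: ", paste(missing, collapse = ", "))
  }
  if (is.null(genomes)) genomes <- sort(unique(genes$genome))
  if (anyDuplicated(genomes)) stop("genome names must be unique")
  if (is.null(index)) {
    index <- tibble::tibble(pillar_id = sort(unique(genes$pillar_id)),
                            reference_gene = NA_character_)
  }
  index <- tibble::as_tibble(index)
  if (is.unsorted(index$pillar_id, strictly = TRUE)) {
    stop("pillar_ids must be strictly increasing")
  }
  bad <- setdiff(genes$genome, genomes)
  if (length(bad) > 0) stop("unknown genome(s): ", paste(bad, collapse = ", "))
  if (!all(genes$pillar_id %in% index$pillar_id)) {
    stop("gene rows reference pillar_ids absent from the index")
  }
  if (!all(genes$track %in% 1:3)) stop("track must be 1, 2 or 3")
  if (any(genes$start >= genes$end)) {
    stop("coordinates must satisfy start < end (0-based half-open)")
  }
  dup_slot <- genes |>
    dplyr::count(.data$pillar_id, .data$genome, .data$track) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup_slot) > 0) {
    stop("duplicate (pillar, genome, track) slot at pillar ",
         dup_slot$pillar_id[1])
  }
  dup_gene <- genes |>
    dplyr::count(.data$genome, .data$gene_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup_gene) > 0) {
    stop("duplicate gene_id within genome ", dup_gene$genome[1], ": ",
         dup_gene$gene_id[1])
  }
  empty <- setdiff(index$pillar_id, genes$pillar_id)
  if (length(empty) > 0) {
    stop("pillar ", empty[1], " has no genes in any genome")
  }
  if (any(grepl("[:\t]", genes$gene_id))) {
    stop("gene_ids must not contain ':' or tab characters")
  }

  genes$pos <- match(genes$pillar_id, index$pillar_id)
  genes <- dplyr::arrange(genes, .data$pos, .data$genome, .data$track)

  # coordinate rank within (genome, chromosome), over the pillar genes only
  genes <- genes |>
    dplyr::group_by(.data$genome, .data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(.rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$pos, .data$genome, .data$track)

  prev <- genes |>
    dplyr::transmute(.data$genome, .data$track, pos = .data$pos + 1L,
                     prev_chrom = .data$chrom, prev_rank = .data$.rank)
  genes <- genes |>
    dplyr::left_join(prev, by = c("genome", "track", "pos")) |>
    dplyr::mutate(adjacent = !is.na(.data$prev_chrom) &
                    .data$chrom == .data$prev_chrom &
                    abs(.data$.rank - .data$prev_rank) == 1L) |>
    dplyr::select(-".rank", -"prev_chrom", -"prev_rank")

  n_pillars <- nrow(index)
  new_block <- logical(n_pillars)
  if (detect_breaks) {
    any_adj <- genes |>
      dplyr::group_by(.data$pos) |>
      dplyr::summarise(any_adj = any(.data$adjacent))
    adj_at <- logical(n_pillars)
    adj_at[any_adj$pos] <- any_adj$any_adj
    new_block <- !adj_at
  }
  new_block[1] <- TRUE
  ok_breaks <- explicit_breaks[explicit_breaks >= 1 &
                                 explicit_breaks <= n_pillars]
  new_block[ok_breaks] <- TRUE
  # a declared break severs adjacency across the junction
  genes$adjacent[new_block[genes$pos]] <- FALSE
  index$new_block <- new_block

  structure(list(genomes = genomes, index = index, genes = genes),
            class = "pillar_set")
}

#' @export
print.pillar_set <- function(x, ...) {
  cat(sprintf("<pillar_set> %d pillars, %d genomes (%s), %d genes, %d blocks\n",
              nrow(x$index), length(x$genomes),
              paste(x$genomes, collapse = ", "), nrow(x$genes),
              sum(x$index$new_block)))
  invisible(x)
}

#' @export
as_tibble.pillar_set <- function(x, ...) x$genes

#' Number of pillars in a pillar set
#' @param pillars A `pillar_set`.
#' @return Integer count.
#' @export
n_pillars <- function(pillars) nrow(pillars$index)

#' Contiguity-break positions of a pillar set
#'
#' @param pillars A `pillar_set`.
#' @return Integer vector of pillar positions (1-based) that start a new
#'   contiguity block; position 1 is always a block start.
#' @export
contiguity_breaks <- function(pillars) which(pillars$index$new_block)

#' Read a pillar TSV file
#'
#' The pillar dialect is a tab-separated table with comment lines starting
#' `#`. The header `# genomes:` line names the genomes; the column header row
#' is `pillar_id`, `reference_gene`, then three columns `<genome>.1..3` per
#' genome. Each track cell is either `-` (empty) or
#' `gene_id:chrom:start:end:strand` with 0-based half-open coordinates.
#' A line consisting of `#BREAK` declares a contiguity break before the next
#' pillar row.
#'
#' @param path Path to the TSV file.
#' @param detect_breaks Declare extra contiguity breaks at junctions with no
#'   adjacency evidence (see [pillar_set()]); default `FALSE`.
#' @return A validated [pillar_set()].
#' @export
read_pillars <- function(path, detect_breaks = FALSE) {
  lines <- readr::read_lines(path)
  if (length(lines) == 0) stop("empty pillar file: ", path)
  header_row <- NULL
  genomes <- NULL
  rows <- list()
  breaks_before_next <- FALSE
  explicit_breaks <- integer()
  n_rows <- 0L
  cols <- NULL
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (line == "") next
    if (line == "#BREAK") { breaks_before_next <- TRUE; next }
    if (startsWith(line, "# genomes:")) {
      genomes <- strsplit(trimws(sub("^# genomes:", "", line)), ",")[[1]]
      genomes <- trimws(genomes)
      next
    }
    if (startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (is.null(header_row)) {
      header_row <- fields
      if (length(header_row) < 5 || header_row[1] != "pillar_id") {
        stop("line ", i, ": malformed header row")
      }
      if (is.null(genomes)) {
        genomes <- unique(sub("\\.[123]$", "", header_row[-(1:2)]))
      }
      cols <- c("pillar_id", "reference_gene",
                paste0(rep(genomes, each = 3), ".", 1:3))
      if (!identical(header_row, cols)) {
        stop("line ", i, ": header columns do not match the declared genomes")
      }
      next
    }
    if (length(fields) != length(cols)) {
      stop("line ", i, ": expected ", length(cols), " fields, found ",
           length(fields))
    }
    n_rows <- n_rows + 1L
    if (breaks_before_next) {
      explicit_breaks <- c(explicit_breaks, n_rows)
      breaks_before_next <- FALSE
    }
    rows[[n_rows]] <- list(line = i, fields = fields)
  }
  if (is.null(header_row)) stop("no header row found in ", path)
  if (n_rows == 0) stop("no pillar rows found in ", path)

  parse_cell <- function(cell, line, genome, track) {
    if (cell == "-") return(NULL)
    parts <- strsplit(cell, ":", fixed = TRUE)[[1]]
    if (length(parts) != 5) {
      stop("line ", line, ": malformed track cell '", cell, "'")
    }
    start <- suppressWarnings(as.numeric(parts[3]))
    end <- suppressWarnings(as.numeric(parts[4]))
    if (is.na(start) || is.na(end)) {
      stop("line ", line, ": non-numeric coordinates in '", cell, "'")
    }
    list(genome = genome, track = track, gene_id = parts[1],
         chrom = parts[2], start = start, end = end, strand = parts[5])
  }

  idx <- vector("list", n_rows)
  gene_rows <- list()
  for (r in seq_len(n_rows)) {
    fields <- rows[[r]]$fields
    line <- rows[[r]]$line
    pid <- suppressWarnings(as.integer(fields[1]))
    if (is.na(pid)) stop("line ", line, ": non-integer pillar_id '",
                         fields[1], "'")
    ref <- if (fields[2] == "-") NA_character_ else fields[2]
    idx[[r]] <- tibble::tibble(pillar_id = pid, reference_gene = ref)
    k <- 2L
    for (g in genomes) {
      for (t in 1:3) {
        k <- k + 1L
        cell <- parse_cell(fields[k], line, g, t)
        if (!is.null(cell)) {
          gene_rows[[length(gene_rows) + 1L]] <-
            tibble::tibble(pillar_id = pid, genome = cell$genome,
                           track = cell$track, gene_id = cell$gene_id,
                           chrom = cell$chrom, start = cell$start,
                           end = cell$end, strand = cell$strand)
        }
      }
    }
  }
  index <- dplyr::bind_rows(idx)
  genes <- dplyr::bind_rows(gene_rows)
  pillar_set(genes, genomes = genomes, index = index,
             explicit_breaks = explicit_breaks, detect_breaks = detect_breaks)
}

#' Write a pillar set to the pillar TSV dialect
#'
#' Writes the canonical form read back by [read_pillars()]: pillars in
#' ancestral order, a `#BREAK` line before every contiguity-block start
#' (except the first pillar). `write_pillars()` then `read_pillars()` is an
#' identity, and re-writing reproduces the file byte for byte.
#'
#' @param pillars A `pillar_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pillars <- function(pillars, path) {
  stopifnot(inherits(pillars, "pillar_set"))
  genomes <- pillars$genomes
  cols <- c("pillar_id", "reference_gene",
            paste0(rep(genomes, each = 3), ".", 1:3))
  genes <- pillars$genes
  key <- paste(genes$pos, genes$genome, genes$track)
  cell <- sprintf("%s:%s:%d:%d:%s", genes$gene_id, genes$chrom,
                  as.integer(genes$start), as.integer(genes$end),
                  genes$strand)
  cells <- setNames(cell, key)
  out <- character(0)
  out <- c(out, "# pillar TSV v1",
           paste0("# genomes: ", paste(genomes, collapse = ",")),
           paste(cols, collapse = "\t"))
  for (r in seq_len(nrow(pillars$index))) {
    if (r > 1 && pillars$index$new_block[r]) out <- c(out, "#BREAK")
    ref <- pillars$index$reference_gene[r]
    fields <- c(as.character(pillars$index$pillar_id[r]),
                if (is.na(ref)) "-" else ref)
    for (g in genomes) {
      for (t in 1:3) {
        v <- cells[paste(r, g, t)]
        fields <- c(fields, if (is.na(v)) "-" else v)
      }
    }
    out <- c(out, paste(fields, collapse = "\t"))
  }
  readr::write_lines(out, path)
  invisible(path)
}

# presence bitmask matrix, n_pillars x genomes (in the given order)
pillar_masks <- function(pillars, genome_order = pillars$genomes) {
  n <- n_pillars(pillars)
  masks <- matrix(0L, nrow = n, ncol = length(genome_order),
                  dimnames = list(NULL, genome_order))
  g <- pillars$genes
  j <- match(g$genome, genome_order)
  bit <- bitwShiftL(1L, g$track - 1L)
  for (k in seq_along(j)) {
    masks[g$pos[k], j[k]] <- bitwOr(masks[g$pos[k], j[k]], bit[k])
  }
  masks
}
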