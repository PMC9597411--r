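#' Load repetitive-element hit tables
#'
#' Reads repeat hits against SAIR sequences from BLASTN tabular output
#' (`-outfmt 6`) or nhmmer `--tblout` format, applies the E-value cutoff
#' (hits with E-value exactly at the cutoff are kept), and normalises
#' coordinates to 0-based half-open with `start < end` (minus-strand hits are
#' reported reversed by both tools).
#'
#' For `blast6` the SAIR is taken to be the query (the regions are searched
#' against the element library) unless `sair_is = "subject"`. For `nhmmer`
#' the SAIR is the target sequence and the element the profile query.
#' SAIR sequence names of the form `<sair_id>|<genome>` are split into the
#' two columns.
#'
#' @param path Path to the hit table.
#' @param dialect `"blast6"` or `"nhmmer"`.
#' @param e_cutoff Maximum E-value retained (default `1e-5`).
#' @param sair_is For `blast6`: which side of the pair is the SAIR.
#' @return A tibble: `element_id`, `sair_id`, `genome` (`NA` if not encoded),
#'   `start`, `end`, `score`, `evalue`.
#' @export
load_hits <- function(path, dialect = c("blast6", "nhmmer"), e_cutoff = 1e-5,
                      sair_is = c("query", "subject")) {
  dialect <- match.arg(dialect)
  sair_is <- match.arg(sair_is)
  if (dialect == "blast6") {
    cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")
    tab <- readr::read_tsv(path, col_names = cols, comment = "#",
                           show_col_types = FALSE, progress = FALSE)
    if (sair_is == "query") {
      out <- tibble::tibble(element_id = tab$sseqid, sair_name = tab$qseqid,
                            from = tab$qstart, to = tab$qend,
                            score = tab$bitscore, evalue = tab$evalue)
    } else {
      out <- tibble::tibble(element_id = tab$qseqid, sair_name = tab$sseqid,
                            from = tab$sstart, to = tab$send,
                            score = tab$bitscore, evalue = tab$evalue)
    }
  } else {
    lines <- readr::read_lines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (length(lines) == 0) {
      out <- tibble::tibble(element_id = character(), sair_name = character(),
                            from = numeric(), to = numeric(),
                            score = numeric(), evalue = numeric())
    } else {
      fields <- strsplit(trimws(lines), "\\s+")
      bad <- which(lengths(fields) < 14)
      if (length(bad) > 0) {
        stop("malformed nhmmer tblout line ", bad[1])
      }
      get <- function(k) vapply(fields, `[[`, character(1), k)
      out <- tibble::tibble(
        element_id = get(3), sair_name = get(1),
        from = as.numeric(get(7)), to = as.numeric(get(8)),  # alifrom/ali to
        score = as.numeric(get(14)), evalue = as.numeric(get(13))
      )
    }
  }
  if (any(is.na(out$from)) || any(is.na(out$to))) {
    stop("non-numeric hit coordinates in ", path)
  }
  if (any(out$from < 1 | out$to < 1)) stop("hit coordinates must be >= 1")
  out <- out |>
    dplyr::filter(.data$evalue <= e_cutoff) |>
    dplyr::mutate(
      start = pmin(.data$from, .data$to) - 1,  # 1-based closed in, 0-based out
      end = pmax(.data$from, .data$to),
      sair_id = sub("\\|.*$", "", .data$sair_name),
      genome = ifelse(grepl("\\|", .data$sair_name),
                      sub("^[^|]*\\|", "", .data$sair_name), NA_character_)
    ) |>
    dplyr::select("element_id", "sair_id", "genome", "start", "end",
                  "score", "evalue")
  out
}

#' Merge overlapping repeat hits into regions
#'
#' Hits to the same SAIR that overlap by at least one base are merged into a
#' single region (interval union via [IRanges::reduce()]); abutting hits
#' (zero overlap) stay separate. The operation is idempotent and
#' order-invariant.
#'
#' @param hits A hit tibble (needs `sair_id`, `start`, `end`; a `genome`
#'   column, if present, takes part in the grouping).
#' @return A tibble: grouping columns, `start`, `end`, `n_hits`, `elements`
#'   (comma-collapsed contributing element ids, when available).
#' @export
merge_regions <- function(hits) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(sair_id = character(), start = numeric(),
                          end = numeric(), n_hits = integer(),
                          elements = character()))
  }
  grp_cols <- intersect(c("sair_id", "genome"), names(hits))
  hits |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::group_modify(function(d, key) {
      ir <- IRanges::IRanges(start = d$start + 1, end = d$end)
      red <- IRanges::reduce(ir, min.gapwidth = 0L)
      ov <- IRanges::findOverlaps(ir, red)
      elements <- vapply(seq_along(red), function(k) {
        ids <- if ("element_id" %in% names(d)) {
          unique(d$element_id[S4Vectors::queryHits(ov)[
            S4Vectors::subjectHits(ov) == k]])
        } else character(0)
        paste(sort(ids), collapse = ",")
      }, character(1))
      tibble::tibble(start = IRanges::start(red) - 1,
                     end = as.numeric(IRanges::end(red)),
                     n_hits = tabulate(S4Vectors::subjectHits(ov),
                                       nbins = length(red)),
                     elements = elements)
    }) |>
    dplyr::ungroup()
}

#' Smith-Waterman local alignment
#'
#' Best local alignment under the repeat-conservation scoring scheme:
#' match +4, mismatch -5 (N matches nothing), first gapped base -8, each
#' additional gapped base -4 (affine). Computed with
#' [Biostrings::pairwiseAlignment()] (`type = "local"`). The alignment length
#' is the number of alignment columns, gaps included.
#'
#' @param query,target DNA sequences (character or `DNAString`), non-empty,
#'   over `A C G T N`.
#' @return A list with `score` and `length`.
#' @export
local_align <- function(query, target) {
  q <- toupper(as.character(query)); t <- toupper(as.character(target))
  if (nchar(q) == 0 || nchar(t) == 0) stop("empty sequence")
  if (grepl("[^ACGTN]", q) || grepl("[^ACGTN]", t)) {
    stop("sequences must be over the alphabet {A, C, G, T, N}")
  }
  aln <- Biostrings::pairwiseAlignment(
    q, t, type = "local",
    substitutionMatrix = repeat_scoring_matrix(),
    gapOpening = 4, gapExtension = 4, scoreOnly = FALSE
  )
  list(score = as.numeric(Biostrings::score(aln)),
       length = nchar(as.character(Biostrings::alignedPattern(aln))))
}

repeat_scoring_matrix <- function() {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-5, 5, 5, dimnames = list(letters, letters))
  diag(m) <- 4
  m["N", "N"] <- -5  # N is never a match
  m
}

#' Call ancestral repeats by presence parsimony
#'
#' An element is called ancestral for a SAIR group when a passing hit to that
#' element is present in the orthologous intergenic region of *every* genome
#' of the group.
#'
#' @param hits Hit tibble with `element_id`, `sair_id`, `genome` (E-value
#'   filtering is assumed done by [load_hits()]).
#' @param genomes Character vector of the genomes that must all carry the
#'   element.
#' @return A tibble: `sair_id`, `element_id`, `n_genomes`, `ancestral`.
#' @export
call_ancestral_parsimony <- function(hits, genomes) {
  hits |>
    dplyr::distinct(.data$sair_id, .data$element_id, .data$genome) |>
    dplyr::count(.data$sair_id, .data$element_id, name = "n_genomes") |>
    dplyr::mutate(ancestral = .data$n_genomes >= length(genomes))
}

#' Call ancestral repeat regions by conserved local alignment
#'
#' For each merged repeat region in the reference genome, aligns the region's
#' sequence against the orthologous SAIR sequence of every other genome with
#' [local_align()]; the region is ancestral when every genome yields an
#' alignment of at least `min_length` columns scoring at least `min_score`.
#'
#' @param regions Regions tibble from [merge_regions()] restricted to the
#'   reference genome (`sair_id`, `start`, `end`).
#' @param sairs SAIR tibble with sequences (from [extract_sequences()]).
#' @param reference Reference genome name (the genome the regions live in).
#' @param min_length Minimum alignment columns (default 80).
#' @param min_score Minimum alignment score (default 200).
#' @return `regions` with added `ancestral` plus per-genome score/length
#'   columns; regions whose group lacks a genome's sequence are dropped with
#'   a message.
#' @export
call_ancestral_regions <- function(regions, sairs, reference,
                                   min_length = 80, min_score = 200) {
  stopifnot("sequence" %in% names(sairs))
  others <- setdiff(unique(sairs$genome), reference)
  seq_of <- function(sid, g) {
    s <- sairs$sequence[sairs$sair_id == sid & sairs$genome == g]
    if (length(s) == 1) s else NA_character_
  }
  out <- vector("list", nrow(regions))
  for (k in seq_len(nrow(regions))) {
    sid <- regions$sair_id[k]
    refseq <- seq_of(sid, reference)
    if (is.na(refseq)) {
      message("skipping region in ", sid, ": no reference sequence")
      next
    }
    qseq <- substr(refseq, regions$start[k] + 1, regions$end[k])
    res <- tibble::tibble(genome = others, score = NA_real_,
                          length = NA_integer_)
    ok <- TRUE
    complete <- TRUE
    for (i in seq_along(others)) {
      tseq <- seq_of(sid, others[i])
      if (is.na(tseq)) { complete <- FALSE; break }
      al <- local_align(qseq, tseq)
      res$score[i] <- al$score
      res$length[i] <- al$length
      if (al$score < min_score || al$length < min_length) ok <- FALSE
    }
    if (!complete) {
      message("skipping region in ", sid, ": missing orthologous sequence")
      next
    }
    row <- regions[k, ]
    row$ancestral <- ok
    row$alignments <- list(res)
    out[[k]] <- row
  }
  dplyr::bind_rows(out)
}

#' Repeat density per subgenome
#'
#' Density is the number of hits (or regions, or ancestral calls) assigned to
#' a subgenome's SAIRs divided by the total length of those SAIRs, in hits
#' per kilobase. Grouping by genome is added automatically when the hit table
#' carries a `genome` column.
#'
#' @param hits Tibble with `sair_id` (one row per counted hit) and optionally
#'   `genome`.
#' @param sairs SAIR tibble (`sair_id`, `genome`, `subgenome`, `start`,
#'   `end`).
#' @param by Extra grouping columns (default `"subgenome"`, with `"genome"`
#'   added when present in `hits`).
#' @return A tibble: grouping columns, `n_hits`, `total_length`,
#'   `density` (hits/kB).
#' @export
re_density <- function(hits, sairs, by = NULL) {
  sair_len <- sairs |>
    dplyr::mutate(length = .data$end - .data$start)
  per_genome <- !is.null(hits$genome) && !anyNA(hits$genome)
  grp <- by %||% c("subgenome", if (per_genome) "genome")
  lens <- sair_len |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(total_length = sum(.data$length), .groups = "drop")
  if (any(lens$total_length <= 0)) {
    stop("zero total SAIR length for a subgenome; density undefined")
  }
  key <- dplyr::distinct(sair_len, .data$sair_id, .data$genome,
                         .data$subgenome)
  joined <- if (per_genome) {
    dplyr::inner_join(hits, key, by = c("sair_id", "genome"))
  } else {
    dplyr::inner_join(hits, dplyr::distinct(key, .data$sair_id,
                                            .data$subgenome),
                      by = "sair_id")
  }
  counts <- joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n_hits = dplyr::n(), .groups = "drop")
  lens |>
    dplyr::left_join(counts, by = grp) |>
    dplyr::mutate(n_hits = dplyr::coalesce(.data$n_hits, 0L),
                  density = 1000 * .data$n_hits / .data$total_length) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grp)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
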