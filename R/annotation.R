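#' Read gene annotations from GFF3
#'
#' Imports gene features from a GFF3 file (via \pkg{rtracklayer}) and converts
#' the 1-based closed GFF coordinates to the package's 0-based half-open
#' convention (`start0 = start - 1`, `end0 = end`).
#'
#' @param path Path to a GFF3 file.
#' @param genome Genome name to attach to the records.
#' @param feature_type GFF3 `type` to keep (default `"gene"`).
#' @return A tibble with `genome`, `gene_id`, `chrom`, `start`, `end`,
#'   `strand`. An empty file yields an empty tibble with a warning.
#' @export
read_annotation <- function(path, genome, feature_type = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_annotation() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) {
    warning("no features found in ", path)
    return(tibble::tibble(genome = character(), gene_id = character(),
                          chrom = character(), start = numeric(),
                          end = numeric(), strand = character()))
  }
  gr <- gr[as.character(gr$type) == feature_type]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  if (anyNA(ids)) stop("gene features without an ID attribute in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id in ", path, ": ", ids[duplicated(ids)][1])
  }
  out <- tibble::tibble(
    genome = genome,
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr))
  )
  if (any(out$start >= out$end)) {
    bad <- which(out$start >= out$end)[1]
    stop("coordinate inversion (end <= start) for gene ", out$gene_id[bad])
  }
  out
}
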