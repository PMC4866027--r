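#' Read / write per-probe log2-ratio tracks
#'
#' Probe tracks are tab-separated files with columns `chrom`, `pos`, `log2`,
#' one file per hybridization (one test sample against one reference).
#'
#' @param path File path.
#' @param sample_id Sample identifier attached to the probes (defaults to the
#'   file name without extension).
#' @return Tibble `sample_id`, `chromosome`, `position`, `log2_ratio`.
#' @export
read_probe_track <- function(path, sample_id = NULL) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    pos = readr::col_double(),
    log2 = readr::col_double()
  ))
  tibble(
    sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)),
    chromosome = x$chrom,
    position = x$pos,
    log2_ratio = x$log2
  ) |>
    arrange(chromosome, position)
}

#' @rdname read_probe_track
#' @param track Probe tibble (single sample).
#' @export
write_probe_track <- function(track, path) {
  check_track(track)
  readr::write_tsv(
    tibble(chrom = track$chromosome, pos = track$position, log2 = track$log2_ratio),
    path
  )
  invisible(path)
}

#' Read gene models from a GFF3 annotation
#'
#' Keeps records of the requested feature type and returns the 1-based
#' inclusive gene intervals used for overlap accounting.
#'
#' @param path GFF3 file.
#' @param feature_type Feature to keep (default `"gene"`).
#' @return Tibble `gene_id`, `chromosome`, `start_bp`, `end_bp`.
#' @export
read_gene_models <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  if (!length(gr)) {
    return(tibble(gene_id = character(), chromosome = character(),
                  start_bp = numeric(), end_bp = numeric()))
  }
  tibble(
    gene_id = as.character(gr$ID),
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start_bp = GenomicRanges::start(gr),
    end_bp = GenomicRanges::end(gr)
  )
}

#' Write SV calls as BED
#'
#' BED5: chrom, 0-based start, end, `sample|class` name, score = mean log2
#' ratio x 1000 rounded. Internal coordinates are 1-based inclusive; only the
#' BED start is shifted.
#'
#' @param calls Call tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  bed <- tibble(
    chrom = calls$chromosome,
    start = calls$start_bp - 1,
    end = calls$end_bp,
    name = paste(calls$sample_id, calls$call_class, sep = "|"),
    score = round(calls$mean_log2 * 1000)
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file of regions
#'
#' @param path BED file (chrom, start, end, optional name).
#' @return Tibble `chromosome`, `start_bp`, `end_bp` (1-based inclusive) and
#'   `name` when present.
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- tibble(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start_bp = GenomicRanges::start(gr),
    end_bp = GenomicRanges::end(gr)
  )
  if (!is.null(gr$name)) out$name <- gr$name
  out
}
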