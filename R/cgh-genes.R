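#' Genes overlapped by copy-number calls
#'
#' A gene counts as duplicated (UpCNV) or deleted (DownCNV) in a sample when
#' its annotated interval overlaps a call span by at least 1 bp; each gene is
#' counted once per sample per class no matter how many calls hit it. Calls
#' flagged as intra-cultivar heterogeneity are excluded.
#'
#' @param calls Call tibble ([classify_segments()], optionally after
#'   [filter_heterogeneity()]).
#' @param genes Gene tibble: `gene_id`, `chromosome`, `start_bp`, `end_bp`
#'   (1-based inclusive), e.g. from [read_gene_models()].
#' @return Tibble `sample_id`, `call_class`, `gene_id`, one row per
#'   (sample, class, gene).
#' @export
genes_overlapping <- function(calls, genes) {
  stopifnot(all(c("gene_id", "chromosome", "start_bp", "end_bp") %in% names(genes)))
  if ("filtered_as_heterogeneity" %in% names(calls)) {
    calls <- filter(calls, !filtered_as_heterogeneity)
  }
  if (nrow(calls) == 0) {
    return(tibble(sample_id = character(), call_class = character(),
                  gene_id = character()))
  }
  bad <- setdiff(unique(calls$chromosome), unique(genes$chromosome))
  if (length(bad)) {
    abort(paste0(
      "call chromosome(s) absent from the gene annotation: ",
      paste(bad, collapse = ", ")
    ))
  }
  gr_calls <- GenomicRanges::GRanges(
    calls$chromosome, IRanges::IRanges(calls$start_bp, calls$end_bp)
  )
  gr_genes <- GenomicRanges::GRanges(
    genes$chromosome, IRanges::IRanges(genes$start_bp, genes$end_bp)
  )
  hits <- GenomicRanges::findOverlaps(gr_calls, gr_genes)
  tibble(
    sample_id = calls$sample_id[S4Vectors::queryHits(hits)],
    call_class = calls$call_class[S4Vectors::queryHits(hits)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)]
  ) |>
    distinct()
}

#' Summarize structural variation for a genotypic class
#'
#' Produces the per-class summary used to compare standing, mutagenized and
#' transformation-induced variation: for UpCNV and DownCNV separately, the
#' number of unique genes affected in the whole class, the max/median/min
#' per-genotype gene counts, the number of genic segments (calls overlapping
#' at least one gene), and mean/median segment size in bp. Only calls
#' overlapping genes enter the size summaries; when a direction has no genic
#' segment its sizes are reported as `NA`, not zero.
#'
#' @param calls Call tibble for the class (heterogeneity-flagged calls are
#'   excluded).
#' @param genes Gene model tibble.
#' @param class_label Label for the genotypic class (e.g. `"Transgenic"`).
#' @return Tibble with one row per direction (`"UpCNV"`, `"DownCNV"`).
#' @export
summarize_class <- function(calls, genes, class_label) {
  if ("filtered_as_heterogeneity" %in% names(calls)) {
    calls <- filter(calls, !filtered_as_heterogeneity)
  }
  samples <- unique(calls$sample_id)
  hits <- genes_overlapping(calls, genes)
  per_dir <- lapply(c("UpCNV", "DownCNV"), function(dir) {
    h <- filter(hits, call_class == dir)
    per_sample <- vapply(
      samples,
      function(s) length(unique(h$gene_id[h$sample_id == s])),
      integer(1)
    )
    dcalls <- filter(calls, call_class == dir)
    # a genic segment is a call overlapping >= 1 gene
    if (nrow(dcalls)) {
      gr_calls <- GenomicRanges::GRanges(
        dcalls$chromosome, IRanges::IRanges(dcalls$start_bp, dcalls$end_bp)
      )
      gr_genes <- GenomicRanges::GRanges(
        genes$chromosome, IRanges::IRanges(genes$start_bp, genes$end_bp)
      )
      genic <- dcalls[GenomicRanges::countOverlaps(gr_calls, gr_genes) > 0, ]
    } else {
      genic <- dcalls
    }
    sizes <- genic$end_bp - genic$start_bp + 1
    tibble(
      class_label = class_label,
      direction = dir,
      total_genes = length(unique(h$gene_id)),
      max_genes = if (length(per_sample)) max(per_sample) else 0L,
      median_genes = if (length(per_sample)) median(per_sample) else 0L,
      min_genes = if (length(per_sample)) min(per_sample) else 0L,
      n_genic_segments = nrow(genic),
      mean_size_bp = if (length(sizes)) mean(sizes) else NA_real_,
      median_size_bp = if (length(sizes)) median(sizes) else NA_real_
    )
  })
  bind_rows(per_dir)
}
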