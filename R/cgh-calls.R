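#' Copy-number call thresholds
#'
#' Log2-ratio thresholds separating significant copy gains and losses from
#' noise. The defaults were calibrated empirically on hemizygous deletions
#' and duplications in previously characterized fast-neutron plants: segments
#' whose mean exceeds `upper` are UpCNV (duplication-like), segments below
#' `lower` are DownCNV (hemizygous or homozygous deletion-like). Comparison is
#' strict: a mean exactly equal to a threshold is not a call. `min_probes_call`
#' (default 3) guards against single-probe noise.
#'
#' @param upper Upper log2-ratio threshold. Default 0.3484.
#' @param lower Lower log2-ratio threshold. Default -0.5257.
#' @param min_probes_call Minimum probes for a callable segment. Default 3.
#' @return A list of class `sv_thresholds`.
#' @export
sv_thresholds <- function(upper = 0.3484, lower = -0.5257, min_probes_call = 3L) {
  stopifnot(lower < 0, upper > 0, min_probes_call >= 1)
  structure(
    list(upper = upper, lower = lower, min_probes_call = as.integer(min_probes_call)),
    class = "sv_thresholds"
  )
}

#' Classify segments into UpCNV / DownCNV calls
#'
#' @param segments Segment tibble from [segment_track()] (may hold several
#'   samples bound together).
#' @param thresholds An [sv_thresholds()] object.
#' @return Tibble of calls: segment columns plus `call_class`
#'   (`"UpCNV"`/`"DownCNV"`) and `filtered_as_heterogeneity = FALSE`.
#'   Segments inside the open interval (lower, upper), or supported by fewer
#'   than `min_probes_call` probes, are dropped.
#' @export
classify_segments <- function(segments, thresholds = sv_thresholds()) {
  stopifnot(inherits(thresholds, "sv_thresholds"))
  segments |>
    filter(
      n_probes >= thresholds$min_probes_call,
      mean_log2 > thresholds$upper | mean_log2 < thresholds$lower
    ) |>
    mutate(
      call_class = ifelse(mean_log2 > thresholds$upper, "UpCNV", "DownCNV"),
      filtered_as_heterogeneity = FALSE
    )
}

#' List sub-threshold segments for visual review
#'
#' Mechanizes the manual review step in which segments missed by the strict
#' thresholds are inspected by eye: returns segments that fail the strict
#' call but would pass thresholds relaxed by `relax_factor`, sorted by
#' |mean log2| descending. Never alters the call set.
#'
#' @param segments Segment tibble.
#' @param thresholds An [sv_thresholds()] object.
#' @param relax_factor Multiplier in (0, 1] applied to both thresholds.
#' @return Tibble of candidate segments for human review.
#' @export
candidate_review <- function(segments, thresholds = sv_thresholds(),
                             relax_factor = 0.8) {
  stopifnot(relax_factor > 0, relax_factor <= 1)
  segments |>
    filter(
      n_probes >= thresholds$min_probes_call,
      mean_log2 <= thresholds$upper, mean_log2 >= thresholds$lower,
      mean_log2 > thresholds$upper * relax_factor |
        mean_log2 < thresholds$lower * relax_factor
    ) |>
    arrange(desc(abs(mean_log2)))
}

#' Flag intra-cultivar heterogeneity shared across plants
#'
#' Residual variation segregating within a cultivar shows up as significant
#' segments at the same location in multiple plants hybridized against the
#' same reference, and must not be attributed to mutagenesis or
#' transformation. A call is flagged when at least `min_recurrence` samples
#' carry a same-class call at the same location. In `"exact"` mode (the
#' default, matching a shared probe grid) the location match is identical
#' chromosome, start and end; `"reciprocal"` mode instead requires pairwise
#' reciprocal overlap of at least `reciprocal_overlap`, for designs where
#' replicate arrays do not reproduce boundaries perfectly. Flagged calls are
#' retained in the tibble (for audit) but must be excluded from downstream
#' counts; [genes_overlapping()] and [summarize_class()] do this themselves.
#' Idempotent.
#'
#' @param calls Call tibble for all samples of one background group.
#' @param mode `"exact"` or `"reciprocal"`.
#' @param min_recurrence Minimum number of samples sharing the location.
#' @param reciprocal_overlap Reciprocal-overlap fraction for mode
#'   `"reciprocal"`.
#' @return `calls` with `filtered_as_heterogeneity` set.
#' @export
filter_heterogeneity <- function(calls, mode = c("exact", "reciprocal"),
                                 min_recurrence = 2L, reciprocal_overlap = 1.0) {
  mode <- match.arg(mode)
  if (nrow(calls) == 0) return(calls)
  if (length(unique(calls$sample_id)) < 2) {
    warn("heterogeneity filtering needs >= 2 samples sharing a background; no calls flagged")
    calls$filtered_as_heterogeneity <- FALSE
    return(calls)
  }
  if (mode == "exact") {
    calls |>
      group_by(chromosome, start_bp, end_bp, call_class) |>
      mutate(filtered_as_heterogeneity =
               dplyr::n_distinct(sample_id) >= min_recurrence) |>
      ungroup()
  } else {
    flag <- vapply(seq_len(nrow(calls)), function(i) {
      a <- calls[i, ]
      peers <- calls[calls$chromosome == a$chromosome &
                       calls$call_class == a$call_class, ]
      ov_start <- pmax(peers$start_bp, a$start_bp)
      ov_end <- pmin(peers$end_bp, a$end_bp)
      ov <- pmax(0, ov_end - ov_start + 1)
      recip <- ov / pmax(peers$end_bp - peers$start_bp + 1,
                         a$end_bp - a$start_bp + 1)
      length(unique(peers$sample_id[recip >= reciprocal_overlap])) >= min_recurrence
    }, logical(1))
    calls$filtered_as_heterogeneity <- flag
    calls
  }
}
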