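#' Segmentation parameters
#'
#' Parameters for the recursive binary-splitting segmentation of per-probe
#' log2-ratio tracks. The defaults are the calibrated values used for the
#' soybean tiling arrays: a candidate split is accepted only when the absolute
#' difference of segment means is at least `min_segment_difference` **and**
#' exceeds the `acceptance_percentile` quantile of the same statistic computed
#' on `n_permutations` random shufflings of the interval's probe values.
#'
#' @param min_segment_difference Minimum absolute difference between adjacent
#'   segment means (log2 units) for a split to be considered. Default 0.1.
#' @param min_probes_segment Minimum number of probes on each side of an
#'   accepted split. Default 2.
#' @param acceptance_percentile Quantile of the permutation null that the
#'   observed split statistic must exceed. Default 0.99.
#' @param n_permutations Number of random shufflings per tested split.
#'   Default 10.
#' @param seed Run seed; the permutation stream is re-seeded per
#'   (sample, chromosome) so results do not depend on evaluation order.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(min_segment_difference = 0.1,
                       min_probes_segment = 2L,
                       acceptance_percentile = 0.99,
                       n_permutations = 10L,
                       seed = 1L) {
  stopifnot(
    acceptance_percentile > 0, acceptance_percentile < 1,
    n_permutations >= 1, min_probes_segment >= 1,
    min_segment_difference >= 0
  )
  structure(
    list(
      min_segment_difference = min_segment_difference,
      min_probes_segment = as.integer(min_probes_segment),
      acceptance_percentile = acceptance_percentile,
      n_permutations = as.integer(n_permutations),
      seed = seed
    ),
    class = "seg_params"
  )
}

#' Median-center a probe track
#'
#' Subtracts the genome-wide median log2 ratio from every probe, so a track
#' whose bulk is copy-neutral sits at 0. Idempotent. This is the only
#' normalization applied here; spatial correction and qspline normalization
#' belong to the raw two-channel intensity processing upstream of this
#' package.
#'
#' @param track Tibble with columns `chromosome`, `position`, `log2_ratio`
#'   (and optionally `sample_id`; centering is per sample when present).
#' @return The track with centered `log2_ratio`.
#' @export
center_track <- function(track) {
  check_track(track)
  if ("sample_id" %in% names(track)) {
    track |>
      group_by(sample_id) |>
      mutate(log2_ratio = log2_ratio - median(log2_ratio)) |>
      ungroup()
  } else {
    mutate(track, log2_ratio = log2_ratio - median(log2_ratio))
  }
}

check_track <- function(track) {
  if (!is.data.frame(track) || nrow(track) == 0) {
    abort("`track` must be a non-empty data frame of probes.")
  }
  need <- c("chromosome", "position", "log2_ratio")
  miss <- setdiff(need, names(track))
  if (length(miss)) {
    abort(paste0("`track` is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(track$log2_ratio))) {
    abort("`log2_ratio` must be finite for every probe.")
  }
  invisible(track)
}

#' Segment a probe track into regions of constant copy number
#'
#' Recursive splitting with a two-boundary (circular-style) changepoint
#' scan: within each current interval, candidate sub-intervals are ranked
#' by the size-weighted statistic
#' `|mean(in) - mean(out)| * sqrt(n_in * n_out / n)` (leftmost, then
#' shortest, on ties); a sub-interval anchored at either end is an
#' ordinary binary split, while an interior one isolates an embedded
#' shift its two halves would dilute. The best candidate is accepted iff
#' its raw mean difference is at least `min_segment_difference` and its
#' weighted statistic strictly exceeds the `acceptance_percentile`
#' quantile of the null distribution of the maximal statistic, estimated
#' from `n_permutations` shufflings of the interval's values by a
#' moment-matched Gumbel tail fit (the appropriate extreme-value law for
#' a maximum, resolvable from few permutations); the up-to-three
#' resulting pieces are recursed into. Chromosomes with fewer than `2 * min_probes_segment` probes
#' are returned as a single segment. Segments partition every chromosome's
#' probes exactly once. A segment's genomic span runs from its first to its
#' last probe position; inter-probe gaps are included, so probe spacing limits
#' boundary resolution.
#'
#' @param track Probe tibble (`chromosome`, `position`, `log2_ratio`,
#'   optional `sample_id` -- must be a single sample).
#' @param params A [seg_params()] object.
#' @return Tibble of segments: `chromosome`, `first_probe`, `last_probe`
#'   (1-based indices within the chromosome), `start_bp`, `end_bp`,
#'   `n_probes`, `mean_log2`, plus `sample_id` when present in the input.
#' @export
segment_track <- function(track, params = seg_params()) {
  check_track(track)
  stopifnot(inherits(params, "seg_params"))
  sample_id <- if ("sample_id" %in% names(track)) {
    ids <- unique(track$sample_id)
    if (length(ids) > 1) abort("`segment_track()` takes one sample at a time.")
    ids
  } else {
    NA_character_
  }
  track <- arrange(track, chromosome, position)
  out <- lapply(split(track, track$chromosome), function(ch) {
    if (is.unsorted(ch$position, strictly = TRUE)) {
      abort("probe positions must be strictly increasing within a chromosome")
    }
    segs <- with_seed(
      derive_seed(params$seed, paste(sample_id, ch$chromosome[1])),
      segment_values(ch$log2_ratio, params)
    )
    tibble(
      chromosome = ch$chromosome[1],
      first_probe = segs$first,
      last_probe = segs$last,
      start_bp = ch$position[segs$first],
      end_bp = ch$position[segs$last],
      n_probes = segs$last - segs$first + 1L,
      mean_log2 = segs$mean
    )
  })
  out <- bind_rows(out)
  out$sample_id <- sample_id
  arrange(out, chromosome, start_bp)
}

# Best sub-interval of v by the two-boundary changepoint statistic
# |mean(in) - mean(out)| * sqrt(n_in * n_out / m). Scanning intervals
# rather than half-vs-half cuts lets a short run of shifted probes stand
# out against the permutation null, which a plain binary cut cannot do: a
# contiguous 5-probe shift barely beats shuffled arrangements on any
# half-mean difference. An interval anchored at either end is an ordinary
# binary split. Candidate intervals leave each resulting piece with >=
# minp probes (or empty); `delta` is the raw in/out mean difference,
# gated separately against min_segment_difference. Leftmost start, then
# shortest interval, on ties. Returns list(from, to, stat, delta) or NULL.
best_split <- function(v, minp) {
  m <- length(v)
  if (m < 2L * minp) return(NULL)
  cs <- c(0, cumsum(v))
  total <- cs[m + 1]
  best <- NULL
  for (len in minp:(m - minp)) {
    i <- seq_len(m - len + 1L)
    left <- i - 1L
    right <- m - len - left
    ok <- (left == 0L | left >= minp) & (right == 0L | right >= minp)
    if (!any(ok)) next
    i <- i[ok]
    s_in <- cs[i + len] - cs[i]
    d <- abs(s_in / len - (total - s_in) / (m - len))
    w <- sqrt(len * (m - len) / m)
    k <- which.max(d) # leftmost maximum
    if (is.null(best) || d[k] * w > best$stat) {
      best <- list(from = i[k], to = i[k] + len - 1L,
                   stat = d[k] * w, delta = d[k])
    }
  }
  best
}

# Recursive splitting over a numeric vector; permutation RNG assumed
# already seeded by the caller. Returns first/last indices and means.
segment_values <- function(v, params) {
  minp <- params$min_probes_segment
  bounds <- list()
  recurse <- function(lo, hi) {
    seg <- v[lo:hi]
    sp <- best_split(seg, minp)
    accept <- FALSE
    if (!is.null(sp) && sp$delta >= params$min_segment_difference) {
      null_stats <- vapply(seq_len(params$n_permutations), function(i) {
        best_split(sample(seg), minp)$stat
      }, numeric(1))
      # The permutation maxima follow an extreme-value law; with few
      # permutations the empirical quantile cannot resolve a high
      # acceptance percentile (the observed maximum is exchangeable with
      # them, so it would clear the sample 0.99 quantile ~1 time in 11 on
      # pure noise). A Gumbel tail fitted by moments to the permuted
      # maxima gives the percentile its intended meaning.
      beta <- sd(null_stats) * sqrt(6) / pi
      mu <- mean(null_stats) - 0.5772156649 * beta
      thr <- mu - beta * log(-log(params$acceptance_percentile))
      accept <- sp$stat > thr
    }
    if (accept) {
      if (sp$from > 1L) recurse(lo, lo + sp$from - 2L)
      recurse(lo + sp$from - 1L, lo + sp$to - 1L)
      if (sp$to < length(seg)) recurse(lo + sp$to, hi)
    } else {
      bounds[[length(bounds) + 1L]] <<- c(lo, hi)
    }
  }
  recurse(1L, length(v))
  b <- do.call(rbind, bounds)
  b <- b[order(b[, 1]), , drop = FALSE]
  list(
    first = as.integer(b[, 1]),
    last = as.integer(b[, 2]),
    mean = apply(b, 1, function(x) mean(v[x[1]:x[2]]))
  )
}
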