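# Independent oracles and small fixture builders used across tests.

# Exhaustive single-changepoint scan: the cut index c in [minp, m - minp]
# maximizing |mean(v[1:c]) - mean(v[(c+1):m])| * sqrt(c * (m - c) / m),
# computed by direct enumeration with mean() (no shared code with the
# segmentation path). The size weighting is part of the definition: the
# unweighted scan is edge-biased -- a 2-probe tail whose noise overshoots
# the shift outscores the true changepoint -- and so does not locate the
# planted boundary.
oracle_single_changepoint <- function(v, minp = 2L) {
  m <- length(v)
  cuts <- minp:(m - minp)
  stats <- vapply(cuts, function(c) {
    abs(mean(v[1:c]) - mean(v[(c + 1):m])) * sqrt(c * (m - c) / m)
  }, numeric(1))
  cuts[which.max(stats)]
}

# Brute-force junction decomposition: enumerate every (retained-left length
# t, retained-right start r) with both blocks >= min_match and exactly
# found in their flanks; among valid pairs minimize the filler length.
# Returns list(mh, filler, breakpoint_left, breakpoint_right) or NULL.
oracle_junction <- function(junction, left_flank, right_flank,
                            left_anchor, right_anchor, min_match = 15L) {
  n <- nchar(junction)
  valid <- list()
  for (t in min_match:(n - min_match)) {
    if (!grepl(substr(junction, 1, t), left_flank, fixed = TRUE)) next
    for (r in (t + 1):(n - min_match + 1)) {
      if (grepl(substr(junction, r, n), right_flank, fixed = TRUE)) {
        valid[[length(valid) + 1L]] <- c(t = t, r = r)
        break # larger r only increases filler for this t
      }
    }
  }
  if (!length(valid)) return(NULL)
  v <- do.call(rbind, valid)
  fill_len <- v[, "r"] - v[, "t"] - 1L
  best <- v[fill_len == min(fill_len), , drop = FALSE]
  t_min <- min(best[, "t"])
  r_min <- best[best[, "t"] == t_min, "r"][1]
  # rightmost occurrence of the retained-left block in the left flank
  occs <- gregexpr(substr(junction, 1, t_min), left_flank, fixed = TRUE)[[1]]
  left_end_idx <- max(occs) + t_min - 1L
  occ_r <- gregexpr(substr(junction, r_min, n), right_flank, fixed = TRUE)[[1]]
  list(
    mh = nrow(best) - 1L,
    filler = substr(junction, t_min + 1L, r_min - 1L),
    breakpoint_left = left_anchor - nchar(left_flank) + left_end_idx,
    breakpoint_right = right_anchor + min(occ_r) - 1L
  )
}

# single-chromosome probe track with given log2 values at unit kb spacing
toy_track <- function(values, chromosome = "Gm01", sample_id = "S1",
                      spacing = 1000) {
  tibble::tibble(
    sample_id = sample_id,
    chromosome = chromosome,
    position = seq_along(values) * spacing,
    log2_ratio = values
  )
}

# segment tibble row for classification tests
toy_segment <- function(mean_log2, n_probes = 5L, chromosome = "Gm01",
                        sample_id = "S1", start_bp = 1000) {
  tibble::tibble(
    chromosome = chromosome,
    first_probe = 1L, last_probe = n_probes,
    start_bp = start_bp, end_bp = start_bp + (n_probes - 1L) * 1000,
    n_probes = n_probes, mean_log2 = mean_log2, sample_id = sample_id
  )
}

# long genotype tibble for one site across samples
toy_site <- function(position, gt, depth, ref = "A", alt = "G",
                     chromosome = "Gm01") {
  tibble::tibble(
    chromosome = chromosome, position = position,
    ref_base = ref, alt_base = alt,
    sample_id = names(gt), gt_class = unname(gt),
    depth = unname(depth[names(gt)])
  )
}

# planted-event recovery: match calls to truth rows by overlap + class.
# Overlapping same-class calls are taken as a unit (an event recovered as
# abutting calls of one class is recovered); the probe boundary error is
# measured on their union's outer bounds.
match_events <- function(calls, truth) {
  cls_map <- c(dup = "UpCNV", del = "DownCNV")
  purrr::pmap_dfr(truth, function(...) {
    e <- list(...)
    hit <- calls[calls$sample_id == e$sample_id &
                   calls$chromosome == e$chromosome &
                   calls$call_class == cls_map[[e$class]] &
                   calls$start_bp <= e$end_bp & calls$end_bp >= e$start_bp, ]
    if (nrow(hit) == 0) {
      tibble::tibble(found = FALSE, boundary_err = NA_integer_,
                     class_ok = NA)
    } else {
      err <- max(abs(min(hit$first_probe) - e$first_probe),
                 abs(max(hit$last_probe) - e$last_probe))
      tibble::tibble(found = TRUE, boundary_err = err, class_ok = TRUE)
    }
  })
}
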