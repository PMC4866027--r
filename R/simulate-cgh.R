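#' Simulate per-probe CGH log2-ratio tracks with known ground truth
#'
#' Generates evenly spaced probes per chromosome whose log2 ratios are
#' Gaussian noise around 0, with planted deletion-like / duplication-like
#' mean shifts. Two event layers are supported: `events` private to
#' individual samples (as induced by mutagenesis or transformation) and
#' `shared_events` realized at identical probe boundaries in every sample
#' (emulating intra-cultivar heterogeneity, the target of
#' [filter_heterogeneity()]). The same seed reproduces the output exactly.
#'
#' @param samples Character vector of sample ids.
#' @param chrom_sizes Tibble `chromosome`, `length_bp`.
#' @param events Tibble of private events: `sample_id`, `chromosome`,
#'   `start_bp`, `end_bp`, `class` (`"dup"`/`"del"`), `mean_shift` (log2
#'   units). May be empty.
#' @param shared_events Same columns minus `sample_id`; planted identically
#'   in every sample. May be `NULL`.
#' @param noise_sd Per-probe Gaussian noise sd (log2 units), >= 0.
#' @param probe_spacing_bp Distance between consecutive probe positions.
#' @param seed Seed for reproducibility.
#' @param dir Optional directory: when given, per-sample probe-track TSVs
#'   and a `truth.tsv` manifest are written there.
#' @return List with `tracks` (long probe tibble over all samples) and
#'   `truth` (event manifest: `sample_id`, `chromosome`, `start_bp`,
#'   `end_bp`, `class`, `mean_shift`, `shared`, `first_probe`,
#'   `last_probe`).
#' @export
simulate_cgh <- function(samples, chrom_sizes, events,
                         shared_events = NULL, noise_sd = 0.15,
                         probe_spacing_bp = 1000L, seed = 1L, dir = NULL) {
  stopifnot(noise_sd >= 0, probe_spacing_bp >= 1)
  events <- as_tibble(events)
  if (!is.null(shared_events) && nrow(shared_events) > 0) {
    shared_long <- tidyr::expand_grid(sample_id = samples,
                                      as_tibble(shared_events))
    shared_long$shared <- TRUE
  } else {
    shared_long <- NULL
  }
  if (nrow(events) > 0) events$shared <- FALSE
  all_events <- bind_rows(events, shared_long)

  probe_pos <- lapply(seq_len(nrow(chrom_sizes)), function(i) {
    seq(probe_spacing_bp, chrom_sizes$length_bp[i], by = probe_spacing_bp)
  })
  names(probe_pos) <- chrom_sizes$chromosome

  # validate: every event spans >= 3 probes; events disjoint within sample
  if (nrow(all_events) > 0) {
    for (i in seq_len(nrow(all_events))) {
      e <- all_events[i, ]
      np <- sum(probe_pos[[e$chromosome]] >= e$start_bp &
                  probe_pos[[e$chromosome]] <= e$end_bp)
      if (np < 3) {
        abort(paste0("event ", e$chromosome, ":", e$start_bp, "-", e$end_bp,
                     " spans ", np, " probes; events must span >= 3"))
      }
    }
    ov <- all_events |>
      group_by(sample_id, chromosome) |>
      arrange(start_bp, .by_group = TRUE) |>
      summarise(bad = any(start_bp[-1] <= head(end_bp, -1)), .groups = "drop")
    if (any(ov$bad)) abort("planted events overlap within a sample")
  }

  tracks <- lapply(samples, function(s) {
    per_chrom <- lapply(chrom_sizes$chromosome, function(ch) {
      pos <- probe_pos[[ch]]
      lr <- with_seed(derive_seed(seed, paste(s, ch)),
                      rnorm(length(pos), 0, noise_sd))
      ev <- all_events[all_events$sample_id == s & all_events$chromosome == ch, ]
      if (nrow(ev)) {
        for (i in seq_len(nrow(ev))) {
          inside <- pos >= ev$start_bp[i] & pos <= ev$end_bp[i]
          lr[inside] <- lr[inside] + ev$mean_shift[i]
        }
      }
      tibble(sample_id = s, chromosome = ch, position = pos, log2_ratio = lr)
    })
    bind_rows(per_chrom)
  })
  tracks <- bind_rows(tracks)

  truth <- if (nrow(all_events) > 0) {
    all_events |>
      mutate(
        first_probe = purrr::map2_int(chromosome, start_bp, function(ch, sb) {
          which(probe_pos[[ch]] >= sb)[1]
        }),
        last_probe = purrr::map2_int(chromosome, end_bp, function(ch, eb) {
          max(which(probe_pos[[ch]] <= eb))
        })
      ) |>
      arrange(sample_id, chromosome, start_bp)
  } else {
    tibble(sample_id = character(), chromosome = character(),
           start_bp = numeric(), end_bp = numeric(), class = character(),
           mean_shift = numeric(), shared = logical(),
           first_probe = integer(), last_probe = integer())
  }

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (s in samples) {
      write_probe_track(tracks[tracks$sample_id == s, ],
                        file.path(dir, paste0(s, ".track.tsv")))
    }
    readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  }
  list(tracks = tracks, truth = truth)
}
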