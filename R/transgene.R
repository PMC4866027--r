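#' Cluster orphan host alignments into T-DNA insertion calls
#'
#' Orphan ends aligned to the host genome mark the integration
#' neighborhood: reads on the forward strand approach the insertion from
#' the left flank, reverse-strand reads from the right flank. Orphans of
#' one flank within `2 * insert_size_mean` of each other on one chromosome
#' form a flank cluster; a call pairs a left-flank cluster with the
#' nearest compatible right-flank cluster (up to `max_pair_gap` bp away,
#' since an insertion-adjacent deletion widens the separation), each
#' supported by at least `min_support` pairs with mapping quality >=
#' `min_mapq`. The reported coordinate is the innermost host base on the
#' left-border side: the flank whose mates sit nearest the construct start
#' faces the left border, which also fixes the orientation (`"+"` when the
#' left flank faces LB, i.e. the construct runs LB->RB on the host forward
#' strand).
#'
#' @param orphan_host_aln Tibble of orphan host alignments: `read_id`,
#'   `chromosome`, `pos`, `strand`, `mapq`, `read_len`, and mate construct
#'   columns `mate_pos`, `mate_strand` from [extract_orphans()].
#' @param insert_size_mean Library insert-size mean (bp).
#' @param min_support Minimum supporting pairs per flank. Default 3.
#' @param max_pair_gap Maximum separation between paired flank clusters.
#'   Default 20000.
#' @param min_mapq Minimum host mapping quality. Default 20.
#' @return Tibble of insertion calls: `chromosome`,
#'   `lb_adjacent_coordinate`, `orientation`, `n_supporting_pairs_left`,
#'   `n_supporting_pairs_right`, `filtered_homologous`, `refined`, plus a
#'   `support` list-column holding each call's orphan rows.
#' @export
cluster_insertions <- function(orphan_host_aln, insert_size_mean,
                               min_support = 3L, min_mapq = 20L,
                               max_pair_gap = 20000L) {
  aln <- orphan_host_aln |>
    filter(aligned, mapq >= min_mapq) |>
    arrange(chromosome, pos)
  empty <- tibble(
    chromosome = character(), lb_adjacent_coordinate = numeric(),
    orientation = character(), n_supporting_pairs_left = integer(),
    n_supporting_pairs_right = integer(), filtered_homologous = logical(),
    refined = logical(), support = list()
  )
  if (nrow(aln) == 0) return(empty)
  # cluster each flank separately: forward-strand orphans approach the
  # insertion from the left, reverse-strand from the right; an
  # insertion-adjacent deletion can separate the two flanks by more than
  # the insert size, so flanks are paired afterwards across a wider gap
  aln <- aln |>
    group_by(chromosome, strand) |>
    mutate(cluster = cumsum(c(1, diff(pos) > 2 * insert_size_mean))) |>
    ungroup()
  flanks <- aln |>
    group_by(chromosome, strand, cluster) |>
    summarise(
      n = dplyr::n(),
      inner = if (strand[1] == "+") max(pos + read_len - 1) else min(pos),
      mate_mean = mean(mate_pos),
      rows = list(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    ) |>
    filter(n >= min_support)
  calls <- list()
  for (ch in unique(flanks$chromosome)) {
    lefts <- flanks[flanks$chromosome == ch & flanks$strand == "+", ]
    rights <- flanks[flanks$chromosome == ch & flanks$strand == "-", ]
    for (i in seq_len(nrow(lefts))) {
      if (nrow(rights) == 0) break
      gap <- rights$inner - lefts$inner[i]
      ok <- gap > -insert_size_mean & gap < max_pair_gap
      if (!any(ok)) next
      j <- which(ok)[which.min(abs(gap[ok]))]
      orientation <- if (lefts$mate_mean[i] <= rights$mate_mean[j]) "+" else "-"
      lb <- if (orientation == "+") lefts$inner[i] else rights$inner[j]
      calls[[length(calls) + 1L]] <- tibble(
        chromosome = ch,
        lb_adjacent_coordinate = lb,
        orientation = orientation,
        n_supporting_pairs_left = lefts$n[i],
        n_supporting_pairs_right = rights$n[j],
        filtered_homologous = FALSE,
        refined = FALSE,
        support = list(bind_rows(lefts$rows[[i]], rights$rows[[j]]))
      )
      rights <- rights[-j, ]
    }
  }
  if (length(calls) == 0) empty else bind_rows(calls)
}

#' Flag insertion calls driven by transgene-genome homology
#'
#' Construct components with genomic paralogs (promoters, RNAi hairpin
#' targets) seed spurious integration loci: pairs whose construct end lies
#' in such an element find "orphan" homes at the paralog. A call is flagged
#' -- not deleted, preserving auditability -- when more than half of its
#' supporting mates align within a listed homologous element *and* its
#' coordinate falls inside a listed paralog region.
#'
#' @param calls Insertion-call tibble from [cluster_insertions()].
#' @param elements Construct element tibble `name`, `start`, `end`.
#' @param homologous_elements Character vector of element names with known
#'   genomic paralogs.
#' @param paralog_regions Tibble `chromosome`, `start_bp`, `end_bp` (e.g.
#'   from [read_regions_bed()]); `NULL` or empty means no flagging.
#' @return `calls` with `filtered_homologous` set.
#' @export
filter_homologous_loci <- function(calls, elements, homologous_elements,
                                   paralog_regions = NULL) {
  if (nrow(calls) == 0 || is.null(paralog_regions) ||
      nrow(paralog_regions) == 0 || length(homologous_elements) == 0) {
    if (nrow(calls)) calls$filtered_homologous <- FALSE
    return(calls)
  }
  hom <- elements[elements$name %in% homologous_elements, ]
  calls$filtered_homologous <- vapply(seq_len(nrow(calls)), function(i) {
    g <- calls$support[[i]]
    in_hom <- vapply(g$mate_pos, function(p) {
      any(p >= hom$start & p <= hom$end)
    }, logical(1))
    in_paralog <- any(
      paralog_regions$chromosome == calls$chromosome[i] &
        calls$lb_adjacent_coordinate[i] >= paralog_regions$start_bp &
        calls$lb_adjacent_coordinate[i] <= paralog_regions$end_bp
    )
    mean(in_hom) > 0.5 && in_paralog
  }, logical(1))
  calls
}

#' Detect a deletion adjacent to a located insertion
#'
#' An insertion-adjacent host deletion leaves two footprints in the host
#' alignments: a read-depth hole (normalized depth below
#' `depth_ratio` x the flanking median over at least `min_gap_bp`
#' consecutive bases, for a homozygous event) and host-host pairs whose
#' apparent insert spacing exceeds `insert_size_mean + 3 *
#' insert_size_sd`. The gap bounds give the deletion span; junction-
#' spanning reads refine it to base precision (see [locate_insertion()]).
#' With flanking depth below 5x the status is `"undetermined"`.
#'
#' @param host_aln Per-end host alignment tibble (`read_id`, `end`,
#'   `aligned`, `pos`, `strand`) for *all* reads, not only orphans.
#' @param call One-row insertion-call tibble.
#' @param insert_size_mean,insert_size_sd Library insert distribution.
#' @param host_length Host chromosome length.
#' @param read_length Read length. Default 100.
#' @param min_gap_bp Minimum deletion size detectable by depth. Default 200.
#' @param depth_ratio Depth fraction defining the hole. Default 0.2.
#' @param search_window_bp How far from the insertion to search. Default
#'   10000.
#' @return Tibble (possibly empty) of local SV calls: `chromosome`,
#'   `start_bp`, `end_bp`, `size_bp`, `evidence` (comma-joined subset of
#'   `coverage_gap`, `pair_spacing`), `status`.
#' @export
detect_local_deletion <- function(host_aln, call, insert_size_mean,
                                  insert_size_sd, host_length,
                                  read_length = 100L, min_gap_bp = 200L,
                                  depth_ratio = 0.2,
                                  search_window_bp = 10000L) {
  empty <- tibble(
    chromosome = character(), start_bp = numeric(), end_bp = numeric(),
    size_bp = numeric(), evidence = character(), status = character()
  )
  aln <- filter(host_aln, aligned)
  if (nrow(aln) == 0) return(empty)
  cov <- coverage_vector(aln$pos, read_length, host_length)
  flank_med <- median(cov)
  if (flank_med < 5) {
    return(tibble(
      chromosome = call$chromosome, start_bp = NA_real_, end_bp = NA_real_,
      size_bp = NA_real_, evidence = "", status = "undetermined"
    ))
  }
  lo <- max(1, call$lb_adjacent_coordinate - search_window_bp)
  hi <- min(host_length, call$lb_adjacent_coordinate + search_window_bp)
  low <- cov < depth_ratio * flank_med
  low[-(lo:hi)] <- FALSE
  runs <- rle_runs(low)
  runs <- runs[runs$length >= min_gap_bp, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)
  # nearest run to the insertion point
  dist <- pmin(abs(runs$start - call$lb_adjacent_coordinate),
               abs(runs$end - call$lb_adjacent_coordinate))
  run <- runs[which.min(dist), ]
  # trim to the interior zero-depth run when one exists: the depth ramp
  # near a junction spans up to a read length of partially covered bases
  zero_idx <- which(cov[run$start:run$end] == 0)
  if (length(zero_idx)) {
    start <- run$start + min(zero_idx) - 1
    end <- run$start + max(zero_idx) - 1
  } else {
    start <- run$start
    end <- run$end
  }
  evidence <- "coverage_gap"
  # discordant pair spacing across the hole
  pairs <- host_pair_spans(aln)
  if (nrow(pairs)) {
    disc <- pairs$span > insert_size_mean + 3 * insert_size_sd &
      pairs$start < start & pairs$end > end
    if (any(disc)) evidence <- paste(evidence, "pair_spacing", sep = ",")
  }
  tibble(
    chromosome = call$chromosome, start_bp = start, end_bp = end,
    size_bp = end - start + 1, evidence = evidence, status = "detected"
  )
}

coverage_vector <- function(pos, read_length, len) {
  delta <- numeric(len + 1)
  starts <- pmax(1, pos)
  ends <- pmin(len, pos + read_length - 1)
  delta_add <- tabulate(starts, nbins = len)
  delta_sub <- tabulate(ends + 1, nbins = len + 1)
  cumsum(delta_add - delta_sub[seq_len(len)])
}

host_pair_spans <- function(aln) {
  w <- aln |>
    select(read_id, end, pos, strand) |>
    tidyr::pivot_wider(names_from = end, values_from = c(pos, strand))
  if (!all(c("pos_1", "pos_2") %in% names(w))) {
    return(tibble(start = numeric(), end = numeric(), span = numeric()))
  }
  w <- w[!is.na(w$pos_1) & !is.na(w$pos_2), ]
  tibble(
    start = pmin(w$pos_1, w$pos_2),
    end = pmax(w$pos_1, w$pos_2),
    span = abs(w$pos_2 - w$pos_1)
  )
}

rle_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values],
             length = r$lengths[r$values])
}

#' Count read pairs spanning a construct element
#'
#' A pair whose two ends align to the construct strictly flanking an
#' internal element, with an apparent insert span too short to have
#' accommodated the element (`< element length + insert_size_mean +
#' 3 * sd`), can only derive from a template in which the element is
#' absent -- evidence that one homologous chromosome carries a transgene
#' copy with that portion excised. The interpretation (hemizygous excision
#' vs re-mobilization) is left to the caller.
#'
#' @param construct_aln Per-end construct alignment tibble
#'   ([match_reads_to_construct()]), with `read_len` when read lengths
#'   vary (default 100).
#' @param element One-row tibble/list with `start`, `end` on the construct.
#' @param insert_size_mean,insert_size_sd Library insert distribution.
#' @param read_length Read length. Default 100.
#' @return Integer count of element-spanning pairs.
#' @export
count_spanning_pairs <- function(construct_aln, element,
                                 insert_size_mean, insert_size_sd,
                                 read_length = 100L) {
  aln <- filter(construct_aln, aligned)
  w <- aln |>
    select(read_id, end, pos) |>
    tidyr::pivot_wider(names_from = end, values_from = pos,
                       names_prefix = "pos_")
  if (!all(c("pos_1", "pos_2") %in% names(w))) return(0L)
  w <- w[!is.na(w$pos_1) & !is.na(w$pos_2), ]
  left <- pmin(w$pos_1, w$pos_2)
  right <- pmax(w$pos_1, w$pos_2)
  span <- right + read_length - left
  el_len <- element$end - element$start + 1
  sum(
    left + read_length - 1 < element$start &
      right > element$end &
      span < el_len + insert_size_mean + 3 * insert_size_sd
  )
}
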