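# Built-in read matcher: exact k-mer seeding + ungapped extension.
# Designed for fixture-scale data; externally produced alignments (SAM
# parsed to the same tibble shape) are accepted equivalently by the
# downstream operations.

# Align `reads` (character vector) against a single target sequence.
# A read is aligned when a shared exact k-mer seed extends (ungapped) to
# >= min_identity over a span covering >= min_cov of the read, on either
# strand. Returns one row per read: pos is the 1-based leftmost target
# coordinate of the (possibly clipped) alignment; mapq is 60 for a unique
# best diagonal, 0 for ties.
align_to_target <- function(reads, target, k = 21L,
                            min_identity = 0.9, min_cov = 0.9) {
  n_reads <- length(reads)
  empty <- tibble(
    read_idx = integer(0), pos = integer(0), strand = character(0),
    mismatches = integer(0), span = integer(0)
  )
  if (n_reads == 0 || nchar(target) < k) {
    return(tibble(read_idx = seq_len(n_reads), aligned = FALSE,
                  pos = NA_integer_, strand = NA_character_,
                  mismatches = NA_integer_, mapq = NA_integer_))
  }
  tlen <- nchar(target)
  kmers <- substring(target, 1:(tlen - k + 1L), k:tlen)
  tr <- charToRaw(target)

  hits_one_strand <- function(qreads, strand) {
    rl <- nchar(qreads)
    max_rl <- max(rl)
    offsets <- unique(pmin(seq(1L, max_rl, by = k - 1L), max_rl - k + 1L))
    cand <- list()
    for (o in offsets) {
      ok <- rl >= o + k - 1L
      seeds <- substring(qreads[ok], o, o + k - 1L)
      hit <- match(seeds, kmers)
      found <- !is.na(hit)
      if (any(found)) {
        cand[[length(cand) + 1L]] <- tibble(
          read_idx = which(ok)[found],
          start = hit[found] - o + 1L
        )
      }
    }
    if (!length(cand)) return(empty)
    cand <- distinct(bind_rows(cand))
    # ungapped comparison along the implied diagonal, clipped at target ends
    rl_c <- rl[cand$read_idx]
    span_start <- pmax(1L, cand$start)
    span_end <- pmin(tlen, cand$start + rl_c - 1L)
    span <- span_end - span_start + 1L
    q_from <- span_start - cand$start + 1L
    mm <- integer(nrow(cand))
    full <- span == rl_c
    if (any(full)) {
      w <- max(rl_c[full])
      # all reads same length in practice; group by length to vectorize
      for (len in unique(rl_c[full])) {
        sel <- which(full & rl_c == len)
        qmat <- matrix(charToRaw(paste(qreads[cand$read_idx[sel]], collapse = "")),
                       ncol = len, byrow = TRUE)
        tmat <- matrix(tr[outer(span_start[sel] - 1L, seq_len(len), "+")],
                       ncol = len)
        mm[sel] <- as.integer(rowSums(qmat != tmat))
      }
    }
    part <- which(!full)
    for (i in part) {
      q <- substr(qreads[cand$read_idx[i]], q_from[i], q_from[i] + span[i] - 1L)
      t <- substr(target, span_start[i], span_end[i])
      mm[i] <- sum(charToRaw(q) != charToRaw(t))
    }
    tibble(
      read_idx = cand$read_idx, pos = span_start, strand = strand,
      mismatches = mm, span = span, read_len = rl_c, diag = cand$start
    )
  }

  fw <- hits_one_strand(reads, "+")
  rv <- hits_one_strand(revcomp(reads), "-")
  all_hits <- bind_rows(fw, rv)
  if (nrow(all_hits)) {
    all_hits <- all_hits |>
      filter(span >= min_cov * read_len,
             (span - mismatches) / span >= min_identity)
  }
  out <- tibble(read_idx = seq_len(n_reads), aligned = FALSE,
                pos = NA_integer_, strand = NA_character_,
                mismatches = NA_integer_, mapq = NA_integer_)
  if (nrow(all_hits)) {
    best <- all_hits |>
      group_by(read_idx) |>
      arrange(mismatches, .by_group = TRUE) |>
      summarise(
        mapq = if (dplyr::n_distinct(
          paste(diag, strand)[mismatches == mismatches[1]]) > 1) 0L else 60L,
        pos = pos[1], strand = strand[1], mismatches = mismatches[1],
        .groups = "drop"
      )
    out$aligned[best$read_idx] <- TRUE
    out$pos[best$read_idx] <- best$pos
    out$strand[best$read_idx] <- best$strand
    out$mismatches[best$read_idx] <- best$mismatches
    out$mapq[best$read_idx] <- best$mapq
  }
  out
}

#' Align paired reads to the construct sequence
#'
#' Flags, for each end of each pair, whether it aligns to the transgene
#' sequence between the left and right borders, using the built-in exact
#' k-mer seed + ungapped extension matcher (a read aligns when it shares a
#' seed and extends to at least `min_identity` over at least `min_cov` of
#' its length, on either strand).
#'
#' @param pairs Tibble `read_id`, `seq1`, `seq2` (e.g. from
#'   [read_fastq_pairs()] or [simulate_insertion_reads()]).
#' @param construct Construct DNA string (LB to RB).
#' @param k Seed length. Default 21.
#' @param min_identity,min_cov Extension acceptance thresholds.
#' @return Tibble with one row per read end: `read_id`, `end` (1/2),
#'   `aligned`, `pos`, `strand`, `mismatches`, `mapq`.
#' @export
match_reads_to_construct <- function(pairs, construct, k = 21L,
                                     min_identity = 0.9, min_cov = 0.9) {
  if (nchar(construct) == 0) abort("empty construct sequence")
  long <- pairs_to_ends(pairs)
  aln <- align_to_target(long$seq, construct, k, min_identity, min_cov)
  bind_cols(select(long, read_id, end), select(aln, -read_idx))
}

pairs_to_ends <- function(pairs) {
  bind_rows(
    tibble(read_id = pairs$read_id, end = 1L, seq = pairs$seq1),
    tibble(read_id = pairs$read_id, end = 2L, seq = pairs$seq2)
  )
}

#' Extract orphaned read ends
#'
#' An orphan is the end of a pair that itself fails to align to the
#' construct while its mate aligns -- the mate anchors the pair to the
#' transgene and the orphan's genomic alignment marks the integration
#' neighborhood. Ends from incomplete pairs are skipped and counted in the
#' `n_unpaired` attribute.
#'
#' @param construct_aln Per-end alignment tibble from
#'   [match_reads_to_construct()].
#' @return Tibble of orphan ends: `read_id`, `end`, plus the mate's
#'   construct `mate_pos` and `mate_strand`.
#' @export
extract_orphans <- function(construct_aln) {
  counts <- table(construct_aln$read_id)
  unpaired <- names(counts)[counts != 2]
  if (length(unpaired)) {
    inform(paste0(length(unpaired), " unpaired read(s) skipped"))
    construct_aln <- filter(construct_aln, !read_id %in% unpaired)
  }
  mates <- construct_aln |>
    mutate(end = 3L - end) |>
    select(read_id, end, mate_aligned = aligned,
           mate_pos = pos, mate_strand = strand)
  out <- construct_aln |>
    left_join(mates, by = c("read_id", "end")) |>
    filter(!aligned, mate_aligned) |>
    select(read_id, end, mate_pos, mate_strand)
  attr(out, "n_unpaired") <- length(unpaired)
  out
}
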