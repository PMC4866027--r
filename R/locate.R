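#' Localize a T-DNA insertion from paired-end reads
#'
#' Runs the full insertion-mapping pipeline on one sample: (1) align both
#' ends of every pair to the construct (LB-RB) sequence; (2) extract
#' orphaned ends (mate construct-aligned, self not) and align them to the
#' host genome; (3) cluster orphans into insertion calls with orientation
#' and left-border-adjacent coordinate; (4) flag homology-driven loci when
#' paralog knowledge is supplied; (5) refine the coordinate to base
#' precision from junction-spanning reads (reads aligning to neither
#' target whose sequence resolves across the host/construct junction);
#' (6) detect insertion-adjacent deletions from read depth and pair
#' spacing, refined by the right-border junction when junction reads
#' exist. Ambiguous junction bases (left-border microhomology) are
#' assigned to the host, so the construct is reported full length.
#'
#' @param pairs Read-pair tibble (`read_id`, `seq1`, `seq2`).
#' @param construct Construct DNA string (LB to RB).
#' @param host Host chromosome DNA string.
#' @param host_name Host chromosome name used in reports.
#' @param insert_size_mean,insert_size_sd Library insert distribution.
#' @param min_support,min_mapq Call thresholds (see
#'   [cluster_insertions()]).
#' @param elements,homologous_elements,paralog_regions Optional homology
#'   filtering inputs (see [filter_homologous_loci()]).
#' @param k Seed length for the built-in matcher.
#' @return An object of class `insertion_analysis`: a list with `calls`
#'   (refined insertion calls), `local_sv` (adjacent deletions),
#'   `construct_aln`, `host_aln`, `orphans`, and the inputs' summary
#'   stats. `tidy()` returns the calls, `glance()` a one-row summary.
#' @export
locate_insertion <- function(pairs, construct, host, host_name = "host1",
                             insert_size_mean = 350, insert_size_sd = 30,
                             min_support = 3L, min_mapq = 20L,
                             elements = NULL, homologous_elements = NULL,
                             paralog_regions = NULL, k = 21L) {
  read_length <- max(nchar(pairs$seq1))
  construct_aln <- match_reads_to_construct(pairs, construct, k)
  orphans <- extract_orphans(construct_aln)

  ends <- pairs_to_ends(pairs)
  orphan_seqs <- ends |>
    dplyr::semi_join(orphans, by = c("read_id", "end"))
  orph_aln <- align_to_target(orphan_seqs$seq, host, k)
  orphan_host <- bind_cols(
    select(orphan_seqs, read_id, end),
    select(orph_aln, -read_idx)
  ) |>
    left_join(orphans, by = c("read_id", "end")) |>
    mutate(chromosome = host_name,
           read_len = nchar(orphan_seqs$seq))

  calls <- cluster_insertions(orphan_host, insert_size_mean,
                              min_support, min_mapq)
  if (!is.null(elements) && !is.null(homologous_elements)) {
    calls <- filter_homologous_loci(calls, elements, homologous_elements,
                                    paralog_regions)
  }

  # host alignments of every end, for depth/spacing and junction hunting
  host_aln_all <- align_to_target(ends$seq, host, k)
  host_aln <- bind_cols(select(ends, read_id, end),
                        select(host_aln_all, -read_idx))

  local_sv <- tibble()
  if (nrow(calls) > 0) {
    unmapped <- ends[!construct_aln$aligned & !host_aln$aligned, ]
    for (i in seq_len(nrow(calls))) {
      ref <- refine_call(calls[i, ], unmapped$seq, construct, host,
                         insert_size_mean, read_length)
      if (!is.null(ref$lb)) {
        calls$lb_adjacent_coordinate[i] <- ref$lb
        calls$refined[i] <- TRUE
      }
      sv <- detect_local_deletion(host_aln, calls[i, ], insert_size_mean,
                                  insert_size_sd, nchar(host), read_length)
      if (nrow(sv) && !is.null(ref$rb_host) && !is.null(ref$lb) &&
          identical(sv$status, "detected")) {
        # exact bounds from the two junction resolutions
        if (calls$orientation[i] == "+") {
          sv$start_bp <- ref$lb + 1
          sv$end_bp <- ref$rb_host - 1
        } else {
          sv$start_bp <- ref$rb_host + 1
          sv$end_bp <- ref$lb - 1
        }
        sv$size_bp <- sv$end_bp - sv$start_bp + 1
        sv$evidence <- paste(sv$evidence, "junction_read", sep = ",")
      }
      local_sv <- bind_rows(local_sv, sv)
    }
  }
  structure(
    list(
      calls = calls, local_sv = local_sv,
      construct_aln = construct_aln, host_aln = host_aln,
      orphans = orphan_host, host_name = host_name,
      n_pairs = nrow(pairs), read_length = read_length,
      insert_size_mean = insert_size_mean, insert_size_sd = insert_size_sd
    ),
    class = "insertion_analysis"
  )
}

# Resolve the LB (and RB) junctions from reads mapping to neither target.
# Returns list(lb = refined LB-adjacent host coordinate or NULL,
#              rb_host = host coordinate of the first/last retained base on
#              the RB side, or NULL).
refine_call <- function(call, unmapped_seqs, construct, host,
                        insert_size_mean, read_length) {
  win <- 2 * insert_size_mean + 2 * read_length
  lb0 <- call$lb_adjacent_coordinate
  ori <- call$orientation
  cwin <- min(nchar(construct), 400L)
  lb_votes <- numeric(0)
  rb_votes <- numeric(0)
  seqs <- unique(c(unmapped_seqs, revcomp(unmapped_seqs)))
  for (s in seqs) {
    if (nchar(s) < 30) next
    if (ori == "+") {
      # LB junction: host(left) | construct start(right)
      lf <- subseq_chr(host, lb0 - win, lb0 + win)
      r <- try_resolve(s, lf, substr(construct, 1, cwin),
                       min(nchar(host), lb0 + win), 1)
      if (!is.null(r)) lb_votes <- c(lb_votes, r$breakpoint_left)
      # RB junction: construct end(left) | host(right)
      rf <- subseq_chr(host, lb0 - win, min(nchar(host), lb0 + 3 * win))
      r2 <- try_resolve(s, substr(construct, nchar(construct) - cwin + 1,
                                  nchar(construct)),
                        rf, nchar(construct),
                        max(1, lb0 - win))
      if (!is.null(r2)) rb_votes <- c(rb_votes, r2$breakpoint_right)
    } else {
      # LB junction: construct(rc) left | host(right)
      rcc <- revcomp(construct)
      rgt <- subseq_chr(host, lb0 - win, lb0 + win)
      r <- try_resolve(s, substr(rcc, nchar(rcc) - cwin + 1, nchar(rcc)),
                       rgt, nchar(construct), max(1, lb0 - win))
      if (!is.null(r)) {
        lb_votes <- c(lb_votes, r$breakpoint_right + r$mh_left_bp)
      }
      # RB junction: host(left) | construct(rc) start
      lf <- subseq_chr(host, max(1, lb0 - 3 * win), lb0 + win)
      r2 <- try_resolve(s, lf, substr(rcc, 1, cwin),
                        min(nchar(host), lb0 + win), 1)
      if (!is.null(r2)) rb_votes <- c(rb_votes, r2$breakpoint_left)
    }
  }
  vote <- function(v) {
    if (!length(v)) return(NULL)
    tab <- table(v)
    as.numeric(names(tab)[which.max(tab)])
  }
  list(lb = vote(lb_votes), rb_host = vote(rb_votes))
}

try_resolve <- function(jx, left_flank, right_flank, left_anchor,
                        right_anchor) {
  if (nchar(jx) < 20) return(NULL)
  r <- resolve_junction(jx, left_flank, right_flank, left_anchor,
                        right_anchor, event_type = "insertion_junction")
  if (identical(r$status, "resolved")) r else NULL
}

#' @export
print.insertion_analysis <- function(x, ...) {
  cat("T-DNA insertion analysis (", x$n_pairs, " read pairs)\n", sep = "")
  if (nrow(x$calls) == 0) {
    cat("No insertion call met the support thresholds.\n")
  } else {
    for (i in seq_len(nrow(x$calls))) {
      c_ <- x$calls[i, ]
      cat(sprintf(
        "  %s:%s (%s)  support L=%d R=%d%s%s\n",
        c_$chromosome, format(c_$lb_adjacent_coordinate, big.mark = ","),
        c_$orientation, c_$n_supporting_pairs_left,
        c_$n_supporting_pairs_right,
        if (c_$refined) "  [junction-refined]" else "",
        if (c_$filtered_homologous) "  [homology-flagged]" else ""
      ))
    }
  }
  if (nrow(x$local_sv)) {
    cat(sprintf("  adjacent SV: %s bp deletion (%s)\n",
                format(x$local_sv$size_bp, big.mark = ","),
                x$local_sv$evidence))
  }
  invisible(x)
}
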