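#' Microhomology length between two sequence ends
#'
#' Length of the longest shared suffix: the largest `k <= k_max` such that
#' the last `k` bases of `seq_a_end` equal the last `k` bases of
#' `seq_b_ref_upstream`. At a repair junction this measures the identical
#' tract shared by the retained sequence and the reference immediately
#' upstream of the resumption point -- the signature of
#' microhomology-mediated end joining. Returns 0 when the final bases
#' already differ.
#'
#' @param seq_a_end,seq_b_ref_upstream DNA strings, each at least `k_max`
#'   long.
#' @param k_max Maximum homology length considered. Default 25.
#' @return Integer homology length.
#' @export
microhomology_length <- function(seq_a_end, seq_b_ref_upstream, k_max = 25L) {
  stopifnot(nchar(seq_a_end) >= k_max, nchar(seq_b_ref_upstream) >= k_max)
  a <- substring(seq_a_end, nchar(seq_a_end) - k_max + 1)
  b <- substring(seq_b_ref_upstream, nchar(seq_b_ref_upstream) - k_max + 1)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  k <- 0L
  for (i in seq_len(k_max)) {
    if (av[k_max - i + 1] != bv[k_max - i + 1]) break
    k <- i
  }
  k
}

#' Resolve a breakpoint junction against its reference flanks
#'
#' Given the sequence across a repair junction (from junction-spanning reads
#' or a Sanger product) and the two reference flanks it joins, finds the
#' maximal exact prefix match into the left flank and the maximal exact
#' suffix match into the right flank. Bases between the two matched blocks
#' are filler (junction-inserted sequence matching neither flank
#' continuation). When the blocks overlap, the junction point is ambiguous
#' within the overlap: the overlap length is the microhomology (the same
#' tract is visible at both ends of the event, so it is reported for both
#' sides) and breakpoints are reported at the leftmost consistent position.
#' Matching is exact -- junction consensus or Sanger sequence is assumed
#' error-free -- and each flank must be matched over at least `min_match`
#' bases or the junction is returned with status `"unresolved"`.
#'
#' @param junction_seq Junction sequence (>= 20 bp).
#' @param left_flank Reference sequence containing the left side of the
#'   junction; its *last* base has genomic coordinate `left_anchor`.
#' @param right_flank Reference sequence containing the right side; its
#'   *first* base has genomic coordinate `right_anchor`.
#' @param left_anchor,right_anchor 1-based genomic coordinates anchoring the
#'   flanks.
#' @param event_type `"deletion"`, `"duplication"` or `"insertion_junction"`.
#' @param min_match Minimum exact match per flank. Default 15.
#' @return One-row tibble: `status`, `breakpoint_left` (last retained base
#'   of the left flank), `breakpoint_right` (first retained base of the
#'   right flank), `event_size_bp`, `mh_left_bp`, `mh_right_bp`,
#'   `filler_sequence`.
#' @export
resolve_junction <- function(junction_seq, left_flank, right_flank,
                             left_anchor, right_anchor,
                             event_type = c("deletion", "duplication",
                                            "insertion_junction"),
                             min_match = 15L) {
  event_type <- match.arg(event_type)
  n <- nchar(junction_seq)
  if (n < 20) abort("junction sequence must be at least 20 bp")
  unresolved <- tibble(
    status = "unresolved", breakpoint_left = NA_real_,
    breakpoint_right = NA_real_, event_size_bp = NA_real_,
    mh_left_bp = NA_integer_, mh_right_bp = NA_integer_,
    filler_sequence = NA_character_
  )

  pre <- match_block_forward(junction_seq, left_flank, min_match)
  suf <- match_block_backward(junction_seq, right_flank, min_match)
  if (is.null(pre) || is.null(suf)) return(unresolved)

  p_l <- pre$len                 # junction position where prefix block ends
  p_r <- n - suf$len + 1         # junction position where suffix block starts
  coord_left <- function(flank_idx) left_anchor - nchar(left_flank) + flank_idx
  coord_right <- function(flank_idx) right_anchor + flank_idx - 1

  if (p_r > p_l + 1) {
    filler <- substr(junction_seq, p_l + 1, p_r - 1)
    mh <- 0L
    bp_left <- coord_left(pre$flank_end)
    bp_right <- coord_right(suf$flank_start)
  } else {
    overlap <- p_l - p_r + 1
    filler <- ""
    mh <- as.integer(overlap)
    # leftmost consistent breakpoint: give the overlap to the right flank
    bp_left <- coord_left(pre$flank_end - overlap)
    bp_right <- coord_right(suf$flank_start)
  }
  size <- switch(event_type,
    deletion = bp_right - bp_left - 1,
    duplication = bp_left - bp_right + 1,
    insertion_junction = NA_real_
  )
  tibble(
    status = "resolved",
    breakpoint_left = bp_left,
    breakpoint_right = bp_right,
    event_size_bp = size,
    mh_left_bp = mh,
    mh_right_bp = mh,
    filler_sequence = filler
  )
}

# Maximal prefix of `jx` matching a substring of `flank`. Seeds on the first
# `min_match` bases; among seed occurrences takes the longest forward
# extension (rightmost occurrence on ties, i.e. nearest the flank end).
# Returns list(len, flank_end = flank index of the last matched base).
match_block_forward <- function(jx, flank, min_match) {
  n <- nchar(jx)
  if (n < min_match || nchar(flank) < min_match) return(NULL)
  seed <- substr(jx, 1, min_match)
  occ <- str_locate_all_fixed(flank, seed)
  if (!length(occ)) return(NULL)
  jv <- strsplit(jx, "")[[1]]
  fv <- strsplit(flank, "")[[1]]
  best <- NULL
  for (s in occ) {
    len <- min_match
    while (len < n && s + len <= length(fv) && jv[len + 1] == fv[s + len]) {
      len <- len + 1
    }
    if (is.null(best) || len > best$len ||
        (len == best$len && s > best$start)) {
      best <- list(len = len, start = s)
    }
  }
  list(len = best$len, flank_end = best$start + best$len - 1)
}

# Mirror image: maximal suffix of `jx` matching a substring of `flank`,
# extended backwards; leftmost occurrence on ties.
match_block_backward <- function(jx, flank, min_match) {
  n <- nchar(jx)
  if (n < min_match || nchar(flank) < min_match) return(NULL)
  seed <- substr(jx, n - min_match + 1, n)
  occ <- str_locate_all_fixed(flank, seed)
  if (!length(occ)) return(NULL)
  jv <- strsplit(jx, "")[[1]]
  fv <- strsplit(flank, "")[[1]]
  best <- NULL
  for (s in occ) {
    len <- min_match
    while (len < n && s - 1 >= 1 && jv[n - len] == fv[s - 1]) {
      len <- len + 1
      s <- s - 1
    }
    if (is.null(best) || len > best$len ||
        (len == best$len && s < best$start)) {
      best <- list(len = len, start = s)
    }
  }
  list(len = best$len, flank_start = best$start)
}

# all start positions of fixed pattern `pat` in `x` (overlapping)
str_locate_all_fixed <- function(x, pat) {
  out <- integer(0)
  from <- 1L
  repeat {
    hit <- regexpr(pat, substring(x, from), fixed = TRUE)
    if (hit == -1) break
    out <- c(out, from + hit - 1L)
    from <- from + hit # advance one past the found start: overlapping hits
  }
  out
}

#' Event size from resolved breakpoints
#'
#' Deletion size is the number of reference bases absent between the
#' retained flanks; duplication size is the duplicated span length. A
#' resolution whose breakpoints imply no missing/duplicated base is rejected
#' as a no-event.
#'
#' @param resolution One-row tibble from [resolve_junction()].
#' @return Event size in bp.
#' @export
size_from_breakpoints <- function(resolution) {
  stopifnot(nrow(resolution) == 1)
  if (!identical(resolution$status, "resolved")) {
    abort("cannot size an unresolved junction")
  }
  size <- resolution$event_size_bp
  if (is.na(size)) abort("insertion junctions have no deletion/duplication size")
  if (size <= 0) abort("breakpoints imply no event (size 0)")
  size
}
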