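#' Sample error-free paired-end reads from a sequence
#'
#' Fragments are placed uniformly; insert sizes are Normal(`insert_size_mean`,
#' `insert_size_sd`) truncated to be larger than twice the read length.
#' Read 1 is the fragment's 5' end on the forward strand, read 2 the reverse
#' complement of its 3' end. No sequencing-error or base-quality model is
#' applied.
#'
#' @param sequence Template DNA string.
#' @param coverage_depth Target mean depth.
#' @param read_length Read length in bp. Default 100.
#' @param insert_size_mean,insert_size_sd Fragment-length distribution.
#' @param seed Seed.
#' @param id_prefix Prefix for read names.
#' @return Tibble `read_id`, `seq1`, `seq2`, `fragment_start`,
#'   `fragment_end` (1-based template coordinates).
#' @export
simulate_read_pairs <- function(sequence, coverage_depth,
                                read_length = 100L,
                                insert_size_mean = 350,
                                insert_size_sd = 30,
                                seed = 1L, id_prefix = "frag") {
  stopifnot(coverage_depth > 0, nchar(sequence) > insert_size_mean)
  L <- nchar(sequence)
  n_frag <- round(coverage_depth * L / (2 * read_length))
  with_seed(derive_seed(seed, paste0("pairs_", id_prefix)), {
    isize <- round(rnorm(n_frag, insert_size_mean, insert_size_sd))
    isize <- pmax(isize, 2L * read_length + 1L)
    isize <- pmin(isize, L)
    fstart <- floor(runif(n_frag, 1, L - isize + 1))
    fend <- fstart + isize - 1
    tibble(
      read_id = sprintf("%s_%06d", id_prefix, seq_len(n_frag)),
      seq1 = substring(sequence, fstart, fstart + read_length - 1),
      seq2 = revcomp(substring(sequence, fend - read_length + 1, fend)),
      fragment_start = fstart,
      fragment_end = fend
    )
  })
}

#' Simulate a T-DNA insertion locus and its paired-end read set
#'
#' Builds a random host chromosome and a random construct (the sequence
#' between the T-DNA left and right borders), integrates the construct at a
#' known site with a known orientation, an insertion-adjacent deletion of
#' host sequence on the right-border side, filler bases at the right-border
#' junction, and an optional microhomology tract at the left-border
#' junction; then samples error-free paired-end reads from the
#' post-insertion allele. By default the insertion is simulated homozygous
#' (all reads from the variant allele); `zygosity = "hemizygous"` mixes
#' reads 50:50 from the variant and reference alleles.
#'
#' Coordinate conventions: `insertion_site` is the 1-based host base
#' adjacent to the left border. For orientation `"+"` the construct runs
#' LB->RB on the host forward strand, the deleted host interval is
#' `[insertion_site + 1, insertion_site + adjacent_deletion_bp]`, and filler
#' sits between the construct right border and the downstream host. For
#' `"-"` the layout is mirrored. The left-border microhomology tract is
#' written so that the host bases continuing past the insertion site also
#' open the construct, making the junction ambiguous by `microhomology_bp`
#' bases; truth records the full-construct convention (ambiguity assigned to
#' the host), which [locate_insertion()] reports.
#'
#' @param host_length_bp Host chromosome length.
#' @param insertion_site Host base adjacent to the left border.
#' @param orientation `"+"` or `"-"`.
#' @param construct_length_bp Length of the LB-RB construct sequence.
#' @param adjacent_deletion_bp Host bases deleted on the right-border side
#'   (0 for none).
#' @param filler Filler bases at the right-border junction (`""` for none).
#' @param microhomology_bp Left-border junction microhomology tract length.
#' @param elements Optional tibble `name`, `start`, `end` of construct
#'   elements (coordinates on the LB->RB sequence); stored on the result.
#' @param coverage_depth,read_length,insert_size_mean,insert_size_sd Read
#'   sampling parameters (see [simulate_read_pairs()]).
#' @param zygosity `"homozygous"` (default) or `"hemizygous"`.
#' @param host_name Chromosome name. Default `"host1"`.
#' @param seed Seed.
#' @param dir Optional directory: writes `host.fa`, `construct.fa`,
#'   `reads_1.fastq`, `reads_2.fastq` and `truth.tsv`.
#' @return List: `host_seq`, `construct_seq`, `variant_seq`, `reads`
#'   (tibble from [simulate_read_pairs()]), `elements`, and `truth` (a
#'   one-row tibble with the planted parameters).
#' @export
simulate_insertion_reads <- function(host_length_bp = 40000L,
                                     insertion_site = 20000L,
                                     orientation = c("+", "-"),
                                     construct_length_bp = 3000L,
                                     adjacent_deletion_bp = 1500L,
                                     filler = "ACGTAC",
                                     microhomology_bp = 5L,
                                     elements = NULL,
                                     coverage_depth = 30,
                                     read_length = 100L,
                                     insert_size_mean = 350,
                                     insert_size_sd = 30,
                                     zygosity = c("homozygous", "hemizygous"),
                                     host_name = "host1",
                                     seed = 1L, dir = NULL) {
  orientation <- match.arg(orientation)
  zygosity <- match.arg(zygosity)
  if (construct_length_bp < read_length) {
    abort("construct must be at least one read length long")
  }
  if (orientation == "+" &&
      insertion_site + adjacent_deletion_bp > host_length_bp) {
    abort("insertion_site + adjacent_deletion_bp exceeds the host length")
  }
  if (orientation == "-" && insertion_site - adjacent_deletion_bp < 1) {
    abort("adjacent deletion extends past the host start")
  }
  stopifnot(coverage_depth > 0, microhomology_bp >= 0)

  if (adjacent_deletion_bp > 0 && adjacent_deletion_bp <= microhomology_bp) {
    abort("adjacent_deletion_bp must be 0 or exceed microhomology_bp")
  }
  host <- with_seed(derive_seed(seed, "host"), random_dna(host_length_bp))
  construct <- with_seed(derive_seed(seed, "construct"),
                         random_dna(construct_length_bp))
  s <- insertion_site
  d <- adjacent_deletion_bp
  m <- microhomology_bp
  # last junction base on the construct/filler side of the RB junction,
  # whose accidental match with the flanking host base would shift the
  # resolved breakpoint by one
  c_last <- substr(construct, nchar(construct), nchar(construct))
  if (orientation == "+") {
    rb_inner <- if (nchar(filler)) substr(filler, nchar(filler), nchar(filler)) else c_last
    if (d > 0) host <- forbid_base_at(host, s + d, rb_inner)
    # LB junction: host[..s] | construct; tract = host bases s+1..s+m open C
    if (m > 0) construct <- splice_str(construct, 1, substr(host, s + 1, s + m))
    # guard: no accidental junction-match extension beyond the planted tract
    construct <- forbid_base_at(construct, m + 1, substr(host, s + m + 1, s + m + 1))
    variant <- paste0(
      substr(host, 1, s), construct, filler,
      substr(host, s + d + 1, nchar(host))
    )
  } else {
    rb_inner <- if (nchar(filler)) substr(filler, 1, 1) else revcomp(c_last)
    if (d > 0) host <- forbid_base_at(host, s - d, rb_inner)
    rc_host_tract <- revcomp(substr(host, s - m, s - 1))
    if (m > 0) construct <- splice_str(construct, 1, rc_host_tract)
    construct <- forbid_base_at(construct, m + 1,
                                revcomp(substr(host, s - m - 1, s - m - 1)))
    variant <- paste0(
      substr(host, 1, s - d - 1), filler, revcomp(construct),
      substr(host, s, nchar(host))
    )
  }
  reads <- if (zygosity == "homozygous") {
    simulate_read_pairs(variant, coverage_depth, read_length,
                        insert_size_mean, insert_size_sd, seed, "var")
  } else {
    bind_rows(
      simulate_read_pairs(variant, coverage_depth / 2, read_length,
                          insert_size_mean, insert_size_sd, seed, "var"),
      simulate_read_pairs(host, coverage_depth / 2, read_length,
                          insert_size_mean, insert_size_sd, seed, "ref")
    )
  }
  truth <- tibble(
    host_name = host_name,
    host_length_bp = host_length_bp,
    insertion_site = insertion_site,
    orientation = orientation,
    construct_length_bp = nchar(construct),
    adjacent_deletion_bp = adjacent_deletion_bp,
    filler_sequence = filler,
    microhomology_bp = m,
    deleted_start = if (orientation == "+") s + 1 else s - d,
    deleted_end = if (orientation == "+") s + d else s - 1,
    coverage_depth = coverage_depth,
    zygosity = zygosity,
    seed = seed
  )
  out <- list(host_seq = host, construct_seq = construct,
              variant_seq = variant, reads = reads,
              elements = elements, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(setNames(host, host_name), file.path(dir, "host.fa"))
    write_fasta(c(construct = construct), file.path(dir, "construct.fa"))
    write_fastq(reads$read_id, reads$seq1, file.path(dir, "reads_1.fastq"))
    write_fastq(reads$read_id, reads$seq2, file.path(dir, "reads_2.fastq"))
    readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  }
  out
}

# overwrite position `at` of `x` so it differs from `base` (deterministic)
forbid_base_at <- function(x, at, base) {
  if (at > nchar(x) || nchar(base) == 0) return(x)
  if (substr(x, at, at) != base) return(x)
  splice_str(x, at, setdiff(BASES, base)[1])
}

write_fasta <- function(named_seqs, path) {
  xs <- Biostrings::DNAStringSet(named_seqs)
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

write_fastq <- function(ids, seqs, path) {
  xs <- Biostrings::DNAStringSet(seqs)
  names(xs) <- ids
  q <- Biostrings::PhredQuality(vapply(nchar(seqs), function(n) {
    paste(rep("I", n), collapse = "")
  }, character(1)))
  xq <- Biostrings::QualityScaledDNAStringSet(xs, q)
  Biostrings::writeQualityScaledXStringSet(xq, path)
  invisible(path)
}

#' Read paired FASTQ files into a read-pair tibble
#'
#' @param path1,path2 FASTQ files for read 1 and read 2.
#' @return Tibble `read_id`, `seq1`, `seq2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  tibble(
    read_id = sub("[/ ].*$", "", names(r1)),
    seq1 = as.character(r1),
    seq2 = as.character(r2)
  )
}

#' Simulate a breakpoint junction with planted microhomology or filler
#'
#' Constructs a deletion on a random reference so that junction resolution
#' recovers the planted values exactly: a microhomology tract of
#' `mh_left_bp` (= `mh_right_bp`) bases is written immediately upstream of
#' both deletion ends, or `filler` bases are inserted at the junction.
#' Under exact matching a filler-free junction exposes a single shared
#' tract, so the two per-side lengths must be equal; and when filler is
#' present the resolvable microhomology is 0 (the truth records the values
#' [resolve_junction()] must return). Guard bases ensure no accidental
#' match extension beyond the planted tract.
#'
#' @param mh_left_bp,mh_right_bp Planted microhomology (must be equal).
#' @param filler Filler sequence (`""` for none).
#' @param flank_len Retained flank length on each side, must exceed
#'   `mh + nchar(filler)`; also used as the reference flank window.
#' @param deletion_bp Deleted reference span. Default 200.
#' @param seed Seed.
#' @return List: `junction_seq`, `left_flank`, `right_flank`,
#'   `left_anchor`, `right_anchor`, and `truth` (one-row tibble with
#'   `breakpoint_left`, `breakpoint_right`, `event_size_bp`, `mh_left_bp`,
#'   `mh_right_bp`, `filler_sequence`).
#' @export
simulate_junction <- function(mh_left_bp = 0L, mh_right_bp = mh_left_bp,
                              filler = "", flank_len = 60L,
                              deletion_bp = 200L, seed = 1L) {
  stopifnot(mh_left_bp >= 0, mh_right_bp >= 0)
  if (mh_left_bp != mh_right_bp) {
    abort(paste(
      "exact-match junctions expose one shared microhomology tract;",
      "mh_left_bp and mh_right_bp must be equal"
    ))
  }
  m <- mh_left_bp
  if (flank_len <= m + nchar(filler)) {
    abort("flank_len must exceed microhomology + filler length")
  }
  if (deletion_bp <= m + 1) abort("deletion_bp must exceed microhomology + 1")
  G <- 2L * flank_len + deletion_bp + 20L
  ref <- with_seed(derive_seed(seed, "junction_ref"), random_dna(G))
  bl <- flank_len + 10L          # last retained base of the left flank
  br <- bl + deletion_bp + 1L    # first retained base of the right flank
  if (m > 0) {
    # one tract: the last m retained left bases recur just before br
    ref <- splice_str(ref, br - m, substr(ref, bl - m + 1, bl))
    # stop backward extension beyond the tract
    ref <- forbid_base_at(ref, br - m - 1, substr(ref, bl - m, bl - m))
  }
  if (nchar(filler) == 0) {
    # stop forward extension across the clean junction
    ref <- forbid_base_at(ref, br, substr(ref, bl + 1, bl + 1))
    if (m == 0) {
      # and backward extension, which for m > 0 is exactly the tract
      ref <- forbid_base_at(ref, br - 1, substr(ref, bl, bl))
    }
  } else {
    f1 <- substr(filler, 1, 1)
    if (f1 == substr(ref, bl + 1, bl + 1)) {
      ref <- forbid_base_at(ref, bl + 1, f1)
    }
    fe <- substr(filler, nchar(filler), nchar(filler))
    if (fe == substr(ref, br - 1, br - 1)) {
      ref <- forbid_base_at(ref, br - 1, fe)
    }
  }
  left_flank <- substr(ref, bl - flank_len + 1, bl + 10L)
  right_flank <- substr(ref, br - 10L, br + flank_len - 1L)
  junction <- paste0(
    substr(ref, bl - flank_len + 1, bl), filler,
    substr(ref, br, br + flank_len - 1L)
  )
  truth <- tibble(
    breakpoint_left = if (m > 0 && nchar(filler) == 0) bl - m else bl,
    breakpoint_right = if (m > 0 && nchar(filler) == 0) br - m else br,
    event_size_bp = deletion_bp,
    mh_left_bp = if (nchar(filler) == 0) m else 0L,
    mh_right_bp = if (nchar(filler) == 0) m else 0L,
    filler_sequence = filler
  )
  list(
    junction_seq = junction,
    left_flank = left_flank,
    right_flank = right_flank,
    left_anchor = bl + 10L,
    right_anchor = br - 10L,
    truth = truth
  )
}
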