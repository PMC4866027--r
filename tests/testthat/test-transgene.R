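# T-DNA insertion mapping: matcher, orphans, clustering, local SV.

test_that("the matcher accepts construct reads on both strands, rejects noise", {
  set.seed(3)
  construct <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  reads <- substring(construct, c(1, 501, 1201), c(100, 600, 1300))
  pairs <- tibble::tibble(read_id = c("a", "b", "c"), seq1 = reads,
                          seq2 = somavar:::revcomp(reads))
  aln <- match_reads_to_construct(pairs, construct)
  expect_true(all(aln$aligned))
  expect_equal(aln$strand[aln$end == 1], rep("+", 3))
  expect_equal(aln$strand[aln$end == 2], rep("-", 3))
  expect_equal(aln$pos[aln$end == 1], c(1L, 501L, 1201L))
  # random reads share no seed
  rand <- tibble::tibble(
    read_id = "r",
    seq1 = paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""),
    seq2 = paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  )
  expect_false(any(match_reads_to_construct(rand, construct)$aligned))
  expect_error(match_reads_to_construct(pairs, ""), "empty construct")
})

test_that("a half-construct half-host chimera fails the identity threshold", {
  set.seed(4)
  construct <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  host <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  chimera <- paste0(substr(host, 1, 50), substr(construct, 1, 50))
  pairs <- tibble::tibble(read_id = "x", seq1 = chimera,
                          seq2 = substr(construct, 101, 200))
  aln <- match_reads_to_construct(pairs, construct)
  expect_false(aln$aligned[aln$end == 1])
  expect_true(aln$aligned[aln$end == 2])
})

test_that("orphan extraction returns ends whose mate alone is aligned", {
  aln <- tibble::tibble(
    read_id = rep(c("p1", "p2", "p3"), each = 2),
    end = rep(1:2, 3),
    aligned = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
    pos = c(10L, NA, 20L, 400L, NA, NA),
    strand = c("+", NA, "+", "-", NA, NA),
    mismatches = 0L, mapq = 60L
  )
  orph <- extract_orphans(aln)
  expect_equal(nrow(orph), 1)
  expect_equal(orph$read_id, "p1")
  expect_equal(orph$end, 2L)
  expect_equal(orph$mate_pos, 10L)
  # unpaired records are skipped with a counter
  lone <- dplyr::bind_rows(aln, tibble::tibble(
    read_id = "p4", end = 1L, aligned = TRUE, pos = 5L, strand = "+",
    mismatches = 0L, mapq = 60L
  ))
  expect_message(orph2 <- extract_orphans(lone), "unpaired")
  expect_equal(attr(orph2, "n_unpaired"), 1L)
})

test_that("clustering requires support on both flanks", {
  mk_orph <- function(n_left, n_right) {
    tibble::tibble(
      read_id = paste0("r", seq_len(n_left + n_right)),
      chromosome = "host1",
      aligned = TRUE,
      pos = c(seq(4500, length.out = n_left, by = 10),
              seq(5400, length.out = n_right, by = 10)),
      strand = c(rep("+", n_left), rep("-", n_right)),
      mapq = 60L, read_len = 100L,
      mate_pos = c(rep(50L, n_left), rep(900L, n_right))
    )
  }
  calls <- cluster_insertions(mk_orph(5, 5), insert_size_mean = 350)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$orientation, "+")
  expect_equal(calls$lb_adjacent_coordinate, 4540 + 99)
  expect_equal(nrow(cluster_insertions(mk_orph(2, 5), 350)), 0)
  expect_equal(nrow(cluster_insertions(mk_orph(5, 0), 350)), 0)
  # mates near the construct end on the left flank flip the orientation
  flipped <- mk_orph(5, 5)
  flipped$mate_pos <- rev(flipped$mate_pos)
  calls2 <- cluster_insertions(flipped, 350)
  expect_equal(calls2$orientation, "-")
  expect_equal(calls2$lb_adjacent_coordinate, 5400)
})

test_that("insertion recovery is exact across orientations on fixtures", {
  for (ori in c("+", "-")) {
    sim <- simulate_insertion_reads(
      host_length_bp = 30000, insertion_site = 15000, orientation = ori,
      construct_length_bp = 2500, adjacent_deletion_bp = 1200,
      filler = "ACGTAC", microhomology_bp = 5, coverage_depth = 30, seed = 13
    )
    ia <- suppressMessages(locate_insertion(
      sim$reads, sim$construct_seq, sim$host_seq,
      insert_size_mean = 350, insert_size_sd = 30
    ))
    calls <- tidy(ia)
    expect_equal(nrow(calls), 1)
    expect_equal(calls$orientation, ori)
    expect_true(calls$refined)
    expect_equal(calls$lb_adjacent_coordinate, 15000)
    expect_equal(ia$local_sv$size_bp, 1200)
    expect_equal(ia$local_sv$start_bp, sim$truth$deleted_start)
    expect_equal(ia$local_sv$end_bp, sim$truth$deleted_end)
    expect_match(ia$local_sv$evidence, "junction_read")
  }
})

test_that("no adjacent deletion is reported when none is planted", {
  sim <- simulate_insertion_reads(
    host_length_bp = 25000, insertion_site = 12000,
    adjacent_deletion_bp = 0, filler = "", microhomology_bp = 0,
    coverage_depth = 25, seed = 19
  )
  ia <- suppressMessages(locate_insertion(sim$reads, sim$construct_seq,
                                          sim$host_seq))
  expect_equal(tidy(ia)$lb_adjacent_coordinate, 12000)
  expect_true(nrow(ia$local_sv) == 0 ||
                all(ia$local_sv$status != "detected"))
})

test_that("homology filtering flags paralog-driven loci only", {
  support <- tibble::tibble(mate_pos = c(10L, 20L, 30L, 800L))
  calls <- tibble::tibble(
    chromosome = "host1", lb_adjacent_coordinate = 5000,
    orientation = "+", n_supporting_pairs_left = 2L,
    n_supporting_pairs_right = 2L, filtered_homologous = FALSE,
    refined = FALSE, support = list(support)
  )
  elements <- tibble::tibble(name = c("GmUbi", "BAR"),
                             start = c(1L, 700L), end = c(120L, 1000L))
  paralogs <- tibble::tibble(chromosome = "host1", start_bp = 4000,
                             end_bp = 6000)
  out <- filter_homologous_loci(calls, elements, "GmUbi", paralogs)
  expect_true(out$filtered_homologous) # 3/4 mates in GmUbi, call in paralog
  # mates mostly in an unlisted element: retained
  out2 <- filter_homologous_loci(calls, elements, "BAR", paralogs)
  expect_false(out2$filtered_homologous)
  # no paralog list: never flagged
  out3 <- filter_homologous_loci(calls, elements, "GmUbi", NULL)
  expect_false(out3$filtered_homologous)
  # call outside the paralog region: retained
  far <- dplyr::mutate(calls, lb_adjacent_coordinate = 9000)
  expect_false(filter_homologous_loci(far, elements, "GmUbi",
                                      paralogs)$filtered_homologous)
})

test_that("spanning pairs appear only when the element is absent from copies", {
  set.seed(6)
  construct <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  element <- list(name = "mPing", start = 1000L, end = 2200L)
  excised <- paste0(substr(construct, 1, 999), substr(construct, 2201, 3000))
  intact_reads <- simulate_read_pairs(construct, 20, seed = 41, id_prefix = "i")
  excised_reads <- simulate_read_pairs(excised, 20, seed = 42, id_prefix = "e")
  aln_intact <- match_reads_to_construct(
    tibble::tibble(read_id = intact_reads$read_id, seq1 = intact_reads$seq1,
                   seq2 = intact_reads$seq2), construct)
  aln_mixed <- match_reads_to_construct(
    tibble::tibble(
      read_id = c(intact_reads$read_id, excised_reads$read_id),
      seq1 = c(intact_reads$seq1, excised_reads$seq1),
      seq2 = c(intact_reads$seq2, excised_reads$seq2)
    ), construct)
  # intact template with a tight insert distribution: no spanning pair
  expect_equal(count_spanning_pairs(aln_intact, element, 350, 30), 0L)
  # hemizygous excision: spanning pairs roughly track the excised coverage
  n <- count_spanning_pairs(aln_mixed, element, 350, 30)
  expect_gt(n, 0)
  # pairs from the excised allele straddling position 1000 with both ends
  # >= ~100 bp clear of the junction
  expect_lt(n, nrow(excised_reads))
})

test_that("deletion detection reports an undetermined status at low depth", {
  aln <- tibble::tibble(
    read_id = paste0("r", 1:8), end = 1L, aligned = TRUE,
    pos = seq(100, 8000, length.out = 8), strand = "+"
  )
  call <- tibble::tibble(chromosome = "host1",
                         lb_adjacent_coordinate = 5000)
  out <- detect_local_deletion(aln, call, 350, 30, host_length = 10000)
  expect_equal(out$status, "undetermined")
})
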