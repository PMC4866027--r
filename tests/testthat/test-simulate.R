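# Synthetic-data generators: determinism, planted ground truth, bookkeeping.

test_that("simulate_cgh plants exact shifts at zero noise and is deterministic", {
  cs <- tibble::tibble(chromosome = "Gm01", length_bp = 60000)
  ev <- tibble::tibble(sample_id = "A", chromosome = "Gm01",
                       start_bp = 20000, end_bp = 30000,
                       class = "del", mean_shift = -1)
  sim <- simulate_cgh("A", cs, ev, noise_sd = 0, seed = 7)
  inside <- sim$tracks$position >= 20000 & sim$tracks$position <= 30000
  expect_true(all(sim$tracks$log2_ratio[inside] == -1))
  expect_true(all(sim$tracks$log2_ratio[!inside] == 0))

  sim2 <- simulate_cgh("A", cs, ev, noise_sd = 0, seed = 7)
  expect_identical(sim, sim2)
  sim3 <- simulate_cgh("A", cs, ev, noise_sd = 0.1, seed = 7)
  sim4 <- simulate_cgh("A", cs, ev, noise_sd = 0.1, seed = 8)
  expect_false(identical(sim3$tracks$log2_ratio, sim4$tracks$log2_ratio))
})

test_that("simulate_cgh truth manifest separates shared and private events", {
  cs <- tibble::tibble(chromosome = "Gm01", length_bp = 100000)
  samples <- paste0("S", 1:4)
  priv <- tibble::tibble(
    sample_id = samples, chromosome = "Gm01",
    start_bp = c(10000, 30000, 50000, 70000),
    end_bp = c(15000, 35000, 55000, 75000),
    class = "del", mean_shift = -1
  )
  shr <- tibble::tibble(chromosome = "Gm01", start_bp = 90000,
                        end_bp = 95000, class = "del", mean_shift = -1)
  sim <- simulate_cgh(samples, cs, priv, shared_events = shr,
                      noise_sd = 0, seed = 1)
  expect_equal(sum(!sim$truth$shared), 4)
  # one shared event realized in each of the four samples, same boundaries
  shared_rows <- sim$truth[sim$truth$shared, ]
  expect_equal(nrow(shared_rows), 4)
  expect_equal(dplyr::n_distinct(shared_rows$first_probe), 1)
  expect_equal(dplyr::n_distinct(shared_rows$last_probe), 1)
})

test_that("simulate_cgh rejects events spanning fewer than 3 probes", {
  cs <- tibble::tibble(chromosome = "Gm01", length_bp = 60000)
  tiny <- tibble::tibble(sample_id = "A", chromosome = "Gm01",
                         start_bp = 20000, end_bp = 21000,
                         class = "del", mean_shift = -1)
  expect_error(simulate_cgh("A", cs, tiny, seed = 1), "3")
})

test_that("cohort simulator plants the requested private sites", {
  sim <- simulate_cohort_vcf(n_samples = 3, n_sites = 200,
                             private_counts = c(2L, 0L, 1L),
                             shared_poly_fraction = 0, het_fraction = 0,
                             missing_fraction = 0, seed = 5)
  expect_equal(nrow(sim$truth), 3)
  expect_equal(
    as.integer(table(factor(sim$truth$sample_id, levels = sim$samples))),
    c(2L, 0L, 1L)
  )
  # planted sites are hom_alt in exactly one sample, hom_ref with depth >= 5
  # elsewhere
  planted <- dplyr::semi_join(sim$sites, sim$truth,
                              by = c("chromosome", "position"))
  per <- planted |>
    dplyr::group_by(position) |>
    dplyr::summarise(n_alt = sum(gt_class == "hom_alt"),
                     min_dp = min(depth))
  expect_true(all(per$n_alt == 1))
  expect_true(all(per$min_dp >= 5))
})

test_that("cohort simulator rejects impossible private counts", {
  expect_error(
    simulate_cohort_vcf(n_samples = 2, n_sites = 3,
                        private_counts = c(2L, 2L), seed = 1),
    "n_sites"
  )
})

test_that("cohort VCF round-trips through write and read", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  sim <- simulate_cohort_vcf(n_samples = 4, n_sites = 300,
                             private_counts = c(3L, 1L, 0L, 2L),
                             seed = 11, vcf = tmp)
  back <- read_site_genotypes(tmp)
  orig <- dplyr::arrange(sim$sites, position, sample_id)
  back <- dplyr::arrange(back, position, sample_id)
  expect_equal(back$gt_class, orig$gt_class)
  expect_equal(back$depth, orig$depth)
  expect_equal(back$ref_base, orig$ref_base)
  # monomorphic sites come back with ALT "."
  expect_setequal(unique(back$alt_base[orig$alt_base == "."]), ".")
})

test_that("insertion read simulator leaves the deleted interval uncovered", {
  sim <- simulate_insertion_reads(host_length_bp = 30000,
                                  insertion_site = 15000,
                                  adjacent_deletion_bp = 1500,
                                  coverage_depth = 30, seed = 2)
  ends <- rbind(
    data.frame(seq = sim$reads$seq1), data.frame(seq = sim$reads$seq2)
  )
  aln <- somavar:::align_to_target(ends$seq, sim$host_seq)
  cov <- somavar:::coverage_vector(aln$pos[aln$aligned], 100, 30000)
  del <- sim$truth$deleted_start:sim$truth$deleted_end
  # near-zero: the odd junction-hugging read squeaks past the 90% identity
  # rule and leaks a few bases over a deletion edge
  expect_lt(mean(cov[del]), 0.5)
  expect_gt(mean(cov[del] == 0), 0.95)
  expect_gt(median(cov[-del]), 15)
})

test_that("junction-spanning reads carry the filler verbatim", {
  sim <- simulate_insertion_reads(filler = "ACGTAC", microhomology_bp = 0,
                                  coverage_depth = 30, seed = 4)
  # the filler sits between construct RB end and retained host: the exact
  # 31-mer around it must appear in at least one read
  fill_at <- sim$truth$insertion_site + nchar(sim$construct_seq)
  ctx <- substr(sim$variant_seq, fill_at - 12, fill_at + 18)
  expect_true(grepl("ACGTAC", ctx, fixed = TRUE))
  hits <- grepl(ctx, sim$reads$seq1, fixed = TRUE) |
    grepl(ctx, sim$reads$seq2, fixed = TRUE) |
    grepl(somavar:::revcomp(ctx), sim$reads$seq1, fixed = TRUE) |
    grepl(somavar:::revcomp(ctx), sim$reads$seq2, fixed = TRUE)
  expect_gt(sum(hits), 0)
})

test_that("read count scales with coverage and is seed-reproducible", {
  s10 <- simulate_read_pairs(strrep("ACGT", 5000), 10, seed = 9)
  s20 <- simulate_read_pairs(strrep("ACGT", 5000), 20, seed = 9)
  expect_lt(abs(nrow(s20) - 2 * nrow(s10)) / (2 * nrow(s10)), 0.01)
  expect_identical(s10, simulate_read_pairs(strrep("ACGT", 5000), 10, seed = 9))
  # insert sizes truncated above twice the read length
  expect_true(all(s10$fragment_end - s10$fragment_start + 1 > 200))
})

test_that("insertion simulator rejects a construct shorter than a read", {
  expect_error(
    simulate_insertion_reads(construct_length_bp = 50, seed = 1),
    "read length"
  )
})

test_that("simulate_junction is deterministic and validates inputs", {
  a <- simulate_junction(5, 5, flank_len = 60, seed = 3)
  b <- simulate_junction(5, 5, flank_len = 60, seed = 3)
  expect_identical(a, b)
  expect_error(simulate_junction(3, 7, seed = 1), "equal")
  expect_error(simulate_junction(10, 10, filler = "ACGTACGTAC",
                                 flank_len = 15, seed = 1), "flank_len")
})
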