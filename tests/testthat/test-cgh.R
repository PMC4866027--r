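# CGH segmentation, classification, heterogeneity filter, gene overlap.

test_that("center_track removes the genome-wide median and is idempotent", {
  tr <- toy_track(c(0.2, 0.2, 0.2, 0.2))
  expect_equal(center_track(tr)$log2_ratio, rep(0, 4))
  tr2 <- toy_track(c(-1, 0, 1))
  expect_equal(center_track(tr2)$log2_ratio, c(-1, 0, 1))
  noisy <- toy_track(rnorm(50) + 0.3)
  once <- center_track(noisy)
  expect_equal(center_track(once), once)
  expect_error(center_track(noisy[0, ]), "non-empty")
})

test_that("segmentation returns one segment for constant or tiny tracks", {
  flat <- toy_track(rep(0.05, 40))
  segs <- segment_track(flat, seg_params(seed = 1))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_probes, 40L)
  tiny <- toy_track(c(0, 5, 0))
  expect_equal(nrow(segment_track(tiny, seg_params(seed = 1))), 1)
})

test_that("segmentation splits exactly at a zero-noise changepoint", {
  tr <- toy_track(c(rep(0, 100), rep(-1, 50)))
  segs <- segment_track(tr, seg_params(seed = 1))
  expect_equal(nrow(segs), 2)
  expect_equal(segs$last_probe[1], 100L)
  expect_equal(segs$first_probe[2], 101L)
  expect_equal(segs$mean_log2, c(0, -1))
})

test_that("segmentation covers every probe exactly once", {
  cs <- tibble::tibble(chromosome = c("Gm01", "Gm02"),
                       length_bp = c(80000, 60000))
  ev <- tibble::tibble(sample_id = "A", chromosome = "Gm01",
                       start_bp = 20000, end_bp = 40000, class = "del",
                       mean_shift = -1)
  sim <- simulate_cgh("A", cs, ev, noise_sd = 0.15, seed = 3)
  segs <- segment_track(sim$tracks, seg_params(seed = 3))
  per_chrom <- split(segs, segs$chromosome)
  for (ch in per_chrom) {
    ch <- dplyr::arrange(ch, first_probe)
    expect_equal(ch$first_probe[1], 1L)
    if (nrow(ch) > 1) {
      expect_equal(ch$first_probe[-1], head(ch$last_probe, -1) + 1L)
    }
    n_probes_chrom <- sum(sim$tracks$chromosome == ch$chromosome[1])
    expect_equal(ch$last_probe[nrow(ch)], n_probes_chrom)
  }
})

test_that("accepted boundaries match the exhaustive single-changepoint scan", {
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(100:500, 1)
    cut_true <- sample(20:(n - 20), 1)
    v <- c(rnorm(cut_true, 0, 0.15), rnorm(n - cut_true, -1, 0.15))
    tr <- toy_track(v)
    segs <- segment_track(tr, seg_params(seed = rep))
    oracle_cut <- oracle_single_changepoint(v)
    expect_gte(nrow(segs), 2)
    expect_true(oracle_cut %in% segs$last_probe)
  }
})

test_that("classification applies strict thresholds and the 3-probe minimum", {
  thr <- sv_thresholds()
  up <- classify_segments(toy_segment(0.40, 5), thr)
  expect_equal(up$call_class, "UpCNV")
  down <- classify_segments(toy_segment(-0.60, 3), thr)
  expect_equal(down$call_class, "DownCNV")
  expect_equal(nrow(classify_segments(toy_segment(-0.60, 2), thr)), 0)
  expect_equal(nrow(classify_segments(toy_segment(0, 5), thr)), 0)
  # boundary: a mean exactly at a threshold is not a call
  expect_equal(nrow(classify_segments(toy_segment(0.3484, 5), thr)), 0)
  expect_equal(nrow(classify_segments(toy_segment(-0.5257, 5), thr)), 0)
})

test_that("tightening thresholds only shrinks the call sets", {
  set.seed(7)
  segs <- dplyr::bind_rows(lapply(runif(60, -1, 1), toy_segment))
  base <- classify_segments(segs, sv_thresholds())
  stricter_up <- classify_segments(segs, sv_thresholds(upper = 0.5))
  stricter_down <- classify_segments(segs, sv_thresholds(lower = -0.8))
  expect_true(all(stricter_up$mean_log2[stricter_up$call_class == "UpCNV"] %in%
                    base$mean_log2[base$call_class == "UpCNV"]))
  expect_lte(sum(stricter_up$call_class == "UpCNV"),
             sum(base$call_class == "UpCNV"))
  expect_lte(sum(stricter_down$call_class == "DownCNV"),
             sum(base$call_class == "DownCNV"))
})

test_that("candidate review lists only sub-threshold segments", {
  segs <- dplyr::bind_rows(
    toy_segment(0.30), toy_segment(0.40), toy_segment(-0.45),
    toy_segment(0.10)
  )
  rev <- candidate_review(segs, sv_thresholds(), relax_factor = 0.8)
  expect_setequal(rev$mean_log2, c(0.30, -0.45))
  # sorted by |mean| descending
  expect_equal(rev$mean_log2, c(-0.45, 0.30))
  expect_equal(nrow(candidate_review(segs, sv_thresholds(), 1.0)), 0)
})

test_that("heterogeneity filter flags shared locations and is idempotent", {
  mk <- function(s, start = 5000, end = 9000, cls = "DownCNV") {
    tibble::tibble(sample_id = s, chromosome = "Gm05", start_bp = start,
                   end_bp = end, first_probe = 5L, last_probe = 9L,
                   n_probes = 5L, mean_log2 = -1, call_class = cls,
                   filtered_as_heterogeneity = FALSE)
  }
  calls <- dplyr::bind_rows(mk("A"), mk("B"), mk("C"),
                            mk("D", 20000, 24000))
  out <- filter_heterogeneity(calls, mode = "exact")
  expect_equal(sum(out$filtered_as_heterogeneity), 3)
  expect_false(out$filtered_as_heterogeneity[out$sample_id == "D"])
  expect_identical(filter_heterogeneity(out, mode = "exact"), out)
  # same location, different class: not heterogeneity
  mixed <- dplyr::bind_rows(mk("A"), mk("B", cls = "UpCNV"))
  expect_false(any(filter_heterogeneity(mixed, mode = "exact")$filtered_as_heterogeneity))
  # single sample: warning, no-op
  expect_warning(out1 <- filter_heterogeneity(mk("A")), "2 samples")
  expect_false(any(out1$filtered_as_heterogeneity))
})

test_that("reciprocal mode honors the overlap threshold", {
  a <- tibble::tibble(sample_id = "A", chromosome = "Gm01", start_bp = 1000,
                      end_bp = 2000, call_class = "DownCNV",
                      filtered_as_heterogeneity = FALSE)
  b <- a; b$sample_id <- "B"; b$start_bp <- 1500; b$end_bp <- 2500
  both <- dplyr::bind_rows(a, b) # ~50% reciprocal overlap
  out <- filter_heterogeneity(both, mode = "reciprocal",
                              reciprocal_overlap = 0.8)
  expect_false(any(out$filtered_as_heterogeneity))
  out2 <- filter_heterogeneity(both, mode = "reciprocal",
                               reciprocal_overlap = 0.4)
  expect_true(all(out2$filtered_as_heterogeneity))
})

test_that("gene overlap counts >= 1 bp overlaps once per sample and class", {
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:5), chromosome = "Gm11",
    start_bp = c(1000, 3000, 5000, 7000, 20000),
    end_bp = c(1999, 3999, 5999, 7999, 21000)
  )
  # one DownCNV spanning genes 1-4: 2 fully, 2 partially
  call <- tibble::tibble(
    sample_id = "T1", chromosome = "Gm11", start_bp = 1500, end_bp = 7500,
    call_class = "DownCNV", mean_log2 = -1, n_probes = 5L,
    first_probe = 1L, last_probe = 5L, filtered_as_heterogeneity = FALSE
  )
  hits <- genes_overlapping(call, genes)
  expect_equal(sort(hits$gene_id), paste0("g", 1:4))
  # a call entirely intergenic touches nothing
  gap_call <- dplyr::mutate(call, start_bp = 8200, end_bp = 9000,
                            call_class = "UpCNV")
  expect_equal(nrow(genes_overlapping(gap_call, genes)), 0)
  # abutting without overlap (gene starts at call end + 1) is not counted
  abut <- dplyr::mutate(call, start_bp = 100, end_bp = 999)
  expect_equal(nrow(genes_overlapping(abut, genes)), 0)
  # two calls hitting the same gene count it once
  twice <- dplyr::bind_rows(call, dplyr::mutate(call, start_bp = 3500,
                                                end_bp = 3600))
  expect_equal(sum(genes_overlapping(twice, genes)$gene_id == "g2"), 1)
  # unknown chromosome in calls errors with its name
  bad <- dplyr::mutate(call, chromosome = "Gm99")
  expect_error(genes_overlapping(bad, genes), "Gm99")
})

test_that("class summaries report gene counts and genic segment sizes", {
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:12), chromosome = "Gm01",
    start_bp = seq(1000, 111999, by = 10000)[1:12],
    end_bp = seq(1000, 111999, by = 10000)[1:12] + 1999
  )
  mk <- function(s, start, end, cls) {
    tibble::tibble(sample_id = s, chromosome = "Gm01", start_bp = start,
                   end_bp = end, call_class = cls, mean_log2 = ifelse(cls == "UpCNV", 1, -1),
                   n_probes = 5L, first_probe = 1L, last_probe = 5L,
                   filtered_as_heterogeneity = FALSE)
  }
  calls <- dplyr::bind_rows(
    mk("A", 1000, 40000, "DownCNV"),   # genes g1-g4
    mk("B", 1000, 100000, "DownCNV"),  # g1-g10
    mk("C", 200000, 201000, "DownCNV") # non-genic
  )
  s <- summarize_class(calls, genes, "FN")
  down <- s[s$direction == "DownCNV", ]
  expect_equal(down$total_genes, 10)
  expect_equal(down$max_genes, 10)
  expect_equal(down$median_genes, 4)
  expect_equal(down$min_genes, 0)
  expect_equal(down$n_genic_segments, 2)
  expect_equal(down$mean_size_bp, mean(c(39001, 99001)))
  # a single genic Up segment: mean = median = its size
  up1 <- summarize_class(mk("A", 1000, 7433, "UpCNV"), genes, "Transgenic")
  up <- up1[up1$direction == "UpCNV", ]
  expect_equal(up$mean_size_bp, 6434)
  expect_equal(up$median_size_bp, 6434)
  # no genic segments: sizes are absent, not zero
  none <- summarize_class(mk("A", 200000, 201000, "UpCNV"), genes, "X")
  expect_true(is.na(none$mean_size_bp[none$direction == "UpCNV"]))
})

test_that("heterogeneity-flagged calls are excluded from gene accounting", {
  genes <- tibble::tibble(gene_id = "g1", chromosome = "Gm01",
                          start_bp = 1000, end_bp = 2000)
  call <- tibble::tibble(
    sample_id = "A", chromosome = "Gm01", start_bp = 500, end_bp = 2500,
    call_class = "DownCNV", mean_log2 = -1, n_probes = 5L,
    first_probe = 1L, last_probe = 5L, filtered_as_heterogeneity = TRUE
  )
  expect_equal(nrow(genes_overlapping(call, genes)), 0)
})

test_that("probe tracks round-trip through TSV files", {
  tr <- toy_track(c(0.1, -0.2, 0.3), sample_id = "S9")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_probe_track(tr, tmp)
  back <- read_probe_track(tmp, sample_id = "S9")
  expect_equal(back$log2_ratio, tr$log2_ratio)
  expect_equal(back$position, tr$position)
})
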