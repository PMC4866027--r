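#' Simulate a jointly genotyped cohort with planted private substitutions
#'
#' Builds a multi-sample genotype matrix in which a known number of sites
#' per sample are homozygous-alternate in exactly that sample and
#' homozygous-reference (with adequate depth) everywhere else -- the ground
#' truth for [apply_site_filters()]. The remaining sites are distractors
#' drawn from the failure modes the filter must reject: shared polymorphisms
#' (homozygous alternate in two or more samples), heterozygous calls,
#' missing calls, and sites left monomorphic for the reference. Per-sample
#' depths are Poisson around `depth_mean`; planted private sites are
#' guaranteed depth >= `min_planted_depth` in every sample so that only
#' distractors can fail the depth rule.
#'
#' @param n_samples Number of samples (named `S01`, `S02`, ...).
#' @param n_sites Total number of sites.
#' @param private_counts Integer vector (length `n_samples`) of planted
#'   private homozygous substitutions per sample; the sum must not exceed
#'   `n_sites`.
#' @param shared_poly_fraction,het_fraction,missing_fraction Fractions of
#'   the non-planted sites realized as shared polymorphisms, as sites with a
#'   heterozygous call, and as sites with a missing call.
#' @param depth_mean Mean Poisson read depth per sample.
#' @param min_planted_depth Depth floor applied to planted sites (default 5,
#'   the filter's depth rule).
#' @param constant_depth When `TRUE` every depth equals `depth_mean` exactly
#'   (no Poisson sampling, no planted-site floor); useful for exercising the
#'   depth-rule boundary.
#' @param chromosome Chromosome name for all sites.
#' @param seed Seed.
#' @param vcf Optional path: when given, the cohort is also written as a
#'   VCF v4.2 and a `*.truth.tsv` manifest alongside.
#' @return List with `sites` (long tibble for [apply_site_filters()]),
#'   `truth` (planted private sites: `sample_id`, `chromosome`, `position`,
#'   `ref_base`, `alt_base`) and `samples`.
#' @export
simulate_cohort_vcf <- function(n_samples = 5L, n_sites = 1000L,
                                private_counts = rep(2L, n_samples),
                                shared_poly_fraction = 0.3,
                                het_fraction = 0.05,
                                missing_fraction = 0.02,
                                depth_mean = 20,
                                min_planted_depth = 5L,
                                constant_depth = FALSE,
                                chromosome = "Gm01",
                                seed = 1L, vcf = NULL) {
  stopifnot(
    length(private_counts) == n_samples,
    all(private_counts >= 0),
    shared_poly_fraction >= 0, shared_poly_fraction <= 1,
    het_fraction >= 0, het_fraction <= 1,
    missing_fraction >= 0, missing_fraction <= 1,
    depth_mean > 0
  )
  if (sum(private_counts) > n_sites) {
    abort("sum(private_counts) must not exceed n_sites")
  }
  samples <- sprintf("S%02d", seq_len(n_samples))
  with_seed(derive_seed(seed, "cohort"), {
    positions <- sort(sample.int(n_sites * 100L, n_sites))
    ref <- sample(BASES, n_sites, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1),
                  USE.NAMES = FALSE)

    # assign site roles
    role <- rep("mono_ref", n_sites)
    planted_idx <- sample.int(n_sites, sum(private_counts))
    role[planted_idx] <- "private"
    planted_sample <- rep(samples, times = private_counts)
    planted_sample <- sample(planted_sample) # shuffle order across positions
    rest <- which(role == "mono_ref")
    n_rest <- length(rest)
    n_shared <- round(shared_poly_fraction * n_rest)
    n_het <- round(het_fraction * n_rest)
    n_miss <- round(missing_fraction * n_rest)
    pool <- sample(rest)
    take <- function(n) {
      out <- head(pool, n)
      pool <<- tail(pool, length(pool) - n)
      out
    }
    role[take(n_shared)] <- "shared"
    role[take(n_het)] <- "het"
    role[take(n_miss)] <- "missing"

    gt <- matrix("hom_ref", nrow = n_sites, ncol = n_samples,
                 dimnames = list(NULL, samples))
    dp <- if (constant_depth) {
      matrix(depth_mean, nrow = n_sites, ncol = n_samples)
    } else {
      matrix(rpois(n_sites * n_samples, depth_mean),
             nrow = n_sites, ncol = n_samples)
    }
    k <- 0L
    for (i in seq_len(n_sites)) {
      if (role[i] == "private") {
        k <- k + 1L
        gt[i, planted_sample[k]] <- "hom_alt"
        if (!constant_depth) dp[i, ] <- pmax(dp[i, ], min_planted_depth)
      } else if (role[i] == "shared") {
        carriers <- sample.int(n_samples, sample(2:n_samples, 1))
        gt[i, carriers] <- "hom_alt"
      } else if (role[i] == "het") {
        gt[i, sample.int(n_samples, 1)] <- "het"
      } else if (role[i] == "missing") {
        gt[i, sample.int(n_samples, 1)] <- "missing"
      }
    }

    sites <- tibble(
      chromosome = chromosome,
      position = rep(positions, each = n_samples),
      ref_base = rep(ref, each = n_samples),
      alt_base = rep(ifelse(role == "mono_ref", ".", alt), each = n_samples),
      sample_id = rep(samples, times = n_sites),
      gt_class = as.vector(t(gt)),
      depth = as.vector(t(dp))
    )
  })
  # planted private sites are exactly the hom_alt sites with one carrier:
  # shared-polymorphism distractors always have >= 2 carriers
  truth <- sites |>
    filter(gt_class == "hom_alt") |>
    group_by(chromosome, position, ref_base, alt_base) |>
    filter(dplyr::n() == 1) |>
    ungroup() |>
    select(sample_id, chromosome, position, ref_base, alt_base) |>
    arrange(position)

  if (!is.null(vcf)) {
    write_cohort_vcf(sites, vcf)
    readr::write_tsv(truth, paste0(vcf, ".truth.tsv"))
  }
  list(sites = sites, truth = truth, samples = samples)
}
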