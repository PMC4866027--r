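#' Filtering criteria for private homozygous substitutions
#'
#' Criteria reducing a jointly genotyped cohort to substitutions that are
#' homozygous, private differences from the reference in exactly one
#' individual -- the signature expected of a de novo mutation observed once.
#' The defaults exclude: sites where any sample has fewer than `min_depth`
#' reads; sites monomorphic for the reference (or for any single allele,
#' since neither can be private); sites with heterozygous or missing calls;
#' and sites where more than `max_alt_carriers` individuals are homozygous
#' for the alternate base.
#'
#' @param min_depth Minimum read depth per sample at a site. Default 5.
#' @param max_alt_carriers Maximum number of homozygous-alternate
#'   individuals. Default 1 (private).
#' @param require_homozygous Keep only fully homozygous sites. Default TRUE.
#' @param exclusion_regions Optional tibble `chromosome`, `start_bp`,
#'   `end_bp` (1-based inclusive) and optional `sample_id`, applied by
#'   [apply_region_exclusion()].
#' @param depth_scope `"site"` (default): a site is dropped when *any*
#'   sample is under-covered, the conservative site-level reading;
#'   `"carrier"`: only the alternate carrier's depth is checked.
#' @return A list of class `filter_criteria`.
#' @export
filter_criteria <- function(min_depth = 5L, max_alt_carriers = 1L,
                            require_homozygous = TRUE,
                            exclusion_regions = NULL,
                            depth_scope = c("site", "carrier")) {
  stopifnot(min_depth >= 1, max_alt_carriers >= 1)
  structure(
    list(
      min_depth = min_depth,
      max_alt_carriers = max_alt_carriers,
      require_homozygous = isTRUE(require_homozygous),
      exclusion_regions = exclusion_regions,
      depth_scope = match.arg(depth_scope)
    ),
    class = "filter_criteria"
  )
}

#' Extract substitutions private to one individual
#'
#' Applies the site-level filters to long-format genotype calls. A site
#' yields exactly one private substitution iff every sample meets the depth
#' rule, no sample is heterozygous or missing, exactly one sample is
#' homozygous alternate and all others homozygous reference. Only biallelic
#' single-base substitutions are eligible; indel and multiallelic records are
#' skipped and counted in the `skipped` attribute of the result.
#'
#' @param sites Long tibble with one row per site x sample: `chromosome`,
#'   `position`, `ref_base`, `alt_base`, `sample_id`,
#'   `gt_class` (`"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`) and
#'   `depth`. See [read_site_genotypes()].
#' @param criteria A [filter_criteria()] object.
#' @return Tibble of private substitutions: `sample_id`, `chromosome`,
#'   `position`, `ref_base`, `alt_base`, `is_transition`; attribute
#'   `skipped` holds the count of ineligible (non-SNV / multiallelic)
#'   records dropped. Exclusion regions in `criteria` are applied last.
#' @export
apply_site_filters <- function(sites, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  if (nrow(sites) == 0 || length(unique(sites$sample_id)) == 0) {
    abort("`sites` must contain at least one sample")
  }
  snv_ok <- sites$ref_base %in% BASES & sites$alt_base %in% c(BASES, ".", NA) &
    nchar(sites$ref_base) == 1 &
    (is.na(sites$alt_base) | nchar(sites$alt_base) == 1) &
    !grepl(",", sites$alt_base %||% "")
  bad_sites <- distinct(sites[!snv_ok, ], chromosome, position)
  n_skipped <- nrow(bad_sites)
  if (n_skipped > 0) {
    inform(paste0(n_skipped, " multiallelic/indel site(s) skipped"))
    sites <- dplyr::anti_join(sites, bad_sites, by = c("chromosome", "position"))
  }
  per_site <- sites |>
    group_by(chromosome, position, ref_base, alt_base) |>
    summarise(
      min_depth_site = min(depth),
      any_het_missing = any(gt_class %in% c("het", "missing")),
      n_hom_alt = sum(gt_class == "hom_alt"),
      alt_carrier = if (sum(gt_class == "hom_alt") == 1)
        sample_id[gt_class == "hom_alt"] else NA_character_,
      carrier_depth = if (sum(gt_class == "hom_alt") == 1)
        depth[gt_class == "hom_alt"] else NA_real_,
      .groups = "drop"
    )
  depth_ok <- if (criteria$depth_scope == "site") {
    per_site$min_depth_site >= criteria$min_depth
  } else {
    !is.na(per_site$carrier_depth) & per_site$carrier_depth >= criteria$min_depth
  }
  keep <- depth_ok &
    !per_site$any_het_missing &
    per_site$n_hom_alt >= 1 &
    per_site$n_hom_alt <= criteria$max_alt_carriers &
    !is.na(per_site$alt_carrier) &
    !is.na(per_site$alt_base) & per_site$alt_base %in% BASES &
    per_site$alt_base != per_site$ref_base
  out <- per_site[keep, ] |>
    mutate(
      sample_id = alt_carrier,
      is_transition = is_transition_pair(ref_base, alt_base)
    ) |>
    select(sample_id, chromosome, position, ref_base, alt_base, is_transition) |>
    arrange(sample_id, chromosome, position)
  if (!is.null(criteria$exclusion_regions)) {
    out <- apply_region_exclusion(out, criteria$exclusion_regions)
  }
  attr(out, "skipped") <- n_skipped
  out
}

#' Remove substitutions inside exclusion regions
#'
#' Regions known to harbor residual cultivar heterogeneity inflate private
#' substitution counts and are subtracted before summarizing. Regions are
#' 1-based inclusive; a region with a `sample_id` column restricts removal to
#' that sample.
#'
#' @param subs Private-substitution tibble from [apply_site_filters()].
#' @param regions Tibble `chromosome`, `start_bp`, `end_bp`, optional
#'   `sample_id`.
#' @return Filtered tibble; the number of removed records is attached as the
#'   `n_removed` attribute.
#' @export
apply_region_exclusion <- function(subs, regions) {
  if (is.null(regions) || nrow(regions) == 0 || nrow(subs) == 0) {
    attr(subs, "n_removed") <- 0L
    return(subs)
  }
  drop <- rep(FALSE, nrow(subs))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    hit <- subs$chromosome == r$chromosome &
      subs$position >= r$start_bp & subs$position <= r$end_bp
    if ("sample_id" %in% names(regions) && !is.na(r$sample_id)) {
      hit <- hit & subs$sample_id == r$sample_id
    }
    drop <- drop | hit
  }
  out <- subs[!drop, ]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Exclusion preset: heterogeneous region on chromosome 12
#'
#' The 10-23 Mb interval of chromosome Gm12 is heterogeneous within the
#' 'M92-220' cultivar and contaminates private-substitution counts for the
#' fast-neutron plant carrying it; this preset region (default-off) removes
#' it for a named sample.
#'
#' @param sample_id Sample the exclusion applies to (default `"FN_07"`).
#' @return One-row region tibble usable as `exclusion_regions`.
#' @export
gm12_heterogeneity_region <- function(sample_id = "FN_07") {
  tibble(
    chromosome = "Gm12",
    start_bp = 10e6,
    end_bp = 23e6,
    sample_id = sample_id
  )
}

#' Per-sample private-substitution counts
#'
#' @param subs Private-substitution tibble.
#' @param samples Character vector of all cohort samples, so samples with
#'   zero substitutions appear with count 0. Defaults to the samples present
#'   in `subs`.
#' @return Tibble `sample_id`, `n_private`.
#' @export
per_sample_counts <- function(subs, samples = NULL) {
  samples <- samples %||% sort(unique(subs$sample_id))
  counts <- table(factor(subs$sample_id, levels = samples))
  tibble(sample_id = samples, n_private = as.integer(counts))
}

#' Transition:transversion ratio
#'
#' Transitions are A<->G and C<->T. Returns `NA` when there are no
#' transversions (the ratio is undefined), including for an empty set.
#'
#' @param subs Private-substitution tibble with `is_transition`.
#' @return A single number, or `NA_real_` when undefined.
#' @export
titv_ratio <- function(subs) {
  ti <- sum(subs$is_transition)
  tv <- sum(!subs$is_transition)
  if (tv == 0) NA_real_ else ti / tv
}
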