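#' Read multi-sample genotype calls from a VCF
#'
#' Converts a VCF v4.2 (plain or bgzipped) into the long site-by-sample
#' tibble consumed by [apply_site_filters()]. Genotype classes come from the
#' GT field; depth from FORMAT/DP, falling back to the sum of FORMAT/AD;
#' a missing depth is recorded as 0 so the site fails the depth rule rather
#' than passing silently.
#'
#' @param path VCF file.
#' @return Long tibble: `chromosome`, `position`, `ref_base`, `alt_base`,
#'   `sample_id`, `gt_class`, `depth`.
#' @export
read_site_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (is.null(dp) || all(is.na(dp))) {
    ad <- vcfR::extract.gt(v, element = "AD")
    if (!is.null(ad)) {
      dp <- apply(ad, c(1, 2), function(x) {
        if (is.na(x)) NA_real_ else sum(as.numeric(strsplit(x, ",")[[1]]))
      })
    }
  }
  samples <- colnames(gt)
  n_sites <- nrow(fix)
  classify_gt <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return("missing")
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return("missing")
    if (length(unique(alleles)) > 1) return("het")
    if (all(alleles == "0")) "hom_ref" else "hom_alt"
  }
  long <- tidyr::expand_grid(site = seq_len(n_sites), sample_id = samples)
  long$chromosome <- fix$CHROM[long$site]
  long$position <- as.numeric(fix$POS[long$site])
  long$ref_base <- fix$REF[long$site]
  alt <- fix$ALT[long$site]
  long$alt_base <- ifelse(is.na(alt), ".", alt) # "." means no alternate
  gt_vec <- gt[cbind(long$site, match(long$sample_id, samples))]
  u <- unique(gt_vec)
  long$gt_class <- unname(vapply(u, classify_gt, character(1))[match(gt_vec, u)])
  dp_vec <- if (!is.null(dp)) dp[cbind(long$site, match(long$sample_id, samples))] else NA_real_
  long$depth <- ifelse(is.na(dp_vec), 0, dp_vec)
  long |>
    select(chromosome, position, ref_base, alt_base, sample_id, gt_class, depth)
}

# Write a long site-by-sample genotype tibble as a minimal VCF v4.2 with GT
# and DP. Used by the cohort simulator; production call sets come from
# upstream callers and are only read.
write_cohort_vcf <- function(sites, path) {
  samples <- sort(unique(sites$sample_id))
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  wide <- sites |>
    mutate(cell = paste0(gt_code[gt_class], ":", depth)) |>
    select(chromosome, position, ref_base, alt_base, sample_id, cell) |>
    tidyr::pivot_wider(names_from = sample_id, values_from = cell) |>
    arrange(chromosome, position)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  alt <- ifelse(is.na(wide$alt_base) | wide$alt_base == "", ".", wide$alt_base)
  cells <- do.call(paste, c(unname(as.list(wide[, samples])), list(sep = "\t")))
  body <- paste(wide$chromosome,
                format(wide$position, scientific = FALSE, trim = TRUE),
                ".", wide$ref_base, alt, ".", "PASS", ".", "GT:DP", cells,
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
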