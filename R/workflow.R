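#' Configuration for a full comparative run
#'
#' Bundles the inputs and thresholds for the three-way comparison of
#' standing (inter-cultivar), fast-neutron induced, and
#' transformation-induced variation. Any stage whose inputs are absent is
#' skipped with a notice, so a config carrying only a genotype cohort
#' yields only the substitution report.
#'
#' @param sample_classes Tibble `sample_id`, `class` (e.g.
#'   `"inter-cultivar"`, `"FN-phenotype"`, `"FN-no-phenotype"`,
#'   `"transgenic"`, `"control"`) and `background_group` naming the group
#'   of samples sharing a reference background for heterogeneity
#'   filtering.
#' @param tracks Long probe tibble over all CGH samples, or `NULL`.
#' @param genes Gene-model tibble, or `NULL`.
#' @param sites Long genotype tibble (see [read_site_genotypes()]), or
#'   `NULL`.
#' @param criteria [filter_criteria()] for the substitution stage.
#' @param tdna Named list (per transgenic sample) of lists with elements
#'   `pairs`, `construct`, `host`, `host_name`, and optionally `elements`,
#'   `homologous_elements`, `paralog_regions`, `insert_size_mean`,
#'   `insert_size_sd`; or `NULL`.
#' @param seg_params [seg_params()] used for segmentation.
#' @param thresholds [sv_thresholds()] used for classification.
#' @param het_mode,min_recurrence Heterogeneity-filter settings.
#' @param seed Run seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sample_classes, tracks = NULL, genes = NULL,
                       sites = NULL, criteria = filter_criteria(),
                       tdna = NULL, seg_params = somavar::seg_params(),
                       thresholds = sv_thresholds(),
                       het_mode = "exact", min_recurrence = 2L,
                       seed = 1L) {
  stopifnot(all(c("sample_id", "class") %in% names(sample_classes)))
  if (anyDuplicated(sample_classes$sample_id)) {
    abort("every sample must appear in exactly one class")
  }
  structure(
    list(
      sample_classes = as_tibble(sample_classes),
      tracks = tracks, genes = genes, sites = sites, criteria = criteria,
      tdna = tdna, seg_params = seg_params, thresholds = thresholds,
      het_mode = het_mode, min_recurrence = min_recurrence, seed = seed
    ),
    class = "run_config"
  )
}

#' Run the full comparative pipeline
#'
#' Orchestrates the stages over one [run_config()]: per-sample
#' segmentation and SV classification, per-background-group heterogeneity
#' filtering, gene overlap and per-class summaries; the private-homozygous
#' substitution filter with per-sample counts and Ti/Tv; and insertion
#' localization plus junction resolution per transgenic sample. Every
#' number in the report bundle is carried from a stage output; record
#' counts in and out of each filter are logged through messages.
#'
#' @param config A [run_config()].
#' @return A list of class `somavar_report`: `calls`, `gene_hits`,
#'   `class_summary`, `substitutions`, `substitution_counts`, `titv`,
#'   `insertions`, `local_sv`, `skipped` (character vector of skipped
#'   stages).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  skipped <- character(0)
  calls <- gene_hits <- class_summary <- NULL
  if (!is.null(config$tracks)) {
    sp <- config$seg_params
    sp$seed <- config$seed
    samples <- unique(config$tracks$sample_id)
    segs <- bind_rows(lapply(samples, function(s) {
      segment_track(config$tracks[config$tracks$sample_id == s, ], sp)
    }))
    calls <- classify_segments(segs, config$thresholds)
    inform(paste0("cgh: ", nrow(segs), " segments -> ", nrow(calls), " calls"))
    cls <- config$sample_classes
    if ("background_group" %in% names(cls)) {
      calls <- calls |>
        left_join(select(cls, sample_id, group = background_group),
                  by = "sample_id")
      calls <- bind_rows(lapply(split(calls, calls$group), function(g) {
        if (length(unique(g$sample_id)) >= 2) {
          filter_heterogeneity(g, mode = config$het_mode,
                               min_recurrence = config$min_recurrence)
        } else {
          g$filtered_as_heterogeneity <- FALSE
          g
        }
      }))
      inform(paste0("cgh: ", sum(calls$filtered_as_heterogeneity),
                    " calls flagged as intra-cultivar heterogeneity"))
    }
    if (!is.null(config$genes)) {
      gene_hits <- genes_overlapping(calls, config$genes)
      class_summary <- bind_rows(lapply(
        split(config$sample_classes$sample_id, config$sample_classes$class),
        function(ids) {
          cc <- calls[calls$sample_id %in% ids, ]
          if (nrow(cc) == 0) return(NULL)
          summarize_class(cc, config$genes,
                          config$sample_classes$class[
                            match(ids[1], config$sample_classes$sample_id)])
        }
      ))
    }
  } else {
    skipped <- c(skipped, "cgh")
    inform("cgh stage skipped: no probe tracks configured")
  }

  substitutions <- substitution_counts <- titv <- NULL
  if (!is.null(config$sites)) {
    substitutions <- apply_site_filters(config$sites, config$criteria)
    cohort <- sort(unique(config$sites$sample_id))
    substitution_counts <- per_sample_counts(substitutions, cohort)
    titv <- substitutions |>
      group_by(sample_id) |>
      summarise(titv = titv_ratio(dplyr::pick(is_transition)), .groups = "drop")
    inform(paste0("substitutions: ", nrow(substitutions),
                  " private homozygous substitutions across ",
                  length(cohort), " samples"))
  } else {
    skipped <- c(skipped, "substitutions")
    inform("substitution stage skipped: no genotype calls configured")
  }

  insertions <- local_sv <- NULL
  if (!is.null(config$tdna)) {
    res <- lapply(names(config$tdna), function(s) {
      td <- config$tdna[[s]]
      ia <- locate_insertion(
        td$pairs, td$construct, td$host,
        host_name = td$host_name %||% "host1",
        insert_size_mean = td$insert_size_mean %||% 350,
        insert_size_sd = td$insert_size_sd %||% 30,
        elements = td$elements,
        homologous_elements = td$homologous_elements,
        paralog_regions = td$paralog_regions
      )
      list(
        calls = mutate(ia$calls, sample_id = s, .before = 1),
        sv = if (nrow(ia$local_sv)) mutate(ia$local_sv, sample_id = s, .before = 1)
             else ia$local_sv
      )
    })
    insertions <- bind_rows(lapply(res, `[[`, "calls"))
    if ("support" %in% names(insertions)) insertions$support <- NULL
    local_sv <- bind_rows(lapply(res, `[[`, "sv"))
    inform(paste0("tdna: ", nrow(insertions), " insertion call(s) across ",
                  length(config$tdna), " sample(s)"))
  } else {
    skipped <- c(skipped, "tdna")
    inform("transgene stage skipped: no read sets configured")
  }

  structure(
    list(
      calls = calls, gene_hits = gene_hits, class_summary = class_summary,
      substitutions = substitutions,
      substitution_counts = substitution_counts, titv = titv,
      insertions = insertions, local_sv = local_sv,
      skipped = skipped, seed = config$seed
    ),
    class = "somavar_report"
  )
}

#' @export
print.somavar_report <- function(x, ...) {
  cat("somavar comparative report\n")
  if (!is.null(x$class_summary)) {
    cat("\nPer-class SV summary:\n")
    print(x$class_summary)
  }
  if (!is.null(x$substitution_counts)) {
    cat("\nPrivate homozygous substitutions per sample:\n")
    print(x$substitution_counts)
  }
  if (!is.null(x$insertions)) {
    cat("\nT-DNA insertions:\n")
    print(x$insertions)
  }
  if (length(x$skipped)) {
    cat("\nSkipped stages:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}
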