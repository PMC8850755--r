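# End-to-end pipeline: configuration, stage execution, run manifest, and
# report generation. Stages: simulate -> quantify -> normalize -> filter ->
# temporal statistics -> injury associations. Real-mode configs point the
# quantify stage at user-supplied peak-area/clinical CSVs and skip simulate.

#' Default pipeline configuration
#'
#' Every analysis choice that is a genuine convention (correction-factor
#' convention, CoV timing, Bonferroni family, log base for composition
#' ratios) is a named key so a run records its own settings.
#'
#' @param seed Master seed.
#' @param outdir Output directory.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L, outdir = "results") {
  list(
    seed = seed,
    outdir = outdir,
    mode = "synthetic",            # or "real" with input paths below
    inputs = list(peak_areas = NULL, clinical = NULL, troponin = NULL,
                  panel = NULL),
    design = list(n_stemi = 80, n_control = 50, n_late_subset = 30),
    acquisition = list(drift_amplitude = 0.3, noise_cv = 0.15),
    quantify = list(cf_convention = "divide"),
    normalize = list(method = "serrf", k_correlated = 10, trees = 500,
                     cov_threshold = 20, cov_timing = "post_normalization"),
    stats = list(alpha = 0.05, bonferroni_family = "per_species",
                 log_ratio_base = 2, troponin_window_h = Inf)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Keys missing from the file fall back to [default_config()] values.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user)
}

#' Run the full pipeline
#'
#' Executes simulate, quantify, normalize, filter and statistics stages,
#' writes every stage table as CSV under `config$outdir`, and returns a run
#' manifest (config digest, seed, per-stage row counts, retained species,
#' output file digests). Re-running with an identical config and seed
#' reproduces identical digests.
#'
#' @param config Configuration list (see [default_config()]) or a path to a
#'   YAML file.
#' @return A `run_manifest` list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- load_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  stage_counts <- list()

  panel <- if (!is.null(config$inputs$panel)) {
    load_panel(config$inputs$panel)
  } else default_panel()

  if (identical(config$mode, "real")) {
    if (is.null(config$inputs$peak_areas) || is.null(config$inputs$clinical)) {
      abort("real mode requires inputs$peak_areas and inputs$clinical paths")
    }
    areas <- readr::read_csv(config$inputs$peak_areas, show_col_types = FALSE)
    clinical <- readr::read_csv(config$inputs$clinical, show_col_types = FALSE)
    troponin <- if (!is.null(config$inputs$troponin)) {
      readr::read_csv(config$inputs$troponin, show_col_types = FALSE)
    }
  } else {
    design <- study_design(n_stemi = config$design$n_stemi,
                           n_control = config$design$n_control,
                           n_late_subset = config$design$n_late_subset)
    truth <- ground_truth(panel)
    cohort <- generate_cohort(design, truth, seed = seed)
    areas <- generate_acquisition(
      cohort, design, truth, panel,
      drift_amplitude = config$acquisition$drift_amplitude,
      noise_cv = config$acquisition$noise_cv, seed = seed)
    clinical <- cohort$clinical
    troponin <- cohort$troponin
    readr::write_csv(areas, file.path(outdir, "peak_areas.csv"))
    readr::write_csv(clinical, file.path(outdir, "clinical.csv"))
    readr::write_csv(troponin, file.path(outdir, "troponin.csv"))
  }
  stage_counts$peak_area_rows <- nrow(areas)

  # quantify
  deiso <- deisotope(areas, panel)
  conc <- quantify(deiso, panel)
  study_meta <- dplyr::distinct(
    areas[areas$sample_type == "study",
          c("sample_id", "subject_id", "timepoint")])
  conc <- dplyr::left_join(conc, study_meta, by = "sample_id")
  readr::write_csv(conc, file.path(outdir, "concentrations.csv"))
  stage_counts$concentration_rows <- nrow(conc)

  # normalize + filter
  norm <- if (identical(config$normalize$method, "loess")) {
    loess_normalize(conc)
  } else {
    serrf_normalize(conc, k_correlated = config$normalize$k_correlated,
                    trees = config$normalize$trees, seed = seed)
  }
  filt <- qc_filter(norm, threshold_pct = config$normalize$cov_threshold)
  readr::write_csv(filt$conc,
                   file.path(outdir, "concentrations_normalized.csv"))
  readr::write_csv(filt$metrics, file.path(outdir, "qc_metrics.csv"))
  stage_counts$species_retained <- sum(filt$metrics$retained)
  stage_counts$species_total <- nrow(filt$metrics)

  study <- filt$conc[filt$conc$sample_type == "study", ]

  # temporal statistics on STEMI subjects, core timepoints
  stemi <- study[grepl("^S", study$subject_id), ]
  screen <- species_temporal_screen(stemi, alpha = config$stats$alpha)
  readr::write_csv(screen$anova, file.path(outdir, "anova_results.csv"))
  readr::write_csv(screen$pairwise, file.path(outdir, "pairwise_results.csv"))
  totals <- class_totals(stemi)
  readr::write_csv(totals, file.path(outdir, "class_totals.csv"))
  stage_counts$species_tested <- nrow(screen$anova)

  # injury associations
  regression <- NULL
  if (!is.null(troponin) && nrow(troponin) > 0L) {
    delta <- cohort_delta_troponin(troponin,
                                   window_h = config$stats$troponin_window_h)
    conc_t1 <- stemi[stemi$timepoint == "t1", ]
    regression <- regression_screen(conc_t1, delta, clinical)
    readr::write_csv(regression, file.path(outdir, "regression_results.csv"))
    split <- tertile_split(delta$delta_tnt)
    lab <- tibble::tibble(subject_id = delta$subject_id,
                          tertile = split$labels)
    sig_species <- regression$species[regression$significant &
                                        regression$flag == "ok"]
    group_cmp <- purrr::map_dfr(sig_species, function(s) {
      d <- dplyr::inner_join(conc_t1[conc_t1$species == s, ], lab,
                             by = "subject_id")
      dplyr::mutate(group_fold_change(d$concentration, d$tertile,
                                      group_a = "top"),
                    species = s, grouping = "tertile_top_vs_rest",
                    .before = 1L)
    })
    if (nrow(group_cmp) == 0L) {
      group_cmp <- tibble::tibble(
        species = character(), grouping = character(), log2_fc = numeric(),
        p = numeric(), n_a = integer(), n_b = integer(),
        significant = logical())
    }
    readr::write_csv(group_cmp, file.path(outdir, "group_comparisons.csv"))
    stage_counts$troponin_associated <- length(sig_species)
  }

  manifest <- structure(list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = seed,
    config_digest = {
      h <- fnv1a32(jsonlite::toJSON(config[setdiff(names(config), "outdir")],
                                    auto_unbox = TRUE))
      sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
    },
    package_version = as.character(utils::packageVersion("lipidflux")),
    stage_counts = stage_counts,
    outputs = output_digests(outdir)
  ), class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

output_digests <- function(outdir) {
  files <- sort(list.files(outdir, pattern = "\\.csv$", full.names = TRUE))
  digests <- as.list(tools::md5sum(files))
  names(digests) <- basename(files)
  digests
}

#' Write a human-readable run report
#'
#' Emits a Markdown summary (class-level percent differences, fraction of
#' significant species, injury-associated species) and a JSON twin of the
#' same content.
#'
#' @param manifest A `run_manifest` from [run_pipeline()].
#' @param outdir The pipeline output directory holding the stage CSVs.
#' @return Paths of the written report files (invisibly).
#' @export
write_report <- function(manifest, outdir) {
  pairwise_path <- file.path(outdir, "pairwise_results.csv")
  anova_path <- file.path(outdir, "anova_results.csv")
  regression_path <- file.path(outdir, "regression_results.csv")

  report <- list(seed = manifest$seed,
                 config_digest = manifest$config_digest,
                 stage_counts = manifest$stage_counts)
  lines <- c("# Pipeline run report", "",
             sprintf("- seed: %s", manifest$seed),
             sprintf("- config digest: %s", manifest$config_digest),
             sprintf("- species retained: %s / %s",
                     manifest$stage_counts$species_retained %||% NA,
                     manifest$stage_counts$species_total %||% NA))

  if (file.exists(pairwise_path)) {
    pw <- readr::read_csv(pairwise_path, show_col_types = FALSE)
    frac <- pw |>
      dplyr::group_by(.data$pair) |>
      dplyr::summarise(fraction_significant = mean(.data$significant),
                       .groups = "drop")
    report$fraction_significant <- frac
    lines <- c(lines, "", "## Significantly altered species", "",
               sprintf("- %s: %.1f%%", frac$pair,
                       100 * frac$fraction_significant))
  }
  if (file.exists(regression_path)) {
    rg <- readr::read_csv(regression_path, show_col_types = FALSE)
    sig <- rg[which(rg$significant), ]
    report$injury_associated <- sig$species
    lines <- c(lines, "", "## Injury-associated species (adjusted p < 0.05)", "",
               if (nrow(sig) == 0L) "- no significant species" else
                 sprintf("- %s (B = %.0f, p = %.3g)", sig$species, sig$B,
                         sig$p))
  } else {
    lines <- c(lines, "", "## Injury-associated species", "",
               "- no significant species")
  }
  md_path <- file.path(outdir, "report.md")
  json_path <- file.path(outdir, "report.json")
  writeLines(lines, md_path)
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows")
  invisible(c(md_path, json_path))
}

#' Is the deposited study data available locally?
#'
#' The headline numbers of the original dataset (species retained after QC,
#' fraction altered within 24 h, class-level percent differences) are only
#' reproducible from the deposited MetaboLights tables, which are not
#' packaged. Regression tests against those numbers activate when the
#' environment variable `LIPIDFLUX_MTBLS3839_DIR` points at a directory
#' containing the downloaded study tables.
#'
#' @return `TRUE` if the directory is set and exists, else `FALSE`.
#' @export
mtbls3839_available <- function() {
  dir <- Sys.getenv("LIPIDFLUX_MTBLS3839_DIR", "")
  nzchar(dir) && dir.exists(dir)
}
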