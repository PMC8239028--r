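# End-to-end orchestration: generate -> threshold -> quantify -> polar ->
# communities -> morphometry, with a validated config, per-stage outputs on
# disk, and a consolidated summary JSON.

#' Assemble a run configuration
#'
#' One master seed fans out to named substreams (cohort, rendering, Louvain
#' runs, neuron batches) so every stage is independently reproducible.
#'
#' @param master_seed integer master seed.
#' @param out_dir output directory for all artifacts.
#' @param groups named integer vector of cohort cases per dominant zone.
#' @param n_terminal_pixels terminal pixels per case per level.
#' @param purity,dispersion,passage_fraction generator parameters (see
#'   [roi_spec()]).
#' @param render if `TRUE`, intensity images are rendered and re-thresholded
#'   so quantification runs on recovered rather than planted pixels.
#' @param threshold_method,threshold_value thresholding stage parameters.
#' @param polar_level ARA level for the angular-density validation.
#' @param bandwidth,grid_step,min_prominence_frac,min_separation polar stage
#'   parameters (degrees; `bandwidth = NULL` means Scott's rule).
#' @param gamma,n_runs community detection parameters.
#' @param morpho_groups neuron roster (see [generate_neuron_cohort()]);
#'   `NULL` for the default.
#' @return List of class `run_config`.
#' @export
run_config <- function(master_seed = 1L,
                       out_dir = file.path(tempdir(), "tectomap-run"),
                       groups = c("SC.m" = 14, "SC.cm" = 8,
                                  "SC.cl" = 24, "SC.l" = 40),
                       n_terminal_pixels = 600,
                       purity = 0.85,
                       dispersion = 4,
                       passage_fraction = 0.10,
                       render = FALSE,
                       threshold_method = "fixed",
                       threshold_value = 100,
                       polar_level = 90,
                       bandwidth = NULL,
                       grid_step = 0.5,
                       min_prominence_frac = 0.10,
                       min_separation = 5,
                       gamma = 1.0,
                       n_runs = 1000,
                       morpho_groups = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Checks all constraints and returns the aggregated list of problems rather
#' than failing on the first.
#'
#' @param config a `run_config`.
#' @return Character vector of error messages (empty when the config is ok).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(is.numeric(config$master_seed) && length(config$master_seed) == 1,
      "master_seed: must be a single integer")
  chk(is.numeric(config$gamma) && config$gamma > 0, "gamma: must be > 0")
  chk(is.numeric(config$n_runs) && config$n_runs >= 1, "n_runs: must be >= 1")
  chk(all(names(config$groups) %in% SC_ZONES) && all(config$groups >= 1),
      "groups: names must be SC zones and counts >= 1")
  chk(config$purity >= 0 && config$purity <= 1, "purity: must lie in [0, 1]")
  chk(config$passage_fraction >= 0 && config$passage_fraction < 1,
      "passage_fraction: must lie in [0, 1)")
  chk(config$dispersion > 0, "dispersion: must be > 0")
  chk(config$n_terminal_pixels >= 0, "n_terminal_pixels: must be >= 0")
  chk(config$threshold_method %in% c("fixed", "percentile"),
      "threshold_method: must be 'fixed' or 'percentile'")
  chk(as.character(config$polar_level) %in% names(.zone_table),
      "polar_level: must be one of the atlas levels")
  chk(config$grid_step > 0, "grid_step: must be > 0")
  chk(config$min_prominence_frac >= 0 && config$min_prominence_frac <= 1,
      "min_prominence_frac: must lie in [0, 1]")
  chk(config$min_separation >= 0, "min_separation: must be >= 0")
  errs
}

# re-derive a case's terminal pixels from its rendered image: threshold, then
# treat the recovered set (terminals plus passage) as the raw labeling with
# the sidecar passage mask still attached
.rethreshold_case <- function(case, atlas, method, value) {
  for (key in names(case$levels)) {
    img <- render_intensity_image(case, atlas[[key]])
    px <- threshold_image(img, method, value)
    case$levels[[key]]$terminal <- px
  }
  case
}

#' Run the full pipeline
#'
#' Executes every stage on a synthetic cohort and writes all intermediate
#' artifacts (atlas JSON, counts and proportion CSVs, density and boundary
#' CSVs, overlap/weight matrices, partition JSON, morphometry CSVs, figures)
#' under `config$out_dir`, plus a consolidated `summary.json`. Idempotent for
#' a fixed master seed.
#'
#' @param config a `run_config`.
#' @param quiet suppress per-stage messages.
#' @return The summary list, invisibly.
#' @export
run_all <- function(config = run_config(), quiet = FALSE) {
  errs <- validate_config(config)
  if (length(errs) > 0)
    stop("invalid config:\n", paste("-", errs, collapse = "\n"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[tectomap] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  say("stage atlas")
  atlas <- stage("atlas", build_default_atlas())
  atlas_to_json(atlas, file.path(out, "atlas.json"))

  say("stage generate (", sum(config$groups), " cases)")
  cspec <- stage("generate", cohort_spec(
    groups = config$groups,
    seed = substream_seed(config$master_seed, "cohort"),
    n_terminal_pixels = config$n_terminal_pixels,
    purity = config$purity, dispersion = config$dispersion,
    passage_fraction = config$passage_fraction))
  cases <- stage("generate", generate_cohort(cspec, atlas))
  assignment <- attr(cases, "group_assignment")

  if (config$render) {
    say("stage threshold (render + recover)")
    cases[] <- stage("threshold", lapply(cases, .rethreshold_case, atlas = atlas,
                                         method = config$threshold_method,
                                         value = config$threshold_value))
  }

  say("stage quantify")
  counts <- stage("quantify", quantify_cohort(cases, atlas))
  utils::write.csv(counts, file.path(out, "compartment_counts.csv"),
                   row.names = FALSE)
  props <- stage("quantify", proportions_table(counts, "zone"))
  utils::write.csv(props, file.path(out, "zone_proportions.csv"),
                   row.names = FALSE)
  plot_proportions(props, file.path(out, "zone_proportions.png"))

  say("stage polar (level ", config$polar_level, ")")
  level <- atlas[[as.character(config$polar_level)]]
  # cap the confined-subset sizes at what the cohort actually provides, so
  # reduced cohorts still exercise the polar stage
  assignment <- attr(cases, "group_assignment")
  default_sizes <- c("SC.m" = 7, "SC.cm" = 4, "SC.cl" = 12, "SC.l" = 20)
  avail <- vapply(names(default_sizes), function(z) sum(assignment == z),
                  integer(1))
  subset <- stage("polar",
                  confined_subset(cases, pmin(default_sizes, avail)))
  avg <- stage("polar", zone_average_densities(
    subset, level, bandwidth = config$bandwidth,
    grid_step = config$grid_step))
  write_densities_csv(avg, file.path(out, "zone_average_densities.csv"))
  plot_densities(avg, file.path(out, "zone_average_densities.png"),
                 level_label = paste("ARA", config$polar_level))
  peaks <- lapply(avg, detect_peaks,
                  min_prominence_frac = config$min_prominence_frac,
                  min_separation = config$min_separation)
  breport <- stage("polar", boundary_report(peaks, level))
  utils::write.csv(breport, file.path(out, "boundary_report.csv"),
                   row.names = FALSE)

  say("stage communities (", config$n_runs, " runs)")
  wmat <- stage("communities", build_weight_matrix(counts, "zone"))
  wnorm <- stage("communities", normalize_totals(wmat))
  utils::write.csv(wnorm, file.path(out, "weight_matrix_normalized.csv"))
  omat <- stage("communities", overlap_matrix(cases))
  utils::write.csv(omat$symmetric, file.path(out, "overlap_matrix.csv"))
  comres <- stage("communities", louvain_consensus(
    omat, gamma = config$gamma, n_runs = config$n_runs,
    master_seed = substream_seed(config$master_seed, "louvain")))
  partition_to_json(comres, file.path(out, "communities.json"))
  reord <- reorder_matrix(omat$symmetric, comres$consensus)
  plot_matrix(reord$matrix, file.path(out, "overlap_matrix_reordered.png"),
              reord$block_boundaries)
  wta <- winner_takes_all(cases, comres$consensus, level)
  utils::write.csv(wta, file.path(out, "winner_takes_all.csv"),
                   row.names = FALSE)
  ari <- adjusted_rand(comres$consensus$membership[names(assignment)],
                       assignment)

  say("stage morphometry")
  morpho <- stage("morphometry", generate_neuron_cohort(
    seed = substream_seed(config$master_seed, "neurons"),
    groups = config$morpho_groups))
  utils::write.csv(morpho, file.path(out, "morphometry.csv"),
                   row.names = FALSE)
  pca <- stage("morphometry", morpho_pca(morpho))
  utils::write.csv(pca$scores, file.path(out, "pca_scores.csv"))
  cmp <- stage("morphometry", group_compare(morpho))
  utils::write.csv(cmp, file.path(out, "group_comparisons.csv"),
                   row.names = FALSE)

  summary <- list(
    master_seed = config$master_seed,
    n_cases = length(cases),
    cases_per_zone = as.list(table(assignment)[SC_ZONES]),
    peak_table = breport,
    n_peaks_aligned = sum(breport$status == "aligned"),
    consensus_n_communities = comres$consensus$n_communities,
    consensus_mode_count = comres$mode_count,
    n_communities_mean = comres$n_communities_mean,
    n_communities_sd = comres$n_communities_sd,
    consensus_modularity = comres$consensus$modularity,
    ari_vs_generator = ari,
    n_significant_morpho = sum(cmp$significant),
    n_morpho_tests = nrow(cmp)
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  say("done: ", out)
  invisible(summary)
}
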