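#' Radar-chart data export
#'
#' Long-format per-pattern mean item scores, directly plottable as radar
#' charts, optionally for two cohorts side by side using a consistency
#' pairing so matched patterns share a row label.
#'
#' @param profiles Profile tibble (exploration cohort).
#' @param profiles_b Optional second profile tibble (validation cohort).
#' @param pairing Optional `pairs` tibble from [profile_consistency()]; when
#'   omitted and `profiles_b` is given the pairing is computed.
#' @return A tibble: `pattern`, `name`, `cohort`, `item`, `mean_score`.
#' @export
export_radar <- function(profiles, profiles_b = NULL, pairing = NULL) {
  long <- function(p, cohort) {
    tidyr::pivot_longer(p[c("pattern", "name", item_names())],
                        cols = all_of(item_names()),
                        names_to = "item", values_to = "mean_score") |>
      mutate(cohort = cohort)
  }
  out <- long(profiles, "exploration")
  if (!is.null(profiles_b)) {
    if (is.null(pairing)) pairing <- profile_consistency(profiles, profiles_b)$pairs
    b <- long(profiles_b, "validation")
    # matched validation patterns inherit the exploration pattern id
    remap <- setNames(pairing$pattern_a, pairing$pattern_b)
    b$pattern <- unname(remap[as.character(b$pattern)])
    out <- bind_rows(out, b[!is.na(b$pattern), ])
  }
  select(out, "pattern", "name", "cohort", "item", "mean_score")
}

#' Run the whole pipeline end to end
#'
#' Simulates (or loads) a cohort, runs discovery, evaluates quality against
#' the K-means and hierarchical baselines, applies the fitted pipeline to an
#' independent validation cohort, fits the association suite, and writes
#' every artifact as CSV into `out_dir` together with a JSON manifest of
#' content hashes, the configuration and per-stage counts. All randomness
#' flows from `seed`; identical configurations produce identical manifests.
#'
#' @param out_dir Output directory (created if needed).
#' @param n,seed Cohort size and master seed for the synthetic cohort.
#' @param cohort Optional pre-built `psy_cohort`; when supplied `n` and
#'   `seed` only control the pipeline stages.
#' @param n_validation Size of the independent validation cohort (0 skips
#'   the transfer stage).
#' @param baselines Evaluate K-means/hierarchical baselines (on the weighted
#'   item representation).
#' @param subgroups Also fit per-surgery-site association suites.
#' @return Invisibly, a list with every in-memory artifact and the manifest.
#' @export
full_run <- function(out_dir, n = 10000, seed = 1L, cohort = NULL,
                     n_validation = ceiling(n / 2), baselines = TRUE,
                     subgroups = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cohort)) cohort <- simulate_cohort(n = n, seed = seed)
  n <- nrow(cohort$items)

  fit <- run_discovery(cohort$items, discovery_config(n, seed = seed))

  quality <- tibble(
    method = "umap_hdbscan",
    k = nrow(fit$profiles),
    silhouette = silhouette_score(as.matrix(fit$embedding[c("u1", "u2")]),
                                  fit$assignment$pattern),
    dunn = dunn_index(as.matrix(fit$embedding[c("u1", "u2")]),
                      fit$assignment$pattern),
    noise_frac = mean(fit$assignment$pattern == NOISE_LABEL),
    space = "embedding")
  if (baselines) {
    weighted <- reweight_items(cohort$items, fit$item_weights)
    base <- baseline_compare(weighted, k_range = 2:8, seed = seed) |>
      mutate(space = "weighted_items")
    quality <- bind_rows(quality, base)
  }

  consistency <- NULL
  radar <- export_radar(fit$profiles)
  if (n_validation > 0) {
    vcoh <- simulate_cohort(n = n_validation, seed = derive_seed(seed, 31L),
                            config = cohort$config)
    val <- validate_cohort(fit, vcoh$items)
    consistency <- val$consistency$pairs
    radar <- export_radar(fit$profiles, val$profiles)
  }

  analysis <- assemble_analysis_table(cohort, fit)
  forest <- run_association_suite(analysis)
  if (subgroups) forest <- bind_rows(forest, subgroup_analyses(analysis))

  files <- list(
    items = cohort$items, covariates = cohort$covariates,
    outcomes = cohort$outcomes, truth = cohort$truth,
    item_clusters = fit$symptom_clusters, weights = fit$item_weights,
    embedding = fit$embedding, assignment = fit$assignment,
    profiles = fit$profiles, quality_report = quality,
    radar = radar, forest = forest)
  if (!is.null(consistency)) files$consistency_report <- consistency
  paths <- character(0)
  for (nm in names(files)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(files[[nm]], p)
    paths[nm] <- p
  }
  manifest <- list(
    seed = seed, n = n, n_validation = n_validation,
    counts = list(
      n_patterns = nrow(fit$profiles),
      n_symptom_clusters = length(unique(fit$symptom_clusters$cluster)),
      n_noise = sum(fit$assignment$pattern == NOISE_LABEL)),
    hashes = as.list(tools::md5sum(unname(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, list(fit = fit, manifest = manifest)))
}
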