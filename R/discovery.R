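#' Discovery pipeline configuration
#'
#' Bundles the two embedding/clustering stages, the merge threshold and the
#' profile-naming margin. Stage-1 (item clustering) uses a 2-neighbour
#' embedding and a density parameter of 2; stage-2 (patient clustering) uses
#' 30 neighbours and a density parameter of 95 at the reference exploration
#' size of 11,376 patients. For other cohort sizes the density and merge
#' parameters scale proportionally: `min_pts = max(5, round(95 n / 11376))`
#' and `min_size = max(10, round(200 n / 11376))`, so the published values are
#' recovered exactly at the reference size.
#'
#' @param n Cohort size the parameters are scaled to.
#' @param seed Integer seed; each stage derives its own child seed.
#' @param stage1_umap,stage2_umap [umap_params()] for the two stages.
#' @param stage1_hdbscan,stage2_hdbscan [hdbscan_params()] for the two stages.
#' @param min_size Merge threshold: smallest surviving patient cluster.
#' @param naming_margin Item-mean excess over the cohort mean required for an
#'   item to feature in a pattern's auto-generated name.
#' @return A list of class `discovery_config`.
#' @export
discovery_config <- function(n, seed = 1L,
                             stage1_umap = umap_params_items(seed = derive_seed(seed, 11L)),
                             stage1_hdbscan = hdbscan_params(min_pts = 2,
                                                             epsilon_rel = 0.1),
                             stage2_umap = umap_params(seed = derive_seed(seed, 12L)),
                             stage2_hdbscan = hdbscan_params(
                               min_pts = max(5L, round(95 * n / 11376))),
                             min_size = max(10L, round(200 * n / 11376)),
                             naming_margin = 0.5) {
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 stage1_umap = stage1_umap, stage1_hdbscan = stage1_hdbscan,
                 stage2_umap = stage2_umap, stage2_hdbscan = stage2_hdbscan,
                 min_size = as.integer(min_size), naming_margin = naming_margin),
            class = "discovery_config")
}

#' Embed questionnaire items (stage 1)
#'
#' Each item is represented as the vector of its z-scored values across
#' patients, so that distance between items reflects their co-occurrence
#' structure and high-prevalence items cannot dominate, then reduced with
#' UMAP.
#'
#' @param items Item tibble (16 item columns, optionally `patient_id`).
#' @param params Stage-1 [umap_params()].
#' @return A tibble with one row per item: `item`, `u1`, `u2`, carrying the
#'   underlying fit in attribute `"umap_fit"`.
#' @export
embed_items <- function(items, params = umap_params_items()) {
  m <- assert_item_matrix(items)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant item (zero variance): ",
                 paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  z <- scale(m)
  fit <- umap_embed(t(z), params)
  out <- bind_cols(tibble(item = colnames(m)), as_tibble(fit$embedding))
  attr(out, "umap_fit") <- fit
  out
}

#' Cluster items into symptom clusters (stage 1)
#'
#' Density clustering of the 16 embedded items. Every item must end up in a
#' cluster — an item labeled noise by the density method is force-assigned to
#' the cluster of its nearest non-noise item, because every item must carry a
#' weight in the reweighting step.
#'
#' With only 16 points, excess-of-mass selection is prone to carving dense
#' item pairs out of a visually obvious clump; the default parameters
#' therefore use a cluster-selection epsilon of 10% of the embedding's root
#' merge distance, which merges such micro-clusters back into their clump
#' while leaving well-separated clumps untouched.
#'
#' @param item_embedding Output of [embed_items()].
#' @param params Stage-1 [hdbscan_params()] (density parameter 2 by default).
#' @return A tibble `item`, `cluster` (1..C).
#' @export
cluster_items <- function(item_embedding,
                          params = hdbscan_params(min_pts = 2, epsilon_rel = 0.1)) {
  pts <- as.matrix(item_embedding[c("u1", "u2")])
  fit <- hdbscan_fit(pts, params)
  lab <- fit$labels
  if (all(lab == NOISE_LABEL)) {
    abort("all items labeled noise; decrease min_pts or revisit the embedding")
  }
  if (any(lab == NOISE_LABEL)) {
    noise <- which(lab == NOISE_LABEL)
    kept <- which(lab != NOISE_LABEL)
    for (i in noise) {
      d <- sqrt(colSums((t(pts[kept, , drop = FALSE]) - pts[i, ])^2))
      lab[i] <- lab[kept[which.min(d)]]
    }
  }
  tibble(item = item_embedding$item, cluster = as.integer(lab))
}

#' Item weights for equal symptom-cluster importance
#'
#' Each item receives weight 1 / (size of its symptom cluster), the minimal
#' rule under which every symptom cluster contributes identical total weight
#' (exactly 1), so clusters defined by many items cannot dominate the
#' patient-level clustering.
#'
#' @param symptom_clusters Tibble `item`, `cluster` from [cluster_items()].
#' @return A tibble `item`, `cluster`, `weight`.
#' @export
compute_item_weights <- function(symptom_clusters) {
  sizes <- table(symptom_clusters$cluster)
  if (any(sizes == 0)) abort("empty symptom cluster")
  mutate(symptom_clusters,
         weight = 1 / as.numeric(sizes[as.character(.data$cluster)]))
}

#' Reweight item scores
#'
#' Column-wise multiplication of the item scores by the item weights.
#'
#' @param items Item tibble.
#' @param weights Tibble with `item` and `weight` columns, or a named numeric
#'   vector covering all 16 items.
#' @return A tibble with `patient_id` (if present) and the 16 weighted
#'   columns.
#' @export
reweight_items <- function(items, weights) {
  if (is.data.frame(weights)) weights <- setNames(weights$weight, weights$item)
  missing_w <- setdiff(item_names(), names(weights))
  if (length(missing_w)) {
    abort(paste0("missing weight for item: ", paste(missing_w, collapse = ", ")))
  }
  out <- items
  for (col in item_names()) out[[col]] <- items[[col]] * weights[[col]]
  out
}

#' Embed and cluster patients (stage 2, pre-merge)
#'
#' Patients are embedded from the reweighted item scores and density-
#' clustered; patients in no dense region are labeled noise (`-1`) rather
#' than force-assigned. Deterministic for a given seed.
#'
#' Because item scores are coarse ordinals, many patients share exact
#' response profiles and the data live on a lattice, which degenerates
#' neighbourhood graphs (a duplicated profile's neighbours are its own
#' copies). Before embedding, each weighted column is therefore dequantised
#' with seeded uniform jitter of one lattice-spacing width — the standard
#' dither treatment of interval-censored scores. The jitter is drawn from
#' the stage seed, so results are reproducible, and it tiles the lattice
#' exactly (no overlap between adjacent score levels).
#'
#' @param weighted Reweighted item tibble from [reweight_items()].
#' @param umap Stage-2 [umap_params()].
#' @param hdbscan Stage-2 [hdbscan_params()].
#' @param dequantize Apply lattice-width uniform dither before embedding.
#' @return A list: `assignment` (tibble `patient_id`, `pattern` with noise =
#'   -1), `embedding` (tibble `patient_id`, `u1`, `u2`), the `umap_fit`, and
#'   the raw cluster `hierarchy` for audit.
#' @export
cluster_patients <- function(weighted, umap = umap_params(),
                             hdbscan = hdbscan_params(), dequantize = TRUE) {
  m <- as.matrix(weighted[item_names()])
  n <- nrow(m)
  if (n <= hdbscan$min_pts) {
    abort(sprintf(
      "cohort size %d is not larger than min_pts %d; scale min_pts down (see discovery_config)",
      n, hdbscan$min_pts))
  }
  if (dequantize) m <- dequantize_columns(m, derive_seed(umap$seed, 13L))
  ufit <- umap_embed(m, umap)
  hfit <- hdbscan_fit(ufit$embedding, hdbscan)
  pid <- if ("patient_id" %in% names(weighted)) weighted$patient_id else seq_len(n)
  list(assignment = tibble(patient_id = pid, pattern = hfit$labels),
       embedding = bind_cols(tibble(patient_id = pid), as_tibble(ufit$embedding)),
       umap_fit = ufit, hdbscan_fit = hfit, hierarchy = hfit$hierarchy)
}

#' Merge undersized patient clusters
#'
#' Iteratively merges the smallest non-noise cluster below `min_size` into its
#' neighbouring cluster — the cluster with the nearest centroid in the stage-2
#' embedding, a proxy for dendrogram adjacency — until every surviving cluster
#' has at least `min_size` patients. Noise is untouched; labels are re-indexed
#' contiguously by decreasing cluster size.
#'
#' @param assignment Tibble `patient_id`, `pattern` (noise = -1).
#' @param embedding Tibble with `u1`, `u2` row-aligned with `assignment`.
#' @param min_size Smallest surviving cluster.
#' @return Assignment tibble of the same shape.
#' @export
merge_small_clusters <- function(assignment, embedding, min_size) {
  lab <- assignment$pattern
  pts <- as.matrix(embedding[c("u1", "u2")])
  repeat {
    sizes <- table(lab[lab != NOISE_LABEL])
    if (length(sizes) <= 1) {
      if (length(sizes) == 1 && sizes[1] < min_size) {
        warn(sprintf("single cluster of size %d below min_size %d; keeping it",
                     sizes[1], min_size))
      }
      break
    }
    small <- sizes[sizes < min_size]
    if (!length(small)) break
    victim <- as.integer(names(small)[which.min(small)])
    cents <- vapply(as.integer(names(sizes)), function(cl) {
      colMeans(pts[lab == cl, , drop = FALSE])
    }, numeric(2))
    others <- setdiff(as.integer(names(sizes)), victim)
    vcent <- cents[, match(victim, as.integer(names(sizes)))]
    d <- vapply(others, function(cl) {
      sum((cents[, match(cl, as.integer(names(sizes)))] - vcent)^2)
    }, numeric(1))
    lab[lab == victim] <- others[which.min(d)]
  }
  keep <- sort(unique(lab[lab != NOISE_LABEL]))
  sizes <- table(factor(lab, levels = keep))
  relabel <- setNames(rank(-as.numeric(sizes), ties.method = "first"), keep)
  new_lab <- ifelse(lab == NOISE_LABEL, NOISE_LABEL,
                    as.integer(relabel[as.character(lab)]))
  tibble(patient_id = assignment$patient_id, pattern = as.integer(new_lab))
}

# Uniform dither of one lattice-spacing width per column; spacing inferred
# from the data (minimum positive gap between distinct values). Constant
# columns are left untouched.
dequantize_columns <- function(m, seed) {
  withr::with_seed(seed, {
    for (j in seq_len(ncol(m))) {
      u <- sort(unique(m[, j]))
      if (length(u) < 2) next
      spacing <- min(diff(u))
      m[, j] <- m[, j] + runif(nrow(m), -spacing / 2, spacing / 2)
    }
    m
  })
}

# clinical shorthand for each questionnaire item, used in pattern names
item_symptom_labels <- function() {
  setNames(c("anhedonia", "depressed mood", "sleep disturbance", "fatigue",
             "eating disturbance", "worthlessness", "poor concentration",
             "psychomotor change", "suicidal ideation",
             "nervousness", "uncontrollable worry", "excessive worry",
             "trouble relaxing", "restlessness", "irritability", "fear"),
           item_names())
}

#' Mean item-score profiles per pattern
#'
#' Per-pattern means of the raw (unweighted) item scores — the radar-chart
#' data. Patterns are auto-named from their most featured items: every item
#' whose pattern mean exceeds the cohort-wide item mean by at least
#' `naming_margin` contributes its clinical label; the pattern with no such
#' item and the lowest total mean score is called "normal psychological
#' functioning". A pattern with featured items spanning nearly the whole
#' instrument (12 or more of the 16) is called "highly combined symptoms".
#'
#' @param assignment Tibble `patient_id`, `pattern` (noise = -1).
#' @param items Raw item tibble, row-aligned.
#' @param naming_margin Elevation threshold in score points (default 0.5).
#' @return A tibble: `pattern`, `name`, `size` and the 16 item means.
#' @export
build_profiles <- function(assignment, items, naming_margin = 0.5) {
  m <- as.matrix(items[item_names()])
  keep <- assignment$pattern != NOISE_LABEL
  if (!any(keep)) abort("no non-noise cluster to profile")
  cohort_mean <- colMeans(m)
  labs <- item_symptom_labels()
  prof <- as_tibble(cbind(pattern = sort(unique(assignment$pattern[keep])))) |>
    mutate(size = 0L)
  means <- matrix(0, nrow(prof), 16, dimnames = list(NULL, item_names()))
  for (r in seq_len(nrow(prof))) {
    rows <- keep & assignment$pattern == prof$pattern[r]
    prof$size[r] <- sum(rows)
    means[r, ] <- colMeans(m[rows, , drop = FALSE])
  }
  featured <- lapply(seq_len(nrow(prof)),
                     function(r) item_names()[means[r, ] >= cohort_mean + naming_margin])
  name <- vapply(seq_len(nrow(prof)), function(r) {
    f <- featured[[r]]
    if (length(f) == 0) return(NA_character_)
    if (length(f) >= 12) return("highly combined symptoms")
    paste(unique(labs[f]), collapse = " and ")
  }, character(1))
  unnamed <- which(is.na(name))
  if (length(unnamed)) {
    lowest <- unnamed[which.min(rowSums(means)[unnamed])]
    name[lowest] <- "normal psychological functioning"
    for (r in setdiff(unnamed, lowest)) {
      name[r] <- paste0("low-severity (", labs[which.max(means[r, ])], ")")
    }
  }
  bind_cols(prof[, "pattern"], tibble(name = name), prof[, "size"], as_tibble(means))
}

#' Run the full two-stage discovery pipeline
#'
#' Executes, in order: item embedding, item clustering, equal-importance
#' reweighting, patient embedding and density clustering, small-cluster
#' merging, and profile building. All intermediate artifacts are retained in
#' the returned object; any stage error is re-raised with the stage name.
#'
#' @param items Item tibble (16 item columns, optionally `patient_id`).
#' @param config A [discovery_config()]; defaults to parameters scaled to the
#'   cohort size.
#' @return An object of class `pattern_discovery` with elements
#'   `item_embedding`, `symptom_clusters`, `item_weights`, `embedding`,
#'   `assignment` (noise = -1), `profiles`, `hierarchy`, `config`, plus the
#'   fitted stage models used by [transform_assign()].
#' @export
#' @examples
#' coh <- simulate_cohort(n = 600, seed = 3)
#' fit <- run_discovery(coh$items)
#' fit$profiles[c("pattern", "name", "size")]
run_discovery <- function(items, config = discovery_config(nrow(items))) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  item_emb <- stage("embed_items", embed_items(items, config$stage1_umap))
  sym <- stage("cluster_items", cluster_items(item_emb, config$stage1_hdbscan))
  w <- stage("compute_item_weights", compute_item_weights(sym))
  weighted <- stage("reweight", reweight_items(items, w))
  pc <- stage("cluster_patients",
              cluster_patients(weighted, config$stage2_umap, config$stage2_hdbscan))
  merged <- stage("merge_small_clusters",
                  merge_small_clusters(pc$assignment, pc$embedding, config$min_size))
  prof <- stage("build_profiles",
                build_profiles(merged, items, config$naming_margin))
  structure(list(items = items, item_embedding = item_emb,
                 symptom_clusters = sym, item_weights = w,
                 embedding = pc$embedding, assignment = merged,
                 assignment_premerge = pc$assignment, profiles = prof,
                 hierarchy = pc$hierarchy, umap_fit = pc$umap_fit,
                 config = config),
            class = "pattern_discovery")
}

#' @export
print.pattern_discovery <- function(x, ...) {
  k <- sum(x$profiles$size > 0)
  n <- nrow(x$assignment)
  n_noise <- sum(x$assignment$pattern == NOISE_LABEL)
  cat("Two-stage pattern discovery\n")
  cat("  patients:", n, " symptom clusters:",
      length(unique(x$symptom_clusters$cluster)),
      " patterns:", k, sprintf(" noise: %d (%.1f%%)\n", n_noise, 100 * n_noise / n))
  for (r in seq_len(nrow(x$profiles))) {
    cat(sprintf("  %d. %-55s n=%d\n", x$profiles$pattern[r],
                x$profiles$name[r], x$profiles$size[r]))
  }
  invisible(x)
}

#' Tidy per-pattern summary of a discovery fit
#'
#' @param x A `pattern_discovery` object.
#' @param ... Unused.
#' @return A tibble: one row per pattern with its name, size, share of the
#'   cohort, and mean PHQ-9/GAD-7 totals.
#' @export
tidy.pattern_discovery <- function(x, ...) {
  n <- nrow(x$assignment)
  mutate(x$profiles,
         share = .data$size / n,
         phq_total = rowSums(across(all_of(paste0("phq", 1:9)))),
         gad_total = rowSums(across(all_of(paste0("gad", 1:7))))) |>
    select("pattern", "name", "size", "share", "phq_total", "gad_total")
}

#' One-row summary of a discovery fit
#'
#' @param x A `pattern_discovery` object.
#' @param ... Unused.
#' @return A tibble with cohort size, numbers of symptom clusters and
#'   patterns, and the noise fraction.
#' @export
glance.pattern_discovery <- function(x, ...) {
  n <- nrow(x$assignment)
  tibble(n = n,
         n_symptom_clusters = length(unique(x$symptom_clusters$cluster)),
         n_patterns = nrow(x$profiles),
         n_noise = sum(x$assignment$pattern == NOISE_LABEL),
         noise_frac = sum(x$assignment$pattern == NOISE_LABEL) / n)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
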