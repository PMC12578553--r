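#' Assign new patients with a fitted discovery pipeline
#'
#' Projects new patients through the fitted stage-2 embedding (stage-1 item
#' weights reused unchanged, dequantisation replayed from the stored stage
#' seed) and assigns each to an existing pattern by a distance-weighted vote
#' among its nearest embedded training patients — an approximate membership
#' prediction in which noise votes count, so new patients may be labeled
#' noise. Applying the pipeline to its own training items reproduces the
#' stored assignment exactly: a training profile projects onto its own
#' embedded coordinates.
#'
#' @param fitted A `pattern_discovery` object from [run_discovery()].
#' @param new_items Item tibble sharing the 16-item schema.
#' @param k Number of embedded training neighbours in the vote.
#' @return A tibble `patient_id`, `pattern` (noise = -1).
#' @export
transform_assign <- function(fitted, new_items, k = 15) {
  stopifnot(inherits(fitted, "pattern_discovery"))
  if (nrow(new_items) == 0) abort("empty input: no patients to assign")
  missing_cols <- setdiff(item_names(), names(new_items))
  if (length(missing_cols)) {
    abort(paste0("schema mismatch; missing item columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  assert_item_matrix(new_items)
  weighted <- reweight_items(new_items, fitted$item_weights)
  m <- as.matrix(weighted[item_names()])
  m <- dequantize_columns(m, derive_seed(fitted$config$stage2_umap$seed, 13L))
  emb_new <- umap_transform(fitted$umap_fit, m)

  emb_train <- as.matrix(fitted$embedding[c("u1", "u2")])
  lab_train <- fitted$assignment$pattern
  k <- min(k, nrow(emb_train))
  nn <- cross_knn(emb_new, emb_train, k)
  w <- 1 / (nn$dist + 1e-12)
  labels <- vapply(seq_len(nrow(emb_new)), function(i) {
    if (nn$dist[i, 1] < 1e-6) return(lab_train[nn$idx[i, 1]]) # exact duplicate
    votes <- tapply(w[i, ], lab_train[nn$idx[i, ]], sum)
    as.integer(names(votes)[which.max(votes)])
  }, integer(1))
  pid <- if ("patient_id" %in% names(new_items)) new_items$patient_id else seq_len(nrow(new_items))
  tibble(patient_id = pid, pattern = labels)
}

# optimal one-to-one pairing maximizing total similarity; exhaustive over
# permutations for small k (<= 8), greedy otherwise
best_pairing <- function(sim) {
  ka <- nrow(sim); kb <- ncol(sim)
  if (ka <= kb && ka <= 8) {
    perms <- gtools_permutations(kb, ka)
    tot <- apply(perms, 1, function(p) sum(sim[cbind(seq_len(ka), p)]))
    cbind(a = seq_len(ka), b = perms[which.max(tot), ])
  } else if (kb < ka && kb <= 8) {
    p <- best_pairing(t(sim))
    cbind(a = p[, "b"], b = p[, "a"])
  } else {
    pairs <- matrix(0L, 0, 2, dimnames = list(NULL, c("a", "b")))
    s <- sim
    for (step in seq_len(min(ka, kb))) {
      ij <- which(s == max(s, na.rm = TRUE), arr.ind = TRUE)[1, ]
      pairs <- rbind(pairs, ij)
      s[ij[1], ] <- NA; s[, ij[2]] <- NA
    }
    pairs
  }
}

# all permutations of k elements taken from n (rows), base R
gtools_permutations <- function(n, k) {
  if (k == 1) return(matrix(seq_len(n), ncol = 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- gtools_permutations(n, k - 1)
    rest <- rest[apply(rest != i, 1, all), , drop = FALSE]
    out <- rbind(out, cbind(i, rest))
  }
  unname(out)
}

#' Consistency of pattern profiles between two cohorts
#'
#' Pairs the patterns of two profile sets one-to-one so that total profile
#' similarity (Pearson correlation over the 16 item means) is maximal, and
#' reports the per-pair correlations, cosine similarities and relative sizes
#' — the quantitative counterpart of overlaying the two cohorts' radar
#' charts.
#'
#' @param profiles_a,profiles_b Profile tibbles from [build_profiles()]
#'   (exploration and validation cohorts).
#' @return A list with `pairs` (tibble: one row per matched pair with
#'   `pattern_a`, `pattern_b`, names, sizes, `r`, `cosine`), `mean_r`, and the
#'   unmatched pattern ids of either set.
#' @export
profile_consistency <- function(profiles_a, profiles_b) {
  if (!nrow(profiles_a) || !nrow(profiles_b)) abort("empty profile set")
  ma <- as.matrix(profiles_a[item_names()])
  mb <- as.matrix(profiles_b[item_names()])
  sim <- suppressWarnings(cor(t(ma), t(mb)))
  sim[!is.finite(sim)] <- 0
  pairs <- best_pairing(sim)
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  out <- tibble(
    pattern_a = profiles_a$pattern[pairs[, "a"]],
    name_a = profiles_a$name[pairs[, "a"]],
    size_a = profiles_a$size[pairs[, "a"]],
    pattern_b = profiles_b$pattern[pairs[, "b"]],
    name_b = profiles_b$name[pairs[, "b"]],
    size_b = profiles_b$size[pairs[, "b"]],
    r = sim[pairs],
    cosine = vapply(seq_len(nrow(pairs)),
                    function(i) cosine(ma[pairs[i, "a"], ], mb[pairs[i, "b"], ]),
                    numeric(1)))
  list(pairs = out, mean_r = mean(out$r),
       unmatched_a = setdiff(profiles_a$pattern, out$pattern_a),
       unmatched_b = setdiff(profiles_b$pattern, out$pattern_b))
}

#' Apply a fitted pipeline to an independent cohort
#'
#' Either projects the new cohort through the fitted model (the default,
#' testing algorithmic transferability) or, with `refit = TRUE`, re-runs the
#' whole discovery pipeline on the new items independently; in both cases the
#' new cohort's pattern profiles are paired against the fitted ones and their
#' consistency quantified.
#'
#' @param fitted A `pattern_discovery` object.
#' @param new_items Item tibble for the validation cohort.
#' @param refit Re-run discovery from scratch instead of projecting.
#' @return A list: `assignment`, `profiles`, and the [profile_consistency()]
#'   report against the fitted profiles.
#' @export
validate_cohort <- function(fitted, new_items, refit = FALSE) {
  if (refit) {
    cfg <- discovery_config(nrow(new_items), seed = fitted$config$seed)
    refit_fit <- run_discovery(new_items, cfg)
    assignment <- refit_fit$assignment
    profiles <- refit_fit$profiles
  } else {
    assignment <- transform_assign(fitted, new_items)
    profiles <- build_profiles(assignment, new_items,
                               fitted$config$naming_margin)
  }
  list(assignment = assignment, profiles = profiles,
       consistency = profile_consistency(fitted$profiles, profiles))
}

#' Save or load a fitted discovery pipeline
#'
#' Serialisation round trip: a reloaded pipeline reproduces identical
#' assignments under [transform_assign()].
#'
#' @param fitted A `pattern_discovery` object.
#' @param path File path.
#' @return `load_pipeline()` returns the `pattern_discovery` object.
#' @export
save_pipeline <- function(fitted, path) {
  stopifnot(inherits(fitted, "pattern_discovery"))
  saveRDS(fitted, path)
  invisible(path)
}

#' @rdname save_pipeline
#' @export
load_pipeline <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "pattern_discovery"))
  obj
}
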