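#' Mean silhouette score
#'
#' For each point, `(b - a) / max(a, b)` where `a` is its mean distance to
#' its own cluster's other members and `b` the smallest mean distance to any
#' other cluster; the score is the mean over points. Noise-labeled points
#' (`-1`) are excluded before computation, and the silhouette of a singleton
#' cluster's point is defined as 0. Computed in row blocks so no full n x n
#' distance matrix is held in memory.
#'
#' @param points Numeric matrix of coordinates (rows are points).
#' @param labels Integer labels, noise = -1.
#' @return A number in `[-1, 1]`.
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  keep <- labels != NOISE_LABEL
  points <- points[keep, , drop = FALSE]
  labels <- labels[keep]
  cl <- sort(unique(labels))
  if (length(cl) < 2) abort("silhouette needs at least two non-noise clusters")
  n <- nrow(points)
  sizes <- as.numeric(table(factor(labels, levels = cl)))
  ind <- outer(labels, cl, "==") * 1 # n x k membership
  sq <- rowSums(points^2)
  sil <- numeric(n)
  block <- max(1L, as.integer(2e7 / n))
  for (s in seq(1, n, by = block)) {
    e <- min(n, s + block - 1)
    d2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(points[s:e, , drop = FALSE], points)
    d2[d2 < 0] <- 0
    dmat <- sqrt(d2)
    sums <- dmat %*% ind # row sums of distance to each cluster
    for (r in seq_len(e - s + 1)) {
      i <- s + r - 1
      ci <- match(labels[i], cl)
      if (sizes[ci] == 1) { sil[i] <- 0; next }
      a <- sums[r, ci] / (sizes[ci] - 1)
      b <- min(sums[r, -ci] / sizes[-ci])
      sil[i] <- (b - a) / max(a, b)
    }
  }
  mean(sil)
}

#' Dunn's index
#'
#' The smallest between-cluster point-pair distance divided by the largest
#' within-cluster diameter. Higher is better; invariant under uniform
#' scaling. Noise-labeled points are excluded.
#'
#' Because the index is a ratio of two extreme distances, the fast expansion
#' identity used for the blocked pairwise pass is followed by an exact
#' recomputation of every near-extreme pair, so the result matches a direct
#' O(n^2) evaluation to full precision even when clusters nearly touch.
#'
#' @inheritParams silhouette_score
#' @return A nonnegative number.
#' @export
dunn_index <- function(points, labels) {
  points <- as.matrix(points)
  keep <- labels != NOISE_LABEL
  points <- points[keep, , drop = FALSE]
  labels <- labels[keep]
  cl <- sort(unique(labels))
  if (length(cl) < 2) abort("Dunn's index needs at least two non-noise clusters")
  n <- nrow(points)
  sq <- rowSums(points^2)
  err <- 1e-9 * (1 + 2 * max(sq)) # generous bound on expansion cancellation
  min_between <- Inf
  max_within <- 0
  block <- max(1L, as.integer(2e7 / n))
  d2_block <- function(s, e) {
    d2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(points[s:e, , drop = FALSE], points)
    d2[d2 < 0] <- 0
    d2[cbind(seq_len(e - s + 1), s:e)] <- NA # self-distances ignored
    d2
  }
  for (s in seq(1, n, by = block)) {
    e <- min(n, s + block - 1)
    d2 <- d2_block(s, e)
    same <- outer(labels[s:e], labels, "==")
    w <- suppressWarnings(max(d2[same], na.rm = TRUE))
    b <- suppressWarnings(min(d2[!same], na.rm = TRUE))
    if (is.finite(w)) max_within <- max(max_within, w)
    if (is.finite(b)) min_between <- min(min_between, b)
  }
  if (max_within == 0) abort("all cluster diameters are zero; Dunn's index undefined")
  # exact pass over the pairs that could be the true extremes
  exact <- function(i, j) sum((points[i, ] - points[j, ])^2)
  min_b <- Inf
  max_w <- 0
  for (s in seq(1, n, by = block)) {
    e <- min(n, s + block - 1)
    d2 <- d2_block(s, e)
    same <- outer(labels[s:e], labels, "==")
    cb <- which(!same & d2 <= min_between + err, arr.ind = TRUE)
    for (r in seq_len(nrow(cb))) {
      min_b <- min(min_b, exact(s + cb[r, 1] - 1, cb[r, 2]))
    }
    cw <- which(same & !is.na(d2) & d2 >= max_within - err, arr.ind = TRUE)
    for (r in seq_len(nrow(cw))) {
      max_w <- max(max_w, exact(s + cw[r, 1] - 1, cw[r, 2]))
    }
  }
  sqrt(min_b) / sqrt(max_w)
}

#' Compare against K-means and hierarchical baselines
#'
#' Fits K-means and agglomerative hierarchical clustering (Ward linkage) for
#' each candidate cluster count and scores both with the silhouette and Dunn
#' metrics on the same matrix, giving the traditional-method comparison table
#' for the representation supplied (raw items, weighted items, or an
#' embedding).
#'
#' @param x Numeric matrix or item tibble.
#' @param k_range Integer vector of cluster counts.
#' @param methods Subset of `c("kmeans", "hierarchical")`.
#' @param seed Seed for K-means initialisation.
#' @return A tibble: `method`, `k`, `silhouette`, `dunn`, `noise_frac` (always
#'   0 for these methods).
#' @export
baseline_compare <- function(x, k_range = 2:8,
                             methods = c("kmeans", "hierarchical"),
                             seed = 1L) {
  if (is.data.frame(x)) x <- as.matrix(x[setdiff(names(x), "patient_id")])
  n <- nrow(x)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) abort("no valid k in k_range")
  hc <- if ("hierarchical" %in% methods) hclust(dist(x), method = "ward.D2")
  rows <- list()
  for (k in k_range) {
    for (m in methods) {
      lab <- if (m == "kmeans") {
        withr::with_seed(derive_seed(seed, 21L + k),
                         kmeans(x, centers = k, nstart = 5, iter.max = 50)$cluster)
      } else {
        cutree(hc, k = k)
      }
      if (length(unique(lab)) < 2) {
        warn(sprintf("%s with k=%d produced a degenerate partition; skipped", m, k))
        next
      }
      rows[[length(rows) + 1]] <- tibble(
        method = m, k = k,
        silhouette = silhouette_score(x, lab),
        dunn = dunn_index(x, lab),
        noise_frac = 0)
    }
  }
  bind_rows(rows)
}

#' Grid search over pipeline hyperparameters
#'
#' Runs the patient-level stage (embedding + density clustering) for every
#' combination in the grid and scores the result on the embedding with the
#' silhouette and Dunn metrics (noise excluded). Ties are broken toward
#' smaller `min_pts`, then smaller `n_neighbors`.
#'
#' @param weighted Reweighted item tibble (stage-2 input).
#' @param n_neighbors,min_pts Candidate values for the stage-2 embedding
#'   neighbourhood and density parameter.
#' @param objective `"silhouette"`, `"dunn"`, or `"combo"` (mean of the
#'   silhouette and the Dunn index capped at 1).
#' @param seed Seed passed to the embedding.
#' @return A list: `best` (one-row tibble) and `trace` (one row per grid
#'   point, including failures with `NA` metrics and the error message).
#' @export
grid_search_params <- function(weighted, n_neighbors = c(15, 30),
                               min_pts = c(50, 95),
                               objective = c("silhouette", "dunn", "combo"),
                               seed = 1L) {
  objective <- match.arg(objective)
  grid <- tidyr::expand_grid(n_neighbors = sort(n_neighbors),
                             min_pts = sort(min_pts))
  rows <- purrr::pmap(grid, function(n_neighbors, min_pts) {
    res <- tryCatch({
      pc <- cluster_patients(weighted,
                             umap = umap_params(n_neighbors = n_neighbors,
                                                seed = derive_seed(seed, 12L)),
                             hdbscan = hdbscan_params(min_pts = min_pts))
      emb <- as.matrix(pc$embedding[c("u1", "u2")])
      lab <- pc$assignment$pattern
      tibble(n_neighbors = n_neighbors, min_pts = min_pts,
             k = length(setdiff(unique(lab), NOISE_LABEL)),
             noise_frac = mean(lab == NOISE_LABEL),
             silhouette = silhouette_score(emb, lab),
             dunn = dunn_index(emb, lab), error = NA_character_)
    }, error = function(e) {
      tibble(n_neighbors = n_neighbors, min_pts = min_pts, k = NA_integer_,
             noise_frac = NA_real_, silhouette = NA_real_, dunn = NA_real_,
             error = conditionMessage(e))
    })
    res
  })
  trace <- bind_rows(rows)
  trace$score <- switch(objective,
    silhouette = trace$silhouette,
    dunn = trace$dunn,
    combo = (trace$silhouette + pmin(trace$dunn, 1)) / 2)
  ok <- !is.na(trace$score)
  if (!any(ok)) {
    abort(paste0("all grid points failed:\n",
                 paste(trace$error[!ok], collapse = "\n")))
  }
  cand <- trace[ok, ]
  cand <- cand[order(-cand$score, cand$min_pts, cand$n_neighbors), ]
  list(best = cand[1, ], trace = trace)
}
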