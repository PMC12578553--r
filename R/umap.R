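#' UMAP parameter set
#'
#' Parameters of the nonlinear embedding stage. The defaults correspond to the
#' patient-level (stage 2) settings; [umap_params_items()] gives the item-level
#' (stage 1) settings, which differ only in `n_neighbors`.
#'
#' @param n_neighbors Size of the local neighbourhood used to build the fuzzy
#'   topological representation (>= 2).
#' @param n_components Output dimensionality.
#' @param n_epochs Number of optimisation epochs.
#' @param min_dist Minimum separation enforced between embedded points.
#' @param negative_rate Negative samples per positive edge sample.
#' @param seed Integer seed for the layout optimiser.
#' @return A list of class `umap_params`.
#' @export
umap_params <- function(n_neighbors = 30, n_components = 2, n_epochs = 500,
                        min_dist = 0.01, negative_rate = 5, seed = 42L) {
  stopifnot(n_neighbors >= 2, n_components >= 1, min_dist >= 0, n_epochs >= 1)
  structure(list(n_neighbors = as.integer(n_neighbors),
                 n_components = as.integer(n_components),
                 n_epochs = as.integer(n_epochs),
                 min_dist = min_dist,
                 negative_rate = as.integer(negative_rate),
                 seed = as.integer(seed)),
            class = "umap_params")
}

#' @rdname umap_params
#' @export
umap_params_items <- function(n_neighbors = 2, n_components = 2, n_epochs = 500,
                              min_dist = 0.01, negative_rate = 5, seed = 42L) {
  umap_params(n_neighbors, n_components, n_epochs, min_dist, negative_rate, seed)
}

# Fit the a, b parameters of the low-dimensional similarity curve
# 1 / (1 + a * d^(2b)) to the piecewise target defined by min_dist, as in the
# reference implementation. Memoised per (min_dist, spread).
find_ab_params <- function(min_dist, spread = 1) {
  key <- paste0("ab_", signif(min_dist, 10), "_", signif(spread, 10))
  if (!is.null(the[[key]])) return(the[[key]])
  xv <- seq(0, spread * 3, length.out = 300)
  yv <- ifelse(xv < min_dist, 1, exp(-(xv - min_dist) / spread))
  fit <- nls(yv ~ 1 / (1 + a * xv^(2 * b)),
             start = list(a = 1.5, b = 0.9),
             control = nls.control(maxiter = 500, warnOnly = TRUE))
  out <- as.list(coef(fit))
  the[[key]] <- out
  out
}

# Smooth-kNN weight calibration: for each point find sigma_i (binary search)
# such that sum_j exp(-max(0, d_ij - rho_i) / sigma_i) = log2(k), with rho_i
# the distance to the nearest neighbour.
smooth_knn_weights <- function(knn_dist, n_iter = 64, tol = 1e-5) {
  k <- ncol(knn_dist)
  target <- log2(k)
  rho <- knn_dist[, 1]
  lo <- rep(0, nrow(knn_dist))
  hi <- rep(Inf, nrow(knn_dist))
  mid <- rep(1, nrow(knn_dist))
  d <- pmax(knn_dist - rho, 0)
  for (iter in seq_len(n_iter)) {
    val <- rowSums(exp(-d / mid))
    done <- abs(val - target) < tol
    if (all(done)) break
    up <- val > target
    hi[up & !done] <- mid[up & !done]
    lo[!up & !done] <- mid[!up & !done]
    mid[!done] <- ifelse(is.finite(hi[!done]),
                         (lo[!done] + hi[!done]) / 2,
                         mid[!done] * 2)
  }
  w <- exp(-d / mid)
  w[knn_dist == 0] <- 1 # duplicates always fully connected
  w
}

#' Embed points with UMAP
#'
#' A self-contained implementation of the UMAP algorithm: exact kNN graph,
#' smooth-kNN weight calibration, fuzzy simplicial-set union, and stochastic
#' gradient layout optimisation with negative sampling. The layout is
#' initialised from a scaled PCA (plus seeded jitter), runs single-threaded,
#' and is fully deterministic for a given seed.
#'
#' With `dedupe = TRUE` (the default) exact duplicate rows are collapsed
#' before the graph is built and re-expanded afterwards, duplicates sharing
#' the embedded coordinates of their representative. On heavily discretised
#' data (ordinal questionnaire items) duplicate multiplicities can exceed
#' `n_neighbors`, in which case a duplicated profile's neighbour list is
#' entirely its own copies and the graph disconnects; collapsing removes the
#' pathology while downstream density clustering still sees multiplicity
#' through coincident points.
#'
#' @param x Numeric matrix, rows are points.
#' @param params A [umap_params()] object.
#' @param dedupe Collapse exact duplicate rows for graph construction.
#' @return A list with `embedding` (n x n_components matrix), plus the kNN
#'   graph over distinct rows and the fitted curve parameters, so new
#'   points can later be projected with [umap_transform()].
#' @export
umap_embed <- function(x, params = umap_params(), dedupe = TRUE) {
  x_full <- as.matrix(x)
  if (nrow(x_full) <= params$n_neighbors) {
    abort(sprintf("need more points (%d) than n_neighbors (%d)",
                  nrow(x_full), params$n_neighbors))
  }
  if (dedupe) {
    key <- apply(x_full, 1, paste, collapse = "\r")
    first <- !duplicated(key)
    x <- x_full[first, , drop = FALSE]
    map <- match(key, key[first])
  } else {
    x <- x_full
    map <- seq_len(nrow(x_full))
  }
  n <- nrow(x)
  k <- min(params$n_neighbors, n - 1L)
  knn <- cpp_knn(x, k)
  w <- smooth_knn_weights(knn$dist)

  p <- Matrix::sparseMatrix(
    i = rep(seq_len(n), times = k),
    j = as.vector(knn$idx),
    x = as.vector(w),
    dims = c(n, n)
  )
  graph <- p + Matrix::t(p) - p * Matrix::t(p) # probabilistic t-conorm union
  tr <- Matrix::summary(graph)
  keep <- tr$x >= max(tr$x) / params$n_epochs
  tr <- tr[keep, , drop = FALSE]
  eps <- max(tr$x) / tr$x # epochs between samples of each edge

  ab <- find_ab_params(params$min_dist)

  # deterministic init: PCA scaled to a 10-unit box + tiny seeded jitter
  init <- withr::with_seed(params$seed, {
    pc <- prcomp(x, rank. = params$n_components, center = TRUE, scale. = FALSE)$x
    if (ncol(pc) < params$n_components) {
      pc <- cbind(pc, matrix(0, n, params$n_components - ncol(pc)))
    }
    span <- max(abs(pc))
    if (span > 0) pc <- pc / span * 10
    pc + matrix(rnorm(length(pc), sd = 1e-4), n)
  })

  emb <- cpp_umap_optimize(init,
                           head = tr$i - 1L, tail = tr$j - 1L,
                           epochs_per_sample = eps,
                           a = ab$a, b = ab$b, gamma = 1,
                           n_epochs = params$n_epochs,
                           negative_rate = params$negative_rate,
                           initial_alpha = 1, seed = params$seed,
                           move_other = TRUE)
  colnames(emb) <- paste0("u", seq_len(params$n_components))
  full <- emb[map, , drop = FALSE]
  rownames(full) <- NULL
  list(embedding = full, unique_embedding = emb, data = x, map = map,
       knn_idx = knn$idx, knn_dist = knn$dist, params = params, ab = ab)
}

#' Project new points into a fitted embedding
#'
#' Places each new point at the smooth-kNN-weighted average of the embedded
#' coordinates of its nearest training points (the initialisation step of the
#' reference transform). An exact duplicate of a training point lands exactly
#' on that point's coordinates.
#'
#' @param fit Result of [umap_embed()].
#' @param x_new Numeric matrix with the same columns as the training data.
#' @return Matrix of embedded coordinates for the new points.
#' @export
umap_transform <- function(fit, x_new) {
  x_new <- as.matrix(x_new)
  if (ncol(x_new) != ncol(fit$data)) {
    abort("new data must have the same columns as the training data")
  }
  k <- min(fit$params$n_neighbors, nrow(fit$data))
  nn <- cross_knn(x_new, fit$data, k)
  w <- smooth_knn_weights(nn$dist)
  # exact matches take all the weight (tolerance absorbs float fuzz in the
  # blocked distance computation)
  exact <- nn$dist[, 1] < 1e-6
  if (any(exact)) {
    w[exact, ] <- 0
    w[exact, 1] <- 1
  }
  w <- w / rowSums(w)
  emb <- fit$unique_embedding
  out <- matrix(0, nrow(x_new), ncol(emb))
  for (m in seq_len(k)) {
    out <- out + w[, m] * emb[nn$idx[, m], , drop = FALSE]
  }
  colnames(out) <- colnames(emb)
  out
}

# kNN of rows of `query` among rows of `ref` (brute force, self not excluded)
cross_knn <- function(query, ref, k) {
  nq <- nrow(query)
  idx <- matrix(0L, nq, k)
  dmat <- matrix(0, nq, k)
  # process in blocks to bound memory
  block <- max(1L, as.integer(2e7 / nrow(ref)))
  for (s in seq(1, nq, by = block)) {
    e <- min(nq, s + block - 1)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rowSums(ref^2), "+") - 2 * tcrossprod(q, ref)
    d2[d2 < 0] <- 0
    for (r in seq_len(nrow(q))) {
      o <- order(d2[r, ])[seq_len(k)]
      idx[s + r - 1, ] <- o
      dmat[s + r - 1, ] <- sqrt(d2[r, o])
    }
  }
  list(idx = idx, dist = dmat)
}
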