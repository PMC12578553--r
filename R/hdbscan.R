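#' HDBSCAN parameter set
#'
#' The published pipeline reports a single `min_pts` density parameter per
#' stage; following classic DBSCAN* semantics it is mapped onto both the
#' minimum cluster size and the core-point neighbourhood count, each
#' independently overridable.
#'
#' @param min_pts Density parameter (>= 2).
#' @param min_cluster_size Smallest condensed cluster retained; defaults to
#'   `min_pts`.
#' @param min_samples Neighbourhood count defining the core distance;
#'   defaults to `min_pts`.
#' @param epsilon_rel Cluster-selection epsilon, expressed as a fraction of
#'   the hierarchy's root merge distance. Excess-of-mass selection on very
#'   few points favours micro-clusters; a positive epsilon merges selected
#'   clusters that split off below that distance into their ancestors
#'   (Malzer-Baum cluster selection). 0 disables it.
#' @return A list of class `hdbscan_params`.
#' @export
hdbscan_params <- function(min_pts = 95, min_cluster_size = min_pts,
                           min_samples = min_pts, epsilon_rel = 0) {
  stopifnot(min_pts >= 2, min_cluster_size >= 2, min_samples >= 2,
            epsilon_rel >= 0, epsilon_rel < 1)
  structure(list(min_pts = as.integer(min_pts),
                 min_cluster_size = as.integer(min_cluster_size),
                 min_samples = as.integer(min_samples),
                 epsilon_rel = epsilon_rel),
            class = "hdbscan_params")
}

#' Hierarchical density-based clustering with noise (HDBSCAN)
#'
#' A self-contained implementation: core distances from the exact kNN graph,
#' minimum spanning tree of the mutual-reachability graph, single-linkage
#' hierarchy, tree condensation at `min_cluster_size`, and excess-of-mass
#' cluster selection. Points never attached to a selected cluster are labeled
#' noise (`-1`).
#'
#' @param points Numeric matrix, rows are points (typically an embedding).
#' @param params An [hdbscan_params()] object.
#' @param allow_single_cluster Whether the hierarchy root may be selected.
#' @return A list with integer `labels` (1..k, noise = -1), the single-linkage
#'   `hierarchy` (merge table, scipy-style), the condensed tree, per-cluster
#'   stabilities and the core distances.
#' @export
hdbscan_fit <- function(points, params = hdbscan_params(),
                        allow_single_cluster = FALSE) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n <= params$min_samples) {
    abort(sprintf(
      "need more points (%d) than min_samples (%d); scale min_pts to the cohort size",
      n, params$min_samples))
  }
  knn <- cpp_knn(points, params$min_samples - 1L)
  core <- if (params$min_samples == 2L) knn$dist[, 1] else knn$dist[, params$min_samples - 1L]
  mst <- cpp_mreach_mst(points, core)
  hierarchy <- single_linkage(mst, n)
  cond <- condense_tree(hierarchy, n, params$min_cluster_size)
  eps <- params$epsilon_rel * max(hierarchy[, "dist"])
  sel <- eom_select(cond, allow_single_cluster, epsilon = eps)
  labels <- condensed_labels(cond, sel$selected, n)
  list(labels = labels, hierarchy = hierarchy, condensed = cond,
       stability = sel$stability, selected = sel$selected, core_dist = core)
}

# Single-linkage dendrogram from sorted MST edges via union-find.
# Returns a (n-1) x 4 matrix: child1, child2, dist, size; node ids are
# 1..n for points and n+i for the i-th merge.
single_linkage <- function(mst, n) {
  o <- order(mst$dist)
  from <- mst$from[o]; to <- mst$to[o]; d <- mst$dist[o]
  parent <- seq_len(2L * n - 1L)
  sizes <- c(rep(1L, n), integer(n - 1L))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  out <- matrix(0, n - 1L, 4L,
                dimnames = list(NULL, c("child1", "child2", "dist", "size")))
  for (m in seq_len(n - 1L)) {
    ra <- find(from[m]); rb <- find(to[m])
    node <- n + m
    sizes[node] <- sizes[ra] + sizes[rb]
    parent[ra] <- node; parent[rb] <- node
    out[m, ] <- c(ra, rb, d[m], sizes[node])
  }
  out
}

# Condense the single-linkage tree: walking from the root, a split where both
# children reach min_cluster_size creates two new condensed clusters; smaller
# children "fall out" of the current cluster, their leaf points leaving at the
# split's lambda = 1/distance. Returns the condensed tree in long form plus
# per-cluster birth lambdas and the cluster parent links.
condense_tree <- function(hierarchy, n, min_cluster_size) {
  n_nodes <- 2L * n - 1L
  child1 <- c(rep(NA_integer_, n), as.integer(hierarchy[, 1]))
  child2 <- c(rep(NA_integer_, n), as.integer(hierarchy[, 2]))
  ndist <- c(rep(0, n), hierarchy[, 3])
  nsize <- c(rep(1L, n), as.integer(hierarchy[, 4]))

  leaves_under <- function(node) {
    acc <- integer(0)
    stack <- node
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (v <= n) acc[length(acc) + 1L] <- v
      else stack <- c(stack, child1[v], child2[v])
    }
    acc
  }

  max_rows <- 3L * n
  r_parent <- integer(max_rows); r_child <- integer(max_rows)
  r_lambda <- numeric(max_rows); r_size <- integer(max_rows)
  r_is_cluster <- logical(max_rows)
  nr <- 0L
  add_row <- function(p, ch, lam, sz, is_cl) {
    nr <<- nr + 1L
    r_parent[nr] <<- p; r_child[nr] <<- ch
    r_lambda[nr] <<- lam; r_size[nr] <<- sz; r_is_cluster[nr] <<- is_cl
  }

  cl_parent <- integer(0); cl_birth <- numeric(0)
  new_cluster <- function(parent_id, birth) {
    cl_parent[length(cl_parent) + 1L] <<- parent_id
    cl_birth[length(cl_birth) + 1L] <<- birth
    length(cl_parent)
  }
  root_cl <- new_cluster(0L, 0)

  stack_node <- n_nodes; stack_cl <- root_cl
  while (length(stack_node)) {
    v <- stack_node[length(stack_node)]; cid <- stack_cl[length(stack_cl)]
    stack_node <- stack_node[-length(stack_node)]
    stack_cl <- stack_cl[-length(stack_cl)]
    # descend along "large child" chains without recursion
    repeat {
      if (v <= n) { # a bare point at the top of a cluster: it falls out at birth
        add_row(cid, v, cl_birth[cid], 1L, FALSE)
        break
      }
      l <- child1[v]; r <- child2[v]
      lam <- 1 / max(ndist[v], 1e-12)
      big_l <- nsize[l] >= min_cluster_size
      big_r <- nsize[r] >= min_cluster_size
      if (big_l && big_r) {
        cl <- new_cluster(cid, lam)
        cr <- new_cluster(cid, lam)
        add_row(cid, -cl, lam, nsize[l], TRUE)
        add_row(cid, -cr, lam, nsize[r], TRUE)
        stack_node <- c(stack_node, r); stack_cl <- c(stack_cl, cr)
        v <- l; cid <- cl
      } else if (big_l || big_r) {
        small <- if (big_l) r else l
        for (p in leaves_under(small)) add_row(cid, p, lam, 1L, FALSE)
        v <- if (big_l) l else r
      } else {
        for (p in c(leaves_under(l), leaves_under(r))) add_row(cid, p, lam, 1L, FALSE)
        break
      }
    }
  }
  idx <- seq_len(nr)
  list(parent = r_parent[idx], child = r_child[idx], lambda = r_lambda[idx],
       size = r_size[idx], is_cluster = r_is_cluster[idx],
       cluster_parent = cl_parent, cluster_birth = cl_birth)
}

# Excess-of-mass cluster selection over the condensed tree, with optional
# epsilon-based promotion: a selected cluster that split off at a merge
# distance below `epsilon` is replaced by its lowest ancestor that split off
# at or above it.
eom_select <- function(cond, allow_single_cluster = FALSE, epsilon = 0) {
  n_cl <- length(cond$cluster_parent)
  stability <- numeric(n_cl)
  contrib <- (cond$lambda - cond$cluster_birth[cond$parent]) * cond$size
  agg <- tapply(contrib, cond$parent, sum)
  stability[as.integer(names(agg))] <- as.numeric(agg)

  children <- split(seq_len(n_cl)[-1], cond$cluster_parent[-1])
  score <- stability
  selected <- logical(n_cl)
  for (cid in rev(seq_len(n_cl))) {
    kids <- children[[as.character(cid)]]
    if (is.null(kids)) {
      selected[cid] <- !(cid == 1L && !allow_single_cluster)
      next
    }
    kid_total <- sum(score[kids])
    if ((cid == 1L && !allow_single_cluster) || kid_total > stability[cid]) {
      score[cid] <- kid_total
      selected[cid] <- FALSE
    } else {
      selected[cid] <- TRUE
    }
  }
  if (epsilon > 0 && any(selected)) {
    # birth distance of a cluster = 1 / birth lambda (root: infinite)
    birth_dist <- ifelse(cond$cluster_birth > 0, 1 / cond$cluster_birth, Inf)
    for (cid in which(selected)) {
      if (birth_dist[cid] >= epsilon) next
      p <- cid
      while (cond$cluster_parent[p] != 0L && birth_dist[p] < epsilon) {
        p <- cond$cluster_parent[p]
      }
      if (p == 1L && !allow_single_cluster) {
        # stop just below the root
        q <- cid
        while (cond$cluster_parent[q] != 1L) q <- cond$cluster_parent[q]
        p <- q
      }
      selected[cid] <- FALSE
      selected[p] <- TRUE
    }
  }
  # a selected ancestor silences all descendants
  for (cid in seq_len(n_cl)[-1]) {
    p <- cond$cluster_parent[cid]
    while (p != 0L) {
      if (selected[p]) { selected[cid] <- FALSE; break }
      p <- cond$cluster_parent[p]
    }
  }
  list(stability = stability, selected = selected)
}

# Point labels from the condensed tree and the selected cluster set.
condensed_labels <- function(cond, selected, n) {
  n_cl <- length(cond$cluster_parent)
  # nearest selected ancestor-or-self per condensed cluster (0 = none)
  anc <- integer(n_cl)
  for (cid in seq_len(n_cl)) {
    p <- cid
    while (p != 0L && !selected[p]) p <- cond$cluster_parent[p]
    anc[cid] <- p
  }
  sel_ids <- which(selected)
  relabel <- integer(n_cl)
  relabel[sel_ids] <- seq_along(sel_ids)
  labels <- rep(NOISE_LABEL, n)
  pts <- !cond$is_cluster
  owner <- anc[cond$parent[pts]]
  lab <- ifelse(owner == 0L, NOISE_LABEL, relabel[pmax(owner, 1L)])
  labels[cond$child[pts]] <- lab
  labels
}
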