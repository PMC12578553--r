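# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# a small cohort + fitted pipeline shared by several test files
small_cohort <- function() cached("coh", simulate_cohort(n = 1500, seed = 42))

small_fit <- function() cached("fit", {
  coh <- small_cohort()
  run_discovery(coh$items, discovery_config(nrow(coh$items), seed = 42))
})

analysis_table <- function() cached("assoc_tab", {
  assemble_analysis_table(small_cohort(), small_fit())
})

# brute-force O(n^2) cluster-metric oracles, straight from the definitions
brute_silhouette <- function(points, labels) {
  points <- as.matrix(points)
  keep <- labels != -1
  points <- points[keep, , drop = FALSE]
  labels <- labels[keep]
  n <- nrow(points)
  d <- as.matrix(dist(points))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(d[i, labels == cl]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

brute_dunn <- function(points, labels) {
  points <- as.matrix(points)
  keep <- labels != -1
  points <- points[keep, , drop = FALSE]
  labels <- labels[keep]
  d <- as.matrix(dist(points))
  n <- nrow(points)
  min_between <- Inf
  max_within <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (labels[i] == labels[j]) max_within <- max(max_within, d[i, j])
      else min_between <- min(min_between, d[i, j])
    }
  }
  min_between / max_within
}

# random labeled point sets for metric oracle checks
random_metric_instance <- function(seed) {
  withr::with_seed(seed, {
    k <- sample(2:5, 1)
    n <- sample(20:200, 1)
    dims <- sample(1:3, 1)
    centers <- matrix(runif(k * dims, -10, 10), k)
    lab <- sample(seq_len(k), n, replace = TRUE)
    pts <- centers[lab, , drop = FALSE] + matrix(rnorm(n * dims), n)
    list(points = pts, labels = lab)
  })
}
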