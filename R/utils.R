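#' Derive a per-stage child seed from a single run seed
#'
#' All randomness in the package flows from one integer seed; each pipeline
#' stage draws from its own child seed so stages are independently
#' reproducible. Child seeds stay below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param stage Integer stage index (>= 0).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stage))
  as.integer((abs(as.numeric(seed)) * 7919 + as.numeric(stage) * 104729) %% 2147483647)
}

#' Adjusted Rand index between two labelings
#'
#' Thin wrapper over [mclust::adjustedRandIndex()] returning the
#' chance-corrected agreement between two partitions.
#'
#' @param a,b Label vectors of equal length.
#' @return A number, 1 for identical partitions (up to relabeling).
#' @export
ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

#' @noRd
assert_item_matrix <- function(items, call = rlang::caller_env()) {
  missing_cols <- setdiff(item_names(), names(items))
  if (length(missing_cols) > 0) {
    abort(paste0("item columns missing: ", paste(missing_cols, collapse = ", ")),
          call = call)
  }
  m <- as.matrix(items[item_names()])
  if (anyNA(m)) abort("item scores contain missing values", call = call)
  bad <- !(m %in% 0:3)
  if (any(bad)) {
    abort("item scores must be integers in 0..3", call = call)
  }
  storage.mode(m) <- "double"
  m
}

#' @noRd
item_names <- function() {
  c(paste0("phq", 1:9), paste0("gad", 1:7))
}

# label used for density-clustering noise throughout the package
NOISE_LABEL <- -1L
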