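#' Sliding-window removal of identical markers
#'
#' Scans markers left to right in genomic column order; marker j is
#' eliminated when some *surviving* marker i with j - w <= i < j has an
#' identical column (every individual carries the same code at both).
#' Comparing against survivors (rather than all predecessors) makes the
#' result a fixed point: in original marker order, no two survivors within
#' the window are identical, so rescanning the survivors at their original
#' positions removes nothing further. (Distances are positional: compacting
#' the matrix first would move once-distant columns into the window.)
#'
#' @param genotypes Integer matrix (individuals x markers).
#' @param w Window width (compare each marker with the next `w` markers).
#'   Default 8: redundant-pair counts stabilize at that width on dense panels.
#' @return A `gp_selection` with the surviving column indices.
#' @export
window_dedup <- function(genotypes, w = 8L) {
  stopifnot(w >= 1L)
  m <- ncol(genotypes)
  # hash columns so the window comparison is a string equality
  keys <- column_keys(genotypes)
  keep <- logical(m)
  for (j in seq_len(m)) {
    lo <- max(1L, j - w)
    window <- if (j == 1L) integer(0) else (lo:(j - 1L))
    window <- window[keep[window]]
    keep[j] <- !any(keys[window] == keys[j])
  }
  new_gp_selection(which(keep), method = "window_dedup",
                   params = list(w = as.integer(w)))
}

#' Count redundant marker pairs within a window
#'
#' Number of ordered-position pairs (i, j) with i < j <= i + w whose columns
#' are identical. Non-decreasing in `w`; the width at which the count
#' stabilizes indicates how local exact redundancy is.
#'
#' @inheritParams window_dedup
#' @return Integer count.
#' @export
count_redundant_pairs <- function(genotypes, w = 8L) {
  stopifnot(w >= 1L)
  m <- ncol(genotypes)
  keys <- column_keys(genotypes)
  total <- 0L
  for (i in seq_len(m - 1L)) {
    js <- (i + 1L):min(m, i + w)
    total <- total + sum(keys[js] == keys[i])
  }
  total
}

column_keys <- function(genotypes) {
  apply(genotypes, 2L, paste, collapse = "\r")
}

#' Mutual-information marker ranking
#'
#' Scores each marker by the plug-in (empirical joint histogram) mutual
#' information between its discrete codes and the trait discretized into
#' `bins` equal-frequency bins, then keeps the `k` top-scoring markers.
#' The estimator is fully deterministic; ties are broken toward the lower
#' original column index so selections are reproducible.
#'
#' @param genotypes Integer matrix (individuals x markers).
#' @param trait Numeric vector aligned with rows of `genotypes` (fit this on
#'   the training fold only).
#' @param k Number of markers to keep; clipped (with a warning) to the number
#'   of available markers.
#' @param bins Number of equal-frequency trait bins for the estimator.
#' @return A `gp_selection` with `kept_indices` and the full `scores` vector
#'   (nats).
#' @export
mi_rank <- function(genotypes, trait, k, bins = 10L) {
  stopifnot(k >= 1L, bins >= 2L)
  if (length(trait) != nrow(genotypes))
    stop("trait is not aligned with genotype rows")
  m <- ncol(genotypes)
  if (k > m) {
    warning("k = ", k, " exceeds ", m, " available markers; clipping")
    k <- m
  }
  yb <- equal_freq_bin(trait, bins)
  scores <- vapply(seq_len(m),
                   function(j) mutual_info_disc(genotypes[, j], yb),
                   numeric(1L))
  ord <- order(-scores, seq_len(m))  # ties -> lower index first
  kept <- sort(ord[seq_len(k)])
  new_gp_selection(kept, method = "mutual_info", scores = scores,
                   params = list(k = as.integer(k), bins = as.integer(bins)))
}

# equal-frequency discretization: rank-based so repeated trait values land in
# one bin; returns integer bin labels
equal_freq_bin <- function(x, bins) {
  qs <- stats::quantile(x, probs = seq_len(bins - 1L) / bins,
                        type = 7, names = FALSE)
  findInterval(x, unique(qs)) + 1L
}

# plug-in MI (nats) between two discrete labellings
mutual_info_disc <- function(x, y) {
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
}

#' Random marker selection
#'
#' Uniform sample of `k` marker positions without replacement, reproducible
#' from `seed`. Used as the baseline against informed (mutual-information)
#' selection.
#'
#' @param n_markers Total marker count.
#' @param k Number to select, `1 <= k <= n_markers`.
#' @param seed Integer seed.
#' @return A `gp_selection`.
#' @export
random_select <- function(n_markers, k, seed) {
  if (k < 1L || k > n_markers)
    stop("parameter error: k must be in [1, n_markers]")
  kept <- withr::with_seed(seed, sort(sample.int(n_markers, k)))
  new_gp_selection(kept, method = "random",
                   params = list(k = as.integer(k), seed = as.integer(seed)))
}

new_gp_selection <- function(kept, method, scores = NULL, params = list()) {
  structure(list(kept_indices = as.integer(kept), method = method,
                 scores = scores, params = params),
            class = "gp_selection")
}

#' @export
print.gp_selection <- function(x, ...) {
  cat(sprintf("<gp_selection> %s: %d markers kept\n",
              x$method, length(x$kept_indices)))
  invisible(x)
}

#' Tidy a marker selection
#'
#' @param x A `gp_selection`.
#' @param ... Unused.
#' @return A tibble with `marker` (original column index), `kept`, and
#'   `score` (NA unless the method produced scores).
#' @exportS3Method generics::tidy
tidy.gp_selection <- function(x, ...) {
  n <- if (!is.null(x$scores)) length(x$scores) else max(x$kept_indices)
  tibble::tibble(
    marker = seq_len(n),
    kept = seq_len(n) %in% x$kept_indices,
    score = if (is.null(x$scores)) NA_real_ else x$scores)
}

#' Serialize / restore a marker selection as JSON
#'
#' @param x A `gp_selection`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_selection()` returns the restored
#'   `gp_selection`.
#' @export
write_selection <- function(x, path) {
  jsonlite::write_json(
    list(method = x$method, params = x$params,
         kept_indices = x$kept_indices, scores = x$scores),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_gp_selection(o$kept_indices, method = o$method,
                   scores = o$scores, params = as.list(o$params))
}
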