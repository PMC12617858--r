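#' Select reference instances at random
#'
#' Draws the indices of the reference instances — the training-fold
#' (genotype, phenotype) pairs an ensemble prediction averages over — as a
#' uniform sample without replacement of size
#' `max(1, round(fraction * train_size))` (round half away from zero).
#'
#' @param train_size Training-fold size.
#' @param fraction Fraction of the training fold to keep, in (0, 1].
#' @param seed Integer seed; identical seeds give identical selections.
#' @return Sorted integer indices into the training fold.
#' @export
select_references_random <- function(train_size, fraction, seed) {
  check_fraction(fraction)
  stopifnot(train_size >= 1L)
  k <- reference_count(train_size, fraction)
  withr::with_seed(seed, sort(sample.int(train_size, k)))
}

#' Per-candidate mean squared error profile over the training fold
#'
#' For each training instance j acting as the reference, the mean squared
#' error of predicting every other training instance i from the pair
#' (obscured(g_i, g_j), y_j). Candidates with low profile values predict the
#' rest of the training fold well and are preferred by the targeted
#' selection strategy. The self pair (i = j) is excluded.
#'
#' @param model A trained [obscured_net()] (trained on this training fold).
#' @param genotypes Training-fold marker matrix restricted to the model's
#'   active features.
#' @param phenotypes Standardized training-fold trait values.
#' @return Numeric vector of length `nrow(genotypes)`.
#' @export
reference_mse_profile <- function(model, genotypes, phenotypes) {
  n <- nrow(genotypes)
  if (n < 2L)
    stop("undefined profile: need at least 2 training instances")
  if (length(phenotypes) != n) stop("phenotypes not aligned with genotypes")
  pairs <- pair_dataset(genotypes, phenotypes, include_self = FALSE,
                        ordered = TRUE)
  mat <- pair_design(pairs)
  pred <- predict_model_pairs(model, mat)
  sqerr <- (pred - mat$target)^2
  # average over queries i for each reference j
  as.vector(tapply(sqerr, factor(mat$pair_index$ref, levels = seq_len(n)),
                   mean))
}

# dispatch point so tests can exercise ensemble arithmetic with stub models
predict_model_pairs <- function(model, mat) {
  if (inherits(model, "obscured_net"))
    predict_pair(model, mat$bits, mat$y_ref)
  else if (is.function(model))
    model(mat)  # stub: function of the materialized design
  else stop("unsupported model object")
}

#' Select reference instances by training-set prediction accuracy
#'
#' Keeps the `max(1, round(fraction * n))` candidates with the lowest mean
#' MSE profile (ties broken toward the lower index).
#'
#' @param mse_profile Vector from [reference_mse_profile()].
#' @param fraction Fraction in (0, 1].
#' @return Sorted integer indices into the training fold.
#' @export
select_references_targeted <- function(mse_profile, fraction) {
  check_fraction(fraction)
  if (!all(is.finite(mse_profile))) stop("non-finite MSE profile")
  n <- length(mse_profile)
  k <- reference_count(n, fraction)
  sort(order(mse_profile, seq_len(n))[seq_len(k)])
}

#' Assemble a reference set
#'
#' A reference set is fixed after construction: its (genotype, phenotype)
#' pairs are internal to the ensemble and do not vary with the query input.
#'
#' @param indices Training-fold positions of the chosen references.
#' @param genotypes Training-fold marker matrix (active features).
#' @param phenotypes Standardized training-fold trait values.
#' @param strategy One of `"all"`, `"random"`, `"targeted"`.
#' @param fraction Fraction used to choose `indices`.
#' @param seed Seed used (random strategy), or `NULL`.
#' @param mse_scores Full MSE profile (targeted strategy), or `NULL`.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(indices, genotypes, phenotypes,
                          strategy = c("all", "random", "targeted"),
                          fraction = 1, seed = NULL, mse_scores = NULL) {
  strategy <- match.arg(strategy)
  indices <- as.integer(indices)
  if (length(indices) == 0L) stop("parameter error: empty reference set")
  if (anyDuplicated(indices)) stop("duplicate reference indices")
  if (any(indices < 1L | indices > nrow(genotypes)))
    stop("reference indices outside the training fold")
  structure(list(indices = indices,
                 genotypes = genotypes[indices, , drop = FALSE],
                 phenotypes = phenotypes[indices],
                 strategy = strategy, fraction = fraction,
                 seed = seed, mse_scores = mse_scores),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d references (%s, fraction %.2f)\n",
              length(x$indices), x$strategy, x$fraction))
  invisible(x)
}

#' Ensemble phenotype prediction for query genotypes
#'
#' The obscured ensemble: a query genotype is paired with every reference
#' instance, the base model predicts the query trait from each
#' (obscured vector, reference phenotype) pair, and the final prediction is
#' the plain mean of those pair predictions. The base model is trained once;
#' choosing a reference subset is purely an inference-time decision.
#'
#' @param model A trained [obscured_net()].
#' @param refs A [reference_set()].
#' @param query A marker-code vector of active-feature length, or a matrix of
#'   queries (one per row).
#' @return Numeric prediction(s) on the standardized trait scale.
#' @export
ensemble_predict <- function(model, refs, query) {
  stopifnot(inherits(refs, "reference_set"))
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  if (ncol(query) != ncol(refs$genotypes))
    stop("shape error: query has ", ncol(query), " markers, references have ",
         ncol(refs$genotypes))
  nq <- nrow(query)
  nr <- length(refs$phenotypes)
  # all (query, reference) combinations, reference varying fastest
  qi <- rep(seq_len(nq), each = nr)
  ri <- rep(seq_len(nr), times = nq)
  bits <- (query[qi, , drop = FALSE] == refs$genotypes[ri, , drop = FALSE]) * 1
  pred <- predict_model_pairs(model, list(bits = bits,
                                          y_ref = refs$phenotypes[ri]))
  as.vector(rowMeans(matrix(pred, nrow = nq, byrow = TRUE)))
}

#' Serialize a reference set as JSON
#'
#' @param x A `reference_set`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_reference_set <- function(x, path) {
  jsonlite::write_json(
    list(strategy = x$strategy, fraction = x$fraction, seed = x$seed,
         indices = x$indices, mse_scores = x$mse_scores),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

reference_count <- function(n, fraction) {
  max(1L, as.integer(floor(fraction * n + 0.5)))
}

check_fraction <- function(fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("parameter error: fraction must lie in (0, 1]")
  invisible(fraction)
}
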