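#' Ridge regression on marker codes
#'
#' Closed-form ridge: minimizes `||y - X beta - b||^2 + lambda ||beta||^2`
#' with an unpenalized intercept, via the normal equations on column-centered
#' markers. The workhorse linear baseline of the comparison harness.
#'
#' @param genotypes Training marker matrix (individuals x markers).
#' @param trait Standardized trait vector.
#' @param lambda Positive penalty.
#' @return A list of class `gp_ridge`: `beta`, `intercept`, `centers`,
#'   `lambda`.
#' @export
ridge_fit <- function(genotypes, trait, lambda) {
  stopifnot(lambda > 0, nrow(genotypes) == length(trait))
  X <- as.matrix(genotypes)
  centers <- colMeans(X)
  Xc <- sweep(X, 2L, centers)
  yc <- trait - mean(trait)
  m <- ncol(Xc)
  beta <- solve(crossprod(Xc) + diag(lambda, m), crossprod(Xc, yc))
  structure(list(beta = as.vector(beta), intercept = mean(trait),
                 centers = centers, lambda = lambda),
            class = "gp_ridge")
}

#' @rdname ridge_fit
#' @param fit A `gp_ridge` object.
#' @param newdata Marker matrix to predict for.
#' @export
ridge_predict <- function(fit, newdata) {
  Xc <- sweep(as.matrix(newdata), 2L, fit$centers)
  as.vector(Xc %*% fit$beta) + fit$intercept
}

#' VanRaden genomic relationship matrix
#'
#' Method-1 GRM from biallelic dosages: `G = Z Z' / (2 sum p_j (1 - p_j))`
#' where Z holds the codes centered by twice the allele frequency. Allele
#' frequencies default to the in-sample estimates `p_j = mean(codes_j) / 2`;
#' pass training-fold frequencies explicitly to keep test individuals out of
#' the centering.
#'
#' @param genotypes Dosage matrix with codes in \{0, 1, 2\}.
#' @param freqs Per-marker allele frequencies, or `NULL` to estimate from
#'   `genotypes`.
#' @return A list of class `gp_grm`: `G` (n x n symmetric PSD matrix),
#'   `allele_freqs`, `denom`.
#' @export
grm_vanraden <- function(genotypes, freqs = NULL) {
  M <- as.matrix(genotypes)
  if (any(M < 0 | M > 2)) stop("GRM expects dosage codes in {0,1,2}")
  if (is.null(freqs)) freqs <- colMeans(M) / 2
  if (length(freqs) != ncol(M)) stop("one allele frequency per marker required")
  denom <- 2 * sum(freqs * (1 - freqs))
  if (denom <= 0)
    stop("zero-denominator error: all markers monomorphic at the given frequencies")
  Z <- sweep(M, 2L, 2 * freqs)
  G <- tcrossprod(Z) / denom
  structure(list(G = G, allele_freqs = freqs, denom = denom),
            class = "gp_grm")
}

#' GBLUP prediction in GRM form
#'
#' Solves the ridge-equivalent mixed model on the relationship matrix:
#' `u_hat = G[test, train] (G[train, train] + lambda I)^-1 (y - mean(y))`,
#' prediction = training mean + `u_hat`. `lambda` plays the role of the
#' error-to-genetic variance ratio; it is a fixed tuning constant here, not a
#' REML estimate.
#'
#' @param grm A `gp_grm` covering train and test individuals (or a bare
#'   matrix).
#' @param train_idx,test_idx Row indices of training and test individuals.
#' @param train_trait Standardized training trait values (aligned with
#'   `train_idx`).
#' @param lambda Positive variance-ratio stand-in.
#' @return Numeric predictions for `test_idx`.
#' @export
gblup_predict <- function(grm, train_idx, test_idx, train_trait, lambda) {
  stopifnot(lambda > 0, length(train_idx) == length(train_trait))
  G <- if (inherits(grm, "gp_grm")) grm$G else as.matrix(grm)
  mu <- mean(train_trait)
  Gtt <- G[train_idx, train_idx, drop = FALSE]
  alpha <- solve(Gtt + diag(lambda, length(train_idx)), train_trait - mu)
  as.vector(G[test_idx, train_idx, drop = FALSE] %*% alpha) + mu
}
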