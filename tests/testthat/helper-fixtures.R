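# shared fixtures: everything is generated in code at test time

# small random dosage matrix with ids
rand_geno <- function(n, m, seed = 1L, maxcode = 2L) {
  withr::with_seed(seed, {
    g <- matrix(sample(0:maxcode, n * m, replace = TRUE), n, m)
    dimnames(g) <- list(sprintf("ind_%03d", seq_len(n)),
                        sprintf("m%04d", seq_len(m)))
    g
  })
}

# standardized random trait aligned with a genotype matrix
rand_trait <- function(n, seed = 1L) {
  y <- withr::with_seed(seed, stats::rnorm(n))
  as.vector(scale(y))
}

# write a toy genotype+phenotype CSV and return its path
write_toy_csv <- function(lines, path = withr::local_tempfile(fileext = ".csv",
                                                              .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

# deterministic stub "models" for the ensemble/evaluation arithmetic; they
# consume the materialized pair design like a trained network would
stub_echo_ref <- function(mat) mat$y_ref          # always outputs y_j
stub_perfect <- function(mat) mat$target          # always outputs the true y_i
stub_constant <- function(c0) function(mat) rep(c0, length(mat$y_ref))

# harness stub model specs
stub_mean_model <- function() {
  list(label = "stub_mean",
       fit = function(X, y, seed) list(mu = mean(y)),
       predict = function(fit, Xnew) rep(fit$mu, nrow(Xnew)))
}

# perfect-oracle stub: reproduces the harness's fold-scoped standardization
# from the raw trait table, so held-out predictions equal the actual values
stub_oracle_model <- function(phenotypes, trait) {
  raw <- stats::setNames(phenotypes[[trait]], phenotypes$id)
  list(label = "stub_oracle",
       fit = function(X, y, seed) zscore_fit(raw[rownames(X)]),
       predict = function(fit, Xnew) zscore_apply(raw[rownames(Xnew)], fit))
}

failing_model <- function() {
  list(label = "stub_fail",
       fit = function(X, y, seed) stop("deliberate failure"),
       predict = function(fit, Xnew) stop("unreachable"))
}

# tiny network configuration for fast structural tests
tiny_net_config <- function(n_features, ...) {
  args <- list(...)
  defaults <- list(n_features = n_features, conv_filters = 4L,
                   conv_width = 5L, pool_width = 2L, embed_dim = 8L,
                   estimator_width = 8L, epochs = 3L, batch_size = 32L,
                   seed = 1L)
  do.call(net_config, utils::modifyList(defaults, args))
}
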