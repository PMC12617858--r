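#' Pearson correlation between actual and predicted phenotypes
#'
#' Plain product-moment correlation. A constant input makes the correlation
#' undefined; this is reported as an explicit error rather than silently
#' returned as 0, because near-constant predictions are exactly the failure
#' mode that a correlation-only evaluation hides (use [mse()] alongside).
#'
#' @param actual,predicted Numeric vectors of equal length >= 2.
#' @return Scalar correlation in `[-1, 1]`.
#' @export
pcc <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("shape error: vectors differ in length")
  if (length(actual) < 2L) stop("need at least 2 observations")
  if (stats::sd(actual) == 0 || stats::sd(predicted) == 0)
    stop("undefined correlation: constant input vector")
  stats::cor(actual, predicted)
}

pcc_safe <- function(actual, predicted) {
  tryCatch(list(value = pcc(actual, predicted), defined = TRUE),
           error = function(e) list(value = NA_real_, defined = FALSE))
}

#' Mean squared error
#'
#' @param actual,predicted Numeric vectors of equal length.
#' @return Mean of squared differences.
#' @export
mse <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("shape error: vectors differ in length")
  mean((actual - predicted)^2)
}

#' Cross-validation fold plan
#'
#' Seeded shuffle followed by round-robin assignment, so fold sizes differ by
#' at most one. The same plan object is reused for every model compared, so
#' all models see identical folds; plans serialize to JSON and reload
#' byte-identically.
#'
#' @param individual_ids Character vector of individual identifiers.
#' @param k Number of folds (default 3).
#' @param seed Integer seed.
#' @return A tibble of class `gp_folds` with columns `id` and `fold`.
#' @export
make_folds <- function(individual_ids, k = 3L, seed = 1L) {
  n <- length(individual_ids)
  if (k > n) stop("parameter error: more folds than individuals")
  if (anyDuplicated(individual_ids)) stop("duplicate individual ids")
  shuffled <- withr::with_seed(seed, sample(individual_ids))
  plan <- tibble::tibble(id = shuffled,
                         fold = rep_len(seq_len(k), n)) |>
    dplyr::arrange(match(.data$id, individual_ids))
  attr(plan, "k") <- as.integer(k)
  attr(plan, "seed") <- as.integer(seed)
  class(plan) <- c("gp_folds", class(plan))
  plan
}

#' @rdname make_folds
#' @param plan A `gp_folds` plan.
#' @param path JSON file path.
#' @export
write_folds <- function(plan, path) {
  jsonlite::write_json(list(k = attr(plan, "k"), seed = attr(plan, "seed"),
                            id = plan$id, fold = plan$fold),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname make_folds
#' @export
read_folds <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  plan <- tibble::tibble(id = o$id, fold = as.integer(o$fold))
  attr(plan, "k") <- as.integer(o$k)
  attr(plan, "seed") <- as.integer(o$seed)
  class(plan) <- c("gp_folds", class(plan))
  plan
}

# ---------------------------------------------------------------------------
# model specifications for the comparison harness: a named list with
# fit(X, y, seed) and predict(fit, Xnew); X is the training-fold marker
# matrix restricted to the active features, y the fold-standardized trait

#' Model specifications for the cross-validation harness
#'
#' Constructors returning the fit/predict pair [run_cv()] consumes.
#'
#' * `model_obscured()` — the obscured ensemble: trains the base network on
#'   all ordered training pairs, then predicts held-out individuals by
#'   averaging pair predictions over the configured reference set.
#' * `model_ridge()` — closed-form ridge regression on marker codes.
#' * `model_gblup()` — GBLUP on the VanRaden GRM with training-fold allele
#'   frequencies; `lambda = "grid"` picks the penalty from {0.01, 0.1, 1, 10}
#'   by an internal split of the training fold.
#' * `model_rf()` — thin wrapper around `randomForest` (requires the
#'   randomForest package).
#' * `model_deepgs()` — thin direct-prediction comparator: the same
#'   convolutional engine applied to raw dosages without obscuring.
#'
#' @param config Optional [net_config()] template; `n_features` and `seed`
#'   are overridden per fold.
#' @param reference_strategy,reference_fraction Reference-instance selection
#'   used at prediction time.
#' @param include_self Include self pairs when building the training pairs.
#' @param lambda Ridge/GBLUP penalty (`"grid"` allowed for GBLUP).
#' @param ntree Number of trees for the random-forest wrapper.
#' @return A list with elements `label`, `fit`, `predict`.
#' @name model_specs
NULL

#' @rdname model_specs
#' @export
model_obscured <- function(config = NULL,
                           reference_strategy = c("all", "random", "targeted"),
                           reference_fraction = 1, include_self = FALSE) {
  reference_strategy <- match.arg(reference_strategy)
  list(
    label = "obscured",
    fit = function(X, y, seed) {
      cfg <- resolve_net_config(config, ncol(X), seed)
      net <- obscured_net(cfg)
      pairs <- pair_dataset(X, y, include_self = include_self)
      net <- train_obscured(net, pairs)
      refs <- build_reference_set(net, X, y, reference_strategy,
                                  reference_fraction, seed)
      list(net = net, refs = refs)
    },
    predict = function(fit, Xnew) ensemble_predict(fit$net, fit$refs, Xnew))
}

resolve_net_config <- function(config, n_features, seed) {
  if (is.null(config)) return(net_config(n_features, seed = seed))
  config$n_features <- as.integer(n_features)
  config$seed <- as.integer(seed)
  config
}

build_reference_set <- function(net, X, y, strategy, fraction, seed) {
  n <- nrow(X)
  if (strategy == "all") {
    reference_set(seq_len(n), X, y, "all", 1)
  } else if (strategy == "random") {
    idx <- select_references_random(n, fraction, seed)
    reference_set(idx, X, y, "random", fraction, seed = seed)
  } else {
    prof <- reference_mse_profile(net, X, y)
    idx <- select_references_targeted(prof, fraction)
    reference_set(idx, X, y, "targeted", fraction, mse_scores = prof)
  }
}

#' @rdname model_specs
#' @export
model_ridge <- function(lambda = 1) {
  list(label = "ridge",
       fit = function(X, y, seed) ridge_fit(X, y, lambda),
       predict = function(fit, Xnew) ridge_predict(fit, Xnew))
}

#' @rdname model_specs
#' @export
model_gblup <- function(lambda = "grid") {
  list(
    label = "gblup",
    fit = function(X, y, seed) {
      freqs <- colMeans(X) / 2
      lam <- if (identical(lambda, "grid"))
        gblup_grid_lambda(X, y, freqs, seed) else lambda
      list(X = X, y = y, freqs = freqs, lambda = lam)
    },
    predict = function(fit, Xnew) {
      all_geno <- rbind(fit$X, Xnew)
      grm <- grm_vanraden(all_geno, freqs = fit$freqs)
      ntr <- nrow(fit$X)
      gblup_predict(grm, seq_len(ntr), ntr + seq_len(nrow(Xnew)),
                    fit$y, fit$lambda)
    })
}

gblup_grid_lambda <- function(X, y, freqs, seed, grid = c(0.01, 0.1, 1, 10)) {
  n <- nrow(X)
  inner <- withr::with_seed(seed, sample(rep_len(1:2, n)))
  grm <- grm_vanraden(X, freqs = freqs)
  score <- vapply(grid, function(lam) {
    errs <- vapply(1:2, function(h) {
      tr <- which(inner != h); te <- which(inner == h)
      mse(y[te], gblup_predict(grm, tr, te, y[tr], lam))
    }, numeric(1L))
    mean(errs)
  }, numeric(1L))
  grid[which.min(score)]
}

#' @rdname model_specs
#' @export
model_rf <- function(ntree = 200L) {
  list(
    label = "rf",
    fit = function(X, y, seed) {
      if (!requireNamespace("randomForest", quietly = TRUE))
        stop("the randomForest package is required for model_rf()")
      withr::with_seed(seed,
        randomForest::randomForest(x = X, y = y, ntree = ntree))
    },
    predict = function(fit, Xnew) as.vector(stats::predict(fit, Xnew)))
}

#' @rdname model_specs
#' @export
model_deepgs <- function(config = NULL) {
  list(
    label = "deepgs",
    fit = function(X, y, seed) {
      cfg <- resolve_net_config(config, ncol(X), seed)
      d <- net_dims(cfg$n_features, cfg$conv_filters, cfg$conv_width,
                    cfg$pool_width, cfg$embed_dim, cfg$estimator_width,
                    n_aux = 0L)
      idxvec <- net_patch_index(d)
      withr::with_seed(cfg$seed, {
        par <- net_init_params(d)
        fit <- net_train_loop(par, d, idxvec, as.matrix(X) * 1, NULL, y, cfg)
        list(par = fit$par, d = d, idxvec = idxvec)
      })
    },
    predict = function(fit, Xnew)
      net_predict(fit$par, fit$d, fit$idxvec, as.matrix(Xnew) * 1, NULL))
}

# ---------------------------------------------------------------------------

#' Cross-validated model comparison
#'
#' Runs every model over the same fold plan with leakage-safe preprocessing:
#' trait standardization, the sliding-window redundancy filter, and the
#' mutual-information ranking are all re-fit on each training fold only and
#' applied to the held-out fold. Every report row carries both PCC and MSE;
#' an undefined correlation (constant predictions) is flagged, never masked.
#'
#' @param data A `gp_data` (or [simulate_gp()] result).
#' @param trait Name of the trait column in `data$phenotypes`.
#' @param models Named list of model specifications (see [model_specs]).
#' @param fold_plan A [make_folds()] plan over the data's individuals.
#' @param n_features If non-`NULL`, keep this many markers per training fold
#'   by mutual-information ranking (after the redundancy filter, if any).
#' @param dedup_w If non-`NULL`, apply [window_dedup()] with this window on
#'   the training fold first.
#' @param mi_bins Trait bins for the MI estimator.
#' @param seed Base seed; each (model, fold) derives its own seed from it.
#' @return A tibble of class `gp_eval` with columns `model`, `fold`,
#'   `n_features`, `pcc`, `pcc_defined`, `mse`, `error`; the per-individual
#'   predictions are attached and retrievable with [cv_predictions()].
#' @export
run_cv <- function(data, trait, models, fold_plan, n_features = NULL,
                   dedup_w = NULL, mi_bins = 10L, seed = 1L) {
  stopifnot(inherits(fold_plan, "gp_folds"))
  geno <- data$genotypes
  y_raw <- data$phenotypes[[trait]]
  if (is.null(y_raw)) stop("trait not found: ", trait)
  ids <- rownames(geno)
  if (!setequal(ids, fold_plan$id)) stop("fold plan does not cover the data")
  fold_of <- fold_plan$fold[match(ids, fold_plan$id)]
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- vapply(models, `[[`, character(1L), "label")

  rows <- list(); preds <- list()
  for (f in sort(unique(fold_plan$fold))) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    prep <- prepare_fold(geno, y_raw, tr, te, n_features, dedup_w, mi_bins)
    for (mn in names(models)) {
      spec <- models[[mn]]
      fit_seed <- as.integer(seed) * 131L + f
      res <- tryCatch({
        fit <- spec$fit(prep$X_tr, prep$y_tr, fit_seed)
        pred <- spec$predict(fit, prep$X_te)
        list(pred = pred, error = NA_character_)
      }, error = function(e) list(pred = NULL, error = conditionMessage(e)))
      if (is.null(res$pred)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          model = mn, fold = f, n_features = ncol(prep$X_tr),
          pcc = NA_real_, pcc_defined = NA, mse = NA_real_,
          error = res$error)
      } else {
        pc <- pcc_safe(prep$y_te, res$pred)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          model = mn, fold = f, n_features = ncol(prep$X_tr),
          pcc = pc$value, pcc_defined = pc$defined,
          mse = mse(prep$y_te, res$pred), error = NA_character_)
        preds[[length(preds) + 1L]] <- tibble::tibble(
          model = mn, fold = f, id = ids[te],
          actual = prep$y_te, predicted = res$pred)
      }
    }
  }
  report <- dplyr::bind_rows(rows)
  attr(report, "predictions") <- dplyr::bind_rows(preds)
  class(report) <- c("gp_eval", class(report))
  report
}

# fold-scoped preprocessing: standardization and feature selection are fit on
# the training rows only
prepare_fold <- function(geno, y_raw, tr, te, n_features, dedup_w, mi_bins) {
  zs <- zscore_fit(y_raw[tr])
  y_tr <- zscore_apply(y_raw[tr], zs)
  y_te <- zscore_apply(y_raw[te], zs)
  cols <- seq_len(ncol(geno))
  if (!is.null(dedup_w)) {
    sel <- window_dedup(geno[tr, , drop = FALSE], w = dedup_w)
    cols <- sel$kept_indices
  }
  if (!is.null(n_features)) {
    k <- min(n_features, length(cols))
    if (k < n_features)
      warning("requested ", n_features, " features but only ", length(cols),
              " available; clipping")
    sel <- mi_rank(geno[tr, cols, drop = FALSE], y_tr, k = k, bins = mi_bins)
    cols <- cols[sel$kept_indices]
  }
  list(X_tr = geno[tr, cols, drop = FALSE],
       X_te = geno[te, cols, drop = FALSE],
       y_tr = y_tr, y_te = y_te, zs = zs, cols = cols)
}

#' Per-individual predictions of a cross-validation report
#'
#' @param report A `gp_eval` from [run_cv()] or the sweep functions.
#' @return Tibble with `model`, `fold`, `id`, `actual`, `predicted` (plus
#'   sweep axis columns when present).
#' @export
cv_predictions <- function(report) {
  attr(report, "predictions")
}

#' Marker-density sweep
#'
#' Re-runs [run_cv()] at each feature count (mutual-information selection
#' re-fit per training fold), producing the PCC/MSE-versus-count curves used
#' to study how prediction quality depends on marker density.
#'
#' @inheritParams run_cv
#' @param counts Integer vector of feature counts (each clipped to the number
#'   of markers surviving the redundancy filter).
#' @return A `gp_eval` tibble with an additional `count` column.
#' @export
sweep_feature_counts <- function(data, trait, models, fold_plan, counts,
                                 dedup_w = 8L, mi_bins = 10L, seed = 1L) {
  out <- purrr::map(counts, function(cnt) {
    rep <- run_cv(data, trait, models, fold_plan, n_features = cnt,
                  dedup_w = dedup_w, mi_bins = mi_bins, seed = seed)
    prd <- attr(rep, "predictions")
    attr(rep, "predictions") <- NULL
    list(report = dplyr::mutate(rep, count = cnt, .before = 1L),
         preds = dplyr::mutate(prd, count = cnt, .before = 1L))
  })
  report <- dplyr::bind_rows(purrr::map(out, "report"))
  attr(report, "predictions") <- dplyr::bind_rows(purrr::map(out, "preds"))
  class(report) <- c("gp_eval", class(report))
  report
}

#' Reference-fraction sweep for the obscured ensemble
#'
#' Trains the obscured base model once per fold on the full training fold,
#' then evaluates [ensemble_predict()] on the held-out fold for every
#' combination of reference fraction, selection strategy and seed. The base
#' model is never retrained across fractions — reference selection is an
#' inference-time choice.
#'
#' @inheritParams run_cv
#' @param fractions Numeric vector in (0, 1].
#' @param strategies Subset of `c("random", "targeted")`.
#' @param seeds Integer seeds for the random strategy (targeted selection is
#'   deterministic; its rows are replicated per seed for a balanced table).
#' @param config Optional [net_config()] template.
#' @return A `gp_eval` tibble with columns `fraction`, `strategy`, `seed`
#'   ahead of the usual metrics.
#' @export
sweep_reference_fractions <- function(data, trait, fold_plan, fractions,
                                      strategies = c("random", "targeted"),
                                      seeds = 1L, config = NULL,
                                      n_features = NULL, dedup_w = 8L,
                                      mi_bins = 10L, seed = 1L) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  geno <- data$genotypes
  y_raw <- data$phenotypes[[trait]]
  ids <- rownames(geno)
  fold_of <- fold_plan$fold[match(ids, fold_plan$id)]
  rows <- list()
  for (f in sort(unique(fold_plan$fold))) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    prep <- prepare_fold(geno, y_raw, tr, te, n_features, dedup_w, mi_bins)
    cfg <- resolve_net_config(config, ncol(prep$X_tr),
                              as.integer(seed) * 131L + f)
    net <- train_obscured(obscured_net(cfg), pair_dataset(prep$X_tr, prep$y_tr))
    profile <- if ("targeted" %in% strategies)
      reference_mse_profile(net, prep$X_tr, prep$y_tr) else NULL
    for (frac in fractions) for (strat in strategies) for (s in seeds) {
      refs <- if (strat == "random") {
        idx <- select_references_random(nrow(prep$X_tr), frac, s)
        reference_set(idx, prep$X_tr, prep$y_tr, "random", frac, seed = s)
      } else {
        idx <- select_references_targeted(profile, frac)
        reference_set(idx, prep$X_tr, prep$y_tr, "targeted", frac,
                      mse_scores = profile)
      }
      pred <- ensemble_predict(net, refs, prep$X_te)
      pc <- pcc_safe(prep$y_te, pred)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        fraction = frac, strategy = strat, seed = s,
        model = "obscured", fold = f, n_features = ncol(prep$X_tr),
        pcc = pc$value, pcc_defined = pc$defined,
        mse = mse(prep$y_te, pred), error = NA_character_)
    }
  }
  report <- dplyr::bind_rows(rows)
  class(report) <- c("gp_eval", class(report))
  report
}

#' Training-versus-test squared-error heatmap matrix
#'
#' Entry (j, t) is the squared error of predicting test individual t from the
#' pair (obscured(g_t, g_j), y_j): rows are training (candidate reference)
#' instances, columns are test instances. Column means restricted to the test
#' instances mirror the targeted-selection MSE profile; similar values down a
#' column explain why random reference selection performs comparably to
#' targeted selection.
#'
#' @param model A trained [obscured_net()].
#' @param train_genotypes,train_phenotypes Training-fold markers (active
#'   features) and standardized traits.
#' @param test_genotypes,test_phenotypes Held-out fold, same feature space.
#' @return Numeric matrix (n_train x n_test) with dimnames from rownames.
#' @export
mse_heatmap <- function(model, train_genotypes, train_phenotypes,
                        test_genotypes, test_phenotypes) {
  ntr <- nrow(train_genotypes); nte <- nrow(test_genotypes)
  ti <- rep(seq_len(nte), each = ntr)   # test (query) index
  ji <- rep(seq_len(ntr), times = nte)  # training (reference) index
  bits <- (test_genotypes[ti, , drop = FALSE] ==
             train_genotypes[ji, , drop = FALSE]) * 1
  pred <- predict_model_pairs(model, list(bits = bits,
                                          y_ref = train_phenotypes[ji],
                                          target = test_phenotypes[ti]))
  err2 <- (pred - test_phenotypes[ti])^2
  matrix(err2, nrow = ntr, ncol = nte,
         dimnames = list(rownames(train_genotypes),
                         rownames(test_genotypes)))
}
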