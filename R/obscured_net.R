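#' Configuration of the obscured network
#'
#' Architecture and training hyper-parameters for the base model that predicts
#' one genotype's trait from the obscured vector of a pair plus the partner's
#' trait. The extractor follows the DeepGS convolutional motif: a small bank
#' of 1-D convolution filters over the obscured bits in marker order, ReLU,
#' max pooling, dropout, and a fully connected reduction to a low-dimensional
#' embedding of the between-genotype differences. The embedding is
#' concatenated with the scalar reference phenotype and passed to a two-layer
#' fully connected estimator ending in a single linear output; the network is
#' trained end to end on a mean squared regression loss.
#'
#' @param n_features Number of active markers (after any feature selection).
#' @param conv_filters,conv_width Filter count and width of the 1-D
#'   convolution (width is clipped to `n_features` for very small inputs).
#' @param pool_width Max-pooling width (non-overlapping windows).
#' @param dropout Length-2 rates in `[0, 1)`: after pooling, and after the
#'   estimator's hidden layer. Inactive at inference.
#' @param embed_dim Width of the extractor's fully connected reduction.
#' @param estimator_width Hidden width of the estimator.
#' @param epochs Number of end-to-end training passes (default 20).
#' @param batch_size Mini-batch size.
#' @param step_size Adam learning rate.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @return A list of class `net_config`.
#' @export
net_config <- function(n_features, conv_filters = 8L, conv_width = 18L,
                       pool_width = 4L, dropout = c(0.2, 0.1),
                       embed_dim = 32L, estimator_width = 32L,
                       epochs = 20L, batch_size = 64L, step_size = 1e-3,
                       seed = 1L) {
  stopifnot(n_features >= 1L, conv_filters >= 1L, conv_width >= 1L,
            pool_width >= 1L, length(dropout) == 2L,
            all(dropout >= 0), all(dropout < 1),
            embed_dim >= 1L, estimator_width >= 1L,
            epochs >= 1L, batch_size >= 1L, step_size > 0)
  structure(list(n_features = as.integer(n_features),
                 conv_filters = as.integer(conv_filters),
                 conv_width = as.integer(conv_width),
                 pool_width = as.integer(pool_width),
                 dropout = dropout,
                 embed_dim = as.integer(embed_dim),
                 estimator_width = as.integer(estimator_width),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 step_size = step_size, seed = as.integer(seed)),
            class = "net_config")
}

#' Build an (untrained) obscured network
#'
#' Instantiates the topology described in [net_config()] with parameters
#' initialized reproducibly from `config$seed` (He-scaled normal weights,
#' zero biases). Train it with [train_obscured()].
#'
#' @param config A [net_config()].
#' @return An object of class `obscured_net` with `NULL` training log.
#' @export
obscured_net <- function(config) {
  stopifnot(inherits(config, "net_config"))
  d <- net_dims(config$n_features, config$conv_filters, config$conv_width,
                config$pool_width, config$embed_dim, config$estimator_width,
                n_aux = 1L)
  par <- withr::with_seed(config$seed, net_init_params(d))
  structure(list(config = config, dims = d, idxvec = net_patch_index(d),
                 parameters = par, training_log = NULL,
                 standardization = NULL),
            class = "obscured_net")
}

#' Train the obscured network on a pair dataset
#'
#' Minimizes the mean squared regression loss over pair rows — each row is
#' the obscured vector of a (query, reference) genotype pair concatenated
#' with the reference phenotype, the target being the query phenotype — by
#' mini-batch Adam for exactly `config$epochs` passes. Shuffling and dropout
#' are controlled by `config$seed`, so the training-loss trajectory is
#' reproducible from (data, config, seed).
#'
#' The network never receives raw marker codes: the training API accepts only
#' pair rows, i.e. binary agreement bits plus a reference phenotype.
#'
#' @param model An [obscured_net()].
#' @param pairs A [pair_dataset()] whose phenotypes are standardized.
#' @param standardization Optional `gp_zscore` recording the trait scale the
#'   model was trained under (kept with the model for bookkeeping).
#' @return The trained `obscured_net`, with `training_log` holding the mean
#'   mini-batch loss of each epoch.
#' @export
train_obscured <- function(model, pairs, standardization = NULL) {
  stopifnot(inherits(model, "obscured_net"), inherits(pairs, "gp_pairs"))
  if (pairs$n_features != model$config$n_features)
    stop("shape error: pair dataset has ", pairs$n_features,
         " features, model expects ", model$config$n_features)
  if (nrow(pairs$pairs) == 0L) stop("empty pair dataset")
  mat <- pair_design(pairs)
  fit <- withr::with_seed(model$config$seed,
    net_train_loop(model$parameters, model$dims, model$idxvec,
                   mat$bits, mat$y_ref, mat$target, model$config))
  model$parameters <- fit$par
  model$training_log <- fit$training_log
  model$standardization <- standardization
  model
}

#' Predict a query phenotype from one obscured pair
#'
#' Deterministic inference: all stochastic layers are disabled, so the output
#' is a pure function of the learned parameters and the inputs. Accepts a
#' single obscured vector or a matrix of them (one per row) with one
#' reference phenotype per row.
#'
#' @param model A trained [obscured_net()].
#' @param bits Obscured 0/1 vector of length `n_features`, or a matrix with
#'   that many columns.
#' @param y_ref Reference phenotype(s) on the standardized trait scale.
#' @return Numeric prediction(s) on the standardized trait scale.
#' @export
predict_pair <- function(model, bits, y_ref) {
  stopifnot(inherits(model, "obscured_net"))
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1L)
  if (ncol(bits) != model$config$n_features)
    stop("shape error: obscured vector has ", ncol(bits),
         " entries, model expects ", model$config$n_features)
  y_ref <- rep_len(y_ref, nrow(bits))
  net_predict(model$parameters, model$dims, model$idxvec, bits, y_ref)
}

#' Number of learnable parameters of a network
#'
#' @param model An `obscured_net` (trained or not).
#' @return Integer parameter count.
#' @export
net_n_params <- function(model) {
  net_n_params_list(model$parameters)
}

#' @export
print.obscured_net <- function(x, ...) {
  cat(sprintf("<obscured_net> %d features, %d parameters, %s\n",
              x$config$n_features, net_n_params(x),
              if (is.null(x$training_log)) "untrained"
              else sprintf("trained %d epochs (final loss %.4f)",
                           length(x$training_log),
                           x$training_log[length(x$training_log)])))
  invisible(x)
}

#' Tidy the training log of an obscured network
#'
#' @param x A trained `obscured_net`.
#' @param ... Unused.
#' @return Tibble with `epoch` and `loss` (mean mini-batch MSE).
#' @exportS3Method generics::tidy
tidy.obscured_net <- function(x, ...) {
  if (is.null(x$training_log)) stop("model is untrained")
  tibble::tibble(epoch = seq_along(x$training_log), loss = x$training_log)
}

#' One-row summary of an obscured network
#'
#' @param x An `obscured_net`.
#' @param ... Unused.
#' @return Tibble with `n_features`, `n_params`, `epochs`, `final_loss`.
#' @exportS3Method generics::glance
glance.obscured_net <- function(x, ...) {
  tibble::tibble(
    n_features = x$config$n_features,
    n_params = net_n_params(x),
    epochs = if (is.null(x$training_log)) 0L else length(x$training_log),
    final_loss = if (is.null(x$training_log)) NA_real_
                 else x$training_log[length(x$training_log)])
}

#' Save / load an obscured-network checkpoint as JSON
#'
#' The checkpoint stores the configuration, learned parameters and training
#' log as plain JSON, so models round-trip through text.
#'
#' @param model A trained or untrained `obscured_net`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_obscured_net()` returns the restored model.
#' @export
write_obscured_net <- function(model, path) {
  pars <- lapply(model$parameters, function(p) {
    if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
    else list(dim = NULL, data = as.vector(p))
  })
  jsonlite::write_json(
    list(config = unclass(model$config), parameters = pars,
         training_log = model$training_log),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_obscured_net
#' @export
read_obscured_net <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(net_config, o$config[setdiff(names(o$config), NULL)])
  model <- obscured_net(cfg)
  model$parameters <- lapply(o$parameters, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2L) matrix(p$data, p$dim[1L], p$dim[2L])
    else as.vector(p$data)
  })
  model$training_log <- o$training_log
  model
}
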