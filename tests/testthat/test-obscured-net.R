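test_that("a freshly built network has the configured shape and finite output", {
  cfg <- net_config(32, seed = 4)
  net <- obscured_net(cfg)
  ones <- matrix(1, 16, 32)
  out <- predict_pair(net, ones, rep(0.5, 16))
  expect_length(out, 16)
  expect_true(all(is.finite(out)))
  expect_error(predict_pair(net, matrix(1, 2, 31), c(0, 0)), "shape error")
})

test_that("parameter count equals the closed-form layer arithmetic", {
  cfg <- net_config(64, conv_filters = 8, conv_width = 18, pool_width = 4,
                    embed_dim = 32, estimator_width = 32)
  net <- obscured_net(cfg)
  kw <- 18; out_len <- 64 - kw + 1; npool <- ceiling(out_len / 4)
  flat <- npool * 8
  expected <- (kw * 8 + 8) +              # conv filters + biases
    (flat * 32 + 32) +                    # extractor reduction
    ((32 + 1) * 32 + 32) +                # estimator hidden (embedding + y_ref)
    (32 * 1 + 1)                          # linear output
  expect_equal(net_n_params(net), expected)

  # conv width clipped when markers are scarce
  net2 <- obscured_net(net_config(8, conv_width = 18))
  expect_equal(net2$dims$kw, 8)
  expect_equal(net2$dims$out_len, 1)
})

test_that("initialization and predictions are reproducible from the seed", {
  probe <- matrix(rbinom(160, 1, 0.5), 5, 32)
  yref <- rnorm(5)
  a <- predict_pair(obscured_net(net_config(32, seed = 11)), probe, yref)
  b <- predict_pair(obscured_net(net_config(32, seed = 11)), probe, yref)
  c <- predict_pair(obscured_net(net_config(32, seed = 12)), probe, yref)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a, c)))
})

test_that("backpropagated gradients match central finite differences", {
  # continuous probe inputs keep pre-activations off the ReLU kink
  ns <- asNamespace("obscuredgp")
  withr::with_seed(33, {
    d <- ns$net_dims(18L, 3L, 5L, 3L, 4L, 4L, 1L)
    idx <- ns$net_patch_index(d)
    par <- ns$net_init_params(d)
    par$bc <- rnorm(3, 0, 0.1)  # non-zero biases avoid exact-zero kinks
    B <- 6
    X <- matrix(rnorm(B * 18), B, 18)
    aux <- rnorm(B)
    y <- rnorm(B)
  })
  lossfun <- function(p)
    mean((ns$net_forward(p, d, idx, X, aux, c(0, 0), FALSE) - y)^2)
  fw <- ns$net_forward(par, d, idx, X, aux, c(0, 0), TRUE)
  g <- ns$net_backward(par, d, fw, matrix(2 * (fw$out - y) / B, ncol = 1))
  eps <- 1e-6
  for (nm in names(par)) {
    num <- par[[nm]] * 0
    for (i in seq_along(num)) {
      p1 <- par; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- par; p2[[nm]][i] <- p2[[nm]][i] - eps
      num[i] <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
    }
    expect_equal(as.vector(num), as.vector(g[[nm]]), tolerance = 1e-5,
                 label = paste("finite-difference gradient for", nm))
  }
})

test_that("training reduces the loss and is reproducible bit for bit", {
  g <- rand_geno(12, 16, seed = 21)
  y <- rep(0, 12)  # constant target: loss must fall toward the constant predictor
  pd <- pair_dataset(g, y)
  cfg <- tiny_net_config(16, epochs = 30L, seed = 2)
  net <- train_obscured(obscured_net(cfg), pd)
  expect_length(net$training_log, 30)
  expect_lt(net$training_log[30], net$training_log[1])

  net2 <- train_obscured(obscured_net(cfg), pd)
  expect_identical(net$training_log, net2$training_log)
  expect_identical(net$parameters, net2$parameters)
})

test_that("inference is deterministic and batching-consistent", {
  g <- rand_geno(10, 20, seed = 31)
  y <- rand_trait(10, seed = 32)
  net <- train_obscured(obscured_net(tiny_net_config(20)), pair_dataset(g, y))
  bits <- (g[1:6, ] == g[c(2:7), ]) * 1
  yref <- y[c(2:7)]
  batch <- predict_pair(net, bits, yref)
  expect_identical(batch, predict_pair(net, bits, yref))
  singles <- vapply(1:6, function(i) predict_pair(net, bits[i, ], yref[i]),
                    numeric(1))
  expect_equal(batch, singles, tolerance = 1e-12)
})

test_that("a model trained with self-pairs maps the all-ones vector near y_ref", {
  g <- rand_geno(30, 24, seed = 41)
  y <- rand_trait(30, seed = 42)
  pd <- pair_dataset(g, y, include_self = TRUE)
  cfg <- tiny_net_config(24, epochs = 40L, seed = 5)
  net <- train_obscured(obscured_net(cfg), pd)
  grid <- seq(-1.5, 1.5, by = 0.5)
  pred <- predict_pair(net, matrix(1, length(grid), 24), grid)
  # tolerance anchored to what the run itself achieved on its training pairs
  tol <- 2 * sqrt(net$training_log[length(net$training_log)])
  expect_lt(mean(abs(pred - grid)), tol)
})

test_that("the trained ensemble recovers a noiseless oligogenic trait", {
  withr::with_seed(61, {
    n <- 200; m <- 100
    geno <- matrix(rbinom(n * m, 2, 0.5), n, m)
  })
  eff <- c(1.2, -0.8, 1.0)
  qtl <- c(10, 50, 90)
  y_raw <- as.vector(geno[, qtl] %*% eff)
  zs <- zscore_fit(y_raw)
  y <- zscore_apply(y_raw, zs)
  tr <- 1:140; te <- 141:200
  net <- train_obscured(obscured_net(net_config(m, seed = 2)),
                        pair_dataset(geno[tr, ], y[tr]))
  expect_lt(net$training_log[20], net$training_log[1])
  refs <- reference_set(seq_along(tr), geno[tr, ], y[tr], "all")
  pred <- ensemble_predict(net, refs, geno[te, ])
  expect_gt(pcc(y[te], pred), 0.6)
})

test_that("checkpoints round-trip through JSON", {
  g <- rand_geno(8, 16, seed = 51)
  y <- rand_trait(8, seed = 52)
  net <- train_obscured(obscured_net(tiny_net_config(16)), pair_dataset(g, y))
  path <- withr::local_tempfile(fileext = ".json")
  write_obscured_net(net, path)
  back <- read_obscured_net(path)
  probe <- (g[1:4, ] == g[5:8, ]) * 1
  expect_equal(predict_pair(back, probe, y[5:8]),
               predict_pair(net, probe, y[5:8]), tolerance = 1e-12)
  expect_equal(back$training_log, net$training_log, tolerance = 1e-12)
})
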