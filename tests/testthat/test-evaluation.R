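test_that("metrics match their definitions and flag degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pcc(x, x), 1)
  expect_equal(pcc(x, -x), -1)
  y <- c(2.0, 1.5, 4.0, 3.0, 6.5)
  byhand <- sum((x - mean(x)) * (y - mean(y))) /
    ((length(x) - 1) * sd(x) * sd(y))
  expect_equal(pcc(x, y), byhand, tolerance = 1e-12)
  expect_error(pcc(x, rep(1, 5)), "undefined correlation")
  expect_error(pcc(x, y[1:3]), "shape error")

  expect_equal(mse(x, x), 0)
  expect_equal(mse(c(0, 0), c(1, 1)), 1)
  a <- withr::with_seed(1, rnorm(100)); b <- withr::with_seed(2, rnorm(100))
  loop <- 0
  for (i in 1:100) loop <- loop + (a[i] - b[i])^2
  expect_equal(mse(a, b), loop / 100, tolerance = 1e-12)
})

test_that("fold plans are balanced, deterministic and serializable", {
  ids9 <- sprintf("g%02d", 1:9)
  plan <- make_folds(ids9, k = 3, seed = 4)
  expect_identical(sort(as.integer(table(plan$fold))), c(3L, 3L, 3L))
  expect_identical(plan, make_folds(ids9, k = 3, seed = 4))

  ids10 <- sprintf("g%02d", 1:10)
  sizes <- sort(as.integer(table(make_folds(ids10, k = 3, seed = 1)$fold)))
  expect_identical(sizes, c(3L, 3L, 4L))
  expect_error(make_folds(ids9, k = 12, seed = 1), "parameter error")

  path <- withr::local_tempfile(fileext = ".json")
  write_folds(plan, path)
  back <- read_folds(path)
  expect_identical(back$id, plan$id)
  expect_identical(back$fold, plan$fold)
  path2 <- withr::local_tempfile(fileext = ".json")
  write_folds(back, path2)
  expect_identical(readLines(path), readLines(path2))  # byte-identical replay
})

test_that("the harness records both metrics, flags undefined PCC, isolates failures", {
  sim <- simulate_gp(sim_config(n_individuals = 60, n_markers = 40,
                                n_qtl = 5, duplicate_frac = 0, seed = 3))
  plan <- make_folds(sim$phenotypes$id, k = 3, seed = 7)
  models <- list(stub_mean = stub_mean_model(),
                 stub_oracle = stub_oracle_model(sim$phenotypes, "trait"),
                 stub_fail = failing_model())
  rep <- run_cv(sim, "trait", models, plan)

  expect_equal(nrow(rep), 3 * 3)  # k folds x models
  expect_true(all(c("pcc", "mse") %in% names(rep)))

  mean_rows <- dplyr::filter(rep, model == "stub_mean")
  expect_true(all(!mean_rows$pcc_defined))   # constant predictions flagged
  expect_true(all(is.na(mean_rows$pcc)))
  expect_true(all(abs(mean_rows$mse - 1) < 0.45))  # ~ variance of z-scored trait

  oracle_rows <- dplyr::filter(rep, model == "stub_oracle")
  expect_true(all(oracle_rows$mse == 0))
  expect_equal(oracle_rows$pcc, rep(1, 3), tolerance = 1e-12)

  fail_rows <- dplyr::filter(rep, model == "stub_fail")
  expect_true(all(!is.na(fail_rows$error)))
  expect_true(all(is.na(fail_rows$mse)))

  prd <- cv_predictions(rep)
  expect_equal(nrow(prd), 2 * 60)  # two working models cover every individual
})

test_that("heatmap entries follow the stub arithmetic and the loop oracle", {
  gtr <- rand_geno(5, 12, seed = 11)
  gte <- rand_geno(4, 12, seed = 12)
  ytr <- rand_trait(5, seed = 13)
  yte <- rand_trait(4, seed = 14)

  expect_equal(mse_heatmap(stub_perfect, gtr, ytr, gte, yte),
               matrix(0, 5, 4, dimnames = list(rownames(gtr), rownames(gte))))

  hm_c <- mse_heatmap(stub_constant(0.25), gtr, ytr, gte, yte)
  for (t in 1:4) expect_equal(unname(hm_c[, t]), rep((0.25 - yte[t])^2, 5))

  net <- obscured_net(tiny_net_config(12, seed = 4))
  hm <- mse_heatmap(net, gtr, ytr, gte, yte)
  for (j in 1:5) for (t in 1:4) {
    p <- predict_pair(net, obscured_vector(gte[t, ], gtr[j, ]), ytr[j])
    expect_equal(hm[j, t], (p - yte[t])^2, tolerance = 1e-12)
  }
})

test_that("feature-count sweeps reduce to plain runs and keep the bookkeeping", {
  sim <- simulate_gp(sim_config(n_individuals = 45, n_markers = 60,
                                n_qtl = 5, seed = 5))
  plan <- make_folds(sim$phenotypes$id, k = 3, seed = 2)
  models <- list(ridge = model_ridge(lambda = 1))
  swept <- sweep_feature_counts(sim, "trait", models, plan,
                                counts = c(8, 16), dedup_w = 8, seed = 3)
  expect_equal(nrow(swept), 2 * 3 * 1)
  expect_setequal(unique(swept$count), c(8, 16))

  direct <- run_cv(sim, "trait", models, plan, n_features = 8, dedup_w = 8,
                   seed = 3)
  one <- dplyr::filter(swept, count == 8)
  expect_equal(one$pcc, direct$pcc)
  expect_equal(one$mse, direct$mse)
})

test_that("reference-fraction sweeps reuse one base model per fold", {
  sim <- simulate_gp(sim_config(n_individuals = 24, n_markers = 30,
                                block_size = 5, n_qtl = 4,
                                duplicate_frac = 0, seed = 6))
  plan <- make_folds(sim$phenotypes$id, k = 2, seed = 5)
  cfg <- tiny_net_config(30, epochs = 2L)
  swept <- sweep_reference_fractions(
    sim, "trait", plan, fractions = c(0.5, 1.0),
    strategies = c("random", "targeted"), seeds = c(1, 2),
    config = cfg, dedup_w = NULL, seed = 9)
  expect_equal(nrow(swept), 2 * 2 * 2 * 2)  # folds x fractions x strategies x seeds

  # at fraction 1.0 every strategy and seed sees the full reference set
  full <- dplyr::filter(swept, fraction == 1.0)
  for (f in unique(full$fold)) {
    rows <- dplyr::filter(full, fold == f)
    expect_equal(diff(range(rows$pcc)), 0, tolerance = 1e-12)
    expect_equal(diff(range(rows$mse)), 0, tolerance = 1e-12)
  }
})

test_that("training-fold artifacts ignore held-out phenotypes entirely", {
  sim <- simulate_gp(sim_config(n_individuals = 36, n_markers = 40,
                                n_qtl = 4, seed = 8))
  geno <- sim$genotypes
  y <- sim$phenotypes$trait
  tr <- 1:24; te <- 25:36

  y_poisoned <- y
  y_poisoned[te] <- -999  # destroy the held-out phenotypes

  prep1 <- obscuredgp:::prepare_fold(geno, y, tr, te,
                                     n_features = 12, dedup_w = 8, mi_bins = 8)
  prep2 <- obscuredgp:::prepare_fold(geno, y_poisoned, tr, te,
                                     n_features = 12, dedup_w = 8, mi_bins = 8)
  expect_identical(prep1$cols, prep2$cols)       # same marker selection
  expect_identical(prep1$y_tr, prep2$y_tr)       # same standardization
  expect_identical(prep1$zs, prep2$zs)

  cfg <- tiny_net_config(12, epochs = 2L)
  n1 <- train_obscured(obscured_net(cfg), pair_dataset(prep1$X_tr, prep1$y_tr))
  n2 <- train_obscured(obscured_net(cfg), pair_dataset(prep2$X_tr, prep2$y_tr))
  expect_identical(n1$parameters, n2$parameters)  # identical trained weights
  expect_identical(n1$training_log, n2$training_log)
})
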