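# independent survivor-semantics oracle: explicit column comparison, no hashing
dedup_oracle <- function(g, w) {
  m <- ncol(g)
  keep <- logical(m)
  for (j in seq_len(m)) {
    elim <- FALSE
    for (i in seq_len(m)) {
      if (i >= j || j - i > w || !keep[i]) next
      if (all(g[, i] == g[, j])) { elim <- TRUE; break }
    }
    keep[j] <- !elim
  }
  which(keep)
}

count_pairs_oracle <- function(g, w) {
  m <- ncol(g); total <- 0L
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i < j && j <= i + w && all(g[, i] == g[, j])) total <- total + 1L
  }
  total
}

# matrix with duplicates planted at known offsets
planted_matrix <- function(n = 40, m = 200, seed = 2) {
  g <- rand_geno(n, m, seed = seed)
  withr::with_seed(seed + 100, {
    for (j in sample(10:m, 30)) {
      d <- sample(1:10, 1)  # some within the window, some beyond
      g[, j] <- g[, j - d]
    }
  })
  g
}

test_that("window dedup removes in-window identical columns only", {
  g <- rand_geno(20, 10, seed = 1)
  g[, 4] <- g[, 3]
  sel <- window_dedup(g, w = 2)
  expect_false(4 %in% sel$kept_indices)
  expect_true(3 %in% sel$kept_indices)

  # identical columns at distance w + 1 both survive
  g2 <- rand_geno(20, 10, seed = 2)
  g2[, 8] <- g2[, 5]
  sel2 <- window_dedup(g2, w = 2)
  expect_true(all(c(5, 8) %in% sel2$kept_indices))
  sel3 <- window_dedup(g2, w = 3)
  expect_false(8 %in% sel3$kept_indices)
})

test_that("survivors match the explicit pairwise-comparison oracle", {
  g <- planted_matrix()
  for (w in c(1, 4, 8)) {
    expect_identical(window_dedup(g, w)$kept_indices, dedup_oracle(g, w))
  }
})

test_that("the survivor set is a fixed point: no in-window identical pair remains", {
  g <- planted_matrix(seed = 7)
  for (w in c(1, 2, 4, 8, 12)) {
    kept <- window_dedup(g, w)$kept_indices
    # in original marker order, no two survivors within w are identical,
    # so a second pass over the survivors (at their original positions)
    # would remove nothing
    for (a in seq_along(kept)) {
      b <- a + 1L
      while (b <= length(kept) && kept[b] - kept[a] <= w) {
        expect_false(all(g[, kept[a]] == g[, kept[b]]))
        b <- b + 1L
      }
    }
  }
})

test_that("redundant-pair counts match the all-pairs oracle and are monotone", {
  g <- rand_geno(30, 25, seed = 3)  # distinct columns w.h.p.
  expect_equal(count_redundant_pairs(g, 8), 0)

  g3 <- rand_geno(30, 10, seed = 4)
  g3[, 5] <- g3[, 4]; g3[, 6] <- g3[, 4]  # three consecutive identical
  expect_equal(count_redundant_pairs(g3, 2), 3)  # C(3,2)

  gp <- planted_matrix(seed = 9)
  counts <- vapply(1:12, function(w) count_redundant_pairs(gp, w), integer(1))
  expect_identical(counts, vapply(1:12, function(w) count_pairs_oracle(gp, w),
                                  integer(1)))
  expect_true(all(diff(counts) >= 0))
})

test_that("MI ranking scores match the histogram double-sum oracle", {
  n <- 80
  g <- rand_geno(n, 50, seed = 5)
  y <- withr::with_seed(6, rnorm(n))
  sel <- mi_rank(g, y, k = 10, bins = 10)
  yb <- obscuredgp:::equal_freq_bin(y, 10L)

  mi_oracle <- function(x, b) {
    total <- 0
    for (xv in unique(x)) for (bv in unique(b)) {
      pxy <- mean(x == xv & b == bv)
      if (pxy == 0) next
      total <- total + pxy * log(pxy / (mean(x == xv) * mean(b == bv)))
    }
    total
  }
  oracle <- vapply(seq_len(50), function(j) mi_oracle(g[, j], yb), numeric(1))
  expect_equal(sel$scores, oracle, tolerance = 1e-12)
  expect_identical(sel$kept_indices,
                   sort(order(-oracle, seq_len(50))[1:10]))
})

test_that("MI extremes: deterministic dependence is maximal, constants are zero", {
  n <- 60
  y <- withr::with_seed(8, rnorm(n))
  yb <- obscuredgp:::equal_freq_bin(y, 5L)
  g <- rand_geno(n, 10, seed = 9)
  g[, 3] <- yb          # marker identical to the trait labelling
  g[, 7] <- 1L          # constant marker
  sel <- mi_rank(g, y, k = 1, bins = 5)
  expect_identical(sel$kept_indices, 3L)
  expect_equal(max(sel$scores), sel$scores[3])
  expect_equal(sel$scores[7], 0)
})

test_that("MI ranking is invariant to individual order and honours k", {
  n <- 50
  g <- rand_geno(n, 20, seed = 10)
  y <- withr::with_seed(11, rnorm(n))
  perm <- withr::with_seed(12, sample(n))
  s1 <- mi_rank(g, y, k = 20)
  s2 <- mi_rank(g[perm, ], y[perm], k = 20)
  expect_equal(s1$scores, s2$scores, tolerance = 1e-12)
  expect_identical(s1$kept_indices, seq_len(20))  # k = n keeps everything
  expect_warning(s3 <- mi_rank(g, y, k = 99), "clipping")
  expect_identical(s3$kept_indices, seq_len(20))
})

test_that("random selection is seeded, in-range and uniform", {
  expect_identical(random_select(15, 15, seed = 1)$kept_indices, 1:15)
  expect_identical(random_select(100, 10, seed = 7)$kept_indices,
                   random_select(100, 10, seed = 7)$kept_indices)
  expect_error(random_select(10, 0, seed = 1), "parameter error")
  expect_error(random_select(10, 11, seed = 1), "parameter error")

  draws <- vapply(1:4000, function(s) random_select(10, 1, seed = s)$kept_indices,
                  integer(1))
  freq <- tabulate(draws, 10) / 4000
  expect_true(all(abs(freq - 0.1) < 0.025))  # ~5 sd of binomial(4000, .1)/4000
})

test_that("selections serialize to JSON and reload identically", {
  g <- rand_geno(40, 30, seed = 13)
  y <- withr::with_seed(14, rnorm(40))
  sel <- mi_rank(g, y, k = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_selection(sel, path)
  back <- read_selection(path)
  expect_identical(back$kept_indices, sel$kept_indices)
  expect_equal(back$scores, sel$scores, tolerance = 1e-12)
  expect_identical(back$method, sel$method)
})
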