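#' Configuration for the synthetic genotype/phenotype generator
#'
#' The generator emulates the structure a genomic-prediction panel presents to
#' this package: a few hundred lines scored at 10^3--10^4 biallelic markers
#' coded 0/1/2, local linkage-disequilibrium (LD) blocks in which adjacent
#' markers are correlated, a fraction of markers that are exact copies of a
#' nearby column (to exercise the redundancy filter), and a standardized
#' additive polygenic trait with controllable heritability.
#'
#' Markers are laid down in blocks of `block_size` consecutive columns. Each
#' block draws an allele frequency p uniformly from `allele_freq_range` and a
#' template dosage column from Binomial(2, p); the other block members copy
#' the template entrywise, redrawing each entry from Binomial(2, p) with
#' probability `flip_prob`, so within-block correlation decays with
#' `flip_prob` and vanishes across blocks. Afterwards a `duplicate_frac` share
#' of columns is overwritten with an exact copy of a non-duplicate column at
#' most 8 positions to the left, mirroring the redundancy the sliding-window
#' filter targets.
#'
#' The trait is additive: `n_qtl` causal markers (chosen among non-duplicate
#' columns) receive effects ~ Normal(0, 1); the genetic value is the
#' effect-weighted dosage sum, and Gaussian noise is scaled so that
#' var(g) / var(g + e) equals `heritability` in expectation. The trait is
#' returned raw; standardization is fold-scoped and happens downstream.
#'
#' @param n_individuals,n_markers Panel dimensions.
#' @param block_size Markers per LD block.
#' @param flip_prob Per-entry probability that a block member diverges from
#'   the block template.
#' @param n_qtl Number of causal markers.
#' @param heritability Target narrow-sense heritability in (0, 1).
#' @param duplicate_frac Fraction of markers emitted as exact copies of a
#'   neighbour at distance <= 8.
#' @param allele_freq_range Range for the per-block template allele frequency.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 300L, n_markers = 1000L,
                       block_size = 10L, flip_prob = 0.1,
                       n_qtl = 20L, heritability = 0.6,
                       duplicate_frac = 0.05,
                       allele_freq_range = c(0.1, 0.9), seed = 1L) {
  stopifnot(n_individuals >= 2L, n_markers >= 1L, block_size >= 1L,
            flip_prob >= 0, flip_prob <= 1,
            heritability > 0, heritability < 1,
            duplicate_frac >= 0, duplicate_frac < 1,
            length(allele_freq_range) == 2L)
  if (block_size > n_markers)
    stop("infeasible config: block_size exceeds n_markers")
  if (n_qtl > n_markers) stop("infeasible config: n_qtl exceeds n_markers")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_markers = as.integer(n_markers),
                 block_size = as.integer(block_size),
                 flip_prob = flip_prob, n_qtl = as.integer(n_qtl),
                 heritability = heritability,
                 duplicate_frac = duplicate_frac,
                 allele_freq_range = allele_freq_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genotype/phenotype panel
#'
#' @param config A [sim_config()].
#' @return A list of class `gp_sim` (which is also a valid `gp_data`):
#'   * `genotypes` — integer dosage matrix (individuals x markers),
#'   * `phenotypes` — tibble with `id` and raw `trait`,
#'   * `truth` — ground-truth record: `qtl` (causal column indices),
#'     `effects`, `realized_h2`, `duplicates` (tibble with `copy` and
#'     `source` column indices), `genetic_value`.
#' @export
simulate_gp <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_individuals
    m <- config$n_markers
    bs <- config$block_size
    n_blocks <- ceiling(m / bs)
    geno <- matrix(0L, n, m)
    for (b in seq_len(n_blocks)) {
      cols <- (((b - 1L) * bs + 1L):min(b * bs, m))
      p <- stats::runif(1L, config$allele_freq_range[1L],
                        config$allele_freq_range[2L])
      template <- stats::rbinom(n, 2L, p)
      for (j in cols) {
        col <- template
        if (config$flip_prob > 0) {
          flip <- stats::runif(n) < config$flip_prob
          if (any(flip)) col[flip] <- stats::rbinom(sum(flip), 2L, p)
        }
        geno[, j] <- col
      }
    }

    # plant exact duplicates: each copies a non-duplicate column <= 8 back,
    # so a window-8 dedup pass removes exactly the planted set
    n_dup <- round(config$duplicate_frac * m)
    dup_copy <- integer(0)
    dup_source <- integer(0)
    if (n_dup > 0L) {
      candidates <- sample(9:m)
      is_dup <- logical(m)
      is_src <- logical(m)
      for (j in candidates) {
        if (length(dup_copy) >= n_dup) break
        if (is_src[j]) next  # keep sources intact so every copy stays exact
        window <- (j - 8L):(j - 1L)
        window <- window[!is_dup[window]]
        if (length(window) == 0L) next
        src <- if (length(window) == 1L) window else sample(window, 1L)
        geno[, j] <- geno[, src]
        is_dup[j] <- TRUE
        is_src[src] <- TRUE
        dup_copy <- c(dup_copy, j)
        dup_source <- c(dup_source, src)
      }
    } else {
      is_dup <- logical(m)
    }

    qtl <- sort(sample(which(!is_dup), config$n_qtl))
    effects <- stats::rnorm(config$n_qtl)
    g <- as.vector(geno[, qtl, drop = FALSE] %*% effects)
    vg <- stats::var(g)
    if (vg == 0) stop("degenerate simulation: no genetic variance; adjust config")
    ve <- vg * (1 - config$heritability) / config$heritability
    e <- stats::rnorm(n, 0, sqrt(ve))
    y <- g + e
    realized_h2 <- vg / stats::var(y)

    ids <- sprintf("ind_%04d", seq_len(n))
    dimnames(geno) <- list(ids, sprintf("m%05d", seq_len(m)))
    ord <- order(dup_copy)
    structure(list(
      genotypes = geno,
      phenotypes = tibble::tibble(id = ids, trait = y),
      truth = list(qtl = qtl, effects = effects,
                   realized_h2 = realized_h2,
                   duplicates = tibble::tibble(copy = dup_copy[ord],
                                               source = dup_source[ord]),
                   genetic_value = g)),
      class = c("gp_sim", "gp_data"))
  })
}

#' Recall of causal markers under a feature selection
#'
#' Fraction of simulated causal markers recovered by a selection, where an
#' exact planted copy of a causal column counts as recovering it.
#'
#' @param selection A `gp_selection` (from [mi_rank()], [window_dedup()], or
#'   [random_select()]), or an integer vector of kept column indices.
#' @param truth The `truth` record of a [simulate_gp()] result.
#' @return Recall in `[0, 1]`.
#' @export
truth_eval <- function(selection, truth) {
  kept <- if (is.numeric(selection)) as.integer(selection) else selection$kept_indices
  hits <- vapply(truth$qtl, function(q) {
    aliases <- c(q, truth$duplicates$copy[truth$duplicates$source == q])
    any(aliases %in% kept)
  }, logical(1L))
  mean(hits)
}
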