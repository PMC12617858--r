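#' Obscured vector of a genotype pair
#'
#' The binary agreement vector between two genotypes: position i is 1 when
#' the two marker codes are exactly equal and 0 otherwise. This is the only
#' genomic information the obscured model ever sees — marker content is
#' hidden, only the positions of similarity remain. Agreement is exact code
#' equality; heterozygote and homozygote codes never partially match.
#'
#' @param a,b Integer code vectors of equal length (rows of a genotype
#'   matrix), no missing values.
#' @return Integer 0/1 vector of the same length.
#' @export
obscured_vector <- function(a, b) {
  if (length(a) != length(b))
    stop("shape error: genotype rows differ in length (",
         length(a), " vs ", length(b), ")")
  if (anyNA(a) || anyNA(b)) stop("missing marker codes are not allowed")
  as.integer(a == b)
}

# obscured vectors for many (query, ref) pairs at once: rows of the result
# are obscured(geno[q, ], geno[r, ])
obscure_rows <- function(geno, query, ref) {
  out <- (geno[query, , drop = FALSE] == geno[ref, , drop = FALSE]) * 1
  dimnames(out) <- NULL
  out
}

#' Pair dataset for training the obscured model
#'
#' Enumerates genotype pairs (query q, reference r) over a training set. Each
#' pair contributes one training row: the obscured vector of (q, r)
#' concatenated with the reference phenotype y_r, with the query phenotype
#' y_q as the regression target. By default pairs are ordered and both
#' directions are present (n(n-1) rows) and self-pairs are excluded.
#'
#' Rows are materialized lazily: the object stores indices plus the genotype
#' matrix, and [pair_design()] builds any subset of rows on demand, so the
#' full n^2 x markers design never needs to exist at once.
#'
#' @param genotypes Integer matrix (individuals x active markers).
#' @param phenotypes Numeric trait vector aligned with the rows of
#'   `genotypes`, already standardized.
#' @param include_self Also emit (i, i) pairs (all-ones obscured vector,
#'   target equal to the supplied phenotype). Default `FALSE`.
#' @param ordered Emit both (q, r) and (r, q). Default `TRUE`; with
#'   `ordered = FALSE` only q < r pairs are emitted.
#' @return A list of class `gp_pairs` with elements `pairs` (tibble of
#'   `query`, `ref` indices), `genotypes`, `phenotypes`, `n_features`.
#' @export
pair_dataset <- function(genotypes, phenotypes, include_self = FALSE,
                         ordered = TRUE) {
  n <- nrow(genotypes)
  if (length(phenotypes) != n)
    stop("phenotypes are not aligned with genotype rows")
  if (n < 2L && !include_self)
    stop("empty pair dataset: need at least 2 individuals")
  idx <- expand.grid(ref = seq_len(n), query = seq_len(n))[, c("query", "ref")]
  keep <- if (include_self) rep(TRUE, nrow(idx)) else idx$query != idx$ref
  if (!ordered) keep <- keep & idx$query <= idx$ref
  idx <- idx[keep, , drop = FALSE]
  structure(list(pairs = tibble::tibble(query = idx$query, ref = idx$ref),
                 genotypes = genotypes,
                 phenotypes = as.numeric(phenotypes),
                 n_features = ncol(genotypes)),
            class = "gp_pairs")
}

#' Materialize rows of a pair dataset
#'
#' @param pairs A `gp_pairs` object.
#' @param rows Integer row indices into `pairs$pairs` (default: all rows).
#' @return A list with `bits` (pair-rows x markers 0/1 matrix), `y_ref`
#'   (reference phenotypes), `target` (query phenotypes), and `pair_index`
#'   (the tibble of indices materialized).
#' @export
pair_design <- function(pairs, rows = NULL) {
  stopifnot(inherits(pairs, "gp_pairs"))
  p <- if (is.null(rows)) pairs$pairs else pairs$pairs[rows, , drop = FALSE]
  list(bits = obscure_rows(pairs$genotypes, p$query, p$ref),
       y_ref = pairs$phenotypes[p$ref],
       target = pairs$phenotypes[p$query],
       pair_index = p)
}

#' @export
print.gp_pairs <- function(x, ...) {
  cat(sprintf("<gp_pairs> %d pairs over %d individuals x %d markers\n",
              nrow(x$pairs), nrow(x$genotypes), x$n_features))
  invisible(x)
}

#' @export
length.gp_pairs <- function(x) nrow(x$pairs)
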