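#' Read a genotype + phenotype table
#'
#' Reads the single-file CSV dialect used throughout the package: the first
#' column (or `id_col`) holds the individual identifier, the columns named in
#' `traits` hold numeric trait values, and every remaining column is a marker
#' with a small non-negative integer allele code (biallelic dosages 0/1/2
#' typically, but any finite discrete alphabet is accepted).
#'
#' Marker codes must be non-missing after loading: equality-based obscuring is
#' undefined for missing codes. By default any missing or non-numeric marker
#' cell is an error naming the offending row and column; with
#' `missing_policy = "mode_impute"` such cells are replaced by the column's
#' most frequent observed code (ties broken by the smaller code).
#'
#' @param path Path to a CSV file with a header row.
#' @param traits Character vector of trait column names present in the file.
#' @param id_col Name or index of the identifier column. Default: first column.
#' @param missing_policy Either `"error"` (default) or `"mode_impute"`.
#'
#' @return An object of class `gp_data`: a list with
#'   * `genotypes` — integer matrix (individuals x markers) with individual
#'     ids as rownames and marker ids as colnames,
#'   * `phenotypes` — tibble with an `id` column followed by one numeric
#'     column per trait (raw scale; standardization is fold-scoped and happens
#'     downstream).
#' @seealso [write_gp_csv()], [zscore_fit()]
#' @export
read_gp_csv <- function(path, traits, id_col = 1L,
                        missing_policy = c("error", "mode_impute")) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0L) stop("structural error: file has no data rows: ", path)
  if (is.numeric(id_col)) id_col <- names(df)[id_col]
  if (!id_col %in% names(df)) stop("id column not found: ", id_col)
  missing_traits <- setdiff(traits, names(df))
  if (length(missing_traits) > 0L)
    stop("trait column(s) not in file: ", paste(missing_traits, collapse = ", "))

  ids <- df[[id_col]]
  if (anyDuplicated(ids)) {
    stop("structural error: duplicate individual ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  marker_cols <- setdiff(names(df), c(id_col, traits))
  if (length(marker_cols) < 1L) stop("structural error: no marker columns found")

  geno <- vapply(df[marker_cols],
                 function(x) suppressWarnings(as.numeric(x)),
                 numeric(nrow(df)))
  if (nrow(df) == 1L) geno <- matrix(geno, nrow = 1L)
  bad <- !is.finite(geno)
  if (any(bad)) {
    if (missing_policy == "error") {
      hit <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "parse error: missing/non-numeric marker code at row '%s', column '%s'",
        ids[hit[1L]], marker_cols[hit[2L]]))
    }
    geno <- apply(geno, 2L, impute_mode)
  }
  storage.mode(geno) <- "integer"
  if (any(geno < 0L)) stop("parse error: negative marker code encountered")
  dimnames(geno) <- list(ids, marker_cols)

  phen <- tibble::tibble(id = ids)
  for (tr in traits) {
    v <- suppressWarnings(as.numeric(df[[tr]]))
    if (anyNA(v)) stop("parse error: non-numeric value in trait column '", tr, "'")
    phen[[tr]] <- v
  }
  new_gp_data(geno, phen)
}

#' Write a genotype + phenotype table
#'
#' Writes the CSV dialect read by [read_gp_csv()]: `ID`, then marker columns,
#' then trait columns. Traits are written with full double precision so a
#' round trip reproduces codes exactly and traits to numerical precision.
#'
#' @param data A `gp_data` object (or the list returned by [simulate_gp()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gp_csv <- function(data, path) {
  geno <- data$genotypes
  phen <- data$phenotypes
  df <- tibble::as_tibble(as.data.frame(geno, optional = TRUE))
  df <- dplyr::bind_cols(tibble::tibble(ID = rownames(geno)), df,
                         phen[setdiff(names(phen), "id")])
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

new_gp_data <- function(genotypes, phenotypes) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) >= 1L)
  if (anyDuplicated(colnames(genotypes)))
    stop("structural error: duplicate marker ids")
  structure(list(genotypes = genotypes, phenotypes = phenotypes),
            class = "gp_data")
}

#' @export
print.gp_data <- function(x, ...) {
  cat(sprintf("<gp_data> %d individuals x %d markers; traits: %s\n",
              nrow(x$genotypes), ncol(x$genotypes),
              paste(setdiff(names(x$phenotypes), "id"), collapse = ", ")))
  invisible(x)
}

impute_mode <- function(x) {
  if (!anyNA(x)) return(x)
  obs <- x[is.finite(x)]
  if (length(obs) == 0L) stop("parse error: marker column entirely missing")
  tab <- table(obs)
  top <- as.numeric(names(tab)[tab == max(tab)])
  x[!is.finite(x)] <- min(top)
  x
}

#' Fit a z-score standardization
#'
#' Computes the sample mean and sample standard deviation (denominator n - 1)
#' of a trait vector. Standardization is always fit on a stated subset
#' (typically the training fold) and applied elsewhere with [zscore_apply()];
#' nothing in the package re-fits it silently.
#'
#' @param trait Numeric vector, length >= 2, non-constant.
#' @return A list with elements `mean` and `sd`, class `gp_zscore`.
#' @export
zscore_fit <- function(trait) {
  if (length(trait) < 2L) stop("need at least 2 observations to standardize")
  if (anyNA(trait)) stop("missing trait values")
  s <- stats::sd(trait)
  if (!is.finite(s) || s <= 0)
    stop("degenerate trait: zero variance, cannot z-score")
  structure(list(mean = mean(trait), sd = s), class = "gp_zscore")
}

#' Apply (or invert) a fitted z-score standardization
#'
#' @param trait Numeric vector.
#' @param stats A `gp_zscore` object (or list with `mean` and `sd`).
#' @return `(trait - mean) / sd` for [zscore_apply()];
#'   `trait * sd + mean` for [zscore_invert()].
#' @export
zscore_apply <- function(trait, stats) {
  if (!is.finite(stats$sd) || stats$sd <= 0) stop("sd must be positive")
  (trait - stats$mean) / stats$sd
}

#' @rdname zscore_apply
#' @export
zscore_invert <- function(trait, stats) {
  trait * stats$sd + stats$mean
}
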