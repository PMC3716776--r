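#' Within-fraction replicate size factors
#'
#' Median-of-ratios size factors in the style of count-data size-factor
#' normalization: within each fraction, each replicate's factor is the
#' median, over proteins observed in every replicate of that fraction, of
#' the ratio of the replicate's abundance to the protein's geometric-mean
#' reference. The median update is iterated to its fixed point with the
#' factors constrained to geometric mean 1 per fraction (the overall
#' scale is unidentifiable because the reference moves with it). After
#' division every replicate of a fraction has the same median ratio of
#' complete proteins to the (recomputed) reference, and re-running the
#' normalization yields factors of exactly 1.
#'
#' @param mat proteins x samples abundance matrix with
#'   \code{"fraction|replicate"} column names (see [qrollup()]).
#' @return list with \code{factors} (named per column),
#'   \code{complete_within} (list of protein id vectors per fraction).
#' @export
replicate_size_factors <- function(mat) {
  frac <- col_fraction(mat)
  factors <- stats::setNames(rep(1, ncol(mat)), colnames(mat))
  complete_within <- list()
  for (f in unique(frac)) {
    cols <- which(frac == f)
    if (length(cols) < 2)
      stop("fraction ", f, " has fewer than 2 replicates")
    sub <- mat[, cols, drop = FALSE]
    complete <- rowSums(is.na(sub)) == 0 & rowSums(sub <= 0, na.rm = TRUE) == 0
    if (!any(complete))
      stop("no protein is complete in every replicate of fraction ", f)
    complete_within[[f]] <- rownames(mat)[complete]
    factors[cols] <- median_ratio_factors(sub[complete, , drop = FALSE])
  }
  list(factors = factors, complete_within = complete_within)
}

#' Between-fraction size factors
#'
#' After within-fraction normalization, the fractions themselves are
#' normalized against each other: per-protein fraction averages are
#' computed for the proteins observed in every replicate of every fraction
#' (the globally complete set), and the same fixed-point median-of-ratios
#' factor is derived per fraction.
#'
#' @param mat a replicate-normalized abundance matrix.
#' @return list with \code{factors} (named per fraction, expanded to
#'   \code{per_column}), \code{complete_global} (protein ids),
#'   \code{n_complete_global}.
#' @export
fraction_size_factors <- function(mat) {
  frac <- col_fraction(mat)
  fracs <- unique(frac)
  complete <- rowSums(is.na(mat)) == 0 & rowSums(mat <= 0, na.rm = TRUE) == 0
  if (!any(complete))
    stop("no protein occurs in every replicate of every fraction")
  avg <- vapply(fracs, function(f)
    rowMeans(mat[complete, frac == f, drop = FALSE]), numeric(sum(complete)))
  if (!is.matrix(avg)) avg <- matrix(avg, nrow = sum(complete),
                                     dimnames = list(NULL, fracs))
  sf <- median_ratio_factors(avg)
  list(factors = stats::setNames(sf, fracs),
       per_column = stats::setNames(sf[frac], colnames(mat)),
       complete_global = rownames(mat)[complete],
       n_complete_global = sum(complete))
}

# fixed point of the median-of-ratios update on a complete positive matrix:
# columns are divided by the median ratio to the row geometric mean until
# the update stabilises; returns the accumulated factors. The raw update is
# invariant under a common rescaling of all columns (the ratios to the row
# geometric mean do not change), so the overall scale is unidentifiable and
# each update is pinned to geometric mean 1. At the fixed point every
# column has the same median ratio to the recomputed reference, and
# re-running on the normalized matrix returns factors of exactly 1.
median_ratio_factors <- function(x, tol = 1e-12, max_iter = 100L) {
  f <- rep(1, ncol(x))
  for (it in seq_len(max_iter)) {
    ref <- exp(rowMeans(log(x)))
    s <- apply(x / ref, 2, stats::median)
    s <- s / exp(mean(log(s)))
    f <- f * s
    x <- sweep(x, 2, s, "/")
    if (max(abs(s - 1)) < tol) break
  }
  f
}

#' Apply size factors to an abundance matrix
#' @param mat abundance matrix.
#' @param factors named per-column factors (division is applied).
#' @export
apply_size_factors <- function(mat, factors) {
  sweep(mat, 2, factors[colnames(mat)], "/")
}

#' Two-level normalization of a protein abundance matrix
#'
#' Runs [replicate_size_factors()] then [fraction_size_factors()] and
#' returns the normalized matrix together with both factor sets and the
#' globally complete protein count.
#'
#' @param mat proteins x samples abundance matrix from [qrollup()].
#' @return list with \code{matrix}, \code{replicate_factors},
#'   \code{fraction_factors}, \code{complete_global},
#'   \code{n_complete_global}.
#' @export
normalize_abundance <- function(mat) {
  rf <- replicate_size_factors(mat)
  m1 <- apply_size_factors(mat, rf$factors)
  ff <- fraction_size_factors(m1)
  m2 <- apply_size_factors(m1, ff$per_column)
  list(matrix = m2,
       replicate_factors = rf$factors,
       fraction_factors = ff$factors,
       complete_within = rf$complete_within,
       complete_global = ff$complete_global,
       n_complete_global = ff$n_complete_global)
}
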