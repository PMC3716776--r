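#' Fit the mean-variance power law
#'
#' Pools replicate variance information across the proteome by fitting
#' \code{variance = a * mean^b} to the per-fraction replicate means and
#' variances of all proteins without missing values, by least squares on
#' the log-log scale. The fitted law supplies variance estimates for
#' proteins with too few observations of their own.
#'
#' @param mat normalized proteins x samples abundance matrix.
#' @return object of class \code{variance_model}: \code{a}, \code{b},
#'   \code{fit_n} (complete proteins used), \code{fit_range} (range of
#'   means used).
#' @export
fit_variance_model <- function(mat) {
  frac <- col_fraction(mat)
  complete <- rowSums(is.na(mat)) == 0
  if (sum(complete) < 10)
    stop("need at least 10 proteins without missing values; have ",
         sum(complete))
  ms <- vs <- NULL
  for (f in unique(frac)) {
    sub <- mat[complete, frac == f, drop = FALSE]
    ms <- c(ms, rowMeans(sub))
    vs <- c(vs, apply(sub, 1, stats::var))
  }
  keep <- vs > 0 & ms > 0
  if (!any(keep)) stop("all replicate variances are zero; cannot fit")
  fit <- stats::lm(log(vs[keep]) ~ log(ms[keep]))
  structure(list(a = exp(unname(stats::coef(fit)[1])),
                 b = unname(stats::coef(fit)[2]),
                 fit_n = sum(complete),
                 fit_range = range(ms[keep])),
            class = "variance_model")
}

#' @export
print.variance_model <- function(x, ...) {
  cat(sprintf(
    "variance_model: var = %.4g * mean^%.3f (fit on %d complete proteins)\n",
    x$a, x$b, x$fit_n))
  invisible(x)
}

#' Predicted (pooled) variance at a mean abundance
#' @param object a \code{variance_model}.
#' @param newdata numeric vector of mean abundances.
#' @param ... ignored.
#' @export
predict.variance_model <- function(object, newdata, ...) {
  object$a * newdata^object$b
}

#' Censored-data differential representation test
#'
#' Tests each protein for overrepresentation in the supernatant fraction
#' relative to the cellular fractions, on a normalized abundance matrix
#' with left-censored missing values. Missing values are imputed at a
#' detection-floor constant slightly below the smallest observed
#' normalized abundance; group means are taken over all replicates
#' (imputed included). The per-fraction variance estimator is chosen by a
#' hybrid rule: the ordinary sample variance when the fraction is fully
#' observed; the average of the sample variance (on the imputed-complete
#' replicates) and the power-law pooled variance when exactly one
#' replicate is missing; the pooled variance \code{a * mean^b} when at
#' most one replicate was observed. The statistic is a Welch two-sample t
#' comparing the supernatant replicates against all cellular replicates
#' combined, with Satterthwaite degrees of freedom (bounded below at 1).
#'
#' @param mat normalized proteins x samples matrix (see
#'   [normalize_abundance()]).
#' @param model a [fit_variance_model()] result.
#' @param floor imputation constant; default \code{0.75 *} the minimum
#'   observed abundance in \code{mat}.
#' @param supernatant label of the supernatant fraction.
#' @param alpha significance level used for flagging.
#' @param fold_min minimum supernatant/cellular fold change for flagging.
#' @return data.frame: protein_id, per-fraction censored means,
#'   \code{fold_change}, \code{t_statistic}, \code{df}, \code{p_value},
#'   \code{variance_mode} (complete/hybrid/pooled), \code{flagged}.
#' @export
differential_test <- function(mat, model, floor = NULL,
                              supernatant = "supernatant",
                              alpha = 0.05, fold_min = 2) {
  stopifnot(inherits(model, "variance_model"))
  frac <- col_fraction(mat)
  if (!supernatant %in% frac)
    stop("no fraction labelled '", supernatant, "' in the matrix")
  if (is.null(floor)) floor <- 0.75 * min(mat, na.rm = TRUE)
  stopifnot(floor > 0)
  imp <- mat
  imp[is.na(imp)] <- floor
  fracs <- unique(frac)
  cellular <- setdiff(fracs, supernatant)

  group_stats <- function(i, f) {
    cols <- which(frac == f)
    obs <- sum(!is.na(mat[i, cols]))
    n <- length(cols)
    vals <- imp[i, cols]
    m <- mean(vals)
    if (obs == n && n >= 2) {
      list(mean = m, var = stats::var(vals), n = n, mode = "complete")
    } else if (n - obs == 1 && n >= 2) {
      list(mean = m,
           var = (stats::var(vals) + predict(model, m)) / 2,
           n = n, mode = "hybrid")
    } else {
      list(mean = m, var = predict(model, m), n = n, mode = "pooled")
    }
  }

  out <- vector("list", nrow(mat))
  for (i in seq_len(nrow(mat))) {
    gs <- lapply(fracs, function(f) group_stats(i, f))
    names(gs) <- fracs
    sup <- gs[[supernatant]]
    cn <- sum(vapply(gs[cellular], `[[`, 0, "n"))
    cmean <- sum(vapply(gs[cellular], function(g) g$mean * g$n, 0)) / cn
    cvar_of_mean <- sum(vapply(gs[cellular],
                               function(g) g$n * g$var, 0)) / cn^2
    se2_sup <- sup$var / sup$n
    se2 <- se2_sup + cvar_of_mean
    diff <- sup$mean - cmean
    if (se2 <= 0) {
      t <- if (diff == 0) 0 else sign(diff) * Inf
      df <- 1
    } else {
      t <- diff / sqrt(se2)
      denom <- se2_sup^2 / max(sup$n - 1, 1) +
        sum(vapply(gs[cellular], function(g)
          (g$n * g$var / cn^2)^2 / max(g$n - 1, 1), 0))
      df <- if (denom > 0) max(se2^2 / denom, 1) else 1
    }
    p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
    modes <- vapply(gs, `[[`, "", "mode")
    mode <- if (any(modes == "pooled")) "pooled"
            else if (any(modes == "hybrid")) "hybrid" else "complete"
    fold <- sup$mean / cmean
    row <- data.frame(protein_id = rownames(mat)[i], stringsAsFactors = FALSE)
    for (f in fracs) row[[paste0("mean_", f)]] <- gs[[f]]$mean
    row$fold_change <- fold
    row$t_statistic <- t
    row$df <- df
    row$p_value <- p
    row$variance_mode <- mode
    row$flagged <- fold >= fold_min & p < alpha
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pathway / category enrichment of flagged proteins
#'
#' Two-sided Fisher exact test per category on the 2x2 table of flagged
#' versus non-flagged proteins inside versus outside the category, with a
#' Benjamini-Hochberg correction over all tested categories; significance
#' is called at the given false discovery rate (default 10%).
#'
#' @param flagged character vector of flagged protein ids.
#' @param categories data.frame with columns \code{protein_id},
#'   \code{category}.
#' @param universe background protein ids (default: all proteins in
#'   \code{categories}).
#' @param fdr false discovery rate for the significance call.
#' @return data.frame: category, k_flagged_in, n_in, k_flagged_out,
#'   n_out, odds_ratio, p, q, significant.
#' @export
enrichment <- function(flagged, categories,
                       universe = unique(categories$protein_id),
                       fdr = 0.10) {
  stopifnot(all(c("protein_id", "category") %in% names(categories)))
  if (nrow(categories) == 0) stop("empty category map")
  categories <- categories[categories$protein_id %in% universe, ]
  flagged <- intersect(unique(flagged), universe)
  n_univ <- length(universe)
  n_flag <- length(flagged)
  cats <- split(categories$protein_id, categories$category)
  rows <- lapply(names(cats), function(cc) {
    members <- unique(cats[[cc]])
    k_in <- length(intersect(members, flagged))
    n_in <- length(members)
    k_out <- n_flag - k_in
    n_out <- n_univ - n_in
    tab <- matrix(c(k_in, n_in - k_in, k_out, n_out - k_out), 2)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    or <- (k_in / max(n_in - k_in, 0)) / (k_out / max(n_out - k_out, 0))
    if (is.nan(or)) or <- NA_real_
    data.frame(category = cc, k_flagged_in = k_in, n_in = n_in,
               k_flagged_out = k_out, n_out = n_out, odds_ratio = or,
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$q <= fdr
  res[order(res$p, res$category), ]
}

#' Per-fraction relative abundance by bin
#'
#' Sums censor-imputed mean protein abundances by phylogenetic bin within
#' each fraction and renormalizes to proportions of 1 - the stacked
#' community-composition view of the metaproteome.
#'
#' @param mat normalized proteins x samples abundance matrix.
#' @param bin_map named character vector protein id -> bin label; proteins
#'   absent from the map are reported as "unbinned".
#' @param floor imputation constant (default \code{0.75 * min} observed).
#' @return matrix bins x fractions of proportions (columns sum to 1).
#' @export
bin_abundance_summary <- function(mat, bin_map, floor = NULL) {
  if (is.null(floor)) floor <- 0.75 * min(mat, na.rm = TRUE)
  imp <- mat
  imp[is.na(imp)] <- floor
  frac <- col_fraction(mat)
  bins <- bin_map[rownames(mat)]
  bins[is.na(bins)] <- "unbinned"
  out <- vapply(unique(frac), function(f) {
    pm <- rowMeans(imp[, frac == f, drop = FALSE])
    s <- tapply(pm, bins, sum)
    s / sum(s)
  }, numeric(length(unique(bins))))
  if (!is.matrix(out))
    out <- matrix(out, ncol = length(unique(frac)),
                  dimnames = list(unique(bins), unique(frac)))
  out
}
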