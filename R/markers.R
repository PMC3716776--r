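#' Single-copy marker COG set
#'
#' A marker set is a table of single-copy (or almost single-copy)
#' phylogenetic COGs used to estimate genome-reconstruction completeness.
#' Ribosomal COGs are flagged: because ribosomal proteins co-occur in a few
#' large gene clusters they are not independent evidence of completeness,
#' and each is down-weighted to 1/30th of a non-ribosomal COG.
#'
#' The bundled default (see [marker_cogs()]) has 54 COGs of which 30 are
#' ribosomal, giving a weighted denominator of 24 + 30/30 = 25.
#'
#' @param cogs data.frame with columns \code{cog} (unique ids) and
#'   \code{is_ribosomal} (logical).
#' @return A \code{marker_set} object.
#' @export
marker_set <- function(cogs) {
  stopifnot(is.data.frame(cogs), all(c("cog", "is_ribosomal") %in% names(cogs)))
  if (anyDuplicated(cogs$cog)) stop("marker COG ids must be unique")
  cogs$is_ribosomal <- as.logical(cogs$is_ribosomal)
  structure(list(cogs = cogs,
                 n_total = nrow(cogs),
                 n_ribosomal = sum(cogs$is_ribosomal)),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d COGs (%d ribosomal, weighted denominator %.4g)\n",
              x$n_total, x$n_ribosomal,
              (x$n_total - x$n_ribosomal) + x$n_ribosomal / 30))
  invisible(x)
}

#' Default 54-COG marker table
#'
#' A stand-in list of 54 single-copy phylogenetic COGs (30 ribosomal
#' proteins, 24 universal non-ribosomal genes) bundled with the package as
#' \code{extdata/marker_cogs_default.tsv}. The ids are real COG families of
#' the stated kind, but the exact membership is this package's synthetic
#' default rather than any published supplementary list.
#'
#' @return data.frame with columns \code{cog}, \code{is_ribosomal}.
#' @export
marker_cogs <- function() {
  path <- system.file("extdata", "marker_cogs_default.tsv",
                      package = "mgproteo", mustWork = TRUE)
  read_tsv_table(path, c(cog = "character", is_ribosomal = "logical"))
}

#' Read a marker set from TSV
#' @param path TSV with columns \code{cog}, \code{is_ribosomal}.
#' @export
read_marker_set <- function(path) {
  marker_set(read_tsv_table(path, c(cog = "character",
                                    is_ribosomal = "logical")))
}

#' Weighted single-copy marker completeness
#'
#' Estimates genome completeness as the weighted fraction of a marker set
#' present, counting each ribosomal COG as 1/30th of a non-ribosomal COG:
#' \deqn{(n_{nonribo} + n_{ribo}/30) / (N_{nonribo} + N_{ribo}/30).}
#' With the default 54/30 set the denominator is 25, so a reconstruction
#' carrying all 30 ribosomal COGs but nothing else scores only 4%.
#'
#' @param present_cogs character vector of COG ids found in the
#'   reconstruction (duplicates ignored).
#' @param markers a [marker_set()]; defaults to the bundled 54-COG set.
#' @return completeness fraction in [0, 1].
#' @examples
#' ms <- marker_set(data.frame(cog = c("a", "b", "r1"),
#'                             is_ribosomal = c(FALSE, FALSE, TRUE)))
#' completeness(c("a", "r1"), ms)
#' @export
completeness <- function(present_cogs, markers = marker_set(marker_cogs())) {
  stopifnot(inherits(markers, "marker_set"))
  present_cogs <- unique(as.character(present_cogs))
  unknown <- setdiff(present_cogs, markers$cogs$cog)
  if (length(unknown))
    stop("COG ids not in the marker set: ", paste(unknown, collapse = ", "))
  ribo <- markers$cogs$cog[markers$cogs$is_ribosomal]
  nonribo <- markers$cogs$cog[!markers$cogs$is_ribosomal]
  num <- sum(present_cogs %in% nonribo) + sum(present_cogs %in% ribo) / 30
  den <- length(nonribo) + length(ribo) / 30
  num / den
}
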