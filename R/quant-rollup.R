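#' Peptide-to-protein rollup (top-intensity average)
#'
#' Derives protein abundances from peptide peak intensities: peptides
#' mapping to more than one protein are discarded; within each protein and
#' sample the observed unique peptides are ranked by intensity and the top
#' \code{ceiling(top_fraction * n)} (at least one) are averaged. A protein
#' is missing in a sample when none of its unique peptides was observed
#' there.
#'
#' @param peptides data.frame with columns \code{peptide_id},
#'   \code{protein_ids} (";"-separated when shared), \code{fraction},
#'   \code{replicate}, \code{abundance} (\code{NA} = not observed).
#' @param top_fraction fraction of peptides retained (default 0.33).
#' @return numeric matrix, proteins x samples, column names
#'   \code{"fraction|replicate"} ordered by fraction (first-appearance
#'   order) then replicate; \code{NA} marks missing protein/sample cells.
#' @examples
#' p <- data.frame(peptide_id = paste0("p", 1:6), protein_ids = "A",
#'                 fraction = "supernatant", replicate = 1,
#'                 abundance = c(600, 500, 400, 300, 200, 100))
#' qrollup(p)  # mean of the top 2 of 6 = 550
#' @export
qrollup <- function(peptides, top_fraction = 0.33) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  req <- c("peptide_id", "protein_ids", "fraction", "replicate", "abundance")
  stopifnot(all(req %in% names(peptides)))
  frac_levels <- unique(peptides$fraction)
  rep_levels <- sort(unique(peptides$replicate))
  samples <- as.vector(outer(rep_levels, frac_levels,
                             function(r, f) paste(f, r, sep = "|")))
  samples <- samples[order(match(sub("\\|.*$", "", samples), frac_levels))]
  prot_levels <- sort(unique(unlist(strsplit(peptides$protein_ids, ";",
                                             fixed = TRUE))))
  d <- peptides[!grepl(";", peptides$protein_ids, fixed = TRUE) &
                  !is.na(peptides$abundance), ]
  out <- matrix(NA_real_, length(prot_levels), length(samples),
                dimnames = list(prot_levels, samples))
  if (nrow(d) == 0) return(out)
  key <- paste(d$protein_ids, d$fraction, d$replicate, sep = "\r")
  o <- order(key, -d$abundance)
  key <- key[o]; ab <- d$abundance[o]
  sizes <- rle(key)$lengths
  rank_in_group <- sequence(sizes)
  keep_n <- rep(pmax(ceiling(top_fraction * sizes), 1L), sizes)
  keep <- rank_in_group <= keep_n
  sums <- rowsum(ab[keep], key[keep])
  counts <- rowsum(rep(1, sum(keep)), key[keep])
  means <- sums[, 1] / counts[, 1]
  parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
  pid <- vapply(parts, `[`, "", 1L)
  scol <- paste(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 3L),
                sep = "|")
  out[cbind(match(pid, prot_levels), match(scol, samples))] <- means
  out
}

#' Fraction label of each column of an abundance matrix
#'
#' Abundance matrices carry \code{"fraction|replicate"} column names (see
#' [qrollup()]); this strips the replicate part.
#'
#' @param mat a proteins x samples abundance matrix.
#' @return character vector of fraction labels, one per column.
#' @export
col_fraction <- function(mat) sub("\\|[^|]*$", "", colnames(mat))
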