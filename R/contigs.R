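#' Assembled contigs with coverage and marker annotations
#'
#' The binning substrate: a set of assembled contigs, each with its mean
#' read coverage and any single-copy phylogenetic marker genes found on it.
#' GC content is computed over non-N bases only.
#'
#' @param sequences named character vector or \code{DNAStringSet}.
#' @param coverage numeric mean read depth per contig (x-fold), recycled if
#'   length 1; must be >= 0.
#' @param markers optional list, one element per contig (named by contig id
#'   or in order), each a data.frame with columns \code{cog} and
#'   \code{taxon}; or \code{NULL}.
#' @return An object of class \code{contig_set}: a list with
#'   \code{sequences} (\code{DNAStringSet}), \code{meta} (data.frame id,
#'   length, coverage, gc) and \code{markers} (named list of data.frames).
#' @examples
#' cs <- contig_set(c(c1 = "ACGTACGTNN", c2 = "GGGGCCCC"), coverage = c(10, 50))
#' cs$meta
#' @export
contig_set <- function(sequences, coverage, markers = NULL) {
  seqs <- as_dna_set(sequences)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("contigs must have unique names")
  n <- length(seqs)
  coverage <- rep_len(as.numeric(coverage), n)
  if (any(coverage < 0)) stop("coverage must be >= 0")
  acgt <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  nonN <- rowSums(acgt)
  gc <- rowSums(acgt[, c("C", "G"), drop = FALSE]) /
    ifelse(nonN == 0, NA_real_, nonN)
  meta <- data.frame(id = names(seqs),
                     length = Biostrings::width(seqs),
                     coverage = coverage,
                     gc = gc,
                     stringsAsFactors = FALSE)
  rownames(meta) <- meta$id
  mk <- stats::setNames(vector("list", n), names(seqs))
  if (!is.null(markers)) {
    if (is.null(names(markers))) names(markers) <- names(seqs)[seq_along(markers)]
    bad <- setdiff(names(markers), names(seqs))
    if (length(bad)) stop("markers given for unknown contigs: ",
                          paste(bad, collapse = ", "))
    mk[names(markers)] <- markers
  }
  structure(list(sequences = seqs, meta = meta, markers = mk),
            class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  nm <- sum(vapply(x$markers, function(m) !is.null(m) && nrow(m) > 0, TRUE))
  cat(sprintf("contig_set: %d contigs, %s bp total, %d with markers\n",
              nrow(x$meta), format(sum(x$meta$length), big.mark = ","), nm))
  invisible(x)
}

#' @export
length.contig_set <- function(x) nrow(x$meta)

#' Subset a contig set by id or index
#' @param x a \code{contig_set}.
#' @param i contig ids (character) or indices.
#' @param ... ignored.
#' @export
`[.contig_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$meta$id)
  structure(list(sequences = x$sequences[i],
                 meta = x$meta[i, , drop = FALSE],
                 markers = x$markers[i]),
            class = "contig_set")
}

#' Coverage versus GC scatter of a contig set
#'
#' The classic diagnostic for simple communities: each contig plotted at its
#' mean read coverage (log scale) and GC fraction, point area proportional
#' to contig length, coloured by bin when an assignment is supplied.
#'
#' @param x a \code{contig_set}.
#' @param assignment optional named character vector, contig id -> bin label.
#' @param ... passed to \code{plot()}.
#' @export
plot.contig_set <- function(x, assignment = NULL, ...) {
  m <- x$meta[x$meta$coverage > 0, ]
  col <- "grey40"
  if (!is.null(assignment)) {
    lab <- assignment[m$id]
    lab[is.na(lab)] <- "unassigned"
    f <- factor(lab)
    col <- grDevices::hcl.colors(nlevels(f), "Dark 3")[as.integer(f)]
  }
  graphics::plot(m$coverage, 100 * m$gc, log = "x",
                 cex = 0.3 + sqrt(m$length) / 100, col = col,
                 xlab = "mean read coverage (x-fold)", ylab = "GC %", ...)
  invisible(NULL)
}
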