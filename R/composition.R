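#' Order-k De Bruijn chain composition model
#'
#' Summarises the oligonucleotide composition of one or more DNA sequences as
#' a De Bruijn chain of order \code{k}: the empirical distribution of all
#' (k+1)-mers, together with the implied conditional distribution of the next
#' base given the preceding k-mer. With the default \code{order = 3} the
#' signature is the tetranucleotide profile classically used for
#' composition-based contig binning.
#'
#' Windows containing any base outside A/C/G/T (e.g. N) are skipped. Under
#' the default \code{strand = "canonical"} policy every window is counted
#' together with its reverse complement, so the signature is independent of
#' the (arbitrary) orientation in which a contig was assembled;
#' \code{strand = "single"} counts the given strand only.
#'
#' @param sequences character vector, \code{DNAString} or \code{DNAStringSet}.
#' @param order chain order k (>= 1); (k+1)-mers are tallied.
#' @param strand \code{"canonical"} (default) or \code{"single"}.
#' @param smooth_transitions add-one smoothing of the transition rows
#'   (default \code{TRUE}; word frequencies are never smoothed).
#' @return An object of class \code{composition_model} with elements
#'   \code{order}, \code{counts} (named (k+1)-mer counts), \code{frequencies}
#'   (summing to 1), \code{transitions} (4^k x 4 row-stochastic matrix),
#'   \code{unseen} (logical flag per k-mer context never observed),
#'   \code{strand}, and \code{total_windows}.
#' @examples
#' m <- build_composition_model("ACGTACGTACGT", order = 3)
#' sum(m$frequencies)
#' @export
build_composition_model <- function(sequences, order = 3L,
                                    strand = c("canonical", "single"),
                                    smooth_transitions = TRUE) {
  strand <- match.arg(strand)
  if (order < 1L) stop("'order' must be >= 1")
  seqs <- as_dna_set(sequences)
  if (length(seqs) == 0L || sum(Biostrings::width(seqs)) == 0L)
    stop("no input sequence")
  counts <- kmer_counts(seqs, width = order + 1L, strand = strand)
  total <- sum(counts)
  if (total == 0)
    stop("no usable (k+1)-mer windows (sequences too short or all N)")
  if (total < 4^(order + 1L))
    warning(sprintf(
      "only %d usable windows for %d possible %d-mers; model will be sparse",
      total, 4^(order + 1L), order + 1L))
  tmat <- matrix(counts, ncol = 4L, byrow = TRUE)
  rownames(tmat) <- unique(substr(names(counts), 1L, order))
  colnames(tmat) <- c("A", "C", "G", "T")
  rs <- rowSums(tmat)
  unseen <- rs == 0
  if (smooth_transitions) {
    trans <- (tmat + 1) / (rs + 4)
  } else {
    trans <- tmat / ifelse(rs == 0, 1, rs)
  }
  structure(list(order = as.integer(order),
                 counts = counts,
                 frequencies = counts / total,
                 transitions = trans,
                 unseen = unseen,
                 strand = strand,
                 total_windows = total),
            class = "composition_model")
}

#' @export
print.composition_model <- function(x, ...) {
  cat(sprintf(
    "De Bruijn chain composition model (order %d, %s strand)\n",
    x$order, x$strand))
  cat(sprintf("  %d-mer windows counted: %s; unseen contexts: %d/%d\n",
              x$order + 1L, format(x$total_windows, big.mark = ","),
              sum(x$unseen), length(x$unseen)))
  invisible(x)
}

#' Composition dissimilarity score
#'
#' Scores a contig (or a second model) against a composition model. The
#' default metric is the total-variation distance between the two (k+1)-mer
#' frequency distributions, \code{0.5 * sum(|p - q|)}: a bounded metric in
#' [0, 1] that is 0 iff the distributions coincide, so lower scores mean a
#' better composition match. The alternative \code{metric = "nll"} is the
#' negative mean log-likelihood per window of the sequence under the model's
#' (smoothed) De Bruijn chain, in nats; it is unbounded and not symmetric.
#'
#' @param x a DNA sequence (character/\code{DNAString}), a
#'   \code{DNAStringSet}, or another \code{composition_model}.
#' @param model a \code{composition_model}.
#' @param metric \code{"tv"} (default) or \code{"nll"}.
#' @return A single numeric score (lower = more similar).
#' @examples
#' m <- build_composition_model(c("ACGTTGCA", "GGGCCC"))
#' composition_score("ACGTTGCA", m)
#' @export
composition_score <- function(x, model, metric = c("tv", "nll")) {
  metric <- match.arg(metric)
  stopifnot(inherits(model, "composition_model"))
  k1 <- model$order + 1L
  if (inherits(x, "composition_model")) {
    if (x$order != model$order) stop("model orders differ")
    counts <- x$counts
  } else {
    seqs <- as_dna_set(x)
    if (sum(Biostrings::width(seqs)) < k1)
      stop(sprintf("sequence shorter than %d usable bases", k1))
    counts <- kmer_counts(seqs, width = k1, strand = model$strand)
    if (sum(counts) == 0)
      stop(sprintf("sequence has no usable %d-mer windows", k1))
  }
  if (metric == "tv") {
    p <- counts / sum(counts)
    return(0.5 * sum(abs(p - model$frequencies)))
  }
  # negative mean log-likelihood per window under the chain
  logt <- log(pmax(model$transitions, .Machine$double.xmin))
  idx <- cbind(rep(seq_len(nrow(logt)), each = 4L), rep(1:4, nrow(logt)))
  ll <- sum(counts * logt[idx])
  -ll / sum(counts)
}

#' (k+1)-mer frequency profiles for a set of sequences
#'
#' One row per sequence, columns the 4^width words in lexicographic order,
#' rows normalised to sum to 1 (rows with no usable window are all-NA).
#'
#' @param sequences character vector or \code{DNAStringSet}.
#' @param width word size (order + 1).
#' @param strand strand policy, as in [build_composition_model()].
#' @return numeric matrix, sequences x 4^width.
#' @export
kmer_profiles <- function(sequences, width = 4L,
                          strand = c("canonical", "single")) {
  strand <- match.arg(strand)
  seqs <- as_dna_set(sequences)
  m <- Biostrings::oligonucleotideFrequency(seqs, width = width)
  if (strand == "canonical")
    m <- m + Biostrings::oligonucleotideFrequency(
      Biostrings::reverseComplement(seqs), width = width)
  tot <- rowSums(m)
  m <- m / ifelse(tot == 0, NA_real_, tot)
  rownames(m) <- names(seqs)
  m
}

# pooled (k+1)-mer counts over a set of sequences
kmer_counts <- function(seqs, width, strand) {
  m <- Biostrings::oligonucleotideFrequency(seqs, width = width)
  counts <- if (is.matrix(m)) colSums(m) else m
  if (strand == "canonical") {
    m2 <- Biostrings::oligonucleotideFrequency(
      Biostrings::reverseComplement(seqs), width = width)
    counts <- counts + if (is.matrix(m2)) colSums(m2) else m2
  }
  counts
}

# coerce character / DNAString / DNAStringSet to DNAStringSet, upcasing
as_dna_set <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (inherits(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  if (inherits(x, "contig_set")) return(x$sequences)
  if (is.character(x)) return(Biostrings::DNAStringSet(toupper(x)))
  stop("cannot interpret input as DNA sequences")
}
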