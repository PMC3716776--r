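#' Average amino acid identity from best one-way hits
#'
#' Computes AAI between a query gene set and a reference proteome from a
#' table of protein alignments: for each query only the single best hit is
#' kept (highest bitscore; ties broken by identity, then subject id), and
#' that hit is retained only if it has at least \code{min_identity} percent
#' identity over at least \code{min_coverage} of the query length. AAI is
#' the unweighted mean of the retained identities.
#'
#' @param hits data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{percent_identity}, \code{alignment_length}, \code{query_length},
#'   \code{bitscore} (e.g. from [read_hit_table()] or [align_proteins()]).
#' @param min_identity minimum percent identity (default 30).
#' @param min_coverage minimum alignment_length / query_length (default 0.70).
#' @return list with \code{mean_identity} (percent; \code{NA} when no pair
#'   survives), \code{n_pairs}, \code{coverage_of_reference} (fraction of
#'   distinct subjects hit by a retained pair), and \code{retained}
#'   (the per-query best-hit rows kept).
#' @examples
#' h <- data.frame(query_id = c("q1", "q2"), subject_id = c("s1", "s2"),
#'                 percent_identity = c(96, 25), alignment_length = c(90, 100),
#'                 query_length = c(100, 100), bitscore = c(180, 50))
#' aai(h)$mean_identity  # only q1 retained
#' @export
aai <- function(hits, min_identity = 30, min_coverage = 0.70) {
  req <- c("query_id", "subject_id", "percent_identity",
           "alignment_length", "query_length", "bitscore")
  stopifnot(is.data.frame(hits), all(req %in% names(hits)))
  if (nrow(hits) == 0) {
    warning("empty hit table: AAI undefined")
    return(list(mean_identity = NA_real_, n_pairs = 0L,
                coverage_of_reference = NA_real_,
                retained = hits))
  }
  # deterministic best hit per query: bitscore, then identity, then subject
  o <- order(hits$query_id, -hits$bitscore, -hits$percent_identity,
             hits$subject_id)
  h <- hits[o, ]
  best <- h[!duplicated(h$query_id), ]
  keep <- best$percent_identity >= min_identity &
    best$alignment_length / best$query_length >= min_coverage
  retained <- best[keep, ]
  n_subj <- length(unique(hits$subject_id))
  list(mean_identity = if (nrow(retained)) mean(retained$percent_identity)
       else NA_real_,
       n_pairs = nrow(retained),
       coverage_of_reference = if (n_subj) length(unique(retained$subject_id)) / n_subj
       else NA_real_,
       retained = retained)
}

#' Read a tabular alignment file (blast outfmt-6 dialect)
#'
#' Accepts the standard 12-column tab-separated hit format; only query id,
#' subject id, percent identity, alignment length and bitscore are used,
#' and query lengths are supplied separately (the 12-column dialect does
#' not carry them).
#'
#' @param path tab-separated hit file without header.
#' @param query_lengths named numeric vector, query id -> length (residues).
#' @return data.frame suitable for [aai()].
#' @export
read_hit_table <- function(path, query_lengths) {
  d <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 12) stop("expected >= 12 tab-separated columns in ", path)
  out <- data.frame(query_id = as.character(d[[1]]),
                    subject_id = as.character(d[[2]]),
                    percent_identity = as.numeric(d[[3]]),
                    alignment_length = as.numeric(d[[4]]),
                    bitscore = as.numeric(d[[12]]),
                    stringsAsFactors = FALSE)
  ql <- query_lengths[out$query_id]
  if (anyNA(ql)) stop("missing query length for ",
                      out$query_id[which(is.na(ql))[1]])
  out$query_length <- as.numeric(ql)
  out
}

#' All-vs-all local protein alignment for small proteomes
#'
#' Exact Smith-Waterman alignment (BLOSUM62, affine gap open 11 / extend 1)
#' of every query against every subject, reported as a hit table usable by
#' [aai()]. Intended for desk-scale proteomes (tens to a few hundred
#' proteins); \code{percent_identity} is matches over alignment columns and
#' \code{bitscore} carries the raw alignment score as the ranking key.
#'
#' @param queries,subjects named character vectors or \code{AAStringSet}.
#' @return data.frame hit table (one row per query/subject pair with
#'   positive alignment score).
#' @export
align_proteins <- function(queries, subjects) {
  q <- if (inherits(queries, "AAStringSet")) queries
       else Biostrings::AAStringSet(queries)
  s <- if (inherits(subjects, "AAStringSet")) subjects
       else Biostrings::AAStringSet(subjects)
  if (is.null(names(q)) || is.null(names(s)))
    stop("queries and subjects must be named")
  rows <- vector("list", length(q) * length(s))
  r <- 0L
  for (i in seq_along(q)) {
    aln <- Biostrings::pairwiseAlignment(
      rep(q[i], length(s)), s, type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    sc <- Biostrings::score(aln)
    for (j in seq_along(s)) {
      if (sc[j] <= 0) next
      r <- r + 1L
      al <- Biostrings::nchar(aln[j])
      rows[[r]] <- data.frame(
        query_id = names(q)[i], subject_id = names(s)[j],
        percent_identity = 100 * Biostrings::nmatch(aln[j]) / al,
        alignment_length = al,
        query_length = Biostrings::width(q)[i],
        bitscore = sc[j], stringsAsFactors = FALSE)
    }
  }
  if (r == 0L)
    return(data.frame(query_id = character(0), subject_id = character(0),
                      percent_identity = numeric(0),
                      alignment_length = numeric(0),
                      query_length = numeric(0), bitscore = numeric(0)))
  do.call(rbind, rows[seq_len(r)])
}

#' Assembly summary statistics
#'
#' Totals, N50 and GC over a set of contigs. N50 is the largest contig
#' length L in the set such that contigs of length >= L sum to at least
#' half of the total; GC is computed over all non-N bases.
#'
#' @param contigs a [contig_set()], \code{DNAStringSet}, or a numeric
#'   vector of lengths (GC then reported as \code{NA}).
#' @return list with \code{total_bp}, \code{n_contigs}, \code{n50},
#'   \code{gc_percent}, \code{n_ge_1kbp}.
#' @examples
#' assembly_stats(c(8, 8, 4))$n50
#' @export
assembly_stats <- function(contigs) {
  gc_percent <- NA_real_
  if (inherits(contigs, "contig_set")) {
    lens <- contigs$meta$length
    seqs <- contigs$sequences
  } else if (inherits(contigs, "DNAStringSet")) {
    lens <- Biostrings::width(contigs)
    seqs <- contigs
  } else {
    lens <- as.numeric(contigs)
    seqs <- NULL
  }
  if (length(lens) == 0) stop("empty contig set")
  if (!is.null(seqs)) {
    acgt <- colSums(Biostrings::letterFrequency(seqs, c("A", "C", "G", "T")))
    gc_percent <- 100 * sum(acgt[c("C", "G")]) / sum(acgt)
  }
  lens_sorted <- sort(lens, decreasing = TRUE)
  cum <- cumsum(lens_sorted)
  n50 <- lens_sorted[which(cum >= sum(lens) / 2)[1]]
  list(total_bp = sum(lens), n_contigs = length(lens), n50 = n50,
       gc_percent = gc_percent, n_ge_1kbp = sum(lens >= 1000))
}
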