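#' Protein records for reference-database construction
#'
#' Assembles gene calls, protein sequences and contig coverage into the
#' record table used for reliability scoring and dereplication. A gene is
#' flagged \code{near_edge} when it starts within 200 bp of the contig
#' 5' end or ends within 200 bp of the 3' end (1-based inclusive
#' nucleotide coordinates, strand-agnostic): such calls are more likely to
#' be truncated.
#'
#' @param proteins named character vector or \code{AAStringSet} of protein
#'   sequences.
#' @param genes data.frame with columns \code{protein_id},
#'   \code{contig_id}, \code{start}, \code{end}, \code{strand}.
#' @param contig_info data.frame with columns \code{contig_id},
#'   \code{length}, \code{coverage}.
#' @param edge_margin bp from either contig end that flags a gene
#'   (default 200).
#' @return data.frame of class \code{protein_records} with one row per
#'   protein: id, contig, sequence, length (residues), contig_coverage,
#'   start, end, strand, near_edge.
#' @export
protein_records <- function(proteins, genes, contig_info, edge_margin = 200) {
  aa <- if (inherits(proteins, "AAStringSet")) proteins
        else Biostrings::AAStringSet(proteins)
  if (is.null(names(aa)) || anyDuplicated(names(aa)))
    stop("proteins must have unique names")
  stopifnot(all(c("protein_id", "contig_id", "start", "end", "strand")
                %in% names(genes)),
            all(c("contig_id", "length", "coverage") %in% names(contig_info)))
  g <- genes[match(names(aa), genes$protein_id), ]
  if (anyNA(g$protein_id))
    stop("no gene call for protein ", names(aa)[which(is.na(g$protein_id))[1]])
  ci <- contig_info[match(g$contig_id, contig_info$contig_id), ]
  if (anyNA(ci$contig_id))
    stop("unknown contig in gene calls: ", g$contig_id[which(is.na(ci$contig_id))[1]])
  if (any(g$start < 1 | g$end < g$start | g$end > ci$length))
    stop("gene coordinates outside contig bounds")
  out <- data.frame(protein_id = names(aa),
                    contig_id = g$contig_id,
                    aa_sequence = as.character(aa),
                    length = Biostrings::width(aa),
                    contig_coverage = ci$coverage,
                    start = g$start, end = g$end, strand = g$strand,
                    near_edge = g$start <= edge_margin |
                      g$end >= ci$length - edge_margin + 1,
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Reliability score of a protein record
#'
#' Ranks gene calls by how trustworthy their sequence is for use in a
#' proteomics search database: higher contig coverage means fewer
#' sequencing errors, longer proteins are less likely to be truncated by a
#' bad gene call or frameshift, and genes near a contig end are penalised.
#' The default additive log-scale form is
#' \deqn{log10(1 + coverage) + w_{len} log10(length) - w_{edge} [near\_edge]}
#' which realises that ordering with configurable weights. The
#' \code{"lexicographic"} mode instead sorts strictly by (coverage, length,
#' not-near-edge) and returns a rank-based key.
#'
#' @param records a [protein_records()] table (or any data.frame with
#'   \code{contig_coverage}, \code{length}, \code{near_edge}).
#' @param w_len,w_edge weights of the length term and edge penalty.
#' @param mode \code{"additive"} (default) or \code{"lexicographic"}.
#' @return numeric vector of scores (higher = more reliable).
#' @examples
#' r <- data.frame(contig_coverage = c(70, 10), length = c(300, 300),
#'                 near_edge = c(FALSE, FALSE))
#' score_protein(r)
#' @export
score_protein <- function(records, w_len = 1, w_edge = 1,
                          mode = c("additive", "lexicographic")) {
  mode <- match.arg(mode)
  if (any(records$length <= 0)) stop("non-positive protein length")
  if (mode == "additive")
    return(log10(1 + records$contig_coverage) +
             w_len * log10(records$length) -
             w_edge * as.numeric(records$near_edge))
  o <- order(records$contig_coverage, records$length, !records$near_edge)
  rank <- integer(nrow(records)); rank[o] <- seq_len(nrow(records))
  as.numeric(rank)
}

#' Greedy dereplication at a global-identity threshold
#'
#' Collapses near-identical proteins to their most reliable representative
#' (greedy centroid clustering): records are processed in descending
#' reliability score (ties by protein id); each joins the first existing
#' cluster whose representative it matches at \code{>= threshold} global
#' identity (matches over alignment columns of a global alignment, gaps
#' counting against), otherwise it founds a new cluster. Representatives
#' are therefore always the highest-scoring member of their cluster. A
#' 5-mer prefilter skips alignments between hopeless pairs.
#'
#' @param records a [protein_records()] table.
#' @param threshold global identity threshold in (0, 1] (default 0.95).
#' @param scores optional numeric vector of reliability scores (defaults
#'   to [score_protein()] on \code{records}).
#' @return list of class \code{derep_result}: \code{clusters} (data.frame
#'   representative_id, member_id, identity), \code{representatives}
#'   (character vector), \code{threshold}.
#' @export
dereplicate <- function(records, threshold = 0.95,
                        scores = score_protein(records)) {
  stopifnot(nrow(records) > 0, threshold > 0, threshold <= 1,
            length(scores) == nrow(records))
  ord <- order(-scores, records$protein_id)
  ids <- records$protein_id[ord]
  seqs <- records$aa_sequence[ord]
  kmer_sets <- lapply(seqs, function(s) unique(substring(
    s, seq_len(max(nchar(s) - 4L, 1L)),
    pmin(seq_len(max(nchar(s) - 4L, 1L)) + 4L, nchar(s)))))
  rep_idx <- integer(0)           # indices (into ord) of representatives
  assign_to <- integer(length(ids))
  identity <- numeric(length(ids))
  for (i in seq_along(ids)) {
    hit <- 0L
    for (r in rep_idx) {
      shared <- length(intersect(kmer_sets[[i]], kmer_sets[[r]]))
      if (shared / min(lengths(kmer_sets)[c(i, r)]) < 0.5) next
      pid <- global_identity(seqs[i], seqs[r])
      if (pid >= threshold) { hit <- r; identity[i] <- pid; break }
    }
    if (hit == 0L) {
      rep_idx <- c(rep_idx, i)
      assign_to[i] <- i
      identity[i] <- 1
    } else assign_to[i] <- hit
  }
  clusters <- data.frame(representative_id = ids[assign_to],
                         member_id = ids,
                         identity = identity,
                         stringsAsFactors = FALSE)
  structure(list(clusters = clusters,
                 representatives = ids[rep_idx],
                 threshold = threshold),
            class = "derep_result")
}

#' @export
print.derep_result <- function(x, ...) {
  cat(sprintf(
    "derep_result: %d sequences -> %d clusters at %.0f%% identity\n",
    nrow(x$clusters), length(x$representatives), 100 * x$threshold))
  invisible(x)
}

#' Global percent identity of two protein sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 11 / extend 1);
#' identity is matches over alignment columns, so gaps count against.
#'
#' @param a,b protein sequences (character scalars).
#' @return identity fraction in [0, 1].
#' @export
global_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Export a dereplicated database as FASTA
#'
#' One record per cluster representative; headers carry the protein id,
#' contig id, reliability score and cluster size.
#'
#' @param result a [dereplicate()] result.
#' @param records the [protein_records()] the result was computed from.
#' @param path output FASTA path.
#' @param scores reliability scores (defaults to [score_protein()]).
#' @return the path, invisibly.
#' @export
export_database <- function(result, records, path,
                            scores = score_protein(records)) {
  stopifnot(inherits(result, "derep_result"))
  sizes <- table(result$clusters$representative_id)
  idx <- match(result$representatives, records$protein_id)
  headers <- sprintf("%s contig=%s score=%.4f n=%d",
                     result$representatives,
                     records$contig_id[idx],
                     scores[idx],
                     as.integer(sizes[result$representatives]))
  seqs <- Biostrings::AAStringSet(records$aa_sequence[idx])
  names(seqs) <- headers
  write_fasta(seqs, path)
}
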