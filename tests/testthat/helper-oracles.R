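# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths.

# total-variation distance between 4-mer distributions of two DNA strings,
# by direct substring tabulation (single-strand)
oracle_tv4 <- function(a, b) {
  count4 <- function(s) {
    n <- nchar(s)
    words <- substring(s, 1:(n - 3), 4:n)
    words <- words[!grepl("[^ACGT]", words)]
    tab <- table(factor(words, levels = all4mers()))
    tab / sum(tab)
  }
  0.5 * sum(abs(count4(a) - count4(b)))
}

all4mers <- function() {
  b <- c("A", "C", "G", "T")
  apply(expand.grid(b, b, b, b)[, 4:1], 1, paste, collapse = "")
}

# N50 by exhaustive prefix scan
oracle_n50 <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  half <- sum(lens) / 2
  for (i in seq_along(lens)) if (sum(lens[1:i]) >= half) return(lens[i])
}

# best-hit AAI by explicit per-query loops
oracle_aai <- function(hits, min_id = 30, min_cov = 0.70) {
  kept <- c()
  for (q in unique(hits$query_id)) {
    h <- hits[hits$query_id == q, ]
    h <- h[order(-h$bitscore, -h$percent_identity, h$subject_id), ][1, ]
    if (h$percent_identity >= min_id &&
        h$alignment_length / h$query_length >= min_cov)
      kept <- c(kept, h$percent_identity)
  }
  if (length(kept)) mean(kept) else NA_real_
}

# greedy dereplication against a full pairwise identity matrix
oracle_derep <- function(ids, scores, idmat, threshold) {
  ord <- order(-scores, ids)
  reps <- integer(0)
  assign <- setNames(character(length(ids)), ids)
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      if (idmat[i, r] >= threshold) {
        assign[ids[i]] <- ids[r]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[ids[i]] <- ids[i]
    }
  }
  assign
}

# two-sided Fisher p by direct hypergeometric-tail enumeration
oracle_fisher2 <- function(k_in, n_in, k_out, n_out) {
  K <- k_in + k_out                     # total flagged
  ks <- max(0, K - n_out):min(n_in, K)  # feasible flagged-in counts
  d <- dhyper(ks, n_in, n_out, K)
  sum(d[d <= dhyper(k_in, n_in, n_out, K) * (1 + 1e-7)])
}

# BH step-up: largest i with p_(i) <= i*fdr/m marks p_(1..i)
oracle_bh_significant <- function(p, fdr) {
  o <- order(p)
  m <- length(p)
  thresh <- which(p[o] <= seq_len(m) * fdr / m)
  sig <- logical(m)
  if (length(thresh)) sig[o[seq_len(max(thresh))]] <- TRUE
  sig
}

# random protein sequence
random_protein <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random DNA string
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# tiny contig set with given sequences / coverages / markers
tiny_contigs <- function(seqs, coverage = 10, markers = NULL) {
  contig_set(seqs, coverage, markers)
}
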