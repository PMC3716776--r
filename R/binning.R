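#' Marker-seeded composition binning
#'
#' Implements the two-round, composition-based phylogenetic binning
#' procedure for assembled contigs of a simple community:
#' \enumerate{
#'   \item \code{\link{seed_bins}}: contigs carrying a strict majority of
#'     single-copy marker genes from one taxon seed that taxon's bin.
#'   \item \code{\link{assign_round}}: all contigs >= \code{min_len} are
#'     scored against every bin's order-3 De Bruijn chain signature and
#'     assigned to the lowest-scoring bin, provided the score passes
#'     \code{score_max} and the second-best score is at least
#'     \code{margin} times the best (an ambiguity veto that leaves contigs
#'     "falling between two bins" unassigned).
#'   \item \code{\link{merge_or_delete_bins}}: seed bins whose signatures
#'     are mutually indistinguishable are merged; bins that shrank in the
#'     vetoed round and have no merge partner are deleted.
#'   \item a second vetoed round against the revised bins, then
#'     \code{\link{final_classify}}: every contig >= \code{min_len} goes to
#'     its best-scoring bin with no veto.
#' }
#'
#' @param contigs a [contig_set()].
#' @param score_max maximum composition score for the vetoed rounds.
#' @param margin second-best / best score ratio required for assignment.
#' @param min_len minimum contig length (bp) considered.
#' @param order De Bruijn chain order (default 3).
#' @param similarity_max model-to-model score below which two seed bins are
#'   merged.
#' @param strand strand policy for the composition signature.
#' @param metric composition metric, \code{"tv"} or \code{"nll"} (see
#'   [composition_score()]; the score thresholds are on the metric's scale).
#' @return A \code{bin_set} (see [seed_bins()]) after final classification.
#' @export
run_binning <- function(contigs, score_max = 0.01, margin = 1.2,
                        min_len = 1000, order = 3L, similarity_max = 0.01,
                        strand = "canonical", metric = "tv") {
  bins <- seed_bins(contigs, order = order, strand = strand, metric = metric)
  bins <- assign_round(contigs, bins, score_max = score_max, margin = margin,
                       min_len = min_len, round = 1L)
  bins <- merge_or_delete_bins(bins, contigs, similarity_max = similarity_max)
  bins <- assign_round(contigs, bins, score_max = score_max, margin = margin,
                       min_len = min_len, round = 2L)
  final_classify(contigs, bins, min_len = min_len)
}

#' Seed bins from marker-gene majorities
#'
#' Each contig carrying phylogenetic markers votes for the taxon holding a
#' strict majority (> half) of its markers; contigs with tied or plurality-
#' only votes seed nothing. One seed bin is created per taxon that wins at
#' least one contig, and its composition model is built from its member
#' contigs.
#'
#' @inheritParams run_binning
#' @return A \code{bin_set}: list with \code{bins} (named list of
#'   \code{label}, \code{members}, \code{model}), \code{unassigned},
#'   \code{round_log}, \code{seed_sizes} and the scoring settings.
#' @export
seed_bins <- function(contigs, order = 3L, strand = "canonical",
                      metric = "tv") {
  stopifnot(inherits(contigs, "contig_set"))
  has_mk <- vapply(contigs$markers,
                   function(m) !is.null(m) && nrow(m) > 0, TRUE)
  if (!any(has_mk)) stop("no contig carries markers; cannot seed bins")
  votes <- lapply(contigs$markers[has_mk], function(m) {
    tab <- table(m$taxon)
    if (max(tab) > sum(tab) / 2) names(tab)[which.max(tab)] else NA_character_
  })
  votes <- unlist(votes)
  votes <- votes[!is.na(votes)]
  if (length(votes) == 0) stop("all marker-bearing contigs are tied")
  members <- split(names(votes), votes)
  bins <- lapply(names(members), function(lab) {
    ids <- members[[lab]]
    list(label = lab, members = ids,
         model = build_composition_model(contigs[ids]$sequences,
                                         order = order, strand = strand))
  })
  names(bins) <- names(members)
  structure(list(bins = bins,
                 unassigned = setdiff(contigs$meta$id, unlist(members)),
                 round_log = empty_round_log(),
                 seed_sizes = lengths(members),
                 order = as.integer(order), strand = strand, metric = metric),
            class = "bin_set")
}

#' @export
print.bin_set <- function(x, ...) {
  sizes <- vapply(x$bins, function(b) length(b$members), 0L)
  cat(sprintf("bin_set: %d bins, %d contigs assigned, %d unassigned\n",
              length(x$bins), sum(sizes), length(x$unassigned)))
  for (b in x$bins)
    cat(sprintf("  %-28s %d contigs\n", b$label, length(b$members)))
  invisible(x)
}

empty_round_log <- function() {
  data.frame(round = character(0), contig = character(0),
             best_bin = character(0), best_score = numeric(0),
             second_bin = character(0), second_score = numeric(0),
             decision = character(0), stringsAsFactors = FALSE)
}

# score matrix: contigs x bins, given the bin_set's metric/order/strand
score_matrix <- function(contigs, bins) {
  labs <- names(bins$bins)
  if (bins$metric == "tv") {
    P <- kmer_profiles(contigs$sequences, width = bins$order + 1L,
                       strand = bins$strand)
    S <- vapply(labs, function(l) {
      q <- bins$bins[[l]]$model$frequencies
      0.5 * rowSums(abs(sweep(P, 2L, q)))
    }, numeric(nrow(P)))
  } else {
    C <- Biostrings::oligonucleotideFrequency(contigs$sequences,
                                              width = bins$order + 1L)
    if (bins$strand == "canonical")
      C <- C + Biostrings::oligonucleotideFrequency(
        Biostrings::reverseComplement(contigs$sequences),
        width = bins$order + 1L)
    tot <- rowSums(C)
    S <- vapply(labs, function(l) {
      logt <- log(pmax(t(bins$bins[[l]]$model$transitions),
                       .Machine$double.xmin))
      as.numeric(-(C %*% as.vector(logt)) / ifelse(tot == 0, NA_real_, tot))
    }, numeric(nrow(C)))
    S[tot == 0, ] <- NA_real_
  }
  if (!is.matrix(S)) S <- matrix(S, ncol = length(labs),
                                 dimnames = list(contigs$meta$id, labs))
  rownames(S) <- contigs$meta$id
  S
}

#' One vetoed assignment round
#'
#' Scores every contig of at least \code{min_len} bp against all current
#' bin models and assigns it to the lowest-scoring bin iff the best score
#' is below \code{score_max} and the second-best score is at least
#' \code{margin} times the best. Contigs failing either rule stay
#' unassigned ("fell between two bins"). Bin membership is replaced by the
#' round's confident assignments; models are not rebuilt within a round.
#'
#' @inheritParams run_binning
#' @param bins a \code{bin_set}.
#' @param round integer label recorded in the round log.
#' @return The updated \code{bin_set} with an appended \code{round_log}.
#' @export
assign_round <- function(contigs, bins, score_max = 0.01, margin = 1.2,
                         min_len = 1000, round = 1L) {
  stopifnot(inherits(bins, "bin_set"), length(bins$bins) > 0,
            score_max > 0, margin >= 1)
  elig <- contigs$meta$length >= min_len
  sub <- contigs[which(elig)]
  S <- score_matrix(sub, bins)
  log <- decide_assignments(S, score_max = score_max, margin = margin,
                            round = as.character(round))
  assigned <- log$contig[log$decision == "assigned"]
  for (l in names(bins$bins))
    bins$bins[[l]]$members <-
      log$contig[log$decision == "assigned" & log$best_bin == l]
  bins$unassigned <- setdiff(contigs$meta$id, assigned)
  bins$round_log <- rbind(bins$round_log, log)
  bins
}

decide_assignments <- function(S, score_max = Inf, margin = 1,
                               round = "final") {
  labs <- colnames(S)
  n <- nrow(S)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- S[i, ]
    if (anyNA(s)) {
      out[[i]] <- data.frame(round = round, contig = rownames(S)[i],
                             best_bin = NA_character_, best_score = NA_real_,
                             second_bin = NA_character_,
                             second_score = NA_real_,
                             decision = "unscorable",
                             stringsAsFactors = FALSE)
      next
    }
    o <- order(s, labs)  # ties resolved to the lexicographically smallest
    best <- o[1]
    second <- if (length(s) > 1) o[2] else NA_integer_
    bs <- s[best]
    ss <- if (is.na(second)) Inf else s[second]
    tie <- !is.na(second) && ss == bs
    decision <- if (bs >= score_max) "score_above_max"
    else if (ss < margin * bs) "ambiguous"
    else if (tie) "tie"          # only reachable when margin <= 1 (final)
    else "assigned"
    out[[i]] <- data.frame(round = round, contig = rownames(S)[i],
                           best_bin = labs[best], best_score = bs,
                           second_bin = if (is.na(second)) NA_character_
                           else labs[second],
                           second_score = if (is.finite(ss)) ss else NA_real_,
                           decision = decision, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Merge indistinguishable seed bins, delete shrinking ones
#'
#' Any pair of bins whose model-to-model composition score is below
#' \code{similarity_max} is merged (the merged bin takes the larger bin's
#' label with a \code{"+merged"} suffix). A bin that lost members in the
#' preceding vetoed round (its membership fell below its seed size,
#' signalling a signature too similar to other bins) and has no merge
#' partner is deleted; its contigs return to the unassigned pool. Models
#' are rebuilt from the merged memberships.
#'
#' @inheritParams run_binning
#' @param bins a \code{bin_set} after a completed assignment round.
#' @return The revised \code{bin_set}.
#' @export
merge_or_delete_bins <- function(bins, contigs, similarity_max = 0.01) {
  stopifnot(inherits(bins, "bin_set"))
  labs <- names(bins$bins)
  k <- length(labs)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  has_partner <- rep(FALSE, k)
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      d <- composition_score(bins$bins[[i]]$model, bins$bins[[j]]$model,
                             metric = bins$metric)
      if (d < similarity_max) {
        has_partner[c(i, j)] <- TRUE
        parent[find(j)] <- find(i)
      }
    }
  }
  sizes <- vapply(bins$bins, function(b) length(b$members), 0L)
  shrank <- sizes < bins$seed_sizes[labs]
  drop <- shrank & !has_partner
  groups <- split(seq_len(k)[!drop],
                  vapply(seq_len(k)[!drop], find, 0L))
  if (length(groups) == 0)
    stop("merge/delete removed every bin; composition signatures are ",
         "insufficient at these thresholds")
  new_bins <- list()
  new_seed <- integer(0)
  for (g in groups) {
    members <- unique(unlist(lapply(bins$bins[g], `[[`, "members")))
    big <- g[order(-sizes[g], labs[g])][1]
    lab <- if (length(g) > 1) paste0(labs[big], "+merged") else labs[big]
    model <- if (length(members) > 0)
      build_composition_model(contigs[members]$sequences,
                              order = bins$order, strand = bins$strand)
    else bins$bins[[big]]$model
    new_bins[[lab]] <- list(label = lab, members = members, model = model)
    new_seed[lab] <- sum(bins$seed_sizes[labs[g]])
  }
  bins$bins <- new_bins
  bins$seed_sizes <- new_seed
  bins$unassigned <- setdiff(contigs$meta$id,
                             unlist(lapply(new_bins, `[[`, "members")))
  bins
}

#' Final unvetoed classification
#'
#' Rebuilds every bin's model from its current (enlarged) membership and
#' assigns each contig of at least \code{min_len} bp to its best-scoring
#' bin with no score cutoff and no ambiguity veto. Exact score ties go to
#' the lexicographically smallest bin label and are logged. Contigs below
#' \code{min_len} remain unassigned.
#'
#' @inheritParams run_binning
#' @param bins a \code{bin_set} from the second vetoed round.
#' @return The final \code{bin_set}.
#' @export
final_classify <- function(contigs, bins, min_len = 1000) {
  stopifnot(inherits(bins, "bin_set"))
  for (l in names(bins$bins)) {
    m <- bins$bins[[l]]$members
    if (length(m) > 0)
      bins$bins[[l]]$model <-
        build_composition_model(contigs[m]$sequences,
                                order = bins$order, strand = bins$strand)
  }
  elig <- contigs$meta$length >= min_len
  sub <- contigs[which(elig)]
  S <- score_matrix(sub, bins)
  log <- decide_assignments(S, score_max = Inf, margin = 1, round = "final")
  ok <- log$decision %in% c("assigned", "tie")
  for (l in names(bins$bins))
    bins$bins[[l]]$members <- log$contig[ok & log$best_bin == l]
  bins$unassigned <- setdiff(contigs$meta$id, log$contig[ok])
  bins$round_log <- rbind(bins$round_log, log)
  bins
}

#' Contig-to-bin assignment vector
#' @param bins a \code{bin_set}.
#' @return named character vector, contig id -> bin label.
#' @export
bin_assignment <- function(bins) {
  stopifnot(inherits(bins, "bin_set"))
  out <- unlist(unname(lapply(bins$bins, function(b)
    stats::setNames(rep(b$label, length(b$members)), b$members))))
  if (is.null(out)) out <- character(0)
  out
}

#' Extract coverage clusters from a bin
#'
#' Identifies tight clusters of contigs centred on specific read coverages
#' within one bin - the signature of distinct population genome
#' reconstructions sharing a composition signature. A Gaussian kernel
#' density (bandwidth \code{bandwidth_log2}) of length-weighted
#' log2(coverage) is evaluated; each local mode defines a cluster whose
#' members are the contigs in its basin of attraction (between the
#' flanking density minima). This automates what was historically done by
#' eye on a coverage-GC scatter, so the rule is a reproducible surrogate
#' rather than a canonical definition.
#'
#' @param contigs a [contig_set()] holding one bin's members (coverage > 0).
#' @param bandwidth_log2 kernel bandwidth in log2 coverage units.
#' @param bin_label label recorded in the output.
#' @return data.frame with one row per cluster: \code{bin},
#'   \code{coverage_mode}, \code{cov_lo}, \code{cov_hi}, \code{n_contigs},
#'   \code{total_bp}, \code{n50}, \code{mean_gc_percent}; the member ids
#'   are attached as the \code{"members"} attribute (a list).
#' @export
extract_coverage_clusters <- function(contigs, bandwidth_log2 = 0.5,
                                      bin_label = "bin") {
  stopifnot(inherits(contigs, "contig_set"))
  if (nrow(contigs$meta) == 0) stop("empty bin")
  if (any(contigs$meta$coverage <= 0))
    stop("coverage clustering requires coverage > 0")
  x <- log2(contigs$meta$coverage)
  w <- contigs$meta$length / sum(contigs$meta$length)
  if (length(x) == 1 || diff(range(x)) < 1e-12) {
    breaks <- c(-Inf, Inf)
    modes <- x[1]
  } else {
    d <- stats::density(x, bw = bandwidth_log2, weights = w,
                        from = min(x) - 3 * bandwidth_log2,
                        to = max(x) + 3 * bandwidth_log2, n = 512)
    y <- d$y
    n <- length(y)
    is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                  y[2:(n - 1)] >= y[3:n], FALSE)
    is_min <- c(FALSE, y[2:(n - 1)] < y[1:(n - 2)] &
                  y[2:(n - 1)] <= y[3:n], FALSE)
    modes <- d$x[is_max]
    if (length(modes) == 0) modes <- d$x[which.max(y)]
    mins <- d$x[is_min]
    # keep only minima separating consecutive modes
    sep <- vapply(seq_len(length(modes) - 1), function(i) {
      inb <- mins[mins > modes[i] & mins < modes[i + 1]]
      if (length(inb)) inb[which.min(
        y[vapply(inb, function(v) which.min(abs(d$x - v)), 0L)])]
      else mean(modes[i:(i + 1)])
    }, 0)
    breaks <- c(-Inf, sep, Inf)
  }
  grp <- cut(x, breaks = breaks, labels = FALSE)
  rows <- list(); memb <- list()
  for (g in sort(unique(grp))) {
    sel <- grp == g
    m <- contigs$meta[sel, ]
    st <- assembly_stats(m$length)
    rows[[length(rows) + 1L]] <- data.frame(
      bin = bin_label,
      coverage_mode = 2^modes[min(g, length(modes))],
      cov_lo = min(m$coverage), cov_hi = max(m$coverage),
      n_contigs = nrow(m), total_bp = st$total_bp, n50 = st$n50,
      mean_gc_percent = 100 * sum(m$gc * m$length) / sum(m$length),
      stringsAsFactors = FALSE)
    memb[[length(memb) + 1L]] <- m$id
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$coverage_mode), ]
  attr(out, "members") <- memb[order(-vapply(rows, function(r)
    r$coverage_mode, 0))]
  rownames(out) <- NULL
  out
}

#' Per-bin coverage-cluster report
#'
#' Applies [extract_coverage_clusters()] to every bin, producing the
#' genome-reconstruction summary table (coverage mode, GC, size, contig
#' count, N50 per cluster).
#'
#' @param bins a \code{bin_set}.
#' @param contigs the [contig_set()] the bins were built from.
#' @param bandwidth_log2 kernel bandwidth in log2 coverage units.
#' @return data.frame, one row per coverage cluster.
#' @export
bin_report <- function(bins, contigs, bandwidth_log2 = 0.5) {
  stopifnot(inherits(bins, "bin_set"))
  out <- lapply(names(bins$bins), function(l) {
    m <- bins$bins[[l]]$members
    if (length(m) == 0) return(NULL)
    extract_coverage_clusters(contigs[m], bandwidth_log2, bin_label = l)
  })
  do.call(rbind, out)
}
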