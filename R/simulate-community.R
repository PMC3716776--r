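#' Population specification for a synthetic community
#'
#' Describes one member population of a synthetic consortium metagenome:
#' its genome size, GC content, how distinct its oligonucleotide
#' composition is from a GC-matched baseline, its sequencing depth, and how
#' many single-copy marker genes to plant on its contigs.
#'
#' @param label taxon name (unique within a community).
#' @param genome_length total assembled bp for the population.
#' @param gc_target GC fraction in (0, 1); the generator constrains every
#'   transition row so realised GC converges to this value.
#' @param composition_divergence scalar >= 0 controlling how far the
#'   population's order-3 transition matrix is perturbed from the GC-matched
#'   baseline; approximately the expected total-variation separation between
#'   two populations' tetranucleotide profiles at the same setting.
#' @param mean_coverage mean read depth (x-fold), > 0.
#' @param coverage_cv coefficient of variation of per-contig coverage
#'   (log-normal noise).
#' @param n_marker_genes number of single-copy marker COGs to plant (<= 54).
#' @return A \code{population_spec} list.
#' @export
population_spec <- function(label, genome_length = 3e6, gc_target = 0.60,
                            composition_divergence = 0.3,
                            mean_coverage = 30, coverage_cv = 0.15,
                            n_marker_genes = 40) {
  stopifnot(is.character(label), nchar(label) > 0,
            genome_length > 0,
            gc_target > 0, gc_target < 1,
            composition_divergence >= 0,
            mean_coverage > 0, coverage_cv >= 0,
            n_marker_genes >= 0, n_marker_genes <= 54)
  structure(list(label = label, genome_length = genome_length,
                 gc_target = gc_target,
                 composition_divergence = composition_divergence,
                 mean_coverage = mean_coverage, coverage_cv = coverage_cv,
                 n_marker_genes = as.integer(n_marker_genes)),
            class = "population_spec")
}

#' Community specification for the synthetic metagenome generator
#'
#' @param populations list of [population_spec()] objects with unique labels.
#' @param contig_length_meanlog,contig_length_sdlog log-normal parameters of
#'   contig length (bp).
#' @param min_contig_length,max_contig_length truncation bounds on sampled
#'   contig lengths (bp).
#' @param rng_seed integer seed; the generator is a pure function of the
#'   spec, so identical specs give byte-identical output.
#' @return A \code{community_spec} list.
#' @export
community_spec <- function(populations,
                           contig_length_meanlog = log(6000),
                           contig_length_sdlog = 0.9,
                           min_contig_length = 1000,
                           max_contig_length = 50000,
                           rng_seed = 1L) {
  if (length(populations) == 0) stop("at least one population is required")
  if (inherits(populations, "population_spec")) populations <- list(populations)
  labels <- vapply(populations, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("population labels must be unique")
  stopifnot(min_contig_length > 0,
            max_contig_length >= min_contig_length)
  structure(list(populations = populations,
                 contig_length_meanlog = contig_length_meanlog,
                 contig_length_sdlog = contig_length_sdlog,
                 min_contig_length = min_contig_length,
                 max_contig_length = max_contig_length,
                 rng_seed = as.integer(rng_seed)),
            class = "community_spec")
}

#' Four-population demo community
#'
#' The bundled study-like configuration: four populations of 3 Mbp at
#' coverages 70/35/25/10x with distinct GC and composition divergence 0.3,
#' contigs 1-50 kbp.
#'
#' @param rng_seed integer seed.
#' @param composition_divergence divergence applied to every population.
#' @param genome_length bp per population.
#' @export
demo_community_spec <- function(rng_seed = 1L, composition_divergence = 0.3,
                                genome_length = 3e6) {
  pops <- mapply(population_spec,
                 label = c("Thermus", "Rhodothermus", "Paenibacillus",
                           "Gemmatimonas"),
                 gc_target = c(0.68, 0.64, 0.52, 0.60),
                 mean_coverage = c(70, 35, 25, 10),
                 MoreArgs = list(genome_length = genome_length,
                                 composition_divergence = composition_divergence,
                                 coverage_cv = 0.15, n_marker_genes = 40),
                 SIMPLIFY = FALSE)
  community_spec(pops, rng_seed = rng_seed)
}

#' Simulate a synthetic consortium metagenome
#'
#' Generates contigs for each population from its own order-3 Markov chain
#' (De Bruijn chain), perturbed from a GC-matched baseline by the
#' population's \code{composition_divergence}; assigns per-contig coverage
#' as the population mean times log-normal noise; and plants single-copy
#' marker genes on randomly chosen contigs. Ground truth is returned for
#' every contig.
#'
#' Each transition row is Dirichlet-perturbed with concentration
#' \code{1 / divergence^2} and then rescaled so the probability of drawing
#' G or C equals \code{gc_target} exactly, which pins the realised GC of
#' every population at its target regardless of divergence.
#'
#' @param spec a [community_spec()].
#' @return A list with \code{contigs} (a [contig_set()]), \code{truth}
#'   (named character vector contig id -> population label),
#'   \code{marker_truth} (data.frame contig, cog, taxon) and
#'   \code{transition_matrices} (the generating chains, for diagnostics).
#' @examples
#' spec <- community_spec(list(
#'   population_spec("A", genome_length = 5e4, mean_coverage = 50),
#'   population_spec("B", genome_length = 5e4, gc_target = 0.45,
#'                   mean_coverage = 10)), rng_seed = 7)
#' sim <- simulate_community(spec)
#' table(sim$truth)
#' @export
simulate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(spec$rng_seed, {
    seq_list <- list()
    cov_list <- list()
    truth <- character(0)
    marker_rows <- list()
    tmats <- list()
    for (pop in spec$populations) {
      tm <- population_transition_matrix(pop$gc_target,
                                         pop$composition_divergence)
      tmats[[pop$label]] <- tm
      lens <- sample_contig_lengths(pop$genome_length,
                                    spec$contig_length_meanlog,
                                    spec$contig_length_sdlog,
                                    spec$min_contig_length,
                                    spec$max_contig_length)
      ids <- sprintf("%s_c%04d", pop$label, seq_along(lens))
      base_p <- gc_base_probs(pop$gc_target)
      seqs <- vapply(lens, function(L)
        .simulate_chain_cpp(L, tm, base_p, 3L), "")
      names(seqs) <- ids
      sdlog <- sqrt(log(1 + pop$coverage_cv^2))
      covs <- pop$mean_coverage *
        stats::rlnorm(length(lens), -sdlog^2 / 2, sdlog)
      seq_list[[pop$label]] <- seqs
      cov_list[[pop$label]] <- covs
      truth <- c(truth, stats::setNames(rep(pop$label, length(ids)), ids))
      if (pop$n_marker_genes > 0) {
        cogs <- sample(marker_cogs()$cog, pop$n_marker_genes)
        host <- sample(ids, pop$n_marker_genes, replace = TRUE)
        marker_rows[[pop$label]] <- data.frame(
          contig = host, cog = cogs, taxon = pop$label,
          stringsAsFactors = FALSE)
      }
    }
    markers <- do.call(rbind, marker_rows)
    mk <- NULL
    if (!is.null(markers) && nrow(markers) > 0)
      mk <- lapply(split(markers[c("cog", "taxon")], markers$contig),
                   function(d) { rownames(d) <- NULL; d })
    contigs <- contig_set(unlist(unname(seq_list)),
                          unlist(cov_list, use.names = FALSE),
                          markers = mk)
    list(contigs = contigs, truth = truth,
         marker_truth = markers, transition_matrices = tmats)
  })
}

# baseline next-base probabilities implied by a GC target
gc_base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2,
                                G = gc / 2, T = (1 - gc) / 2)

# 64 x 4 transition matrix: GC-matched baseline, Dirichlet-perturbed rows
# (concentration 1/d^2), each row rescaled so P(next in {C,G}) = gc exactly
population_transition_matrix <- function(gc_target, divergence) {
  base <- gc_base_probs(gc_target)
  tm <- matrix(base, nrow = 64, ncol = 4, byrow = TRUE)
  colnames(tm) <- names(base)
  if (divergence > 0) {
    conc <- 1 / divergence^2
    alpha <- tm * conc
    g <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow = 64)
    # guard all-zero rows (possible at extreme divergence)
    g[rowSums(g) == 0, ] <- 1
    tm <- g / rowSums(g)
    gcmass <- tm[, 2] + tm[, 3]
    gcmass <- pmin(pmax(gcmass, 1e-12), 1 - 1e-12)
    tm[, c(2, 3)] <- tm[, c(2, 3)] * gc_target / gcmass
    tm[, c(1, 4)] <- tm[, c(1, 4)] * (1 - gc_target) / (1 - gcmass)
    colnames(tm) <- names(base)
  }
  tm
}

# truncated log-normal lengths whose sum is trimmed to genome_length
sample_contig_lengths <- function(total, meanlog, sdlog, minlen, maxlen) {
  if (minlen > total)
    stop("min_contig_length exceeds the population genome length")
  lens <- integer(0)
  acc <- 0
  while (acc < total) {
    draw <- round(stats::rlnorm(64, meanlog, sdlog))
    draw <- draw[draw >= minlen & draw <= maxlen]
    for (L in draw) {
      if (acc >= total) break
      lens <- c(lens, L)
      acc <- acc + L
    }
  }
  excess <- acc - total
  last <- length(lens)
  if (excess > 0 && lens[last] - excess >= minlen) {
    lens[last] <- lens[last] - excess
  }
  lens
}

# evaluate expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
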