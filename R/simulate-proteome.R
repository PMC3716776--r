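#' Specification for the synthetic metaproteome generator
#'
#' Describes a label-free proteome experiment of \code{n_fractions} culture
#' fractions (default three: supernatant, suspended cells, residual plant
#' biomass) times \code{n_replicates} replicates, measured as peptide peak
#' intensities with multiplicative noise following a mean-variance power
#' law and left-censoring below a detection floor.
#'
#' Optionally a number of "planted" proteins emulate secreted enzymes:
#' their cellular abundance sits below the detection floor (so every
#' cellular observation is censored) while their supernatant abundance is
#' \code{planted_fold} times the floor.
#'
#' @param n_proteins number of proteins.
#' @param n_fractions,n_replicates design size (defaults 3 x 3).
#' @param log_abundance_mean,log_abundance_sd natural-log parameters of the
#'   protein base intensity distribution.
#' @param fraction_effect_sd sd (natural log) of per-protein fraction
#'   effects; 0 gives a null experiment with no fraction differences.
#' @param replicate_noise_sd protein-level per-sample log noise.
#' @param peptide_efficiency_sd log-sd of per-peptide ionisation
#'   efficiency.
#' @param detection_floor intensity below which an observation is recorded
#'   as missing (default 10000).
#' @param variance_power_law numeric \code{c(a, b)}: peptide intensities
#'   scatter around their expectation with variance \code{a * mean^b}.
#' @param peptides_per_protein integer range; each protein gets a uniform
#'   draw from it.
#' @param shared_peptide_fraction fraction of peptides mapped to two
#'   proteins (non-unique).
#' @param dropout_rate additional missing-at-random rate (default 0:
#'   missingness is purely threshold censoring).
#' @param n_planted,planted_fold planted supernatant-only proteins (see
#'   Details).
#' @param rng_seed integer seed.
#' @return A \code{proteome_sim_spec} list.
#' @export
proteome_sim_spec <- function(n_proteins = 1000, n_fractions = 3,
                              n_replicates = 3,
                              log_abundance_mean = log(1e5),
                              log_abundance_sd = 1.5,
                              fraction_effect_sd = 0.8,
                              replicate_noise_sd = 0.2,
                              peptide_efficiency_sd = 0.3,
                              detection_floor = 10000,
                              variance_power_law = c(a = 0.01, b = 2),
                              peptides_per_protein = c(2, 8),
                              shared_peptide_fraction = 0.05,
                              dropout_rate = 0,
                              n_planted = 0, planted_fold = 8,
                              rng_seed = 1L) {
  stopifnot(n_proteins > 0, n_fractions >= 2, n_replicates >= 2,
            detection_floor > 0, log_abundance_sd >= 0,
            fraction_effect_sd >= 0, replicate_noise_sd >= 0,
            peptide_efficiency_sd >= 0,
            length(variance_power_law) == 2, variance_power_law[1] > 0,
            length(peptides_per_protein) == 2,
            peptides_per_protein[1] >= 1,
            shared_peptide_fraction >= 0, shared_peptide_fraction < 1,
            dropout_rate >= 0, dropout_rate < 1,
            n_planted >= 0, n_planted <= n_proteins, planted_fold > 0)
  structure(as.list(environment()), class = "proteome_sim_spec")
}

#' Simulate a censored label-free metaproteome
#'
#' Draws protein base intensities and per-fraction effects on the log
#' scale, adds protein-level replicate noise, spreads each protein over
#' 2-8 peptides with individual ionisation efficiencies, scatters peptide
#' intensities with variance \code{a * mean^b}, and censors every
#' observation below the detection floor (recorded as \code{NA}). A
#' configurable fraction of peptides is shared between two proteins.
#'
#' The first fraction is labelled \code{"supernatant"}; the remaining
#' fractions are the cellular compartments (\code{"cells"},
#' \code{"residual"}, ...).
#'
#' @param spec a [proteome_sim_spec()].
#' @return list with \code{peptides} (data.frame peptide_id, protein_ids
#'   (";"-separated when shared), fraction, replicate, abundance with
#'   \code{NA} for censored) and \code{truth} (list: \code{proteins}
#'   data.frame with base abundance and planted flag, \code{effects}
#'   protein x fraction log-effect matrix, \code{sample_abundance}
#'   protein x sample matrix of true intensities).
#' @examples
#' sim <- simulate_proteome(proteome_sim_spec(n_proteins = 20, rng_seed = 3))
#' head(sim$peptides)
#' @export
simulate_proteome <- function(spec) {
  stopifnot(inherits(spec, "proteome_sim_spec"))
  with_seed(spec$rng_seed, {
    np <- spec$n_proteins
    nf <- spec$n_fractions
    nr <- spec$n_replicates
    fractions <- c("supernatant", "cells", "residual",
                   paste0("fraction", seq_len(max(nf - 3, 0)) + 3))[seq_len(nf)]
    prot_ids <- sprintf("P%05d", seq_len(np))
    base <- stats::rlnorm(np, spec$log_abundance_mean, spec$log_abundance_sd)
    eff <- matrix(stats::rnorm(np * nf, 0, spec$fraction_effect_sd),
                  np, nf, dimnames = list(prot_ids, fractions))
    planted <- rep(FALSE, np)
    if (spec$n_planted > 0) {
      planted[seq_len(spec$n_planted)] <- TRUE
      base[planted] <- spec$detection_floor / 4
      eff[planted, ] <- 0
      eff[planted, 1] <- log(4 * spec$planted_fold)  # supernatant at fold x floor
    }
    # true protein intensity per sample (protein-level replicate noise)
    samples <- expand.grid(replicate = seq_len(nr), fraction = fractions,
                           stringsAsFactors = FALSE)[, c("fraction", "replicate")]
    ns <- nrow(samples)
    A <- base * exp(eff[, samples$fraction] +
                      matrix(stats::rnorm(np * ns, 0, spec$replicate_noise_sd),
                             np, ns))
    colnames(A) <- paste(samples$fraction, samples$replicate, sep = "|")
    # peptides
    npep <- sample(seq(spec$peptides_per_protein[1],
                       spec$peptides_per_protein[2]), np, replace = TRUE)
    pep_prot <- rep(seq_len(np), npep)
    tot <- length(pep_prot)
    pep_ids <- sprintf("pep%06d", seq_len(tot))
    eff_pep <- stats::rlnorm(tot, 0, spec$peptide_efficiency_sd)
    second <- rep(NA_integer_, tot)
    n_shared <- round(spec$shared_peptide_fraction * tot)
    if (n_shared > 0 && np > 1) {
      sh <- sample(tot, n_shared)
      second[sh] <- vapply(pep_prot[sh], function(p)
        sample(setdiff(seq_len(np), p), 1L), 0L)
    }
    protein_ids <- ifelse(is.na(second), prot_ids[pep_prot],
                          paste(prot_ids[pep_prot], prot_ids[second],
                                sep = ";"))
    # long table: peptides x samples
    a <- spec$variance_power_law[[1]]
    b <- spec$variance_power_law[[2]]
    m <- as.vector(A[pep_prot, ]) * rep(eff_pep, times = ns)
    sig2 <- log(1 + a * m^(b - 2))
    vals <- m * exp(stats::rnorm(length(m), -sig2 / 2, sqrt(sig2)))
    vals[vals < spec$detection_floor] <- NA_real_
    if (spec$dropout_rate > 0)
      vals[stats::runif(length(vals)) < spec$dropout_rate] <- NA_real_
    peptides <- data.frame(
      peptide_id = rep(pep_ids, times = ns),
      protein_ids = rep(protein_ids, times = ns),
      fraction = rep(samples$fraction, each = tot),
      replicate = rep(samples$replicate, each = tot),
      abundance = vals, stringsAsFactors = FALSE)
    list(peptides = peptides,
         truth = list(proteins = data.frame(protein_id = prot_ids,
                                            base_abundance = base,
                                            n_peptides = npep,
                                            planted = planted,
                                            stringsAsFactors = FALSE),
                      effects = eff,
                      sample_abundance = `rownames<-`(A, prot_ids)))
  })
}

#' Write / read a peptide table as TSV
#' @param peptides data.frame as produced by [simulate_proteome()].
#' @param path TSV path.
#' @export
write_peptides <- function(peptides, path) {
  write_tsv_table(peptides, path,
                  "peptide intensities; NA = below detection threshold")
}

#' @rdname write_peptides
#' @export
read_peptides <- function(path) {
  read_tsv_table(path, c(peptide_id = "character", protein_ids = "character",
                         fraction = "character", replicate = "integer",
                         abundance = "numeric"))
}
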