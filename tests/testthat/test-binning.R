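biased_dna <- function(n, p) paste(sample(names(p), n, replace = TRUE,
                                          prob = p), collapse = "")
pGC <- c(A = 0.05, C = 0.45, G = 0.45, T = 0.05)
pAT <- c(A = 0.45, C = 0.05, G = 0.05, T = 0.45)

test_that("seed_bins follows strict marker majorities", {
  set.seed(101)
  seqs <- c(s1 = random_dna(2000), s2 = random_dna(2000),
            s3 = random_dna(2000), s4 = random_dna(2000))
  mk <- list(
    s1 = data.frame(cog = c("C1", "C2", "C3"), taxon = c("A", "A", "B")),
    s2 = data.frame(cog = c("C1", "C2"), taxon = c("A", "B")),  # tie
    s3 = data.frame(cog = "C4", taxon = "B"))
  cs <- contig_set(seqs, coverage = 10, markers = mk)
  bins <- seed_bins(cs)
  expect_setequal(names(bins$bins), c("A", "B"))
  expect_equal(bins$bins$A$members, "s1")
  expect_equal(bins$bins$B$members, "s3")
  expect_setequal(bins$unassigned, c("s2", "s4"))
  expect_equal(unname(bins$seed_sizes[c("A", "B")]), c(1L, 1L))
})

test_that("the veto rule's arithmetic is applied exactly", {
  S <- matrix(c(0.005, 0.009), 1, dimnames = list("c1", c("binA", "binB")))
  d <- mgproteo:::decide_assignments(S, score_max = 0.01, margin = 1.2,
                                     round = "1")
  expect_equal(d$decision, "assigned")   # 0.009 >= 1.2 * 0.005
  expect_equal(d$best_bin, "binA")

  S[1, 2] <- 0.0055                      # 0.0055 < 0.006: falls between bins
  expect_equal(mgproteo:::decide_assignments(S, 0.01, 1.2)$decision,
               "ambiguous")

  S[1, ] <- c(0.02, 0.05)                # best not below score_max
  expect_equal(mgproteo:::decide_assignments(S, 0.01, 1.2)$decision,
               "score_above_max")

  S[1, ] <- c(0.004, 0.004)              # exact tie, unvetoed round
  d <- mgproteo:::decide_assignments(S, Inf, 1)
  expect_equal(d$decision, "tie")
  expect_equal(d$best_bin, "binA")       # lexicographically smallest label
})

test_that("the 1000 bp floor is inclusive: 999 bp is skipped, 1000 bp is scored", {
  set.seed(102)
  cs <- contig_set(
    c(seedA = biased_dna(5000, pGC), seedB = biased_dna(5000, pAT),
      q1000 = biased_dna(1000, pGC), q999 = biased_dna(999, pGC)),
    coverage = 10,
    markers = list(seedA = data.frame(cog = "C1", taxon = "A"),
                   seedB = data.frame(cog = "C1", taxon = "B")))
  bins <- seed_bins(cs)
  bins <- assign_round(cs, bins, score_max = 0.6, margin = 1.2,
                       min_len = 1000)
  expect_true("q1000" %in% bins$round_log$contig)
  expect_false("q999" %in% bins$round_log$contig)
  expect_true("q999" %in% bins$unassigned)
  expect_true("q1000" %in% bins$bins$A$members)
})

test_that("twin bins are merged when similar, and deleting all bins is an error", {
  spec <- community_spec(list(
    population_spec("T1", genome_length = 2e5, gc_target = 0.6,
                    composition_divergence = 0, n_marker_genes = 20),
    population_spec("T2", genome_length = 2e5, gc_target = 0.6,
                    composition_divergence = 0, n_marker_genes = 20)),
    rng_seed = 71)
  sim <- simulate_community(spec)
  bins <- seed_bins(sim$contigs)
  bins <- assign_round(sim$contigs, bins, score_max = 0.35, margin = 1.2)
  merged <- merge_or_delete_bins(bins, sim$contigs, similarity_max = 0.05)
  expect_length(merged$bins, 1)
  expect_match(names(merged$bins), "\\+merged$")
  # at a similarity threshold far below the twins' model distance, both
  # shrunken bins are deleted and nothing remains
  expect_error(merge_or_delete_bins(bins, sim$contigs,
                                    similarity_max = 1e-6),
               "removed every bin")
})

test_that("unassignment grows as populations converge", {
  frac_unassigned <- vapply(c(0.4, 0), function(d) {
    spec <- community_spec(list(
      population_spec("A", genome_length = 2e5, gc_target = 0.6,
                      composition_divergence = d, n_marker_genes = 20),
      population_spec("B", genome_length = 2e5, gc_target = 0.6,
                      composition_divergence = d, n_marker_genes = 20)),
      rng_seed = 72)
    sim <- simulate_community(spec)
    bins <- seed_bins(sim$contigs)
    bins <- assign_round(sim$contigs, bins, score_max = 0.35, margin = 1.2)
    length(bins$unassigned) / length(sim$contigs)
  }, 0)
  expect_gt(frac_unassigned[2], frac_unassigned[1])
})

test_that("full binning recovers a four-population community on long contigs", {
  spec <- demo_community_spec(rng_seed = 42, genome_length = 3e5)
  sim <- simulate_community(spec)
  bins <- run_binning(sim$contigs, score_max = 0.35, margin = 1.2,
                      similarity_max = 0.05)
  asg <- bin_assignment(bins)
  long <- sim$contigs$meta$id[sim$contigs$meta$length >= 5000]
  long <- intersect(long, names(asg))
  expect_gt(length(long) / sum(sim$contigs$meta$length >= 5000), 0.95)
  called <- sub("\\+merged$", "", asg[long])
  expect_gt(mean(called == sim$truth[long]), 0.95)
})

test_that("binning is deterministic", {
  spec <- community_spec(list(
    population_spec("A", genome_length = 1e5, gc_target = 0.66,
                    composition_divergence = 0.4, n_marker_genes = 15),
    population_spec("B", genome_length = 1e5, gc_target = 0.5,
                    composition_divergence = 0.4, n_marker_genes = 15)),
    rng_seed = 73)
  sim <- simulate_community(spec)
  b1 <- run_binning(sim$contigs, score_max = 0.35, margin = 1.2,
                    similarity_max = 0.05)
  b2 <- run_binning(sim$contigs, score_max = 0.35, margin = 1.2,
                    similarity_max = 0.05)
  expect_identical(b1$round_log, b2$round_log)
  expect_identical(bin_assignment(b1), bin_assignment(b2))
})

test_that("coverage clustering separates well-spaced modes and keeps close ones together", {
  set.seed(103)
  mkcs <- function(cov) contig_set(
    stats::setNames(replicate(length(cov), random_dna(500)),
                    sprintf("c%02d", seq_along(cov))), coverage = cov)

  one <- extract_coverage_clusters(mkcs(runif(20, 68, 72)))
  expect_equal(nrow(one), 1)
  expect_equal(one$coverage_mode, 70, tolerance = 0.1)

  two <- extract_coverage_clusters(mkcs(c(runif(12, 65, 75),
                                          runif(12, 9, 11))))
  expect_equal(nrow(two), 2)
  expect_gt(two$coverage_mode[1], two$coverage_mode[2])  # sorted descending
  expect_equal(two$n_contigs, c(12, 12))

  close <- extract_coverage_clusters(mkcs(c(rnorm(15, 30, 1),
                                            rnorm(15, 32, 1))))
  expect_equal(nrow(close), 1)   # 30x vs 32x is within one bandwidth
})

test_that("coverage clusters partition the bin", {
  set.seed(104)
  cov <- c(runif(10, 60, 80), runif(10, 8, 12))
  lens <- sample(500:1500, 20)
  cs <- contig_set(stats::setNames(vapply(lens, random_dna, ""),
                                   sprintf("c%02d", 1:20)), coverage = cov)
  out <- extract_coverage_clusters(cs)
  expect_equal(sum(out$total_bp), sum(lens))
  expect_equal(sum(out$n_contigs), 20)
  memb <- attr(out, "members")
  expect_setequal(unlist(memb), cs$meta$id)
  expect_false(any(duplicated(unlist(memb))))
})
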