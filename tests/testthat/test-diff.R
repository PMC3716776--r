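exact_law_matrix <- function(a, b, n = 40) {
  # replicates (m - d, m, m + d) have sample variance d^2 exactly, so
  # d = sqrt(a) * m^(b/2) puts every protein exactly on var = a * mean^b
  means <- 10^seq(3, 6, length.out = n)
  cols <- as.vector(vapply(c("supernatant", "cells", "residual"),
                           function(f) paste(f, 1:3, sep = "|"),
                           character(3)))
  m <- matrix(NA_real_, n, 9, dimnames = list(sprintf("P%03d", 1:n), cols))
  for (f in 0:2) {
    d <- sqrt(a) * means^(b / 2)
    m[, f * 3 + 1] <- means - d
    m[, f * 3 + 2] <- means
    m[, f * 3 + 3] <- means + d
  }
  m
}

test_that("the power law is recovered exactly from exact data", {
  vm <- fit_variance_model(exact_law_matrix(a = 0.01, b = 2))
  expect_equal(vm$a, 0.01, tolerance = 1e-10)
  expect_equal(vm$b, 2, tolerance = 1e-10)
  vm2 <- fit_variance_model(exact_law_matrix(a = 0.5, b = 1.5))
  expect_equal(vm2$a, 0.5, tolerance = 1e-10)
  expect_equal(vm2$b, 1.5, tolerance = 1e-10)
  expect_equal(predict(vm2, 100), 0.5 * 100^1.5)
})

test_that("rescaling the matrix transforms the fitted law as a * c^(2-b)", {
  m <- exact_law_matrix(a = 0.5, b = 1.5)
  vm <- fit_variance_model(m)
  vm10 <- fit_variance_model(10 * m)
  expect_equal(vm10$b, vm$b, tolerance = 1e-9)
  expect_equal(vm10$a, vm$a * 10^(2 - vm$b), tolerance = 1e-8)
})

test_that("the exponent is recovered within 0.15 from a simulated proteome", {
  sim <- simulate_proteome(proteome_sim_spec(
    n_proteins = 1000, variance_power_law = c(a = 0.01, b = 2),
    rng_seed = 7))
  mat <- qrollup(sim$peptides)
  norm <- normalize_abundance(mat)
  vm <- fit_variance_model(norm$matrix)
  expect_lt(abs(vm$b - 2), 0.15)
})

test_that("a constant protein gives t = 0, p = 1; variance modes follow observation counts", {
  m <- exact_law_matrix(0.01, 2, n = 40)
  vm <- fit_variance_model(m)
  m <- rbind(m, Pflat = rep(5e4, 9))
  m["P001", "cells|1"] <- NA                       # one missing -> hybrid
  m["P002", c("cells|1", "cells|2")] <- NA         # two missing -> pooled
  res <- differential_test(m, vm)
  flat <- res[res$protein_id == "Pflat", ]
  expect_equal(flat$t_statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_false(flat$flagged)
  expect_equal(res$variance_mode[res$protein_id == "P001"], "hybrid")
  expect_equal(res$variance_mode[res$protein_id == "P002"], "pooled")
  expect_equal(res$variance_mode[res$protein_id == "P003"], "complete")
  # fold change of a symmetric protein is 1
  expect_equal(res$fold_change[res$protein_id == "P003"], 1,
               tolerance = 1e-12)
  expect_error(differential_test(m, vm, supernatant = "nope"),
               "no fraction labelled")
})

test_that("p-values are invariant under a global rescale with refit", {
  sim <- simulate_proteome(proteome_sim_spec(n_proteins = 300,
                                             n_planted = 10, rng_seed = 8))
  mat <- normalize_abundance(qrollup(sim$peptides))$matrix
  r1 <- differential_test(mat, fit_variance_model(mat))
  r2 <- differential_test(10 * mat, fit_variance_model(10 * mat))
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-8)
  expect_equal(r2$fold_change, r1$fold_change, tolerance = 1e-8)
})

test_that("planted supernatant-only proteins are flagged through the full quant chain", {
  sim <- simulate_proteome(proteome_sim_spec(
    n_proteins = 800, n_planted = 25, planted_fold = 8, rng_seed = 9))
  mat <- qrollup(sim$peptides)
  norm <- normalize_abundance(mat)
  vm <- fit_variance_model(norm$matrix)
  res <- differential_test(norm$matrix, vm)
  planted <- sim$truth$proteins$protein_id[sim$truth$proteins$planted]
  hit <- res[res$protein_id %in% planted, ]
  expect_gt(mean(hit$flagged), 0.8)
  # fully censored cellular side forces the pooled variance path
  expect_true(all(hit$variance_mode == "pooled"))
  expect_true(all(hit$fold_change[hit$flagged] >= 2))
})

test_that("enrichment matches the hypergeometric and BH oracles", {
  set.seed(91)
  prot <- sprintf("P%03d", 1:120)
  categories <- data.frame(
    protein_id = prot,
    category = sample(paste0("PWY_", letters[1:6]), 120, replace = TRUE))
  # make one category entirely flagged
  categories$category[1:12] <- "PWY_hot"
  flagged <- c(prot[1:12], sample(prot[13:120], 8))
  res <- enrichment(flagged, categories, fdr = 0.10)
  hot <- res[res$category == "PWY_hot", ]
  expect_lt(hot$p, 1e-4)
  expect_true(hot$significant)
  # every p agrees with direct hypergeometric enumeration
  for (i in seq_len(nrow(res)))
    expect_equal(res$p[i], oracle_fisher2(res$k_flagged_in[i], res$n_in[i],
                                          res$k_flagged_out[i],
                                          res$n_out[i]),
                 tolerance = 1e-9)
  # significance calls agree with the BH step-up oracle
  expect_equal(res$significant, oracle_bh_significant(res$p, 0.10))
  # no flagged proteins: all p = 1, nothing significant
  none <- enrichment(character(0), categories)
  expect_true(all(none$p == 1))
  expect_false(any(none$significant))
})

test_that("bin abundance proportions sum to one and follow the means", {
  m <- matrix(c(100, 100, 300, 300,
                50,  50, 150, 150,
                25,  25,  75,  75), 3, 4, byrow = TRUE,
              dimnames = list(c("A", "B", "C"),
                              c("supernatant|1", "supernatant|2",
                                "cells|1", "cells|2")))
  bm <- c(A = "binX", B = "binX")
  out <- bin_abundance_summary(m, bm)
  expect_equal(colSums(out), c(supernatant = 1, cells = 1))
  expect_equal(out["binX", "supernatant"], 150 / 175)
  expect_equal(out["unbinned", "cells"], 75 / 525)
})
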