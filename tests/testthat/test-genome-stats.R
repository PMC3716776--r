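test_that("weighted completeness matches the 1/30 ribosomal down-weighting", {
  ms <- marker_set(marker_cogs())
  expect_equal(ms$n_total, 54)
  expect_equal(ms$n_ribosomal, 30)
  all_cogs <- ms$cogs$cog
  ribo <- ms$cogs$cog[ms$cogs$is_ribosomal]
  nonribo <- ms$cogs$cog[!ms$cogs$is_ribosomal]
  expect_equal(completeness(all_cogs, ms), 1)
  # all 30 ribosomal markers alone: (30/30) / 25 = 4%
  expect_equal(completeness(ribo, ms), 0.04)
  # all 24 non-ribosomal markers alone: 24 / 25 = 96%
  expect_equal(completeness(nonribo, ms), 0.96)
  expect_equal(completeness(character(0), ms), 0)
  # monotone in the present set
  sub <- sample(all_cogs, 20)
  expect_lte(completeness(sub, ms), completeness(c(sub, setdiff(all_cogs, sub)[1]), ms))
  # duplicates do not inflate the estimate
  expect_equal(completeness(rep(nonribo[1], 5), ms), completeness(nonribo[1], ms))
  expect_error(completeness("NOT_A_COG", ms), "not in the marker set")
})

test_that("aai keeps one filtered best hit per query", {
  h <- data.frame(
    query_id   = c("q1", "q1", "q2", "q3", "q4"),
    subject_id = c("s1", "s2", "s3", "s4", "s5"),
    percent_identity = c(96, 99, 94, 98, 25),
    alignment_length = c(90, 40, 80, 75, 100),
    query_length     = c(100, 100, 100, 100, 100),
    bitscore         = c(200, 150, 170, 160, 80))
  res <- aai(h)
  # q1's best hit by bitscore is s1 (96%, cov 0.9); s2 fails coverage anyway
  # q4 fails the 30% identity filter
  expect_equal(res$n_pairs, 3)
  expect_equal(res$mean_identity, mean(c(96, 94, 98)))
  expect_setequal(res$retained$query_id, c("q1", "q2", "q3"))

  # row order must not matter
  res2 <- aai(h[sample(nrow(h)), ])
  expect_equal(res2$mean_identity, res$mean_identity)
  expect_equal(res2$n_pairs, res$n_pairs)

  # identity filter is monotone: raising it cannot add pairs
  expect_lte(aai(h, min_identity = 95)$n_pairs, res$n_pairs)
  expect_equal(aai(h, min_identity = 95)$mean_identity, mean(c(96, 98)))

  # coverage boundary is inclusive at exactly 0.70
  h2 <- data.frame(query_id = "q", subject_id = "s", percent_identity = 50,
                   alignment_length = 70, query_length = 100, bitscore = 99)
  expect_equal(aai(h2)$n_pairs, 1)
  h2$alignment_length <- 69
  expect_equal(aai(h2)$n_pairs, 0)
  expect_true(is.na(aai(h2)$mean_identity))

  expect_warning(empty <- aai(h[0, ]), "empty hit table")
  expect_true(is.na(empty$mean_identity))
})

test_that("aai agrees with a brute-force per-query oracle on random tables", {
  set.seed(55)
  for (rep in 1:3) {
    n <- 120
    h <- data.frame(
      query_id = sample(sprintf("q%02d", 1:30), n, replace = TRUE),
      subject_id = sample(sprintf("s%02d", 1:15), n, replace = TRUE),
      percent_identity = round(runif(n, 10, 100), 1),
      alignment_length = sample(30:120, n, replace = TRUE),
      query_length = 100,
      bitscore = round(runif(n, 40, 300), 1))
    got <- aai(h)
    want <- oracle_aai(h)
    if (is.na(want)) expect_true(is.na(got$mean_identity))
    else expect_equal(got$mean_identity, want, tolerance = 1e-12)
  }
})

test_that("align_proteins ranks a true homolog above an unrelated protein", {
  set.seed(56)
  a <- random_protein(120)
  # a close homolog: 10 point substitutions
  b <- strsplit(a, "")[[1]]
  pos <- sample(120, 10)
  b[pos] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 10,
                   replace = TRUE)
  homolog <- paste(b, collapse = "")
  unrelated <- random_protein(120)
  hits <- align_proteins(c(q = a), c(hom = homolog, rnd = unrelated))
  hom_row <- hits[hits$subject_id == "hom", ]
  expect_gte(hom_row$percent_identity, 85)
  expect_gte(hom_row$alignment_length / hom_row$query_length, 0.9)
  if ("rnd" %in% hits$subject_id)
    expect_gt(hom_row$bitscore, hits$bitscore[hits$subject_id == "rnd"])
  # self-alignment gives 100% identity over the full length -> AAI 100
  self <- align_proteins(c(q = a), c(s = a))
  expect_equal(aai(self)$mean_identity, 100)
})

test_that("assembly statistics match exhaustive computation", {
  expect_equal(assembly_stats(c(8, 8, 4))$n50, 8)
  expect_equal(assembly_stats(c(10, 5, 4, 1))$n50, 10)  # 10 >= 20/2
  expect_equal(assembly_stats(c(6, 5, 4, 3, 2))$n50, 5)
  set.seed(57)
  for (rep in 1:20) {
    lens <- sample(1:5000, sample(1:40, 1), replace = TRUE)
    st <- assembly_stats(lens)
    expect_equal(st$n50, oracle_n50(lens))
    expect_equal(st$total_bp, sum(lens))
    expect_equal(st$n_ge_1kbp, sum(lens >= 1000))
  }
  # GC from sequences, Ns excluded
  st <- assembly_stats(Biostrings::DNAStringSet(c(a = "ATGC", b = "GGNN")))
  expect_equal(st$gc_percent, 100 * 4 / 6)
  expect_equal(st$total_bp, 8)
  expect_error(assembly_stats(numeric(0)), "empty")
})
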