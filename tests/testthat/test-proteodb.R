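aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
mutate_protein <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), k)
  v[pos] <- sample(aa20, k, replace = TRUE)
  paste(v, collapse = "")
}
simple_records <- function(seqs, coverage = 50, contig_len = 10000) {
  n <- length(seqs)
  genes <- data.frame(protein_id = names(seqs),
                      contig_id = sprintf("ctg%02d", seq_len(n)),
                      start = 500, end = 500 + 3 * nchar(seqs) - 1,
                      strand = "+", stringsAsFactors = FALSE)
  ci <- data.frame(contig_id = genes$contig_id, length = contig_len,
                   coverage = rep_len(coverage, n),
                   stringsAsFactors = FALSE)
  protein_records(seqs, genes, ci)
}

test_that("near_edge boundaries are exact at 200 bp from either end", {
  set.seed(61)
  seqs <- stats::setNames(replicate(4, random_protein(50)),
                          c("pA", "pB", "pC", "pD"))
  genes <- data.frame(
    protein_id = c("pA", "pB", "pC", "pD"),
    contig_id = "ctg1",
    start = c(200, 201, 5000, 5000),
    end = c(349, 350, 9801, 9800),
    strand = "+", stringsAsFactors = FALSE)
  ci <- data.frame(contig_id = "ctg1", length = 10000, coverage = 30)
  rec <- protein_records(seqs, genes, ci)
  expect_equal(rec$near_edge, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(protein_records(seqs, transform(genes, end = 10001), ci),
               "outside contig bounds")
})

test_that("the reliability score orders records as documented", {
  r <- data.frame(contig_coverage = c(70, 10, 70, 70),
                  length = c(300, 300, 30, 300),
                  near_edge = c(FALSE, FALSE, FALSE, TRUE))
  s <- score_protein(r)
  expect_gt(s[1], s[2])            # higher coverage wins
  expect_equal(s[1] - s[3], 1)     # 10x protein length -> exactly +1
  expect_equal(s[1] - s[4], 1)     # edge penalty subtracts exactly w_edge
  expect_equal(s[1] - score_protein(r, w_edge = 2.5)[4], 2.5)
  # lexicographic mode ranks by coverage first
  lex <- score_protein(r, mode = "lexicographic")
  expect_true(lex[1] > lex[2])
})

test_that("dereplication collapses exact duplicate groups to their best member", {
  set.seed(62)
  a <- random_protein(80); b <- random_protein(80)
  seqs <- stats::setNames(c(rep(a, 5), rep(b, 3)), sprintf("p%d", 1:8))
  rec <- simple_records(seqs, coverage = c(10, 80, 20, 30, 40, 5, 60, 7))
  res <- dereplicate(rec)
  expect_length(res$representatives, 2)
  sizes <- table(res$clusters$representative_id)
  expect_setequal(as.integer(sizes), c(5L, 3L))
  # representatives are the highest-coverage member of each group
  expect_setequal(res$representatives, c("p2", "p7"))
  expect_true(all(res$clusters$identity[res$clusters$member_id %in%
                                          sprintf("p%d", 1:8)] == 1))
})

test_that("a 96%-identical copy joins its source; dissimilar proteins do not", {
  set.seed(63)
  base <- stats::setNames(replicate(10, random_protein(100)),
                          sprintf("b%02d", 1:10))
  copy <- c(dup = mutate_protein(base[["b03"]], 4))  # >= 96% identical
  rec <- simple_records(c(base, copy),
                        coverage = c(rep(50, 10), 5))  # copy scores lowest
  res <- dereplicate(rec, threshold = 0.95)
  expect_length(res$representatives, 10)
  cl <- res$clusters
  expect_equal(cl$representative_id[cl$member_id == "dup"], "b03")
  expect_gte(cl$identity[cl$member_id == "dup"], 0.95)
  # a 30-substitution mutant stays separate
  far <- c(far = mutate_protein(base[["b03"]], 30))
  res2 <- dereplicate(simple_records(c(base, far)), threshold = 0.95)
  expect_length(res2$representatives, 11)
})

test_that("greedy dereplication matches the brute-force oracle on a mixed pool", {
  set.seed(64)
  pool <- character(0)
  for (f in 1:12) {
    b <- random_protein(60)
    fam <- c(b, vapply(seq_len(sample(0:2, 1)),
                       function(i) mutate_protein(b, sample(1:3, 1)), ""))
    pool <- c(pool, fam)
  }
  names(pool) <- sprintf("p%02d", seq_along(pool))
  scores <- round(runif(length(pool), 0, 10), 3)
  rec <- simple_records(pool)
  res <- dereplicate(rec, threshold = 0.95, scores = scores)

  idmat <- outer(seq_along(pool), seq_along(pool),
                 Vectorize(function(i, j) global_identity(pool[i], pool[j])))
  want <- oracle_derep(names(pool), scores, idmat, 0.95)
  got <- stats::setNames(res$clusters$representative_id,
                         res$clusters$member_id)
  expect_equal(got[names(want)], want)
})

test_that("raising the identity threshold never merges more", {
  set.seed(65)
  pool <- character(0)
  for (f in 1:6) {
    b <- random_protein(80)
    pool <- c(pool, b, mutate_protein(b, 2), mutate_protein(b, 8), b)
  }
  names(pool) <- sprintf("p%02d", seq_along(pool))
  rec <- simple_records(pool)
  n_at <- vapply(c(0.90, 0.95, 1.0), function(th)
    length(dereplicate(rec, threshold = th)$representatives), 0L)
  expect_true(all(diff(n_at) >= 0))
  # at threshold 1 only byte-identical duplicates collapse
  res1 <- dereplicate(rec, threshold = 1.0)
  cl <- res1$clusters
  joined <- cl[cl$member_id != cl$representative_id, ]
  expect_true(all(pool[joined$member_id] == pool[joined$representative_id]))
})

test_that("dereplication output partitions the input and is deterministic", {
  set.seed(66)
  pool <- stats::setNames(c(replicate(8, random_protein(70))),
                          sprintf("p%d", 1:8))
  pool <- c(pool, q1 = mutate_protein(pool[["p1"]], 2))
  rec <- simple_records(pool)
  r1 <- dereplicate(rec)
  r2 <- dereplicate(rec)
  expect_identical(r1$clusters, r2$clusters)
  expect_setequal(r1$clusters$member_id, names(pool))
  expect_false(any(duplicated(r1$clusters$member_id)))
  expect_true(all(r1$clusters$representative_id %in% r1$representatives))
  # every representative is the top-scoring member of its own cluster
  sc <- stats::setNames(score_protein(rec), rec$protein_id)
  for (rep_id in r1$representatives) {
    mem <- r1$clusters$member_id[r1$clusters$representative_id == rep_id]
    expect_equal(unname(sc[rep_id]), max(sc[mem]))
  }
})

test_that("the exported database round-trips with cluster sizes in headers", {
  set.seed(67)
  a <- random_protein(60)
  pool <- c(r1 = a, r2 = a, r3 = random_protein(60))
  rec <- simple_records(pool, coverage = c(80, 10, 40))
  res <- dereplicate(rec)
  path <- tempfile(fileext = ".faa")
  on.exit(unlink(path))
  export_database(res, rec, path)
  back <- read_fasta(path, type = "protein")
  expect_length(back, 2)
  expect_setequal(names(back), c("r1", "r3"))  # ids precede the attributes
  expect_setequal(as.character(back), unname(pool[c("r1", "r3")]))
  # full headers carry contig, score and cluster size
  hdr <- sub("^>", "", grep("^>", readLines(path), value = TRUE))
  expect_true(all(grepl("contig=ctg\\d+ score=-?[0-9.]+ n=\\d+$", hdr)))
  n <- as.integer(sub(".* n=(\\d+)$", "\\1", hdr))
  expect_equal(sum(n), 3)
})
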