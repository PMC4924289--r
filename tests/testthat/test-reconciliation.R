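one_exon <- function(id, start, end, seqid = "c1", strand = "+") {
  gene_models(model_id = id, seqid = seqid, strand = strand,
              start = start, end = end)
}

test_that("alignment coverage is the covered fraction of the seed", {
  expect_equal(alignment_coverage(list(q_start = 1L, q_end = 100L), 100), 1.0)
  expect_equal(alignment_coverage(list(q_start = 1L, q_end = 50L), 100), 0.5)
  expect_equal(alignment_coverage(list(q_start = NA, q_end = NA), 100), 0)
  expect_error(alignment_coverage(list(q_start = 0L, q_end = 50L), 100),
               class = "frbpipe_validation_error")
  expect_error(alignment_coverage(list(q_start = 10L, q_end = 150L), 100),
               class = "frbpipe_validation_error")
  set.seed(301)
  for (i in 1:30) {
    L <- sample(50:300, 1)
    qs <- sample(L, 1); qe <- sample(qs:L, 1)
    expect_equal(alignment_coverage(list(q_start = qs, q_end = qe), L),
                 sum(seq_len(L) %in% qs:qe) / L)   # position-count oracle
  }
})

test_that("genomic overlap counts shared exon bases on the same contig/strand", {
  a <- one_exon("a", 100, 200)
  expect_equal(genomic_overlap(a, a), 100L)
  expect_equal(genomic_overlap(a, one_exon("b", 100, 200, seqid = "c2")), 0L)
  expect_equal(genomic_overlap(a, one_exon("b", 100, 200, strand = "-")), 0L)
  set.seed(302)
  for (i in 1:40) {
    mk <- function(id) {
      n <- sample(1:4, 1)
      st <- cumsum(sample(61:140, n)); en <- st + sample(5:60, n)
      gene_models(model_id = id, seqid = "c1", strand = "+",
                  start = st, end = en)
    }
    x <- mk("x"); y <- mk("y")
    expect_equal(genomic_overlap(x, y), oracle_overlap(x, y))
  }
})

test_that("refinement tiers honour the 5%/15% additive boundaries exactly", {
  pub <- one_exon("p1", 100, 400)
  new <- one_exon("n1", 100, 400)
  base <- 0.40
  cases <- list(c(0,     "published_ok"),
                c(0.049, "published_ok"),
                c(0.05,  "minor_refinement"),
                c(0.149, "minor_refinement"),
                c(0.15,  "major_refinement"),
                c(0.5,   "major_refinement"))
  for (cs in cases) {
    delta <- as.numeric(cs[[1]])
    r <- classify_refinement(new, base + delta, pub,
                             published_coverage = c(p1 = base))
    expect_identical(r$tier, cs[[2]], info = paste("delta =", delta))
    expect_identical(r$overlap_class, "one_to_one")
    expect_equal(r$delta, delta)
  }
})

test_that("multiple overlaps flag a split, none a novel locus", {
  new <- one_exon("n1", 100, 700)
  pub2 <- rbind(one_exon("p1", 100, 390), one_exon("p2", 410, 700))
  r <- classify_refinement(new, 0.9, pub2,
                           published_coverage = c(p1 = 0.45, p2 = 0.45))
  expect_identical(r$tier, "major_refinement")
  expect_identical(r$overlap_class, "split")
  expect_setequal(r$overlapping, c("p1", "p2"))

  far <- one_exon("p3", 5000, 5300)
  r2 <- classify_refinement(new, 0.9, far, published_coverage = c(p3 = 0.2))
  expect_identical(r2$tier, "major_refinement")
  expect_identical(r2$overlap_class, "none")

  r3 <- classify_refinement(new, 0.9, gene_models())
  expect_identical(r3$tier, "novel")
})

test_that("tier assignment is monotone in the coverage gain", {
  pub <- one_exon("p1", 0, 300)
  new <- one_exon("n1", 0, 300)
  tiers <- vapply(seq(0, 0.6, by = 0.01), function(d)
    classify_refinement(new, 0.3 + d, pub,
                        published_coverage = c(p1 = 0.3))$tier, character(1))
  ranks <- match(tiers, c("published_ok", "minor_refinement", "major_refinement"))
  expect_false(is.unsorted(ranks))
})

test_that("classification ignores the order of the published-model list", {
  new <- one_exon("n1", 100, 700)
  pubs <- rbind(one_exon("p1", 100, 390), one_exon("p2", 410, 700),
                one_exon("p3", 9000, 9100))
  cov <- c(p1 = 0.45, p2 = 0.4, p3 = 0.1)
  r1 <- classify_refinement(new, 0.9, pubs, cov)
  r2 <- classify_refinement(new, 0.9, pubs[rev(seq_len(nrow(pubs))), ], cov)
  expect_identical(r1$tier, r2$tier)
  expect_setequal(r1$overlapping, r2$overlapping)
})

test_that("merged models are published models overlapped by several predictions", {
  pub <- one_exon("pub", 100, 700)
  preds <- rbind(one_exon("n1", 100, 390), one_exon("n2", 410, 700))
  expect_identical(detect_merged(pub, preds), "merged")
  expect_identical(detect_merged(pub, one_exon("n1", 100, 390)), "one_to_one")
  expect_identical(detect_merged(pub, one_exon("n1", 5000, 5400)), "none")

  set.seed(303)
  for (i in 1:25) {
    npr <- sample(1:4, 1)
    preds <- do.call(rbind, lapply(seq_len(npr), function(k)
      one_exon(paste0("n", k), s <- sample(0:800, 1), s + sample(40:200, 1))))
    n_over <- sum(vapply(unique(preds$model_id), function(id)
      oracle_overlap(pub, preds[preds$model_id == id, ]) >= 30, logical(1)))
    want <- if (n_over >= 2) "merged" else if (n_over == 1) "one_to_one" else "none"
    expect_identical(detect_merged(pub, preds), want)
  }
})
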