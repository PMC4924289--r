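test_that("matrix cells take the best case across evidence streams", {
  calls <- data.frame(seed_gene = c("g1", "g2", "g3"),
                      species = "sp1", positive = c(TRUE, FALSE, FALSE),
                      stringsAsFactors = FALSE)
  tiers <- data.frame(seed_gene = "g1", species = "sp1",
                      tier = "major_refinement", stringsAsFactors = FALSE)
  verdicts <- data.frame(seed_gene = "g2", species = "sp1",
                         supported = TRUE, stringsAsFactors = FALSE)
  m <- build_matrix(calls, tiers, verdicts,
                    genes = c("g1", "g2", "g3"), species = "sp1")
  expect_identical(m["g1", "sp1"], "published_ok")  # FRB beats major refinement
  expect_identical(m["g2", "sp1"], "read_only")
  expect_identical(m["g3", "sp1"], "absent")
})

test_that("duplicate keys within one evidence stream are rejected", {
  empty_calls <- data.frame(seed_gene = character(), species = character(),
                            positive = logical(), stringsAsFactors = FALSE)
  empty_verdicts <- data.frame(seed_gene = character(), species = character(),
                               supported = logical(), stringsAsFactors = FALSE)
  tiers <- data.frame(seed_gene = c("g1", "g1"), species = "sp1",
                      tier = c("minor_refinement", "major_refinement"),
                      stringsAsFactors = FALSE)
  expect_error(build_matrix(empty_calls, tiers, empty_verdicts),
               "duplicate", class = "frbpipe_validation_error")
})

test_that("matrix assembly ignores evidence-stream row order", {
  set.seed(501)
  genes <- paste0("g", 1:6); sps <- paste0("sp", 1:4)
  grid <- expand.grid(seed_gene = genes, species = sps,
                      stringsAsFactors = FALSE)
  calls <- cbind(grid, positive = runif(nrow(grid)) < 0.5)
  sel <- runif(nrow(grid)) < 0.5
  tiers <- cbind(grid[sel, ],
                 tier = sample(c("minor_refinement", "major_refinement"),
                               sum(sel), TRUE))
  verdicts <- cbind(grid, supported = runif(nrow(grid)) < 0.3)
  m1 <- build_matrix(calls, tiers, verdicts, genes, sps)
  m2 <- build_matrix(calls[sample(nrow(calls)), ],
                     tiers[sample(nrow(tiers)), ],
                     verdicts[sample(nrow(verdicts)), ], genes, sps)
  expect_identical(m1, m2)
})

test_that("matrix summaries match direct cell counting", {
  m <- matrix(c("published_ok", "published_ok", "read_only", "absent",
                "minor_refinement", "published_ok"),
              nrow = 3, dimnames = list(paste0("g", 1:3), c("a", "b")))
  s <- summarize_matrix(m)
  expect_equal(s$n_present, 5)
  expect_equal(s$frb_fraction, 3 / 5)
  expect_equal(s$genome_dependent_fraction, 2 / 5)
  grp <- summarize_matrix(m, groups = c(a = "G1", b = "G2"))
  expect_equal(grp$n_present[grp$group == "G1"], 3)
  set.seed(502)
  for (i in 1:10) {
    mm <- matrix(sample(tier_levels(), 24, TRUE), nrow = 4,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
    ss <- summarize_matrix(mm)
    expect_equal(ss$published_ok, sum(mm == "published_ok"))
    expect_equal(ss$n_present, sum(mm != "absent"))
  }
})

test_that("Dollo handles the degenerate presence patterns", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  all_present <- setNames(rep(TRUE, 4), c("A", "B", "C", "D"))
  r <- dollo_reconstruct(all_present, tr)
  expect_equal(r$n_losses, 0L)
  expect_identical(r$gain_node, "nd5")   # the root

  one <- setNames(c(TRUE, FALSE, FALSE, FALSE), c("A", "B", "C", "D"))
  r1 <- dollo_reconstruct(one, tr)
  expect_identical(r1$gain_node, "A")
  expect_equal(r1$n_losses, 0L)

  none <- setNames(rep(FALSE, 4), c("A", "B", "C", "D"))
  r0 <- dollo_reconstruct(none, tr)
  expect_true(is.na(r0$gain_node))
  expect_equal(r0$n_losses, 0L)
})

test_that("Dollo equals exhaustive minimisation on small trees, incl. polytomies", {
  set.seed(503)
  shapes <- unlist(lapply(2:6, all_binary_shapes))
  trees <- lapply(shapes, shape_to_tree)
  # plus random multifurcating trees
  for (i in 1:10) {
    tr <- ape::di2multi(ape::rtree(sample(4:7, 1)), tol = 0.5)
    tr$edge.length <- NULL
    trees <- c(trees, list(tr))
  }
  for (tr in trees) {
    n <- ape::Ntip(tr)
    orc <- dollo_oracle(tr)
    for (pat in seq_len(2^n - 1)) {
      tips <- tr$tip.label[bitwAnd(bitwShiftL(1L, 0:(n - 1)), pat) > 0]
      pres <- setNames(tr$tip.label %in% tips, tr$tip.label)
      rec <- dollo_reconstruct(pres, tr)
      expect_equal(rec$n_losses, orc(pat))
      resim <- simulate_dollo(tr, rec$gain_node, rec$loss_edges)
      expect_identical(resim[tr$tip.label], pres[tr$tip.label])
    }
  }
})

test_that("adding a presence leaf never narrows the gain clade", {
  set.seed(504)
  for (i in 1:20) {
    tr <- ape::rtree(8)
    pres <- setNames(runif(8) < 0.4, tr$tip.label)
    if (!any(pres)) pres[1] <- TRUE
    r1 <- dollo_reconstruct(pres, tr)
    extra <- sample(which(!pres), 1)
    if (length(extra)) {
      pres2 <- pres; pres2[extra] <- TRUE
      r2 <- dollo_reconstruct(pres2, tr)
      clade1 <- simulate_dollo(tr, r1$gain_node, character())
      clade2 <- simulate_dollo(tr, r2$gain_node, character())
      expect_true(all(names(clade1)[clade1] %in% names(clade2)[clade2]))
    }
  }
})

test_that("support collapse contracts exactly the edges below threshold", {
  tr <- ape::read.tree(text = "(((A,B)49,C)50,(D,E)90);")
  out <- collapse_low_support(tr, 50)
  cl <- tree_clades(out)
  expect_setequal(cl$clade, c("A|B|C", "D|E"))   # the 49 edge is gone
  expect_identical(sort(out$tip.label), sort(tr$tip.label))

  expect_identical(ape::write.tree(collapse_low_support(tr, 0)),
                   ape::write.tree(tr))          # threshold 0 is the identity
})

test_that("collapse preserves the support-filtered clade set on random trees", {
  set.seed(505)
  for (i in 1:50) {
    tr <- random_support_tree(sample(5:20, 1))
    thr <- sample(c(30, 50, 70), 1)
    out <- collapse_low_support(tr, thr)
    expect_identical(sort(out$tip.label), sort(tr$tip.label))
    before <- tree_clades(tr)
    keep <- before$clade[is.na(before$support) | before$support >= thr]
    expect_setequal(tree_clades(out)$clade, keep)
  }
})

test_that("collapse keeps root-to-tip path lengths", {
  set.seed(506)
  tr <- random_support_tree(10)
  out <- collapse_low_support(tr, 60)
  d1 <- ape::node.depth.edgelength(tr)[seq_len(10)]
  d2 <- ape::node.depth.edgelength(out)[seq_len(10)]
  expect_equal(d2[match(tr$tip.label, out$tip.label)], d1, tolerance = 1e-9)
})
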