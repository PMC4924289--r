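test_that("the generator validates its configuration", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(seed = 1, loss_rate = 1.2),
               class = "frbpipe_validation_error")
  expect_error(simulation_config(seed = 1,
                                 corruption_mix = c(intact = 1)),
               class = "frbpipe_validation_error")
  bad <- c(intact = 0.9, truncated_minor = 0.2, truncated_major = 0,
           split = 0, merged = 0, model_absent = 0)
  expect_error(simulation_config(seed = 1, corruption_mix = bad),
               "sum to 1", class = "frbpipe_validation_error")
})

test_that("identical config and seed give identical truth sets", {
  cfg <- simulation_config(n_species = 5, n_genes = 8, seed = 99)
  a <- simulate_truth_set(cfg)
  b <- simulate_truth_set(cfg)
  expect_identical(a$truth_matrix, b$truth_matrix)
  expect_identical(a$truth_tiers, b$truth_tiers)
  expect_identical(as.character(a$seeds), as.character(b$seeds))
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$reads, b$reads)
  expect_identical(a$genomes, b$genomes)
})

test_that("planted split and merged pathologies have the promised structure", {
  cfg <- simulation_config(
    n_species = 6, n_genes = 20, seed = 7,
    corruption_mix = c(intact = 0.2, truncated_minor = 0, truncated_major = 0,
                       split = 0.4, merged = 0.4, model_absent = 0))
  ts <- simulate_truth_set(cfg)
  tt <- ts$truth_tiers
  splits <- tt[tt$mode == "split", ]
  expect_gt(nrow(splits), 0)
  for (i in seq_len(nrow(splits))) {
    g <- splits$gene[i]; sp <- splits$species[i]
    ann <- ts$annotations[[sp]]
    parts <- unique(grep(paste0("^", g, "_", sp, "_p"), ann$model_id,
                         value = TRUE))
    expect_length(parts, 2L)   # one true locus split over two models
    pred <- ts$predicted_models[[sp]]
    pm <- pred[pred$seed == g, , drop = FALSE]
    for (p in parts)
      expect_gte(genomic_overlap(pm, ann[ann$model_id == p, ]), 30)
  }
  merges <- tt[tt$mode == "merged", ]
  expect_gt(nrow(merges), 0)
  for (sp in unique(merges$species)) {
    gs <- merges$gene[merges$species == sp]
    expect_equal(length(gs) %% 2, 0)   # merged genes come in pairs
    ann <- ts$annotations[[sp]]
    fused <- unique(grep("__", ann$model_id, value = TRUE))
    pred <- ts$predicted_models[[sp]]
    for (fid in fused) {
      pub1 <- ann[ann$model_id == fid, ]
      n_over <- sum(vapply(unique(pred$model_id), function(id)
        genomic_overlap(pub1, pred[pred$model_id == id, ]) >= 30, logical(1)))
      expect_gte(n_over, 2)   # one published model spans >= 2 true genes
    }
  }
})

test_that("realised read depth matches the configured mean", {
  cfg <- simulation_config(n_species = 3, n_genes = 120, seed = 5,
                           decoy_rate = 0)
  ts <- simulate_truth_set(cfg)
  sp <- setdiff(ts$species, "REF")[1]
  rd <- ts$reads[[sp]]
  genes <- rownames(ts$truth_matrix)[ts$truth_matrix[, sp] == 1]
  seed_len <- setNames(Biostrings::nchar(ts$seeds), names(ts$seeds))
  means <- vapply(genes, function(g) {
    h <- rd[rd$subject_id == g, , drop = FALSE]
    sum(h$s_end - h$s_start + 1) / seed_len[[g]]
  }, numeric(1))
  expect_gte(length(means), 100)
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - cfg$read_depth), 3 * se)
})

test_that("extreme loss settings produce the expected presence patterns", {
  cfg0 <- simulation_config(n_species = 5, n_genes = 6, loss_rate = 0, seed = 3)
  ts0 <- simulate_truth_set(cfg0)
  expect_true(all(ts0$truth_matrix == 1L))
  expect_true(all(lengths(ts0$truth_losses) == 0))

  cfg1 <- simulation_config(n_species = 5, n_genes = 6, loss_rate = 1, seed = 3)
  ts1 <- simulate_truth_set(cfg1)
  expect_true(all(ts1$truth_matrix[, "REF"] == 1L))
  expect_true(all(ts1$truth_matrix[, setdiff(ts1$species, "REF")] == 0L))
})

test_that("recovery scoring counts cells and loss branches directly", {
  cfg <- simulation_config(n_species = 5, n_genes = 10, seed = 21)
  ts <- simulate_truth_set(cfg)
  tm <- ts$truth_matrix
  perfect <- matrix(ifelse(tm == 1L, "published_ok", "absent"),
                    nrow(tm), ncol(tm), dimnames = dimnames(tm))
  gl <- data.frame(
    gene = names(ts$truth_losses),
    loss_edges = vapply(ts$truth_losses, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  rep0 <- score_recovery(ts, perfect, gl)
  expect_equal(rep0$cell_accuracy, 1.0)
  expect_equal(rep0$loss_precision, 1.0)
  expect_equal(rep0$loss_recall, 1.0)

  allabs <- matrix("absent", nrow(tm), ncol(tm), dimnames = dimnames(tm))
  repa <- score_recovery(ts, allabs, gl[0, ])
  expect_equal(repa$cell_accuracy, mean(tm == 0L))

  # flipping k cells costs exactly k / n_cells
  set.seed(22)
  k <- 7
  flip <- sample(length(tm), k)
  noisy <- perfect
  noisy[flip] <- ifelse(perfect[flip] == "absent", "published_ok", "absent")
  repn <- score_recovery(ts, noisy, gl)
  expect_equal(repn$cell_accuracy, 1 - k / length(tm))

  bad <- perfect[, -1, drop = FALSE]
  expect_error(score_recovery(ts, bad, gl), "universe",
               class = "frbpipe_validation_error")
})
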