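# End-to-end orchestration: search -> FRB -> model reconciliation ->
# read evidence -> evidence matrix -> Dollo gain/loss -> summaries.
# Stages are plain functions over in-memory objects so that run_all()
# is exactly the composition of the stage functions; run_all()
# additionally persists every stage's output as TSV and writes a run
# manifest.  All stages are deterministic; randomness exists only in
# the simulator.

#' Pipeline configuration
#'
#' @param input_dir Input bundle directory (layout of
#'   [write_truth_set()]: `tree.nwk`, `seeds.faa`,
#'   `species/<sp>/{published.faa,published.gff3,predicted.faa,
#'   predicted.gff3,reads.tsv}`).
#' @param out_dir Output directory.
#' @param fuzzy A [fuzzy_config()].
#' @param scheme A [scoring_scheme()].
#' @param min_bitscore Search reporting floor (bits).
#' @param min_shared Minimum shared bases for genomic-overlap calls.
#' @param minor_delta,major_delta Refinement-tier thresholds (additive
#'   coverage points).
#' @param min_read_coverage,depth_k Read-evidence thresholds (see
#'   [consistency_test()]).
#' @return A `"run_config"` list.
#' @export
run_config <- function(input_dir, out_dir, fuzzy = fuzzy_config(),
                       scheme = scoring_scheme(), min_bitscore = 25,
                       min_shared = 30L, minor_delta = 0.05,
                       major_delta = 0.15, min_read_coverage = 0.8,
                       depth_k = 3) {
  if (!dir.exists(input_dir)) stop_config("input_dir does not exist: ", input_dir)
  structure(list(input_dir = input_dir, out_dir = out_dir, fuzzy = fuzzy,
                 scheme = scheme, min_bitscore = min_bitscore,
                 min_shared = as.integer(min_shared),
                 minor_delta = minor_delta, major_delta = major_delta,
                 min_read_coverage = min_read_coverage, depth_k = depth_k),
            class = "run_config")
}

#' Load an input bundle from disk
#'
#' @param input_dir Bundle directory (see [run_config()]).
#' @return A list with `tree`, `seeds`, `species` and per-species
#'   `proteomes`, `annotations`, `predicted_models`,
#'   `predicted_proteomes`, `reads`.
#' @export
load_bundle <- function(input_dir) {
  tree <- read_newick(file.path(input_dir, "tree.nwk"))
  seeds <- read_fasta(file.path(input_dir, "seeds.faa"))
  sp_dirs <- list.dirs(file.path(input_dir, "species"), recursive = FALSE)
  if (length(sp_dirs) == 0L)
    stop_config("no species directories under ", input_dir)
  species <- basename(sp_dirs)
  # keep the tree's tip order where possible
  species <- c(intersect(tree$tip.label, species),
               setdiff(species, tree$tip.label))
  bundle <- list(tree = tree, seeds = seeds, species = species,
                 proteomes = list(), annotations = list(),
                 predicted_models = list(), predicted_proteomes = list(),
                 reads = list())
  for (sp in species) {
    d <- file.path(input_dir, "species", sp)
    bundle$proteomes[[sp]] <- read_fasta(file.path(d, "published.faa"))
    bundle$annotations[[sp]] <- read_gff3(file.path(d, "published.gff3"))
    if (file.exists(file.path(d, "predicted.gff3"))) {
      bundle$predicted_models[[sp]] <- read_gff3(file.path(d, "predicted.gff3"))
      bundle$predicted_proteomes[[sp]] <- read_fasta(file.path(d, "predicted.faa"))
    } else {
      bundle$predicted_models[[sp]] <- gene_models()
      bundle$predicted_proteomes[[sp]] <- Biostrings::AAStringSet()
    }
    bundle$reads[[sp]] <- if (file.exists(file.path(d, "reads.tsv")))
      read_hit_table(file.path(d, "reads.tsv")) else empty_hits()
  }
  bundle
}

# shared-bases table between two model sets (long form: a_id, b_id, shared)
overlap_table <- function(a, b) {
  out <- list()
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(a_id = character(), b_id = character(),
                      shared = integer(), stringsAsFactors = FALSE))
  sa <- paste(a$seqid, a$strand); sb <- paste(b$seqid, b$strand)
  for (spc in intersect(unique(sa), unique(sb))) {
    ai <- a[sa == spc, , drop = FALSE]; bi <- b[sb == spc, , drop = FALSE]
    ra <- IRanges::IRanges(ai$start + 1L, ai$end)
    rb <- IRanges::IRanges(bi$start + 1L, bi$end)
    h <- IRanges::findOverlaps(ra, rb)
    if (length(h) == 0L) next
    w <- IRanges::width(IRanges::pintersect(ra[S4Vectors::queryHits(h)],
                                            rb[S4Vectors::subjectHits(h)]))
    df <- data.frame(a_id = ai$model_id[S4Vectors::queryHits(h)],
                     b_id = bi$model_id[S4Vectors::subjectHits(h)],
                     shared = w, stringsAsFactors = FALSE)
    out[[spc]] <- stats::aggregate(shared ~ a_id + b_id, df, sum)
  }
  if (length(out) == 0L)
    return(data.frame(a_id = character(), b_id = character(),
                      shared = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Search stage: reciprocal hit tables plus predicted-model coverage
#'
#' @param bundle From [load_bundle()].
#' @param config A [run_config()].
#' @return List with per-species `hits` (forward/reverse tables against
#'   the published proteomes) and `pred_coverage` (`data.frame`:
#'   species, model_id, seed, coverage, bitscore of each predicted
#'   model's protein aligned to its seed).
#' @export
stage_search <- function(bundle, config) {
  hits <- list(); pc <- list()
  for (sp in bundle$species) {
    hits[[sp]] <- if (length(bundle$proteomes[[sp]]))
      search_reciprocal(bundle$seeds, bundle$proteomes[[sp]],
                        config$scheme, config$min_bitscore)
    else list(forward = empty_hits(), reverse = empty_hits())
    pp <- bundle$predicted_proteomes[[sp]]
    pm <- bundle$predicted_models[[sp]]
    if (length(pp) == 0L) next
    seed_of <- setNames(pm$seed, pm$model_id)
    rows <- lapply(names(pp), function(id) {
      g <- seed_of[[id]]
      if (is.null(g) || is.na(g)) return(NULL)
      aln <- smith_waterman(bundle$seeds[[g]], pp[[id]], config$scheme,
                            query_id = g, subject_id = id)
      data.frame(species = sp, model_id = id, seed = g,
                 coverage = alignment_coverage(
                   aln, Biostrings::nchar(bundle$seeds[[g]])),
                 bitscore = aln$bitscore, stringsAsFactors = FALSE)
    })
    pc[[sp]] <- do.call(rbind, rows)
  }
  pred_coverage <- do.call(rbind, pc) %||%
    data.frame(species = character(), model_id = character(),
               seed = character(), coverage = numeric(),
               bitscore = numeric(), stringsAsFactors = FALSE)
  rownames(pred_coverage) <- NULL
  list(hits = hits, pred_coverage = pred_coverage)
}

#' FRB stage: homology calls for every seed in every species
#'
#' @param bundle From [load_bundle()].
#' @param search From [stage_search()].
#' @param config A [run_config()].
#' @return Calls `data.frame` (one row per seed x species).
#' @export
stage_frb <- function(bundle, search, config) {
  out <- lapply(bundle$species, function(sp)
    suppressWarnings(call_species(bundle$seeds, bundle$proteomes[[sp]],
                                  config$fuzzy, hits = search$hits[[sp]],
                                  species = sp, scheme = config$scheme)))
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  calls
}

#' Reconciliation stage: refinement tiers and split/merged pathologies
#'
#' Each predicted model is graded against the published models it
#' overlaps (coverage deltas on the seed protein); published models
#' overlapped by two or more predictions are flagged as merged.
#'
#' @param bundle From [load_bundle()].
#' @param search From [stage_search()].
#' @param config A [run_config()].
#' @return List with `refinement` (per predicted model: tier,
#'   overlap class, delta), `tiers` (per gene x species stream for
#'   [build_matrix()]) and `merged_models` (published model id,
#'   species, genes involved).
#' @export
stage_reconcile <- function(bundle, search, config) {
  seed_len <- setNames(Biostrings::nchar(bundle$seeds), names(bundle$seeds))
  refinement <- list(); merged <- list()
  for (sp in bundle$species) {
    pm <- bundle$predicted_models[[sp]]
    if (nrow(pm) == 0L) next
    pub <- bundle$annotations[[sp]]
    fwd <- search$hits[[sp]]$forward
    ov <- overlap_table(pm, pub)
    pcov <- search$pred_coverage
    pcov <- pcov[pcov$species == sp, , drop = FALSE]
    for (id in unique(pm$model_id)) {
      g <- pm$seed[pm$model_id == id][1]
      if (is.na(g)) next
      new_cov <- pcov$coverage[pcov$model_id == id]
      if (length(new_cov) == 0L) next
      # seed-protein coverage of each published model, from the forward
      # search of the seed against the published proteome
      fg <- fwd[fwd$query_id == g, , drop = FALSE]
      pub_cov <- setNames((fg$q_end - fg$q_start + 1) / seed_len[[g]],
                          fg$subject_id)
      ovi <- ov[ov$a_id == id, , drop = FALSE]
      shared <- setNames(ovi$shared, ovi$b_id)
      cls <- classify_refinement(
        pm[pm$model_id == id, , drop = FALSE], new_cov, pub,
        published_coverage = pub_cov, min_shared = config$min_shared,
        minor_delta = config$minor_delta, major_delta = config$major_delta,
        overlap_bases = shared)
      refinement[[length(refinement) + 1L]] <- data.frame(
        species = sp, model_id = id, seed = g, tier = cls$tier,
        overlap_class = cls$overlap_class,
        delta = cls$delta %||% NA_real_,
        overlapping = paste(cls$overlapping, collapse = ","),
        stringsAsFactors = FALSE)
    }
    # merged published models: >= 2 predicted models sharing them
    if (nrow(ov)) {
      for (pid in unique(ov$b_id)) {
        pred_ids <- ov$a_id[ov$b_id == pid & ov$shared >= config$min_shared]
        if (length(pred_ids) >= 2L) {
          gs <- unique(pm$seed[pm$model_id %in% pred_ids])
          merged[[length(merged) + 1L]] <- data.frame(
            species = sp, published_model = pid,
            genes = paste(sort(gs), collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  refinement <- do.call(rbind, refinement) %||%
    data.frame(species = character(), model_id = character(),
               seed = character(), tier = character(),
               overlap_class = character(), delta = numeric(),
               overlapping = character(), stringsAsFactors = FALSE)
  rownames(refinement) <- NULL
  merged <- do.call(rbind, merged) %||%
    data.frame(species = character(), published_model = character(),
               genes = character(), stringsAsFactors = FALSE)
  tiers <- data.frame(seed_gene = refinement$seed,
                      species = refinement$species,
                      tier = refinement$tier, stringsAsFactors = FALSE)
  list(refinement = refinement, tiers = tiers, merged_models = merged)
}

#' Read-evidence stage: depth profiles and consistency verdicts
#'
#' Reference profiles are the FRB-confirmed homologues of the same
#' species; when a species has none, the coverage-only fallback rule is
#' applied.
#'
#' @param bundle From [load_bundle()].
#' @param calls From [stage_frb()].
#' @param config A [run_config()].
#' @return Verdicts `data.frame`: seed_gene, species, coverage,
#'   median_depth, z, supported.
#' @export
stage_depth <- function(bundle, calls, config) {
  seed_len <- setNames(Biostrings::nchar(bundle$seeds), names(bundle$seeds))
  out <- list()
  for (sp in bundle$species) {
    rd <- bundle$reads[[sp]]
    if (nrow(rd) == 0L) next
    with_reads <- intersect(names(bundle$seeds), unique(rd$subject_id))
    profiles <- lapply(with_reads, function(g)
      pileup(rd[rd$subject_id == g, , drop = FALSE], seed_len[[g]],
             seed_gene = g, species = sp))
    names(profiles) <- with_reads
    confirmed <- calls$seed_gene[calls$species == sp & calls$positive]
    reference <- profiles[intersect(with_reads, confirmed)]
    for (g in with_reads) {
      p <- profiles[[g]]
      v <- if (length(reference))
        consistency_test(p, reference, config$min_read_coverage,
                         config$depth_k)
      else list(verdict = if (p$coverage >= config$min_read_coverage)
                  "supported" else "unsupported", z = NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        seed_gene = g, species = sp, coverage = p$coverage,
        median_depth = p$median_depth, z = v$z,
        supported = v$verdict == "supported", stringsAsFactors = FALSE)
    }
  }
  verdicts <- do.call(rbind, out) %||%
    data.frame(seed_gene = character(), species = character(),
               coverage = numeric(), median_depth = numeric(),
               z = numeric(), supported = logical(),
               stringsAsFactors = FALSE)
  rownames(verdicts) <- NULL
  verdicts
}

#' Dollo stage: per-gene gain/loss reconstruction from a tier matrix
#'
#' @param matrix Tier matrix from [build_matrix()].
#' @param tree Species tree covering the matrix columns.
#' @return `data.frame`: gene, gain_node, loss_edges (comma-joined
#'   child-node names), n_losses.
#' @export
stage_dollo <- function(matrix, tree) {
  rows <- lapply(rownames(matrix), function(g) {
    pres <- setNames(matrix[g, tree$tip.label] != "absent", tree$tip.label)
    rec <- dollo_reconstruct(pres, tree)
    data.frame(gene = g, gain_node = rec$gain_node,
               loss_edges = paste(rec$loss_edges, collapse = ","),
               n_losses = rec$n_losses, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# pipeline-assigned corruption mode per (gene, species); the counterpart
# of the simulator's planted modes, used by score_recovery()
assign_modes <- function(matrix, reconcile, verdicts) {
  merged_key <- character()
  if (nrow(reconcile$merged_models)) {
    mm <- reconcile$merged_models
    merged_key <- unlist(lapply(seq_len(nrow(mm)), function(i)
      paste(strsplit(mm$genes[i], ",", fixed = TRUE)[[1]], mm$species[i])))
  }
  ref <- reconcile$refinement
  rows <- list()
  for (sp in colnames(matrix)) {
    for (g in rownames(matrix)) {
      key <- paste(g, sp)
      r <- ref[ref$seed == g & ref$species == sp, , drop = FALSE]
      mode <- if (key %in% merged_key) "merged"
      else if (nrow(r) && r$overlap_class[1] == "split") "split"
      else if (nrow(r) && r$tier[1] == "minor_refinement") "truncated_minor"
      else if (nrow(r) && r$tier[1] %in% c("major_refinement", "novel"))
        "truncated_major"
      else if (nrow(r)) "intact"
      else if (matrix[g, sp] == "read_only") "model_absent"
      else if (matrix[g, sp] == "absent") "absent"
      else "intact"
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, species = sp, mode = mode, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the whole pipeline on an input bundle
#'
#' Executes search, FRB, reconciliation, read evidence, matrix
#' assembly, Dollo reconstruction and summaries; persists every stage
#' output as TSV under `out_dir` together with a machine-readable run
#' manifest.  Identical inputs and configuration give byte-identical
#' outputs.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a list with `matrix`, `calls`, `reconcile`,
#'   `verdicts`, `gainloss`, `modes`, `summary` and the output paths.
#' @export
run_all <- function(config) {
  bundle <- load_bundle(config$input_dir)
  search <- stage_search(bundle, config)
  calls <- stage_frb(bundle, search, config)
  reconcile <- stage_reconcile(bundle, search, config)
  verdicts <- stage_depth(bundle, calls, config)
  m <- build_matrix(calls, reconcile$tiers, verdicts,
                    genes = names(bundle$seeds), species = bundle$species)
  gainloss <- stage_dollo(m, bundle$tree)
  modes <- assign_modes(m, reconcile, verdicts)
  summary <- summarize_matrix(m)

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "hits"), showWarnings = FALSE)
  for (sp in bundle$species) {
    write_hit_table(search$hits[[sp]]$forward,
                    file.path(out, "hits", paste0(sp, "_forward.tsv")))
    write_hit_table(search$hits[[sp]]$reverse,
                    file.path(out, "hits", paste0(sp, "_reverse.tsv")))
  }
  write_tsv(search$pred_coverage, file.path(out, "predicted_coverage.tsv"))
  write_tsv(calls, file.path(out, "homology_calls.tsv"))
  write_tsv(reconcile$refinement, file.path(out, "refinement.tsv"))
  write_tsv(reconcile$merged_models, file.path(out, "merged_models.tsv"))
  write_tsv(verdicts, file.path(out, "read_verdicts.tsv"))
  write_tsv(data.frame(gene = rownames(m), m, check.names = FALSE,
                       stringsAsFactors = FALSE),
            file.path(out, "matrix.tsv"))
  write_tsv(gainloss, file.path(out, "gainloss.tsv"))
  write_tsv(modes, file.path(out, "assigned_modes.tsv"))
  write_tsv(summary, file.path(out, "summary.tsv"))
  manifest <- list(
    package = "frbpipe",
    version = as.character(packageVersion("frbpipe")),
    input_dir = config$input_dir,
    parameters = list(fuzz = config$fuzzy$f,
                      max_evalue = config$fuzzy$max_evalue,
                      min_query_coverage = config$fuzzy$min_query_coverage,
                      min_bitscore = config$min_bitscore,
                      min_shared = config$min_shared,
                      minor_delta = config$minor_delta,
                      major_delta = config$major_delta,
                      min_read_coverage = config$min_read_coverage,
                      depth_k = config$depth_k,
                      gap_open = config$scheme$gap_open,
                      gap_extend = config$scheme$gap_extend,
                      lambda = config$scheme$lambda, K = config$scheme$K),
    species = bundle$species, n_genes = length(bundle$seeds))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message("FRB fuzz factor f = ", config$fuzzy$f,
          "; admission filters: E <= ", config$fuzzy$max_evalue,
          ", query coverage >= ", config$fuzzy$min_query_coverage)
  invisible(list(matrix = m, calls = calls, reconcile = reconcile,
                 verdicts = verdicts, gainloss = gainloss, modes = modes,
                 summary = summary, out_dir = out))
}
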