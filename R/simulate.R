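# Synthetic genomes with planted ground truth.  A reference species
# (always carrying every seed gene, placed as the outgroup) plus target
# species related by a known tree; per-gene presence evolves by a single
# origin at the root with Bernoulli per-branch losses; proteins diverge
# by uniform substitution; published annotations are corrupted with the
# pathologies seen in draft genomes (truncated, split, merged, absent
# models); reads are uniform-depth protein-space intervals.

.CORRUPTION_MODES <- c("intact", "truncated_minor", "truncated_major",
                       "split", "merged", "model_absent")

#' Configuration for the synthetic-genome generator
#'
#' Defaults are the benchmark study conditions: 12 species (reference
#' included), 40 seed genes, per-branch loss probability 0.05, recent
#' duplication probability 0.05 per (gene, species), corruption mix
#' 50% intact / 15% minor truncation / 15% major truncation / 10% split
#' / 5% merged / 5% model absent, and mean read depth 20 per residue.
#'
#' @param n_species Number of species including the reference.
#' @param n_genes Number of seed genes.
#' @param tree Optional rooted `"phylo"` species tree whose tips are
#'   the species (must include `"REF"`); `NULL` draws a random ingroup
#'   topology and attaches the reference as outgroup.
#' @param loss_rate Per-branch loss probability on ingroup branches.
#' @param duplication_rate Probability of a recent duplicate
#'   (co-orthologue) per present (gene, species).
#' @param corruption_mix Named probabilities over
#'   `intact, truncated_minor, truncated_major, split, merged,
#'   model_absent`; must sum to 1.
#' @param minor_range,major_range Truncation gap ranges (fractions of
#'   the protein) matching the 5%/15% refinement-tier boundaries.
#' @param read_depth Mean reads per residue.
#' @param read_length Read length in residues (33 aa, about a 100 bp
#'   read).
#' @param mutation_rate Per-residue substitution probability per
#'   branch.
#' @param dup_divergence Per-residue substitution probability between a
#'   gene and its recent duplicate.
#' @param decoy_rate Decoy (non-seed) genes planted per species, as a
#'   fraction of `n_genes`; negative controls for false-positive FRB
#'   calls.
#' @param protein_length Seed protein length range (residues).
#' @param seed RNG seed (mandatory).
#' @return A `"simulation_config"` list.
#' @export
simulation_config <- function(n_species = 12L, n_genes = 40L, tree = NULL,
                              loss_rate = 0.05, duplication_rate = 0.05,
                              corruption_mix = c(intact = 0.5,
                                                 truncated_minor = 0.15,
                                                 truncated_major = 0.15,
                                                 split = 0.1,
                                                 merged = 0.05,
                                                 model_absent = 0.05),
                              minor_range = c(0.05, 0.15),
                              major_range = c(0.15, 0.5),
                              read_depth = 20, read_length = 33L,
                              mutation_rate = 0.02, dup_divergence = 0.01,
                              decoy_rate = 0.2,
                              protein_length = c(150L, 400L), seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_validation("an RNG seed is mandatory")
  if (n_species < 3L) stop_validation("need at least 3 species (incl. reference)")
  if (n_genes < 1L) stop_validation("need at least one gene")
  check_fraction(loss_rate, "loss_rate")
  check_fraction(duplication_rate, "duplication_rate")
  check_fraction(mutation_rate, "mutation_rate")
  if (!setequal(names(corruption_mix), .CORRUPTION_MODES))
    stop_validation("corruption_mix must name exactly the modes: ",
                    paste(.CORRUPTION_MODES, collapse = ", "))
  if (any(corruption_mix < 0) || abs(sum(corruption_mix) - 1) > 1e-8)
    stop_validation("corruption_mix must be non-negative and sum to 1")
  if (read_depth <= 0) stop_validation("read_depth must be positive")
  structure(list(n_species = as.integer(n_species),
                 n_genes = as.integer(n_genes), tree = tree,
                 loss_rate = loss_rate, duplication_rate = duplication_rate,
                 corruption_mix = corruption_mix[.CORRUPTION_MODES],
                 minor_range = minor_range, major_range = major_range,
                 read_depth = read_depth,
                 read_length = as.integer(read_length),
                 mutation_rate = mutation_rate,
                 dup_divergence = dup_divergence,
                 decoy_rate = decoy_rate,
                 protein_length = as.integer(protein_length),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.AA20 <- .AA_ALPHABET[.AA_ALPHABET != "X"]

random_protein <- function(len) paste(sample(.AA20, len, TRUE), collapse = "")

mutate_protein <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    repl <- sample(.AA20, length(hit), TRUE)
    # force an actual substitution at every hit position
    same <- repl == ch[hit]
    while (any(same)) {
      repl[same] <- sample(.AA20, sum(same), TRUE)
      same <- repl == ch[hit]
    }
    ch[hit] <- repl
  }
  paste(ch, collapse = "")
}

.CODON <- setNames(c("GCT","CGT","AAT","GAT","TGT","CAA","GAA","GGT","CAT",
                     "ATT","CTT","AAA","ATG","TTT","CCT","TCT","ACT","TGG",
                     "TAT","GTT"), .AA20)

protein_to_dna <- function(seq)
  paste(.CODON[strsplit(seq, "")[[1]]], collapse = "")

random_dna <- function(len) paste(sample(c("A","C","G","T"), len, TRUE),
                                  collapse = "")

# random ingroup topology with the reference attached as outgroup; the
# root therefore always sits on the reference lineage and every gene's
# single gain is at the root
default_species_tree <- function(n_species) {
  ingroup <- ape::rtree(n_species - 1L, rooted = TRUE,
                        tip.label = sprintf("SP%02d", seq_len(n_species - 1L) + 1L))
  nwk <- sub(";$", "", ape::write.tree(ingroup))
  tr <- ape::read.tree(text = paste0("(REF:1,", nwk, ":1);"))
  tr$node.label <- paste0("N", seq_len(tr$Nnode))
  tr
}

#' Generate a truth-known synthetic input bundle
#'
#' See [simulation_config()] for the generative model.  Fully
#' deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @return A `"truth_set"` list: `tree`, `species`, `seeds`
#'   (AAStringSet), per-species `genomes`, `annotations` (published
#'   gene models), `proteomes`, `predicted_models`,
#'   `predicted_proteomes`, `reads` (hit tables), and the planted truth
#'   (`truth_matrix`, `truth_tiers`, `truth_losses`, `truth_dups`).
#' @export
simulate_truth_set <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop_validation("config must come from simulation_config()")
  set.seed(config$seed)
  n_sp <- config$n_species
  tree <- config$tree %||% default_species_tree(n_sp)
  if (!"REF" %in% tree$tip.label)
    stop_validation("species tree must contain the reference tip 'REF'")
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)))
    tree$node.label <- paste0("N", seq_len(tree$Nnode))
  species <- tree$tip.label
  ntip <- ape::Ntip(tree)
  all_names <- node_name(tree, seq_len(ntip + tree$Nnode))
  ed <- tree$edge  # cladewise: parents before children
  ref_tip <- match("REF", species)

  genes <- sprintf("g%02d", seq_len(config$n_genes))
  lens <- sample(seq(config$protein_length[1], config$protein_length[2]),
                 config$n_genes, replace = TRUE)
  seeds <- setNames(vapply(lens, random_protein, character(1)), genes)

  # -- presence and planted losses --------------------------------------
  truth_matrix <- matrix(0L, config$n_genes, ntip,
                         dimnames = list(genes, species))
  truth_losses <- setNames(vector("list", config$n_genes), genes)
  state_list <- list()
  for (g in genes) {
    state <- rep(TRUE, ntip + tree$Nnode)
    losses <- character()
    for (k in seq_len(nrow(ed))) {
      p <- ed[k, 1]; ch <- ed[k, 2]
      if (!state[p]) { state[ch] <- FALSE; next }
      if (ch == ref_tip) next  # the reference always keeps the gene
      if (runif(1) < config$loss_rate) {
        state[ch] <- FALSE
        losses <- c(losses, all_names[ch])
      }
    }
    truth_matrix[g, ] <- as.integer(state[seq_len(ntip)])
    truth_losses[[g]] <- losses
    state_list[[g]] <- state
  }

  # -- protein evolution down the tree ----------------------------------
  leaf_protein <- matrix(NA_character_, config$n_genes, ntip,
                         dimnames = list(genes, species))
  for (g in genes) {
    node_seq <- character(ntip + tree$Nnode)
    node_seq[ntip + 1L] <- seeds[[g]]
    for (k in seq_len(nrow(ed))) {
      p <- ed[k, 1]; ch <- ed[k, 2]
      node_seq[ch] <- mutate_protein(node_seq[p], config$mutation_rate)
    }
    leaf_protein[g, ] <- node_seq[seq_len(ntip)]
  }

  # -- corruption modes --------------------------------------------------
  modes <- matrix(NA_character_, config$n_genes, ntip,
                  dimnames = list(genes, species))
  for (sp in species) {
    present <- genes[truth_matrix[, sp] == 1L]
    if (sp == "REF") { modes[present, sp] <- "intact"; next }
    m <- sample(.CORRUPTION_MODES, length(present), replace = TRUE,
                prob = config$corruption_mix)
    names(m) <- present
    # merged models need an adjacent seed-gene partner: pair the genes
    # drawn as merged within the species; an unpaired leftover reverts
    # to intact
    merged <- names(m)[m == "merged"]
    if (length(merged) %% 2L == 1L) {
      m[merged[length(merged)]] <- "intact"
      merged <- merged[-length(merged)]
    }
    modes[present, sp] <- m[present]
  }

  # -- duplications ------------------------------------------------------
  truth_dups <- list()
  for (sp in setdiff(species, "REF")) {
    for (g in genes[truth_matrix[, sp] == 1L]) {
      if (runif(1) < config$duplication_rate)
        truth_dups[[length(truth_dups) + 1L]] <- c(gene = g, species = sp)
    }
  }
  truth_dups <- if (length(truth_dups))
    as.data.frame(do.call(rbind, truth_dups), stringsAsFactors = FALSE)
  else data.frame(gene = character(), species = character(),
                  stringsAsFactors = FALSE)

  # -- genomes, annotations, proteomes ----------------------------------
  genomes <- list(); annotations <- list(); proteomes <- list()
  predicted_models <- list(); predicted_proteomes <- list()
  reads <- list()
  n_decoys <- max(0L, round(config$decoy_rate * config$n_genes))

  for (sp in species) {
    present <- genes[truth_matrix[, sp] == 1L]
    ctg <- paste0("ctg_", sp)
    # locus order: merged pairs adjacent, duplicates right after their
    # source, decoys at the end
    merged_here <- present[modes[present, sp] == "merged"]
    order_units <- list(); used <- character()
    for (g in present) {
      if (g %in% used) next
      if (g %in% merged_here) {
        partner <- setdiff(merged_here, used)
        partner <- partner[partner != g][1]
        order_units[[length(order_units) + 1L]] <- c(g, partner)
        used <- c(used, g, partner)
      } else {
        order_units[[length(order_units) + 1L]] <- g
        used <- c(used, g)
      }
    }
    dup_genes <- if (nrow(truth_dups))
      truth_dups$gene[truth_dups$species == sp] else character()

    pos <- 0L
    dna_parts <- character(); locus <- list(); dup_prot <- list()
    add_locus <- function(id, protein) {
      spacer_len <- sample(200:500, 1)
      start <- pos + spacer_len
      dna <- protein_to_dna(protein)
      end <- start + nchar(dna)
      dna_parts[[length(dna_parts) + 1L]] <<- random_dna(spacer_len)
      dna_parts[[length(dna_parts) + 1L]] <<- dna
      locus[[id]] <<- c(start = start, end = end)
      pos <<- end
    }
    for (unit in order_units) {
      for (g in unit) {
        add_locus(g, leaf_protein[g, sp])
        if (g %in% dup_genes) {
          dup_prot[[g]] <- mutate_protein(leaf_protein[g, sp],
                                          config$dup_divergence)
          add_locus(paste0(g, "_d2"), dup_prot[[g]])
        }
      }
    }
    decoy_prot <- character()
    if (sp != "REF" && n_decoys > 0L) {
      for (i in seq_len(n_decoys)) {
        id <- sprintf("dx%02d", i)
        decoy_prot[[id]] <- random_protein(
          sample(seq(config$protein_length[1], config$protein_length[2]), 1))
        add_locus(id, decoy_prot[[id]])
      }
    }
    genomes[[sp]] <- setNames(paste(unlist(dna_parts), collapse = ""), ctg)

    # published annotation (post-corruption) and proteome
    ann <- list(); prot <- character()
    pub_model <- function(id, start, end, protein) {
      ann[[length(ann) + 1L]] <<- data.frame(
        model_id = id, seqid = ctg, strand = "+",
        start = as.integer(start), end = as.integer(end),
        seed = NA_character_, stringsAsFactors = FALSE)
      prot[[id]] <<- protein
    }
    merged_done <- character()
    for (g in present) {
      loc <- locus[[g]]; pr <- leaf_protein[g, sp]; L <- nchar(pr)
      mid <- paste0(g, "_", sp)
      mode <- modes[g, sp]
      if (mode == "intact") {
        pub_model(mid, loc["start"], loc["end"], pr)
      } else if (mode %in% c("truncated_minor", "truncated_major")) {
        rng <- if (mode == "truncated_minor") config$minor_range
               else config$major_range
        gap <- runif(1, rng[1], rng[2])
        keep <- max(10L, as.integer(round((1 - gap) * L)))
        pub_model(mid, loc["start"], loc["start"] + 3L * keep,
                  substr(pr, 1, keep))
      } else if (mode == "split") {
        h <- as.integer(round(L / 2))
        pub_model(paste0(mid, "_p1"), loc["start"], loc["start"] + 3L * h,
                  substr(pr, 1, h))
        pub_model(paste0(mid, "_p2"), loc["start"] + 3L * h, loc["end"],
                  substr(pr, h + 1, L))
      } else if (mode == "merged" && !(g %in% merged_done)) {
        partner <- setdiff(present[modes[present, sp] == "merged"],
                           c(merged_done, g))[1]
        merged_done <- c(merged_done, g, partner)
        loc2 <- locus[[partner]]
        id <- paste0(g, "__", partner, "_", sp)
        ann[[length(ann) + 1L]] <- data.frame(
          model_id = id, seqid = ctg, strand = "+",
          start = as.integer(c(loc["start"], loc2["start"])),
          end = as.integer(c(loc["end"], loc2["end"])),
          seed = NA_character_, stringsAsFactors = FALSE)
        prot[[id]] <- paste0(pr, leaf_protein[partner, sp])
      }  # model_absent: locus in the genome, no published model
    }
    for (g in intersect(present, dup_genes)) {
      d <- locus[[paste0(g, "_d2")]]
      pub_model(paste0(g, "_", sp, "_d2"), d["start"], d["end"], dup_prot[[g]])
    }
    for (id in names(decoy_prot)) {
      loc <- locus[[id]]
      pub_model(paste0(id, "_", sp), loc["start"], loc["end"],
                decoy_prot[[id]])
    }
    annotations[[sp]] <- if (length(ann)) validate_models(do.call(rbind, ann))
                         else gene_models()
    proteomes[[sp]] <- Biostrings::AAStringSet(unlist(prot))

    # predicted models (the surrogate for external protein-to-genome
    # aligners): one faithful model per seed at the true locus, except
    # where the locus evades the aligners entirely (model_absent)
    if (sp != "REF") {
      pred <- list(); pprot <- character()
      for (g in present) {
        if (modes[g, sp] == "model_absent") next
        loc <- locus[[g]]
        id <- paste0(g, "_", sp, ".pred")
        pred[[length(pred) + 1L]] <- data.frame(
          model_id = id, seqid = ctg, strand = "+",
          start = as.integer(loc["start"]), end = as.integer(loc["end"]),
          seed = g, stringsAsFactors = FALSE)
        pprot[[id]] <- leaf_protein[g, sp]
      }
      predicted_models[[sp]] <- if (length(pred))
        validate_models(do.call(rbind, pred)) else gene_models()
      predicted_proteomes[[sp]] <- Biostrings::AAStringSet(unlist(pprot))
    } else {
      predicted_models[[sp]] <- gene_models()
      predicted_proteomes[[sp]] <- Biostrings::AAStringSet()
    }

    # reads: uniform protein-space intervals at mean depth read_depth
    rl <- config$read_length
    rows <- list()
    for (g in present) {
      L <- nchar(leaf_protein[g, sp])
      n <- rpois(1, config$read_depth * L / rl)
      if (n == 0L) next
      st <- sample.int(max(1L, L - rl + 1L), n, replace = TRUE)
      en <- pmin(st + rl - 1L, L)
      rows[[g]] <- data.frame(
        query_id = sprintf("rd_%s_%s_%04d", g, sp, seq_len(n)),
        subject_id = g, identity = 0.95, aln_len = en - st + 1L,
        mismatch = 0L, gap_open = 0L,
        q_start = 1L, q_end = en - st + 1L, s_start = st, s_end = en,
        evalue = 1e-20, bitscore = 2 * rl, stringsAsFactors = FALSE)
    }
    reads[[sp]] <- if (length(rows)) do.call(rbind, rows) else empty_hits()
    rownames(reads[[sp]]) <- NULL
  }

  tiers_df <- data.frame(gene = rep(genes, ntip),
                         species = rep(species, each = config$n_genes),
                         mode = as.vector(modes), stringsAsFactors = FALSE)
  tiers_df <- tiers_df[!is.na(tiers_df$mode), , drop = FALSE]
  rownames(tiers_df) <- NULL

  structure(list(config = config, tree = tree, species = species,
                 seeds = Biostrings::AAStringSet(seeds),
                 genomes = genomes, annotations = annotations,
                 proteomes = proteomes,
                 predicted_models = predicted_models,
                 predicted_proteomes = predicted_proteomes,
                 reads = reads,
                 truth_matrix = truth_matrix, truth_tiers = tiers_df,
                 truth_losses = truth_losses, truth_dups = truth_dups),
            class = "truth_set")
}

#' Write a truth set as an input bundle in standard formats
#'
#' Layout: `tree.nwk`, `seeds.faa`, one directory per species with
#' `genome.fna`, `published.faa`, `published.gff3`, `predicted.faa`,
#' `predicted.gff3` (predicted files only when non-empty) and
#' `reads.tsv`, plus the planted truth under `truth/`.
#'
#' @param ts A `"truth_set"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth_set <- function(ts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(ts$tree, file.path(dir, "tree.nwk"))
  write_fasta(ts$seeds, file.path(dir, "seeds.faa"))
  for (sp in ts$species) {
    d <- file.path(dir, "species", sp)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(ts$genomes[[sp]]),
      file.path(d, "genome.fna"), width = 70L)
    write_fasta(ts$proteomes[[sp]], file.path(d, "published.faa"))
    write_gff3(ts$annotations[[sp]], file.path(d, "published.gff3"),
               source = "published")
    if (length(ts$predicted_proteomes[[sp]])) {
      write_fasta(ts$predicted_proteomes[[sp]], file.path(d, "predicted.faa"))
      write_gff3(ts$predicted_models[[sp]], file.path(d, "predicted.gff3"),
                 source = "predicted")
    }
    write_hit_table(ts$reads[[sp]], file.path(d, "reads.tsv"))
  }
  td <- file.path(dir, "truth")
  dir.create(td, showWarnings = FALSE)
  tm <- data.frame(gene = rownames(ts$truth_matrix), ts$truth_matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(tm, file.path(td, "matrix.tsv"))
  write_tsv(ts$truth_tiers, file.path(td, "tiers.tsv"))
  loss <- data.frame(
    gene = names(ts$truth_losses),
    loss_edges = vapply(ts$truth_losses, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  write_tsv(loss, file.path(td, "losses.tsv"))
  write_tsv(ts$truth_dups, file.path(td, "dups.tsv"))
  invisible(dir)
}

#' Score pipeline output against the planted truth
#'
#' @param truth A `"truth_set"`.
#' @param matrix Tier matrix from [build_matrix()] over the same genes
#'   and species.
#' @param gainloss `data.frame` from the Dollo stage with `gene` and
#'   comma-joined `loss_edges`.
#' @param assigned_modes Optional `data.frame` (`gene`, `species`,
#'   `mode`) of pipeline-assigned corruption modes, for the
#'   tier-confusion report.
#' @return A `"recovery_report"` list: `cell_accuracy` (presence/absence
#'   cells), `mode_agreement` and `confusion` (planted vs assigned mode
#'   on corrupted cells), and micro-averaged `loss_precision` /
#'   `loss_recall` over planted loss branches.
#' @export
score_recovery <- function(truth, matrix, gainloss, assigned_modes = NULL) {
  tm <- truth$truth_matrix
  if (!setequal(rownames(tm), rownames(matrix)) ||
      !setequal(colnames(tm), colnames(matrix)))
    stop_validation("gene/species universes of truth and result differ")
  matrix <- matrix[rownames(tm), colnames(tm), drop = FALSE]
  present <- matrix != "absent"
  cell_accuracy <- mean(present == (tm == 1L))

  mode_agreement <- NA_real_; confusion <- NULL
  if (!is.null(assigned_modes)) {
    planted <- truth$truth_tiers
    planted <- planted[planted$species != "REF" & planted$mode != "intact", ,
                       drop = FALSE]
    key <- paste(assigned_modes$gene, assigned_modes$species)
    got <- assigned_modes$mode[match(paste(planted$gene, planted$species), key)]
    got[is.na(got)] <- "absent"
    mode_agreement <- mean(got == planted$mode)
    confusion <- table(planted = planted$mode, assigned = got)
  }

  truth_edges <- unlist(lapply(names(truth$truth_losses), function(g)
    if (length(truth$truth_losses[[g]]))
      paste(g, truth$truth_losses[[g]]) else character()))
  found_edges <- unlist(lapply(seq_len(nrow(gainloss)), function(i) {
    le <- gainloss$loss_edges[i]
    if (is.na(le) || !nzchar(le)) return(character())
    paste(gainloss$gene[i], strsplit(le, ",", fixed = TRUE)[[1]])
  }))
  tp <- length(intersect(truth_edges, found_edges))
  loss_precision <- if (length(found_edges)) tp / length(found_edges) else 1
  loss_recall <- if (length(truth_edges)) tp / length(truth_edges) else 1

  structure(list(cell_accuracy = cell_accuracy,
                 mode_agreement = mode_agreement, confusion = confusion,
                 loss_precision = loss_precision,
                 loss_recall = loss_recall,
                 n_cells = length(tm)),
            class = "recovery_report")
}
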