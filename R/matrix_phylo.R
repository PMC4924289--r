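# Best-evidence presence/absence matrix assembly, Dollo parsimony
# gain/loss reconstruction on the species tree, and collapsing of
# poorly supported branches.

# -- tree helpers --------------------------------------------------------

node_children <- function(tree) {
  split(tree$edge[, 2], factor(tree$edge[, 1],
                               levels = seq_len(ape::Ntip(tree) + tree$Nnode)))
}

# character name for a node: tip label, internal label, or "nd<i>"
node_name <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  vapply(node, function(i) {
    if (i <= ntip) return(tree$tip.label[i])
    lab <- if (!is.null(tree$node.label)) tree$node.label[i - ntip] else ""
    if (!is.na(lab) && nzchar(lab)) lab else paste0("nd", i)
  }, character(1))
}

# tip indices under every node (list indexed by node number)
node_tipsets <- function(tree) {
  ntip <- ape::Ntip(tree)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(ed)))
    sets[[ed[k, 1]]] <- c(sets[[ed[k, 1]]], sets[[ed[k, 2]]])
  lapply(sets, sort)
}

# -- evidence matrix -----------------------------------------------------

#' Assemble the best-evidence presence/absence matrix
#'
#' Each (gene, species) cell records the best case over three evidence
#' streams, under the order `published_ok > minor_refinement >
#' major_refinement > novel > read_only > absent`: a positive FRB call
#' contributes `published_ok` (the published model matched as-is), a
#' refinement record contributes its tier, and a supported read verdict
#' contributes `read_only`.
#'
#' @param calls `data.frame` with `seed_gene`, `species`, `positive`
#'   (FRB stream).
#' @param tiers `data.frame` with `seed_gene`, `species`, `tier`
#'   (refinement stream).
#' @param verdicts `data.frame` with `seed_gene`, `species`,
#'   `supported` (logical; read stream).
#' @param genes,species Row/column orders; default to the order of
#'   first appearance across the streams.
#' @return Character matrix of tier codes, genes as rows and species as
#'   columns.
#' @export
build_matrix <- function(calls, tiers, verdicts, genes = NULL,
                         species = NULL) {
  streams <- list(calls = calls, tiers = tiers, verdicts = verdicts)
  for (nm in names(streams)) {
    s <- streams[[nm]]
    if (nrow(s) && anyDuplicated(paste(s$seed_gene, s$species)))
      stop_validation("duplicate (gene, species) keys in the ", nm, " stream")
  }
  if (is.null(genes))
    genes <- unique(c(calls$seed_gene, tiers$seed_gene, verdicts$seed_gene))
  if (is.null(species))
    species <- unique(c(calls$species, tiers$species, verdicts$species))
  m <- matrix("absent", nrow = length(genes), ncol = length(species),
              dimnames = list(genes, species))
  bump <- function(g, s, tier) {
    keep <- g %in% genes & s %in% species
    g <- g[keep]; s <- s[keep]; tier <- tier[keep]
    idx <- cbind(match(g, genes), match(s, species))
    better <- tier_rank(tier) > tier_rank(m[idx])
    if (any(better)) m[idx[better, , drop = FALSE]] <<- tier[better]
  }
  if (nrow(calls))
    bump(calls$seed_gene[calls$positive], calls$species[calls$positive],
         rep("published_ok", sum(calls$positive)))
  if (nrow(tiers))
    bump(tiers$seed_gene, tiers$species, tiers$tier)
  if (nrow(verdicts)) {
    sup <- verdicts$supported
    bump(verdicts$seed_gene[sup], verdicts$species[sup],
         rep("read_only", sum(sup)))
  }
  m
}

#' Summarise an evidence matrix per species group
#'
#' @param matrix Tier matrix from [build_matrix()].
#' @param groups Named character vector mapping species (columns) to
#'   group labels; default puts every species in one group `"all"`.
#' @return `data.frame` with, per group: cell counts for each tier,
#'   `n_present`, `frb_fraction` (present cells at `published_ok`) and
#'   `genome_dependent_fraction` (present cells below `published_ok`,
#'   i.e. evidence that required genome-level search or read mapping).
#' @export
summarize_matrix <- function(matrix, groups = NULL) {
  sp <- colnames(matrix)
  if (is.null(groups)) groups <- setNames(rep("all", length(sp)), sp)
  if (!all(sp %in% names(groups)))
    stop_validation("groups must cover every species column")
  out <- lapply(unique(groups[sp]), function(g) {
    sub <- matrix[, sp[groups[sp] == g], drop = FALSE]
    counts <- vapply(.TIERS, function(t) sum(sub == t), integer(1))
    present <- sum(sub != "absent")
    d <- data.frame(group = g, n_cells = length(sub), t(counts),
                    n_present = present,
                    frb_fraction = if (present) counts[["published_ok"]] / present
                                   else NA_real_,
                    genome_dependent_fraction =
                      if (present) 1 - counts[["published_ok"]] / present
                      else NA_real_,
                    stringsAsFactors = FALSE, check.names = FALSE)
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# -- Dollo gain/loss -----------------------------------------------------

#' Dollo parsimony gain/loss reconstruction for one gene
#'
#' The gene is gained exactly once, at the most recent common ancestor
#' of the species in which it is present; losses are the maximal
#' all-absent subtrees below that node, one loss edge each.  The loss
#' count is minimal under the single-gain constraint.
#'
#' @param presence Logical (or 0/1) vector named by tip labels.
#' @param tree Rooted `"phylo"` species tree (polytomies allowed).
#' @return A list with `gain_node` (node name, `NA` when the gene is
#'   present nowhere), `loss_edges` (names of the child nodes of the
#'   loss edges), `loss_clades` (list of tip-label sets under each loss
#'   edge) and `n_losses`.
#' @export
dollo_reconstruct <- function(presence, tree) {
  tips <- tree$tip.label
  if (!all(tips %in% names(presence)))
    stop_validation("presence vector must be named by every tip label")
  pres <- as.logical(presence[tips])
  if (anyNA(pres)) stop_validation("presence contains missing values")
  ntip <- ape::Ntip(tree)
  if (!any(pres))
    return(list(gain_node = NA_character_, loss_edges = character(),
                loss_clades = list(), n_losses = 0L))
  pidx <- which(pres)
  gain <- if (length(pidx) == 1L) pidx else ape::getMRCA(tree, pidx)
  kids <- node_children(tree)
  sets <- node_tipsets(tree)
  losses <- integer()
  walk <- function(nd) {
    for (ch in kids[[nd]] %||% integer()) {
      if (any(pres[sets[[ch]]])) {
        if (ch > ntip) walk(ch)
      } else {
        losses <<- c(losses, ch)
      }
    }
  }
  if (gain > ntip) walk(gain)
  list(gain_node = node_name(tree, gain),
       loss_edges = node_name(tree, losses),
       loss_clades = lapply(losses, function(nd) tips[sets[[nd]]]),
       n_losses = length(losses))
}

#' Forward-simulate a single gain plus losses down a tree
#'
#' The inverse of [dollo_reconstruct()]: plant the gain at `gain_node`,
#' apply each loss edge, and read the leaf presence pattern.
#'
#' @param tree Rooted `"phylo"` tree.
#' @param gain_node Node name of the gain (see `node` naming of
#'   [dollo_reconstruct()]); `NA` gives all-absent.
#' @param loss_edges Character vector of child-node names of loss
#'   edges.
#' @return Logical presence vector named by tip label.
#' @export
simulate_dollo <- function(tree, gain_node, loss_edges = character()) {
  ntip <- ape::Ntip(tree)
  all_names <- node_name(tree, seq_len(ntip + tree$Nnode))
  pres <- setNames(rep(FALSE, ntip), tree$tip.label)
  if (is.na(gain_node)) return(pres)
  sets <- node_tipsets(tree)
  g <- match(gain_node, all_names)
  if (is.na(g)) stop_validation("unknown gain node: ", gain_node)
  pres[sets[[g]]] <- TRUE
  for (le in loss_edges) {
    i <- match(le, all_names)
    if (is.na(i)) stop_validation("unknown loss edge child: ", le)
    pres[sets[[i]]] <- FALSE
  }
  pres
}

# -- support collapse ----------------------------------------------------

#' Collapse poorly supported internal branches into polytomies
#'
#' Every internal edge whose support is below `threshold` is
#' contracted, promoting its children to the parent; edges with support
#' at or above the threshold, or with no support value, are retained.
#' Child branch lengths absorb the contracted edge's length so
#' root-to-tip distances are preserved.
#'
#' @param tree A `"phylo"` tree with support in the internal node
#'   labels (see [tree_support()]; 0-1 scaled input is auto-detected
#'   and rescaled).
#' @param threshold Support threshold on the 0-100 scale.
#' @return The collapsed `"phylo"` tree (leaf set unchanged).
#' @export
collapse_low_support <- function(tree, threshold) {
  if (threshold < 0 || threshold > 100)
    stop_validation("threshold must be in [0, 100]")
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  sup <- tree_support(tree)
  drop <- which(!is.na(sup) & sup < threshold) + ntip
  drop <- setdiff(drop, root)
  if (length(drop) == 0L) return(tree)
  kids <- node_children(tree)
  elen <- function(child) {
    if (is.null(tree$edge.length)) return(NULL)
    tree$edge.length[match(child, tree$edge[, 2])]
  }
  has_len <- !is.null(tree$edge.length)
  nwk <- function(nd, extra) {
    if (nd <= ntip) {
      s <- tree$tip.label[nd]
      if (has_len) s <- paste0(s, ":", format(elen(nd) + extra, digits = 12))
      return(s)
    }
    parts <- unlist(lapply(kids[[nd]], function(ch) {
      if (ch %in% drop) nwk_children(ch, if (has_len) elen(ch) else 0)
      else nwk(ch, 0)
    }))
    s <- paste0("(", paste(parts, collapse = ","), ")")
    lab <- if (!is.null(tree$node.label)) tree$node.label[nd - ntip] else ""
    if (!is.na(lab) && nzchar(lab)) s <- paste0(s, lab)
    if (has_len && nd != root)
      s <- paste0(s, ":", format(elen(nd) + extra, digits = 12))
    s
  }
  # children of a collapsed node are spliced into the grandparent,
  # inheriting the contracted edge length (chains of collapsed nodes
  # accumulate)
  nwk_children <- function(nd, extra) {
    unlist(lapply(kids[[nd]], function(ch) {
      if (ch %in% drop) nwk_children(ch, extra + (if (has_len) elen(ch) else 0))
      else nwk(ch, extra)
    }))
  }
  out <- ape::read.tree(text = paste0(nwk(root, 0), ";"))
  out
}
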