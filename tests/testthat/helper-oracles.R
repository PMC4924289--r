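# Independent oracles used by the property-style tests.  These are
# deliberately naive re-derivations (enumeration, per-base counting,
# bitmask search) kept separate from the implementation code paths.

# optimal local alignment score by exhaustive enumeration of monotone
# residue matchings; with affine gaps a run of length d costs
# gap_open + gap_ext * d per sequence, so the internal gap cost is
# separable between the two sequences
bf_local_score <- function(a, b, submat, gap_open = 11, gap_ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  la <- length(A); lb <- length(B)
  gapcost <- function(idx) {
    if (nrow(idx) < 2L) return(numeric(ncol(idx)))
    d <- idx[-1, , drop = FALSE] - idx[-nrow(idx), , drop = FALSE] - 1L
    colSums((d > 0) * (gap_open + gap_ext * d))
  }
  best <- 0
  for (k in seq_len(min(la, lb))) {
    ia <- combn(la, k); ib <- combn(lb, k)
    ga <- gapcost(ia); gb <- gapcost(ib)
    S <- matrix(0, ncol(ia), ncol(ib))
    for (p in seq_len(k))
      S <- S + submat[A[ia[p, ]], B[ib[p, ]], drop = FALSE]
    best <- max(best, max(S - outer(ga, gb, "+")))
  }
  best
}

# literal evaluation of the fuzzy reciprocal membership definition by
# plain loops over every (seed, subject) pair
bf_frb_members <- function(seed, forward, reverse, f) {
  fw <- forward[forward$query_id == seed, , drop = FALSE]
  if (nrow(fw) == 0L) return(character())
  members <- character()
  fmax <- max(fw$bitscore)
  for (i in seq_len(nrow(fw))) {
    s <- fw$subject_id[i]
    if (fw$bitscore[i] < f * fmax) next
    rv <- reverse[reverse$query_id == s, , drop = FALSE]
    if (nrow(rv) == 0L) next
    rmax <- max(rv$bitscore)
    ok <- any(rv$subject_id == seed & rv$bitscore >= f * rmax)
    if (ok) members <- c(members, s)
  }
  sort(unique(members))
}

# shared bases by per-base membership counting
oracle_overlap <- function(a, b) {
  if (a$seqid[1] != b$seqid[1] || a$strand[1] != b$strand[1]) return(0L)
  span <- max(c(a$end, b$end))
  ina <- logical(span); inb <- logical(span)
  for (i in seq_len(nrow(a))) ina[(a$start[i] + 1L):a$end[i]] <- TRUE
  for (i in seq_len(nrow(b))) inb[(b$start[i] + 1L):b$end[i]] <- TRUE
  sum(ina & inb)
}

# per-position depth counting
oracle_pileup <- function(hits, L) {
  depth <- integer(L)
  for (i in seq_len(nrow(hits)))
    for (p in hits$s_start[i]:hits$s_end[i]) depth[p] <- depth[p] + 1L
  depth
}

# --- Dollo oracle: exhaustive minimisation over every single-gain /
# any-loss-edge assignment, via leaf bitmasks ---------------------------

dollo_oracle <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- i
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(ed)))
    sets[[ed[k, 1]]] <- c(sets[[ed[k, 1]]], sets[[ed[k, 2]]])
  bits <- vapply(sets, function(s) sum(bitwShiftL(1L, s - 1L)), integer(1))
  edge_nodes <- setdiff(seq_len(nn), root)
  ne <- length(edge_nodes)
  nsub <- bitwShiftL(1L, ne)
  un <- integer(nsub); pc <- integer(nsub)
  for (s in seq_len(nsub - 1L)) {
    low <- bitwAnd(s, -s)
    j <- which(bitwAnd(s, bitwShiftL(1L, seq_len(ne) - 1L)) == low &
                 bitwShiftL(1L, seq_len(ne) - 1L) == low)[1]
    rest <- bitwAnd(s, s - 1L)
    un[s + 1L] <- bitwOr(un[rest + 1L], bits[edge_nodes[j]])
    pc[s + 1L] <- pc[rest + 1L] + 1L
  }
  full <- bitwShiftL(1L, ntip) - 1L
  function(target) {  # target: leaf bitmask, nonzero
    best <- Inf
    for (g in seq_len(nn)) {
      bg <- bits[g]
      if (bitwAnd(bg, target) != target) next
      res <- bitwAnd(bg, bitwAnd(bitwNot(un), full))
      hit <- which(res == target)
      if (length(hit)) best <- min(best, min(pc[hit]))
    }
    best
  }
}

leaf_bitmask <- function(tree, present_tips) {
  sum(bitwShiftL(1L, match(present_tips, tree$tip.label) - 1L))
}

# all rooted binary tree shapes with n leaves, as newick strings with
# placeholder leaves "x"
all_binary_shapes <- local({
  memo <- list("1" = "x")
  function(n) {
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- character()
    for (a in seq_len(n %/% 2)) {
      s1 <- all_binary_shapes(a); s2 <- all_binary_shapes(n - a)
      for (i in seq_along(s1)) {
        jj <- if (a == n - a) seq(i, length(s2)) else seq_along(s2)
        for (j in jj) out <- c(out, paste0("(", s1[i], ",", s2[j], ")"))
      }
    }
    memo[[key]] <<- out
    out
  }
})

# instantiate a shape string with tip labels L1..Ln and read as phylo
shape_to_tree <- function(shape) {
  n <- lengths(regmatches(shape, gregexpr("x", shape)))
  for (i in seq_len(n)) shape <- sub("x", paste0("L", i), shape, fixed = TRUE)
  ape::read.tree(text = paste0(shape, ";"))
}

# rooted clade sets (tip-label signature per internal non-root node),
# with the support value carried by each clade
tree_clades <- function(tree) {
  ntip <- ape::Ntip(tree)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(ed)))
    sets[[ed[k, 1]]] <- c(sets[[ed[k, 1]]], sets[[ed[k, 2]]])
  internal <- setdiff(unique(ed[, 1]), ntip + 1L)
  sup <- frbpipe::tree_support(tree)
  data.frame(
    clade = vapply(internal, function(nd)
      paste(sort(tree$tip.label[sets[[nd]]]), collapse = "|"), character(1)),
    support = sup[internal - ntip],
    stringsAsFactors = FALSE)
}

# random support-annotated tree: supports 0-100, some absent
random_support_tree <- function(n, p_missing = 0.2) {
  tr <- ape::rtree(n)
  lab <- as.character(sample(0:100, tr$Nnode, replace = TRUE))
  lab[runif(tr$Nnode) < p_missing] <- ""
  lab[1] <- ""  # root
  tr$node.label <- lab
  tr
}

# random hit tables over small seed/subject universes
random_hit_pair <- function(n_seeds, n_subjects, density = 0.7) {
  seeds <- paste0("s", seq_len(n_seeds))
  subj <- paste0("t", seq_len(n_subjects))
  mk <- function(qs, ss) {
    rows <- expand.grid(query_id = qs, subject_id = ss,
                        stringsAsFactors = FALSE)
    rows <- rows[runif(nrow(rows)) < density, , drop = FALSE]
    n <- nrow(rows)
    cbind(rows,
          data.frame(identity = round(runif(n, 0.2, 1), 2),
                     aln_len = sample(20:200, n, TRUE),
                     mismatch = rep(0L, n), gap_open = rep(0L, n),
                     q_start = rep(1L, n), q_end = rep(50L, n),
                     s_start = rep(1L, n), s_end = rep(50L, n),
                     evalue = rep(1e-10, n),
                     bitscore = round(runif(n, 30, 200), 1)))
  }
  list(forward = mk(seeds, subj), reverse = mk(subj, seeds),
       seeds = seeds, subjects = subj)
}

random_protein_seq <- function(len, alphabet = c("A", "C", "D", "W")) {
  paste(sample(alphabet, len, TRUE), collapse = "")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})
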