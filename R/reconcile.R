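# Reconciliation of newly predicted gene models against published
# annotations.  A new model overlapping exactly one published model is
# graded by the gain in seed-protein alignment coverage (additive
# percentage points): +5 points is a minor refinement, +15 a major one.
# Overlapping two or more published models flags the locus as split
# across the published annotation; a published model overlapped by two
# or more predictions flags it as a merged (fused) model.

#' Fraction of the seed protein covered by an alignment
#'
#' @param aln A `"local_alignment"` (query = seed) or a list/row with
#'   `q_start` and `q_end`.
#' @param seed_length Seed protein length in residues.
#' @return `(q_end - q_start + 1) / seed_length`, clamped to \[0, 1\];
#'   0 for an empty alignment.
#' @export
alignment_coverage <- function(aln, seed_length) {
  if (seed_length < 1) stop_validation("seed_length must be >= 1")
  qs <- aln$q_start; qe <- aln$q_end
  if (is.null(qs) || length(qs) == 0L || is.na(qs)) return(0)
  if (qs < 1 || qe > seed_length || qs > qe)
    stop_validation("alignment interval [", qs, ", ", qe,
                    "] outside the seed [1, ", seed_length, "]")
  min(1, (qe - qs + 1) / seed_length)
}

model_ranges <- function(model) {
  IRanges::IRanges(start = model$start + 1L, end = model$end)
}

#' Shared genomic bases between two gene models
#'
#' @param a,b Gene-model `data.frame`s (exon rows) for one model each.
#' @return Total length of the exon-interval intersection; 0 when the
#'   models sit on different contigs or strands.
#' @export
genomic_overlap <- function(a, b) {
  a <- validate_models(a); b <- validate_models(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  if (length(unique(a$model_id)) != 1L || length(unique(b$model_id)) != 1L)
    stop_validation("genomic_overlap compares exactly one model per side")
  if (a$seqid[1] != b$seqid[1] || a$strand[1] != b$strand[1]) return(0L)
  sum(IRanges::width(IRanges::intersect(model_ranges(a), model_ranges(b))))
}

#' Grade a predicted gene model against the published annotation
#'
#' @param new_model Exon rows of the predicted model.
#' @param new_coverage Seed-protein alignment coverage of the predicted
#'   model (fraction).
#' @param published Gene-model `data.frame` of all published models on
#'   the relevant contigs (possibly zero rows).
#' @param published_coverage Named numeric vector: seed-protein
#'   alignment coverage of each published model (missing ids count as
#'   0).
#' @param min_shared Minimum shared bases for a genomic overlap call
#'   (default 30 bp, about ten residues).
#' @param minor_delta,major_delta Additive coverage-gain thresholds
#'   (defaults 0.05 and 0.15, both inclusive).
#' @param overlap_bases Optional pre-computed named vector of shared
#'   bases between `new_model` and each published model (ids absent
#'   from it count as non-overlapping); when `NULL` overlaps are
#'   computed with [genomic_overlap()].
#' @return A list with `tier` (`published_ok`, `minor_refinement`,
#'   `major_refinement` or `novel`), `overlap_class` (`one_to_one`,
#'   `split`, `none`), `delta` (coverage gain over the overlapped
#'   published model, `NA` otherwise) and `overlapping` (published model
#'   ids).
#' @export
classify_refinement <- function(new_model, new_coverage, published,
                                published_coverage = numeric(),
                                min_shared = 30L,
                                minor_delta = 0.05, major_delta = 0.15,
                                overlap_bases = NULL) {
  if (is.na(new_coverage) || new_coverage < 0)
    stop_validation("new-model coverage must be a non-negative fraction")
  if (min_shared < 1) stop_validation("min_shared must be >= 1")
  published <- validate_models(published)
  pub_ids <- unique(published$model_id)
  if (length(pub_ids) == 0L)
    return(list(tier = "novel", overlap_class = "none", delta = NA_real_,
                overlapping = character()))
  if (is.null(overlap_bases)) {
    ov <- vapply(pub_ids, function(id)
      genomic_overlap(new_model, published[published$model_id == id, ,
                                           drop = FALSE]), numeric(1))
  } else {
    ov <- overlap_bases[pub_ids]
    ov[is.na(ov)] <- 0
  }
  overlapping <- pub_ids[ov >= min_shared]
  if (length(overlapping) == 0L)
    return(list(tier = "major_refinement", overlap_class = "none",
                delta = NA_real_, overlapping = character()))
  if (length(overlapping) >= 2L)
    return(list(tier = "major_refinement", overlap_class = "split",
                delta = NA_real_, overlapping = overlapping))
  pc <- unname(published_coverage[overlapping])
  if (is.na(pc)) pc <- 0
  if (pc < 0) stop_validation("published coverage must be non-negative")
  delta <- new_coverage - pc
  # thresholds are inclusive; the epsilon guards against floating-point
  # representation of coverage differences (e.g. 0.45 - 0.40)
  eps <- 1e-9
  tier <- if (delta >= major_delta - eps) "major_refinement"
          else if (delta >= minor_delta - eps) "minor_refinement"
          else "published_ok"
  list(tier = tier, overlap_class = "one_to_one", delta = delta,
       overlapping = overlapping)
}

#' Detect a published model that fuses several true genes
#'
#' @param published Exon rows of one published model.
#' @param new_models Gene-model `data.frame` of predicted models
#'   (several model ids allowed).
#' @param min_shared Minimum shared bases per overlap (default 30 bp).
#' @return `"merged"` when two or more distinct predicted models each
#'   share at least `min_shared` bases with the published model;
#'   `"one_to_one"` for exactly one; `"none"` for zero.
#' @export
detect_merged <- function(published, new_models, min_shared = 30L) {
  if (min_shared < 1) stop_validation("min_shared must be >= 1")
  new_models <- validate_models(new_models)
  ids <- unique(new_models$model_id)
  n <- sum(vapply(ids, function(id)
    genomic_overlap(published, new_models[new_models$model_id == id, ,
                                          drop = FALSE]) >= min_shared,
    logical(1)))
  if (n >= 2L) "merged" else if (n == 1L) "one_to_one" else "none"
}
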