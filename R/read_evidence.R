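# Rescue of genes missing from assemblies/annotations via read-to-
# protein alignment depth.  Reads enter as 12-column tabular alignments
# against the seed protein (frame/translation handled upstream); a
# candidate profile is "supported" when its coverage clears a floor and
# its median depth sits within depth_k robust deviations of the median
# depth over confirmed homologues of the same species.

#' Per-residue read depth over a seed protein
#'
#' @param read_hits Hit table of read-vs-seed-protein alignments; the
#'   subject interval of each row is the covered stretch of the seed.
#' @param seed_length Seed protein length (residues).
#' @param seed_gene,species Tokens carried into the profile.
#' @return A `"depth_profile"` list: integer `depth` of length
#'   `seed_length`, `coverage` (fraction of positions with depth >= 1)
#'   and `median_depth` (median over all positions).
#' @export
pileup <- function(read_hits, seed_length, seed_gene = NA_character_,
                   species = NA_character_) {
  if (seed_length < 1) stop_validation("seed_length must be >= 1")
  if (nrow(read_hits)) {
    if (any(read_hits$s_start < 1 | read_hits$s_end > seed_length))
      stop_validation("read alignment interval outside [1, ", seed_length, "]")
    cov <- IRanges::coverage(
      IRanges::IRanges(read_hits$s_start, read_hits$s_end),
      width = seed_length)
    depth <- as.integer(cov)
  } else {
    depth <- integer(seed_length)
  }
  structure(list(seed_gene = seed_gene, species = species, depth = depth,
                 coverage = mean(depth >= 1L),
                 median_depth = median(depth)),
            class = "depth_profile")
}

#' Test a depth profile for consistency with confirmed homologues
#'
#' Supported iff `coverage >= min_coverage` and the candidate's median
#' depth lies within `depth_k` scaled median absolute deviations (MAD,
#' floored at 1) of the median of the reference median depths.
#'
#' @param candidate A `"depth_profile"` for the gene under test.
#' @param reference List of `"depth_profile"`s for confirmed homologues
#'   of the same species; must be non-empty (an empty reference is a
#'   configuration error: fall back to a coverage-only rule instead).
#' @param min_coverage Coverage floor (default 0.8).
#' @param depth_k Width of the depth acceptance band in MADs (default 3).
#' @return A list with `verdict` (`"supported"`/`"unsupported"`), `z`
#'   (robust z-like statistic of the candidate median depth),
#'   `ref_median` and `ref_mad`.
#' @export
consistency_test <- function(candidate, reference, min_coverage = 0.8,
                             depth_k = 3) {
  check_fraction(min_coverage, "min_coverage")
  if (length(reference) == 0L)
    stop_config("empty reference set: no confirmed homologues available; ",
                "fall back to the coverage-only rule ",
                "(coverage >= min_coverage)")
  ref_medians <- vapply(reference, function(p) p$median_depth, numeric(1))
  ref_median <- median(ref_medians)
  ref_mad <- max(1, mad(ref_medians))
  z <- (candidate$median_depth - ref_median) / ref_mad
  ok <- candidate$coverage >= min_coverage && abs(z) <= depth_k
  list(verdict = if (ok) "supported" else "unsupported",
       z = z, ref_median = ref_median, ref_mad = ref_mad)
}
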