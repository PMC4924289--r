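# Fuzzy reciprocal best-hit (FRB) homology assignment.  Classical
# reciprocal best hit is relaxed so that every subject scoring within a
# factor f of the best bitscore qualifies, in both search directions;
# two or more members in one species flag a recent duplication
# (co-orthologues).

#' FRB configuration
#'
#' @param f Fuzz factor in (0, 1]: a subject is in the fuzzy best-hit
#'   set when its bitscore is at least `f` times the best bitscore for
#'   that query.  `f = 1` with unique maxima reduces FRB to strict
#'   reciprocal best hit.  Default 0.9.
#' @param max_evalue Hit-admission E-value ceiling (default 1e-5).
#' @param min_query_coverage Hit-admission floor on the fraction of the
#'   query covered by the alignment (default 0.3).  Both admission
#'   filters are deliberately permissive: final judgement about model
#'   quality is deferred to the refinement tiers.
#' @return A `"fuzzy_config"` list.
#' @export
fuzzy_config <- function(f = 0.9, max_evalue = 1e-5,
                         min_query_coverage = 0.3) {
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    stop_validation("fuzz factor f must be in (0, 1]")
  if (max_evalue < 0) stop_validation("max_evalue must be non-negative")
  check_fraction(min_query_coverage, "min_query_coverage")
  structure(list(f = f, max_evalue = max_evalue,
                 min_query_coverage = min_query_coverage),
            class = "fuzzy_config")
}

#' Fuzzy best-hit set for one query
#'
#' @param hits Hit table rows that all share one `query_id`.
#' @param f Fuzz factor in (0, 1].
#' @return Character vector of subject ids with
#'   `bitscore >= f * max(bitscore)`; empty input gives an empty set.
#' @export
fuzzy_set <- function(hits, f) {
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    stop_validation("fuzz factor f must be in (0, 1]")
  if (nrow(hits) == 0L) return(character())
  if (length(unique(hits$query_id)) > 1L)
    stop_validation("fuzzy_set expects hits for a single query, got: ",
                    paste(unique(hits$query_id), collapse = ", "))
  unique(hits$subject_id[hits$bitscore >= f * max(hits$bitscore)])
}

#' Filter hits by E-value and query coverage
#'
#' @param hits A hit table.
#' @param config A [fuzzy_config()].
#' @param query_lengths Named integer vector of query protein lengths
#'   (residues), used for the coverage filter; queries missing from it
#'   are an error.
#' @return The admitted subset of `hits`.
#' @export
filter_hits <- function(hits, config, query_lengths) {
  if (nrow(hits) == 0L) return(hits)
  qlen <- query_lengths[hits$query_id]
  if (anyNA(qlen))
    stop_validation("query length missing for: ",
                    paste(unique(hits$query_id[is.na(qlen)]), collapse = ", "))
  cov <- (hits$q_end - hits$q_start + 1) / qlen
  hits[hits$evalue <= config$max_evalue &
         cov >= config$min_query_coverage, , drop = FALSE]
}

#' Fuzzy reciprocal best-hit call for one seed
#'
#' A subject `s` is a member iff `s` is in the seed's forward fuzzy
#' best-hit set and the seed is in `s`'s reverse fuzzy best-hit set.
#' Both tables are expected to be pre-filtered (see [filter_hits()]).
#'
#' @param forward Hit table, seed proteins vs the target proteome.
#' @param reverse Hit table, target proteome vs the seed proteome.
#' @param config A [fuzzy_config()].
#' @param seed Seed id; defaults to the single query in `forward`.
#' @param species Species token carried into the call.
#' @return A `"homology_call"` list: `seed_gene`, `species`, `members`
#'   (character), `co_orthologous` (`TRUE` iff two or more members),
#'   `positive`, and per-member `forward_bitscore`/`reverse_bitscore`.
#' @export
fuzzy_reciprocal_best <- function(forward, reverse, config = fuzzy_config(),
                                  seed = NULL, species = NA_character_) {
  if (is.null(seed)) {
    qs <- unique(forward$query_id)
    if (length(qs) != 1L)
      stop_validation("seed not given and forward table has ",
                      length(qs), " distinct queries")
    seed <- qs
  }
  fw <- forward[forward$query_id == seed, , drop = FALSE]
  cand <- fuzzy_set(fw, config$f)
  members <- character()
  for (s in cand) {
    rv <- reverse[reverse$query_id == s, , drop = FALSE]
    if (seed %in% fuzzy_set(rv, config$f)) members <- c(members, s)
  }
  members <- sort(members)
  fsc <- setNames(fw$bitscore[match(members, fw$subject_id)], members)
  rsc <- vapply(members, function(s) {
    rv <- reverse[reverse$query_id == s & reverse$subject_id == seed, ,
                  drop = FALSE]
    if (nrow(rv)) max(rv$bitscore) else NA_real_
  }, numeric(1))
  structure(list(seed_gene = seed, species = species, members = members,
                 co_orthologous = length(members) >= 2L,
                 positive = length(members) >= 1L,
                 forward_bitscore = fsc, reverse_bitscore = rsc),
            class = "homology_call")
}

#' FRB calls for a whole seed set against one species
#'
#' Produces exactly one call per seed.  Hit tables may be supplied
#' (external search output) or computed internally with
#' [search_reciprocal()]; admission filters from `config` are applied
#' to both directions before the reciprocal test.  A seed absent from
#' the forward table yields a negative call with a warning, not an
#' error.
#'
#' @param seeds Named [Biostrings::AAStringSet] of seed proteins.
#' @param proteome Named [Biostrings::AAStringSet] of the species'
#'   (published) proteins.
#' @param config A [fuzzy_config()].
#' @param hits Optional `list(forward = , reverse = )` of pre-computed
#'   hit tables; `NULL` runs the internal aligner.
#' @param species Species token stamped on every call.
#' @param scheme Scoring scheme for the internal aligner.
#' @return A `data.frame` with one row per seed: `seed_gene`,
#'   `species`, `positive`, `co_orthologous`, `n_members`, `members`
#'   (comma-joined), `best_bitscore`.
#' @export
call_species <- function(seeds, proteome, config = fuzzy_config(),
                         hits = NULL, species = NA_character_,
                         scheme = scoring_scheme()) {
  if (length(proteome) == 0L) {
    hits <- list(forward = empty_hits(), reverse = empty_hits())
  } else if (is.null(hits)) {
    hits <- search_reciprocal(seeds, proteome, scheme)
  }
  seed_len <- setNames(Biostrings::nchar(seeds), names(seeds))
  prot_len <- if (length(proteome))
    setNames(Biostrings::nchar(proteome), names(proteome)) else integer()
  fwd <- filter_hits(hits$forward, config, seed_len)
  rev <- filter_hits(hits$reverse, config, prot_len)
  missing <- setdiff(names(seeds), unique(hits$forward$query_id))
  if (length(missing))
    warning("no forward hits for seed(s): ",
            paste(missing, collapse = ", "), " (negative calls)")
  calls <- lapply(names(seeds), function(g)
    fuzzy_reciprocal_best(fwd, rev, config, seed = g, species = species))
  data.frame(
    seed_gene = names(seeds),
    species = species,
    positive = vapply(calls, `[[`, logical(1), "positive"),
    co_orthologous = vapply(calls, `[[`, logical(1), "co_orthologous"),
    n_members = vapply(calls, function(x) length(x$members), integer(1)),
    members = vapply(calls, function(x) paste(x$members, collapse = ","),
                     character(1)),
    best_bitscore = vapply(calls, function(x)
      if (length(x$forward_bitscore)) max(x$forward_bitscore) else NA_real_,
      numeric(1)),
    stringsAsFactors = FALSE)
}
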