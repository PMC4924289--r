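# Local protein alignment front-end.  The affine-gap Smith-Waterman
# dynamic programme itself is delegated to Biostrings::pairwiseAlignment;
# this module fixes the scoring scheme, converts raw scores to bits with
# the Karlin-Altschul constants, and emits 12-column hit records so that
# internal searches are interchangeable with external tabular hit files.

#' Protein alignment scoring scheme
#'
#' BLOSUM62 with affine gaps (open -11, extend -1 per residue) and the
#' standard gapped Karlin-Altschul constants for that parameterisation
#' (lambda = 0.267, K = 0.041), so internal bitscores are commensurate
#' with external protein-search output.
#'
#' @param matrix Symmetric integer substitution matrix (default
#'   BLOSUM62 from Biostrings).
#' @param gap_open,gap_extend Negative integers; a gap of length L costs
#'   `-(gap_open + L * gap_extend)` score units (`gap_open <= gap_extend < 0`).
#' @param lambda,K Karlin-Altschul constants for the bitscore
#'   conversion `bits = (lambda * S - ln K) / ln 2`.
#' @return A `"scoring_scheme"` list.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = -11L,
                           gap_extend = -1L, lambda = 0.267, K = 0.041) {
  if (is.null(matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62
  }
  if (!isSymmetric(unname(matrix)))
    stop_validation("substitution matrix must be symmetric")
  if (!(gap_open <= gap_extend && gap_extend < 0))
    stop_validation("gap penalties must satisfy gap_open <= gap_extend < 0")
  if (lambda <= 0 || K <= 0)
    stop_validation("lambda and K must be positive")
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Convert a raw local-alignment score to bits
#'
#' @param raw_score Raw score(s) in matrix units.
#' @param scheme A [scoring_scheme()].
#' @return Bitscore(s): `(lambda * S - ln K) / ln 2`.
#' @export
bitscore <- function(raw_score, scheme = scoring_scheme()) {
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

check_residues <- function(seq, what) {
  ch <- strsplit(toupper(as.character(seq)), "")[[1]]
  if (length(ch) == 0L) stop_validation(what, ": empty sequence")
  bad <- setdiff(unique(ch), .AA_ALPHABET)
  if (length(bad))
    stop_validation(what, ": residue(s) outside the amino-acid alphabet: ",
                    paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Optimal local alignment of two protein sequences
#'
#' Affine-gap Smith-Waterman via [Biostrings::pairwiseAlignment()]
#' under the given scheme.  When no residue pair scores positively the
#' optimal local alignment is empty: raw score 0 and `NA` intervals.
#'
#' @param query,subject Protein sequences (character or `AAString`).
#' @param scheme A [scoring_scheme()].
#' @param query_id,subject_id Sequence identifiers carried into the
#'   result.
#' @return A `"local_alignment"` list with `raw_score`, `bitscore`,
#'   1-based inclusive `q_start`/`q_end`/`s_start`/`s_end`, `identity`
#'   (fraction of identical aligned columns) and `aln_len`.
#' @export
smith_waterman <- function(query, subject, scheme = scoring_scheme(),
                           query_id = "query", subject_id = "subject") {
  check_residues(query, "query")
  check_residues(subject, "subject")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(as.character(query))),
    Biostrings::AAString(toupper(as.character(subject))),
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = -scheme$gap_open, gapExtension = -scheme$gap_extend)
  s <- Biostrings::score(pa)
  if (s <= 0 || Biostrings::nchar(pa) == 0L) {
    return(structure(list(query_id = query_id, subject_id = subject_id,
                          raw_score = 0, bitscore = bitscore(0, scheme),
                          q_start = NA_integer_, q_end = NA_integer_,
                          s_start = NA_integer_, s_end = NA_integer_,
                          identity = NA_real_, aln_len = 0L),
                     class = "local_alignment"))
  }
  p <- Biostrings::pattern(pa)
  sj <- Biostrings::subject(pa)
  structure(list(
    query_id = query_id, subject_id = subject_id,
    raw_score = s, bitscore = bitscore(s, scheme),
    q_start = Biostrings::start(p), q_end = Biostrings::end(p),
    s_start = Biostrings::start(sj), s_end = Biostrings::end(sj),
    identity = Biostrings::pid(pa) / 100,
    aln_len = Biostrings::nchar(pa)),
    class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("local alignment %s vs %s: raw %g (%.1f bits), q %s-%s, s %s-%s, id %.1f%%\n",
              x$query_id, x$subject_id, x$raw_score, x$bitscore,
              x$q_start, x$q_end, x$s_start, x$s_end, 100 * (x$identity %||% NA)))
  invisible(x)
}

# align one query against a whole proteome in a single vectorised call
align_one_vs_set <- function(query, set, scheme) {
  pa <- Biostrings::pairwiseAlignment(
    set, Biostrings::AAString(as.character(query)),
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = -scheme$gap_open, gapExtension = -scheme$gap_extend)
  # note: 'pattern' here is the set member (the subject of the search),
  # 'subject' is the query protein
  data.frame(
    subject_id = names(set),
    raw = Biostrings::score(pa),
    s_start = Biostrings::start(Biostrings::pattern(pa)),
    s_end = Biostrings::end(Biostrings::pattern(pa)),
    q_start = Biostrings::start(Biostrings::subject(pa)),
    q_end = Biostrings::end(Biostrings::subject(pa)),
    identity = Biostrings::pid(pa) / 100,
    aln_len = Biostrings::nchar(pa),
    stringsAsFactors = FALSE)
}

#' Search query proteins against a proteome
#'
#' Every query is locally aligned against every proteome member; hits at
#' or above `min_bitscore` are reported, sorted per query by descending
#' bitscore then subject id.  E-values use the pairwise Karlin-Altschul
#' search space `K * m * n * exp(-lambda * S)`.
#'
#' @param queries,proteome Named [Biostrings::AAStringSet]s (or named
#'   character vectors).
#' @param scheme A [scoring_scheme()].
#' @param min_bitscore Hits below this bitscore are dropped (default 25
#'   bits, a conventional noise floor for protein searches).
#' @return A hit-table `data.frame` (see [empty_hits()]).
#' @export
search_all <- function(queries, proteome, scheme = scoring_scheme(),
                       min_bitscore = 25) {
  if (is.character(queries)) queries <- Biostrings::AAStringSet(queries)
  if (is.character(proteome)) proteome <- Biostrings::AAStringSet(proteome)
  S4Vectors::mcols(queries) <- NULL
  S4Vectors::mcols(proteome) <- NULL
  if (length(proteome) == 0L) stop_validation("empty proteome")
  if (is.null(names(queries)) || is.null(names(proteome)))
    stop_validation("queries and proteome must be named")
  out <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    d <- align_one_vs_set(queries[[i]], proteome, scheme)
    d$query_id <- names(queries)[i]
    d$bitscore <- bitscore(d$raw, scheme)
    d$evalue <- scheme$K * Biostrings::nchar(queries[[i]]) *
      Biostrings::nchar(proteome) * exp(-scheme$lambda * d$raw)
    d <- d[d$raw > 0 & d$bitscore >= min_bitscore, , drop = FALSE]
    d <- d[order(-d$bitscore, d$subject_id), , drop = FALSE]
    out[[i]] <- d
  }
  d <- do.call(rbind, out)
  if (is.null(d) || nrow(d) == 0L) return(empty_hits())
  hits <- data.frame(query_id = d$query_id, subject_id = d$subject_id,
                     identity = round(d$identity, 4),
                     aln_len = as.integer(d$aln_len),
                     mismatch = as.integer(round((1 - d$identity) * d$aln_len)),
                     gap_open = 0L,
                     q_start = as.integer(d$q_start),
                     q_end = as.integer(d$q_end),
                     s_start = as.integer(d$s_start),
                     s_end = as.integer(d$s_end),
                     evalue = d$evalue, bitscore = round(d$bitscore, 1),
                     stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  validate_hits(hits)
  hits
}

#' Reciprocal search between seeds and a target proteome
#'
#' Local alignment scores are symmetric, so the reverse table is derived
#' from the forward one by swapping query/subject roles and coordinates
#' rather than recomputing the dynamic programme.
#'
#' @inheritParams search_all
#' @param seeds Seed proteins (named set).
#' @return `list(forward = , reverse = )` of hit tables
#'   (seeds vs proteome and proteome vs seeds).
#' @export
search_reciprocal <- function(seeds, proteome, scheme = scoring_scheme(),
                              min_bitscore = 25) {
  fwd <- search_all(seeds, proteome, scheme, min_bitscore)
  rev <- data.frame(query_id = fwd$subject_id, subject_id = fwd$query_id,
                    identity = fwd$identity, aln_len = fwd$aln_len,
                    mismatch = fwd$mismatch, gap_open = fwd$gap_open,
                    q_start = fwd$s_start, q_end = fwd$s_end,
                    s_start = fwd$q_start, s_end = fwd$q_end,
                    evalue = fwd$evalue, bitscore = fwd$bitscore,
                    stringsAsFactors = FALSE)
  rev <- rev[order(match(rev$query_id, names(proteome)),
                   -rev$bitscore, rev$subject_id), , drop = FALSE]
  rownames(rev) <- NULL
  list(forward = fwd, reverse = rev)
}
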