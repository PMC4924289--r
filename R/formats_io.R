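# Readers and writers for the external formats the pipeline touches.
# Dialects are deliberately strict: malformed records are rejected with
# the offending line named, never silently repaired.  Genomic
# coordinates are 0-based half-open internally and converted at the file
# boundary (GFF3 and tabular hits are 1-based inclusive on disk).

.AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                  "F","P","S","T","W","Y","V","X")

# 12-column tabular hit layout (the classic protein-search tabular
# dialect: qseqid sseqid pident length mismatch gapopen qstart qend
# sstart send evalue bitscore)
.HIT_COLS <- c("query_id", "subject_id", "identity", "aln_len",
               "mismatch", "gap_open", "q_start", "q_end",
               "s_start", "s_end", "evalue", "bitscore")

# FASTA -----------------------------------------------------------------

#' Read a protein FASTA file
#'
#' Sequences are uppercased on input and validated against the 20-letter
#' amino-acid alphabet plus `X`.  Record ids (the first whitespace-token
#' of each header) must be unique; the remainder of the header is kept
#' as a per-record `description` in `mcols()`.
#'
#' @param path Path to a FASTA file.
#' @return An [Biostrings::AAStringSet] named by record id, with a
#'   `description` metadata column.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format("FASTA file not found: ", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop_format("not valid FASTA (", path,
                                                "): ", conditionMessage(e)))
  if (length(x) == 0L) stop_format("empty FASTA file: ", path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids)))
    stop_validation("FASTA record ", which(!nzchar(ids))[1], " has an empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_validation("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(x))
  if (any(!nzchar(seqs)))
    stop_validation("zero-length sequence for id ",
                    ids[which(!nzchar(seqs))[1]])
  bad <- vapply(strsplit(seqs, ""),
                function(ch) any(!ch %in% .AA_ALPHABET), logical(1))
  if (any(bad))
    stop_validation("residues outside the amino-acid alphabet in record ",
                    ids[which(bad)[1]])
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Write a protein FASTA file
#'
#' @param seqs A named [Biostrings::AAStringSet] (or named character
#'   vector); an optional `description` metadata column is appended to
#'   each header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop_validation("all sequences must be named before writing FASTA")
  out <- seqs
  mc <- S4Vectors::mcols(seqs)
  if (!is.null(mc) && "description" %in% colnames(mc)) {
    desc <- as.character(mc$description)
    keep <- !is.na(desc) & nzchar(desc)
    names(out)[keep] <- paste(names(seqs)[keep], desc[keep])
  }
  S4Vectors::mcols(out) <- NULL
  Biostrings::writeXStringSet(out, path, width = 60L)
  invisible(path)
}

# tabular hits -----------------------------------------------------------

#' Construct an empty hit table
#'
#' @return A zero-row `data.frame` with the 12 hit-table columns
#'   (`query_id`, `subject_id`, `identity` as a fraction, `aln_len`,
#'   `mismatch`, `gap_open`, `q_start`, `q_end`, `s_start`, `s_end`,
#'   `evalue`, `bitscore`).
#' @export
empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             identity = numeric(), aln_len = integer(),
             mismatch = integer(), gap_open = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

validate_hits <- function(hits, what = "hit table") {
  if (!is.data.frame(hits) || !all(.HIT_COLS %in% names(hits)))
    stop_validation(what, " must contain columns: ",
                    paste(.HIT_COLS, collapse = ", "))
  if (nrow(hits) == 0L) return(invisible(hits))
  bad <- which(hits$q_start > hits$q_end | hits$s_start > hits$s_end)
  if (length(bad))
    stop_validation(what, " record ", bad[1],
                    ": interval start exceeds end")
  if (any(hits$bitscore < 0)) stop_validation(what, ": negative bitscore")
  if (any(hits$evalue < 0)) stop_validation(what, ": negative evalue")
  if (any(hits$identity < 0 | hits$identity > 1))
    stop_validation(what, ": identity must be a fraction in [0, 1]")
  invisible(hits)
}

#' Read a 12-column tabular hit file
#'
#' The classic tabular protein-search layout: qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore.  Percent identity is converted to a fraction; line order is
#' preserved; comment lines (`#`) are skipped.  Extra columns beyond 12
#' are dropped with a warning; fewer than 12 is an error naming the
#' line.
#'
#' @param path Path to a tab-separated hit file.
#' @return A hit-table `data.frame` (see [empty_hits()] for the
#'   columns).
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop_format("hit table not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    i <- which(nf < 12L)[1]
    stop_format("line ", lineno[i], ": expected 12 tab-separated columns, found ",
                nf[i])
  }
  if (any(nf > 12L)) {
    warning("ignoring ", max(nf) - 12L, " extra column(s) beyond the ",
            "12-column hit-table layout")
    fields <- lapply(fields, `[`, 1:12)
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- function(j, name) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop_format("line ", lineno[which(is.na(v))[1]],
                  ": non-numeric value in column ", name)
    v
  }
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    identity = num(3, "pident") / 100,
    aln_len = as.integer(num(4, "length")),
    mismatch = as.integer(num(5, "mismatch")),
    gap_open = as.integer(num(6, "gapopen")),
    q_start = as.integer(num(7, "qstart")),
    q_end = as.integer(num(8, "qend")),
    s_start = as.integer(num(9, "sstart")),
    s_end = as.integer(num(10, "send")),
    evalue = num(11, "evalue"),
    bitscore = num(12, "bitscore"),
    stringsAsFactors = FALSE)
  validate_hits(hits, paste0("hit table ", path))
  hits
}

#' Write a hit table in the 12-column tabular layout
#'
#' @param hits A hit-table `data.frame` (internal representation;
#'   identity as a fraction).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  validate_hits(hits)
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3e\t%.1f",
                   hits$query_id, hits$subject_id, hits$identity * 100,
                   hits$aln_len, hits$mismatch, hits$gap_open,
                   hits$q_start, hits$q_end, hits$s_start, hits$s_end,
                   hits$evalue, hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}

# gene models ------------------------------------------------------------

#' Construct a gene-model table
#'
#' Gene models are represented as a `data.frame` with one row per exon:
#' `model_id`, `seqid`, `strand` (`+`/`-`), `start`, `end` (0-based
#' half-open, forward-strand coordinates), and `seed` (the seed protein
#' a predicted model derives from; `NA` for published models).
#'
#' @param model_id,seqid,strand,start,end,seed Per-exon vectors
#'   (recycled where length one).
#' @return A validated gene-model `data.frame`.
#' @export
gene_models <- function(model_id = character(), seqid = character(),
                        strand = character(), start = integer(),
                        end = integer(), seed = NA_character_) {
  if (length(model_id) == 0L) seed <- character()
  df <- data.frame(model_id = as.character(model_id),
                   seqid = as.character(seqid),
                   strand = as.character(strand),
                   start = as.integer(start), end = as.integer(end),
                   seed = as.character(seed), stringsAsFactors = FALSE)
  validate_models(df)
}

validate_models <- function(models) {
  req <- c("model_id", "seqid", "strand", "start", "end")
  if (!is.data.frame(models) || !all(req %in% names(models)))
    stop_validation("gene models must contain columns: ",
                    paste(req, collapse = ", "))
  if (!"seed" %in% names(models)) models$seed <- NA_character_
  models$start <- as.integer(models$start)
  models$end <- as.integer(models$end)
  if (nrow(models) == 0L) return(models)
  if (any(!models$strand %in% c("+", "-")))
    stop_validation("strand must be '+' or '-'")
  if (any(models$start >= models$end))
    stop_validation("every exon must satisfy start < end (0-based half-open)")
  models <- models[order(match(models$model_id, unique(models$model_id)),
                         models$start), , drop = FALSE]
  rownames(models) <- NULL
  for (id in unique(models$model_id)) {
    ex <- models[models$model_id == id, , drop = FALSE]
    if (length(unique(ex$seqid)) > 1L || length(unique(ex$strand)) > 1L)
      stop_validation("model ", id, ": exons span multiple contigs or strands")
    if (nrow(ex) > 1L && any(ex$start[-1] < ex$end[-nrow(ex)]))
      stop_validation("model ", id, ": overlapping exons")
  }
  models
}

#' Read gene models from GFF3
#'
#' mRNA features define models; CDS features are grouped into exons by
#' their `Parent` attribute.  File coordinates (1-based inclusive) are
#' converted to the internal 0-based half-open convention.  A custom
#' `seed` attribute on mRNA features (used for predicted models) is
#' carried through.
#'
#' @param path Path to a GFF3 file.
#' @return A gene-model `data.frame` (see [gene_models()]).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop_format("GFF3 file not found: ", path)
  g <- tryCatch(rtracklayer::import(path, format = "gff3"),
                error = function(e) stop_format("not valid GFF3 (", path,
                                                "): ", conditionMessage(e)))
  mc <- S4Vectors::mcols(g)
  type <- as.character(mc$type)
  ids <- as.character(mc$ID)
  parent <- vapply(as.list(mc$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  mrna <- which(type == "mRNA")
  cds <- which(type == "CDS")
  if (length(cds) == 0L)
    stop_format("no CDS features in ", path)
  if (anyNA(parent[cds]))
    stop_validation("CDS feature without a Parent attribute in ", path,
                    " (feature ", cds[which(is.na(parent[cds]))[1]], ")")
  mrna_ids <- ids[mrna]
  unknown <- setdiff(unique(parent[cds]), mrna_ids)
  if (length(unknown))
    stop_validation("CDS Parent(s) not matching any mRNA ID in ", path,
                    ": ", paste(unknown, collapse = ", "))
  seed <- if ("seed" %in% colnames(mc)) as.character(mc$seed)
          else rep(NA_character_, length(g))
  seed_by_mrna <- setNames(seed[mrna], mrna_ids)
  df <- data.frame(
    model_id = parent[cds],
    seqid = as.character(GenomicRanges::seqnames(g))[cds],
    strand = as.character(GenomicRanges::strand(g))[cds],
    start = GenomicRanges::start(g)[cds] - 1L,
    end = GenomicRanges::end(g)[cds],
    seed = unname(seed_by_mrna[parent[cds]]),
    stringsAsFactors = FALSE)
  df <- df[order(match(df$model_id, mrna_ids), df$start), , drop = FALSE]
  rownames(df) <- NULL
  validate_models(df)
}

#' Write gene models to GFF3
#'
#' Each model is written as one mRNA feature plus its CDS exons; internal
#' 0-based half-open coordinates are converted back to the 1-based
#' inclusive file convention.
#'
#' @param models A gene-model `data.frame`.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path, source = "frbpipe") {
  models <- validate_models(models)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (id in unique(models$model_id)) {
    ex <- models[models$model_id == id, , drop = FALSE]
    attrs <- paste0("ID=", id)
    sd <- ex$seed[1]
    if (!is.na(sd) && nzchar(sd)) attrs <- paste0(attrs, ";seed=", sd)
    writeLines(sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\t%s",
                       ex$seqid[1], source, min(ex$start) + 1L, max(ex$end),
                       ex$strand[1], attrs), con)
    writeLines(sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;Parent=%s",
                       ex$seqid, source, ex$start + 1L, ex$end, ex$strand,
                       paste0(id, ".cds", seq_len(nrow(ex))), id), con)
  }
  invisible(path)
}

# newick -----------------------------------------------------------------

#' Read a Newick tree with optional internal support labels
#'
#' @param path Path to a Newick file.
#' @return An [ape::read.tree()] `"phylo"` object; polytomies are
#'   preserved, numeric internal labels are interpreted as branch
#'   support by [tree_support()].
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop_format("Newick file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop_format("not valid Newick (", path,
                                                 "): ", conditionMessage(e)))
  if (is.null(tr)) stop_format("not valid Newick: ", path)
  if (anyDuplicated(tr$tip.label))
    stop_validation("duplicate leaf labels in ", path)
  tr
}

#' Write a tree in Newick format
#'
#' @param tree A `"phylo"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Extract per-internal-node branch support from node labels
#'
#' Numeric internal node labels are read as support for the edge above
#' the node; non-numeric or empty labels (and the root) give `NA`.
#' Values are returned on the 0-100 scale: if every non-missing value is
#' at most 1 (and at least one is positive), the vector is assumed to be
#' on the 0-1 scale and rescaled with a warning.
#'
#' @param tree A `"phylo"` object.
#' @return Numeric vector of length `tree$Nnode` (one entry per internal
#'   node, in node-number order).
#' @export
tree_support <- function(tree) {
  n <- tree$Nnode
  lab <- tree$node.label %||% rep("", n)
  sup <- suppressWarnings(as.numeric(lab))
  sup[!nzchar(lab)] <- NA_real_
  ok <- !is.na(sup)
  if (any(ok) && all(sup[ok] <= 1) && any(sup[ok] > 0)) {
    warning("support values all <= 1; assuming 0-1 scale and rescaling to 0-100")
    sup <- sup * 100
  }
  sup[1] <- NA_real_  # root carries no branch
  sup
}
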