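test_that("FASTA parsing keeps order, uppercases and validates ids", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">a first seed", "mkv", ">b", "ACDEF"), f)
  x <- read_fasta(f)
  expect_identical(names(x), c("a", "b"))
  expect_identical(as.character(x[["a"]]), "MKV")
  expect_identical(S4Vectors::mcols(x)$description, c("first seed", ""))

  writeLines(c(">a", "MK", ">a", "MV"), f)
  expect_error(read_fasta(f), "duplicate", class = "frbpipe_validation_error")
  writeLines(character(), f)
  expect_error(read_fasta(f), class = "frbpipe_format_error")
  writeLines(c(">a", "MK1"), f)
  expect_error(read_fasta(f), "alphabet", class = "frbpipe_validation_error")
})

test_that("FASTA write/read round-trips random records", {
  set.seed(11)
  f <- withr::local_tempfile(fileext = ".faa")
  for (rep in 1:10) {
    n <- sample(1:8, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A","C","D","E","G","K","X"), sample(1:200, 1), TRUE),
            collapse = ""), character(1))
    names(seqs) <- paste0("id", seq_len(n))
    x <- Biostrings::AAStringSet(seqs)
    S4Vectors::mcols(x) <- S4Vectors::DataFrame(
      description = sample(c("", "some description"), n, TRUE))
    write_fasta(x, f)
    y <- read_fasta(f)
    expect_identical(as.character(y), as.character(x))
    expect_identical(S4Vectors::mcols(y)$description,
                     S4Vectors::mcols(x)$description)
  }
})

test_that("hit tables parse the 12-column dialect strictly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q\ts\t100.00\t50\t0\t0\t1\t50\t1\t50\t1e-30\t100.0", f)
  h <- read_hit_table(f)
  expect_equal(h$identity, 1.0)
  expect_equal(h$bitscore, 100)
  expect_equal(h$q_start, 1L)
  expect_equal(h$evalue, 1e-30)

  writeLines("q\ts\t100.00\t50\t0\t0\t1\t50\t1\t50\t1e-30", f)
  expect_error(read_hit_table(f), "line 1", class = "frbpipe_format_error")

  writeLines(c("q\ts\t90\t50\t5\t0\t1\t50\t1\t50\t1e-30\t99.1\textra"), f)
  expect_warning(h <- read_hit_table(f), "extra column")
  expect_equal(nrow(h), 1L)

  writeLines("q\ts\tNOTANUMBER\t50\t0\t0\t1\t50\t1\t50\t1e-30\t100", f)
  expect_error(read_hit_table(f), "non-numeric", class = "frbpipe_format_error")
})

test_that("hit tables round-trip through write_hit_table", {
  set.seed(12)
  f <- withr::local_tempfile(fileext = ".tsv")
  for (rep in 1:10) {
    n <- sample(1:30, 1)
    h <- data.frame(
      query_id = paste0("q", sample(5, n, TRUE)),
      subject_id = paste0("s", sample(9, n, TRUE)),
      identity = round(runif(n), 2),
      aln_len = sample(500, n), mismatch = sample(0:50, n, TRUE),
      gap_open = sample(0:5, n, TRUE),
      q_start = s <- sample(100, n), q_end = s + sample(50, n),
      s_start = s2 <- sample(100, n), s_end = s2 + sample(50, n),
      evalue = signif(10^runif(n, -60, -2), 3),
      bitscore = round(runif(n, 0, 900), 1),
      stringsAsFactors = FALSE)
    write_hit_table(h, f)
    g <- read_hit_table(f)
    expect_equal(g$identity, h$identity, tolerance = 1e-9)
    expect_equal(g$evalue, h$evalue, tolerance = 1e-3)
    expect_equal(g$bitscore, h$bitscore)
    expect_identical(g[c("query_id", "subject_id", "q_start", "q_end",
                         "s_start", "s_end", "aln_len")],
                     h[c("query_id", "subject_id", "q_start", "q_end",
                         "s_start", "s_end", "aln_len")])
  }
})

test_that("GFF3 IO converts coordinates and groups CDS by mRNA parent", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "ctg1\tx\tmRNA\t101\t160\t.\t+\t.\tID=m1;seed=g7",
               "ctg1\tx\tCDS\t101\t130\t.\t+\t0\tID=c1;Parent=m1",
               "ctg1\tx\tCDS\t141\t160\t.\t+\t0\tID=c2;Parent=m1"), f)
  m <- read_gff3(f)
  expect_equal(nrow(m), 2L)
  expect_equal(m$start, c(100L, 140L))   # 1-based inclusive -> 0-based half-open
  expect_equal(m$end, c(130L, 160L))
  expect_identical(unique(m$model_id), "m1")
  expect_identical(unique(m$seed), "g7")

  writeLines(c("##gff-version 3",
               "ctg1\tx\tmRNA\t101\t160\t.\t+\t.\tID=m1",
               "ctg1\tx\tCDS\t101\t130\t.\t+\t0\tID=c1"), f)
  expect_error(read_gff3(f), "Parent", class = "frbpipe_validation_error")
})

test_that("GFF3 write/read round-trips synthetic annotations", {
  set.seed(13)
  f <- withr::local_tempfile(fileext = ".gff3")
  for (rep in 1:8) {
    n_models <- sample(1:6, 1)
    rows <- lapply(seq_len(n_models), function(i) {
      n_ex <- sample(1:4, 1)
      starts <- cumsum(sample(61:150, n_ex))
      ends <- starts + sample(10:60, n_ex)
      data.frame(model_id = paste0("m", i),
                 seqid = sample(c("c1", "c2"), 1),
                 strand = sample(c("+", "-"), 1),
                 start = starts, end = ends,
                 seed = sample(c(NA, "gX"), 1), stringsAsFactors = FALSE)
    })
    m <- validate_models(do.call(rbind, rows))
    write_gff3(m, f)
    g <- read_gff3(f)
    expect_identical(g[c("model_id", "seqid", "strand", "start", "end", "seed")],
                     m[c("model_id", "seqid", "strand", "start", "end", "seed")])
  }
})

test_that("Newick IO keeps support labels and polytomies", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A,B)95,C);", f)
  tr <- read_newick(f)
  sup <- tree_support(tr)
  expect_equal(sup[2], 95)
  expect_true(is.na(sup[1]))

  writeLines("(A,B,C);", f)
  tr <- read_newick(f)
  expect_equal(tr$Nnode, 1L)   # root trifurcation preserved
  expect_equal(ape::Ntip(tr), 3L)

  writeLines("((A,B,C);", f)
  expect_error(read_newick(f), class = "frbpipe_format_error")
})

test_that("Newick write/read round-trips random trees", {
  set.seed(14)
  f <- withr::local_tempfile(fileext = ".nwk")
  for (rep in 1:10) {
    tr <- ape::rtree(sample(3:16, 1))
    tr$node.label <- as.character(sample(0:100, tr$Nnode, TRUE))
    write_newick(tr, f)
    tr2 <- read_newick(f)
    expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = FALSE))
    expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
    expect_identical(sort(tr2$node.label), sort(tr$node.label))
  }
})

test_that("support auto-detects the 0-1 scale", {
  tr <- ape::read.tree(text = "((A,B)0.95,(C,D)0.4);")
  expect_warning(sup <- tree_support(tr), "0-1 scale")
  expect_equal(sup[-1], c(95, 40))
})
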