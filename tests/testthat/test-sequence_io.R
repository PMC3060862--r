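test_that("FASTA reading preserves order, upper-cases and strips stops", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">B some description", "mvkae", "ikldw", ">A", "QQNNW*"), f)
  recs <- read_fasta(f)
  expect_equal(recs$id, c("B", "A"))
  expect_equal(recs$sequence, c("MVKAEIKLDW", "QQNNW"))
})

test_that("FASTA write-read round trip is the identity", {
  proteins <- data.frame(id = c("P1", "P2"),
                         sequence = c("MVKAEIKLDW", strrep("QASW", 40)))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(proteins, f)
  expect_equal(read_fasta(f), proteins)
})

test_that("duplicate ids and empty files are handled as contracted", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "AAA", ">P1", "CCC"), f)
  expect_error(read_fasta(f), "P1")
  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_warning(recs <- read_fasta(empty), "empty")
  expect_equal(nrow(recs), 0)
})

test_that("typed tables parse and validate coordinates against proteins", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tdomain\tstart\tend", "P1\tHD\t20\t76"), f)
  hits <- read_table(f, "domains")
  expect_equal(hits$protein_id, "P1")
  expect_equal(hits$domain, "HD")
  expect_identical(hits$start, 20L)
  expect_identical(hits$end, 76L)

  s <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tkind\tstart\tscore\tresidue",
               "P1\tphospho\t30\t0.95\tS"), s)
  sites <- read_table(s, "sites")
  expect_equal(sites$kind, "phospho")
  expect_equal(sites$score, 0.95)

  proteins <- data.frame(id = "P1", sequence = strrep("A", 50))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tdomain\tstart\tend", "P1\tHD\t20\t76"), bad)
  expect_error(read_table(bad, "domains", proteins), "P1")
  expect_error(read_table(f, "no_such_schema"), "unknown table schema")
})

test_that("table round trip preserves content and comments are skipped", {
  df <- data.frame(protein_id = c("P1", "P2"), group = c("II", "V"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_table(df, f, comment = "provenance stamp")
  expect_equal(read_table(f, "groups"), df)
  expect_match(readLines(f)[1], "^# provenance stamp")
})

test_that("newick leaf order is left-to-right and intersects with the family", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A,(B,C));", f)
  expect_equal(read_tree_leaf_order(f), c("A", "B", "C"))
  writeLines("((A,B),(C,D));", f)
  expect_equal(read_tree_leaf_order(f), c("A", "B", "C", "D"))
  expect_warning(order <- read_tree_leaf_order(f, ids = c("A", "B", "C", "E")),
                 "intersection")
  expect_equal(order, c("A", "B", "C"))
})

test_that("aligned FASTA rows ungap back to their source sequences", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MV-KAE", ">P2", "MVQK-E"), f)
  aln <- read_alignment(f)
  expect_equal(unname(nchar(aln)), c(6, 6))
  expect_equal(gsub("-", "", aln[["P1"]]), "MVKAE")
  m <- flankscan:::as_alignment_matrix(aln)
  expect_equal(dim(m), c(2, 6))
})

test_that("the MEME plain-text adapter yields rows in the motifs schema", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "MOTIF DEWF MEME-1\tsites sorted by position p-value",
    "------------------------------------------------------------",
    "Sequence name  Start  P-value           Site",
    "-------------  -----  -------           ----",
    "P1                12  1.2e-08 AAAA DEWFDE AAAA",
    "P2                 3  4.5e-06 CCCC DEWFEE CCCC",
    "------------------------------------------------------------"), f)
  occ <- read_meme_occurrences(f)
  expect_equal(nrow(occ), 2)
  expect_equal(occ$protein_id, c("P1", "P2"))
  expect_equal(occ$motif_id, rep("DEWF", 2))
  expect_equal(occ$start, c(12L, 3L))
  expect_equal(occ$end - occ$start + 1L, nchar(occ$matched_seq))
  expect_equal(occ$matched_seq[1], "DEWFDE")
})
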