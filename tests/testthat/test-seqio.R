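test_that("read_fasta uppercases, maps U to T and preserves order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1", "acgt", ">g2 some description", "AAuUGG"), f)
  x <- read_fasta(f)
  expect_equal(x$id, c("g1", "g2"))
  expect_equal(x$seq, c("ACGT", "AATTGG"))

  # agreement with an independent FASTA reader on the U-containing record
  y <- seqinr::read.fasta(f, as.string = TRUE, forceDNAtolower = FALSE)
  expect_equal(x$seq[2], gsub("U", "T", toupper(as.character(y[[2]]))))

  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_equal(nrow(read_fasta(empty)), 0)
})

test_that("read_fasta rejects illegal characters, naming the record", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">ok", "ACGT", ">bad", "AC!T"), f)
  expect_error(read_fasta(f), "bad")
})

test_that("gene_model enforces its invariants", {
  expect_error(gene_model("g", "ACGT", exons = data.frame(start = 1, end = 5)),
               "bounds")
  expect_error(gene_model("g", "ACGTACGT",
                          exons = data.frame(start = c(1, 3), end = c(4, 6))),
               "overlap")
  expect_error(gene_model("g", "ACGTACGT", cds_start = 9), "within an exon")
  expect_error(gene_model("g", "AC-GT"), "illegal character")
  g <- gene_model("g", "acgu")
  expect_equal(g$seq, "ACGT")
})

test_that("read_gff3 builds sense-strand local models from both strands", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ATGTAACCC", ">chr2", "AAACAT"), fa)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t6\t.\t+\t.\tID=gp",
    "chr1\ttest\tmRNA\t1\t6\t.\t+\t.\tID=mplus;Parent=gp",
    "chr1\ttest\texon\t1\t6\t.\t+\t.\tID=e1;Parent=mplus",
    "chr1\ttest\tCDS\t1\t6\t.\t+\t.\tID=c1;Parent=mplus",
    "chr2\ttest\tgene\t4\t6\t.\t-\t.\tID=gm",
    "chr2\ttest\tmRNA\t4\t6\t.\t-\t.\tID=mminus;Parent=gm",
    "chr2\ttest\texon\t4\t6\t.\t-\t.\tID=e2;Parent=mminus"), gff)
  models <- read_gff3(gff, fa)
  expect_equal(models$mplus$exons, tibble::tibble(start = 1L, end = 6L))
  expect_equal(models$mplus$seq, "ATGTAA")
  expect_equal(models$mplus$cds_start, 1L)
  # minus strand: the CAT exon of AAACAT reverse-complements to ATG
  expect_equal(models$mminus$seq, "ATG")
  expect_true(is.na(models$mminus$cds_start))
  expect_match(models$mminus$source, "no_cds")
})

test_that("two mRNAs under one gene become two models", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ATGGCCTAAGGG"), fa)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t12\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t1\t9\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\ttest\texon\t1\t9\t.\t+\t.\tParent=g1.t1",
    "chr1\ttest\tmRNA\t1\t12\t.\t+\t.\tID=g1.t2;Parent=g1",
    "chr1\ttest\texon\t1\t12\t.\t+\t.\tParent=g1.t2"), gff)
  models <- read_gff3(gff, fa)
  expect_equal(sort(names(models)), c("g1.t1", "g1.t2"))
})

test_that("GFF3 round trip preserves exon coordinates", {
  sim <- generate(architecture_spec("EXON_SKIP", seed = 7))
  g <- sim$genes[[1]]
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "x.gff3")
  fa <- file.path(dir, "x.fa")
  write_fasta(tibble::tibble(id = g$id, seq = g$seq), fa)
  write_gff3(list(g), gff)
  back <- read_gff3(gff, fa)[[g$id]]
  expect_equal(back$exons, g$exons)
  expect_equal(back$seq, g$seq)
  expect_equal(back$cds_start, g$cds_start)
})

test_that("write_isoforms emits paired FASTAs with deterministic order", {
  dir <- withr::local_tempdir()
  nt <- file.path(dir, "iso.fa"); aa <- file.path(dir, "iso_aa.fa")

  empty <- enumerate_isoforms(gene_model("g", "ATGTAA"), events = character(0))
  write_isoforms(empty[0, ], nt, aa)
  expect_equal(file.size(nt), 0)
  expect_equal(file.size(aa), 0)

  g <- gene_model("g1", "ATGTAA", cds_start = 1L)
  iso <- enumerate_isoforms(g)
  write_isoforms(iso, nt, aa)
  nt_back <- read_fasta(nt)
  expect_equal(nt_back$seq, "ATGTAA")
  aa_back <- Biostrings::readBStringSet(aa)
  expect_equal(as.character(aa_back[[1]]), "M")

  sim <- generate(architecture_spec("ALT3SS", seed = 3))
  iso2 <- enumerate_isoforms(sim$genes[[1]],
                             enumerate_introns(sim$genes[[1]]))
  write_isoforms(iso2, nt, aa)
  first <- read_fasta(nt)
  write_isoforms(iso2[rev(seq_len(nrow(iso2))), ], nt, aa)
  second <- read_fasta(nt)
  expect_identical(first, second)
})
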