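motifs <- ski7_hbs1_motifs()
pat <- function(id) motifs$pattern[motifs$id == id]

random_protein <- function(n) {
  paste(sample(names(splicedup:::AA_MASS), n, replace = TRUE), collapse = "")
}

test_that("a protein equal to a motif consensus scores a maximal hit at 1", {
  for (id in c("S1", "H1", "G3")) {
    hits <- scan_motifs(pat(id), motifs[motifs$id == id, ])
    expect_equal(hits$start, 1L)
    expect_equal(hits$score, 1)
  }
})

test_that("random proteins rarely produce motif hits (permutation null)", {
  withr::with_seed(41, {
    fp <- 0
    for (i in 1:100) {
      hits <- scan_motifs(random_protein(250), motifs[motifs$in_class, ])
      if (nrow(hits) > 0) fp <- fp + 1
    }
    expect_lt(fp / 100, 0.05)
  })
})

test_that("planted motifs are reported in ascending positional order", {
  withr::with_seed(43, {
    prot <- paste0(random_protein(10), pat("S1"), random_protein(7),
                   pat("S2"), random_protein(12), pat("S3"), random_protein(9))
    hits <- scan_motifs(prot, motifs[motifs$id %in% c("S1", "S2", "S3"), ])
    expect_equal(hits$id, c("S1", "S2", "S3"))
    expect_false(is.unsorted(hits$start, strictly = TRUE))
  })
})

test_that("the catalytic His check accepts H and rejects S/N/D substitutions", {
  g3 <- motifs[motifs$id == "G3", ]
  base <- pat("G3")
  swap <- function(aa) {
    p <- base
    substr(p, g3$special_pos, g3$special_pos) <- aa
    scan_motifs(p, g3)
  }
  expect_true(catalytic_his_ok(swap("H")))
  expect_false(catalytic_his_ok(swap("N")))
  expect_false(catalytic_his_ok(swap("S")))
  expect_false(catalytic_his_ok(swap("D")))
  expect_error(catalytic_his_ok(swap("H")[0, ]), "no G3")
})

test_that("classification follows the motif-complement criteria", {
  hit <- function(id, start, special = NA_character_) {
    tibble::tibble(id = id, start = start, score = 1, special_residue = special)
  }
  full_g <- dplyr::bind_rows(
    hit("G1", 100), hit("G2", 120), hit("G3", 140, "H"),
    hit("G4", 160), hit("G5", 180))
  ski7_set <- dplyr::bind_rows(hit("S1", 10), hit("S2", 30), hit("S3", 50))

  dual <- dplyr::bind_rows(ski7_set, hit("H1", 70), full_g)
  expect_equal(classify_isoform(dual)$class, "DUAL")

  hbs1 <- dplyr::bind_rows(hit("H1", 70), full_g)
  expect_equal(classify_isoform(hbs1)$class, "HBS1_LIKE")

  # degenerate catalytic His keeps the Ski7 side only
  g_deg <- dplyr::mutate(full_g,
                         special_residue = ifelse(id == "G3", "N", special_residue))
  ski7 <- dplyr::bind_rows(ski7_set, g_deg)
  expect_equal(classify_isoform(ski7)$class, "SKI7_LIKE")

  none <- dual[0, ]
  expect_equal(classify_isoform(none)$class, "NEITHER")

  # pure function of the hit set: order never matters
  shuffled <- dual[sample(nrow(dual)), ]
  expect_equal(classify_isoform(shuffled)$class, "DUAL")

  # removing S1 and S2 from a DUAL hit set yields HBS1_LIKE
  expect_equal(classify_isoform(dual[!dual$id %in% c("S1", "S2"), ])$class,
               "HBS1_LIKE")

  # evidence is complete and the class is re-derivable from it
  ev <- generics::tidy(classify_isoform(dual))
  expect_true(all(ev$satisfied[ev$criterion != "NTD_supporting"]))
  gl <- generics::glance(classify_isoform(hbs1))
  expect_equal(gl$class, "HBS1_LIKE")
})

test_that("order violations downgrade confidence but not class", {
  hit <- function(id, start, special = NA_character_) {
    tibble::tibble(id = id, start = start, score = 1, special_residue = special)
  }
  swapped <- dplyr::bind_rows(
    hit("S1", 50), hit("S2", 10), hit("S3", 60),
    hit("H1", 70), hit("G1", 80), hit("G2", 90), hit("G3", 100, "H"),
    hit("G4", 110), hit("G5", 120))
  cls <- classify_isoform(swapped)
  expect_equal(cls$class, "DUAL")
  expect_equal(cls$confidence, "reduced")
})

test_that("motif config round-trips through TSV, validating fields", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_motifs(motifs, f)
  back <- read_motifs(f)
  expect_equal(back$pattern, motifs$pattern)
  expect_equal(back$special_pos, motifs$special_pos)

  bad <- dplyr::mutate(motifs, threshold = 1.5)
  write_motifs(bad, f)
  expect_error(read_motifs(f), "threshold")
})

test_that("the shipped motif config matches the built-in defaults", {
  shipped <- read_motifs(system.file("extdata", "motifs_synthetic_default.tsv",
                                     package = "splicedup"))
  expect_equal(shipped$id, motifs$id)
  expect_equal(shipped$pattern, motifs$pattern)
  # S1' ships as optional and is excluded from classification
  expect_false(shipped$in_class[shipped$id == "S1p"])
})
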