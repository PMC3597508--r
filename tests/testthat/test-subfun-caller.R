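test_that("verdicts follow capability partitioning", {
  anc <- c("SKI7_LIKE", "HBS1_LIKE")
  expect_equal(call_subfunctionalization(anc, "SKI7_LIKE", "HBS1_LIKE")$verdict,
               "SUBFUNCTIONALIZED")
  expect_equal(call_subfunctionalization(anc, "DUAL", "DUAL")$verdict,
               "REDUNDANT")
  expect_equal(call_subfunctionalization(anc, "SKI7_LIKE", "SKI7_LIKE")$verdict,
               "INCOMPLETE_PARTITION")
  expect_equal(call_subfunctionalization(anc, "DUAL", "HBS1_LIKE")$verdict,
               "INCOMPLETE_PARTITION")
  expect_equal(call_subfunctionalization(anc, "NEITHER", "DUAL")$verdict,
               "INCOMPLETE_PARTITION")

  # canonical case: the ancestral long isoform carries the full motif set
  expect_equal(call_subfunctionalization(c("DUAL", "HBS1_LIKE"),
                                         "SKI7_LIKE", "HBS1_LIKE")$verdict,
               "SUBFUNCTIONALIZED")

  # single ancestral class: nothing to partition
  expect_equal(call_subfunctionalization(c("DUAL", "DUAL"),
                                         "SKI7_LIKE", "HBS1_LIKE")$verdict,
               "NOT_COMPARABLE")
})

test_that("the verdict is symmetric under paralog swap", {
  anc <- c("DUAL", "HBS1_LIKE")
  combos <- expand.grid(p1 = c("SKI7_LIKE", "HBS1_LIKE", "DUAL", "NEITHER"),
                        p2 = c("SKI7_LIKE", "HBS1_LIKE", "DUAL", "NEITHER"),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    expect_equal(
      call_subfunctionalization(anc, combos$p1[i], combos$p2[i])$verdict,
      call_subfunctionalization(anc, combos$p2[i], combos$p1[i])$verdict,
      label = paste(combos$p1[i], combos$p2[i]))
  }
})

test_that("the localization axis partitions PTC7-style pairs", {
  anc <- c("NUCLEAR_ENVELOPE", "MITOCHONDRIAL")
  expect_equal(call_subfunctionalization(anc, "NUCLEAR_ENVELOPE", "MITOCHONDRIAL",
                                         axis = "LOCALIZATION")$verdict,
               "SUBFUNCTIONALIZED")
  expect_equal(call_subfunctionalization(anc, "MITOCHONDRIAL", "MITOCHONDRIAL",
                                         axis = "LOCALIZATION")$verdict,
               "INCOMPLETE_PARTITION")
})

test_that("precise intron loss needs the exact junction within the mismatch budget", {
  sim <- generate(architecture_spec("ALT3SS", seed = 37))
  anc <- sim$genes[[1]]
  found <- enumerate_introns(anc)
  acc <- found$acceptors[[1]]$acceptor_pos
  excised <- paste0(substr(anc$seq, 1, found$donor_pos - 1),
                    substr(anc$seq, acc[2] + 1, nchar(anc$seq)))

  hit <- detect_precise_intron_loss(anc, found[1, ], excised)
  expect_true(hit$flag)
  expect_equal(hit$best_mismatches, 0L)

  # intron retained: the junction 24-mer does not occur
  expect_false(detect_precise_intron_loss(anc, found[1, ], anc$seq)$flag)

  # 3 point mutations across the junction: false at m = 2, true at m = 3
  mut <- excised
  jstart <- found$donor_pos - 12L
  for (k in c(0L, 5L, 14L)) {
    pos <- jstart + k
    old <- substr(mut, pos, pos)
    substr(mut, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  expect_false(detect_precise_intron_loss(anc, found[1, ], mut, m = 2)$flag)
  expect_true(detect_precise_intron_loss(anc, found[1, ], mut, m = 3)$flag)

  # short flanks shrink k with a warning
  tiny <- gene_model("t", paste0("AAAGT", strrep("T", 40), "AGCCC"))
  row <- tibble::tibble(donor_pos = 4L,
                        acceptors = list(tibble::tibble(acceptor_pos = 46L)))
  expect_warning(detect_precise_intron_loss(tiny, row, "AAACCC"), "shrinking")
})

test_that("exon loss with a new start is detected at the S1 position", {
  sim <- generate(architecture_spec("ALT3SS", seed = 39))
  anc <- sim$genes[[1]]
  rep <- analyze_gene(anc)
  long_hits <- rep$hits[[which(rep$isoforms$event == "ALT3SS_PROXIMAL")]]
  s1 <- sim$truth$ranges
  s1 <- s1[s1$label == "S1", ]

  # paralog built by truncating the ancestor to the S1 start
  par <- gene_model("p", paste0("AAAAAAAAAACCCCCCCCCC",
                                substr(anc$seq, s1$start, nchar(anc$seq))),
                    cds_start = 21L)
  res <- detect_exon_loss_new_start(long_hits, par)
  expect_true(res$flag)
  expect_equal(res$s1_offset_aa, 0L)

  # full-length copy: S1 is internal and the NTD sits upstream of it
  full <- gene_model("f", splice(anc, enumerate_introns(anc)[1, ], 1),
                     cds_start = anc$cds_start)
  expect_false(detect_exon_loss_new_start(long_hits, full)$flag)

  # start 5 residues upstream of S1: false at d = 3, true at d = 5
  par5 <- gene_model("p5", paste0("AAAAAAAAAACCCCCCCCCC", "ATG",
                                  strrep("GCT", 4),
                                  substr(anc$seq, s1$start, nchar(anc$seq))),
                     cds_start = 21L)
  expect_false(detect_exon_loss_new_start(long_hits, par5, d = 3)$flag)
  expect_true(detect_exon_loss_new_start(long_hits, par5, d = 5)$flag)

  # ancestor without S1 is not comparable
  res2 <- detect_exon_loss_new_start(long_hits[long_hits$id != "S1", ], par)
  expect_equal(res2$verdict, "NOT_COMPARABLE")
})

test_that("the full pair pipeline recovers the planted history", {
  sim <- generate(architecture_spec("POST_WGD_PAIR", seed = 47))
  rep <- analyze_wgd_pair(sim$genes$ancestor, sim$genes$paralog1,
                          sim$genes$paralog2)
  expect_equal(rep$verdict, "SUBFUNCTIONALIZED")
  expect_equal(rep$paralog_classes, c("HBS1_LIKE", "SKI7_LIKE"))
  mech <- generics::tidy(rep)
  expect_equal(mech$precise_intron_loss, c(TRUE, FALSE))
  expect_equal(mech$exon_loss_new_start, c(FALSE, TRUE))
  gl <- generics::glance(rep)
  expect_equal(gl$verdict, "SUBFUNCTIONALIZED")
})
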