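intron_row <- function(donor, acceptors) {
  tibble::tibble(donor_pos = as.integer(donor), donor_score = NA_real_,
                 branch_pos = NA_integer_, branch_score = NA_real_,
                 acceptors = list(tibble::tibble(acceptor_pos = as.integer(acceptors),
                                                 score = NA_real_)),
                 n_acceptors = length(acceptors),
                 alternative = length(acceptors) >= 2)
}

test_that("splice removes exactly the intron interval", {
  # AAA|GT....AG|CCC
  seq <- paste0("AAA", "GT", strrep("T", 10), "AG", "CCC")
  row <- intron_row(4, 17)
  expect_equal(splice(seq, row, 1), "AAACCC")
  expect_error(splice(seq, row, 2), "out of range")

  # proximal vs distal differ exactly by the inter-acceptor segment
  g <- toy_alt_gene()
  found <- enumerate_introns(g)
  prox <- splice(g, found[1, ], 1)
  dist <- splice(g, found[1, ], 2)
  acc <- found$acceptors[[1]]$acceptor_pos
  expect_equal(nchar(prox) - nchar(dist), acc[2] - acc[1])
  # distal mRNA is the proximal mRNA minus the alternative segment
  expect_equal(dist, paste0(substr(prox, 1, found$donor_pos - 1),
                            substr(prox, found$donor_pos + (acc[2] - acc[1]),
                                   nchar(prox))))
})

test_that("spliced mRNA equals the exon-concatenation oracle", {
  withr::with_seed(17, {
    for (rep in 1:10) {
      exon1 <- random_dna(50); exon2 <- random_dna(50)
      intron <- paste0("GT", random_dna(40), "AG")
      seq <- paste0(exon1, intron, exon2)
      row <- intron_row(51, 50 + nchar(intron))
      expect_equal(splice(seq, row, 1), paste0(exon1, exon2))
    }
  })
})

test_that("isoform counts match the event inventory", {
  # alternative intron with functional retention: proximal, distal, retention
  g <- toy_alt_gene()
  iso <- enumerate_isoforms(g, enumerate_introns(g))
  expect_setequal(iso$event, c("ALT3SS_PROXIMAL", "ALT3SS_DISTAL", "RETENTION"))

  # retention-ineligible alternative intron: exactly 2 isoforms
  sim <- generate(architecture_spec("ALT3SS", seed = 13))
  iso2 <- enumerate_isoforms(sim$genes[[1]], enumerate_introns(sim$genes[[1]]))
  expect_setequal(iso2$event, c("ALT3SS_PROXIMAL", "ALT3SS_DISTAL"))

  # no introns: single constitutive isoform
  iso3 <- enumerate_isoforms(gene_model("g", "ATGGCCTAA", cds_start = 1))
  expect_equal(iso3$event, "CONSTITUTIVE")

  # Saitoella-like: 7 introns, second alternative -> 2 spliced isoforms
  sim7 <- generate(architecture_spec("MULTI_INTRON_ALT3SS", seed = 13))
  g7 <- sim7$genes[[1]]
  found7 <- enumerate_introns(g7)
  expect_equal(nrow(found7), 7)
  expect_equal(which(found7$alternative), 2L)
  iso7 <- enumerate_isoforms(g7, found7)
  expect_setequal(iso7$event, c("ALT3SS_PROXIMAL", "ALT3SS_DISTAL"))
})

test_that("mRNA lengths shrink by exactly the removed intron lengths", {
  sim <- generate(architecture_spec("MULTI_INTRON_ALT3SS", seed = 21))
  g <- sim$genes[[1]]
  found <- enumerate_introns(g)
  iso <- enumerate_isoforms(g, found)
  ilen <- function(choice) {
    sum(purrr::map2_int(found$acceptors, choice,
                        ~ .x$acceptor_pos[.y]) - found$donor_pos + 1L)
  }
  prox_removed <- ilen(rep(1L, nrow(found)))
  expect_equal(nchar(iso$mrna[iso$event == "ALT3SS_PROXIMAL"]),
               nchar(g$seq) - prox_removed)
  # distal-spliced mRNA is shorter by the inter-acceptor distance
  acc2 <- found$acceptors[[2]]$acceptor_pos
  expect_equal(nchar(iso$mrna[iso$event == "ALT3SS_PROXIMAL"]) -
                 nchar(iso$mrna[iso$event == "ALT3SS_DISTAL"]),
               acc2[2] - acc2[1])
})

test_that("translation follows the standard and alternative yeast codes", {
  expect_equal(translate_cds("ATGTAA"), "M")
  expect_equal(translate_cds("ATGCTGTAA", 1), "ML")
  expect_equal(translate_cds("ATGCTGTAA", 12), "MS")
  expect_warning(translate_cds("AT"), "shorter")
  expect_warning(translate_cds("ATGTAAG"), "incomplete")

  # all 64 codons against the hand-written standard table
  codons <- names(STD_CODE)
  for (cod in codons) {
    expect_equal(translate_cds(paste0(cod, "TAA"), 1),
                 if (STD_CODE[[cod]] == "*") "" else STD_CODE[[cod]],
                 label = cod)
  }
  # table 12 differs from table 1 on exactly one codon
  diff <- vapply(codons, function(cod) {
    !identical(translate_cds(paste0(cod, "TAATAA"), 1),
               translate_cds(paste0(cod, "TAATAA"), 12))
  }, logical(1))
  expect_equal(names(which(diff)), "CTG")
  # ambiguity codes translate conservatively to X
  expect_equal(translate_cds("ATGANGTAA"), "MX")
})

test_that("retention consequences follow the 3n / stop-free rule", {
  mk <- function(intron) {
    g <- gene_model("g", paste0("ATG", intron, "GGTGGATAA"), cds_start = 1)
    list(gene = g, row = intron_row(4, 3 + nchar(intron)))
  }
  x <- mk("GTATGTCAG")  # 9 nt, codons GTA TGT CAG
  rc <- retention_consequence(x$gene, x$row)
  expect_true(rc$frame_preserving)
  expect_true(rc$stop_free)
  expect_true(rc$functional_retention)
  expect_true(is.na(rc$stop_offset_aa))

  x <- mk("GTATGTCCAG")  # 10 nt
  rc <- retention_consequence(x$gene, x$row)
  expect_false(rc$frame_preserving)
  expect_false(rc$functional_retention)

  x <- mk("GTATAGCAG")  # TAG in frame
  rc <- retention_consequence(x$gene, x$row)
  expect_true(rc$frame_preserving)
  expect_false(rc$stop_free)
  expect_false(rc$functional_retention)
  expect_equal(rc$stop_offset_aa, 2L)  # M V then stop

  # intron upstream of the CDS is out of scope
  g <- gene_model("g", paste0("GTATGTCAG", "ATGTAA"), cds_start = 10)
  expect_error(retention_consequence(g, intron_row(1, 9)), "upstream")
})

test_that("alternative-start isoforms begin at the S1 ATG", {
  sim <- generate(architecture_spec("ALT_TSS", seed = 19))
  g <- sim$genes[[1]]
  iso <- find_alt_start(g)
  expect_equal(nrow(iso), 1)
  expect_equal(iso$event, "ALT_START")
  s1_pat <- ski7_hbs1_motifs()$pattern[ski7_hbs1_motifs()$id == "S1"]
  expect_equal(substr(iso$protein, 1, nchar(s1_pat)), s1_pat)
  expect_equal(iso$start_offset, sim$truth$s1_pos)

  # no ATG at the requested position -> no isoform, reason recorded
  none <- find_alt_start(g, s1_pos_nt = g$cds_start + 3L)
  expect_equal(nrow(none), 0)
  expect_match(attr(none, "reason"), "ATG")

  # same-frame internal start yields a suffix of the long protein
  long <- paste0("ATGGCTGCT", "ATGTCTAACGAATGGAAAGATCGT", "GCTGCTTAA")
  g2 <- gene_model("g2", long, cds_start = 1)
  full <- translate_cds(long)
  alt <- find_alt_start(g2, s1_pos_nt = 10L)
  expect_true(endsWith(full, alt$protein))
})

test_that("molecular weight uses average residue masses plus one water", {
  expect_error(molecular_weight(""), "empty")
  expect_error(molecular_weight("MZ"), "Z")
  # hand-summed from published average residue masses
  expect_equal(molecular_weight("MG"), (131.1926 + 57.0519 + 18.01524) / 1000,
               tolerance = 1e-6)
  # additivity: mass(a + b) = mass(a) + mass(b) - water
  a <- "MKTAYIAK"; b <- "QRQISFVK"
  expect_equal(molecular_weight(paste0(a, b)),
               molecular_weight(a) + molecular_weight(b) - 18.01524 / 1000,
               tolerance = 1e-9)
})

test_that("premature stops are flagged against the constitutive 3' anchor", {
  # a non-functional retention (stop in intron) marks a premature stop; use a
  # single-acceptor intron with an in-frame TAA planted
  intron <- paste0("GTATGT", strrep("GCT", 6), "TAA", "TTACTAACC", "CTT", "CAG")
  g <- gene_model("g", paste0("ATGGCT", intron, strrep("GCT", 4), "TAA",
                              strrep("CT", 10)), cds_start = 1)
  found <- enumerate_introns(g)
  expect_equal(nrow(found), 1)
  iso <- enumerate_isoforms(g, found)
  expect_equal(iso$event, "CONSTITUTIVE")  # retention ineligible
  expect_false(iso$premature_stop[1])
})
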