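#' Translate a coding sequence
#'
#' Translation stops at the first stop codon. Codons containing ambiguity
#' codes translate to `X`. Genetic code 12 (alternative yeast nuclear)
#' differs from the standard code only at CUG (Ser instead of Leu).
#'
#' @param cds nucleotide string starting at the first codon
#' @param genetic_code 1 or 12
#' @param keep_stops if `TRUE`, do not truncate: return the full-frame
#'   translation with stops as `*` (used for frame scanning)
#' @return amino-acid string
#' @export
translate_cds <- function(cds, genetic_code = 1L, keep_stops = FALSE) {
  tab <- codon_table(genetic_code)
  if (nchar(cds) < 3) {
    warn("coding sequence shorter than one codon; empty protein")
    return("")
  }
  if (nchar(cds) %% 3 != 0 && !keep_stops) {
    warn(sprintf("incomplete final codon (%d nt) ignored", nchar(cds) %% 3))
  }
  cods <- split_codons(toupper(cds))
  aa <- unname(tab[cods])
  aa[is.na(aa)] <- "X"
  if (keep_stops) return(paste(aa, collapse = ""))
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0) aa <- aa[seq_len(stop_at[1] - 1L)]
  paste(aa, collapse = "")
}

#' Average molecular weight of a protein in kDa
#'
#' Sum of average residue masses plus one water, divided by 1000.
#'
#' @param protein amino-acid string (standard 20 residues)
#' @return mass in kilodaltons
#' @export
molecular_weight <- function(protein) {
  if (!nzchar(protein)) abort("molecular_weight: empty protein")
  aa <- chars(protein)
  bad <- setdiff(unique(aa), names(AA_MASS))
  if (length(bad) > 0) {
    abort(sprintf("molecular_weight: unknown residue(s): %s",
                  paste(bad, collapse = ", ")))
  }
  (sum(AA_MASS[aa]) + WATER_MASS) / 1000
}

#' Remove one intron from a gene sequence
#'
#' Returns the gene sequence with the closed interval from the donor position
#' through the chosen acceptor position removed; sequence outside the intron
#' is untouched.
#'
#' @param gene a [gene_model()] or nucleotide string
#' @param intron one row of the tibble from [enumerate_introns()]
#' @param acceptor_index which acceptor to splice at (1 = proximal)
#' @return spliced nucleotide string
#' @export
splice <- function(gene, intron, acceptor_index = 1L) {
  seq <- if (inherits(gene, "gene_model")) gene$seq else gene
  acc <- intron$acceptors[[1]]
  if (acceptor_index < 1 || acceptor_index > nrow(acc)) {
    abort(sprintf("acceptor_index %d out of range (1..%d)", acceptor_index, nrow(acc)))
  }
  apos <- acc$acceptor_pos[acceptor_index]
  paste0(str_sub(seq, 1L, intron$donor_pos - 1L), str_sub(seq, apos + 1L))
}

# Remove several (donor, acceptor) intervals at once; intervals must be
# disjoint and sorted.
splice_at <- function(seq, donor_pos, acceptor_pos) {
  if (length(donor_pos) == 0) return(seq)
  keep_start <- c(1L, acceptor_pos + 1L)
  keep_end <- c(donor_pos - 1L, nchar(seq))
  paste(str_sub(seq, keep_start, keep_end), collapse = "")
}

#' Consequences of retaining an intron in the mRNA
#'
#' Retention preserves a functional reading frame only when the intron length
#' is a multiple of three and the retained sequence contains no stop codon in
#' the reading frame of the retained transcript. When translation of the
#' retained mRNA terminates inside or because of the intron, the termination
#' point is reported in amino acids from the start codon.
#'
#' @param gene a [gene_model()] with a `cds_start`
#' @param intron one row of the tibble from [enumerate_introns()]
#' @param acceptor_index acceptor defining the intron 3' end (defaults to the
#'   last, i.e. the full intron extent)
#' @return list with `frame_preserving`, `stop_free`, `functional_retention`,
#'   and `stop_offset_aa` (`NA` when translation of the retained mRNA runs to
#'   the normal stop)
#' @export
retention_consequence <- function(gene, intron, acceptor_index = NULL) {
  if (is.na(gene$cds_start)) abort("retention_consequence: gene has no cds_start")
  acc <- intron$acceptors[[1]]
  if (is.null(acceptor_index)) acceptor_index <- nrow(acc)
  apos <- acc$acceptor_pos[acceptor_index]
  dpos <- intron$donor_pos
  if (apos <= gene$cds_start) {
    abort("retention_consequence: intron upstream of the CDS is out of scope")
  }
  ilen <- apos - dpos + 1L
  frame_preserving <- ilen %% 3L == 0L
  # reading frame of the retained transcript: translate the pre-mRNA from the
  # start codon and ask whether any stop falls within the intron
  pre <- str_sub(gene$seq, gene$cds_start)
  aa <- translate_cds(pre, gene$genetic_code, keep_stops = TRUE)
  stops <- which(chars(aa) == "*")
  in_intron <- function(aa_idx) {
    nt_start <- gene$cds_start + (aa_idx - 1L) * 3L
    nt_end <- nt_start + 2L
    nt_end >= dpos && nt_start <= apos
  }
  intron_stops <- stops[vapply(stops, in_intron, logical(1))]
  stop_free <- length(intron_stops) == 0L
  first_stop <- if (length(stops) > 0) stops[1] else NA_integer_
  # termination point if the retained mRNA is translated as-is
  stop_offset_aa <- NA_integer_
  if (!stop_free || !frame_preserving) {
    stop_offset_aa <- if (!is.na(first_stop)) first_stop - 1L else NA_integer_
  }
  list(frame_preserving = frame_preserving,
       stop_free = stop_free,
       functional_retention = frame_preserving && stop_free,
       stop_offset_aa = stop_offset_aa)
}

iso_row <- function(gene, event, detail, mrna, start_offset) {
  cds <- str_sub(mrna, start_offset)
  protein <- suppressWarnings(translate_cds(cds, gene$genetic_code))
  full <- suppressWarnings(translate_cds(cds, gene$genetic_code, keep_stops = TRUE))
  has_stop <- grepl("*", full, fixed = TRUE)
  stop_aa <- if (has_stop) nchar(protein) + 1L else NA_integer_
  # distance (nt) from the end of the stop codon to the mRNA 3' end
  stop_to_3p <- if (has_stop) nchar(mrna) - (start_offset - 1L + stop_aa * 3L) else NA_integer_
  tibble(
    gene_id = gene$id, event = event, detail = detail,
    mrna = mrna, cds = cds, protein = protein,
    start_offset = start_offset,
    length_aa = nchar(protein),
    mass_kda = ifelse(nchar(protein) > 0, molecular_weight(protein), NA_real_),
    stop_offset_aa = stop_aa, stop_to_3prime_nt = stop_to_3p
  )
}

start_offset_for <- function(gene, removed) {
  # map the annotated cds_start onto an mRNA built by removing `removed`
  # (tibble with donor/acceptor columns) from the gene sequence
  if (is.na(gene$cds_start)) return(NA_integer_)
  off <- gene$cds_start
  if (nrow(removed) > 0) {
    before <- removed[removed$acceptor_pos < gene$cds_start, , drop = FALSE]
    off <- off - sum(before$acceptor_pos - before$donor_pos + 1L)
  }
  off
}

#' Enumerate event-labelled transcript isoforms
#'
#' Events are enumerated one at a time against the constitutive background:
#' for each alternatively spliced intron one isoform per acceptor (labelled
#' `ALT3SS_PROXIMAL` / `ALT3SS_DISTAL`), a `RETENTION` isoform for each
#' CDS-overlapping intron whose retention is functional (3n length, no
#' in-frame stop), an `EXON_SKIP` isoform for each annotated skippable exon
#' group, and, when `alt_start` hits are supplied, `ALT_START` isoforms.
#' When no intron is alternative a single `CONSTITUTIVE` isoform represents
#' the fully spliced mRNA. Overlapping candidate introns are resolved 5' to
#' 3': a candidate is kept only if its donor lies downstream of the previous
#' kept acceptor.
#'
#' Premature stops are flagged relative to the constitutive isoform: a stop
#' lying further from the mRNA 3' end than the constitutive stop is premature.
#'
#' @param gene a [gene_model()]
#' @param introns tibble from [enumerate_introns()] or
#'   [introns_from_annotation()]; `NULL` uses the annotation when the model
#'   has more than one exon
#' @param events character subset of
#'   `c("ALT3SS", "RETENTION", "EXON_SKIP")`
#' @return tibble of isoforms, one row per isoform
#' @export
enumerate_isoforms <- function(gene, introns = NULL,
                               events = c("ALT3SS", "RETENTION", "EXON_SKIP")) {
  if (is.null(introns)) introns <- introns_from_annotation(gene)
  # resolve overlapping candidates 5' -> 3'
  kept <- list(); last_end <- 0L
  if (nrow(introns) > 0) {
    for (i in seq_len(nrow(introns))) {
      row <- introns[i, ]
      if (row$donor_pos > last_end) {
        kept[[length(kept) + 1L]] <- row
        last_end <- max(row$acceptors[[1]]$acceptor_pos)
      }
    }
  }
  introns <- if (length(kept) > 0) bind_rows(kept) else introns[0, ]
  n_int <- nrow(introns)

  removal <- function(acc_choice) {
    # acc_choice: integer vector, acceptor index per intron
    tibble(donor_pos = introns$donor_pos,
           acceptor_pos = purrr::map2_int(introns$acceptors, acc_choice,
                                          ~ .x$acceptor_pos[.y]))
  }
  build <- function(event, detail, removed, start_override = NULL) {
    mrna <- splice_at(gene$seq, removed$donor_pos, removed$acceptor_pos)
    off <- start_override %||% start_offset_for(gene, removed)
    if (is.na(off)) {
      loc <- str_locate_all(mrna, "ATG")[[1]]
      if (nrow(loc) == 0) return(NULL)
      off <- as.integer(loc[1, 1])
    }
    iso_row(gene, event, detail, mrna, off)
  }

  out <- list()
  baseline_choice <- rep(1L, n_int)
  alt_idx <- which(introns$alternative)
  if ("ALT3SS" %in% events && length(alt_idx) > 0) {
    for (i in alt_idx) {
      n_acc <- introns$n_acceptors[i]
      labels <- if (n_acc == 2) c("ALT3SS_PROXIMAL", "ALT3SS_DISTAL")
                else paste0("ALT3SS_", seq_len(n_acc))
      for (a in seq_len(n_acc)) {
        choice <- baseline_choice; choice[i] <- a
        out[[length(out) + 1L]] <-
          build(labels[a], sprintf("intron%d:acceptor%d", i, a), removal(choice))
      }
    }
  } else if (n_int >= 0) {
    out[[length(out) + 1L]] <- build("CONSTITUTIVE", "all_introns_spliced",
                                     removal(baseline_choice))
  }

  if ("RETENTION" %in% events && n_int > 0 && !is.na(gene$cds_start)) {
    for (i in seq_len(n_int)) {
      full_extent <- max(introns$acceptors[[i]]$acceptor_pos)
      if (full_extent <= gene$cds_start) next  # intron outside CDS
      rc <- retention_consequence(gene, introns[i, ])
      if (!rc$functional_retention) next
      choice <- baseline_choice
      removed <- removal(choice)[-i, , drop = FALSE]
      out[[length(out) + 1L]] <- build("RETENTION", sprintf("intron%d", i), removed)
    }
  }

  if ("EXON_SKIP" %in% events && length(gene$skippable) > 0) {
    for (grp in gene$skippable) {
      removed <- removal(baseline_choice)
      # extend removal across the skipped exon(s) and flanking introns
      lo <- min(grp); hi <- max(grp)
      if (lo <= 1 || hi >= nrow(gene$exons)) {
        warn("terminal exons cannot be skipped; ignoring")
        next
      }
      span <- tibble(donor_pos = gene$exons$end[lo - 1L] + 1L,
                     acceptor_pos = gene$exons$start[hi + 1L] - 1L)
      keep <- removed[removed$acceptor_pos < span$donor_pos |
                        removed$donor_pos > span$acceptor_pos, , drop = FALSE]
      removed <- arrange(bind_rows(keep, span), .data$donor_pos)
      out[[length(out) + 1L]] <-
        build("EXON_SKIP", paste0("exon", paste(grp, collapse = "+")), removed)
    }
  }

  iso <- bind_rows(purrr::compact(out))
  if (nrow(iso) == 0) return(iso)
  # premature-stop flag: anchored at the 3' end, compared to the reference
  # (first ALT3SS/CONSTITUTIVE) isoform
  ref <- iso$stop_to_3prime_nt[match(TRUE, iso$event %in%
                                       c("CONSTITUTIVE", "ALT3SS_PROXIMAL"))]
  iso$premature_stop <- !is.na(iso$stop_to_3prime_nt) & !is.na(ref) &
    iso$stop_to_3prime_nt > ref
  iso
}

#' Emit an alternative-start isoform at the S1 motif
#'
#' Models the Candida-style short transcript: an mRNA initiated at the ATG
#' encoding the first residue of motif S1, translated without splicing.
#' The S1 site is located by scanning the three-frame translation of the
#' pre-mRNA; absent an S1 hit beginning with ATG, no isoform is emitted and
#' the reason is recorded.
#'
#' @param gene a [gene_model()]
#' @param motifs motif set from [ski7_hbs1_motifs()] (only S1 is used), or a
#'   precomputed S1 nucleotide position via `s1_pos_nt`
#' @param s1_pos_nt optional 1-based position of the A of the S1 ATG on the
#'   gene sequence; overrides motif scanning
#' @return one-row isoform tibble, or a zero-row tibble with attribute
#'   `reason` when no ATG-initiated S1 exists
#' @export
find_alt_start <- function(gene, motifs = ski7_hbs1_motifs(), s1_pos_nt = NULL) {
  none <- function(reason) {
    z <- iso_row(gene, "ALT_START", "", "ATGTAA", 1L)[0, ]
    z$premature_stop <- logical(0)
    attr(z, "reason") <- reason
    z
  }
  if (is.null(s1_pos_nt)) {
    s1 <- motifs[motifs$id == "S1", ]
    if (nrow(s1) == 0) return(none("no S1 model supplied"))
    best <- NULL
    for (frame in 0:2) {
      aa <- suppressWarnings(
        translate_cds(str_sub(gene$seq, 1L + frame), gene$genetic_code,
                      keep_stops = TRUE))
      hits <- scan_motifs(aa, s1)
      if (nrow(hits) == 0) next
      pos_nt <- 1L + frame + (hits$start[1] - 1L) * 3L
      if (is.null(best) || hits$score[1] > best$score) {
        best <- list(pos = pos_nt, score = hits$score[1])
      }
    }
    if (is.null(best)) return(none("no S1 motif found in any frame"))
    s1_pos_nt <- best$pos
  }
  if (str_sub(gene$seq, s1_pos_nt, s1_pos_nt + 2L) != "ATG") {
    return(none(sprintf("S1 at nt %d does not begin with ATG", s1_pos_nt)))
  }
  iso <- iso_row(gene, "ALT_START", sprintf("start%d", s1_pos_nt),
                 gene$seq, s1_pos_nt)
  iso$premature_stop <- FALSE
  iso
}
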