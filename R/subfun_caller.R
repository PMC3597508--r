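class_capabilities <- function(cls, axis) {
  if (axis == "MOTIF_COMPLEMENT") {
    switch(cls,
           DUAL = c("SKI7", "HBS1"),
           SKI7_LIKE = "SKI7",
           HBS1_LIKE = "HBS1",
           NEITHER = character(0),
           abort(sprintf("unknown motif class '%s'", cls)))
  } else {
    if (!cls %in% c("NUCLEAR_ENVELOPE", "MITOCHONDRIAL", "OTHER")) {
      abort(sprintf("unknown localization class '%s'", cls))
    }
    if (cls == "OTHER") character(0) else cls
  }
}

#' Classify the evolutionary outcome of a gene duplication
#'
#' Compares the functional classes of an alternatively spliced ancestor's
#' isoforms with the classes of a duplicated gene pair, on one function axis
#' (Ski7/Hbs1 motif complement, or PTC7-style localization; never mixed).
#' Classes are expanded to functional capabilities (`DUAL` covers both the
#' Ski7 and the Hbs1 function) and the verdict is:
#'
#' * `SUBFUNCTIONALIZED` — the paralogs carry different, proper, non-empty
#'   subsets of the ancestral capabilities that together restore the full set;
#' * `REDUNDANT` — each paralog carries the full ancestral capability set;
#' * `INCOMPLETE_PARTITION` — anything else;
#' * `NOT_COMPARABLE` — the ancestor does not have two distinct isoform
#'   classes (no partition to inherit).
#'
#' @param ancestor_isoform_classes character vector of the ancestor's
#'   per-isoform classes (>= 2 distinct values required)
#' @param paralog1_class,paralog2_class classes of the two paralogs
#' @param axis `"MOTIF_COMPLEMENT"` or `"LOCALIZATION"`
#' @param mechanisms optional tibble of per-paralog mechanism flags to attach
#' @return object of class `subfun_report`
#' @export
call_subfunctionalization <- function(ancestor_isoform_classes,
                                      paralog1_class, paralog2_class,
                                      axis = c("MOTIF_COMPLEMENT", "LOCALIZATION"),
                                      mechanisms = NULL) {
  axis <- match.arg(axis)
  anc_cap <- sort(unique(unlist(
    purrr::map(ancestor_isoform_classes, class_capabilities, axis = axis))))
  p1 <- sort(class_capabilities(paralog1_class, axis))
  p2 <- sort(class_capabilities(paralog2_class, axis))
  if (length(unique(ancestor_isoform_classes)) < 2) {
    verdict <- "NOT_COMPARABLE"
  } else if (length(p1) > 0 && length(p2) > 0 &&
             setequal(p1, anc_cap) && setequal(p2, anc_cap)) {
    verdict <- "REDUNDANT"
  } else if (!identical(p1, p2) &&
             length(p1) > 0 && length(p2) > 0 &&
             !setequal(p1, anc_cap) && !setequal(p2, anc_cap) &&
             setequal(union(p1, p2), anc_cap)) {
    verdict <- "SUBFUNCTIONALIZED"
  } else {
    verdict <- "INCOMPLETE_PARTITION"
  }
  structure(list(
    verdict = verdict, axis = axis,
    ancestor_classes = ancestor_isoform_classes,
    paralog_classes = c(paralog1_class, paralog2_class),
    ancestor_capabilities = anc_cap,
    mechanisms = mechanisms),
    class = "subfun_report")
}

#' @export
print.subfun_report <- function(x, ...) {
  cat(sprintf("<subfun_report> %s (axis: %s)\n  ancestor isoforms: %s\n  paralogs: %s\n",
              x$verdict, x$axis, paste(x$ancestor_classes, collapse = ", "),
              paste(x$paralog_classes, collapse = " / ")))
  invisible(x)
}

#' Tidy the per-paralog mechanism evidence of a subfunctionalization report
#' @param x a `subfun_report`
#' @param ... unused
#' @export
tidy.subfun_report <- function(x, ...) {
  if (is.null(x$mechanisms)) {
    return(tibble(paralog = character(0), precise_intron_loss = logical(0),
                  exon_loss_new_start = logical(0)))
  }
  x$mechanisms
}

#' One-row summary of a subfunctionalization report
#' @param x a `subfun_report`
#' @param ... unused
#' @export
glance.subfun_report <- function(x, ...) {
  tibble(verdict = x$verdict, axis = x$axis,
         ancestor_n_classes = length(unique(x$ancestor_classes)),
         paralog1_class = x$paralog_classes[1],
         paralog2_class = x$paralog_classes[2])
}

#' Detect precise intron loss in a paralog
#'
#' A paralog shows precise intron loss (the cDNA-recombination signature)
#' when it contains the exact exon-exon junction formed by concatenating the
#' ancestor's flanking exonic k-mers with zero intervening nucleotides,
#' allowing a small number of mismatches to absorb post-duplication
#' divergence.
#'
#' @param ancestor a [gene_model()]
#' @param intron one row from [enumerate_introns()] on the ancestor
#' @param paralog_seq paralog nucleotide string
#' @param acceptor_index which ancestor acceptor defines the lost intron
#'   (defaults to the distal one, the junction of the short isoform)
#' @param k flanking k-mer length on each side
#' @param m maximal mismatches across the 2k-nt junction
#' @return list with `flag`, and evidence: `junction`, `best_pos`,
#'   `best_mismatches`
#' @export
detect_precise_intron_loss <- function(ancestor, intron, paralog_seq,
                                       acceptor_index = NULL, k = 12L, m = 3L) {
  acc <- intron$acceptors[[1]]
  if (is.null(acceptor_index)) acceptor_index <- nrow(acc)
  apos <- acc$acceptor_pos[acceptor_index]
  dpos <- intron$donor_pos
  k_left <- min(k, dpos - 1L)
  k_right <- min(k, nchar(ancestor$seq) - apos)
  if (k_left < k || k_right < k) {
    warn(sprintf("flanking exon shorter than k; shrinking to %d/%d nt",
                 k_left, k_right))
  }
  junction <- paste0(str_sub(ancestor$seq, dpos - k_left, dpos - 1L),
                     str_sub(ancestor$seq, apos + 1L, apos + k_right))
  jl <- nchar(junction)
  n <- nchar(paralog_seq) - jl + 1L
  if (n < 1L) {
    return(list(flag = FALSE, junction = junction, best_pos = NA_integer_,
                best_mismatches = NA_integer_))
  }
  jv <- chars(junction)
  pv <- chars(paralog_seq)
  mis <- vapply(seq_len(n), function(i) sum(pv[i:(i + jl - 1L)] != jv),
                integer(1))
  best <- which.min(mis)
  list(flag = mis[best] <= m, junction = junction,
       best_pos = as.integer(best), best_mismatches = mis[best])
}

#' Detect exon loss with gain of a new initiation codon
#'
#' The post-duplication Ski7 signature: the paralog's start codon sits within
#' `d` residues of the position of the ancestor's motif S1 (which starts with
#' Met at the extreme N-terminus of derived Ski7 proteins), and no sequence
#' homologous to ancestor exon 1 — diagnosed by the structured N-terminal
#' domain (NTD) motif — remains upstream of the paralog start.
#'
#' @param ancestor_hits motif hits of the ancestor's long isoform (must
#'   contain S1)
#' @param paralog a [gene_model()] with an annotated `cds_start`
#' @param motifs motif set (S1 and NTD are used)
#' @param d maximal offset (residues) between the paralog start and S1
#' @return list with `flag` (or `verdict = "NOT_COMPARABLE"` when the
#'   ancestor lacks S1) and evidence: `s1_offset_aa`, `ntd_upstream`
#' @export
detect_exon_loss_new_start <- function(ancestor_hits, paralog,
                                       motifs = ski7_hbs1_motifs(), d = 3L) {
  if (!"S1" %in% ancestor_hits$id) {
    return(list(flag = NA, verdict = "NOT_COMPARABLE",
                reason = "ancestor long isoform has no S1 motif"))
  }
  if (is.na(paralog$cds_start)) abort("paralog has no annotated start codon")
  prot <- suppressWarnings(
    translate_cds(str_sub(paralog$seq, paralog$cds_start), paralog$genetic_code))
  if (!nzchar(prot)) {
    return(list(flag = FALSE, s1_offset_aa = NA_integer_, ntd_upstream = NA))
  }
  hits <- scan_motifs(prot, motifs[motifs$id %in% c("S1"), ])
  s1_off <- if (nrow(hits) > 0) hits$start[1] - 1L else NA_integer_
  # translate the region upstream of the start, in the start's frame, and
  # look for residual NTD (exon 1) homology
  up_len <- paralog$cds_start - 1L
  ntd_up <- FALSE
  if (up_len >= 3L) {
    up_start <- 1L + (up_len %% 3L)
    up_aa <- suppressWarnings(
      translate_cds(str_sub(paralog$seq, up_start, paralog$cds_start - 1L),
                    paralog$genetic_code, keep_stops = TRUE))
    if (nzchar(up_aa)) {
      ntd_hits <- scan_motifs(up_aa, motifs[motifs$id == "NTD", ])
      ntd_up <- nrow(ntd_hits) > 0
    }
  }
  flag <- !is.na(s1_off) && s1_off <= d && !ntd_up
  list(flag = flag, s1_offset_aa = s1_off, ntd_upstream = ntd_up)
}
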