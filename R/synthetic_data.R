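# Synthetic fungal gene loci with planted splice architectures, motifs and
# localization signals, plus ground truth, so every pipeline stage is
# testable without downloads.
#
# Layout coordinates are fixed per architecture (only background sequence
# varies with the seed); coding segments inside branch-to-acceptor geometry
# windows are encoded with acceptor-window-safe codons (see encode_protein)
# so the planted acceptors are the only YAG trinucleotides in reach.

ARCHITECTURES <- c("ALT3SS", "MULTI_INTRON_ALT3SS", "ALT_TSS", "EXON_SKIP",
                   "RETENTION_PAIR", "POST_WGD_PAIR")

# hydrophilic-biased background alphabet: keeps random coding sequence free
# of spurious Kyte-Doolittle TM windows so planted TMs are the only ones
BG_AA <- c("G", "S", "T", "N", "Q", "D", "E", "K", "R", "H", "P", "Y", "A", "W")

# planted mitochondrial presequence (25 aa, Arg/Leu/Ser/Ala-rich, acidic-free)
MTS_PEPTIDE <- "LRSLRRASRLLSARTSALRSASLRA"

bg_aa <- function(n) paste(sample(BG_AA, n, replace = TRUE), collapse = "")

weaken_signal <- function(sig, strength) {
  if (strength >= 1) return(sig)
  v <- chars(sig)
  hit <- stats::runif(length(v)) > strength
  v[hit] <- sample(NT, sum(hit), replace = TRUE)
  paste(v, collapse = "")
}

tape_new <- function() new.env(parent = emptyenv())

tape_add <- function(tp, s, label = NULL) {
  cur <- get0("seq", tp, ifnotfound = "")
  start <- nchar(cur) + 1L
  assign("seq", paste0(cur, s), tp)
  if (!is.null(label)) {
    rngs <- get0("ranges", tp, ifnotfound = list())
    rngs[[length(rngs) + 1L]] <- tibble(label = label, start = start,
                                        end = start + nchar(s) - 1L)
    assign("ranges", rngs, tp)
  }
  invisible(start)
}

tape_seq <- function(tp) get0("seq", tp, ifnotfound = "")
tape_ranges <- function(tp) bind_rows(get0("ranges", tp, ifnotfound = list()))
tape_range <- function(tp, label) {
  r <- tape_ranges(tp)
  r[r$label == label, ][1, ]
}

motif_pattern <- function(motifs, id) motifs$pattern[motifs$id == id]

# single-acceptor intron: donor(6) + 24 nt + branch(7) + 20 nt + TAG = 60 nt,
# branch -> acceptor distance 29 nt
add_intron_single <- function(tp, idx, strength, gc, motifs = NULL) {
  d <- tape_add(tp, weaken_signal("GTATGT", strength), sprintf("donor%d", idx))
  tape_add(tp, sample_nt(24, gc))
  b <- tape_add(tp, weaken_signal("TACTAAC", strength), sprintf("branch%d", idx))
  tape_add(tp, sample_nt(20, gc))
  a <- tape_add(tp, weaken_signal("TAG", strength), sprintf("acceptor%d", idx))
  tibble(intron = idx, donor_pos = d, branch_pos = b,
         acceptor_pos = list(a + 2L))
}

# alternative-acceptor intron: proximal part as above, then a 117-nt coding
# alternative segment carrying S1 and S2, closed by the distal CAG acceptor
# (the CAG is the final codon, Gln, of the alternative segment)
add_intron_alt <- function(tp, idx, strength, gc, motifs) {
  d <- tape_add(tp, weaken_signal("GTATGT", strength), sprintf("donor%d", idx))
  tape_add(tp, sample_nt(24, gc))
  b <- tape_add(tp, weaken_signal("TACTAAC", strength), sprintf("branch%d", idx))
  tape_add(tp, sample_nt(20, gc))
  a1 <- tape_add(tp, weaken_signal("TAG", strength), sprintf("acceptor%d_prox", idx))
  tape_add(tp, encode_protein(bg_aa(2)))
  tape_add(tp, encode_protein(motif_pattern(motifs, "S1")), "S1")
  tape_add(tp, encode_protein(bg_aa(4)))
  tape_add(tp, encode_protein(motif_pattern(motifs, "S2")), "S2")
  tape_add(tp, encode_protein(bg_aa(17)))
  a2 <- tape_add(tp, weaken_signal("CAG", strength), sprintf("acceptor%d_dist", idx))
  tibble(intron = idx, donor_pos = d, branch_pos = b,
         acceptor_pos = list(c(a1 + 2L, a2 + 2L)))
}

# first coding exon: Met + spacer + structured N-terminal domain + spacer
add_exon1 <- function(tp, motifs) {
  s <- tape_add(tp, encode_protein(paste0("M", bg_aa(5))), "cds_start")
  tape_add(tp, encode_protein(motif_pattern(motifs, "NTD")), "NTD")
  tape_add(tp, encode_protein(bg_aa(5)))
  s
}

# GTPase-bearing 3' coding block: S3, H1, G1..G5 (70 codons) + stop
add_gtpase_exon <- function(tp, motifs, extra_codon = NULL) {
  tape_add(tp, encode_protein(bg_aa(3)))
  tape_add(tp, encode_protein(motif_pattern(motifs, "S3")), "S3")
  tape_add(tp, encode_protein(bg_aa(4)))
  tape_add(tp, encode_protein(motif_pattern(motifs, "H1")), "H1")
  tape_add(tp, encode_protein(bg_aa(2)))
  if (!is.null(extra_codon)) tape_add(tp, extra_codon, "extra_codon")
  tape_add(tp, encode_protein(bg_aa(2)))
  for (g in paste0("G", 1:5)) {
    tape_add(tp, encode_protein(motif_pattern(motifs, g)), g)
    tape_add(tp, encode_protein(bg_aa(2)))
  }
  tape_add(tp, encode_protein(bg_aa(1)))
  tape_add(tp, "TAA", "stop")
}

build_alt3ss <- function(strength, gc, motifs) {
  tp <- tape_new()
  tape_add(tp, sample_nt(30, gc))
  cds_start <- add_exon1(tp, motifs)
  intron <- add_intron_alt(tp, 1L, strength, gc, motifs)
  add_gtpase_exon(tp, motifs)
  tape_add(tp, sample_nt(60, gc))
  list(tp = tp, cds_start = cds_start, introns = intron)
}

build_multi_intron <- function(strength, gc, motifs) {
  tp <- tape_new()
  tape_add(tp, sample_nt(30, gc))
  cds_start <- add_exon1(tp, motifs)
  introns <- list(add_intron_single(tp, 1L, strength, gc))
  tape_add(tp, encode_protein(bg_aa(40)))
  introns[[2]] <- add_intron_alt(tp, 2L, strength, gc, motifs)
  blocks <- list(
    function() {  # S3 + H1 exon
      tape_add(tp, encode_protein(bg_aa(3)))
      tape_add(tp, encode_protein(motif_pattern(motifs, "S3")), "S3")
      tape_add(tp, encode_protein(bg_aa(4)))
      tape_add(tp, encode_protein(motif_pattern(motifs, "H1")), "H1")
      tape_add(tp, encode_protein(bg_aa(17)))
    })
  for (g in paste0("G", 1:5)) {
    local({
      gg <- g
      blocks[[length(blocks) + 1L]] <<- function() {
        tape_add(tp, encode_protein(bg_aa(16)))
        tape_add(tp, encode_protein(motif_pattern(motifs, gg)), gg)
        tape_add(tp, encode_protein(bg_aa(16)))
      }
    })
  }
  for (i in seq_along(blocks)) {
    blocks[[i]]()
    if (i < length(blocks)) {
      introns[[i + 2L]] <- add_intron_single(tp, i + 2L, strength, gc)
    }
  }
  tape_add(tp, "TAA", "stop")
  tape_add(tp, sample_nt(60, gc))
  list(tp = tp, cds_start = cds_start, introns = bind_rows(introns))
}

build_alt_tss <- function(strength, gc, motifs) {
  tp <- tape_new()
  tape_add(tp, sample_nt(30, gc))
  cds_start <- add_exon1(tp, motifs)
  d <- tape_add(tp, weaken_signal("GTATGT", strength), "donor1")
  tape_add(tp, sample_nt(11, gc))  # 11 nt keeps the intron length off 3n
  tape_add(tp, encode_protein(bg_aa(2)))
  s1 <- tape_add(tp, encode_protein(motif_pattern(motifs, "S1")), "S1")
  tape_add(tp, encode_protein(bg_aa(4)))
  tape_add(tp, encode_protein(motif_pattern(motifs, "S2")), "S2")
  tape_add(tp, encode_protein(bg_aa(2)))
  b <- tape_add(tp, "T", "branch_pad") + 1L
  tape_add(tp, weaken_signal("TACTAAC", strength), "branch1")
  tape_add(tp, "C")
  tape_add(tp, encode_protein(bg_aa(6)))
  a <- tape_add(tp, weaken_signal("CAG", strength), "acceptor1")
  add_gtpase_exon(tp, motifs, extra_codon = "CTG")
  tape_add(tp, sample_nt(60, gc))
  list(tp = tp, cds_start = cds_start, s1_pos = s1,
       introns = tibble(intron = 1L, donor_pos = d, branch_pos = b,
                        acceptor_pos = list(a + 2L)))
}

build_exon_skip <- function(strength, gc, motifs) {
  tp <- tape_new()
  tape_add(tp, sample_nt(30, gc))
  cds_start <- add_exon1(tp, motifs)
  e1_end <- nchar(tape_seq(tp))
  introns <- list(add_intron_single(tp, 1L, strength, gc))
  e2_start <- nchar(tape_seq(tp)) + 1L
  tape_add(tp, encode_protein(bg_aa(2)))
  tape_add(tp, encode_protein(motif_pattern(motifs, "S1")), "S1")
  tape_add(tp, encode_protein(bg_aa(4)))
  tape_add(tp, encode_protein(motif_pattern(motifs, "S2")), "S2")
  tape_add(tp, encode_protein(bg_aa(18)))
  e2_end <- nchar(tape_seq(tp))
  introns[[2]] <- add_intron_single(tp, 2L, strength, gc)
  e3_start <- nchar(tape_seq(tp)) + 1L
  add_gtpase_exon(tp, motifs)
  tape_add(tp, sample_nt(60, gc))  # 3' UTR is part of the terminal exon
  e3_end <- nchar(tape_seq(tp))
  exons <- tibble(start = c(1L, e2_start, e3_start),
                  end = c(e1_end, e2_end, e3_end))
  list(tp = tp, cds_start = cds_start, introns = bind_rows(introns),
       exons = exons)
}

build_retention_pair <- function(strength, gc, motifs) {
  tp <- tape_new()
  tape_add(tp, sample_nt(30, gc))
  cds_start <- tape_add(tp, encode_protein(paste0("M", bg_aa(2))), "cds_start")
  d <- tape_add(tp, weaken_signal("GTATGT", strength), "donor1")
  tape_add(tp, strrep("ATC", 19), "TM")  # poly-Ile transmembrane helix
  b <- tape_add(tp, "T", "branch_pad") + 1L
  tape_add(tp, weaken_signal("TACTAAC", strength), "branch1")
  tape_add(tp, "C")
  tape_add(tp, encode_protein(bg_aa(7)))
  a <- tape_add(tp, weaken_signal("CAG", strength), "acceptor1")
  tape_add(tp, encode_protein(MTS_PEPTIDE), "MTS")
  tape_add(tp, encode_protein(bg_aa(40)))
  tape_add(tp, "TAA", "stop")
  tape_add(tp, sample_nt(60, gc))
  list(tp = tp, cds_start = cds_start,
       introns = tibble(intron = 1L, donor_pos = d, branch_pos = b,
                        acceptor_pos = list(a + 2L)))
}

# per-site divergence outside protected ranges; substitutions that would
# create a stop codon in the main reading frame are suppressed
diverge_seq <- function(seq, rate, protected, cds_start, cds_end) {
  v <- chars(seq)
  n <- length(v)
  prot <- rep(FALSE, n)
  if (!is.null(protected) && nrow(protected) > 0) {
    for (i in seq_len(nrow(protected))) {
      prot[protected$start[i]:protected$end[i]] <- TRUE
    }
  }
  targets <- which(stats::runif(n) < rate & !prot)
  for (p in targets) {
    new <- sample(setdiff(NT, v[p]), 1L)
    if (!is.na(cds_start) && p >= cds_start && p <= cds_end) {
      ci <- (p - cds_start) %/% 3L
      c0 <- cds_start + ci * 3L
      codon <- paste(replace(v[c0:(c0 + 2L)], p - c0 + 1L, new), collapse = "")
      if (codon %in% STOP_CODONS) next
    }
    v[p] <- new
  }
  paste(v, collapse = "")
}

shift_ranges <- function(ranges, cut_start, cut_end) {
  w <- cut_end - cut_start + 1L
  keep <- ranges[ranges$end < cut_start | ranges$start > cut_end, , drop = FALSE]
  mutate(keep,
         start = ifelse(.data$start > cut_end, .data$start - w, .data$start),
         end = ifelse(.data$end > cut_end, .data$end - w, .data$end))
}

#' Specify a synthetic locus architecture
#'
#' @param kind one of `ALT3SS` (Lachancea-style alternative 3' splice sites),
#'   `MULTI_INTRON_ALT3SS` (Saitoella-style: 7 introns, the second
#'   alternative), `ALT_TSS` (Candida-style internal start codon at motif S1,
#'   genetic code 12), `EXON_SKIP` (basidiomycete-style skippable internal
#'   exon), `RETENTION_PAIR` (PTC7-style frame-preserving retainable intron
#'   with TM/MTS partition), `POST_WGD_PAIR` (ALT3SS ancestor plus two
#'   diverged paralogs: one with the intron precisely excised, one starting
#'   at S1 with a degenerate G3 histidine)
#' @param signal_strength between 0 and 1: 1 plants consensus signals; lower values
#'   mutate each signal position with probability `1 - signal_strength`
#' @param gc background GC content
#' @param divergence per-site substitution rate applied to the paralogs of
#'   `POST_WGD_PAIR` (never inside motifs or the start/stop codons)
#' @param seed integer seed; generation is deterministic given the spec
#' @return object of class `architecture_spec`
#' @export
architecture_spec <- function(kind = ARCHITECTURES, signal_strength = 1,
                              gc = 0.4, divergence = 0.05, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(signal_strength >= 0, signal_strength <= 1, gc > 0, gc < 1)
  structure(list(kind = kind, signal_strength = signal_strength, gc = gc,
                 divergence = divergence, seed = as.integer(seed)),
            class = "architecture_spec")
}

planted_introns_found <- function(gene, planted, model) {
  found <- enumerate_introns(gene, model)
  if (nrow(found) != nrow(planted)) return(FALSE)
  for (i in seq_len(nrow(planted))) {
    if (found$donor_pos[i] != planted$donor_pos[i]) return(FALSE)
    if (found$branch_pos[i] != planted$branch_pos[i]) return(FALSE)
    if (!identical(found$acceptors[[i]]$acceptor_pos,
                   as.integer(planted$acceptor_pos[[i]]))) return(FALSE)
  }
  TRUE
}

generate_once <- function(spec, motifs, model) {
  kind <- spec$kind
  s <- spec$signal_strength; gc <- spec$gc
  built <- switch(kind,
    ALT3SS = , POST_WGD_PAIR = build_alt3ss(s, gc, motifs),
    MULTI_INTRON_ALT3SS = build_multi_intron(s, gc, motifs),
    ALT_TSS = build_alt_tss(s, gc, motifs),
    EXON_SKIP = build_exon_skip(s, gc, motifs),
    RETENTION_PAIR = build_retention_pair(s, gc, motifs))

  code <- if (kind == "ALT_TSS") 12L else 1L
  gid <- paste0(tolower(kind), "_locus")
  gene <- gene_model(gid, tape_seq(built$tp),
                     exons = built$exons,
                     cds_start = built$cds_start,
                     genetic_code = code,
                     skippable = if (kind == "EXON_SKIP") list(2L) else list(),
                     source = sprintf("splicedup::generate(%s)", kind))

  truth <- list(kind = kind, cds_start = built$cds_start,
                introns = built$introns,
                ranges = tape_ranges(built$tp))

  truth$expected_isoforms <- switch(kind,
    ALT3SS = tibble(event = c("ALT3SS_PROXIMAL", "ALT3SS_DISTAL"),
                    class = c("DUAL", "HBS1_LIKE")),
    MULTI_INTRON_ALT3SS = tibble(event = c("ALT3SS_PROXIMAL", "ALT3SS_DISTAL"),
                                 class = c("DUAL", "HBS1_LIKE")),
    ALT_TSS = tibble(event = c("CONSTITUTIVE", "ALT_START"),
                     class = c("HBS1_LIKE", "DUAL")),
    EXON_SKIP = tibble(event = c("CONSTITUTIVE", "EXON_SKIP"),
                       class = c("DUAL", "HBS1_LIKE")),
    RETENTION_PAIR = tibble(event = c("CONSTITUTIVE", "RETENTION"),
                            class = c(NA_character_, NA_character_),
                            localization = c("MITOCHONDRIAL", "NUCLEAR_ENVELOPE")),
    POST_WGD_PAIR = tibble(event = c("ALT3SS_PROXIMAL", "ALT3SS_DISTAL"),
                           class = c("DUAL", "HBS1_LIKE")))
  if (kind == "ALT_TSS") truth$s1_pos <- built$s1_pos

  genes <- list(gene)
  if (kind == "POST_WGD_PAIR") {
    ranges <- tape_ranges(built$tp)
    acc <- built$introns$acceptor_pos[[1]]
    dpos <- built$introns$donor_pos[1]
    distal <- acc[length(acc)]
    stop_rng <- ranges[ranges$label == "stop", ]

    # paralog 1: precise excision of the full (distal) intron, then divergence
    p1_seq <- paste0(str_sub(gene$seq, 1L, dpos - 1L),
                     str_sub(gene$seq, distal + 1L))
    p1_prot <- shift_ranges(
      ranges[ranges$label %in% c("NTD", "S3", "H1", paste0("G", 1:5),
                                 "stop", "cds_start"), ], dpos, distal)
    p1_cds_end <- stop_rng$end - (distal - dpos + 1L)
    p1_seq <- diverge_seq(p1_seq, spec$divergence, p1_prot,
                          built$cds_start, p1_cds_end)
    p1 <- gene_model(paste0(gid, "_paralog1"), p1_seq,
                     cds_start = built$cds_start,
                     source = "splicedup::generate(POST_WGD_PAIR) hbs1-like copy")

    # paralog 2: exon-1 loss, new start at S1, degenerate G3 His, divergence
    s1 <- ranges[ranges$label == "S1", ]
    lead <- sample_nt(20, gc)
    off <- nchar(lead) - s1$start + 1L
    p2_seq <- paste0(lead, str_sub(gene$seq, s1$start))
    g3 <- ranges[ranges$label == "G3", ]
    his_nt <- g3$start + off + 4L * 3L  # codon of the catalytic His (pos 5)
    substr(p2_seq, his_nt, his_nt + 2L) <- "AAC"  # His -> Asn
    p2_prot <- ranges[ranges$label %in% c("S1", "S2", "S3", "H1",
                                          paste0("G", 1:5), "stop"), ]
    p2_prot <- mutate(p2_prot, start = .data$start + off, end = .data$end + off)
    p2_seq <- diverge_seq(p2_seq, spec$divergence, p2_prot,
                          s1$start + off, stop_rng$end + off)
    p2 <- gene_model(paste0(gid, "_paralog2"), p2_seq,
                     cds_start = s1$start + off,
                     source = "splicedup::generate(POST_WGD_PAIR) ski7-like copy")

    genes <- list(ancestor = gene, paralog1 = p1, paralog2 = p2)
    truth$expected_paralog_classes <- c(paralog1 = "HBS1_LIKE",
                                        paralog2 = "SKI7_LIKE")
    truth$expected_verdict <- "SUBFUNCTIONALIZED"
    truth$expected_mechanisms <- tibble(
      paralog = c("paralog1", "paralog2"),
      precise_intron_loss = c(TRUE, FALSE),
      exon_loss_new_start = c(FALSE, TRUE))
  }
  list(kind = kind, genes = genes, truth = truth, spec = spec)
}

#' Generate a synthetic locus with ground truth
#'
#' Deterministic for a fixed spec (seed included): architecture coordinates
#' depend only on the architecture, background sequence only on the seed.
#' Loci are rejection-sampled until signal enumeration at default thresholds
#' recovers exactly the planted intron candidates, so false-positive
#' measurements downstream are meaningful. At `signal_strength` well below 1
#' planted signals routinely fail the thresholds; rejection is then skipped
#' (the point of a weak-signal locus is that recovery degrades).
#'
#' @param spec an [architecture_spec()]
#' @param motifs motif set used for planting
#' @param model splice model used for the planted-candidate check
#' @param max_tries rejection-sampling budget
#' @return list with `kind`, `genes` (list of [gene_model()]; three named
#'   models for `POST_WGD_PAIR`), `truth` (planted coordinates, expected
#'   isoforms/classes/calls/verdict), and `spec`
#' @export
generate <- function(spec, motifs = ski7_hbs1_motifs(),
                     model = splice_signal_model(), max_tries = 40L) {
  withr::with_seed(spec$seed, {
    check <- spec$signal_strength >= 1
    for (i in seq_len(max_tries)) {
      out <- generate_once(spec, motifs, model)
      g <- if (spec$kind == "POST_WGD_PAIR") out$genes$ancestor else out$genes[[1]]
      if (!check || planted_introns_found(g, out$truth$introns, model)) {
        return(out)
      }
    }
    abort(sprintf("could not generate a clean %s locus in %d tries",
                  spec$kind, max_tries))
  })
}

#' Generate a labelled corpus across architectures
#'
#' @param n loci per architecture
#' @param seed master seed; per-locus seeds are derived deterministically
#' @param kinds architectures to include
#' @param signal_strength,gc,divergence forwarded to [architecture_spec()]
#' @return tibble manifest with one row per locus: `locus_id`, `kind`,
#'   `seed`, `locus` (list column of [generate()] results)
#' @export
generate_suite <- function(n = 10L, seed = 1L, kinds = ARCHITECTURES,
                           signal_strength = 1, gc = 0.4, divergence = 0.05) {
  stopifnot(n >= 1)
  grid <- tidyr::expand_grid(kind = kinds, rep = seq_len(n))
  seeds <- as.integer((as.numeric(seed) * 7919 +
                         seq_len(nrow(grid)) * 104729) %% 2147483647)
  loci <- purrr::map2(grid$kind, seeds, function(k, s) {
    generate(architecture_spec(kind = k, signal_strength = signal_strength,
                               gc = gc, divergence = divergence, seed = s))
  })
  tibble(locus_id = sprintf("%s_%02d", tolower(grid$kind), grid$rep),
         kind = grid$kind, seed = seeds, locus = loci)
}

#' Write a generated corpus to disk
#'
#' Emits per-locus FASTA and GFF3, a manifest TSV and a ground-truth JSON.
#'
#' @param suite tibble from [generate_suite()]
#' @param dir output directory (created if needed)
#' @export
write_suite <- function(suite, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(suite))) {
    loc <- suite$locus[[i]]
    genes <- loc$genes
    fa <- tibble(id = purrr::map_chr(genes, "id"),
                 seq = purrr::map_chr(genes, "seq"))
    write_fasta(fa, file.path(dir, paste0(suite$locus_id[i], ".fa")))
    write_gff3(genes, file.path(dir, paste0(suite$locus_id[i], ".gff3")))
    truth <- loc$truth
    truth$introns <- as.list(truth$introns)
    jsonlite::write_json(truth, file.path(dir, paste0(suite$locus_id[i], ".truth.json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  manifest <- select(suite, "locus_id", "kind", "seed")
  manifest$fasta <- paste0(manifest$locus_id, ".fa")
  manifest$truth <- paste0(manifest$locus_id, ".truth.json")
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
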