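#' Run the full single-gene analysis
#'
#' Enumerates candidate introns, assembles event-labelled isoforms,
#' translates them, scans each protein for Ski7/Hbs1 diagnostic motifs,
#' classifies the motif complement and issues a localization call.
#'
#' @param gene a [gene_model()]
#' @param model a [splice_signal_model()]
#' @param motifs motif set from [ski7_hbs1_motifs()] or [read_motifs()]
#' @param events events to enumerate (see [enumerate_isoforms()])
#' @param alt_start also look for a Candida-style internal start at motif S1
#' @param seed recorded in provenance (the analysis itself is deterministic)
#' @return object of class `splice_report`: list with `gene_id`, `introns`,
#'   `isoforms` (tibble with `class` and `localization` columns), `hits`
#'   (per-isoform motif hits), `provenance`
#' @export
analyze_gene <- function(gene, model = splice_signal_model(),
                         motifs = ski7_hbs1_motifs(),
                         events = c("ALT3SS", "RETENTION", "EXON_SKIP"),
                         alt_start = FALSE, seed = NA_integer_) {
  introns <- enumerate_introns(gene, model)
  iso <- enumerate_isoforms(gene, introns, events)
  if (alt_start) {
    extra <- find_alt_start(gene, motifs)
    if (nrow(extra) > 0) iso <- bind_rows(iso, extra)
  }
  hits <- purrr::map(iso$protein, function(p) {
    if (nzchar(p)) scan_motifs(p, motifs) else scan_motifs("X", motifs)
  })
  iso$class <- purrr::map_chr(hits, ~ classify_isoform(.x)$class)
  iso$localization <- purrr::map_chr(iso$protein, function(p) {
    if (nzchar(p)) localize(p)$call else "OTHER"
  })
  structure(list(
    gene_id = gene$id, introns = introns, isoforms = iso, hits = hits,
    provenance = list(
      package = "splicedup", version = as.character(utils::packageVersion("splicedup")),
      genetic_code = gene$genetic_code, seed = seed,
      thresholds = model$thresholds,
      motif_source = "synthetic stand-in consensus patterns",
      localization = "heuristic stand-in (hydropathy + composition)")),
    class = "splice_report")
}

#' @export
print.splice_report <- function(x, ...) {
  cat(sprintf("<splice_report> %s: %d intron candidate(s), %d isoform(s)\n",
              x$gene_id, nrow(x$introns), nrow(x$isoforms)))
  print(select(x$isoforms, "event", "detail", "length_aa", "mass_kda",
               "class", "localization"))
  invisible(x)
}

#' Tidy the isoform table of a splice report
#' @param x a `splice_report`
#' @param ... unused
#' @export
tidy.splice_report <- function(x, ...) {
  select(x$isoforms, "gene_id", "event", "detail", "length_aa", "mass_kda",
         "premature_stop", "class", "localization")
}

#' One-row summary of a splice report
#' @param x a `splice_report`
#' @param ... unused
#' @export
glance.splice_report <- function(x, ...) {
  tibble(gene_id = x$gene_id,
         n_intron_candidates = nrow(x$introns),
         n_alternative_introns = sum(x$introns$alternative),
         n_isoforms = nrow(x$isoforms),
         n_classes = length(unique(x$isoforms$class)))
}

#' Serialize / restore an analysis report as JSON
#'
#' The JSON round trip is lossless for the isoform and hit tables and the
#' provenance block.
#'
#' @param report a `splice_report`
#' @param path JSON file
#' @export
write_report <- function(report, path) {
  df_rows <- function(df) purrr::transpose(as.list(df))
  payload <- list(
    gene_id = report$gene_id,
    introns = purrr::map(seq_len(nrow(report$introns)), function(i) {
      r <- report$introns[i, ]
      list(donor_pos = r$donor_pos, donor_score = r$donor_score,
           branch_pos = r$branch_pos, branch_score = r$branch_score,
           n_acceptors = r$n_acceptors, alternative = r$alternative,
           acceptors = df_rows(r$acceptors[[1]]))
    }),
    isoforms = df_rows(report$isoforms),
    hits = purrr::map(report$hits, df_rows),
    provenance = report$provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

rows_to_tibble <- function(rows, proto) {
  if (length(rows) == 0) return(proto[0, ])
  bind_rows(purrr::map(rows, function(r) {
    as_tibble(purrr::map2(r, proto[0, names(r)],
                          ~ if (is.null(.x)) .y[NA_integer_] else
                            vctrs::vec_cast(.x, .y)))
  }))
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  acc_proto <- tibble(acceptor_pos = integer(0), score = numeric(0))
  iso_proto <- tibble(gene_id = character(0), event = character(0),
                      detail = character(0), mrna = character(0),
                      cds = character(0), protein = character(0),
                      start_offset = integer(0), length_aa = integer(0),
                      mass_kda = numeric(0), stop_offset_aa = integer(0),
                      stop_to_3prime_nt = integer(0),
                      premature_stop = logical(0), class = character(0),
                      localization = character(0))
  hit_proto <- tibble(id = character(0), start = integer(0),
                      score = numeric(0), special_residue = character(0))
  intron_proto <- tibble(donor_pos = integer(0), donor_score = numeric(0),
                         branch_pos = integer(0), branch_score = numeric(0),
                         acceptors = list(), n_acceptors = integer(0),
                         alternative = logical(0))
  if (length(p$introns) == 0) return(structure(
    list(gene_id = p$gene_id, introns = intron_proto,
         isoforms = rows_to_tibble(p$isoforms, iso_proto),
         hits = purrr::map(p$hits, rows_to_tibble, proto = hit_proto),
         provenance = p$provenance), class = "splice_report"))
  introns <- bind_rows(purrr::map(p$introns, function(r) {
    tibble(donor_pos = as.integer(r$donor_pos),
           donor_score = as.numeric(r$donor_score),
           branch_pos = as.integer(r$branch_pos),
           branch_score = as.numeric(r$branch_score),
           acceptors = list(rows_to_tibble(r$acceptors, acc_proto)),
           n_acceptors = as.integer(r$n_acceptors),
           alternative = as.logical(r$alternative))
  }))
  iso_names <- if (length(p$isoforms) > 0) names(p$isoforms[[1]]) else names(iso_proto)
  structure(list(gene_id = p$gene_id, introns = introns,
                 isoforms = rows_to_tibble(p$isoforms, iso_proto[, iso_names]),
                 hits = purrr::map(p$hits, rows_to_tibble, proto = hit_proto),
                 provenance = p$provenance),
            class = "splice_report")
}

#' Analyse an (ancestor, paralog pair) triple for subfunctionalization
#'
#' Runs the single-gene pipeline on the ancestor, classifies both paralog
#' proteins, tests the two mechanism signatures (precise intron loss against
#' the ancestor's alternatively spliced intron; exon loss with a new start at
#' motif S1) and calls the evolutionary outcome on the motif-complement axis.
#'
#' @param ancestor,paralog1,paralog2 [gene_model()] objects; the paralogs
#'   need an annotated `cds_start`
#' @param model,motifs as in [analyze_gene()]
#' @return a `subfun_report` (see [call_subfunctionalization()]) with a
#'   `mechanisms` tibble attached
#' @export
analyze_wgd_pair <- function(ancestor, paralog1, paralog2,
                             model = splice_signal_model(),
                             motifs = ski7_hbs1_motifs()) {
  anc <- analyze_gene(ancestor, model, motifs)
  paralog_class <- function(p) {
    prot <- suppressWarnings(
      translate_cds(str_sub(p$seq, p$cds_start), p$genetic_code))
    list(class = classify_isoform(scan_motifs(prot, motifs))$class, prot = prot)
  }
  c1 <- paralog_class(paralog1); c2 <- paralog_class(paralog2)

  alt <- which(anc$introns$alternative)
  target <- if (length(alt) > 0) alt[1] else 1L
  mech <- NULL
  if (nrow(anc$introns) > 0) {
    long_iso <- anc$isoforms[anc$isoforms$event %in%
                               c("ALT3SS_PROXIMAL", "CONSTITUTIVE"), ]
    anc_hits <- if (nrow(long_iso) > 0) {
      scan_motifs(long_iso$protein[1], motifs)
    } else tibble(id = character(0))
    mech <- bind_rows(purrr::imap(list(paralog1 = paralog1, paralog2 = paralog2),
      function(p, nm) {
        pil <- detect_precise_intron_loss(ancestor, anc$introns[target, ], p$seq)
        eln <- detect_exon_loss_new_start(anc_hits, p, motifs)
        tibble(paralog = nm,
               precise_intron_loss = isTRUE(pil$flag),
               intron_loss_mismatches = pil$best_mismatches,
               exon_loss_new_start = isTRUE(eln$flag),
               s1_offset_aa = eln$s1_offset_aa %||% NA_integer_)
      }))
  }
  call_subfunctionalization(anc$isoforms$class, c1$class, c2$class,
                            axis = "MOTIF_COMPLEMENT", mechanisms = mech)
}

#' Score pipeline recovery of a synthetic locus against its ground truth
#'
#' @param sim result of [generate()]
#' @param model,motifs as in [analyze_gene()]
#' @return one-row tibble with per-aspect logical columns and `recovered`
#' @export
evaluate_locus <- function(sim, model = splice_signal_model(),
                           motifs = ski7_hbs1_motifs()) {
  truth <- sim$truth
  kind <- sim$kind
  if (kind == "POST_WGD_PAIR") {
    rep <- analyze_wgd_pair(sim$genes$ancestor, sim$genes$paralog1,
                            sim$genes$paralog2, model, motifs)
    classes_ok <- identical(unname(rep$paralog_classes),
                            unname(truth$expected_paralog_classes))
    verdict_ok <- rep$verdict == truth$expected_verdict
    mech <- rep$mechanisms
    mech_ok <- !is.null(mech) &&
      identical(mech$precise_intron_loss,
                truth$expected_mechanisms$precise_intron_loss) &&
      identical(mech$exon_loss_new_start,
                truth$expected_mechanisms$exon_loss_new_start)
    return(tibble(kind = kind, events_ok = NA, classes_ok = classes_ok,
                  localization_ok = NA, verdict_ok = verdict_ok,
                  mechanisms_ok = mech_ok,
                  recovered = classes_ok && verdict_ok))
  }
  gene <- sim$genes[[1]]
  rep <- analyze_gene(gene, model, motifs, alt_start = kind == "ALT_TSS")
  exp <- truth$expected_isoforms
  obs <- rep$isoforms
  events_ok <- setequal(obs$event, exp$event)
  classes_ok <- NA
  localization_ok <- NA
  if (!all(is.na(exp$class))) {
    classes_ok <- events_ok &&
      all(purrr::map2_lgl(exp$event, exp$class,
                          ~ .y %in% obs$class[obs$event == .x]))
  }
  if ("localization" %in% names(exp)) {
    localization_ok <- events_ok &&
      all(purrr::map2_lgl(exp$event, exp$localization,
                          ~ .y %in% obs$localization[obs$event == .x]))
  }
  tibble(kind = kind, events_ok = events_ok, classes_ok = classes_ok,
         localization_ok = localization_ok, verdict_ok = NA,
         mechanisms_ok = NA,
         recovered = events_ok && (is.na(classes_ok) || classes_ok) &&
           (is.na(localization_ok) || localization_ok))
}

#' Score pipeline recovery over a whole synthetic corpus
#'
#' @param suite tibble from [generate_suite()]
#' @param model,motifs as in [analyze_gene()]
#' @return the manifest with the [evaluate_locus()] columns appended
#' @export
evaluate_suite <- function(suite, model = splice_signal_model(),
                           motifs = ski7_hbs1_motifs()) {
  res <- purrr::map(suite$locus, evaluate_locus, model = model, motifs = motifs)
  bind_cols(select(suite, "locus_id", "kind", "seed"),
            select(bind_rows(res), -"kind"))
}

#' Diagram a gene model with its intron candidates
#'
#' Exons are drawn as boxes on a baseline, candidate introns as arcs with
#' donor/branch/acceptor marks; alternative acceptors are highlighted.
#'
#' @param gene a [gene_model()]
#' @param introns optional tibble from [enumerate_introns()]
#' @return a ggplot
#' @export
plot_gene_model <- function(gene, introns = NULL) {
  ex <- mutate(gene$exons, what = "exon")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(ggplot2::aes(x = 1, xend = nchar(gene$seq)),
                          y = 0, yend = 0, linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_rect(data = ex,
                       ggplot2::aes(xmin = .data$start, xmax = .data$end),
                       ymin = -0.25, ymax = 0.25, fill = "grey75",
                       colour = "grey30") +
    ggplot2::labs(x = "position (nt)", y = NULL, title = gene$id) +
    ggplot2::scale_y_continuous(limits = c(-1, 1), breaks = NULL)
  if (!is.na(gene$cds_start)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(x = gene$cds_start, y = 0.35),
                                 shape = 25, fill = "black")
  }
  if (!is.null(introns) && nrow(introns) > 0) {
    sites <- tidyr::unnest(
      select(introns, "donor_pos", "acceptors"), "acceptors")
    p <- p +
      ggplot2::geom_curve(
        data = sites,
        ggplot2::aes(x = .data$donor_pos, xend = .data$acceptor_pos),
        y = 0.25, yend = 0.25, curvature = -0.35, colour = "firebrick") +
      ggplot2::geom_point(
        data = sites,
        ggplot2::aes(x = .data$acceptor_pos), y = 0.25, size = 1.5,
        colour = "firebrick")
  }
  p
}
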