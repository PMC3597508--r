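#' Predict transmembrane helices by windowed hydropathy
#'
#' A transparent heuristic stand-in for HMM-based TM predictors: mean
#' Kyte-Doolittle hydropathy over a sliding window; maximal runs of windows
#' at or above the threshold are merged into helices. The N-terminal flag is
#' set when a helix starts within the first `n_terminal_span` residues —
#' the signature of nuclear-envelope-targeted PP2C isoforms.
#'
#' @param protein amino-acid string
#' @param window window length in residues
#' @param threshold minimal mean hydropathy for a TM window
#' @param n_terminal_span span (residues) defining "N-terminal"
#' @return object of class `tm_prediction`: list with `scores` tibble
#'   (`pos` = window start, `hydropathy`), `helices` tibble
#'   (`start`, `end`, `mean_hydropathy`), `n_terminal_tm` flag
#' @export
hydropathy_tm <- function(protein, window = 19L, threshold = 1.6,
                          n_terminal_span = 60L) {
  aa <- chars(protein)
  kd <- unname(KD_SCALE[aa])
  kd[is.na(kd)] <- 0  # unknown residues treated as neutral
  n <- length(aa) - window + 1L
  if (n < 1L) {
    warn("protein shorter than the hydropathy window; no TM prediction")
    return(structure(list(
      scores = tibble(pos = integer(0), hydropathy = numeric(0)),
      helices = tibble(start = integer(0), end = integer(0),
                       mean_hydropathy = numeric(0)),
      n_terminal_tm = FALSE, window = window, threshold = threshold),
      class = "tm_prediction"))
  }
  means <- as.numeric(stats::filter(kd, rep(1 / window, window), sides = 1))
  means <- means[window:length(kd)]  # mean of window ending at that residue
  scores <- tibble(pos = seq_len(n), hydropathy = means)
  above <- scores$hydropathy >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  hel <- tibble(start = starts[r$values], end = ends[r$values] + window - 1L)
  hel$mean_hydropathy <- purrr::map2_dbl(hel$start, hel$end,
                                         ~ mean(kd[.x:.y]))
  structure(list(scores = scores, helices = hel,
                 n_terminal_tm = any(hel$start <= n_terminal_span),
                 window = window, threshold = threshold),
            class = "tm_prediction")
}

#' @export
print.tm_prediction <- function(x, ...) {
  cat(sprintf("<tm_prediction> %d helix(es); N-terminal TM: %s\n",
              nrow(x$helices), x$n_terminal_tm))
  invisible(x)
}

#' Mitochondrial targeting sequence score
#'
#' A transparent heuristic stand-in for presequence predictors, scored on the
#' first `span` residues: rises with Arg/Lys, falls with Asp/Glu, and rewards
#' Ser/Leu/Ala enrichment; monotone in each component and clamped to the unit interval.
#'
#' score = clamp(0.5 + 0.04 (nRK - nDE) + 0.25 (fSLA - 0.35), 0, 1)
#'
#' @param protein amino-acid string
#' @param span N-terminal span in residues
#' @return score between 0 and 1
#' @export
mts_score <- function(protein, span = 30L) {
  if (!nzchar(protein)) abort("mts_score: empty protein")
  head_aa <- chars(str_sub(protein, 1L, span))
  n_rk <- sum(head_aa %in% c("R", "K"))
  n_de <- sum(head_aa %in% c("D", "E"))
  f_sla <- mean(head_aa %in% c("S", "L", "A"))
  min(1, max(0, 0.5 + 0.04 * (n_rk - n_de) + 0.25 * (f_sla - 0.35)))
}

#' Localization call for a protein isoform
#'
#' Mirrors the PTC7 logic: an N-terminal transmembrane helix targets the
#' protein to the nuclear envelope and takes total precedence; otherwise a
#' mitochondrial targeting score at or above the cutoff calls mitochondrial;
#' otherwise `OTHER`.
#'
#' @param protein amino-acid string
#' @param mts_cutoff minimal MTS score for a mitochondrial call
#' @param ... passed to [hydropathy_tm()]
#' @return object of class `localization_call`: list with `call`
#'   (`NUCLEAR_ENVELOPE`, `MITOCHONDRIAL`, `OTHER`) and `evidence`
#' @export
localize <- function(protein, mts_cutoff = 0.5, ...) {
  tm <- suppressWarnings(hydropathy_tm(protein, ...))
  mts <- mts_score(protein)
  call <- if (tm$n_terminal_tm) "NUCLEAR_ENVELOPE"
          else if (mts >= mts_cutoff) "MITOCHONDRIAL"
          else "OTHER"
  structure(list(call = call,
                 evidence = list(n_terminal_tm = tm$n_terminal_tm,
                                 mts_score = mts, mts_cutoff = mts_cutoff,
                                 tm = tm),
                 provenance = "heuristic stand-in (windowed hydropathy + composition score)"),
            class = "localization_call")
}

#' @export
print.localization_call <- function(x, ...) {
  cat(sprintf("<localization_call> %s (N-terminal TM: %s, MTS score: %.2f)\n",
              x$call, x$evidence$n_terminal_tm, x$evidence$mts_score))
  invisible(x)
}

#' Plot a hydropathy profile with called helices
#'
#' @param object a `tm_prediction`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.tm_prediction <- function(object, ...) {
  p <- ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$pos, y = .data$hydropathy)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "window start (aa)", y = "mean Kyte-Doolittle hydropathy")
  if (nrow(object$helices) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$helices,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "steelblue",
      inherit.aes = FALSE)
  }
  p
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
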