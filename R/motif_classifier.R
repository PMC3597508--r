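#' Default Ski7/Hbs1 diagnostic motif set
#'
#' Degenerate consensus patterns for the Ski7-diagnostic motifs (S1, S2, S3),
#' the Hbs1 linker motif (H1), the GTPase motifs (G1-G5, with the
#' catalytically important His of G3 as a special position) and the structured
#' Hbs1 N-terminal domain (NTD, supporting evidence only). `X` positions match
#' any residue. These patterns are synthetic stand-ins distilled to mirror the
#' *roles* of the published motif maps, not matrices fitted to any alignment;
#' they are versioned configuration (see
#' `inst/extdata/motifs_synthetic_default.tsv`) and fully overridable.
#' The optional S1' motif (fission-yeast lineage) ships in the config but is
#' never used for classification.
#'
#' @return tibble with columns `id`, `pattern`, `threshold` (fraction of
#'   fixed positions that must match), `special_pos` (NA or position of the
#'   catalytic residue), `special_aa`, `in_class` (whether the motif enters
#'   classification)
#' @export
ski7_hbs1_motifs <- function() {
  tibble(
    id = c("NTD", "S1", "S2", "S3", "H1", "G1", "G2", "G3", "G4", "G5", "S1p"),
    pattern = c("DKEYNQWTGH",  # structured N-terminal domain (exon 1)
                "MSNEWKDR",    # Ski7 motif S1; starts with Met
                "QDHYTNKE",    # Ski7 motif S2
                "WNDQTKYE",    # Ski7 motif S3
                "KPNEYWSD",    # Hbs1 linker motif H1
                "GHNDSGKT",    # GTPase P-loop-like G1
                "RGDTKWSE",    # G2
                "DTPGHQDW",    # G3; position 5 is the catalytic His
                "NKGDEQTY",    # G4
                "SAGKWEDQ",    # G5
                "MSNEWKDS"),   # optional S1' variant; not used in classification
    threshold = 0.8,
    special_pos = c(NA, NA, NA, NA, NA, NA, NA, 5L, NA, NA, NA),
    special_aa = c(NA, NA, NA, NA, NA, NA, NA, "H", NA, NA, NA),
    in_class = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
}

#' Read / write a motif configuration TSV
#'
#' Columns as in [ski7_hbs1_motifs()].
#' @param path TSV file
#' @export
read_motifs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("id", "pattern", "threshold", "special_pos", "special_aa", "in_class")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) abort(sprintf("motif config missing column(s): %s",
                                      paste(miss, collapse = ", ")))
  bad <- which(df$threshold <= 0 | df$threshold > 1)
  if (length(bad) > 0) abort(sprintf("motif '%s': threshold must be in (0, 1]", df$id[bad[1]]))
  bad <- which(!is.na(df$special_pos) & df$special_pos > nchar(df$pattern))
  if (length(bad) > 0) abort(sprintf("motif '%s': special_pos beyond pattern", df$id[bad[1]]))
  as_tibble(df)
}

#' @rdname read_motifs
#' @param motifs motif tibble
#' @export
write_motifs <- function(motifs, path) {
  utils::write.table(motifs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

score_motif_windows <- function(protein, pattern) {
  m <- nchar(pattern)
  n <- nchar(protein) - m + 1L
  if (n < 1L) return(numeric(0))
  pat <- chars(pattern)
  fixed <- which(pat != "X")
  aa <- chars(protein)
  sc <- numeric(n)
  for (j in fixed) sc <- sc + (aa[j:(j + n - 1L)] == pat[j])
  sc / length(fixed)
}

#' Scan a protein for diagnostic motifs
#'
#' Reports the single best hit per motif when it reaches the motif's match
#' threshold (fraction of fixed pattern positions matched); motifs without a
#' qualifying hit are absent from the result. Ties go to the leftmost window.
#'
#' @param protein amino-acid string
#' @param motifs motif tibble from [ski7_hbs1_motifs()] or [read_motifs()]
#' @return tibble with `id`, `start` (1-based aa offset), `score`,
#'   `special_residue` (residue at the motif's special position, or NA)
#' @export
scan_motifs <- function(protein, motifs = ski7_hbs1_motifs()) {
  if (!nzchar(protein)) abort("scan_motifs: empty protein")
  rows <- purrr::pmap(motifs, function(id, pattern, threshold, special_pos,
                                       special_aa, in_class, ...) {
    sc <- score_motif_windows(protein, pattern)
    if (length(sc) == 0) return(NULL)
    best <- which.max(sc)
    if (sc[best] < threshold) return(NULL)
    sp <- if (!is.na(special_pos)) str_sub(protein, best + special_pos - 1L,
                                           best + special_pos - 1L) else NA_character_
    tibble(id = id, start = as.integer(best), score = sc[best],
           special_residue = sp)
  })
  out <- bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    return(tibble(id = character(0), start = integer(0), score = numeric(0),
                  special_residue = character(0)))
  }
  out
}

#' Is the catalytic histidine of motif G3 intact?
#'
#' Post-duplication Ski7-type proteins replace the catalytically important
#' His of GTPase motif G3 (typically with Ser, Asn or Asp); only an intact
#' His supports Hbs1-type GTPase function.
#'
#' @param g3_hit one-row tibble for the G3 hit (from [scan_motifs()])
#' @return `TRUE` iff the residue at the special position is H
#' @export
catalytic_his_ok <- function(g3_hit) {
  if (is.null(g3_hit) || nrow(g3_hit) == 0) abort("catalytic_his_ok: no G3 hit")
  identical(g3_hit$special_residue[[1]], "H")
}

#' Classify a protein isoform by its motif complement
#'
#' Hbs1-type criteria: motif H1 present, all of G1-G5 present, and the G3
#' catalytic His intact. Ski7-type criteria: motifs S1, S2 and S3 present.
#' `DUAL` when both criterion sets hold, `NEITHER` when neither. NTD presence
#' is recorded as supporting (not required) evidence for the Hbs1 side. The
#' expected motif order along the sequence (NTD, S1, S2, S3, H1, G1-G5) is a
#' soft check: violations lower `confidence` but never change the class.
#'
#' @param hits tibble from [scan_motifs()]
#' @return object of class `functional_class`: list with `class`
#'   (`SKI7_LIKE`, `HBS1_LIKE`, `DUAL`, `NEITHER`), `evidence` tibble,
#'   `confidence` (`"high"` or `"reduced"`)
#' @export
classify_isoform <- function(hits) {
  has <- function(id) id %in% hits$id
  g_all <- all(vapply(paste0("G", 1:5), has, logical(1)))
  his_ok <- if (has("G3")) catalytic_his_ok(hits[hits$id == "G3", ]) else FALSE
  ski7 <- c(S1 = has("S1"), S2 = has("S2"), S3 = has("S3"))
  hbs1 <- c(H1 = has("H1"), G1_G5 = g_all, G3_catalytic_His = his_ok)
  cls <- if (all(ski7) && all(hbs1)) "DUAL"
         else if (all(ski7)) "SKI7_LIKE"
         else if (all(hbs1)) "HBS1_LIKE"
         else "NEITHER"
  evidence <- bind_rows(
    tibble(criterion = names(ski7), side = "SKI7", satisfied = unname(ski7)),
    tibble(criterion = names(hbs1), side = "HBS1", satisfied = unname(hbs1)),
    tibble(criterion = "NTD_supporting", side = "HBS1_support",
           satisfied = has("NTD"))
  )
  # soft order check on the hits that are present
  expected <- c("NTD", "S1", "S2", "S3", "H1", paste0("G", 1:5))
  present <- hits[hits$id %in% expected, ]
  present <- present[order(match(present$id, expected)), ]
  ordered <- nrow(present) < 2 || !is.unsorted(present$start, strictly = FALSE)
  structure(list(class = cls, evidence = evidence,
                 confidence = if (ordered) "high" else "reduced"),
            class = "functional_class")
}

#' @export
print.functional_class <- function(x, ...) {
  cat(sprintf("<functional_class> %s (confidence: %s)\n", x$class, x$confidence))
  ok <- x$evidence$criterion[x$evidence$satisfied]
  if (length(ok)) cat("  satisfied:", paste(ok, collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Tidy the evidence underlying a functional classification
#' @param x a `functional_class` object
#' @param ... unused
#' @export
tidy.functional_class <- function(x, ...) x$evidence

#' One-row summary of a functional classification
#' @param x a `functional_class` object
#' @param ... unused
#' @export
glance.functional_class <- function(x, ...) {
  tibble(class = x$class, confidence = x$confidence,
         n_criteria_satisfied = sum(x$evidence$satisfied))
}
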