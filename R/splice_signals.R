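#' Build a position weight matrix from aligned sites
#'
#' Per-column letter frequencies with a pseudocount added per letter and
#' renormalized, plus log-odds against a uniform 0.25 background (base 2).
#'
#' @param sites character vector of equal-length A/C/G/T strings (>= 1)
#' @param pseudocount number added to each letter count per column
#' @return object of class `pwm`: list with `prob` and `logodds` 4 x L
#'   matrices (rows A, C, G, T) and the maximal attainable score `max_score`
#' @export
build_pwm <- function(sites, pseudocount = 0.5) {
  if (length(sites) == 0) abort("build_pwm: need at least one site")
  L <- unique(nchar(sites))
  if (length(L) != 1) abort("build_pwm: sites must have equal length")
  mat <- do.call(rbind, strsplit(toupper(sites), ""))
  if (any(!mat %in% NT)) abort("build_pwm: sites must contain only A/C/G/T")
  counts <- apply(mat, 2, function(col) {
    vapply(NT, function(b) sum(col == b) + pseudocount, numeric(1))
  })
  prob <- sweep(counts, 2, colSums(counts), "/")
  rownames(prob) <- NT
  logodds <- log2(prob / 0.25)
  structure(list(prob = prob, logodds = logodds,
                 max_score = sum(apply(logodds, 2, max)), n_sites = length(sites)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %d columns, %d training sites, max log-odds %.2f\n",
              ncol(x$prob), x$n_sites, x$max_score))
  invisible(x)
}

pwm_length <- function(pwm) ncol(pwm$prob)

# Score every window of seq against the pwm; windows with ambiguity codes get
# -Inf. Vectorized over positions.
score_windows <- function(seq, pwm) {
  L <- pwm_length(pwm)
  n <- nchar(seq) - L + 1L
  if (n < 1L) return(numeric(0))
  v <- chars(seq)
  idx <- match(v, NT)  # NA for ambiguity codes
  sc <- numeric(n)
  ok <- rep(TRUE, n)
  for (j in seq_len(L)) {
    col_idx <- idx[j:(j + n - 1L)]
    miss <- is.na(col_idx)
    ok <- ok & !miss
    col_idx[miss] <- 1L
    sc <- sc + unname(pwm$logodds[, j])[col_idx]
  }
  sc[!ok] <- -Inf
  unname(sc)
}

#' Scan a sequence with a PWM
#'
#' Reports every window whose log-odds score meets the threshold, sorted by
#' position. Windows containing ambiguity codes are skipped (conservative:
#' an N can never be part of a splice signal).
#'
#' @param seq nucleotide string
#' @param pwm object from [build_pwm()]
#' @param threshold absolute log-odds cutoff
#' @return tibble with `pos` (1-based window start) and `score`
#' @export
scan_signal <- function(seq, pwm, threshold) {
  sc <- score_windows(seq, pwm)
  keep <- which(sc >= threshold)
  tibble(pos = keep, score = sc[keep])
}

#' Default fungal splice-signal model
#'
#' Bundles the three signal PWMs with the geometric constraints used for
#' intron enumeration. Training sites default to the canonical budding-yeast
#' consensus signals (donor GTATGT with the GTAAGT variant, branch point
#' TACTAAC, acceptor TAG/CAG); they are configuration, not measurements, and
#' can be overridden with matrices trained on any alignment.
#'
#' Score thresholds are expressed as fractions of each PWM's maximal log-odds
#' score. The defaults (donor 0.90, branch 0.80, acceptor 0.60) admit only
#' consensus-matching donors and branch points and exactly the TAG/CAG
#' acceptors, which keeps the genome-scale false-candidate rate negligible.
#'
#' @param donor_sites,branch_sites,acceptor_sites training sites per signal
#' @param pseudocount pseudocount for [build_pwm()]
#' @param min_intron_len,max_intron_len intron length bounds in nt
#' @param branch_to_acceptor_window allowed distance (nt) from branch-point
#'   heptamer start to the final G of the acceptor
#' @param thresholds named fractions of maximal log-odds per signal
#' @return object of class `splice_signal_model`
#' @export
splice_signal_model <- function(donor_sites = c("GTATGT", "GTAAGT"),
                                branch_sites = "TACTAAC",
                                acceptor_sites = c("TAG", "CAG"),
                                pseudocount = 0.5,
                                min_intron_len = 40L,
                                max_intron_len = 1000L,
                                branch_to_acceptor_window = c(10L, 200L),
                                thresholds = c(donor = 0.90, branch = 0.80,
                                               acceptor = 0.60)) {
  stopifnot(min_intron_len < max_intron_len, branch_to_acceptor_window[1] >= 1)
  donor <- build_pwm(donor_sites, pseudocount)
  branch <- build_pwm(branch_sites, pseudocount)
  acceptor <- build_pwm(acceptor_sites, pseudocount)
  structure(list(
    donor_pwm = donor, branch_pwm = branch, acceptor_pwm = acceptor,
    min_intron_len = as.integer(min_intron_len),
    max_intron_len = as.integer(max_intron_len),
    branch_to_acceptor_window = as.integer(branch_to_acceptor_window),
    thresholds = thresholds,
    cutoffs = c(donor = unname(thresholds["donor"]) * donor$max_score,
                branch = unname(thresholds["branch"]) * branch$max_score,
                acceptor = unname(thresholds["acceptor"]) * acceptor$max_score)
  ), class = "splice_signal_model")
}

#' @export
print.splice_signal_model <- function(x, ...) {
  cat(sprintf(paste0("<splice_signal_model> intron %d-%d nt, branch->acceptor %d-%d nt\n",
                     "  cutoffs: donor %.2f, branch %.2f, acceptor %.2f (log-odds)\n"),
              x$min_intron_len, x$max_intron_len,
              x$branch_to_acceptor_window[1], x$branch_to_acceptor_window[2],
              x$cutoffs["donor"], x$cutoffs["branch"], x$cutoffs["acceptor"]))
  invisible(x)
}

#' Enumerate candidate introns, including alternative 3' splice sites
#'
#' For each donor passing its threshold, the best-scoring compatible branch
#' point is selected (ties broken leftmost), and every acceptor satisfying
#' the geometry (intron length bounds, branch-to-acceptor window, terminal
#' AG) is collected. Candidates with two or more acceptors are flagged
#' alternatively spliced; acceptors are ordered proximal to distal.
#'
#' @param gene a [gene_model()] (or a plain nucleotide string)
#' @param model a [splice_signal_model()]
#' @return tibble with one row per candidate: `donor_pos` (first nt of the
#'   intron, the G of GT), `donor_score`, `branch_pos` (heptamer start),
#'   `branch_score`, `acceptors` (list column of tibbles with `acceptor_pos`,
#'   the final G of the intron, and `score`), `n_acceptors`, `alternative`
#' @export
enumerate_introns <- function(gene, model = splice_signal_model()) {
  seq <- if (inherits(gene, "gene_model")) gene$seq else toupper(gene)
  empty <- tibble(donor_pos = integer(0), donor_score = numeric(0),
                  branch_pos = integer(0), branch_score = numeric(0),
                  acceptors = list(), n_acceptors = integer(0),
                  alternative = logical(0))
  if (nchar(seq) < model$min_intron_len) return(empty)

  donors <- scan_signal(seq, model$donor_pwm, model$cutoffs["donor"])
  # candidate donors must open the intron with GT
  donors <- donors[str_sub(seq, donors$pos, donors$pos + 1L) == "GT", ]
  if (nrow(donors) == 0) return(empty)
  branches <- scan_signal(seq, model$branch_pwm, model$cutoffs["branch"])
  acc_win <- scan_signal(seq, model$acceptor_pwm, model$cutoffs["acceptor"])
  acc_len <- pwm_length(model$acceptor_pwm)
  # acceptor_pos = final G of the intron
  acceptors <- tibble(acceptor_pos = acc_win$pos + acc_len - 1L, score = acc_win$score)
  acceptors <- acceptors[str_sub(seq, acceptors$acceptor_pos - 1L,
                                 acceptors$acceptor_pos) == "AG", ]
  if (nrow(branches) == 0 || nrow(acceptors) == 0) return(empty)

  bw <- model$branch_to_acceptor_window
  blen <- pwm_length(model$branch_pwm)
  dlen <- pwm_length(model$donor_pwm)

  rows <- purrr::map(seq_len(nrow(donors)), function(i) {
    dpos <- donors$pos[i]
    cand_b <- branches[branches$pos > dpos + dlen - 1L, , drop = FALSE]
    if (nrow(cand_b) == 0) return(NULL)
    # acceptors compatible with a given branch
    best <- NULL
    for (k in order(-cand_b$score, cand_b$pos)) {
      bpos <- cand_b$pos[k]
      acc <- acceptors[
        acceptors$acceptor_pos - bpos >= max(bw[1], blen) &
        acceptors$acceptor_pos - bpos <= bw[2] &
        acceptors$acceptor_pos - dpos + 1L >= model$min_intron_len &
        acceptors$acceptor_pos - dpos + 1L <= model$max_intron_len, , drop = FALSE]
      if (nrow(acc) > 0) {
        best <- list(bpos = bpos, bscore = cand_b$score[k],
                     acc = arrange(acc, .data$acceptor_pos))
        break
      }
    }
    if (is.null(best)) return(NULL)
    tibble(donor_pos = dpos, donor_score = donors$score[i],
           branch_pos = best$bpos, branch_score = best$bscore,
           acceptors = list(best$acc), n_acceptors = nrow(best$acc),
           alternative = nrow(best$acc) >= 2L)
  })
  out <- bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) empty else arrange(out, .data$donor_pos)
}

#' Derive intron candidates from an annotated exon structure
#'
#' Gaps between consecutive annotated exons become single-acceptor intron
#' candidates (scores `NA`), so annotation-driven and signal-driven gene
#' models feed the same isoform machinery.
#'
#' @param gene a [gene_model()] with >= 2 exons
#' @return tibble in the format of [enumerate_introns()]
#' @export
introns_from_annotation <- function(gene) {
  ex <- gene$exons
  if (nrow(ex) < 2) {
    return(tibble(donor_pos = integer(0), donor_score = numeric(0),
                  branch_pos = integer(0), branch_score = numeric(0),
                  acceptors = list(), n_acceptors = integer(0),
                  alternative = logical(0)))
  }
  tibble(
    donor_pos = ex$end[-nrow(ex)] + 1L,
    donor_score = NA_real_,
    branch_pos = NA_integer_,
    branch_score = NA_real_,
    acceptors = purrr::map(ex$start[-1] - 1L,
                           ~ tibble(acceptor_pos = .x, score = NA_real_)),
    n_acceptors = 1L,
    alternative = FALSE
  )
}

#' Candidate splice sites as a BED-style tibble
#'
#' @param introns tibble from [enumerate_introns()]
#' @param gene_id sequence name for the first BED column
#' @return tibble with 0-based half-open `start`/`end` (BED convention),
#'   `name` and `score` columns
#' @export
splice_sites_bed <- function(introns, gene_id = "locus") {
  if (nrow(introns) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  name = character(0), score = numeric(0)))
  }
  rows <- purrr::pmap(introns, function(donor_pos, donor_score, branch_pos,
                                        branch_score, acceptors, ...) {
    bind_rows(
      tibble(start = donor_pos - 1L, end = donor_pos + 1L,
             name = "donor_5ss", score = donor_score),
      tibble(start = branch_pos - 1L, end = branch_pos + 6L,
             name = "branch_point", score = branch_score),
      tibble(start = acceptors$acceptor_pos - 2L, end = acceptors$acceptor_pos,
             name = if (nrow(acceptors) == 1) "acceptor_3ss"
                    else paste0("acceptor_3ss_", seq_len(nrow(acceptors))),
             score = acceptors$score)
    )
  })
  mutate(bind_rows(rows), chrom = gene_id, .before = 1)
}
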