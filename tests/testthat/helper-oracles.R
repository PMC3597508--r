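# Independent oracles: deliberately dumb, self-contained re-implementations
# used to cross-check the package. They share only model *parameters* with
# the implementation, never code paths.

# The standard genetic code, written out by hand.
STD_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(cds, code = STD_CODE) {
  n <- nchar(cds) %/% 3
  out <- character(0)
  for (i in seq_len(n)) {
    aa <- unname(code[substr(cds, 3 * i - 2, 3 * i)])
    if (is.na(aa)) aa <- "X"
    if (aa == "*") break
    out <- c(out, aa)
  }
  paste(out, collapse = "")
}

# plain per-window log-odds score from the PWM probability matrix
oracle_score <- function(seq_chars, pos, prob) {
  L <- ncol(prob)
  s <- 0
  for (j in seq_len(L)) {
    b <- seq_chars[pos + j - 1]
    if (!b %in% rownames(prob)) return(-Inf)
    s <- s + log2(prob[b, j] / 0.25)
  }
  unname(s)
}

# exhaustive GT..AG enumeration under the same geometry and thresholds,
# with the same best-branch-per-donor rule (max score, ties leftmost)
oracle_enumerate <- function(seq, model) {
  v <- strsplit(seq, "")[[1]]
  L <- length(v)
  dlen <- ncol(model$donor_pwm$prob)
  blen <- ncol(model$branch_pwm$prob)
  alen <- ncol(model$acceptor_pwm$prob)
  bw <- model$branch_to_acceptor_window
  out <- list()
  for (i in seq_len(max(0, L - dlen + 1))) {
    if (i + 1 > L || v[i] != "G" || v[i + 1] != "T") next
    ds <- oracle_score(v, i, model$donor_pwm$prob)
    if (ds < model$cutoffs["donor"]) next
    best <- NULL
    for (j in seq(i + dlen, max(i + dlen, L - blen + 1))) {
      if (j + blen - 1 > L) break
      bs <- oracle_score(v, j, model$branch_pwm$prob)
      if (bs < model$cutoffs["branch"]) next
      accs <- integer(0); asc <- numeric(0)
      a_lo <- j + max(bw[1], blen); a_hi <- min(j + bw[2], L)
      if (a_lo > a_hi) next
      for (a in seq(a_lo, a_hi)) {
        if (a < 2 || v[a - 1] != "A" || v[a] != "G") next
        ilen <- a - i + 1
        if (ilen < model$min_intron_len || ilen > model$max_intron_len) next
        sc <- oracle_score(v, a - alen + 1, model$acceptor_pwm$prob)
        if (sc < model$cutoffs["acceptor"]) next
        accs <- c(accs, a); asc <- c(asc, sc)
      }
      if (length(accs) == 0) next
      if (is.null(best) || bs > best$bs) {
        best <- list(j = j, bs = bs, accs = accs, asc = asc)
      }
    }
    if (!is.null(best)) {
      out[[length(out) + 1]] <- list(donor = i, dscore = ds,
                                     branch = best$j, bscore = best$bs,
                                     acceptors = best$accs)
    }
  }
  out
}

same_candidates <- function(found, oracle) {
  if (nrow(found) != length(oracle)) return(FALSE)
  for (i in seq_along(oracle)) {
    o <- oracle[[i]]
    if (found$donor_pos[i] != o$donor) return(FALSE)
    if (found$branch_pos[i] != o$branch) return(FALSE)
    if (!identical(found$acceptors[[i]]$acceptor_pos, as.integer(o$acceptors))) {
      return(FALSE)
    }
  }
  TRUE
}

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# minimal single-intron gene with a functional (3n, stop-free) retainable
# intron and an alternative distal acceptor in the downstream exon
toy_alt_gene <- function() {
  intron <- paste0("GTATGT", strrep("GCT", 6), "TTACTAACC", strrep("CTT", 2), "CAG")
  stopifnot(nchar(intron) == 42)
  seq <- paste0("ATGGCT", intron, paste0(strrep("GCT", 5), "CAG"),
                "GCTGCTTAA", strrep("CT", 10))
  gene_model("toy_alt", seq, cds_start = 1L)
}
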