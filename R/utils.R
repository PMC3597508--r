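#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr filter mutate arrange select bind_rows bind_cols group_by summarise ungroup
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_dbl map_lgl map_int pmap imap
#' @importFrom stringr str_sub str_detect str_length str_locate_all
#' @importFrom vctrs vec_cast
NULL

NT <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Average (not monoisotopic) residue masses in Da; free water added once per chain.
AA_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

# Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

is_valid_nt <- function(seq) {
  !str_detect(seq, "[^ACGTNRYSWKMBDHVU]")
}

#' Split a nucleotide string into codons
#'
#' Trailing bases that do not fill a codon are dropped.
#' @param seq nucleotide string
#' @return character vector of 3-nt codons
#' @keywords internal
split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, by = 3L, length.out = n), seq(3L, by = 3L, length.out = n))
}

codon_table <- function(genetic_code = 1L) {
  if (!genetic_code %in% c(1L, 12L)) {
    abort(sprintf("unsupported genetic code id: %s (only 1 and 12)", genetic_code))
  }
  Biostrings::getGeneticCode(as.character(genetic_code))
}

# Codons safe for use inside splice-geometry windows of simulated loci: no stop
# codons, no CAG, no AG-initial codons, no codons ending in TA/CA.  With these
# constraints no TAG/CAG trinucleotide can arise at any frame offset within or
# across codons, so planted acceptors are the only YAG sites in the window.
# Every amino acid retains at least one codon.
safe_codons_for <- function(aa, genetic_code = 1L) {
  tab <- codon_table(genetic_code)
  cods <- names(tab)[tab == aa]
  ok <- !cods %in% c(STOP_CODONS, "CAG") &
    !startsWith(cods, "AG") &
    !endsWith(cods, "TA") & !endsWith(cods, "CA")
  cods[ok]
}

#' Encode a protein as nucleotides using acceptor-window-safe codons
#' @keywords internal
encode_protein <- function(protein, genetic_code = 1L) {
  if (!nzchar(protein)) return("")
  paste(vapply(chars(protein), function(a) {
    cods <- safe_codons_for(a, genetic_code)
    if (length(cods) == 0L) abort(sprintf("no safe codon for residue '%s'", a))
    sample(cods, 1L)
  }, character(1)), collapse = "")
}

# Random nucleotides at a given GC content avoiding the given trinucleotides.
sample_nt <- function(n, gc = 0.4, banned = c("TAG", "CAG"), context_left = "",
                      context_right = "", max_iter = 200L) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  draw <- function(k) paste(sample(NT, k, replace = TRUE, prob = p), collapse = "")
  s <- draw(n)
  for (i in seq_len(max_iter)) {
    full <- paste0(context_left, s, context_right)
    hit <- NA_integer_
    for (b in banned) {
      loc <- str_locate_all(full, stringr::fixed(b))[[1]]
      if (nrow(loc) > 0) { hit <- loc[1, 1]; break }
    }
    if (is.na(hit)) return(s)
    # resample one base of the offending trinucleotide that falls inside s
    off <- (hit:(hit + 2)) - nchar(context_left)
    off <- off[off >= 1 & off <= n]
    if (length(off) == 0L) abort("banned motif entirely within fixed context")
    j <- sample(off, 1L)
    substr(s, j, j) <- sample(NT, 1L, prob = p)
  }
  abort("could not sample sequence avoiding banned motifs")
}

json_num <- function(x) unname(as.numeric(x))
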