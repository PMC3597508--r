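#' Construct a gene model
#'
#' A gene model is a locus on the sense strand: the nucleotide sequence, the
#' annotated exon structure (1-based inclusive intervals on `seq`), the offset
#' of the annotated start codon, and the genetic code used for translation
#' (1 = standard, 12 = alternative yeast nuclear, where CUG encodes serine).
#'
#' @param id gene identifier
#' @param seq nucleotide string (sense strand; uppercased, U mapped to T)
#' @param exons two-column data frame / tibble with `start` and `end`
#'   (1-based inclusive), non-overlapping and sorted. Defaults to a single
#'   exon spanning the whole sequence.
#' @param cds_start 1-based offset of the A of the annotated ATG, or `NA`
#' @param genetic_code integer NCBI table id, 1 or 12
#' @param skippable list of integer vectors: exon indices that may be skipped
#'   together in one event (e.g. `list(2)` or `list(c(4, 5))`)
#' @param source free-text provenance
#' @return an object of class `gene_model`
#' @export
gene_model <- function(id, seq, exons = NULL, cds_start = NA_integer_,
                       genetic_code = 1L, skippable = list(), source = "") {
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  if (!is_valid_nt(seq)) {
    bad <- regmatches(seq, regexpr("[^ACGTNRYSWKMBDHV]", seq))
    abort(sprintf("gene '%s': illegal character '%s' in sequence", id, bad))
  }
  if (is.null(exons)) exons <- tibble(start = 1L, end = nchar(seq))
  exons <- as_tibble(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  exons <- arrange(exons, .data$start)
  if (any(exons$end < exons$start)) abort(sprintf("gene '%s': empty exon", id))
  if (any(exons$end > nchar(seq)) || any(exons$start < 1L)) {
    abort(sprintf("gene '%s': exon outside sequence bounds", id))
  }
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    abort(sprintf("gene '%s': overlapping exons", id))
  }
  if (!is.na(cds_start)) {
    cds_start <- as.integer(cds_start)
    inside <- any(cds_start >= exons$start & cds_start <= exons$end)
    if (!inside) abort(sprintf("gene '%s': cds_start %d not within an exon", id, cds_start))
  }
  structure(
    list(id = id, seq = seq, exons = exons, cds_start = cds_start,
         genetic_code = as.integer(genetic_code), skippable = skippable,
         source = source),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: %d nt, %d exon(s), cds_start=%s, code=%d\n",
              x$id, nchar(x$seq), nrow(x$exons),
              ifelse(is.na(x$cds_start), "NA", x$cds_start), x$genetic_code))
  invisible(x)
}

#' Read a FASTA file into a tibble
#'
#' Sequences are uppercased and U is mapped to T; record order is preserved.
#'
#' @param path FASTA file
#' @return tibble with columns `id` (first word of the header) and `seq`
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(sprintf("FASTA parse error in %s: %s",
                                                    path, conditionMessage(e))))
  seqs <- gsub("U", "T", toupper(as.character(set)), fixed = TRUE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  bad <- which(!vapply(seqs, is_valid_nt, logical(1)))
  if (length(bad) > 0) {
    abort(sprintf("FASTA parse error: illegal character in record '%s'", ids[bad[1]]))
  }
  tibble(id = unname(ids), seq = unname(seqs))
}

#' Write sequences to FASTA
#' @param x tibble with `id` and `seq`, or a named character vector
#' @param path output file
#' @param width line width
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.data.frame(x)) x <- stats::setNames(x$seq, x$id)
  if (length(x) == 0) { file.create(path); return(invisible(path)) }
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

local_coords <- function(gstart, gend, span_start, span_end, strand) {
  if (strand == "+") {
    cbind(gstart - span_start + 1L, gend - span_start + 1L)
  } else {
    cbind(span_end - gend + 1L, span_end - gstart + 1L)
  }
}

#' Read gene models from a GFF3 file
#'
#' Builds one `gene_model` per mRNA. Coordinates are converted from GFF3's
#' 1-based inclusive genome coordinates to 1-based inclusive locus-local
#' coordinates on the sense strand; minus-strand genes are
#' reverse-complemented so `seq` always reads 5' to 3' in gene orientation.
#' An mRNA without CDS features yields a model with `cds_start = NA`, flagged
#' in `source`.
#'
#' @param path GFF3 file with gene/mRNA/exon/CDS features
#' @param fasta FASTA file (or tibble from [read_fasta()]) with the reference
#'   sequences named in column 1 of the GFF3
#' @return list of [gene_model()] objects
#' @export
read_gff3 <- function(path, fasta) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (is.character(fasta)) fasta <- read_fasta(fasta)
  refs <- stats::setNames(fasta$seq, fasta$id)

  feats <- as_tibble(as.data.frame(gr))
  feats$type <- as.character(feats$type)
  feats$seqnames <- as.character(feats$seqnames)
  feats$strand <- as.character(feats$strand)
  mrnas <- feats[feats$type %in% c("mRNA", "transcript"), ]
  out <- list()
  for (i in seq_len(nrow(mrnas))) {
    m <- mrnas[i, ]
    mid <- if (!is.null(m$ID)) m$ID[[1]] else sprintf("mrna_%d", i)
    kids <- feats[vapply(feats$Parent, function(p) mid %in% p, logical(1)), ]
    ex <- kids[kids$type == "exon", ]
    cds <- kids[kids$type == "CDS", ]
    ref <- refs[[m$seqnames]]
    if (is.null(ref)) abort(sprintf("GFF3 references unknown sequence '%s'", m$seqnames))
    if (nrow(ex) == 0) ex <- m[, c("seqnames", "start", "end", "strand")]
    span_start <- min(ex$start); span_end <- max(ex$end)
    if (span_end > nchar(ref)) {
      abort(sprintf("mRNA '%s': exon end %d outside sequence bounds (%d nt)",
                    mid, span_end, nchar(ref)))
    }
    locus_seq <- substr(ref, span_start, span_end)
    if (m$strand == "-") locus_seq <- revcomp(locus_seq)
    exl <- local_coords(ex$start, ex$end, span_start, span_end, m$strand)
    exons <- arrange(tibble(start = exl[, 1], end = exl[, 2]), .data$start)
    cds_start <- NA_integer_
    src <- sprintf("gff3:%s", basename(path))
    if (nrow(cds) > 0) {
      cl <- local_coords(cds$start, cds$end, span_start, span_end, m$strand)
      cds_start <- min(cl[, 1])
    } else {
      src <- paste0(src, ";no_cds")
    }
    out[[mid]] <- gene_model(id = mid, seq = locus_seq, exons = exons,
                             cds_start = cds_start, source = src)
  }
  out
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3()] for plus-strand, locus-local models: each model is
#' written against its own sequence id with gene/mRNA/exon/CDS rows.
#'
#' @param models list of [gene_model()] objects
#' @param path output file
#' @export
write_gff3 <- function(models, path) {
  rows <- purrr::map(models, function(g) {
    n_ex <- nrow(g$exons)
    gr <- GenomicRanges::GRanges(
      seqnames = g$id,
      ranges = IRanges::IRanges(
        start = c(1L, 1L, g$exons$start,
                  if (!is.na(g$cds_start)) g$cds_start),
        end = c(nchar(g$seq), nchar(g$seq), g$exons$end,
                if (!is.na(g$cds_start)) nchar(g$seq))),
      strand = "+")
    gr$type <- c("gene", "mRNA", rep("exon", n_ex),
                 if (!is.na(g$cds_start)) "CDS")
    gr$ID <- c(paste0(g$id, ".gene"), g$id,
               paste0(g$id, ".exon", seq_len(n_ex)),
               if (!is.na(g$cds_start)) paste0(g$id, ".cds"))
    gr$Parent <- c(NA, paste0(g$id, ".gene"), rep(g$id, n_ex),
                   if (!is.na(g$cds_start)) g$id)
    gr$phase <- c(rep(NA_integer_, 2 + n_ex),
                  if (!is.na(g$cds_start)) 0L)
    gr
  })
  gr <- suppressWarnings(do.call(c, unname(rows)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write isoform sequences to nucleotide and protein FASTA files
#'
#' Headers encode gene id, event type and isoform index; protein records end
#' at the first stop. Records are ordered deterministically by event type and
#' position detail.
#'
#' @param isoforms isoform tibble from [enumerate_isoforms()]
#' @param path_nt nucleotide FASTA output path
#' @param path_aa protein FASTA output path
#' @export
write_isoforms <- function(isoforms, path_nt, path_aa) {
  if (nrow(isoforms) == 0) {
    file.create(path_nt); file.create(path_aa)
    return(invisible(c(path_nt, path_aa)))
  }
  iso <- arrange(isoforms, .data$event, .data$detail)
  hdr <- sprintf("%s|%s|%d", iso$gene_id, iso$event, seq_len(nrow(iso)))
  write_fasta(stats::setNames(iso$mrna, hdr), path_nt)
  write_fasta(stats::setNames(iso$protein, hdr), path_aa)
  invisible(c(path_nt, path_aa))
}
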