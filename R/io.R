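#' Read a locus catalog from GFF3
#'
#' On-disk GFF3 uses 1-based closed intervals; the returned catalog uses
#' 0-based half-open coordinates. The RNA class and NAT pairing are stored
#' in the `rna_class` and `partner_id` attribute keys.
#'
#' @param path GFF3 file.
#' @return a [locus_catalog()].
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  getcol <- function(name) {
    if (name %in% names(m)) as.character(m[[name]]) else
      rep(NA_character_, length(gr))
  }
  feats <- data.frame(
    id = getcol("ID"),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,  # 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    rna_class = getcol("rna_class"),
    partner_id = getcol("partner_id"),
    family = getcol("family"),
    stringsAsFactors = FALSE
  )
  if (anyNA(feats$id)) stop("read_gff3: every feature needs an ID attribute",
                            call. = FALSE)
  feats$rna_class[is.na(feats$rna_class)] <- "other"
  locus_catalog(feats)
}

#' Write a locus catalog to GFF3
#'
#' @param cat a [locus_catalog()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(cat, path) {
  gr <- catalog_granges(cat)
  S4Vectors::mcols(gr)$type <- cat$rna_class
  S4Vectors::mcols(gr)$ID <- cat$id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read/write a count matrix (features x samples) as TSV
#'
#' First column `feature` holds feature ids; remaining columns are samples.
#'
#' @param path TSV file.
#' @return integer matrix with feature rownames.
#' @export
read_counts <- function(path) {
  df <- read_tsv_file(path, required = "feature")
  m <- as.matrix(df[, setdiff(names(df), "feature"), drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- df$feature
  m
}

#' @rdname read_counts
#' @param counts matrix to write.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(feature = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}

#' Read a sample design sheet
#'
#' Requires columns `sample`, `condition` (control/cold), `time`
#' (3h/6h/2d) and `replicate`.
#'
#' @param path TSV file.
#' @return data frame.
#' @export
read_design <- function(path) {
  d <- read_tsv_file(path, required = c("sample", "condition", "time",
                                        "replicate"))
  validate_design(d)
  d
}

validate_design <- function(design) {
  if (!all(design$condition %in% c("control", "cold"))) {
    stop("design: condition must be 'control' or 'cold'", call. = FALSE)
  }
  if (!all(design$time %in% TIME_POINTS)) {
    stop("design: time must be one of ", paste(TIME_POINTS, collapse = "/"),
         call. = FALSE)
  }
  invisible(design)
}

#' Read/write sequences as FASTA
#'
#' Thin wrappers over Biostrings, returning plain named character vectors
#' (DNA alphabet, U converted to T on read).
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- as_dna(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(as_dna(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80)
  invisible(path)
}
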