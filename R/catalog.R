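#' Locus catalog of sRNA-producing and transcript features
#'
#' A `locus_catalog` is a data frame of genomic features typed by RNA class,
#' with optional NAT pairing partners and miRNA family labels. Coordinates
#' are held internally as 0-based half-open intervals; GFF3 input/output
#' converts to and from the on-disk 1-based closed convention.
#'
#' @param features data frame with columns `id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`), `rna_class`, and
#'   optionally `partner_id` and `family`.
#' @return an object of class `locus_catalog`.
#' @export
locus_catalog <- function(features) {
  req <- c("id", "chrom", "start", "end", "strand", "rna_class")
  missing <- setdiff(req, names(features))
  if (length(missing)) {
    stop("locus_catalog: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"partner_id" %in% names(features)) features$partner_id <- NA_character_
  if (!"family" %in% names(features)) features$family <- NA_character_
  features$start <- as.numeric(features$start)
  features$end <- as.numeric(features$end)
  if (anyDuplicated(features$id)) {
    stop("locus_catalog: duplicate feature ids", call. = FALSE)
  }
  if (any(features$start >= features$end)) {
    stop("locus_catalog: start must be < end for every feature", call. = FALSE)
  }
  if (!all(features$strand %in% c("+", "-"))) {
    stop("locus_catalog: strand must be '+' or '-'", call. = FALSE)
  }
  if (!all(features$rna_class %in% RNA_CLASSES)) {
    stop("locus_catalog: unknown rna_class value(s): ",
         paste(setdiff(features$rna_class, RNA_CLASSES), collapse = ", "),
         call. = FALSE)
  }
  obj <- structure(features, class = c("locus_catalog", "data.frame"))
  validate_catalog_pairings(obj)
  obj
}

# Partner symmetry and the cis/trans overlap contracts.
validate_catalog_pairings <- function(cat) {
  paired <- !is.na(cat$partner_id)
  if (!any(paired)) return(invisible(TRUE))
  idx <- match(cat$partner_id[paired], cat$id)
  if (anyNA(idx)) {
    stop("locus_catalog: partner_id refers to unknown feature", call. = FALSE)
  }
  back <- cat$partner_id[idx]
  if (anyNA(back) || !all(back == cat$id[paired])) {
    stop("locus_catalog: partner_id must be symmetric (A<->B)", call. = FALSE)
  }
  a <- which(paired)
  b <- idx
  same_chrom <- cat$chrom[a] == cat$chrom[b]
  ovl <- same_chrom & (pmin(cat$end[a], cat$end[b]) >
                         pmax(cat$start[a], cat$start[b]))
  is_cis <- cat$rna_class[a] == "cis_NAT"
  if (any(is_cis & !(ovl & cat$strand[a] != cat$strand[b]))) {
    stop("locus_catalog: cis_NAT partners must overlap on opposite strands",
         call. = FALSE)
  }
  is_trans <- cat$rna_class[a] == "trans_NAT"
  if (any(is_trans & ovl)) {
    stop("locus_catalog: trans_NAT partners must not overlap", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.locus_catalog <- function(x, ...) {
  tab <- table(x$rna_class)
  cat(sprintf("locus_catalog: %d features on %d sequence(s)\n",
              nrow(x), length(unique(x$chrom))))
  for (cl in names(tab)) cat(sprintf("  %-10s %d\n", cl, tab[[cl]]))
  invisible(x)
}

# GRanges view of the catalog (1-based closed, as GRanges requires).
catalog_granges <- function(cat) {
  GenomicRanges::GRanges(
    seqnames = cat$chrom,
    ranges = IRanges::IRanges(start = cat$start + 1, end = cat$end),
    strand = cat$strand,
    id = cat$id, rna_class = cat$rna_class,
    partner_id = cat$partner_id, family = cat$family
  )
}
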