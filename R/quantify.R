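#' Assign sRNA clusters to RNA classes
#'
#' Each cluster receives exactly one class label. When a cluster overlaps
#' features of several classes the label is chosen by class precedence
#' (miRNA > cis_NAT > trans_NAT > TAS > PHAS > lncRNA > tRNA_like >
#' TE_repeat > other); ties within a class are broken by maximal overlap,
#' then lexicographic feature id. Clusters overlapping nothing are labeled
#' `"other"`. Overlap with cis_NAT features is strand-aware (the cluster
#' must be antisense to at least one partner by construction of the pair,
#' so any-strand overlap with either partner counts); all other classes are
#' strand-agnostic.
#'
#' @param clusters data frame with columns `id`, `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `strand`.
#' @param catalog a [locus_catalog()].
#' @param rule `"precedence"` (default) or `"max_overlap"`, which ignores
#'   class precedence and keeps the feature with the largest overlap.
#' @return named character vector: cluster id -> rna_class.
#' @export
assign_class <- function(clusters, catalog, rule = c("precedence",
                                                     "max_overlap")) {
  rule <- match.arg(rule)
  bad <- !is.finite(clusters$start) | !is.finite(clusters$end) |
    clusters$start >= clusters$end
  if (any(bad)) {
    stop(sprintf("assign_class: malformed interval at row(s) %s",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  qry <- GenomicRanges::GRanges(
    seqnames = clusters$chrom,
    ranges = IRanges::IRanges(start = clusters$start + 1,
                              end = clusters$end))
  sbj <- catalog_granges(catalog)
  hits <- GenomicRanges::findOverlaps(qry, sbj, ignore.strand = TRUE)
  out <- rep("other", nrow(clusters))
  names(out) <- clusters$id
  if (length(hits) == 0) return(out)

  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ovl <- GenomicRanges::width(GenomicRanges::pintersect(
    qry[qh], sbj[sh], ignore.strand = TRUE))
  cls <- catalog$rna_class[sh]
  prec <- match(cls, RNA_CLASSES)
  fid <- catalog$id[sh]

  for (q in unique(qh)) {
    sel <- which(qh == q)
    if (rule == "precedence") {
      ord <- order(prec[sel], -ovl[sel], fid[sel])
    } else {
      ord <- order(-ovl[sel], prec[sel], fid[sel])
    }
    out[q] <- cls[sel[ord[1]]]
  }
  out
}

#' Reads-per-million normalization
#'
#' Scales each sample (column) so that its total over all features is 1e6.
#'
#' @param counts numeric matrix, features x samples.
#' @return matrix of the same shape in RPM units.
#' @export
rpm <- function(counts) {
  cs <- colSums(counts)
  zero <- cs <= 0
  if (any(zero)) {
    stop("rpm: zero-depth sample(s): ",
         paste(colnames(counts)[zero] %||% which(zero), collapse = ", "),
         call. = FALSE)
  }
  sweep(counts, 2, cs / 1e6, "/")
}

#' Small RNA size-distribution profile per sample
#'
#' Histograms mapped-read lengths, restricted to the 20-24 nt window, in
#' reads-per-million units (normalized by the total mapped reads of the
#' sample, all lengths).
#'
#' @param read_lengths data frame with columns `sample`, `length`, `reads`.
#' @return matrix lengths (20..24) x samples, RPM units.
#' @export
size_distribution <- function(read_lengths) {
  if (any(read_lengths$length < 15 | read_lengths$length > 35)) {
    stop("size_distribution: read lengths must lie within 15-35 nt",
         call. = FALSE)
  }
  samples <- unique(read_lengths$sample)
  lens <- 20:24
  out <- matrix(0, nrow = length(lens), ncol = length(samples),
                dimnames = list(as.character(lens), samples))
  for (s in samples) {
    sub <- read_lengths[read_lengths$sample == s, , drop = FALSE]
    total <- sum(sub$reads)
    if (total <= 0) next
    for (i in seq_along(lens)) {
      out[i, s] <- sum(sub$reads[sub$length == lens[i]]) / total * 1e6
    }
  }
  out
}

#' Up/down counts per sRNA class and time point
#'
#' Tallies, per class and time point, the features called up or down by the
#' differential-expression stage. Each DE feature is counted once per time
#' point at which it is DE.
#'
#' @param de a `de_result` data frame (see [nb_wald_test()]).
#' @param classes named character vector feature id -> rna_class
#'   (e.g. from [assign_class()]).
#' @return data frame with columns class, time, up, down.
#' @export
class_direction_summary <- function(de, classes) {
  de_hit <- de[de$status %in% c("up", "down"), , drop = FALSE]
  cls <- unname(classes[de_hit$feature])
  cls[is.na(cls)] <- "other"
  grid <- expand.grid(class = sort(unique(unname(classes))),
                      time = TIME_POINTS, stringsAsFactors = FALSE)
  grid$up <- 0L
  grid$down <- 0L
  for (i in seq_len(nrow(de_hit))) {
    r <- which(grid$class == cls[i] & grid$time == de_hit$time[i])
    if (!length(r)) next
    if (de_hit$status[i] == "up") grid$up[r] <- grid$up[r] + 1L else
      grid$down[r] <- grid$down[r] + 1L
  }
  grid
}
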