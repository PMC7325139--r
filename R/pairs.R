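#' Classify a miRNA:mRNA pair by relative expression
#'
#' Category of a (DE miRNA, target) pair at a time point: `inverse` when
#' the two statuses are opposite (up/down or down/up), `same_up` /
#' `same_down` when both move the same way, `partner_unchanged` when the
#' target is expressed but not DE, and `partner_undetected` when the
#' target falls below the detection threshold.
#'
#' @param mirna_status `"up"` or `"down"` (only DE miRNAs enter; anything
#'   else is an error).
#' @param target_status one of `"up"`, `"down"`, `"unchanged"`,
#'   `"undetected"`.
#' @return character vector of categories (vectorized).
#' @export
classify_mirna_pair <- function(mirna_status, target_status) {
  if (any(!mirna_status %in% c("up", "down"))) {
    stop("classify_mirna_pair: miRNA status must be 'up' or 'down' ",
         "(prefilter to DE miRNAs)", call. = FALSE)
  }
  if (any(!target_status %in% c("up", "down", "unchanged", "undetected"))) {
    stop("classify_mirna_pair: invalid target status", call. = FALSE)
  }
  ifelse(target_status == "undetected", "partner_undetected",
  ifelse(target_status == "unchanged", "partner_unchanged",
  ifelse(mirna_status == target_status,
         ifelse(mirna_status == "up", "same_up", "same_down"),
         "inverse")))
}

#' Classify a NAT pair by transcript expression pattern
#'
#' Maps the unordered pair of transcript statuses of a DE-siRNA-producing
#' NAT pair to the five patterns: both up (up_up), one up and the other
#' flat (up_flat), one down and the other flat (down_flat), both flat
#' (flat_flat), and anticorrelated (up_down). `unchanged` and `undetected`
#' both count as flat; missing statuses are treated as undetected and
#' flagged.
#'
#' @param pair_id identifier of the NAT pair.
#' @param kind `"cis"` or `"trans"`.
#' @param status1,status2 DE statuses of the two transcripts.
#' @param sirna_status `"up"` or `"down"` status of the pair's siRNA
#'   cluster (the cluster must be DE).
#' @return one-row data frame: pair, kind, status1, status2, sirna_status,
#'   pattern, flagged_missing.
#' @export
classify_nat_pair <- function(pair_id, kind, status1, status2,
                              sirna_status) {
  stopifnot(kind %in% c("cis", "trans"),
            sirna_status %in% c("up", "down"))
  flag <- FALSE
  fix <- function(s) {
    if (is.na(s) || !nzchar(s)) {
      flag <<- TRUE
      return("undetected")
    }
    s
  }
  status1 <- fix(status1)
  status2 <- fix(status2)
  ss <- c(status1, status2)
  n_up <- sum(ss == "up")
  n_down <- sum(ss == "down")
  # Both-down pairs fall outside the five tabulated patterns; they are kept
  # as an explicit sixth value rather than folded into a neighbor.
  pattern <- if (n_up == 2) "up_up"
  else if (n_up == 1 && n_down == 1) "up_down"
  else if (n_up == 1) "up_flat"
  else if (n_down == 2) "down_down"
  else if (n_down == 1) "down_flat"
  else "flat_flat"
  data.frame(pair = pair_id, kind = kind, status1 = status1,
             status2 = status2, sirna_status = sirna_status,
             pattern = pattern, flagged_missing = flag,
             stringsAsFactors = FALSE)
}

#' Detect a classical nat-siRNA regulon
#'
#' The classical pattern: a stimulus-induced transcript of a NAT pair
#' drives siRNA production that downregulates the partner transcript. In
#' `relaxed` mode (default) the call requires the pair's siRNA cluster up
#' (FC >= 2, adjusted p <= alpha), one transcript up with FC >= 2 and
#' adjusted p <= alpha, and the partner's fold change negative. `strict`
#' mode additionally requires the partner at FC <= -2 with adjusted
#' p <= alpha.
#'
#' @param fc1,fc2 linear fold changes of the two transcripts (signed;
#'   a 2-fold decrease is -2).
#' @param padj1,padj2 adjusted p values of the two transcripts.
#' @param sirna_fc,sirna_padj fold change and adjusted p of the siRNA
#'   cluster.
#' @param mode `"relaxed"` (default) or `"strict"`.
#' @param fc_threshold fold-change threshold (default 2).
#' @param alpha_level adjusted-p threshold (default 0.05).
#' @return logical.
#' @export
detect_classical_regulon <- function(fc1, fc2, padj1, padj2, sirna_fc,
                                     sirna_padj,
                                     mode = c("relaxed", "strict"),
                                     fc_threshold = 2, alpha_level = 0.05) {
  mode <- match.arg(mode)
  sirna_up <- !is.na(sirna_fc) & !is.na(sirna_padj) &
    sirna_fc >= fc_threshold & sirna_padj <= alpha_level
  if (!sirna_up) return(FALSE)
  driver_ok <- function(fc, padj) {
    !is.na(fc) & !is.na(padj) & fc >= fc_threshold & padj <= alpha_level
  }
  partner_relaxed <- function(fc) !is.na(fc) & fc < 0
  partner_strict <- function(fc, padj) {
    !is.na(fc) & !is.na(padj) & fc <= -fc_threshold & padj <= alpha_level
  }
  if (mode == "relaxed") {
    (driver_ok(fc1, padj1) & partner_relaxed(fc2)) ||
      (driver_ok(fc2, padj2) & partner_relaxed(fc1))
  } else {
    (driver_ok(fc1, padj1) & partner_strict(fc2, padj2)) ||
      (driver_ok(fc2, padj2) & partner_strict(fc1, padj1))
  }
}

#' Classify all NAT pairs of a catalog against DE results
#'
#' For every catalog-declared NAT pair whose siRNA cluster is DE, computes
#' the transcript-status pattern and the classical-regulon call.
#'
#' @param catalog a [locus_catalog()].
#' @param sirna_map data frame mapping siRNA clusters to pairs: columns
#'   `cluster` and `member` (one transcript of the pair).
#' @param de_srna,de_mrna `de_result` data frames at one time point.
#' @param mode classical-regulon mode, `"relaxed"` or `"strict"`.
#' @return data frame: one row per DE-cluster NAT pair with pattern and
#'   `classical` flag.
#' @export
classify_nat_pairs <- function(catalog, sirna_map, de_srna, de_mrna,
                               mode = "relaxed") {
  de_clusters <- de_srna[de_srna$status %in% c("up", "down"), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(de_clusters))) {
    cl <- de_clusters$feature[i]
    j <- match(cl, sirna_map$cluster)
    if (is.na(j)) next
    m1 <- sirna_map$member[j]
    k <- match(m1, catalog$id)
    if (is.na(k) || is.na(catalog$partner_id[k])) next
    m2 <- catalog$partner_id[k]
    kind <- if (catalog$rna_class[k] == "cis_NAT") "cis" else "trans"
    rec1 <- de_mrna[de_mrna$feature == m1, , drop = FALSE]
    rec2 <- de_mrna[de_mrna$feature == m2, , drop = FALSE]
    s1 <- if (nrow(rec1)) rec1$status[1] else NA_character_
    s2 <- if (nrow(rec2)) rec2$status[1] else NA_character_
    row <- classify_nat_pair(cl, kind, s1, s2, de_clusters$status[i])
    fc <- function(rec) if (nrow(rec)) sign(rec$log2fc[1]) *
      2^abs(rec$log2fc[1]) else NA_real_
    pa <- function(rec) if (nrow(rec)) rec$p_adj[1] else NA_real_
    row$classical <- de_clusters$status[i] == "up" &&
      detect_classical_regulon(fc(rec1), fc(rec2), pa(rec1), pa(rec2),
                               sirna_fc = sign(de_clusters$log2fc[i]) *
                                 2^abs(de_clusters$log2fc[i]),
                               sirna_padj = de_clusters$p_adj[i],
                               mode = mode)
    row$time <- de_clusters$time[i]
    out[[length(out) + 1]] <- row
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(pair = character(0), kind = character(0),
               status1 = character(0), status2 = character(0),
               sirna_status = character(0), pattern = character(0),
               flagged_missing = logical(0), classical = logical(0),
               time = character(0), stringsAsFactors = FALSE)
}
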