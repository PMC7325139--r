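# Penalty table for miRNA:site duplex scoring: match 0, G:U wobble 0.5,
# mismatch 1.0; penalties doubled at miRNA positions 2-13 from the 5' end.
SEED_START <- 2
SEED_END <- 13

#' Score a miRNA against a candidate target site
#'
#' Ungapped position-wise scoring of the duplex formed by a miRNA
#' (5'->3') and a same-length target site (5'->3'): miRNA position `i`
#' (from its 5' end) pairs with site position `L - i + 1`. Watson-Crick
#' pairs score 0, G:U wobbles 0.5, mismatches 1.0, and penalties are
#' doubled in the seed region (miRNA positions 2-13). The expectation is
#' the total penalty; 0 means a perfect reverse complement.
#'
#' @param mirna_seq miRNA sequence 5'->3' (T and U equivalent).
#' @param site_seq target site sequence 5'->3', same length as the miRNA.
#' @return list with `expectation`, `alignment` (3-line text block, miRNA
#'   printed 3'->5' over the site 5'->3') and `inhibition` (`"cleavage"`
#'   if miRNA positions 9-11 are all paired, else `"translation"`).
#' @export
score_duplex <- function(mirna_seq, site_seq) {
  check_nucleotides(mirna_seq, "miRNA")
  check_nucleotides(site_seq, "target site")
  m <- as_dna(mirna_seq)
  s <- as_dna(site_seq)
  L <- nchar(m)
  if (nchar(s) != L) {
    stop("score_duplex: site length must equal miRNA length", call. = FALSE)
  }
  mv <- strsplit(m, "")[[1]]
  sv <- rev(strsplit(s, "")[[1]])  # sv[i] faces miRNA position i
  pen <- site_penalties(mv, sv)
  seed <- seq_len(L) >= SEED_START & seq_len(L) <= SEED_END
  expectation <- sum(pen * ifelse(seed, 2, 1))
  paired <- pen < 1
  match_line <- ifelse(pen == 0, "|", ifelse(pen == 0.5, "o", " "))
  alignment <- c(
    paste0("miRNA  3' ", paste(rev(chartr("T", "U", mv)), collapse = ""),
           " 5'"),
    paste0("          ", paste(rev(match_line), collapse = "")),
    paste0("target 5' ", chartr("T", "U", s), " 3'"))
  central <- 9:11
  inhibition <- if (all(paired[central])) "cleavage" else "translation"
  list(expectation = expectation, alignment = alignment,
       inhibition = inhibition)
}

# Per-position penalties (unweighted): 0 match, 0.5 G:U, 1 mismatch.
# mv[i] is the miRNA base at position i, sv[i] the site base facing it.
site_penalties <- function(mv, sv) {
  wc <- (mv == "A" & sv == "T") | (mv == "T" & sv == "A") |
    (mv == "G" & sv == "C") | (mv == "C" & sv == "G")
  gu <- (mv == "G" & sv == "T") | (mv == "T" & sv == "G")
  ifelse(wc, 0, ifelse(gu, 0.5, 1))
}

#' Find miRNA target sites in transcripts
#'
#' Slides each miRNA along each transcript, scoring every window of miRNA
#' length with [score_duplex()]. Windows with expectation <= `cutoff` are
#' reported; overlapping windows for the same (miRNA, transcript) pair are
#' reduced to the best-scoring one (ties broken leftmost). If a table of
#' precomputed target-site unpairing energies is supplied, hits with
#' `upe > upe_max` are removed.
#'
#' @param mirnas named character vector of miRNA sequences (5'->3').
#' @param transcripts named character vector of transcript sequences.
#' @param cutoff maximum expectation score (default 2.5).
#' @param upe_table optional data frame (mirna, transcript, position, upe),
#'   `position` 0-based target start of the hit.
#' @param upe_max maximum energy to unpair the target site (default 25).
#' @return data frame of hits: mirna, transcript, target_start, target_end
#'   (0-based half-open), expectation, upe, inhibition.
#' @export
find_targets <- function(mirnas, transcripts, cutoff = 2.5,
                         upe_table = NULL, upe_max = 25) {
  stopifnot(length(mirnas) > 0, length(transcripts) > 0)
  check_nucleotides(mirnas, "miRNA")
  check_nucleotides(transcripts, "transcript")
  hits <- list()
  n_short <- 0L
  for (mi in names(mirnas)) {
    m <- as_dna(mirnas[[mi]])
    L <- nchar(m)
    mv <- strsplit(m, "")[[1]]
    seed_w <- ifelse(seq_len(L) >= SEED_START & seq_len(L) <= SEED_END, 2, 1)
    # Penalty weights indexed by site offset within the window: site
    # position j (1-based, 5'->3') faces miRNA position L - j + 1.
    w_rev <- rev(seed_w)
    m_rev <- rev(mv)
    for (tx in names(transcripts)) {
      tseq <- as_dna(transcripts[[tx]])
      n_win <- nchar(tseq) - L + 1
      if (n_win < 1) {
        n_short <- n_short + 1L
        next
      }
      tv <- strsplit(tseq, "")[[1]]
      # Window starting at s covers site positions s..s+L-1; position
      # s+j-1 faces miRNA position L-j+1 with weight w_rev[j].
      score <- numeric(n_win)
      for (j in seq_len(L)) {
        pen_j <- site_penalties(rep(m_rev[j], length(tv)), tv)
        score <- score + w_rev[j] * pen_j[j:(j + n_win - 1)]
      }
      keep <- which(score <= cutoff)
      if (!length(keep)) next
      # Collapse overlapping windows to the best-scoring (ties leftmost).
      keep <- keep[order(score[keep], keep)]
      chosen <- integer(0)
      for (s in keep) {
        if (!any(abs(chosen - s) < L)) chosen <- c(chosen, s)
      }
      chosen <- sort(chosen)
      for (s in chosen) {
        site <- substr(tseq, s, s + L - 1)
        sc <- score_duplex(m, site)
        hits[[length(hits) + 1]] <- data.frame(
          mirna = mi, transcript = tx, target_start = as.integer(s - 1),
          target_end = as.integer(s - 1 + L), expectation = sc$expectation,
          upe = NA_real_, inhibition = sc$inhibition,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (n_short > 0) {
    message("find_targets: ", n_short,
            " transcript/miRNA combination(s) skipped (transcript shorter ",
            "than miRNA)")
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(mirna = character(0), transcript = character(0),
               target_start = integer(0), target_end = integer(0),
               expectation = numeric(0), upe = numeric(0),
               inhibition = character(0), stringsAsFactors = FALSE)
  if (!is.null(upe_table) && nrow(out)) {
    key <- paste(out$mirna, out$transcript, out$target_start)
    ukey <- paste(upe_table$mirna, upe_table$transcript, upe_table$position)
    out$upe <- upe_table$upe[match(key, ukey)]
    out <- out[is.na(out$upe) | out$upe <= upe_max, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Join target hits to differential-expression calls
#'
#' Builds the miRNA:mRNA pair table: one row per (DE miRNA, target hit,
#' time point), carrying both statuses. miRNAs that are not DE (status up
#' or down) at a time point contribute no rows for that time point.
#'
#' @param hits data frame from [find_targets()].
#' @param de_mirna,de_mrna `de_result` data frames for the two layers.
#' @return data frame with columns mirna, target, time, mirna_status,
#'   mirna_log2fc, target_status, target_log2fc. Hits whose transcript has
#'   no DE record are dropped, with the count reported via a message.
#' @export
join_targets_to_de <- function(hits, de_mirna, de_mrna) {
  de_m <- de_mirna[de_mirna$status %in% c("up", "down"), , drop = FALSE]
  out <- list()
  n_unjoined <- 0L
  for (i in seq_len(nrow(de_m))) {
    hh <- hits[hits$mirna == de_m$feature[i], , drop = FALSE]
    if (!nrow(hh)) next
    tp <- de_m$time[i]
    for (j in seq_len(nrow(hh))) {
      rec <- de_mrna[de_mrna$feature == hh$transcript[j] &
                       de_mrna$time == tp, , drop = FALSE]
      if (!nrow(rec)) {
        n_unjoined <- n_unjoined + 1L
        next
      }
      out[[length(out) + 1]] <- data.frame(
        mirna = de_m$feature[i], target = hh$transcript[j], time = tp,
        mirna_status = de_m$status[i], mirna_log2fc = de_m$log2fc[i],
        target_status = rec$status[1], target_log2fc = rec$log2fc[1],
        stringsAsFactors = FALSE)
    }
  }
  if (n_unjoined > 0) {
    message("join_targets_to_de: ", n_unjoined,
            " hit(s) had no expression record for their transcript")
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(mirna = character(0), target = character(0),
               time = character(0), mirna_status = character(0),
               mirna_log2fc = numeric(0), target_status = character(0),
               target_log2fc = numeric(0), stringsAsFactors = FALSE)
}
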