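# A 21-nt miRNA used across the scoring examples; G at position 15 allows
# a wobble there, C at position 5 needs an engineered wobble partner.
MIR21 <- "UGACCUAGGCUAAGGUAGGCA"

wobble_site <- function(mirna, pos) {
  site <- strsplit(rc_oracle(mirna), "")[[1]]
  L <- nchar(mirna)
  mb <- substr(chartr("U", "T", toupper(mirna)), pos, pos)
  sp <- L - pos + 1
  site[sp] <- if (mb == "G") "T" else if (mb == "T") "G" else
    stop("wobble needs G or U at that miRNA position")
  paste(site, collapse = "")
}

mismatch_site <- function(mirna, pos, site = rc_oracle(mirna)) {
  v <- strsplit(site, "")[[1]]
  L <- nchar(mirna)
  sp <- L - pos + 1
  mb <- substr(chartr("U", "T", toupper(mirna)), pos, pos)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # Pick a base that is neither a Watson-Crick nor a wobble partner.
  cand <- setdiff(c("A", "C", "G", "T"), comp[mb])
  if (mb == "G") cand <- setdiff(cand, "T")
  if (mb == "T") cand <- setdiff(cand, "G")
  v[sp] <- cand[1]
  paste(v, collapse = "")
}

test_that("duplex penalties follow the seed-weighted scoring table", {
  perfect <- rc_oracle(MIR21)
  expect_equal(score_duplex(MIR21, perfect)$expectation, 0)
  # G:U wobble outside the seed costs 0.5; inside the seed it doubles.
  expect_equal(score_duplex(MIR21, wobble_site(MIR21, 15))$expectation, 0.5)
  expect_equal(score_duplex(MIR21, wobble_site(MIR21, 6))$expectation, 1.0)
  # One seed mismatch (x2) plus one non-seed wobble: exactly at the
  # stringent cutoff of 2.5.
  s <- mismatch_site(MIR21, 3, wobble_site(MIR21, 19))
  expect_equal(score_duplex(MIR21, s)$expectation, 2.5)
  # Two seed mismatches: 4.0, beyond the cutoff.
  s2 <- mismatch_site(MIR21, 3, mismatch_site(MIR21, 8))
  expect_equal(score_duplex(MIR21, s2)$expectation, 4.0)
  expect_error(score_duplex("ACGX", "ACGT"), "non-nucleotide")
  expect_error(score_duplex(MIR21, "ACGT"), "length")
})

test_that("central pairing separates cleavage from translation inhibition", {
  expect_identical(score_duplex(MIR21, rc_oracle(MIR21))$inhibition,
                   "cleavage")
  expect_identical(
    score_duplex(MIR21, mismatch_site(MIR21, 10))$inhibition,
    "translation")
})

test_that("duplex scoring is not symmetric under strand exchange", {
  # A perfect duplex is symmetric under reverse-complementing both
  # strands, but a wobble is not: complementing turns G:U into C:A, a
  # full mismatch, so the total penalty changes.
  expect_equal(score_duplex(rc_oracle(rc_oracle(MIR21)),
                            rc_oracle(MIR21))$expectation, 0)
  s <- wobble_site(MIR21, 15)
  e1 <- score_duplex(MIR21, s)$expectation
  e2 <- score_duplex(rc_oracle(s), rc_oracle(MIR21))$expectation
  expect_equal(e1, 0.5)
  expect_equal(e2, 1.0)
  # A plain mismatch keeps its penalty and its position under the
  # exchange, so the seed weighting is preserved for it.
  s3 <- mismatch_site(MIR21, 3)
  expect_equal(score_duplex(MIR21, s3)$expectation, 2.0)
  expect_equal(score_duplex(rc_oracle(s3), rc_oracle(MIR21))$expectation,
               2.0)
})

test_that("find_targets reproduces the exhaustive window oracle", {
  set.seed(17)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:10) {
    mir <- paste(sample(bases, 21, replace = TRUE), collapse = "")
    tx <- paste(sample(bases, 400, replace = TRUE), collapse = "")
    # Embed one near-perfect site so hits exist.
    site <- mismatch_site(mir, 18)
    substr(tx, 101, 121) <- site
    got <- find_targets(c(m = mir), c(t = tx), cutoff = 4)
    exp <- find_targets_oracle(mir, tx, cutoff = 4)
    expect_equal(got$target_start, exp$start)
    expect_equal(got$expectation, exp$score)
  }
})

test_that("planted perfect sites yield a single zero-score hit", {
  set.seed(23)
  mir <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
               collapse = "")
  tx <- paste0(paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                     collapse = ""), rc_oracle(mir),
               paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                     collapse = ""))
  h <- find_targets(c(m1 = mir), c(t1 = tx))
  expect_equal(nrow(h), 1L)
  expect_equal(h$expectation, 0)
  expect_equal(h$target_start, 150)
  expect_equal(h$target_end, 172)
})

test_that("lowering the cutoff never adds hits", {
  set.seed(29)
  mirs <- setNames(replicate(3, paste(sample(c("A", "C", "G", "T"), 21,
                                             replace = TRUE),
                                      collapse = "")),
                   paste0("m", 1:3))
  txs <- setNames(replicate(4, paste(sample(c("A", "C", "G", "T"), 300,
                                            replace = TRUE),
                                     collapse = "")),
                  paste0("t", 1:4))
  hi <- find_targets(mirs, txs, cutoff = 6)
  lo <- find_targets(mirs, txs, cutoff = 3)
  key <- function(h) paste(h$mirna, h$transcript, h$target_start)
  expect_true(all(key(lo) %in% key(hi)))
  expect_true(all(lo$expectation <= 3))
})

test_that("accessibility energies above the maximum remove hits", {
  mir <- MIR21
  tx <- paste0("ACGTACGTAC", rc_oracle(mir), "ACGTACGTAC")
  upe <- data.frame(mirna = "m", transcript = "t", position = 10, upe = 30)
  h0 <- find_targets(c(m = mir), c(t = tx))
  expect_equal(nrow(h0), 1L)
  h1 <- find_targets(c(m = mir), c(t = tx), upe_table = upe, upe_max = 25)
  expect_equal(nrow(h1), 0L)
  upe$upe <- 20
  h2 <- find_targets(c(m = mir), c(t = tx), upe_table = upe, upe_max = 25)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$upe, 20)
})

test_that("transcripts shorter than the miRNA produce no hits", {
  expect_message(h <- find_targets(c(m = MIR21), c(t = "ACGTACGT")),
                 "skipped")
  expect_equal(nrow(h), 0L)
})

test_that("the pair table joins DE miRNAs with their targets per time", {
  hits <- data.frame(mirna = c("m1", "m1"), transcript = c("t1", "t2"),
                     target_start = 0, target_end = 21, expectation = 0,
                     upe = NA_real_, inhibition = "cleavage",
                     stringsAsFactors = FALSE)
  de_m <- data.frame(feature = "m1", time = c("3h", "2d"),
                     base_mean = 50, log2fc = c(2, 2), p = 0.001,
                     p_adj = 0.01, status = "up", stringsAsFactors = FALSE)
  de_t <- expand.grid(feature = c("t1", "t2"), time = c("3h", "2d"),
                      stringsAsFactors = FALSE)
  de_t$base_mean <- 30
  de_t$log2fc <- -1.5
  de_t$p <- 0.01
  de_t$p_adj <- 0.04
  de_t$status <- "down"
  joined <- join_targets_to_de(hits, de_m, de_t)
  expect_equal(nrow(joined), 4L)
  expect_setequal(unique(joined$time), c("3h", "2d"))
  none <- join_targets_to_de(hits, de_m[0, ], de_t)
  expect_equal(nrow(none), 0L)
})

test_that("planted synthetic pairs survive prediction and the DE join", {
  cfg <- sim_config(seed = 19)
  sim <- generate_catalog(cfg)
  cc <- simulate_counts(sim)
  hits <- find_targets(sim$mirna_seq, sim$transcript_seq)
  key <- paste(hits$mirna, hits$transcript)
  planted <- paste(sim$planted_pairs$mirna, sim$planted_pairs$target)
  expect_true(all(planted %in% key))
  de_s <- de_all_timepoints(cc$srna_counts, cc$design)
  de_m <- de_all_timepoints(cc$mrna_counts, cc$design)
  joined <- join_targets_to_de(hits, de_s, de_m)
  truthpairs <- cc$truth$planted_target_pairs
  coupled <- truthpairs[truthpairs$expected == "inverse", , drop = FALSE]
  de_mir <- de_s$feature[de_s$status %in% c("up", "down")]
  got <- paste(joined$mirna, joined$target)
  for (i in seq_len(nrow(coupled))) {
    if (coupled$mirna[i] %in% de_mir) {
      expect_true(paste(coupled$mirna[i], coupled$target[i]) %in% got)
    }
  }
})
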