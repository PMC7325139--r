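test_that("miRNA:mRNA pairs map onto the correlation categories", {
  # The study's worked example: a strongly downregulated miRNA whose
  # target gene rises is an inversely correlated pair.
  expect_identical(classify_mirna_pair("down", "up"), "inverse")
  expect_identical(classify_mirna_pair("up", "down"), "inverse")
  expect_identical(classify_mirna_pair("up", "up"), "same_up")
  expect_identical(classify_mirna_pair("down", "down"), "same_down")
  expect_identical(classify_mirna_pair("up", "unchanged"),
                   "partner_unchanged")
  expect_identical(classify_mirna_pair("up", "undetected"),
                   "partner_undetected")
  expect_error(classify_mirna_pair("unchanged", "up"), "prefilter")
})

test_that("category assignment partitions every eligible pair", {
  set.seed(3)
  ms <- sample(c("up", "down"), 200, replace = TRUE)
  ts <- sample(c("up", "down", "unchanged", "undetected"), 200,
               replace = TRUE)
  cats <- classify_mirna_pair(ms, ts)
  expect_equal(length(cats), 200L)
  expect_true(all(cats %in% c("inverse", "same_up", "same_down",
                              "partner_unchanged", "partner_undetected")))
  expect_equal(sum(table(cats)), 200L)
})

test_that("NAT pair patterns come from the unordered status pair", {
  r <- classify_nat_pair("p1", "cis", "unchanged", "unchanged", "up")
  expect_identical(r$pattern, "flat_flat")
  r2 <- classify_nat_pair("p2", "cis", "up", "down", "up")
  expect_identical(r2$pattern, "up_down")
  expect_identical(classify_nat_pair("p", "cis", "down", "up",
                                     "up")$pattern, "up_down")
  expect_identical(classify_nat_pair("p", "trans", "up", "undetected",
                                     "down")$pattern, "up_flat")
  expect_identical(classify_nat_pair("p", "trans", "down", "unchanged",
                                     "up")$pattern, "down_flat")
  expect_identical(classify_nat_pair("p", "cis", "up", "up", "up")$pattern,
                   "up_up")
  miss <- classify_nat_pair("p", "cis", NA, "up", "up")
  expect_true(miss$flagged_missing)
  expect_identical(miss$pattern, "up_flat")
})

test_that("classical regulon detection distinguishes relaxed and strict", {
  # Printed fold changes of two real gene pairs: a clear reciprocal pair
  # passes both modes; a partner at -1.51 passes only the relaxed mode.
  expect_true(detect_classical_regulon(2.58, -2.17, 0.01, 0.01, 3, 0.01,
                                       mode = "relaxed"))
  expect_true(detect_classical_regulon(2.58, -2.17, 0.01, 0.01, 3, 0.01,
                                       mode = "strict"))
  expect_true(detect_classical_regulon(3.13, -1.51, 0.01, 0.01, 3, 0.01,
                                       mode = "relaxed"))
  expect_false(detect_classical_regulon(3.13, -1.51, 0.01, 0.01, 3, 0.01,
                                        mode = "strict"))
  expect_false(detect_classical_regulon(2.0, 1.2, 0.01, 0.01, 3, 0.01,
                                        mode = "relaxed"))
  # Order of the two transcripts must not matter.
  expect_true(detect_classical_regulon(-2.17, 2.58, 0.01, 0.01, 3, 0.01,
                                       mode = "strict"))
  # No call without an upregulated siRNA cluster.
  expect_false(detect_classical_regulon(2.58, -2.17, 0.01, 0.01, 1.5,
                                        0.01))
  expect_false(detect_classical_regulon(2.58, -2.17, 0.01, 0.01, 3, 0.2))
})

test_that("a strict call always implies a relaxed call", {
  set.seed(11)
  for (i in 1:200) {
    fc1 <- runif(1, -5, 5)
    fc2 <- runif(1, -5, 5)
    p1 <- runif(1)
    p2 <- runif(1)
    sfc <- runif(1, 0, 5)
    sp <- runif(1)
    s <- detect_classical_regulon(fc1, fc2, p1, p2, sfc, sp,
                                  mode = "strict")
    r <- detect_classical_regulon(fc1, fc2, p1, p2, sfc, sp,
                                  mode = "relaxed")
    expect_true(!s || r)
  }
})

test_that("synthetic NAT cohorts match a direct enumeration of patterns", {
  cfg <- sim_config(seed = 37)
  sim <- generate_catalog(cfg)
  cc <- simulate_counts(sim)
  de_s <- de_all_timepoints(cc$srna_counts, cc$design)
  de_m <- de_all_timepoints(cc$mrna_counts, cc$design)
  sirna_map <- data.frame(cluster = sim$clusters$id,
                          member = sim$clusters$source_id,
                          stringsAsFactors = FALSE)
  nat <- do.call(rbind, lapply(c("3h", "6h", "2d"), function(tp) {
    classify_nat_pairs(sim$catalog, sirna_map,
                       de_s[de_s$time == tp, ], de_m[de_m$time == tp, ])
  }))
  # Brute-force tally: recompute each pattern from the DE tables.
  flatten <- function(s) {
    if (is.na(s) || s %in% c("unchanged", "undetected")) "flat" else s
  }
  for (i in seq_len(nrow(nat))) {
    m1 <- sirna_map$member[match(nat$pair[i], sirna_map$cluster)]
    m2 <- sim$catalog$partner_id[match(m1, sim$catalog$id)]
    tp <- nat$time[i]
    s1 <- flatten(de_m$status[de_m$feature == m1 & de_m$time == tp])
    s2 <- flatten(de_m$status[de_m$feature == m2 & de_m$time == tp])
    ss <- sort(c(s1, s2))
    want <- if (all(ss == "up")) "up_up"
    else if (all(ss == "flat")) "flat_flat"
    else if (identical(ss, c("down", "up"))) "up_down"
    else if ("up" %in% ss) "up_flat"
    else if (all(ss == "down")) "down_down"
    else "down_flat"
    expect_identical(nat$pattern[i], want)
  }
  # Planted regulons are all detected in relaxed mode, and their pattern
  # is the anticorrelated one.
  reg <- cc$truth$planted_regulons
  found <- nat[match(paste(reg$pair, reg$time),
                     paste(nat$pair, nat$time)), ]
  expect_true(all(found$classical))
  expect_true(all(found$pattern == "up_down"))
})

test_that("independent NAT transcripts rarely mimic a classical regulon", {
  hits <- 0
  total <- 0
  for (s in 1:3) {
    cfg <- sim_config(seed = 100 + s, de_fraction = 1e-9)
    sim <- generate_catalog(cfg)
    cc <- simulate_counts(sim)
    # Regulons are planted on the first half of each pair set; the rest
    # have independent transcripts.
    de_s <- de_all_timepoints(cc$srna_counts, cc$design)
    de_m <- de_all_timepoints(cc$mrna_counts, cc$design)
    reg_pairs <- cc$truth$planted_regulons$pair
    sirna_map <- data.frame(cluster = sim$clusters$id,
                            member = sim$clusters$source_id,
                            stringsAsFactors = FALSE)
    for (tp in c("3h", "6h", "2d")) {
      nat <- classify_nat_pairs(sim$catalog, sirna_map,
                                de_s[de_s$time == tp, ],
                                de_m[de_m$time == tp, ])
      indep <- nat[!nat$pair %in% reg_pairs, , drop = FALSE]
      hits <- hits + sum(indep$classical)
      total <- total + nrow(indep)
    }
    total <- total + 20  # eligible independent pairs never entering (not DE)
  }
  expect_lte(hits / max(1, total), 0.05)
})
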