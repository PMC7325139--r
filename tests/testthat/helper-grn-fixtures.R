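# Fixture builders for the regulatory-network validation experiments.

# One dedicated regulator per target so that cross-validation folds share
# no regulator series; families are shared so the learner can transfer
# across targets.
single_regulator_network <- function(n_targets = 200, n_families = 10,
                                     seed = 1) {
  set.seed(seed)
  regs <- sprintf("TF%03d", seq_len(n_targets))
  fams <- stats::setNames(
    sprintf("FAM%02d", ((seq_len(n_targets) - 1) %% n_families) + 1), regs)
  edges <- data.frame(regulator = regs,
                      target = sprintf("G%03d", seq_len(n_targets)),
                      binding_site_count = 1)
  net <- build_network(list(validated = edges), families = fams)
  net$edges$weight <- 1
  net
}

# Regulator-driven expression with the noise sd calibrated so the mean
# per-target ceiling correlation equals `ceiling`.
ceiling_expression <- function(net, seed, ceiling = 0.8) {
  sim0 <- simulate_regulated_expression(net, sim_config(seed = seed,
                                                        edge_noise_sd = 0))
  sigma <- noise_sd_for_ceiling(sim0$truth$signal, ceiling)
  sim <- simulate_regulated_expression(net, sim_config(seed = seed,
                                                       edge_noise_sd = sigma))
  list(sim = sim, sigma = sigma,
       expr = rbind(sim$expression, sim$regulator_expression))
}

# Network with the signal split across the four evidence sources, one
# regulator per target, round-robin source assignment.
split_source_network <- function(n_targets = 200, seed = 1) {
  set.seed(seed)
  n_tf <- ceiling(n_targets * 3 / 4)
  n_mir <- n_targets - n_tf
  tf_regs <- sprintf("TF%03d", seq_len(n_tf))
  mir_regs <- sprintf("miR%03d", seq_len(n_mir))
  tgt <- sprintf("G%03d", seq_len(n_targets))
  src <- rep(c("validated", "CE", "FunTFBS", "miRNA"),
             length.out = n_targets)
  fams <- c(stats::setNames(sprintf("TFfam%02d", ((seq_len(n_tf) - 1) %% 8)
                                    + 1), tf_regs),
            stats::setNames(sprintf("MIRfam%02d", ((seq_len(n_mir) - 1) %%
                                                     4) + 1), mir_regs))
  tabs <- list(validated = NULL, CE = NULL, FunTFBS = NULL)
  hits <- NULL
  ti <- mi <- 0
  for (i in seq_len(n_targets)) {
    if (src[i] == "miRNA") {
      mi <- mi + 1
      hits <- rbind(hits, data.frame(mirna = mir_regs[mi],
                                     transcript = tgt[i]))
    } else {
      ti <- ti + 1
      tabs[[src[i]]] <- rbind(tabs[[src[i]]],
                              data.frame(regulator = tf_regs[ti],
                                         target = tgt[i],
                                         binding_site_count = 1))
    }
  }
  net <- build_network(tabs, mirna_hits = hits, families = fams)
  net$edges$weight <- 1
  net
}

permute_regulators <- function(expr, regulators, seed) {
  set.seed(seed)
  reg_rows <- rownames(expr) %in% regulators
  prm <- sample(ncol(expr))
  out <- expr
  out[reg_rows, ] <- expr[reg_rows, prm]
  out
}
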