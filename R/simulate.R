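#' Configuration for the synthetic cold-acclimation study
#'
#' Defines the simulated study: feature inventory per RNA class, the
#' 2-condition x 3-time-point x replicated design, negative-binomial count
#' parameters, and the planted effects (differential expression,
#' miRNA-target coupling, nat-siRNA regulons, regulator-driven targets).
#'
#' @param n_mirna,n_tf,n_targets,n_cis_nat_pairs,n_trans_nat_pairs,n_lncrna
#'   feature counts per class (all > 0).
#' @param n_replicates biological replicates per condition x time point.
#' @param library_size_mean expected total feature-level counts per sample.
#' @param nb_dispersion optional fixed per-feature NB dispersion alpha in
#'   `Var = mu + alpha * mu^2`; default `NULL` draws alpha per feature
#'   log-uniformly in \[0.01, 0.5\].
#' @param de_fraction fraction of features planted as differentially
#'   expressed, in (0, 1).
#' @param de_log2fc planted absolute log2 fold change (>= 1).
#' @param coupling_strength miRNA-to-target anticorrelation strength in
#'   \[0, 1\]: planted targets of a DE miRNA have their cold mean scaled by
#'   `2^(-coupling_strength * beta_miRNA)`.
#' @param edge_noise_sd Gaussian sd of log-scale noise added to
#'   regulator-driven target expression.
#' @param seed integer seed; all substreams derive from it deterministically.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_mirna = 30, n_tf = 15, n_targets = 60,
                       n_cis_nat_pairs = 10, n_trans_nat_pairs = 10,
                       n_lncrna = 10, n_replicates = 3,
                       library_size_mean = 2e5, nb_dispersion = NULL,
                       de_fraction = 0.2, de_log2fc = 2,
                       coupling_strength = 1, edge_noise_sd = 0.5,
                       seed = 1) {
  cfg <- list(n_mirna = n_mirna, n_tf = n_tf, n_targets = n_targets,
              n_cis_nat_pairs = n_cis_nat_pairs,
              n_trans_nat_pairs = n_trans_nat_pairs, n_lncrna = n_lncrna,
              n_replicates = n_replicates,
              library_size_mean = library_size_mean,
              nb_dispersion = nb_dispersion, de_fraction = de_fraction,
              de_log2fc = de_log2fc, coupling_strength = coupling_strength,
              edge_noise_sd = edge_noise_sd, seed = seed)
  counts <- cfg[c("n_mirna", "n_tf", "n_targets", "n_cis_nat_pairs",
                  "n_trans_nat_pairs", "n_lncrna", "n_replicates")]
  if (any(unlist(counts) <= 0)) {
    stop("sim_config: all feature/replicate counts must be > 0", call. = FALSE)
  }
  if (de_fraction <= 0 || de_fraction >= 1) {
    stop("sim_config: de_fraction must be in (0, 1)", call. = FALSE)
  }
  if (de_log2fc < 1) stop("sim_config: de_log2fc must be >= 1", call. = FALSE)
  if (coupling_strength < 0 || coupling_strength > 1) {
    stop("sim_config: coupling_strength must be in [0, 1]", call. = FALSE)
  }
  if (edge_noise_sd < 0) {
    stop("sim_config: edge_noise_sd must be >= 0", call. = FALSE)
  }
  if (library_size_mean <= 0) {
    stop("sim_config: library_size_mean must be > 0", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Sample design sheet for a simulation configuration
#'
#' @param config a [sim_config()].
#' @return data frame with columns sample/condition/time/replicate, ordered
#'   condition-major then time then replicate.
#' @export
make_design <- function(config) {
  g <- expand.grid(replicate = seq_len(config$n_replicates),
                   time = TIME_POINTS, condition = c("control", "cold"),
                   stringsAsFactors = FALSE)
  data.frame(sample = sprintf("%s_%s_r%d", g$condition, g$time, g$replicate),
             condition = g$condition, time = g$time, replicate = g$replicate,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic locus catalog with sequences
#'
#' Lays out miRNA genes, transcription-factor and target transcripts,
#' overlapping opposite-strand cis-NAT pairs, distant trans-NAT pairs and
#' lncRNA loci on a synthetic chromosome, together with the sRNA cluster
#' intervals each class produces. For planted miRNA:target pairs the target
#' transcript embeds a site reverse-complementary to the mature miRNA, with
#' 0-2 mismatches placed outside the seed region.
#'
#' @param config a [sim_config()].
#' @return list with elements `catalog` ([locus_catalog()]), `mirna_seq` and
#'   `transcript_seq` (named character vectors), `clusters` (sRNA cluster
#'   intervals with their source feature) and `planted_pairs`.
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, 1))

  rows <- list()
  cursor <- 1000
  add <- function(id, len, strand, cls, partner = NA_character_,
                  family = NA_character_, start = NULL) {
    s <- if (is.null(start)) cursor else start
    rows[[length(rows) + 1]] <<- data.frame(
      id = id, chrom = "chrS1", start = s, end = s + len, strand = strand,
      rna_class = cls, partner_id = partner, family = family,
      stringsAsFactors = FALSE)
    if (is.null(start)) cursor <<- s + len + 200
    c(s, s + len)
  }

  clusters <- list()
  add_cluster <- function(id, start, end, strand, source_id) {
    clusters[[length(clusters) + 1]] <<- data.frame(
      id = id, chrom = "chrS1", start = start, end = end, strand = strand,
      source_id = source_id, stringsAsFactors = FALSE)
  }

  mirna_ids <- sprintf("miR%03d", seq_len(config$n_mirna))
  mirna_fam <- sprintf("MIRfam%02d", ((seq_len(config$n_mirna) - 1) %/% 3) + 1)
  mirna_len <- sample(20:24, config$n_mirna, replace = TRUE)
  mirna_seq <- random_dna(config$n_mirna, 1)
  for (i in seq_len(config$n_mirna)) {
    mirna_seq[i] <- random_dna(1, mirna_len[i])
    span <- add(paste0("MIR_", mirna_ids[i]), 120, "+", "miRNA",
                family = mirna_fam[i])
    add_cluster(mirna_ids[i], span[1] + 40, span[1] + 40 + mirna_len[i], "+",
                paste0("MIR_", mirna_ids[i]))
  }
  names(mirna_seq) <- mirna_ids

  tf_ids <- sprintf("TF%03d", seq_len(config$n_tf))
  tf_fam <- sprintf("TFfam%02d", ((seq_len(config$n_tf) - 1) %% 5) + 1)
  for (i in seq_len(config$n_tf)) {
    add(tf_ids[i], 600, "+", "other", family = tf_fam[i])
  }

  target_ids <- sprintf("GENE%03d", seq_len(config$n_targets))
  for (id in target_ids) add(id, 500, "+", "other")

  cis_a <- sprintf("CISA%03d", seq_len(config$n_cis_nat_pairs))
  cis_b <- sprintf("CISB%03d", seq_len(config$n_cis_nat_pairs))
  for (i in seq_len(config$n_cis_nat_pairs)) {
    s <- cursor
    add(cis_a[i], 400, "+", "cis_NAT", partner = cis_b[i], start = s)
    add(cis_b[i], 400, "-", "cis_NAT", partner = cis_a[i], start = s + 250)
    add_cluster(sprintf("sirna_cis%03d", i), s + 250, s + 400, "+", cis_a[i])
    cursor <- s + 650 + 200
  }

  tra_a <- sprintf("TRAA%03d", seq_len(config$n_trans_nat_pairs))
  tra_b <- sprintf("TRAB%03d", seq_len(config$n_trans_nat_pairs))
  tra_a_span <- vector("list", config$n_trans_nat_pairs)
  for (i in seq_len(config$n_trans_nat_pairs)) {
    tra_a_span[[i]] <- add(tra_a[i], 400, "+", "trans_NAT", partner = tra_b[i])
  }
  for (i in seq_len(config$n_trans_nat_pairs)) {
    add(tra_b[i], 400, "-", "trans_NAT", partner = tra_a[i])
    sp <- tra_a_span[[i]]
    add_cluster(sprintf("sirna_tra%03d", i), sp[1] + 100, sp[1] + 180, "+",
                tra_a[i])
  }

  lnc_ids <- sprintf("LNC%03d", seq_len(config$n_lncrna))
  for (i in seq_len(config$n_lncrna)) {
    sp <- add(lnc_ids[i], 400, "+", "lncRNA")
    add_cluster(sprintf("sirna_lnc%03d", i), sp[1] + 150, sp[1] + 230, "+",
                lnc_ids[i])
  }

  cat_df <- do.call(rbind, rows)
  catalog <- locus_catalog(cat_df)

  transcript_ids <- c(tf_ids, target_ids, cis_a, cis_b, tra_a, tra_b, lnc_ids)
  lens <- cat_df$end[match(transcript_ids, cat_df$id)] -
    cat_df$start[match(transcript_ids, cat_df$id)]
  transcript_seq <- random_dna(length(transcript_ids), 1)
  for (i in seq_along(transcript_ids)) {
    transcript_seq[i] <- random_dna(1, lens[i])
  }
  names(transcript_seq) <- transcript_ids

  # Plant one target site per miRNA: reverse complement of the mature
  # sequence with 0-2 mismatches, mismatches restricted to miRNA positions
  # outside the heavily weighted seed (2-13) so the planted hit passes the
  # stringent expectation cutoff.
  n_plant <- config$n_mirna
  plant_target <- sample(target_ids, n_plant, replace = n_plant >
                           length(target_ids))
  planted <- data.frame(mirna = mirna_ids, target = plant_target,
                        offset = NA_integer_, mismatches = NA_integer_,
                        stringsAsFactors = FALSE)
  for (i in seq_len(n_plant)) {
    mir <- mirna_seq[[planted$mirna[i]]]
    L <- nchar(mir)
    site <- reverse_complement(mir)
    n_mm <- sample(0:2, 1)
    if (n_mm > 0) {
      # miRNA positions 14..L map to site positions 1..(L-13)
      mm_pos_mir <- sample(setdiff(14:L, integer(0)), n_mm)
      for (p in mm_pos_mir) {
        sp <- L - p + 1
        cur <- substr(site, sp, sp)
        repl <- sample(setdiff(c("A", "C", "G", "T"),
                               c(cur, complement_base(substr(mir, p, p)))), 1)
        substr(site, sp, sp) <- repl
      }
    }
    tlen <- nchar(transcript_seq[[planted$target[i]]])
    off <- sample(seq_len(tlen - L - 10), 1) + 5
    ts <- transcript_seq[[planted$target[i]]]
    substr(ts, off, off + L - 1) <- site
    transcript_seq[[planted$target[i]]] <- ts
    planted$offset[i] <- off - 1  # 0-based
    planted$mismatches[i] <- n_mm
  }

  list(catalog = catalog, mirna_seq = mirna_seq,
       transcript_seq = transcript_seq,
       clusters = do.call(rbind, clusters), planted_pairs = planted,
       config = config)
}

complement_base <- function(b) chartr("ACGT", "TGCA", b)

#' Simulate NB feature counts with planted effects
#'
#' Counts are drawn `NB(mean = s_j * q_i * 2^(beta * x), dispersion alpha)`
#' where `s_j` is a log-normal library-size factor, `q_i` the feature base
#' mean, `beta` the planted log2 fold change and `x` the cold indicator at
#' the planted time point. Planted miRNA:target pairs have the target's cold
#' mean scaled by `2^(-coupling_strength * beta_miRNA)`; planted nat-siRNA
#' regulons have the driver transcript up, the partner down and the pair's
#' siRNA cluster up at the planted time point.
#'
#' @param sim a catalog bundle from [generate_catalog()].
#' @param config a [sim_config()] (defaults to the one stored in `sim`).
#' @return list with `srna_counts`, `mrna_counts` (integer matrices),
#'   `design`, and `truth` (planted effects and pairs).
#' @export
simulate_counts <- function(sim, config = sim$config) {
  set.seed(substream_seed(config$seed, 2))
  design <- make_design(config)
  n_s <- nrow(design)

  srna_ids <- sim$clusters$id
  mrna_ids <- names(sim$transcript_seq)

  draw_base <- function(ids, total) {
    q <- stats::rlnorm(length(ids), meanlog = log(30), sdlog = 2)
    q * (total / sum(q))
  }
  draw_alpha <- function(n) {
    if (!is.null(config$nb_dispersion)) rep(config$nb_dispersion, n) else
      exp(stats::runif(n, log(0.01), log(0.5)))
  }

  sf <- stats::rlnorm(n_s, 0, 0.15)
  names(sf) <- design$sample

  # Planted DE: time-point-specific, independent for the two layers.
  plant_de <- function(ids) {
    n_de <- max(0L, round(config$de_fraction * length(ids)))
    de_ids <- if (n_de > 0) sample(ids, n_de) else character(0)
    data.frame(feature = de_ids,
               time = sample(TIME_POINTS, n_de, replace = TRUE),
               log2fc = sample(c(-1, 1), n_de, replace = TRUE) *
                 config$de_log2fc,
               stringsAsFactors = FALSE)
  }
  de_srna <- plant_de(srna_ids)
  de_mrna <- plant_de(mrna_ids)

  # Planted regulons on the first half of each NAT pair set: driver up,
  # partner down, siRNA cluster up, all at one random time point.
  regulons <- list()
  take_regulon <- function(kind, a_prefix, b_prefix, sirna_prefix, n_pairs) {
    n_reg <- floor(n_pairs / 2)
    for (i in seq_len(n_reg)) {
      tp <- sample(TIME_POINTS, 1)
      regulons[[length(regulons) + 1]] <<- data.frame(
        pair = sprintf("%s%03d", sirna_prefix, i), kind = kind,
        driver = sprintf("%s%03d", a_prefix, i),
        partner = sprintf("%s%03d", b_prefix, i), time = tp,
        stringsAsFactors = FALSE)
    }
  }
  take_regulon("cis", "CISA", "CISB", "sirna_cis", config$n_cis_nat_pairs)
  take_regulon("trans", "TRAA", "TRAB", "sirna_tra",
               config$n_trans_nat_pairs)
  regulons <- if (length(regulons)) do.call(rbind, regulons) else
    data.frame(pair = character(0), kind = character(0),
               driver = character(0), partner = character(0),
               time = character(0))

  add_effect <- function(de, feature, time, log2fc) {
    de <- de[de$feature != feature, , drop = FALSE]
    rbind(de, data.frame(feature = feature, time = time, log2fc = log2fc,
                         stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(regulons))) {
    de_mrna <- add_effect(de_mrna, regulons$driver[i], regulons$time[i],
                          config$de_log2fc)
    de_mrna <- add_effect(de_mrna, regulons$partner[i], regulons$time[i],
                          -config$de_log2fc)
    de_srna <- add_effect(de_srna, regulons$pair[i], regulons$time[i],
                          config$de_log2fc)
  }

  # miRNA:target coupling for planted pairs whose miRNA is DE.
  mir_de <- de_srna[de_srna$feature %in% sim$planted_pairs$mirna, ,
                    drop = FALSE]
  pairs <- sim$planted_pairs
  pairs$expected <- "mirna_not_de"
  coupled <- data.frame(feature = character(0), time = character(0),
                        log2fc = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mir_de))) {
    j <- which(pairs$mirna == mir_de$feature[i])[1]
    beta_t <- -config$coupling_strength * mir_de$log2fc[i]
    de_mrna <- add_effect(de_mrna, pairs$target[j], mir_de$time[i], beta_t)
    coupled <- rbind(coupled, data.frame(feature = pairs$target[j],
                                         time = mir_de$time[i],
                                         log2fc = beta_t,
                                         stringsAsFactors = FALSE))
    pairs$expected[j] <- if (abs(beta_t) >= 1) "inverse" else
      "partner_unchanged"
  }

  # Features carrying planted regulons or miRNA:target couplings get a
  # base-mean floor so the planted effects are detectable at desk scale
  # (the regulons the study describes are all well-expressed loci).
  floor_ids <- unique(c(regulons$pair, regulons$driver, regulons$partner,
                        pairs$mirna, pairs$target))

  # The floor is expressed relative to depth (100 normalized counts at the
  # default 2e5 library) so column sums still scale with library size.
  base_floor <- 100 * config$library_size_mean / 2e5

  # Each layer draws from its own substream so the mRNA draws do not
  # depend on how many uniforms the sRNA NB sampler consumed.
  draw_layer <- function(ids, de, stream) {
    set.seed(substream_seed(config$seed, stream))
    q <- draw_base(ids, config$library_size_mean)
    q[ids %in% floor_ids] <- pmax(q[ids %in% floor_ids], base_floor)
    alpha <- draw_alpha(length(ids))
    alpha[ids %in% floor_ids] <- pmin(alpha[ids %in% floor_ids], 0.05)
    mu <- outer(q, sf)  # features x samples
    for (i in seq_len(nrow(de))) {
      f <- match(de$feature[i], ids)
      cold_cols <- design$condition == "cold" & design$time == de$time[i]
      mu[f, cold_cols] <- mu[f, cold_cols] * 2^de$log2fc[i]
    }
    m <- matrix(stats::rnbinom(length(mu), mu = mu,
                               size = rep(1 / alpha, n_s)),
                nrow = length(ids), dimnames = list(ids, design$sample))
    m
  }

  srna_counts <- draw_layer(srna_ids, de_srna, stream = 21)
  mrna_counts <- draw_layer(mrna_ids, de_mrna, stream = 22)

  truth <- list(
    de_srna = de_srna, de_mrna = de_mrna, coupled_targets = coupled,
    planted_target_pairs = pairs, planted_regulons = regulons,
    noise_sd = config$edge_noise_sd)

  list(srna_counts = srna_counts, mrna_counts = mrna_counts,
       design = design, truth = truth)
}

#' Simulate regulator-driven target expression
#'
#' Regulator log-expression is drawn log-normally per time point; each
#' target's log-expression is an additive signed-weight function of its
#' regulators' expression plus Gaussian noise. The generating weights are
#' returned as ground truth so the analytic noise ceiling of any predictor
#' is computable.
#'
#' @param network a [build_network()] result; every scored target needs at
#'   least one functional edge. If the edge table has a `weight` column it
#'   is used as the generating weight, otherwise weights are drawn
#'   `sign * U(0.5, 1)`.
#' @param config a [sim_config()]; `edge_noise_sd` is the noise sd. Pass
#'   `edge_noise_sd = 0` for a noise-free identity check.
#' @return list with `expression` (targets x samples, log scale),
#'   `regulator_expression`, `design`, and `truth` (functional edges with
#'   weights, noise sd, and the noise-free signal matrix).
#' @export
simulate_regulated_expression <- function(network, config) {
  set.seed(substream_seed(config$seed, 3))
  design <- make_design(config)
  edges <- network$edges
  regulators <- unique(edges$regulator)
  targets <- unique(edges$target)

  # Per-regulator time-point shifts (sd 0.5) on top of dominant per-sample
  # biological variation (sd 1), all on the log scale around a base of 4.
  tmean <- matrix(stats::rnorm(length(regulators) * length(TIME_POINTS),
                               mean = 4, sd = 0.5),
                  nrow = length(regulators),
                  dimnames = list(regulators, TIME_POINTS))
  reg_expr <- tmean[, design$time, drop = FALSE] +
    matrix(stats::rnorm(length(regulators) * nrow(design), 0, 1),
           nrow = length(regulators))
  colnames(reg_expr) <- design$sample

  if (is.null(edges$weight)) {
    edges$weight <- sample(c(-1, 1), nrow(edges), replace = TRUE) *
      stats::runif(nrow(edges), 0.5, 1)
  }

  no_reg <- setdiff(targets, edges$target)
  if (length(no_reg)) {
    message("simulate_regulated_expression: excluding ", length(no_reg),
            " target(s) with no regulator")
  }

  signal <- matrix(0, nrow = length(targets), ncol = nrow(design),
                   dimnames = list(targets, design$sample))
  for (i in seq_len(nrow(edges))) {
    signal[edges$target[i], ] <- signal[edges$target[i], ] +
      edges$weight[i] * reg_expr[edges$regulator[i], ]
  }
  noise <- matrix(stats::rnorm(length(signal), 0, config$edge_noise_sd),
                  nrow = nrow(signal))
  expr <- signal + noise

  list(expression = expr, regulator_expression = reg_expr, design = design,
       truth = list(functional_edges = edges, noise_sd = config$edge_noise_sd,
                    signal = signal))
}

#' Noise sd achieving a prescribed predictive-power ceiling
#'
#' For a target with expression `y = s + e`, `e ~ N(0, sd^2)`, the best
#' attainable within-target Pearson correlation between any prediction of
#' `s` and `y` is `sqrt(V / (V + sd^2))` with `V` the target's signal
#' variance across samples. This solves for the `sd` at which the mean of
#' that ceiling over all targets (rows of the realized signal matrix)
#' equals `r`.
#'
#' @param signal numeric matrix of noise-free signal values
#'   (targets x samples).
#' @param r desired mean ceiling correlation in (0, 1).
#' @return noise standard deviation.
#' @export
noise_sd_for_ceiling <- function(signal, r) {
  stopifnot(r > 0, r < 1)
  v <- apply(signal, 1, stats::var)
  v <- v[v > 0]
  f <- function(s) mean(sqrt(v / (v + s^2))) - r
  stats::uniroot(f, c(1e-9, 1e3 * sqrt(max(v))))$root
}

#' Write all synthetic outputs to a directory
#'
#' Emits the locus catalog (GFF3), mature miRNA and transcript sequences
#' (FASTA), sRNA cluster intervals, count matrices and the design sheet
#' (TSV), and the ground truth as a flat key-value text file.
#'
#' @param sim catalog bundle from [generate_catalog()].
#' @param counts result of [simulate_counts()].
#' @param outdir output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, counts, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_gff3(sim$catalog, file.path(outdir, "catalog.gff3"))
  write_fasta(sim$mirna_seq, file.path(outdir, "mirna.fasta"))
  write_fasta(sim$transcript_seq, file.path(outdir, "transcripts.fasta"))
  write_tsv_file(sim$clusters, file.path(outdir, "clusters.tsv"))
  write_counts(counts$srna_counts, file.path(outdir, "srna_counts.tsv"))
  write_counts(counts$mrna_counts, file.path(outdir, "mrna_counts.tsv"))
  write_tsv_file(counts$design, file.path(outdir, "design.tsv"))
  write_truth(counts$truth, file.path(outdir, "truth.txt"))
  invisible(outdir)
}

write_truth <- function(truth, path) {
  lines <- character(0)
  emit <- function(prefix, df) {
    for (i in seq_len(nrow(df))) {
      kv <- paste(sprintf("%s=%s", names(df), as.character(df[i, ])),
                  collapse = ";")
      lines <<- c(lines, sprintf("%s\t%s", prefix, kv))
    }
  }
  emit("de_srna", truth$de_srna)
  emit("de_mrna", truth$de_mrna)
  emit("planted_pair", truth$planted_target_pairs)
  emit("regulon", truth$planted_regulons)
  lines <- c(lines, sprintf("noise_sd\t%s", truth$noise_sd))
  writeLines(lines, path)
  invisible(path)
}
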