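#' Pipeline configuration
#'
#' Bundles the analysis thresholds and the simulation configuration for
#' [run_pipeline()]. Thresholds default to the study-wide values: fold
#' change 2, adjusted p 0.05, detection at 5 normalized reads, target
#' expectation cutoff 2.5, maximum target-site unpairing energy 25, and
#' the relaxed classical-regulon mode.
#'
#' @param sim a [sim_config()] for the synthetic inputs.
#' @param fc,alpha_level,detection differential-expression thresholds.
#' @param expectation_cutoff,upe_max target-prediction thresholds.
#' @param classical_mode `"relaxed"` or `"strict"`.
#' @param grn_nrounds boosted-tree rounds for predictive power.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), fc = 2, alpha_level = 0.05,
                            detection = 5, expectation_cutoff = 2.5,
                            upe_max = 25,
                            classical_mode = c("relaxed", "strict"),
                            grn_nrounds = 100) {
  classical_mode <- match.arg(classical_mode)
  stopifnot(fc > 0, alpha_level > 0, detection > 0, expectation_cutoff > 0,
            upe_max > 0)
  structure(list(sim = sim, fc = fc, alpha_level = alpha_level,
                 detection = detection,
                 expectation_cutoff = expectation_cutoff, upe_max = upe_max,
                 classical_mode = classical_mode,
                 grn_nrounds = grn_nrounds),
            class = "pipeline_config")
}

#' Run the full synthetic-data pipeline
#'
#' Executes simulate, quantify, differential expression, target
#' prediction, pair classification, enrichment and the regulatory-network
#' stage, writing every stage's tables under `outdir` plus a single
#' machine-readable `summary.json` and a `run.log`. The summary is a pure
#' function of the configuration (including its seed): rerunning with the
#' same seed reproduces it byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return the summary, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  logf("coldsrna %s", as.character(utils::packageVersion("coldsrna")))
  logf("seed=%d fc=%g alpha=%g detection=%g expectation_cutoff=%g upe_max=%g classical_mode=%s",
       config$sim$seed, config$fc, config$alpha_level, config$detection,
       config$expectation_cutoff, config$upe_max, config$classical_mode)

  sim <- stage("simulate", generate_catalog(config$sim))
  counts <- stage("simulate", simulate_counts(sim))
  stage("simulate", write_simulation(sim, counts, file.path(outdir,
                                                            "simulate")))

  classes <- stage("quantify", assign_class(sim$clusters, sim$catalog))
  srna_rpm <- stage("quantify", rpm(counts$srna_counts))
  write_counts(round(srna_rpm, 4), file.path(outdir, "srna_rpm.tsv"))

  de_srna <- stage("de", de_all_timepoints(
    counts$srna_counts, counts$design, batch = classes, fc = config$fc,
    alpha_level = config$alpha_level, detection = config$detection))
  de_mrna <- stage("de", de_all_timepoints(
    counts$mrna_counts, counts$design, fc = config$fc,
    alpha_level = config$alpha_level, detection = config$detection))
  write_tsv_file(de_srna, file.path(outdir, "de_srna.tsv"))
  write_tsv_file(de_mrna, file.path(outdir, "de_mrna.tsv"))
  dir_summary <- stage("quantify",
                       class_direction_summary(de_srna, classes))
  write_tsv_file(dir_summary, file.path(outdir, "class_direction.tsv"))

  hits <- stage("targets", find_targets(sim$mirna_seq, sim$transcript_seq,
                                        cutoff = config$expectation_cutoff,
                                        upe_max = config$upe_max))
  write_tsv_file(hits, file.path(outdir, "target_hits.tsv"))
  de_mir <- de_srna[de_srna$feature %in% names(sim$mirna_seq), ,
                    drop = FALSE]
  pair_table <- stage("targets", join_targets_to_de(hits, de_mir, de_mrna))
  if (nrow(pair_table)) {
    pair_table$category <- classify_mirna_pair(pair_table$mirna_status,
                                               pair_table$target_status)
  } else {
    pair_table$category <- character(0)
  }
  write_tsv_file(pair_table, file.path(outdir, "mirna_mrna_pairs.tsv"))

  sirna_map <- data.frame(cluster = sim$clusters$id,
                          member = sim$clusters$source_id,
                          stringsAsFactors = FALSE)
  nat <- stage("pairs", do.call(rbind, lapply(TIME_POINTS, function(tp) {
    classify_nat_pairs(sim$catalog, sirna_map,
                       de_srna[de_srna$time == tp, , drop = FALSE],
                       de_mrna[de_mrna$time == tp, , drop = FALSE],
                       mode = config$classical_mode)
  })))
  write_tsv_file(nat, file.path(outdir, "nat_pairs.tsv"))

  # Synthetic term map over target genes, derived from the seed.
  set.seed(substream_seed(config$sim$seed, 40))
  genes <- rownames(counts$mrna_counts)
  bm <- rowMeans(sweep(counts$mrna_counts, 2,
                       size_factors(counts$mrna_counts), "/"))
  background <- genes[bm >= config$detection]
  term_map <- data.frame(
    gene = rep(genes, 2),
    term = sprintf("TERM%02d", sample(1:10, 2 * length(genes),
                                      replace = TRUE)),
    stringsAsFactors = FALSE)
  de_genes <- intersect(unique(
    de_mrna$feature[de_mrna$status %in% c("up", "down")]), background)
  enr <- stage("enrich", if (length(de_genes)) {
    enrich(de_genes, term_map, background)
  } else {
    enrich(character(0), term_map, background)
  })
  write_tsv_file(enr, file.path(outdir, "enrichment.tsv"))

  # Regulatory network from synthetic tiered edge tables.
  set.seed(substream_seed(config$sim$seed, 50))
  tf_ids <- grep("^TF", rownames(counts$mrna_counts), value = TRUE)
  gene_ids <- grep("^GENE", rownames(counts$mrna_counts), value = TRUE)
  edge_tabs <- lapply(stats::setNames(TF_SOURCES, TF_SOURCES),
                      function(src) {
    data.frame(regulator = sample(tf_ids, 3 * length(tf_ids),
                                  replace = TRUE),
               target = sample(gene_ids, 3 * length(tf_ids),
                               replace = TRUE),
               binding_site_count = sample(1:3, 3 * length(tf_ids),
                                           replace = TRUE),
               stringsAsFactors = FALSE)
  })
  fam <- sim$catalog$family
  names(fam) <- sim$catalog$id
  fam2 <- fam[!is.na(fam)]
  net <- stage("grn", build_network(edge_tabs, mirna_hits = hits,
                                    families = fam2))
  mods <- stage("grn", detect_modules(net, seed = config$sim$seed))
  net <- mods$network
  de_ids <- unique(c(de_srna$feature[de_srna$status %in% c("up", "down")],
                     de_mrna$feature[de_mrna$status %in% c("up", "down")]))
  subnet <- stage("grn", extract_cold_subnetwork(net, de_ids))
  write_graphml(net, file.path(outdir, "network.graphml"))
  write_gexf(net, file.path(outdir, "network.gexf"))
  write_gexf(subnet, file.path(outdir, "cold_subnetwork.gexf"))

  regexpr_sim <- stage("grn", simulate_regulated_expression(net,
                                                            config$sim))
  expr_all <- rbind(regexpr_sim$expression,
                    regexpr_sim$regulator_expression)
  expr_all <- expr_all[!duplicated(rownames(expr_all)), , drop = FALSE]
  pp <- stage("grn", compare_versions(net, expr_all, regexpr_sim$design,
                                      seed = config$sim$seed,
                                      nrounds = config$grn_nrounds))
  write_tsv_file(pp, file.path(outdir, "predictive_power.tsv"))

  summary <- list(
    seed = config$sim$seed,
    features = list(srna = nrow(counts$srna_counts),
                    mrna = nrow(counts$mrna_counts)),
    de = list(srna = sum(de_srna$status %in% c("up", "down")),
              mrna = sum(de_mrna$status %in% c("up", "down"))),
    mirna_mrna_categories = as.list(table(pair_table$category)),
    nat_patterns = as.list(table(nat$pattern)),
    classical_regulons = sum(nat$classical),
    target_hits = nrow(hits),
    enriched_terms = sum(enr$p_adj <= config$alpha_level),
    network = list(nodes = nrow(net$nodes), edges = nrow(net$edges),
                   modules = length(unique(net$nodes$module)),
                   modularity = round(mods$modularity, 10),
                   subnetwork_nodes = nrow(subnet$nodes),
                   subnetwork_edges = nrow(subnet$edges)),
    predictive_power = stats::setNames(as.list(round(pp$mean_r, 10)),
                                       pp$version))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("completed: %d sRNA features, %d mRNA features, %d network edges",
       nrow(counts$srna_counts), nrow(counts$mrna_counts),
       nrow(net$edges))
  invisible(summary)
}
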