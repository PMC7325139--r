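# Evidence tiers for TF-based edges, highest confidence first. miRNA
# edges are a different regulator kind and never collapse with TF edges.
TF_SOURCES <- c("validated", "CE", "FunTFBS")
EDGE_SOURCES <- c(TF_SOURCES, "miRNA_predicted")

#' Build the miRNA-TF regulatory network from tiered evidence
#'
#' Takes TF edge tables by evidence source plus predicted miRNA target
#' hits, and merges them into one typed network. Duplicate
#' (regulator, target) TF edges collapse to the highest-confidence source
#' (validated > CE > FunTFBS); miRNA-predicted edges are kept separate
#' from TF edges. Rows with missing ids and miRNA self-loops are dropped
#' with a count in a message. Node roles (miRNA/TF/target, not exclusive)
#' are inferred from edge membership.
#'
#' @param edge_tables named list of data frames, names among `validated`,
#'   `CE`, `FunTFBS`, each with columns `regulator`, `target` and
#'   optionally `binding_site_count` (default 1).
#' @param mirna_hits optional data frame from [find_targets()]; the number
#'   of hits per (miRNA, transcript) becomes the binding-site count.
#' @param families optional named vector node id -> family label; nodes
#'   without one form their own singleton family.
#' @return a `regulatory_network`: list with `nodes` (id, is_mirna, is_tf,
#'   is_target, family, module) and `edges` (regulator, target, source,
#'   binding_site_count).
#' @export
build_network <- function(edge_tables = list(), mirna_hits = NULL,
                          families = NULL) {
  bad <- setdiff(names(edge_tables), TF_SOURCES)
  if (length(bad)) {
    stop("build_network: unknown edge table(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tf_edges <- list()
  n_dropped <- 0L
  for (src in intersect(TF_SOURCES, names(edge_tables))) {
    tab <- edge_tables[[src]]
    if (is.null(tab) || !nrow(tab)) next
    bs <- tab$binding_site_count %||% rep(1L, nrow(tab))
    keep <- !is.na(tab$regulator) & !is.na(tab$target) &
      nzchar(tab$regulator) & nzchar(tab$target)
    n_dropped <- n_dropped + sum(!keep)
    tf_edges[[src]] <- data.frame(regulator = tab$regulator[keep],
                                  target = tab$target[keep], source = src,
                                  binding_site_count = bs[keep],
                                  stringsAsFactors = FALSE)
  }
  tf <- if (length(tf_edges)) do.call(rbind, tf_edges) else
    data.frame(regulator = character(0), target = character(0),
               source = character(0), binding_site_count = integer(0),
               stringsAsFactors = FALSE)
  # Collapse duplicates keeping the highest-confidence source.
  if (nrow(tf)) {
    tf <- tf[order(match(tf$source, TF_SOURCES)), , drop = FALSE]
    tf <- tf[!duplicated(paste(tf$regulator, tf$target)), , drop = FALSE]
  }

  mir <- data.frame(regulator = character(0), target = character(0),
                    source = character(0), binding_site_count = integer(0),
                    stringsAsFactors = FALSE)
  if (!is.null(mirna_hits) && nrow(mirna_hits)) {
    keep <- !is.na(mirna_hits$mirna) & !is.na(mirna_hits$transcript)
    n_dropped <- n_dropped + sum(!keep)
    hh <- mirna_hits[keep, , drop = FALSE]
    self <- hh$mirna == hh$transcript
    if (any(self)) {
      n_dropped <- n_dropped + sum(self)
      hh <- hh[!self, , drop = FALSE]
    }
    agg <- stats::aggregate(list(binding_site_count = rep(1L, nrow(hh))),
                            by = list(regulator = hh$mirna,
                                      target = hh$transcript), FUN = sum)
    if (nrow(agg)) {
      mir <- data.frame(regulator = agg$regulator, target = agg$target,
                        source = "miRNA_predicted",
                        binding_site_count = agg$binding_site_count,
                        stringsAsFactors = FALSE)
    }
  }
  if (n_dropped > 0) {
    message("build_network: dropped ", n_dropped,
            " edge row(s) (missing ids or miRNA self-loops)")
  }
  edges <- rbind(tf, mir)
  edges <- edges[order(edges$regulator, edges$target,
                       match(edges$source, EDGE_SOURCES)), , drop = FALSE]
  rownames(edges) <- NULL

  ids <- sort(unique(c(edges$regulator, edges$target)))
  nodes <- data.frame(
    id = ids,
    is_mirna = ids %in% mir$regulator,
    is_tf = ids %in% tf$regulator,
    is_target = ids %in% edges$target,
    family = rep(NA_character_, length(ids)),
    module = rep(NA_integer_, length(ids)),
    stringsAsFactors = FALSE)
  if (!is.null(families)) {
    nodes$family <- unname(families[nodes$id])
  }
  nodes$family[is.na(nodes$family)] <- nodes$id[is.na(nodes$family)]
  structure(list(nodes = nodes, edges = edges),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf(paste0("regulatory_network: %d nodes (%d miRNA, %d TF, ",
                     "%d targets), %d edges\n"),
              nrow(x$nodes), sum(x$nodes$is_mirna), sum(x$nodes$is_tf),
              sum(x$nodes$is_target), nrow(x$edges)))
  if (nrow(x$edges)) print(table(source = x$edges$source))
  if (!all(is.na(x$nodes$module))) {
    cat(sprintf("modules: %d\n", length(unique(stats::na.omit(
      x$nodes$module)))))
  }
  invisible(x)
}

#' Restrict a network to an evidence version
#'
#' Versions are nested on the validated base: `validated_only`, `plus_CE`
#' (validated + CE), `plus_FunTFBS` (+ FunTFBS), and `combined`
#' (+ miRNA-predicted edges).
#'
#' @param network a `regulatory_network`.
#' @param version one of `"validated_only"`, `"plus_CE"`,
#'   `"plus_FunTFBS"`, `"combined"`.
#' @return a `regulatory_network` with the subset of edges.
#' @export
network_version <- function(network, version = c("validated_only",
                                                 "plus_CE", "plus_FunTFBS",
                                                 "combined")) {
  version <- match.arg(version)
  keep_src <- switch(version,
                     validated_only = "validated",
                     plus_CE = c("validated", "CE"),
                     plus_FunTFBS = TF_SOURCES,
                     combined = EDGE_SOURCES)
  edges <- network$edges[network$edges$source %in% keep_src, , drop = FALSE]
  ids <- unique(c(edges$regulator, edges$target))
  nodes <- network$nodes[network$nodes$id %in% ids, , drop = FALSE]
  rownames(edges) <- rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "regulatory_network")
}

# Undirected simple edge list (i, j, weight) over node index 1..n, with
# self-loops and duplicate/antiparallel edges merged away.
undirected_edges <- function(network) {
  ids <- network$nodes$id
  i <- match(network$edges$regulator, ids)
  j <- match(network$edges$target, ids)
  keep <- i != j
  i2 <- pmin(i[keep], j[keep])
  j2 <- pmax(i[keep], j[keep])
  key <- paste(i2, j2)
  dup <- duplicated(key)
  data.frame(i = i2[!dup], j = j2[!dup], w = 1)
}

#' Modularity of a partition
#'
#' `Q = sum_c (e_c / m - gamma * (d_c / (2 m))^2)` over communities `c`,
#' with `e_c` the within-community edge weight, `d_c` the total degree of
#' the community and `m` the total edge weight; the network is treated as
#' undirected and simple.
#'
#' @param network a `regulatory_network`.
#' @param membership integer vector of community labels, one per node (in
#'   `network$nodes` order).
#' @param gamma resolution parameter (default 1).
#' @return modularity Q.
#' @export
modularity_q <- function(network, membership, gamma = 1) {
  ed <- undirected_edges(network)
  m <- sum(ed$w)
  if (m == 0) return(0)
  deg <- numeric(nrow(network$nodes))
  for (r in seq_len(nrow(ed))) {
    deg[ed$i[r]] <- deg[ed$i[r]] + ed$w[r]
    deg[ed$j[r]] <- deg[ed$j[r]] + ed$w[r]
  }
  q <- 0
  for (c in unique(membership)) {
    in_c <- membership == c
    e_c <- sum(ed$w[in_c[ed$i] & in_c[ed$j]])
    d_c <- sum(deg[in_c])
    q <- q + e_c / m - gamma * (d_c / (2 * m))^2
  }
  q
}

#' Detect network modules by greedy modularity maximization
#'
#' Louvain-style community detection: repeated local node moves (in an
#' order shuffled under the seed) followed by community aggregation, until
#' modularity stops improving. Several restarts with derived seeds are run
#' and the best partition kept, so the result is deterministic given the
#' seed.
#'
#' @param network a `regulatory_network` (treated as undirected).
#' @param resolution resolution parameter gamma (default 1).
#' @param seed integer seed for node-order shuffling.
#' @param n_restart independent restarts (default 8).
#' @return list with `membership` (named by node id), `modularity`, and
#'   `network` (input with `nodes$module` filled in).
#' @export
detect_modules <- function(network, resolution = 1.0, seed = 1,
                           n_restart = 8) {
  n <- nrow(network$nodes)
  if (n == 0) stop("detect_modules: empty network", call. = FALSE)
  ed <- undirected_edges(network)
  best <- list(membership = seq_len(n), q = -Inf)
  for (r in seq_len(n_restart)) {
    s <- substream_seed(seed, 100 + r)
    # First restart starts from singletons (classic Louvain); the others
    # start from random coarse partitions, which lets the local moves
    # escape the pairwise-merge local optima of small sparse graphs.
    init <- if (r == 1) seq_len(n) else {
      set.seed(s)
      sample.int(max(2L, sample.int(n, 1)), n, replace = TRUE)
    }
    memb <- louvain_run(ed, n, resolution, s, init)
    q <- modularity_q(network, memb, resolution)
    if (q > best$q + 1e-12) best <- list(membership = memb, q = q)
  }
  memb <- match(best$membership, unique(best$membership))
  names(memb) <- network$nodes$id
  network$nodes$module <- memb
  list(membership = memb, modularity = best$q, network = network)
}

# One full Louvain run (levels of local moves + aggregation), optionally
# from a non-singleton initial partition of the original nodes.
louvain_run <- function(ed, n, gamma, seed, init = seq_len(n)) {
  set.seed(seed)
  # Current aggregated graph: edge list + self weights per super node.
  cur <- ed
  self_w <- numeric(n)
  node_map <- seq_len(n)  # original node -> current super node
  init_cur <- match(init, unique(init))
  first <- TRUE
  repeat {
    n_cur <- max(node_map)
    res <- louvain_local(cur, self_w, n_cur, gamma,
                         init = if (first) init_cur else seq_len(n_cur))
    first <- FALSE
    comm <- match(res$membership, unique(res$membership))
    node_map <- comm[node_map]
    if (!res$moved) break
    # Aggregate: communities become super nodes.
    n_new <- max(comm)
    new_self <- numeric(n_new)
    for (k in seq_len(n_cur)) new_self[comm[k]] <- new_self[comm[k]] +
        self_w[k]
    if (nrow(cur)) {
      ci <- comm[cur$i]
      cj <- comm[cur$j]
      intra <- ci == cj
      for (r in which(intra)) new_self[ci[r]] <- new_self[ci[r]] + cur$w[r]
      inter <- !intra
      i2 <- pmin(ci[inter], cj[inter])
      j2 <- pmax(ci[inter], cj[inter])
      w2 <- cur$w[inter]
      if (length(i2)) {
        key <- paste(i2, j2)
        agg <- rowsum(w2, key)
        parts <- do.call(rbind, strsplit(rownames(agg), " "))
        cur <- data.frame(i = as.integer(parts[, 1]),
                          j = as.integer(parts[, 2]), w = agg[, 1])
      } else {
        cur <- data.frame(i = integer(0), j = integer(0), w = numeric(0))
      }
    }
    self_w <- new_self
    if (n_new == n_cur) break
  }
  node_map
}

# Local-move phase on the aggregated graph. Returns membership over super
# nodes and whether any move improved modularity.
louvain_local <- function(ed, self_w, n, gamma, init = seq_len(n)) {
  memb <- init
  m <- sum(ed$w) + sum(self_w)
  if (m == 0) return(list(membership = memb, moved = FALSE))
  # Adjacency lists.
  nbr <- vector("list", n)
  for (r in seq_len(nrow(ed))) {
    nbr[[ed$i[r]]] <- rbind(nbr[[ed$i[r]]], c(ed$j[r], ed$w[r]))
    nbr[[ed$j[r]]] <- rbind(nbr[[ed$j[r]]], c(ed$i[r], ed$w[r]))
  }
  deg <- self_w * 2
  for (r in seq_len(nrow(ed))) {
    deg[ed$i[r]] <- deg[ed$i[r]] + ed$w[r]
    deg[ed$j[r]] <- deg[ed$j[r]] + ed$w[r]
  }
  tot <- numeric(n)  # total degree per community label
  for (v in seq_len(n)) tot[memb[v]] <- tot[memb[v]] + deg[v]
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    for (v in sample.int(n)) {
      cv <- memb[v]
      links <- nbr[[v]]
      # Weight of links from v to each neighboring community.
      lc <- c()
      if (!is.null(links)) {
        lc <- tapply(links[, 2], memb[links[, 1]], sum)
      }
      tot[cv] <- tot[cv] - deg[v]
      cand <- unique(c(cv, as.integer(names(lc))))
      gain <- vapply(cand, function(cc) {
        l <- if (as.character(cc) %in% names(lc))
          lc[[as.character(cc)]] else 0
        l / m - gamma * deg[v] * tot[cc] / (2 * m^2)
      }, numeric(1))
      bestc <- cand[order(-gain, cand)][1]
      tot[bestc] <- tot[bestc] + deg[v]
      if (bestc != cv) {
        memb[v] <- bestc
        moved <- TRUE
        moved_any <- TRUE
      }
    }
    if (!moved) break
  }
  list(membership = memb, moved = moved_any)
}

#' Extract the cold-responsive subnetwork
#'
#' Keeps differentially expressed miRNAs, their targets DE at one or more
#' time points, TF intermediaries whose own transcript is a kept miRNA
#' target, and those TFs' downstream targets DE at one or more time
#' points; edges are the induced ones. The operation is idempotent.
#'
#' @param network a `regulatory_network`.
#' @param de_sets character vector of DE feature ids, or a list of such
#'   vectors (one per time point; the union is used).
#' @return a `regulatory_network`.
#' @export
extract_cold_subnetwork <- function(network, de_sets) {
  de <- unique(unlist(de_sets))
  nodes <- network$nodes
  edges <- network$edges
  mir_edges <- edges[edges$source == "miRNA_predicted", , drop = FALSE]
  tf_edges <- edges[edges$source != "miRNA_predicted", , drop = FALSE]

  kept_mirna <- intersect(nodes$id[nodes$is_mirna], de)
  mir_targets <- intersect(
    mir_edges$target[mir_edges$regulator %in% kept_mirna], de)
  kept_tf <- intersect(nodes$id[nodes$is_tf], mir_targets)
  tf_targets <- intersect(tf_edges$target[tf_edges$regulator %in% kept_tf],
                          de)
  keep <- unique(c(kept_mirna, mir_targets, kept_tf, tf_targets))
  sub_edges <- edges[edges$regulator %in% keep & edges$target %in% keep, ,
                     drop = FALSE]
  sub_nodes <- nodes[nodes$id %in% keep, , drop = FALSE]
  rownames(sub_edges) <- rownames(sub_nodes) <- NULL
  structure(list(nodes = sub_nodes, edges = sub_edges),
            class = "regulatory_network")
}

#' Validate network edges by predicting target expression
#'
#' For every target with at least one regulator in the network, builds a
#' feature vector per (target, sample): a time-point one-hot, the
#' familywise-aggregated log-expression of the target's regulators (one
#' feature per regulator family, summing that family's regulators
#' restricted to the target's own regulators), and the familywise
#' binding-site counts. A gradient-boosted regression-tree model is fit
#' under k-fold cross-validation partitioned by target gene; the
#' predictive power is the mean over targets of the within-target Pearson
#' correlation between out-of-fold predicted and measured expression (the
#' pooled correlation over all predictions is also reported).
#'
#' @param network a `regulatory_network` (or a version of one).
#' @param expression log-scale expression matrix (features x samples)
#'   covering regulators and targets.
#' @param design design sheet matching the expression columns.
#' @param cv_folds folds for target-partitioned cross-validation.
#' @param seed integer seed (fold assignment; the learner is deterministic
#'   single-threaded).
#' @param nrounds,max_depth,eta boosted-tree hyperparameters.
#' @return a `predictive_power` object: `mean_r` (mean per-target
#'   out-of-fold Pearson r), `pooled_r`, the per-target r distribution,
#'   and the targets scored and excluded.
#' @export
predictive_power <- function(network, expression, design, cv_folds = 5,
                             seed = 1, nrounds = 200, max_depth = 4,
                             eta = 0.1) {
  feats <- pp_features(network, expression, design)
  if (is.null(feats)) {
    stop("predictive_power: no target has a regulator with expression data",
         call. = FALSE)
  }
  x <- feats$x
  y <- feats$y
  tg <- feats$target
  targets <- unique(tg)
  set.seed(substream_seed(seed, 7))
  fold <- sample(rep_len(seq_len(cv_folds), length(targets)))
  names(fold) <- targets
  pred <- rep(NA_real_, length(y))
  for (f in seq_len(cv_folds)) {
    te <- tg %in% targets[fold == f]
    if (!any(te) || all(te)) next
    bst <- xgboost::xgboost(x[!te, , drop = FALSE], y[!te],
                            objective = "reg:squarederror",
                            nrounds = nrounds, max_depth = max_depth,
                            learning_rate = eta, nthreads = 1,
                            seed = substream_seed(seed, 20 + f),
                            verbosity = 0)
    pred[te] <- stats::predict(bst, x[te, , drop = FALSE])
  }
  ok <- !is.na(pred)
  pooled_r <- stats::cor(pred[ok], y[ok])
  per_target <- vapply(targets, function(t) {
    sel <- tg == t & ok
    if (sum(sel) < 3 || stats::sd(y[sel]) == 0 ||
        stats::sd(pred[sel]) == 0) return(NA_real_)
    stats::cor(pred[sel], y[sel])
  }, numeric(1))
  structure(list(mean_r = mean(per_target, na.rm = TRUE),
                 pooled_r = pooled_r,
                 per_target = data.frame(target = targets, r = per_target,
                                         stringsAsFactors = FALSE),
                 n_targets = length(targets),
                 n_excluded = feats$n_excluded,
                 n_samples = ncol(expression)),
            class = "predictive_power")
}

#' @export
print.predictive_power <- function(x, ...) {
  cat(sprintf(paste0("predictive_power: mean per-target out-of-fold ",
                     "Pearson r = %.3f (pooled %.3f) over %d targets ",
                     "(%d excluded, no regulator)\n"),
              x$mean_r, x$pooled_r, x$n_targets, x$n_excluded))
  qq <- stats::quantile(x$per_target$r, c(0.25, 0.5, 0.75), na.rm = TRUE)
  cat(sprintf("per-target r quartiles: %.3f / %.3f / %.3f\n",
              qq[1], qq[2], qq[3]))
  invisible(x)
}

# Feature construction shared by predictive_power.
pp_features <- function(network, expression, design) {
  edges <- network$edges
  nodes <- network$nodes
  fam <- nodes$family
  names(fam) <- nodes$id
  targets <- intersect(unique(edges$target), rownames(expression))
  targets <- targets[vapply(targets, function(t) {
    any(edges$regulator[edges$target == t] %in% rownames(expression))
  }, logical(1))]
  n_excluded <- length(setdiff(unique(edges$target), targets))
  if (!length(targets)) return(NULL)
  samples <- colnames(expression)
  families <- sort(unique(fam[unique(edges$regulator)]))
  tp_mat <- stats::model.matrix(~ 0 + factor(design$time,
                                             levels = TIME_POINTS))
  colnames(tp_mat) <- paste0("time_", TIME_POINTS)

  rows_x <- list()
  rows_y <- list()
  rows_t <- list()
  for (t in targets) {
    ee <- edges[edges$target == t &
                  edges$regulator %in% rownames(expression), , drop = FALSE]
    regf <- fam[ee$regulator]
    agg <- matrix(0, nrow = length(samples), ncol = length(families),
                  dimnames = list(samples, paste0("fam_", families)))
    bs <- stats::setNames(numeric(length(families)),
                          paste0("bs_", families))
    for (k in seq_len(nrow(ee))) {
      fcol <- paste0("fam_", regf[k])
      agg[, fcol] <- agg[, fcol] + expression[ee$regulator[k], samples]
      bs[paste0("bs_", regf[k])] <- bs[paste0("bs_", regf[k])] +
        ee$binding_site_count[k]
    }
    bsm <- matrix(bs, nrow = length(samples), ncol = length(bs),
                  byrow = TRUE, dimnames = list(samples, names(bs)))
    rows_x[[t]] <- cbind(tp_mat, agg, bsm)
    rows_y[[t]] <- expression[t, samples]
    rows_t[[t]] <- rep(t, length(samples))
  }
  list(x = do.call(rbind, rows_x), y = unlist(rows_y),
       target = unlist(rows_t), n_excluded = n_excluded)
}

#' Compare predictive power across nested network versions
#'
#' Runs [predictive_power()] on the four nested versions (validated only,
#' plus CE, plus FunTFBS, combined with miRNA edges) and returns a ranked
#' table.
#'
#' @inheritParams predictive_power
#' @param ... passed to [predictive_power()].
#' @return data frame: version, mean_r, n_targets, ranked by mean_r
#'   (attribute `reports` holds the full `predictive_power` objects).
#' @export
compare_versions <- function(network, expression, design, ...) {
  versions <- c("validated_only", "plus_CE", "plus_FunTFBS", "combined")
  reports <- list()
  rows <- list()
  for (v in versions) {
    nv <- network_version(network, v)
    if (!nrow(nv$edges)) next
    rep_v <- predictive_power(nv, expression, design, ...)
    reports[[v]] <- rep_v
    rows[[v]] <- data.frame(version = v, mean_r = rep_v$mean_r,
                            n_targets = rep_v$n_targets,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_r), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

# igraph view of the network (directed), node attributes carried over.
network_igraph <- function(network) {
  igraph::graph_from_data_frame(
    d = network$edges[, c("regulator", "target", "source",
                          "binding_site_count")],
    directed = TRUE, vertices = network$nodes)
}

#' Export a network to GraphML or GEXF
#'
#' GraphML goes through igraph. GEXF (for Gephi) is written directly as
#' minimal XML with node role and module attributes.
#'
#' @param network a `regulatory_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network_igraph(network), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_gexf <- function(network, path) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  role <- ifelse(network$nodes$is_mirna, "miRNA",
                 ifelse(network$nodes$is_tf, "TF", "target"))
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<gexf xmlns=\"http://www.gexf.net/1.2draft\" version=\"1.2\">",
    "  <graph mode=\"static\" defaultedgetype=\"directed\">",
    "    <attributes class=\"node\">",
    "      <attribute id=\"0\" title=\"role\" type=\"string\"/>",
    "      <attribute id=\"1\" title=\"module\" type=\"integer\"/>",
    "    </attributes>",
    "    <nodes>")
  for (i in seq_len(nrow(network$nodes))) {
    mod <- network$nodes$module[i]
    lines <- c(lines, sprintf(
      paste0("      <node id=\"%s\" label=\"%s\"><attvalues>",
             "<attvalue for=\"0\" value=\"%s\"/>",
             "<attvalue for=\"1\" value=\"%s\"/>",
             "</attvalues></node>"),
      esc(network$nodes$id[i]), esc(network$nodes$id[i]), role[i],
      if (is.na(mod)) "" else mod))
  }
  lines <- c(lines, "    </nodes>", "    <edges>")
  for (i in seq_len(nrow(network$edges))) {
    lines <- c(lines, sprintf(
      "      <edge id=\"%d\" source=\"%s\" target=\"%s\" label=\"%s\"/>",
      i - 1, esc(network$edges$regulator[i]), esc(network$edges$target[i]),
      network$edges$source[i]))
  }
  lines <- c(lines, "    </edges>", "  </graph>", "</gexf>")
  writeLines(lines, path)
  invisible(path)
}
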