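test_that("edge tables merge with source precedence and stable order", {
  val <- data.frame(regulator = c("TF1", "TF2"), target = c("g1", "g2"),
                    binding_site_count = c(2L, 1L))
  ce <- data.frame(regulator = c("TF1", "TF3"), target = c("g1", "g3"),
                   binding_site_count = c(1L, 1L))
  net <- build_network(list(validated = val, CE = ce))
  expect_equal(nrow(net$edges), 3L)
  dup <- net$edges[net$edges$regulator == "TF1" & net$edges$target == "g1", ]
  expect_identical(dup$source, "validated")
  expect_equal(dup$binding_site_count, 2L)
  # Set-arithmetic oracle for the de-duplicated union.
  want <- unique(rbind(val[, 1:2], ce[, 1:2]))
  expect_equal(nrow(net$edges), nrow(want))
  # Row order of the inputs must not matter.
  net2 <- build_network(list(validated = val[2:1, ], CE = ce[2:1, ]))
  expect_identical(net, net2)
  expect_equal(nrow(build_network(list())$edges), 0L)
})

test_that("miRNA edges stay separate from TF edges and drop self-loops", {
  val <- data.frame(regulator = "TFX", target = "g1",
                    binding_site_count = 1L)
  hits <- data.frame(mirna = c("miR1", "miR1", "miR2", "miR2"),
                     transcript = c("g1", "g1", "g2", "miR2"))
  expect_message(net <- build_network(list(validated = val),
                                      mirna_hits = hits), "dropped 1")
  expect_equal(sum(net$edges$source == "miRNA_predicted"), 2L)
  # Two hits on the same transcript become one edge with 2 binding sites.
  e <- net$edges[net$edges$regulator == "miR1", ]
  expect_equal(e$binding_site_count, 2L)
  expect_true(net$nodes$is_mirna[net$nodes$id == "miR1"])
  expect_true(net$nodes$is_tf[net$nodes$id == "TFX"])
  expect_true(net$nodes$is_target[net$nodes$id == "g1"])
  # g1 is a target of both a TF and a miRNA: two separate edges.
  expect_equal(sum(net$edges$target == "g1"), 2L)
})

test_that("network versions are nested on the validated base", {
  tabs <- list(
    validated = data.frame(regulator = "TF1", target = "g1",
                           binding_site_count = 1L),
    CE = data.frame(regulator = "TF2", target = "g2",
                    binding_site_count = 1L),
    FunTFBS = data.frame(regulator = "TF3", target = "g3",
                         binding_site_count = 1L))
  hits <- data.frame(mirna = "miR1", transcript = "g4")
  net <- build_network(tabs, mirna_hits = hits)
  sizes <- vapply(c("validated_only", "plus_CE", "plus_FunTFBS",
                    "combined"),
                  function(v) nrow(network_version(net, v)$edges),
                  numeric(1))
  expect_equal(unname(sizes), c(1, 2, 3, 4))
  keys <- lapply(c("validated_only", "plus_CE", "plus_FunTFBS",
                   "combined"), function(v) {
    e <- network_version(net, v)$edges
    paste(e$regulator, e$target)
  })
  for (i in 1:3) expect_true(all(keys[[i]] %in% keys[[i + 1]]))
})

test_that("modularity matches closed forms on reference graphs", {
  clique <- function(prefix) {
    g <- expand.grid(a = 1:4, b = 1:4)
    g <- g[g$a < g$b, ]
    cbind(paste0(prefix, g$a), paste0(prefix, g$b))
  }
  net <- net_from_pairs(rbind(clique("A"), clique("B")))
  mods <- detect_modules(net, seed = 1)
  expect_equal(mods$modularity, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(mods$membership)), 2L)
  # Both cliques end up whole.
  memb <- mods$membership
  expect_equal(length(unique(memb[paste0("A", 1:4)])), 1L)
  expect_equal(length(unique(memb[paste0("B", 1:4)])), 1L)
  # A complete graph has no community structure.
  g <- expand.grid(a = 1:5, b = 1:5)
  g <- g[g$a < g$b, ]
  full <- net_from_pairs(cbind(paste0("N", g$a), paste0("N", g$b)))
  mfull <- detect_modules(full, seed = 1)
  expect_equal(length(unique(mfull$membership)), 1L)
  expect_lte(mfull$modularity, 1e-12)
})

test_that("modularity agrees with igraph on a random graph", {
  set.seed(14)
  n <- 30
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < 0.12
  pairs <- pairs[keep, , drop = FALSE]
  net <- net_from_pairs(cbind(paste0("n", pairs[, 1]),
                              paste0("n", pairs[, 2])))
  mods <- detect_modules(net, seed = 2)
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                     vertices = net$nodes$id)
  q_ig <- igraph::modularity(g, mods$membership[igraph::V(g)$name])
  expect_equal(mods$modularity, q_ig, tolerance = 1e-12)
})

test_that("greedy module detection attains the exhaustive optimum on small graphs", {
  graphs <- list(
    path6 = cbind(paste0("p", 1:5), paste0("p", 2:6)),
    cycle7 = cbind(paste0("c", 1:7), paste0("c", c(2:7, 1))),
    star7 = cbind(rep("h", 6), paste0("s", 1:6)),
    barbell = rbind(cbind(paste0("a", c(1, 1, 2)), paste0("a", c(2, 3, 3))),
                    cbind(paste0("b", c(1, 1, 2)), paste0("b", c(2, 3, 3))),
                    c("a1", "b1")))
  for (nm in names(graphs)) {
    net <- net_from_pairs(graphs[[nm]])
    ids <- net$nodes$id
    adj <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (r in seq_len(nrow(graphs[[nm]]))) {
      adj[graphs[[nm]][r, 1], graphs[[nm]][r, 2]] <- 1
      adj[graphs[[nm]][r, 2], graphs[[nm]][r, 1]] <- 1
    }
    best <- best_partition_oracle(adj)
    mods <- detect_modules(net, seed = 3)
    expect_equal(mods$modularity, best, tolerance = 1e-9,
                 label = sprintf("modularity on %s", nm))
  }
})

test_that("the cold subnetwork keeps the DE miRNA-TF-target chain", {
  tabs <- list(validated = data.frame(
    regulator = c("TF1", "TF1", "TF2"),
    target = c("g1", "g2", "g3"), binding_site_count = 1L))
  hits <- data.frame(mirna = c("miR1", "miR1", "miR2"),
                     transcript = c("TF1", "g9", "g3"))
  net <- build_network(tabs, mirna_hits = hits)
  de <- c("miR1", "TF1", "g1")
  sub <- extract_cold_subnetwork(net, de)
  expect_setequal(sub$nodes$id, c("miR1", "TF1", "g1"))
  expect_equal(nrow(sub$edges), 2L)
  # Non-DE miR2 and its branch are gone; g2 is not DE so it is gone.
  expect_false("miR2" %in% sub$nodes$id)
  # Idempotence.
  sub2 <- extract_cold_subnetwork(sub, de)
  expect_identical(sub$nodes$id, sub2$nodes$id)
  expect_identical(sub$edges, sub2$edges)
  # No DE features: empty subnetwork.
  empty <- extract_cold_subnetwork(net, character(0))
  expect_equal(nrow(empty$nodes), 0L)
  expect_equal(nrow(empty$edges), 0L)
  # Independent reachability-filter oracle on the same input.
  de2 <- list(`3h` = c("miR1", "g9"), `2d` = c("TF1", "g2"))
  sub3 <- extract_cold_subnetwork(net, de2)
  deu <- unique(unlist(de2))
  mirna_keep <- intersect(c("miR1", "miR2"), deu)
  mt <- intersect(c("TF1", "g9")[c("miR1", "miR1") %in% mirna_keep], deu)
  tfs <- intersect("TF1", mt)
  tt <- intersect(c("g1", "g2"), deu)
  expect_setequal(sub3$nodes$id, unique(c(mirna_keep, mt, tfs, tt)))
})

test_that("noise-free single-regulator targets are predicted exactly", {
  ntg <- 60
  regs <- sprintf("TF%03d", seq_len(ntg))
  fams <- stats::setNames(rep("FAM01", ntg), regs)
  edges <- data.frame(regulator = regs, target = sprintf("G%03d", 1:ntg),
                      binding_site_count = 1)
  net <- build_network(list(validated = edges), families = fams)
  net$edges$weight <- 1
  sim <- simulate_regulated_expression(net, sim_config(seed = 1,
                                                       edge_noise_sd = 0))
  pp <- predictive_power(net, rbind(sim$expression,
                                    sim$regulator_expression),
                         sim$design, seed = 1)
  expect_gte(pp$mean_r, 0.99)
  expect_equal(pp$n_targets, ntg)
  expect_s3_class(pp, "predictive_power")
})

test_that("network exports are readable and carry attributes", {
  tabs <- list(validated = data.frame(regulator = "TF1", target = "g1",
                                      binding_site_count = 1L))
  hits <- data.frame(mirna = "miR1", transcript = "g1")
  net <- build_network(tabs, mirna_hits = hits)
  net <- detect_modules(net, seed = 1)$network
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 3L)
  expect_equal(igraph::gsize(g), 2L)
  gexf <- withr::local_tempfile(fileext = ".gexf")
  write_gexf(net, gexf)
  doc <- xml2::read_xml(gexf)
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:node", ns)), 3L)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:edge", ns)), 2L)
})
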