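# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, closed forms and enumeration.

rc_oracle <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A")
  v <- strsplit(toupper(seq), "")[[1]]
  paste(rev(unname(comp[v])), collapse = "")
}

# Position-by-position duplex penalty, written as an explicit loop.
score_oracle <- function(mirna, site) {
  m <- strsplit(chartr("Uu", "Tt", toupper(mirna)), "")[[1]]
  s <- strsplit(chartr("Uu", "Tt", toupper(site)), "")[[1]]
  L <- length(m)
  total <- 0
  for (i in seq_len(L)) {
    sb <- s[L - i + 1]
    mb <- m[i]
    wc <- (mb == "A" && sb == "T") || (mb == "T" && sb == "A") ||
      (mb == "G" && sb == "C") || (mb == "C" && sb == "G")
    gu <- (mb == "G" && sb == "T") || (mb == "T" && sb == "G")
    pen <- if (wc) 0 else if (gu) 0.5 else 1
    if (i >= 2 && i <= 13) pen <- pen * 2
    total <- total + pen
  }
  total
}

# All-windows target scan with best-window-per-overlap reduction,
# implemented independently of find_targets.
find_targets_oracle <- function(mirna, transcript, cutoff = 2.5) {
  L <- nchar(mirna)
  n_win <- nchar(transcript) - L + 1
  if (n_win < 1) return(data.frame(start = integer(0), score = numeric(0)))
  scores <- vapply(seq_len(n_win), function(s) {
    score_oracle(mirna, substr(transcript, s, s + L - 1))
  }, numeric(1))
  keep <- which(scores <= cutoff)
  keep <- keep[order(scores[keep], keep)]
  chosen <- integer(0)
  for (s in keep) {
    if (!any(abs(chosen - s) < L)) chosen <- c(chosen, s)
  }
  chosen <- sort(chosen)
  data.frame(start = chosen - 1L, score = scores[chosen])
}

# Modularity from the adjacency matrix (configuration-model form),
# independent of the package's edge-list computation.
modularity_adj_oracle <- function(adj, membership, gamma = 1) {
  m <- sum(adj) / 2
  if (m == 0) return(0)
  k <- rowSums(adj)
  q <- 0
  n <- nrow(adj)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + adj[i, j] - gamma * k[i] * k[j] / (2 * m)
      }
    }
  }
  unname(q) / (2 * m)
}

# Enumerate all set partitions of n items as restricted growth strings.
all_partitions <- function(n) {
  out <- list()
  recur <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible(NULL))
    }
    for (v in seq_len(maxv + 1)) {
      recur(c(prefix, v), max(maxv, v))
    }
  }
  recur(integer(0), 0L)
  out
}

best_partition_oracle <- function(adj, gamma = 1) {
  parts <- all_partitions(nrow(adj))
  best <- -Inf
  for (p in parts) {
    q <- modularity_adj_oracle(adj, p, gamma)
    if (q > best) best <- q
  }
  best
}

# Exact hypergeometric upper tail by direct summation of binomial products.
hyper_tail_oracle <- function(k, K, n, N) {
  tot <- 0
  for (j in k:min(K, n)) {
    tot <- tot + choose(K, j) * choose(N - K, n - j)
  }
  tot / choose(N, n)
}

# Median-of-ratios size factors, brute force.
size_factors_oracle <- function(counts) {
  ok <- apply(counts, 1, function(r) all(r > 0))
  sub <- counts[ok, , drop = FALSE]
  gm <- apply(sub, 1, function(r) exp(mean(log(r))))
  f <- vapply(seq_len(ncol(sub)), function(j) {
    stats::median(sub[, j] / gm)
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Small two-group design shared by DE tests.
make_two_group_design <- function(n_rep = 3, time = "3h") {
  data.frame(sample = sprintf("s%d", seq_len(2 * n_rep)),
             condition = rep(c("control", "cold"), each = n_rep),
             time = time, replicate = rep(seq_len(n_rep), 2),
             stringsAsFactors = FALSE)
}

# Build a tiny regulatory network straight from an undirected edge list.
net_from_pairs <- function(pairs) {
  edges <- data.frame(regulator = pairs[, 1], target = pairs[, 2],
                      binding_site_count = 1, stringsAsFactors = FALSE)
  build_network(list(validated = edges))
}
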