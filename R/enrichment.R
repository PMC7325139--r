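#' Term over-representation analysis
#'
#' One-sided hypergeometric (Fisher) test per term: the p value is the
#' upper tail `P(X >= k)` for `k` genes of the query set annotated to a
#' term of size `K`, with a query of size `n` drawn from a background of
#' size `N`. Benjamini-Hochberg correction is applied across the reported
#' terms and results are sorted by p.
#'
#' @param gene_set character vector of query genes (must be a subset of
#'   the background).
#' @param term_map data frame with columns `gene` and `term`, or a named
#'   list term -> gene vector.
#' @param background character vector of background genes.
#' @return data frame: term, k, K, n, N, p, p_adj, sorted by p; one row per
#'   term with k >= 1.
#' @export
enrich <- function(gene_set, term_map, background) {
  if (!length(background)) stop("enrich: empty background", call. = FALSE)
  background <- unique(background)
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% background)) {
    stop("enrich: gene_set must be a subset of the background",
         call. = FALSE)
  }
  if (is.data.frame(term_map)) {
    terms <- split(term_map$gene, term_map$term)
  } else {
    terms <- term_map
  }
  terms <- lapply(terms, function(g) unique(intersect(g, background)))
  N <- length(background)
  n <- length(gene_set)
  rows <- lapply(names(terms), function(tm) {
    K <- length(terms[[tm]])
    k <- length(intersect(gene_set, terms[[tm]]))
    if (k < 1) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), stringsAsFactors = FALSE))
  }
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set file into a term map
#'
#' @param path GMT file (term, description, genes... per line).
#' @return named list term -> character vector of genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t")[[1]]
    if (length(parts) < 3) {
      stop("read_gmt: each line needs term, description and >= 1 gene",
           call. = FALSE)
    }
    out[[parts[1]]] <- parts[-(1:2)]
  }
  out
}
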