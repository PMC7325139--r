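# Internal helpers shared across the pipeline stages.

# Time points of the cold-acclimation design, in chronological order.
TIME_POINTS <- c("3h", "6h", "2d")

# sRNA/RNA class labels, in assignment-precedence order (highest first).
RNA_CLASSES <- c("miRNA", "cis_NAT", "trans_NAT", "TAS", "PHAS",
                 "lncRNA", "tRNA_like", "TE_repeat", "other")

# Derive a deterministic substream seed from the global seed. Stays below
# 2^31 - 1 so it is always a valid R integer seed.
substream_seed <- function(seed, id) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) + 104729 * id) %% 2147483647)
}

# Geometric mean ignoring non-positive entries is deliberately NOT used;
# size-factor code needs the strict all-positive version.
geomean <- function(x) exp(mean(log(x)))

reverse_complement <- function(seq) {
  chartr("ACGTU", "TGCAA", sapply(lapply(strsplit(toupper(seq), ""), rev),
                                  paste, collapse = ""))
}

# DNA-alphabet normalization: U -> T, uppercase.
as_dna <- function(seq) {
  s <- chartr("u", "t", toupper(seq))
  chartr("U", "T", s)
}

check_nucleotides <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGT]", as_dna(seq))
  if (any(bad)) {
    stop(sprintf("non-nucleotide symbol in %s: %s", what,
                 paste(utils::head(seq[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Stable TSV writers/readers: header always present, '.' for missing,
# column order preserved.
write_tsv_file <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    v <- df2[[j]]
    if (is.numeric(v)) v <- as.character(v)
    v[is.na(v)] <- "."
    df2[[j]] <- v
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path, required = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = ".",
                          check.names = FALSE, quote = "")
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop(sprintf("%s: missing required column(s): %s", path,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
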