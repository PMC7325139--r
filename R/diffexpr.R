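#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over all-nonzero features of
#' the count divided by the feature's geometric mean across samples;
#' factors are then rescaled to geometric mean 1. If no feature is nonzero
#' in every sample, falls back to total-count scaling with a warning.
#'
#' @param counts numeric matrix, features x samples.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) {
    warning("size_factors: no feature nonzero in all samples; ",
            "falling back to total-count scaling")
    f <- colSums(counts)
    f <- f / geomean(f)
    names(f) <- colnames(counts)
    return(f)
  }
  sub <- counts[ok, , drop = FALSE]
  gm <- exp(rowMeans(log(sub)))
  f <- apply(sub / gm, 2, stats::median)
  f <- f / geomean(f)
  names(f) <- colnames(counts)
  f
}

#' Method-of-moments NB dispersion with trend shrinkage
#'
#' Per feature, the raw estimate is `max(0, (s2 - m) / m^2)` with the
#' within-group variance `s2` (pooled across groups) and mean `m` of
#' normalized counts. Raw estimates are then shrunk 50/50 toward a fitted
#' mean-dispersion trend `a0 + a1 / mean`.
#'
#' @param norm_counts normalized count matrix, features x samples.
#' @param group factor/character vector of sample groups (>= 2 replicates
#'   per group required).
#' @return numeric vector of per-feature dispersions (alpha >= 0).
#' @export
estimate_dispersion <- function(norm_counts, group) {
  group <- as.character(group)
  tab <- table(group)
  if (any(tab < 2)) {
    stop("estimate_dispersion: needs >= 2 replicates per group; ",
         "supply alpha explicitly for unreplicated designs", call. = FALSE)
  }
  groups <- names(tab)
  n_f <- nrow(norm_counts)
  ss <- numeric(n_f)   # pooled within-group sum of squares
  df <- 0
  mu <- rowMeans(norm_counts)
  for (g in groups) {
    sub <- norm_counts[, group == g, drop = FALSE]
    m_g <- rowMeans(sub)
    ss <- ss + rowSums((sub - m_g)^2)
    df <- df + ncol(sub) - 1
  }
  s2 <- ss / df
  raw <- pmax(0, (s2 - mu) / mu^2)
  raw[!is.finite(raw)] <- 0

  # Parametric mean-dispersion trend alpha(mu) = a0 + a1/mu, fitted by
  # least squares on informative features; degenerate fits fall back to
  # the median raw dispersion.
  use <- mu > 1 & is.finite(raw)
  trend <- rep(stats::median(raw[use]), n_f)
  if (sum(use) >= 10) {
    fit <- try(stats::lm(raw[use] ~ I(1 / mu[use])), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      a0 <- max(0, stats::coef(fit)[1])
      a1 <- max(0, stats::coef(fit)[2])
      trend <- a0 + a1 / mu
      trend[!is.finite(trend)] <- a0
    }
  }
  pmax(0, 0.5 * raw + 0.5 * trend)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return adjusted p values (monotone, order-preserving).
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("bh_adjust: p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Negative-binomial Wald test, cold vs control, at one time point
#'
#' Fits, per feature, an NB GLM with log link on the samples of the given
#' time point: `counts ~ NB(mean = sf_j * exp(b0 + b1 * cold_j))` with the
#' dispersion held at its estimate. Coefficients come from iteratively
#' reweighted least squares; the Wald statistic `z = b1 / SE(b1)` yields a
#' two-sided p, corrected by Benjamini-Hochberg within each batch. Status
#' is the four-state call: `undetected` if the normalized base mean is
#' below `detection`; otherwise `up`/`down` if `|log2FC| >= log2(fc)` and
#' `p_adj <= alpha_level`; otherwise `unchanged`.
#'
#' @param counts integer matrix, features x samples.
#' @param design design sheet (see [read_design()]).
#' @param time_point one of `"3h"`, `"6h"`, `"2d"`.
#' @param sf optional size factors for the selected samples; default
#'   [size_factors()] on the subset.
#' @param dispersion optional per-feature alpha; default
#'   [estimate_dispersion()].
#' @param batch optional named vector feature id -> batch label; BH is
#'   applied within each batch (e.g. per RNA class). Default: one batch.
#' @param fc fold-change threshold (default 2).
#' @param alpha_level adjusted-p threshold (default 0.05).
#' @param detection normalized base-mean detection threshold (default 5).
#' @param max_iter,tol IRLS controls. Non-converged fits get `p = NA` and
#'   status `unchanged` (or `undetected` by base mean).
#' @return `de_result` data frame with columns feature, time, base_mean,
#'   log2fc, p, p_adj, status.
#' @export
nb_wald_test <- function(counts, design, time_point, sf = NULL,
                         dispersion = NULL, batch = NULL, fc = 2,
                         alpha_level = 0.05, detection = 5,
                         max_iter = 100, tol = 1e-8) {
  validate_design(design)
  sel <- design$time == time_point
  if (!any(sel & design$condition == "cold") ||
      !any(sel & design$condition == "control")) {
    stop("nb_wald_test: design needs control and cold samples at ",
         time_point, call. = FALSE)
  }
  d <- design[sel, , drop = FALSE]
  y <- counts[, d$sample, drop = FALSE]
  if (is.null(rownames(y))) {
    rownames(y) <- sprintf("feature_%d", seq_len(nrow(y)))
  }
  x <- as.numeric(d$condition == "cold")
  if (is.null(sf)) sf <- size_factors(y)
  norm <- sweep(y, 2, sf, "/")
  base_mean <- rowMeans(norm)
  if (is.null(dispersion)) dispersion <- estimate_dispersion(norm,
                                                            d$condition)
  alpha <- pmax(dispersion, 1e-8)

  n_f <- nrow(y)
  all_zero <- rowSums(y) == 0
  log_sf <- log(sf)

  # Initialize from group means with a +0.5 pseudo-mean floor for
  # all-zero groups.
  m0 <- rowMeans(norm[, x == 0, drop = FALSE])
  m1 <- rowMeans(norm[, x == 1, drop = FALSE])
  m0 <- pmax(m0, 0.5)
  m1 <- pmax(m1, 0.5)
  b0 <- log(m0)
  b1 <- log(m1) - b0

  active <- !all_zero
  converged <- rep(FALSE, n_f)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    idx <- which(active)
    eta <- outer(b0[idx], rep(1, length(x))) + outer(b1[idx], x) +
      matrix(log_sf, nrow = length(idx), ncol = length(x), byrow = TRUE)
    mu <- exp(eta)
    mu <- pmax(pmin(mu, 1e12), 1e-10)
    w <- mu / (1 + alpha[idx] * mu)
    z <- eta - matrix(log_sf, nrow = length(idx), ncol = length(x),
                      byrow = TRUE) + (y[idx, , drop = FALSE] - mu) / mu
    a11 <- rowSums(w)
    a12 <- as.vector(w %*% x)
    a22 <- as.vector(w %*% x^2)
    r1 <- rowSums(w * z)
    r2 <- rowSums(w * z * matrix(x, nrow = length(idx), ncol = length(x),
                                 byrow = TRUE))
    det <- a11 * a22 - a12^2
    det[det <= 1e-12] <- NA
    new_b1 <- (a11 * r2 - a12 * r1) / det
    new_b0 <- (a22 * r1 - a12 * r2) / det
    delta <- pmax(abs(new_b0 - b0[idx]), abs(new_b1 - b1[idx]))
    ok <- is.finite(new_b0) & is.finite(new_b1)
    b0[idx[ok]] <- new_b0[ok]
    b1[idx[ok]] <- new_b1[ok]
    done <- ok & delta < tol
    converged[idx[done]] <- TRUE
    active[idx[done | !ok]] <- FALSE
  }

  # Final SE from the information at the converged estimate.
  eta <- outer(b0, rep(1, length(x))) + outer(b1, x) +
    matrix(log_sf, nrow = n_f, ncol = length(x), byrow = TRUE)
  mu <- pmax(pmin(exp(eta), 1e12), 1e-10)
  w <- mu / (1 + alpha * mu)
  a11 <- rowSums(w)
  a12 <- as.vector(w %*% x)
  a22 <- as.vector(w %*% x^2)
  det <- a11 * a22 - a12^2
  se_b1 <- sqrt(a11 / det)

  zstat <- b1 / se_b1
  p <- 2 * stats::pnorm(-abs(zstat))
  p[!converged] <- NA
  p[all_zero] <- 1
  log2fc <- b1 / log(2)
  log2fc[all_zero] <- 0

  if (is.null(batch)) {
    p_adj <- bh_adjust(p)
  } else {
    b <- unname(batch[rownames(y)])
    b[is.na(b)] <- "other"
    p_adj <- rep(NA_real_, n_f)
    for (lev in unique(b)) {
      i <- which(b == lev)
      p_adj[i] <- bh_adjust(p[i])
    }
  }

  status <- rep("unchanged", n_f)
  sig <- !is.na(p_adj) & p_adj <= alpha_level & abs(log2fc) >= log2(fc)
  status[sig & log2fc > 0] <- "up"
  status[sig & log2fc < 0] <- "down"
  status[base_mean < detection] <- "undetected"
  status[all_zero] <- "undetected"

  res <- data.frame(feature = rownames(y), time = time_point,
                    base_mean = base_mean, log2fc = log2fc, p = p,
                    p_adj = p_adj, status = status,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, ...) {
  tp <- unique(x$time)
  cat(sprintf("de_result: %d features at %s\n", nrow(x),
              paste(tp, collapse = ", ")))
  print(table(status = x$status))
  invisible(x)
}

#' Run the NB Wald test at every time point
#'
#' @inheritParams nb_wald_test
#' @param ... passed to [nb_wald_test()].
#' @return a `de_result` data frame covering all time points in the design.
#' @export
de_all_timepoints <- function(counts, design, ...) {
  out <- do.call(rbind, lapply(intersect(TIME_POINTS, unique(design$time)),
                               function(tp) {
                                 nb_wald_test(counts, design, tp, ...)
                               }))
  class(out) <- c("de_result", "data.frame")
  out
}
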