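#' Relative quantification by the delta-delta-Ct method
#'
#' Technical-replicate Ct values are averaged arithmetically per condition;
#' `dCt = Ct_target - Ct_ref` within each condition, `ddCt = dCt_treated -
#' dCt_control`, and relative expression is `2^(-ddCt)` (amplification
#' efficiency fixed at 2), so the untreated control is 1 by construction.
#' The sd over technical replicates is propagated to the relative
#' expression by first-order (delta-method) propagation.
#'
#' @param assay assay identifier.
#' @param ct_target_treated,ct_target_control numeric vectors of target
#'   Ct values over technical replicates.
#' @param ct_ref_treated,ct_ref_control reference (housekeeping) gene Ct
#'   values over technical replicates.
#' @return one-row data frame: assay, ddct, relative_expression, sd.
#' @export
ddct <- function(assay, ct_target_treated, ct_target_control,
                 ct_ref_treated, ct_ref_control) {
  vals <- list(ct_target_treated, ct_target_control, ct_ref_treated,
               ct_ref_control)
  if (any(vapply(vals, function(v) length(v) < 1 || anyNA(v) ||
                   any(!is.finite(v)), logical(1)))) {
    stop("ddct: every condition needs >= 1 finite Ct value (reference ",
         "included)", call. = FALSE)
  }
  dct_treated <- mean(ct_target_treated) - mean(ct_ref_treated)
  dct_control <- mean(ct_target_control) - mean(ct_ref_control)
  ddct_val <- dct_treated - dct_control
  rel <- 2^(-ddct_val)
  # Var(ddCt) from the four replicate means; d(rel)/d(ddCt) = -ln(2)*rel.
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  var_ddct <- sum(vapply(vals, function(v) sd0(v)^2 / length(v),
                         numeric(1)))
  sd_rel <- log(2) * rel * sqrt(var_ddct)
  data.frame(assay = assay, ddct = ddct_val, relative_expression = rel,
             sd = sd_rel, stringsAsFactors = FALSE)
}

#' Batch delta-delta-Ct over a long-format qPCR table
#'
#' @param qpcr data frame with columns assay, condition
#'   (`"treated"`/`"control"`), replicate, ct_target, ct_ref.
#' @return data frame with one row per assay (see [ddct()]).
#' @export
ddct_table <- function(qpcr) {
  req <- c("assay", "condition", "ct_target", "ct_ref")
  missing <- setdiff(req, names(qpcr))
  if (length(missing)) {
    stop("ddct_table: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  do.call(rbind, lapply(unique(qpcr$assay), function(a) {
    sub <- qpcr[qpcr$assay == a, , drop = FALSE]
    tr <- sub[sub$condition == "treated", , drop = FALSE]
    co <- sub[sub$condition == "control", , drop = FALSE]
    ddct(a, tr$ct_target, co$ct_target, tr$ct_ref, co$ct_ref)
  }))
}
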