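# Covariate analysis: Pearson and Spearman correlations between network
# metrics and a per-subject covariate (age), with Benjamini-Hochberg FDR
# control over the metric family at the spotlight threshold and an
# uncorrected sweep across the full sparsity range.

#' Correlate one metric with a covariate
#'
#' Two-sided Pearson correlation plus the rank-based Spearman correlation
#' (average ranks for ties; large-sample p, robust to non-normality and
#' outliers).
#'
#' @param values Numeric metric values per subject (n >= 4).
#' @param covariate Numeric covariate per subject, nonconstant.
#' @return One-row data.frame: pearson_r, pearson_p, spearman_rho,
#'   spearman_p, n.
#' @export
correlate_metric_with_covariate <- function(values, covariate) {
  stopifnot(length(values) == length(covariate))
  if (length(values) < 4L) stop("need at least 4 paired observations")
  ok <- is.finite(values) & is.finite(covariate)
  if (any(!ok)) {
    warning(sum(!ok), " non-finite observation(s) dropped")
    values <- values[ok]
    covariate <- covariate[ok]
    if (length(values) < 4L)
      return(data.frame(pearson_r = NA_real_, pearson_p = NA_real_,
                        spearman_rho = NA_real_, spearman_p = NA_real_,
                        n = length(values)))
  }
  if (stats::sd(covariate) == 0) stop("constant covariate")
  if (stats::sd(values) == 0)
    return(data.frame(pearson_r = NA_real_, pearson_p = NA_real_,
                      spearman_rho = NA_real_, spearman_p = NA_real_,
                      n = length(values)))
  pe <- stats::cor.test(values, covariate, method = "pearson")
  sp <- suppressWarnings(
    stats::cor.test(values, covariate, method = "spearman", exact = FALSE))
  data.frame(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
             spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
             n = length(values))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjustment over a family of p-values; a test is significant
#' when its adjusted p falls below `alpha`.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @param alpha Target false-discovery rate (default 0.05).
#' @return List with `p_adjusted` and logical `significant`.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, significant = !is.na(adj) & adj < alpha)
}

#' Covariate sweep over metrics and sparsity thresholds
#'
#' Correlates every global metric with the covariate at every sparsity
#' threshold. At the spotlight threshold the Pearson p-values of the
#' metric family are FDR-corrected (Benjamini-Hochberg); the rest of the
#' sweep is deliberately uncorrected and flagged as exploratory.
#'
#' @param metric_table Long-format data.frame (`subject`, `S`, `metric`,
#'   `value`).
#' @param covariate Named numeric vector (names = subject ids) or
#'   data.frame with columns `subject`, `value`.
#' @param spotlight Sparsity at which the FDR family is formed (default
#'   0.23); set `NA` to skip correction entirely.
#' @param alpha Significance level (default 0.05).
#' @return data.frame: metric, S, pearson_r, pearson_p, spearman_rho,
#'   spearman_p, p_fdr (NA off-spotlight), significant, corrected.
#' @export
sweep_covariate_analysis <- function(metric_table, covariate,
                                     spotlight = 0.23, alpha = 0.05) {
  need <- c("subject", "S", "metric", "value")
  stopifnot(all(need %in% names(metric_table)))
  if (is.data.frame(covariate)) {
    cov <- stats::setNames(covariate$value, covariate$subject)
  } else cov <- covariate
  rows <- list()
  for (met in unique(metric_table$metric)) {
    for (S in sort(unique(metric_table$S))) {
      d <- metric_table[metric_table$metric == met & metric_table$S == S, ]
      if (nrow(d) == 0L) stop("missing cell: ", met, " at S=", S)
      if (!all(d$subject %in% names(cov)))
        stop("covariate missing for subject(s): ",
             paste(setdiff(d$subject, names(cov)), collapse = ", "))
      r <- correlate_metric_with_covariate(d$value, cov[as.character(d$subject)])
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(metric = met, S = S, stringsAsFactors = FALSE), r)
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  out$corrected <- FALSE
  spot <- !is.na(spotlight) & abs(out$S - spotlight) < 1e-9
  if (any(spot)) {
    fdr <- bh_fdr(out$pearson_p[spot], alpha = alpha)
    out$p_fdr[spot] <- fdr$p_adjusted
    out$corrected[spot] <- TRUE
  }
  out$significant <- ifelse(out$corrected,
                            !is.na(out$p_fdr) & out$p_fdr < alpha,
                            !is.na(out$pearson_p) & out$pearson_p < alpha)
  out
}
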