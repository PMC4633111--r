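# Test-retest reliability via the intraclass correlation coefficient:
# one-way random-effects ANOVA, ICC(1,1) = ratio of between-subject
# variance to total variance, applied edge-wise to connection matrices
# and metric-wise across sparsity thresholds.

.icc_band <- function(icc) {
  if (icc >= 0.75) "excellent"
  else if (icc >= 0.59) "good"
  else if (icc >= 0.40) "fair"
  else "poor"
}

#' One-way random-effects intraclass correlation, ICC(1,1)
#'
#' From the one-way ANOVA decomposition with subjects as the random
#' factor: `ICC = (MSB - MSW) / (MSB + (k-1) MSW)` for k sessions, the
#' sample estimate of between-subject variance over total variance.
#' Negative raw estimates are clamped to 0 for reporting (the underlying
#' variance ratio is nonnegative by construction); the raw value is kept
#' for diagnostics. The p-value is the one-way ANOVA F-test
#' (`F = MSB/MSW` on n-1 and n(k-1) degrees of freedom).
#'
#' Reliability bands: >= 0.75 excellent, 0.59-0.75 good, 0.40-0.58 fair,
#' below that poor.
#'
#' @param measurements Numeric matrix, subjects x sessions, no missing
#'   cells; >= 2 subjects and >= 2 sessions.
#' @return An `icc_result` list: icc (clamped), icc_raw, var_between,
#'   var_within, MSB, MSW, F, p, n_subjects, n_sessions, band.
#' @export
icc_oneway <- function(measurements) {
  x <- as.matrix(measurements)
  if (any(is.na(x))) stop("missing cells in the subjects x sessions table")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 sessions")
  m_i <- rowMeans(x)
  grand <- mean(x)
  MSB <- k * sum((m_i - grand)^2) / (n - 1)
  MSW <- sum((x - m_i)^2) / (n * (k - 1))
  if (MSB == 0 && MSW == 0) stop("constant measurements: ICC undefined")
  icc_raw <- (MSB - MSW) / (MSB + (k - 1) * MSW)
  icc <- max(icc_raw, 0)
  Fval <- if (MSW > 0) MSB / MSW else Inf
  p <- stats::pf(Fval, n - 1, n * (k - 1), lower.tail = FALSE)
  structure(list(icc = icc, icc_raw = icc_raw,
                 var_between = (MSB - MSW) / k, var_within = MSW,
                 MSB = MSB, MSW = MSW, F = Fval, p = p,
                 n_subjects = n, n_sessions = k, band = .icc_band(icc)),
            class = "icc_result")
}

#' Edge-wise ICC map between two sessions
#'
#' Runs the one-way ICC on every off-diagonal connection across subjects,
#' with the two scanning sessions as repeated measurements, and summarizes
#' the edge reliability distribution.
#'
#' @param session1,session2 Lists of `similarity_matrix` objects for the
#'   same subjects in the same order, one matrix per subject.
#' @return List with `icc` (R x R matrix, `NA` diagonal) and `summary`
#'   (mean, sd, fraction of edges with ICC > 0.75).
#' @export
edge_icc_map <- function(session1, session2) {
  if (length(session1) != length(session2))
    stop("sessions have different numbers of subjects")
  .check_same_regions(c(session1, session2))
  n <- length(session1)
  if (n < 2L) stop("need >= 2 subjects")
  R <- nrow(session1[[1L]])
  ut <- which(upper.tri(matrix(0, R, R)))
  x1 <- vapply(session1, function(m) unclass(m)[ut], numeric(length(ut)))
  x2 <- vapply(session2, function(m) unclass(m)[ut], numeric(length(ut)))
  m_i <- (x1 + x2) / 2                      # edge x subject means
  grand <- rowMeans(m_i)
  MSB <- 2 * rowSums((m_i - grand)^2) / (n - 1)
  MSW <- rowSums((x1 - m_i)^2 + (x2 - m_i)^2) / n
  icc_raw <- (MSB - MSW) / (MSB + MSW)
  icc_raw[MSB == 0 & MSW == 0] <- NA
  iccs <- pmax(icc_raw, 0)
  out <- matrix(NA_real_, R, R, dimnames = dimnames(session1[[1L]]))
  out[ut] <- iccs
  out <- pmax(out, t(out), na.rm = TRUE)
  diag(out) <- NA
  list(icc = out,
       summary = c(mean = mean(iccs, na.rm = TRUE),
                   sd = stats::sd(iccs, na.rm = TRUE),
                   frac_excellent = mean(iccs > 0.75, na.rm = TRUE)))
}

#' Metric-wise ICC across sparsity thresholds
#'
#' For each global network metric and each sparsity threshold, computes
#' the ICC across subjects between the two sessions, plus the per-metric
#' mean/min/max over thresholds.
#'
#' @param table1,table2 Long-format data.frames (columns `subject`, `S`,
#'   `metric`, `value`) from the two sessions, computed with identical
#'   thresholds and null-model seeds.
#' @param metrics Metrics to include; default all shared.
#' @return List with `curve` (metric, S, icc, p, band) and `summary`
#'   (metric, mean_icc, min_icc, max_icc).
#' @export
metric_icc_curve <- function(table1, table2, metrics = NULL) {
  need <- c("subject", "S", "metric", "value")
  stopifnot(all(need %in% names(table1)), all(need %in% names(table2)))
  if (!setequal(unique(table1$S), unique(table2$S)))
    stop("threshold sets differ between sessions")
  if (is.null(metrics))
    metrics <- intersect(unique(table1$metric), unique(table2$metric))
  rows <- list()
  for (met in metrics) {
    for (S in sort(unique(table1$S))) {
      s1 <- table1[table1$metric == met & table1$S == S, ]
      s2 <- table2[table2$metric == met & table2$S == S, ]
      s1 <- s1[order(s1$subject), ]
      s2 <- s2[order(s2$subject), ]
      if (!identical(s1$subject, s2$subject))
        stop("subject mismatch between sessions for ", met, " at S=", S)
      ok <- is.finite(s1$value) & is.finite(s2$value)
      if (sum(ok) < 2L) {
        warning("fewer than 2 subjects with finite ", met, " at S=", S,
                "; ICC set to NA")
        rows[[length(rows) + 1L]] <-
          data.frame(metric = met, S = S, icc = NA_real_, p = NA_real_,
                     band = NA_character_, stringsAsFactors = FALSE)
        next
      }
      if (any(!ok))
        warning(sum(!ok), " subject(s) with non-finite ", met, " at S=", S,
                " dropped from the ICC")
      r <- icc_oneway(cbind(s1$value[ok], s2$value[ok]))
      rows[[length(rows) + 1L]] <-
        data.frame(metric = met, S = S, icc = r$icc, p = r$p,
                   band = r$band, stringsAsFactors = FALSE)
    }
  }
  curve <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(curve, curve$metric), function(d) {
    data.frame(metric = d$metric[1L], mean_icc = mean(d$icc, na.rm = TRUE),
               min_icc = suppressWarnings(min(d$icc, na.rm = TRUE)),
               max_icc = suppressWarnings(max(d$icc, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(curve = curve, summary = summ)
}
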