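# Diagnostic statistics: ROC/AUC, Youden cut-offs, 2x2 accuracy metrics,
# ICC, sample size, group comparison.
#
# Convention throughout: CRT (conical root) is the positive class and is
# indicated by LOWER metric values ("value < cutoff => CRT").

#' Empirical ROC curve and AUC
#'
#' The classification rule is `value < threshold => positive (CRT)`. The
#' empirical AUC equals the Mann-Whitney probability
#' `P(CRT < NRT) + 0.5 P(tie)`, and the trapezoidal area under the returned
#' curve reproduces it exactly.
#'
#' @param crt_values metric values of the positive (CRT) group.
#' @param nrt_values metric values of the negative (NRT) group.
#' @param parameter optional parameter name carried into the report.
#' @return object of class `diagnostic_roc`: list with `parameter`, `curve`
#'   (data.frame `threshold`, `fpr`, `tpr`), `auc`, and the raw values.
#' @export
roc_auc <- function(crt_values, nrt_values, parameter = "") {
  if (length(crt_values) == 0L || length(nrt_values) == 0L)
    stop("both groups must be non-empty")
  if (any(!is.finite(c(crt_values, nrt_values))))
    stop("values must be finite")
  n_c <- length(crt_values)
  n_n <- length(nrt_values)
  rk <- rank(c(crt_values, nrt_values))
  # P(crt > nrt) + 0.5 P(tie), then flip: lower values indicate CRT
  u_gt <- (sum(rk[seq_len(n_c)]) - n_c * (n_c + 1) / 2) / (n_c * n_n)
  auc <- 1 - u_gt
  thr <- c(sort(unique(c(crt_values, nrt_values))), Inf)
  tpr <- vapply(thr, function(cc) mean(crt_values < cc), numeric(1))
  fpr <- vapply(thr, function(cc) mean(nrt_values < cc), numeric(1))
  curve <- data.frame(threshold = c(-Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  structure(list(parameter = parameter, curve = curve, auc = auc,
                 crt_values = crt_values, nrt_values = nrt_values),
            class = "diagnostic_roc")
}

#' Youden-optimal cut-off
#'
#' Maximises `YI = Se + Sp - 1` over candidate thresholds (midpoints between
#' adjacent distinct pooled values, plus -Inf/+Inf) under the
#' `value < cutoff => CRT` rule. Ties in YI resolve to the smallest
#' qualifying cut-off.
#'
#' @param roc a `diagnostic_roc` from [roc_auc()].
#' @return list with `cutoff`, `se`, `sp`, `yi`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "diagnostic_roc"))
  v <- sort(unique(c(roc$crt_values, roc$nrt_values)))
  cand <- c(-Inf, if (length(v) > 1) (v[-length(v)] + v[-1]) / 2, Inf)
  se <- vapply(cand, function(cc) mean(roc$crt_values < cc), numeric(1))
  sp <- vapply(cand, function(cc) mean(roc$nrt_values >= cc), numeric(1))
  yi <- se + sp - 1
  best <- which(yi >= max(yi) - 1e-12)[1]  # smallest qualifying cutoff
  list(cutoff = cand[best], se = se[best], sp = sp[best], yi = yi[best])
}

#' Classify values by a cut-off
#'
#' `value < cutoff => "CRT"`, otherwise (including exact equality) `"NRT"` —
#' the strict-inequality convention of the published rule.
#'
#' @param values finite numeric metric values.
#' @param cutoff decision threshold.
#' @return character vector of `"CRT"`/`"NRT"` labels.
#' @export
classify <- function(values, cutoff) {
  if (any(!is.finite(values))) stop("values must be finite")
  ifelse(values < cutoff, "CRT", "NRT")
}

#' Accuracy metrics from a 2x2 contingency table
#'
#' Standard definitions with CRT positive: `Se = TP/(TP+FN)`,
#' `Sp = TN/(TN+FP)`, `PV+ = TP/(TP+FP)`, `PV- = TN/(TN+FN)`,
#' `YI = Se+Sp-1`, `LR+ = Se/(1-Sp)`, `LR- = (1-Se)/Sp`. A metric with a
#' zero denominator is returned as `NA` (flagged missing), never as 0.
#'
#' @param tp,fp,fn,tn non-negative counts (true/false positives/negatives).
#' @return named list `se, sp, pv_pos, pv_neg, yi, lr_pos, lr_neg`.
#' @export
contingency_metrics <- function(tp, fp, fn, tn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  if (any(c(tp, fp, fn, tn) < 0)) stop("counts must be >= 0")
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  se <- rat(tp, tp + fn)
  sp <- rat(tn, tn + fp)
  lr_pos <- if (!is.na(se) && !is.na(sp) && sp < 1) se / (1 - sp) else NA_real_
  lr_neg <- if (!is.na(se) && !is.na(sp) && sp > 0) (1 - se) / sp else NA_real_
  list(se = se, sp = sp,
       pv_pos = rat(tp, tp + fp),
       pv_neg = rat(tn, tn + fn),
       yi = if (is.na(se) || is.na(sp)) NA_real_ else se + sp - 1,
       lr_pos = lr_pos, lr_neg = lr_neg)
}

#' Two-group sample size for a mean difference
#'
#' Unequal-allocation two-sample formula with `n1:n2 = 1:k`:
#' `n1 = ceil( ((k+1)/k) * ((z_{alpha/2} + z_beta) * sigma / delta)^2 )`,
#' `n2 = ceil(k * n1)`, with a floor of 2 per group.
#'
#' @param k allocation ratio n2/n1 (> 0).
#' @param alpha two-sided type-I error.
#' @param beta type-II error (power = 1 - beta).
#' @param sigma common SD of the outcome.
#' @param delta detectable mean difference (same units as `sigma`).
#' @return list with integer `n1`, `n2`.
#' @export
sample_size <- function(k, alpha = 0.05, beta = 0.20, sigma, delta) {
  if (k <= 0) stop("k must be > 0")
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1)
    stop("alpha and beta must be in (0, 1)")
  if (sigma <= 0 || delta <= 0) stop("sigma and delta must be > 0")
  z <- qnorm(1 - alpha / 2) + qnorm(1 - beta)
  n1 <- ceiling(((k + 1) / k) * (z * sigma / delta)^2)
  n1 <- max(n1, 2L)
  n2 <- max(ceiling(k * n1), 2L)
  list(n1 = as.integer(n1), n2 = as.integer(n2))
}

#' Two-way random-effects single-measure ICC with absolute agreement
#'
#' ICC(2,1) from the two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with k = 2 occasions.
#' Used to gauge test-retest measurement error; zero between-subject
#' variance makes the coefficient undefined (`NA` with a warning).
#'
#' @param ratings numeric matrix, n subjects x 2 occasions, no missing
#'   values, n >= 3.
#' @return the ICC value.
#' @export
icc <- function(ratings) {
  x <- as.matrix(ratings)
  if (ncol(x) != 2L) stop("exactly 2 measurement occasions are required")
  if (nrow(x) < 3L) stop("need at least 3 subjects")
  if (any(!is.finite(x))) stop("missing or non-finite ratings")
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x)
  rm_ <- rowMeans(x)
  cm <- colMeans(x)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  mse <- sum((x - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + gm)^2) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(denom) < 1e-300 || msr < 1e-300) {
    warning("zero between-subject variance: ICC undefined")
    return(NA_real_)
  }
  (msr - mse) / denom
}

#' Test-retest measurement error summary
#'
#' Paired t-test between the two occasions plus ICC(2,1), mirroring the
#' standard intra-examiner reliability workflow; the per-subject mean of the
#' two occasions is returned for downstream use.
#'
#' @param occasion1,occasion2 numeric vectors of repeated measurements.
#' @return list with `paired_t_p`, `icc`, and `mean_values`.
#' @export
measurement_error <- function(occasion1, occasion2) {
  if (length(occasion1) != length(occasion2))
    stop("occasions must have equal length")
  d <- occasion2 - occasion1
  p <- if (sd(d) < 1e-12) 1 else t.test(occasion1, occasion2, paired = TRUE)$p.value
  list(paired_t_p = p,
       icc = icc(cbind(occasion1, occasion2)),
       mean_values = (occasion1 + occasion2) / 2)
}

#' Two-group comparison: t-test and rank-sum test
#'
#' Two-sided classical (equal-variance) two-sample t-test and Mann-Whitney
#' rank-sum test. Welch's correction is available behind `welch = TRUE`.
#' With zero pooled variance and unequal means the t p-value is reported as
#' 0 (the limit) with an infinite statistic.
#'
#' @param a_values,b_values numeric vectors, each of length >= 2.
#' @param welch use Welch's unequal-variance t-test instead.
#' @return list with `t_stat`, `t_p`, `w_stat`, `w_p`.
#' @export
group_compare <- function(a_values, b_values, welch = FALSE) {
  if (length(a_values) < 2L || length(b_values) < 2L)
    stop("each group needs at least 2 values")
  if (sd(a_values) < 1e-12 && sd(b_values) < 1e-12) {
    if (abs(mean(a_values) - mean(b_values)) < 1e-12) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- list(statistic = Inf, p.value = 0)
    }
  } else {
    t0 <- t.test(a_values, b_values, var.equal = !welch)
    tt <- list(statistic = unname(t0$statistic), p.value = t0$p.value)
  }
  wt <- suppressWarnings(wilcox.test(a_values, b_values, exact = FALSE,
                                     correct = TRUE))
  list(t_stat = tt$statistic, t_p = tt$p.value,
       w_stat = unname(wt$statistic), w_p = wt$p.value)
}

#' Full diagnostic workup of a labelled cohort
#'
#' For each metric column: group mean/SD and comparison tests (a Table-1
#' style summary), ROC AUC with Youden cut-off (Table-2 style), and the 2x2
#' accuracy metrics obtained by re-classifying the cohort at that cut-off
#' (Table-3 style).
#'
#' @param cohort data.frame with a `group` column (`"NRT"`/`"CRT"`) and
#'   numeric metric columns.
#' @param parameters metric columns to analyse (default: the six standard
#'   ones present in the cohort).
#' @return object of class `diagnostic_report`: list of per-parameter
#'   results plus assembled data.frames `table_groups`, `table_roc`,
#'   `table_accuracy`.
#' @export
diagnose_cohort <- function(cohort,
                            parameters = intersect(
                              c("RL", "PRW", "RSA", "RV", "RSA_RL", "RV_RL"),
                              names(cohort))) {
  if (!"group" %in% names(cohort)) stop("cohort needs a 'group' column")
  if (!all(cohort$group %in% c("NRT", "CRT")))
    stop("group labels must be NRT or CRT")
  if (length(parameters) == 0L) stop("no metric columns to analyse")
  per <- lapply(parameters, function(p) {
    crt <- cohort[[p]][cohort$group == "CRT"]
    nrt <- cohort[[p]][cohort$group == "NRT"]
    gc <- group_compare(nrt, crt)
    roc <- roc_auc(crt, nrt, parameter = p)
    yc <- youden_cutoff(roc)
    pred <- classify(cohort[[p]], yc$cutoff)
    tp <- sum(pred == "CRT" & cohort$group == "CRT")
    fp <- sum(pred == "CRT" & cohort$group == "NRT")
    fn <- sum(pred == "NRT" & cohort$group == "CRT")
    tn <- sum(pred == "NRT" & cohort$group == "NRT")
    cm <- contingency_metrics(tp, fp, fn, tn)
    list(parameter = p,
         nrt_mean = mean(nrt), nrt_sd = sd(nrt),
         crt_mean = mean(crt), crt_sd = sd(crt),
         t_p = gc$t_p, w_p = gc$w_p,
         roc = roc, auc = roc$auc,
         cutoff = yc$cutoff, counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
         metrics = cm)
  })
  names(per) <- parameters
  table_groups <- data.frame(
    parameter = parameters,
    nrt_mean = vapply(per, `[[`, 0, "nrt_mean"),
    nrt_sd = vapply(per, `[[`, 0, "nrt_sd"),
    crt_mean = vapply(per, `[[`, 0, "crt_mean"),
    crt_sd = vapply(per, `[[`, 0, "crt_sd"),
    p_t = vapply(per, `[[`, 0, "t_p"),
    p_ranksum = vapply(per, `[[`, 0, "w_p"),
    row.names = NULL)
  table_roc <- data.frame(
    parameter = parameters,
    auc = vapply(per, `[[`, 0, "auc"),
    cutoff = vapply(per, `[[`, 0, "cutoff"),
    row.names = NULL)
  table_accuracy <- data.frame(
    parameter = parameters,
    se = vapply(per, function(x) x$metrics$se, 0),
    sp = vapply(per, function(x) x$metrics$sp, 0),
    pv_pos = vapply(per, function(x) x$metrics$pv_pos, 0),
    pv_neg = vapply(per, function(x) x$metrics$pv_neg, 0),
    yi = vapply(per, function(x) x$metrics$yi, 0),
    lr_pos = vapply(per, function(x) x$metrics$lr_pos, 0),
    lr_neg = vapply(per, function(x) x$metrics$lr_neg, 0),
    row.names = NULL)
  structure(list(per_parameter = per, table_groups = table_groups,
                 table_roc = table_roc, table_accuracy = table_accuracy),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, digits = 2, ...) {
  cat("<diagnostic_report>\n\nGroup comparison:\n")
  print(format_metrics(x$table_groups, digits))
  cat("\nROC:\n")
  print(format_metrics(x$table_roc, digits))
  cat("\nAccuracy at the Youden cut-off:\n")
  print(format_metrics(x$table_accuracy, digits))
  invisible(x)
}
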