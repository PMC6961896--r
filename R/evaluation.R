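# Discrimination and cohort-comparison statistics. The AUC is the
# midrank Mann-Whitney statistic divided by n1*n0; its CI uses the
# DeLong placement-value variance estimator (a percentile bootstrap is
# available by config).

#' ROC curve and AUC with 95% confidence interval
#'
#' AUC is computed through the midrank Mann-Whitney identity (ties get
#' half credit). The default CI is DeLong's; `ci_method = "bootstrap"`
#' uses a percentile bootstrap of patients instead.
#'
#' @param scores numeric risk scores (higher = more positive).
#' @param labels binary 0/1 outcomes.
#' @param conf_level confidence level (default 0.95).
#' @param ci_method "delong" (default) or "bootstrap".
#' @param boot_n bootstrap resamples (default 2000).
#' @return a `roc_result`: list with `auc`, `ci` (length 2), `se`,
#'   `curve` (data.frame FPR/TPR/threshold), `scores`, `labels`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95,
                    ci_method = c("delong", "bootstrap"), boot_n = 2000L) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  auc <- .auc_midrank(scores, labels)

  if (ci_method == "delong") {
    # placement values: V10[i] = P(score_i > neg) + 0.5 P(=);
    # computed from midranks within pooled and within-class rankings
    xs <- scores[labels == 1]; ys <- scores[labels == 0]
    r_all <- rank(c(xs, ys))
    v10 <- (r_all[seq_len(n1)] - rank(xs)) / n0
    v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(ys)) / n1
    # a singleton class contributes no estimable placement variance
    v <- function(x) if (length(x) > 1L) stats::var(x) else 0
    se <- sqrt(v(v10) / n1 + v(v01) / n0)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  } else {
    idx1 <- which(labels == 1); idx0 <- which(labels == 0)
    boots <- vapply(seq_len(boot_n), function(b) {
      i <- c(sample(idx1, n1, replace = TRUE), sample(idx0, n0, replace = TRUE))
      .auc_midrank(scores[i], labels[i])
    }, 0)
    se <- stats::sd(boots)
    ci <- unname(stats::quantile(boots, c((1 - conf_level) / 2,
                                          1 - (1 - conf_level) / 2)))
  }

  o <- order(scores, decreasing = TRUE)
  s_o <- scores[o]
  tp <- cumsum(labels[o] == 1)
  fp <- cumsum(labels[o] == 0)
  cut <- which(!duplicated(s_o, fromLast = TRUE))     # last row per threshold
  curve <- data.frame(
    threshold = c(Inf, s_o[cut]),
    tpr = c(0, tp[cut] / n1),
    fpr = c(0, fp[cut] / n0)
  )
  structure(list(auc = auc, ci = ci, se = se, conf_level = conf_level,
                 method = ci_method, curve = curve,
                 scores = scores, labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%d%% CI: %.3f, %.3f; %s)\n",
              x$auc, round(100 * x$conf_level), x$ci[1L], x$ci[2L], x$method))
  invisible(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed with midranks. For pooled sample sizes of 10 or fewer
#' the two-sided p-value is exact, by enumerating all group assignments
#' of the pooled values (ties handled exactly); otherwise a tie-
#' corrected normal approximation is used.
#'
#' @param x,y numeric samples for the two groups.
#' @return list with `u` (statistic for group x), `p`, and `method`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups need observations")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  ustat <- function(sel) {
    r <- rank(pooled)
    sum(r[sel]) - length(sel) * (length(sel) + 1) / 2
  }
  u <- ustat(seq_len(n1))
  mu <- n1 * n2 / 2
  if (N <= 10L) {
    combos <- utils::combn(N, n1)
    r <- rank(pooled)
    us <- apply(combos, 2L, function(s) sum(r[s])) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation with tie correction"
    p <- min(p, 1)
  }
  list(u = u, p = p, method = method)
}

#' Pearson chi-square test on a contingency table
#'
#' For 2x2 tables the continuity correction is applied by default,
#' matching standard statistical practice for cohort tables of this
#' kind; set `correct = FALSE` for the uncorrected statistic. Expected
#' counts must all be positive.
#'
#' @param tab matrix of counts (2 x k).
#' @param correct apply the continuity correction for 2x2 tables
#'   (default TRUE).
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square <- function(tab, correct = TRUE) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0)) stop("zero expected cell count")
  ct <- stats::chisq.test(tab, correct = correct)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Cohort comparison table
#'
#' Summarizes covariates between two groups the way clinical cohort
#' tables are reported: continuous variables as median (Q1, Q3) per
#' group with a Mann-Whitney U p-value, categorical variables as n (%)
#' with a chi-square p-value.
#'
#' @param data data.frame of per-patient covariates.
#' @param group name of the binary grouping column (e.g. cohort tag or
#'   outcome label).
#' @param variables covariate column names to summarize; numeric columns
#'   with more than two distinct values are treated as continuous,
#'   everything else as categorical.
#' @return data.frame with one row per variable (or per category level):
#'   variable, level, per-group summaries, test, p.
#' @export
cohort_summary <- function(data, group, variables) {
  stopifnot(group %in% names(data))
  miss <- setdiff(variables, names(data))
  if (length(miss)) stop("missing covariate columns: ", paste(miss, collapse = ", "))
  g <- data[[group]]
  lv <- sort(unique(g))
  if (length(lv) != 2L) stop("grouping column must have exactly two levels")
  rows <- list()
  fmt_med <- function(v) sprintf("%.4g (%.4g, %.4g)", stats::median(v),
                                 stats::quantile(v, 0.25, names = FALSE),
                                 stats::quantile(v, 0.75, names = FALSE))
  for (var in variables) {
    v <- data[[var]]
    continuous <- is.numeric(v) && length(unique(v)) > 2L
    if (continuous) {
      test <- mann_whitney(v[g == lv[1L]], v[g == lv[2L]])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = var, level = "",
        group1 = fmt_med(v[g == lv[1L]]), group2 = fmt_med(v[g == lv[2L]]),
        test = "Mann-Whitney U", p = test$p, stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(v), factor(g, levels = lv))
      p <- chi_square(t(tab))$p
      for (cat_lv in rownames(tab)) {
        n1 <- tab[cat_lv, 1L]; n2 <- tab[cat_lv, 2L]
        rows[[length(rows) + 1L]] <- data.frame(
          variable = var, level = cat_lv,
          group1 = sprintf("%d (%.1f%%)", n1, 100 * n1 / sum(tab[, 1L])),
          group2 = sprintf("%d (%.1f%%)", n2, 100 * n2 / sum(tab[, 2L])),
          test = "Chi-square", p = p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  names(out)[3:4] <- paste0(group, "=", lv)
  out
}

#' Write a ROC curve as CSV
#' @param roc a `roc_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  stopifnot(inherits(roc, "roc_result"))
  utils::write.csv(roc$curve[, c("fpr", "tpr", "threshold")], path,
                   row.names = FALSE)
  invisible(path)
}
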