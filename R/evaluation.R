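# Discrimination and calibration metrics: Mann-Whitney AUC with a
# stratified percentile bootstrap, Youden threshold, Wilson-interval
# confusion metrics, Hosmer-Lemeshow deciles-of-risk, an in-module IRLS
# calibration slope, and the Brier score.

.check_two_class <- function(labels) {
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels must be 0/1 without NA")
  if (!any(labels) || all(labels))
    stop("undefined metric: both classes must be present")
  labels
}

#' ROC area under the curve (Mann-Whitney)
#'
#' AUC as the concordance probability: with midranks, ties count 1/2, so
#' \code{auc = (sum of case ranks - n1(n1+1)/2) / (n1 n0)}.
#'
#' @param scores numeric risk scores (higher = more positive).
#' @param labels binary outcomes (logical or 0/1).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- .check_two_class(labels)
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified percentile bootstrap CI for the AUC
#'
#' Resamples cases and controls separately (class sizes preserved) and
#' takes percentile quantiles of the bootstrap AUC distribution.
#'
#' @param scores,labels as in \code{\link{roc_auc}}.
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return Numeric \code{c(lo, hi)}.
#' @export
auc_bootstrap_ci <- function(scores, labels, n_boot = 2000, seed = 1L,
                             conf = 0.95) {
  labels <- .check_two_class(labels)
  s1 <- scores[labels]; s0 <- scores[!labels]
  stat <- .with_seed(seed, vapply(seq_len(n_boot), function(i) {
    b1 <- sample(s1, replace = TRUE)
    b0 <- sample(s0, replace = TRUE)
    roc_auc(c(b1, b0), c(rep(TRUE, length(b1)), rep(FALSE, length(b0))))
  }, numeric(1)))
  unname(stats::quantile(stat, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
}

#' Youden-optimal operating threshold
#'
#' Maximizes J = sensitivity + specificity - 1 over all thresholds midway
#' between adjacent distinct scores (plus the extremes); ties in J are
#' broken toward the higher threshold (higher specificity). Classification
#' is \code{score >= threshold}.
#'
#' @param scores,labels as in \code{\link{roc_auc}}.
#' @return The selected threshold.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- .check_two_class(labels)
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  j <- vapply(cand, function(th) {
    sens <- mean(scores[labels] >= th)
    spec <- mean(scores[!labels] < th)
    sens + spec - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)
  cand[max(best)]
}

# Wilson score interval for a binomial proportion
.wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Confusion-matrix metrics at a threshold
#'
#' Sensitivity, specificity, PPV and NPV of the rule
#' \code{score >= threshold}, each with a Wilson score interval. An empty
#' predicted-positive (or -negative) set leaves the corresponding predictive
#' value NA and sets a flag.
#'
#' @param scores,labels as in \code{\link{roc_auc}}.
#' @param threshold finite classification threshold.
#' @param conf confidence level of the Wilson intervals.
#' @return List with the four proportions, their CIs, the 2x2 counts, and
#'   \code{undefined} flags.
#' @export
confusion_metrics <- function(scores, labels, threshold, conf = 0.95) {
  labels <- .check_two_class(labels)
  if (!is.finite(threshold)) stop("threshold must be finite")
  pred <- scores >= threshold
  tp <- sum(pred & labels); fn <- sum(!pred & labels)
  fp <- sum(pred & !labels); tn <- sum(!pred & !labels)
  res <- list(
    sensitivity = tp / (tp + fn), sensitivity_ci = .wilson_ci(tp, tp + fn, conf),
    specificity = tn / (tn + fp), specificity_ci = .wilson_ci(tn, tn + fp, conf),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    ppv_ci = .wilson_ci(tp, tp + fp, conf),
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    npv_ci = .wilson_ci(tn, tn + fn, conf),
    counts = c(tp = tp, fn = fn, fp = fp, tn = tn),
    undefined = c(ppv = tp + fp == 0, npv = tn + fn == 0)
  )
  res
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups patients into deciles of predicted risk and compares observed and
#' expected event counts: \code{chi2 = sum (O - E)^2 / (E (1 - E/n_g))},
#' with \code{n_groups - 2} degrees of freedom. Quantile ties can yield
#' fewer groups; a group with zero expected events (or non-events) is merged
#' with its neighbour and the merge is reported.
#'
#' @param pred_probs predicted event probabilities.
#' @param outcomes binary outcomes.
#' @param n_groups number of risk groups (default 10).
#' @return List with \code{chi2}, \code{df}, \code{p}, the per-group table,
#'   and \code{merged} (number of merges applied).
#' @export
hosmer_lemeshow <- function(pred_probs, outcomes, n_groups = 10) {
  outcomes <- as.numeric(outcomes)
  n <- length(pred_probs)
  if (n < n_groups) stop("need at least n_groups observations")
  br <- unique(stats::quantile(pred_probs, probs = seq(0, 1, length.out = n_groups + 1)))
  g <- cut(pred_probs, breaks = br, include.lowest = TRUE)
  tab <- data.frame(
    n = as.vector(table(g)),
    obs = as.vector(tapply(outcomes, g, sum)),
    exp = as.vector(tapply(pred_probs, g, sum))
  )
  tab <- tab[tab$n > 0, , drop = FALSE]
  merged <- 0L
  repeat {
    bad <- which(tab$exp < 1e-9 | (tab$n - tab$exp) < 1e-9)
    if (!length(bad) || nrow(tab) <= 2) break
    i <- bad[1]
    j <- if (i == 1) 2L else i - 1L
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$obs[j] <- tab$obs[j] + tab$obs[i]
    tab$exp[j] <- tab$exp[j] + tab$exp[i]
    tab <- tab[-i, , drop = FALSE]
    merged <- merged + 1L
  }
  if (merged > 0)
    message("hosmer_lemeshow: merged ", merged, " group(s) with zero expected count")
  chi2 <- sum((tab$obs - tab$exp)^2 / (tab$exp * (1 - tab$exp / tab$n)))
  df <- nrow(tab) - 2
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       groups = tab, merged = merged)
}

#' Calibration slope via in-module IRLS
#'
#' Fits the logistic recalibration model
#' \code{logit P(y=1) = a + b logit(p)} by iteratively reweighted least
#' squares and returns the slope b (1 = perfectly calibrated spread;
#' < 1 = overdispersed predictions).
#'
#' @param pred_probs predicted probabilities strictly inside (0, 1).
#' @param outcomes binary outcomes.
#' @param max_iter,tol IRLS controls.
#' @return List with \code{slope}, \code{intercept}, \code{converged},
#'   \code{separation} flag, iterations used.
#' @export
calibration_slope <- function(pred_probs, outcomes, max_iter = 25, tol = 1e-8) {
  if (any(pred_probs <= 0 | pred_probs >= 1))
    stop("pred_probs must lie strictly inside (0, 1)")
  y <- as.numeric(outcomes)
  X <- cbind(1, stats::qlogis(pred_probs))
  beta <- c(0, 1)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    delta <- max(abs(beta_new - beta))
    beta <- drop(beta_new)
    if (delta < tol) { converged <- TRUE; break }
  }
  separation <- !converged || max(abs(beta)) > 20
  if (separation)
    warning("calibration_slope: possible separation / non-convergence")
  list(slope = beta[2], intercept = beta[1], converged = converged,
       separation = separation, iterations = it)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and outcome.
#'
#' @param pred_probs predicted probabilities.
#' @param outcomes binary outcomes (same length).
#' @return Brier score in [0, 1].
#' @export
brier_score <- function(pred_probs, outcomes) {
  if (length(pred_probs) != length(outcomes))
    stop("pred_probs and outcomes must have the same length")
  mean((pred_probs - as.numeric(outcomes))^2)
}

#' Full metrics report for one score/outcome pair
#'
#' @param scores risk scores (probabilities enable the calibration block).
#' @param labels binary outcomes.
#' @param n_boot bootstrap resamples for the AUC CI.
#' @param seed bootstrap seed.
#' @param is_probability whether \code{scores} are probabilities (adds
#'   Hosmer-Lemeshow, calibration slope and Brier score).
#' @return A \code{metrics_report} list.
#' @export
metrics_report <- function(scores, labels, n_boot = 2000, seed = 1L,
                           is_probability = all(scores >= 0 & scores <= 1)) {
  th <- youden_threshold(scores, labels)
  cm <- confusion_metrics(scores, labels, th)
  rep <- list(auc = roc_auc(scores, labels),
              auc_ci = auc_bootstrap_ci(scores, labels, n_boot, seed),
              youden_threshold = th,
              sensitivity = cm$sensitivity, sensitivity_ci = cm$sensitivity_ci,
              specificity = cm$specificity, specificity_ci = cm$specificity_ci,
              ppv = cm$ppv, ppv_ci = cm$ppv_ci,
              npv = cm$npv, npv_ci = cm$npv_ci)
  if (is_probability) {
    p <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
    hl <- hosmer_lemeshow(p, labels)
    cs <- tryCatch(calibration_slope(p, labels),
                   warning = function(w) suppressWarnings(calibration_slope(p, labels)))
    rep$hosmer_lemeshow_chi2 <- hl$chi2
    rep$hl_p <- hl$p
    rep$calibration_slope <- cs$slope
    rep$brier <- brier_score(scores, labels)
  }
  class(rep) <- "metrics_report"
  rep
}

#' Comparison table of several scores (one row per score)
#'
#' @param panel score panel from \code{\link{score_panel}}.
#' @param labels binary outcomes aligned with the panel.
#' @param n_boot,seed bootstrap controls.
#' @return data.frame with AUC (CI), threshold metrics, and (for
#'   probability scores) calibration statistics.
#' @export
compare_scores <- function(panel, labels, n_boot = 500, seed = 1L) {
  score_cols <- setdiff(names(panel), "patient_id")
  rows <- lapply(score_cols, function(sc) {
    r <- metrics_report(panel[[sc]], labels, n_boot, seed)
    data.frame(score = sc, auc = r$auc, auc_lo = r$auc_ci[1], auc_hi = r$auc_ci[2],
               sensitivity = r$sensitivity, specificity = r$specificity,
               ppv = r$ppv, npv = r$npv,
               hl_p = if (is.null(r$hl_p)) NA_real_ else r$hl_p,
               calibration_slope = if (is.null(r$calibration_slope)) NA_real_
                                   else r$calibration_slope,
               brier = if (is.null(r$brier)) NA_real_ else r$brier,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
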