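# The statistical layer: one-tailed exact/approximate Wilcoxon signed-rank
# and Mann-Whitney tests, ROC with Youden cutoff, investigator R-squared and
# the per-definition cohort summary table.

#' One-tailed Wilcoxon signed-rank test
#'
#' Tests whether paired differences are shifted above (`greater`) or below
#' (`less`) zero. Zero differences are dropped (the classical convention;
#' documented rather than Pratt's method), tied magnitudes receive midranks.
#' For `n <= exact_max_n` nonzero differences the p-value is computed from
#' the exact null distribution of the positive-rank sum W+ — built by the
#' generating-function recursion over all 2^n sign assignments, which is
#' valid under ties as well — with the convention `p = P(W+ >= w)` for
#' `greater` (and `P(W+ <= w)` for `less`). Above that, a normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param diffs numeric paired differences.
#' @param alternative `"greater"` or `"less"`.
#' @param exact_max_n switchover sample size between exact and approximate.
#' @return list: `statistic` (W+), `p_value`, `n` (nonzero differences),
#'   `exact` (logical).
#' @export
wilcoxon_signed_rank_one_tailed <- function(diffs,
                                            alternative = c("greater", "less"),
                                            exact_max_n = 25L) {
  alternative <- match.arg(alternative)
  d <- as.numeric(diffs)
  d <- d[!is.na(d)]
  d <- d[d != 0]
  if (length(d) == 0)
    stop("all differences are zero: signed-rank test undefined", call. = FALSE)
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max_n) {
    # distribution of 2*W+ over doubled (integer) midranks
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    cnt <- numeric(total + 1)      # index i <-> 2W+ = i-1
    cnt[1] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), cnt[seq_len(total + 1 - rr)])
      cnt <- cnt + shifted
    }
    probs <- cnt / 2^n
    w2 <- as.integer(round(2 * w))
    p <- if (alternative == "greater") sum(probs[(w2 + 1):(total + 1)])
         else sum(probs[1:(w2 + 1)])
    list(statistic = w, p_value = min(1, p), n = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- 0.5
    z <- if (alternative == "greater") (w - mu - cc) / sqrt(sig2)
         else (w - mu + cc) / sqrt(sig2)
    p <- if (alternative == "greater") pnorm(z, lower.tail = FALSE)
         else pnorm(z)
    list(statistic = w, p_value = p, n = n, exact = FALSE)
  }
}

#' One-tailed Mann-Whitney U test
#'
#' `alternative = "greater"` tests that `x` is stochastically larger than
#' `y`. For `length(x) * length(y) <= exact_max_mn` and tie-free data the
#' p-value comes from the exact null distribution of U (count recursion over
#' all orderings); otherwise a normal approximation with tie-corrected
#' variance and continuity correction. When the tie-corrected variance is
#' zero (all values identical) the p-value is 0.5 at the null mean by the
#' symmetry convention.
#'
#' @param x,y numeric samples.
#' @param alternative `"greater"` or `"less"`.
#' @param exact_max_mn switchover product of sample sizes.
#' @return list: `U`, `p_value`, `exact` (logical).
#' @export
mann_whitney_one_tailed <- function(x, y,
                                    alternative = c("greater", "less"),
                                    exact_max_mn = 400L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x[!is.na(x)])
  y <- as.numeric(y[!is.na(y)])
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be nonempty", call. = FALSE)
  m <- length(x); n <- length(y)
  ge <- outer(x, y, `>`)
  eq <- outer(x, y, `==`)
  U <- sum(ge) + 0.5 * sum(eq)
  ties_present <- any(eq) || anyDuplicated(x) || anyDuplicated(y)

  if (!ties_present && m * n <= exact_max_mn) {
    # tie-free exact null distribution of U (rank-subset count recursion)
    u <- as.integer(round(U))
    p <- if (alternative == "greater")
      stats::pwilcox(u - 1, m, n, lower.tail = FALSE)
    else stats::pwilcox(u, m, n)
    return(list(U = U, p_value = min(1, p), exact = TRUE))
  }
  N <- m + n
  mu <- m * n / 2
  tt <- table(c(x, y))
  tiecor <- sum(tt^3 - tt) / (N * (N - 1))
  sig2 <- m * n / 12 * ((N + 1) - tiecor)
  if (sig2 <= 0) {
    p <- if (isTRUE(all.equal(U, mu))) 0.5 else as.numeric(U < mu)
    if (alternative == "greater" && !isTRUE(all.equal(U, mu)))
      p <- as.numeric(U < mu)
    if (alternative == "less" && !isTRUE(all.equal(U, mu)))
      p <- as.numeric(U > mu)
    return(list(U = U, p_value = p, exact = FALSE))
  }
  cc <- 0.5
  z <- if (alternative == "greater") (U - mu - cc) / sqrt(sig2)
       else (U - mu + cc) / sqrt(sig2)
  p <- if (alternative == "greater") pnorm(z, lower.tail = FALSE)
       else pnorm(z)
  list(U = U, p_value = p, exact = FALSE)
}

#' Empirical ROC curve with AUC and Youden-optimal cutoff
#'
#' Classifies positive when `score >= threshold`. The AUC is the trapezoidal
#' area under the empirical curve, which equals the pairwise concordance
#' `(concordant + 0.5 * tied) / (n1 * n0)`. The optimal threshold maximizes
#' Youden's J (sensitivity + specificity - 1); ties are broken toward the
#' lower threshold.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels logical (or coercible) class labels, `TRUE` = positive.
#' @return object of class `roc_result`: `thresholds`, `sensitivities`,
#'   `specificities`, `auc`, `optimal_threshold`.
#' @export
roc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!labels] < t), numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
  j <- sens + spec - 1
  best_j <- max(j)
  cand <- which(j >= best_j - 1e-12)
  optimal <- min(thr[cand])
  structure(
    list(thresholds = thr, sensitivities = sens, specificities = spec,
         auc = auc, optimal_threshold = optimal),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC ", signif(x$auc, 3), ", optimal threshold ",
      signif(x$optimal_threshold, 3), "\n", sep = "")
  invisible(x)
}

#' Coefficient of determination between two investigators' measurements
#'
#' Squared Pearson correlation of paired measurements of the same quantity
#' by two blinded investigators.
#'
#' @param x,y paired numeric measurements, length >= 2.
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least 2 paired values", call. = FALSE)
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance: R-squared undefined", call. = FALSE)
  stats::cor(x, y)^2
}

#' Per-definition growth summary of a cohort
#'
#' One row per growth definition — the prioritized VSG, VSG1 through VSG4
#' and VCG — with the mean and SD of the paired volume differences, the mean
#' and SD of the percent changes, the one-tailed signed-rank p-value (sac
#' growth tested `greater`, coil compaction tested `less`) and the number
#' of subjects for which the definition is computable. Definitions with no
#' computable subject yield NA throughout (for controls this is always the
#' case for VSG1 and VSG2); SD is NA for single-subject rows; the p-value is
#' NA when every difference is exactly zero (test undefined).
#'
#' @param results data.frame of per-subject rows from [growth_result()].
#' @param cohort optional cohort label to filter on.
#' @return data.frame: cohort, definition, n, mean_cc, sd_cc, mean_pct,
#'   sd_pct, p_value.
#' @export
summarize_cohort <- function(results, cohort = NULL) {
  if (!is.null(cohort)) results <- results[results$cohort == cohort, ]
  if (nrow(results) == 0) stop("no subjects in cohort", call. = FALSE)
  lab <- if (is.null(cohort)) paste(unique(results$cohort), collapse = "+")
         else cohort

  defs <- list(
    VSG  = list(diff = results$vsg, pct = results$pct_vsg, alt = "greater"),
    VSG1 = list(diff = results$vs2p - results$vs1m,
                pct = 100 * (results$vs2p - results$vs1m) / results$vs1m,
                alt = "greater"),
    VSG2 = list(diff = results$vs2p - results$vs1p,
                pct = 100 * (results$vs2p - results$vs1p) / results$vs1p,
                alt = "greater"),
    VSG3 = list(diff = results$vs2m - results$vs1m,
                pct = 100 * (results$vs2m - results$vs1m) / results$vs1m,
                alt = "greater"),
    VSG4 = list(diff = results$vs2m - results$vs1p,
                pct = 100 * (results$vs2m - results$vs1p) / results$vs1p,
                alt = "greater"),
    VCG  = list(diff = results$vcg, pct = results$pct_vcg, alt = "less")
  )
  rows <- lapply(names(defs), function(nm) {
    d <- defs[[nm]]
    keep <- !is.na(d$diff)
    dd <- d$diff[keep]; pp <- d$pct[keep]
    n <- length(dd)
    if (n == 0)
      return(data.frame(cohort = lab, definition = nm, n = 0L,
                        mean_cc = NA_real_, sd_cc = NA_real_,
                        mean_pct = NA_real_, sd_pct = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    p <- tryCatch(
      wilcoxon_signed_rank_one_tailed(dd, d$alt)$p_value,
      error = function(e) NA_real_
    )
    data.frame(
      cohort = lab, definition = nm, n = n,
      mean_cc = mean(dd), sd_cc = if (n > 1) sd(dd) else NA_real_,
      mean_pct = mean(pp), sd_pct = if (n > 1) sd(pp) else NA_real_,
      p_value = p, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
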