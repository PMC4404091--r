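# Statistical layer: exact one-tailed tests against enumeration and base R,
# ROC/AUC identities, investigator R^2, cohort summary table.

test_that("signed-rank exact p-values follow the documented convention", {
  r <- wilcoxon_signed_rank_one_tailed(c(1, 2, 3, 4, 5), "greater")
  expect_true(r$exact)
  expect_equal(r$p_value, 1 / 32)   # only the all-positive sign pattern

  # agreement with base R's exact test on tie-free data
  set.seed(10)
  for (i in 1:10) {
    d <- round(rnorm(7, 0.3, 1), 3)
    d <- d[d != 0]
    for (alt in c("greater", "less")) {
      mine <- wilcoxon_signed_rank_one_tailed(d, alt)$p_value
      ref <- suppressWarnings(wilcox.test(d, alternative = alt,
                                          exact = TRUE))$p.value
      expect_equal(mine, ref, tolerance = 1e-10)
    }
  }
  expect_error(wilcoxon_signed_rank_one_tailed(c(0, 0)), "zero")
})

test_that("signed-rank normal approximation tracks the exact tail", {
  set.seed(4)
  d <- rnorm(40, 0.3)
  approx <- wilcoxon_signed_rank_one_tailed(d, "greater")
  expect_false(approx$exact)
  ref <- suppressWarnings(wilcox.test(d, alternative = "greater",
                                      exact = FALSE, correct = TRUE))$p.value
  expect_equal(approx$p_value, ref, tolerance = 1e-6)
})

test_that("Mann-Whitney exact and approximate branches are correct", {
  r <- mann_whitney_one_tailed(c(4, 5, 6), c(1, 2, 3), "greater")
  expect_true(r$exact)
  expect_equal(r$U, 9)
  expect_equal(r$p_value, 0.05)   # 1 of choose(6,3) orderings

  sep <- mann_whitney_one_tailed(10 + 1:9, 1:9 / 10, "greater")
  expect_equal(sep$p_value, 1 / choose(18, 9))

  tie <- mann_whitney_one_tailed(5, 5, "greater")
  expect_equal(tie$p_value, 0.5)

  set.seed(11)
  x <- rnorm(8); y <- rnorm(6)
  for (alt in c("greater", "less")) {
    mine <- mann_whitney_one_tailed(x, y, alt)$p_value
    ref <- suppressWarnings(wilcox.test(x, y, alternative = alt,
                                        exact = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-10)
  }
  # tie-corrected normal branch
  xt <- c(1, 2, 2, 3, 5, 5, 6, 8, 9, 9)
  yt <- c(2, 3, 3, 4, 5, 7, 7, 8, 8, 10)
  mine <- mann_whitney_one_tailed(xt, yt, "greater")
  ref <- suppressWarnings(wilcox.test(xt, yt, alternative = "greater",
                                      exact = FALSE, correct = TRUE))$p.value
  expect_false(mine$exact)
  expect_equal(mine$p_value, ref, tolerance = 1e-6)
  expect_error(mann_whitney_one_tailed(numeric(0), 1:3), "nonempty")
})

test_that("ROC has the concordance AUC and a Youden-optimal cutoff", {
  r <- roc(c(1, 2, 3, 10, 11, 12), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_gt(r$optimal_threshold, 3)
  expect_lte(r$optimal_threshold, 10)

  const <- roc(rep(1, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(const$auc, 0.5)

  expect_error(roc(1:5, rep(TRUE, 5)), "both classes")

  # AUC = U / (n1 * n0) on arbitrary data with ties
  set.seed(5)
  for (i in 1:20) {
    sc <- sample(1:6, 20, replace = TRUE)
    lab <- rbinom(20, 1, 0.5)
    if (length(unique(lab)) < 2) next
    r <- roc(sc, lab == 1)
    U <- mann_whitney_one_tailed(sc[lab == 1], sc[lab == 0], "greater")$U
    expect_equal(r$auc, U / (sum(lab == 1) * sum(lab == 0)),
                 tolerance = 1e-12)
  }
  # cross-check against an independent ROC implementation
  set.seed(6)
  sc <- rnorm(40); lab <- rbinom(40, 1, 0.5)
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc(sc, lab == 1)$auc, ref, tolerance = 1e-9)
  }
})

test_that("investigator R^2 is the squared correlation", {
  x <- c(0.1, 0.4, 0.9, 1.6, 2.2)
  expect_equal(r_squared(x, x), 1)
  expect_equal(r_squared(x, 2 * x + 3), 1)
  y <- x; y[3] <- y[3] + 0.2
  hand <- (sum((x - mean(x)) * (y - mean(y))) /
             sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
  expect_equal(r_squared(x, y), hand)
  expect_error(r_squared(rep(1, 4), 1:4), "variance")
})

test_that("cohort summaries carry per-definition n and one-tailed p-values", {
  set.seed(8)
  n <- 12
  mk <- function(i, cohort, grow) {
    v1m <- runif(1, 0.3, 1.2)
    v1p <- v1m * (1 + rnorm(1, 0, 0.02))
    v2m <- v1m * (1 + grow + rnorm(1, 0, 0.02))
    v2p <- if (cohort == "recurrence") v2m * (1 + rnorm(1, 0, 0.02)) else NA
    vc <- runif(1, 0.1, 0.4)
    growth_result(subject_volumes(
      sprintf("%s%02d", cohort, i), cohort,
      vs1m = v1m, vs1p = v1p, vs2m = v2m, vs2p = v2p,
      vc1p = vc, vc2m = vc * (1 + rnorm(1, 0, 0.03)),
      c1p = c(0, 0, 0), c2m = rnorm(3, 0, 0.3)))
  }
  rec <- do.call(rbind, lapply(1:n, mk, cohort = "recurrence", grow = 0.2))
  ctl <- do.call(rbind, lapply(1:n, mk, cohort = "control", grow = 0))
  res <- rbind(rec, ctl)

  s_rec <- summarize_cohort(res, "recurrence")
  s_ctl <- summarize_cohort(res, "control")
  expect_equal(s_ctl$n[s_ctl$definition %in% c("VSG1", "VSG2")], c(0L, 0L))
  expect_true(all(is.na(
    s_ctl$mean_cc[s_ctl$definition %in% c("VSG1", "VSG2")])))
  expect_lt(s_rec$p_value[s_rec$definition == "VSG"], 0.05)
  expect_equal(s_rec$n[s_rec$definition == "VSG"], n)

  single <- summarize_cohort(res[1, , drop = FALSE], "recurrence")
  expect_true(is.na(single$sd_cc[single$definition == "VSG"]))
  expect_equal(single$n[single$definition == "VSG"], 1L)

  # availability bookkeeping: per-definition n equals computable subjects
  res2 <- rec
  res2$vs2p[1:4] <- NA
  res2$vs1m[5] <- NA
  s2 <- summarize_cohort(res2, "recurrence")
  expect_equal(s2$n[s2$definition == "VSG1"],
               sum(!is.na(res2$vs2p) & !is.na(res2$vs1m)))
  expect_equal(s2$n[s2$definition == "VSG3"],
               sum(!is.na(res2$vs2m) & !is.na(res2$vs1m)))
})
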