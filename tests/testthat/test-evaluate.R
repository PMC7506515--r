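test_that("confusion metrics reproduce published review-count arithmetic", {
  dev <- review_counts_to_cases(dev_band_counts())
  m <- confusion_metrics(dev$labels, dev$scores, threshold = 0.10)
  expect_identical(unname(m$counts),
                   c(13L + 28L, 60L + 39L - 41L, 6L, 282L - 6L))
  expect_equal(round(100 * m$ppv[["est"]], 1), 41.4)
  expect_equal(round(100 * m$sensitivity[["est"]], 1), 87.2)
  expect_equal(round(100 * m$specificity[["est"]], 1), 82.6)
  val <- review_counts_to_cases(val_band_counts())
  m <- confusion_metrics(val$labels, val$scores, threshold = 0.10)
  expect_equal(round(100 * m$ppv[["est"]], 1), 43.5)
  expect_equal(round(100 * m$sensitivity[["est"]], 1), 94.4)
  expect_equal(round(100 * m$specificity[["est"]], 1), 48.8)
  # Clopper-Pearson interval contains the point estimate
  for (metric in c("ppv", "sensitivity", "specificity")) {
    v <- m[[metric]]
    expect_true(v[["lo"]] <= v[["est"]] && v[["est"]] <= v[["hi"]])
  }
})

test_that("degenerate confusion tables are handled explicitly", {
  labels <- data.frame(procedure_id = c("a", "b"), reviewed = TRUE,
                       infection = c(TRUE, FALSE))
  scores <- data.frame(procedure_id = c("a", "b"),
                       probability = c(0.9, 0.01))
  m <- confusion_metrics(labels, scores)
  expect_equal(m$ppv[["est"]], 1)
  expect_equal(m$sensitivity[["est"]], 1)
  expect_equal(m$specificity[["est"]], 1)
  # nothing above threshold: PPV undefined, not zero
  m <- confusion_metrics(labels,
                         data.frame(procedure_id = c("a", "b"),
                                    probability = c(0.05, 0.01)))
  expect_true(is.na(m$ppv[["est"]]))
  expect_equal(m$sensitivity[["est"]], 0)
})

test_that("band table reproduces published distribution and conserves totals", {
  dev <- review_counts_to_cases(dev_band_counts())
  bt <- band_table(dev$scores, dev$labels)
  expect_identical(bt$cohort_n, dev_band_counts()$cohort_n)
  expect_equal(round(bt$cohort_pct, 1), c(92.5, 2.4, 2.3, 1.8, 1.0))
  expect_identical(bt$reviewed_n, dev_band_counts()$reviewed_n)
  expect_identical(bt$infections_n, dev_band_counts()$infections_n)
  expect_equal(round(bt$ppv_pct, 1), c(0.5, 3.8, 7.1, 21.7, 71.8))
  # conservation
  expect_identical(sum(bt$cohort_n), 9606L)
  expect_identical(sum(bt$reviewed_n), 381L)
  expect_identical(sum(bt$infections_n), 47L)
  # all probabilities zero collapse into the lowest band
  z <- data.frame(procedure_id = c("a", "b"), probability = 0)
  zl <- data.frame(procedure_id = c("a", "b"), reviewed = FALSE,
                   infection = FALSE)
  bz <- band_table(z, zl)
  expect_identical(bz$cohort_n[1], 2L)
  expect_identical(sum(bz$cohort_n), 2L)
  # probability 1 lands in the top band
  o <- data.frame(procedure_id = "a", probability = 1)
  expect_identical(band_table(o, zl)$cohort_n[5], 1L)
  expect_error(band_table(z, zl, band_edges = c(0, 0.5)), "from 0 to 1")
})

test_that("AUC equals all-pairs enumeration and behaves at the extremes", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE,
                                                FALSE))$auc, 1.0)
  expect_error(roc_auc(c(0.1, 0.2), c(TRUE, TRUE)), "positive and one negative")
  set.seed(23)
  for (i in 1:30) {
    n <- sample(4:50, 1)
    scores <- round(runif(n), sample(1:2, 1))  # coarse grid forces ties
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    expect_equal(roc_auc(scores, labels)$auc, brute_auc(scores, labels),
                 tolerance = 1e-12)
  }
  # label-independent scores give AUC near 1/2
  set.seed(29)
  n <- 4000
  scores <- runif(n)
  labels <- runif(n) < 0.5
  auc <- roc_auc(scores, labels)$auc
  se <- sqrt((n / 2 + 1) / (12 * (n / 2)^2))  # normal-approx null SE
  expect_lt(abs(auc - 0.5), 3 * se)
  # curve endpoints
  pts <- roc_auc(scores, labels)$points
  expect_equal(pts$sensitivity[1], 0)
  expect_equal(pts$sensitivity[nrow(pts)], 1)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  scores <- runif(300)
  labels <- runif(300) < plogis(3 * scores - 2)
  ours <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<",
                                        levels = c(FALSE, TRUE))))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("Cohen's kappa matches hand computation and its conventions", {
  expect_equal(cohen_kappa(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE)), 1.0)
  # 2x2 agreement table a=40 b=5 c=5 d=50:
  # po = 90/100, pe = (45*45 + 55*55)/100^2 = 0.505, kappa = 0.79797...
  a <- rep(c(TRUE, TRUE, FALSE, FALSE), times = c(40, 5, 5, 50))
  b <- rep(c(TRUE, FALSE, TRUE, FALSE), times = c(40, 5, 5, 50))
  expect_equal(cohen_kappa(a, b), (0.9 - 0.505) / (1 - 0.505),
               tolerance = 1e-12)
  # both raters constant and identical: defined as 1
  expect_equal(cohen_kappa(rep(TRUE, 5), rep(TRUE, 5)), 1.0)
  # independent raters: kappa near 0 (3 SE of the null, approx 1/sqrt(n))
  set.seed(37)
  n <- 5000
  expect_lt(abs(cohen_kappa(runif(n) < 0.5, runif(n) < 0.5)),
            3 / sqrt(n))
  expect_error(cohen_kappa(TRUE, logical(0)), "equal-length")
})

test_that("infection summaries report type shares and onset moments", {
  labels <- data.frame(
    procedure_id = as.character(1:5),
    reviewed = TRUE,
    infection = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    infection_type = c("pocket", "pocket", "endocarditis_or_lead",
                       "cellulitis_only", "none"),
    onset_day = c(20L, 40L, 35L, 10L, NA),
    stringsAsFactors = FALSE)
  s <- infection_summary(labels)
  expect_identical(s$n[s$infection_type == "pocket"], 2L)
  expect_equal(s$pct[s$infection_type == "pocket"], 50)
  expect_equal(s$onset_mean[s$infection_type == "pocket"], 30)
  expect_equal(s$onset_sd[s$infection_type == "pocket"], sd(c(20, 40)))
  # single infection of a type: SD undefined
  expect_true(is.na(s$onset_sd[s$infection_type == "cellulitis_only"]))
  # empty label set
  expect_identical(nrow(infection_summary(labels[labels$infection == FALSE &
                                                   FALSE, ])), 0L)
})
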