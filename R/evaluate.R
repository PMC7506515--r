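clopper_pearson <- function(x, n, conf = 0.95) {
  if (n == 0L) return(c(est = NA_real_, lo = NA_real_, hi = NA_real_))
  ci <- stats::binom.test(x, n, conf.level = conf)$conf.int
  c(est = x / n, lo = ci[1], hi = ci[2])
}

#' Confusion metrics over reviewed cases
#'
#' PPV, sensitivity and specificity with exact Clopper-Pearson 95% CIs,
#' computed **over reviewed cases only** (partial verification: only a
#' sample of cases receives the reference-standard review, and no
#' verification-bias correction is applied — the reported sensitivity and
#' specificity are therefore estimates among reviewed cases, which is how
#' two-phase review designs conventionally report them). A zero denominator
#' yields `NA` ("undefined"), never 0.
#'
#' @param labels Review labels: data frame with `procedure_id`, `reviewed`,
#'   `infection`.
#' @param scores Data frame with `procedure_id` and `probability` (e.g.
#'   [triage_predict()] output).
#' @param threshold Classification threshold (`probability >= threshold` is
#'   test-positive), default 0.10.
#' @return Object of class `confusion_metrics`: `counts` (tp/fp/fn/tn over
#'   reviewed cases) and `ppv`, `sensitivity`, `specificity` each as
#'   `c(est, lo, hi)` proportions.
#' @export
confusion_metrics <- function(labels, scores, threshold = 0.10) {
  reviewed <- labels[labels$reviewed %in% TRUE, , drop = FALSE]
  idx <- match(reviewed$procedure_id, scores$procedure_id)
  if (anyNA(idx)) {
    stop("reviewed labels without a score: ",
         paste(utils::head(reviewed$procedure_id[is.na(idx)], 5L),
               collapse = ", "), call. = FALSE)
  }
  pos <- scores$probability[idx] >= threshold
  truth <- reviewed$infection
  counts <- c(tp = sum(pos & truth), fp = sum(pos & !truth),
              fn = sum(!pos & truth), tn = sum(!pos & !truth))
  structure(list(
    counts = counts,
    threshold = threshold,
    ppv = clopper_pearson(counts[["tp"]], counts[["tp"]] + counts[["fp"]]),
    sensitivity = clopper_pearson(counts[["tp"]],
                                  counts[["tp"]] + counts[["fn"]]),
    specificity = clopper_pearson(counts[["tn"]],
                                  counts[["tn"]] + counts[["fp"]])
  ), class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("<confusion_metrics> threshold %.2f | tp=%d fp=%d fn=%d tn=%d (reviewed n=%d)\n",
              x$threshold, x$counts[["tp"]], x$counts[["fp"]],
              x$counts[["fn"]], x$counts[["tn"]], sum(x$counts)))
  for (m in c("ppv", "sensitivity", "specificity")) {
    v <- x[[m]]
    if (is.na(v[["est"]])) {
      cat(sprintf("  %-12s undefined (zero denominator)\n", m))
    } else {
      cat(sprintf("  %-12s %5.1f%% (95%% CI %.1f%%-%.1f%%)\n", m,
                  100 * v[["est"]], 100 * v[["lo"]], 100 * v[["hi"]]))
    }
  }
  invisible(x)
}

#' Probability-band distribution table
#'
#' Distribution of procedures by predicted probability of infection, with
#' review yield per band: cohort count and percentage, number reviewed,
#' true infections among reviewed, and band PPV. Bands are `[lo, hi)` with
#' the last band closed at 1 (default edges 0, 1%, 3%, 10%, 50%, 100%), so
#' the 10% band edge agrees with the `>=` review threshold.
#'
#' @param scores Data frame with `procedure_id`, `probability` for the whole
#'   cohort.
#' @param labels Review labels (`procedure_id`, `reviewed`, `infection`);
#'   cases absent from `labels` or with `reviewed = FALSE` count only
#'   toward cohort totals.
#' @param band_edges Strictly increasing numeric vector covering `[0, 1]`.
#' @return Data frame: `band`, `cohort_n`, `cohort_pct`, `reviewed_n`,
#'   `infections_n`, `ppv_pct` (NA where no cases were reviewed).
#' @export
band_table <- function(scores, labels,
                       band_edges = c(0, 0.01, 0.03, 0.10, 0.50, 1)) {
  if (is.unsorted(band_edges, strictly = TRUE) ||
      band_edges[1] != 0 || band_edges[length(band_edges)] != 1) {
    stop("band_edges must be strictly increasing from 0 to 1", call. = FALSE)
  }
  p <- scores$probability
  band <- cut(p, breaks = band_edges, right = FALSE, include.lowest = FALSE)
  band[p >= band_edges[length(band_edges) - 1L]] <-
    levels(band)[length(levels(band))]
  band[p == 0] <- levels(band)[1L]
  reviewed <- labels[labels$reviewed %in% TRUE, , drop = FALSE]
  idx <- match(scores$procedure_id, reviewed$procedure_id)
  is_rev <- !is.na(idx)
  is_inf <- is_rev & reviewed$infection[idx] %in% TRUE
  n <- length(p)
  out <- do.call(rbind, lapply(levels(band), function(b) {
    inb <- band == b
    rn <- sum(is_rev & inb)
    infn <- sum(is_inf & inb)
    data.frame(band = b, cohort_n = sum(inb),
               cohort_pct = 100 * sum(inb) / n, reviewed_n = rn,
               infections_n = infn,
               ppv_pct = if (rn > 0) 100 * infn / rn else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' ROC curve and AUC
#'
#' AUC as the Mann-Whitney concordance probability with midrank handling of
#' ties, plus the ROC curve evaluated at every distinct score threshold
#' (test-positive means `score >= threshold`).
#'
#' @param scores Numeric predicted probabilities/scores.
#' @param labels Logical (or 0/1) outcomes; both classes must be present.
#' @return List with `auc` and `points`, a data frame of `threshold`,
#'   `sensitivity`, `specificity`, `fpr` (including the (0,0) and (1,1)
#'   endpoints).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    stop("scores and labels must be equal-length and complete", call. = FALSE)
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("roc_auc requires at least one positive and one negative label",
         call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  pts <- do.call(rbind, lapply(thresholds, function(t) {
    pos <- scores >= t
    data.frame(threshold = t,
               sensitivity = sum(pos & labels) / n1,
               specificity = sum(!pos & !labels) / n0)
  }))
  pts <- rbind(data.frame(threshold = Inf, sensitivity = 0, specificity = 1),
               pts)
  pts$fpr <- 1 - pts$specificity
  rownames(pts) <- NULL
  list(auc = auc, points = pts)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` for two label
#' vectors over the same cases. When both raters are constant and identical
#' (`p_e = 1`), kappa is defined as 1 by convention (perfect observed
#' agreement with no room for chance correction).
#'
#' @param rater_a,rater_b Equal-length label vectors (any atomic type;
#'   compared as factors over the union of observed levels).
#' @return Numeric kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(rater_a, rater_b) {
  if (length(rater_a) != length(rater_b) || length(rater_a) == 0L) {
    stop("rater vectors must be equal-length and non-empty", call. = FALSE)
  }
  levels <- sort(unique(c(as.character(rater_a), as.character(rater_b))))
  a <- factor(as.character(rater_a), levels = levels)
  b <- factor(as.character(rater_b), levels = levels)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) return(1.0)
  (po - pe) / (1 - pe)
}

#' Infection characteristics summary
#'
#' Counts and percentages of confirmed infections by type, with mean (SD)
#' onset day per type. With a single infection of a type the SD is
#' undefined and reported as `NA`.
#'
#' @param labels Review labels with `infection`, `infection_type`,
#'   `onset_day`.
#' @return Data frame: `infection_type`, `n`, `pct`, `onset_mean`,
#'   `onset_sd` (empty for an empty/no-infection label set).
#' @export
infection_summary <- function(labels) {
  inf <- labels[labels$infection %in% TRUE, , drop = FALSE]
  if (nrow(inf) == 0L) {
    return(data.frame(infection_type = character(0), n = integer(0),
                      pct = numeric(0), onset_mean = numeric(0),
                      onset_sd = numeric(0), stringsAsFactors = FALSE))
  }
  types <- sort(unique(inf$infection_type))
  out <- do.call(rbind, lapply(types, function(tp) {
    d <- inf[inf$infection_type == tp, , drop = FALSE]
    onset <- d$onset_day[!is.na(d$onset_day)]
    data.frame(infection_type = tp, n = nrow(d),
               pct = 100 * nrow(d) / nrow(inf),
               onset_mean = if (length(onset)) mean(onset) else NA_real_,
               onset_sd = if (length(onset) > 1L) stats::sd(onset)
                          else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Reconstruct case-level review data from published band summaries
#'
#' Expands a per-band summary (cohort count, number reviewed, true
#' infections per predicted-probability band — the form in which validation
#' studies print their review results) into case-level `scores` and
#' `labels` suitable for [confusion_metrics()] and [band_table()]. Each
#' case in a band is assigned the band's midpoint probability; reviewed
#' infections, reviewed non-infections and unreviewed cases are emitted in
#' that order with sequential ids.
#'
#' @param bands Data frame with columns `lo`, `hi` (band edges on the
#'   probability scale), `cohort_n`, `reviewed_n`, `infections_n`.
#' @param id_prefix Prefix for generated procedure ids.
#' @return List with `scores` (procedure_id, probability) and `labels`
#'   (procedure_id, reviewed, infection).
#' @export
review_counts_to_cases <- function(bands, id_prefix = "case") {
  stopifnot(all(c("lo", "hi", "cohort_n", "reviewed_n", "infections_n") %in%
                  names(bands)),
            all(bands$reviewed_n <= bands$cohort_n),
            all(bands$infections_n <= bands$reviewed_n))
  scores <- list()
  labels <- list()
  k <- 0L
  for (i in seq_len(nrow(bands))) {
    b <- bands[i, ]
    ids <- sprintf("%s%06d", id_prefix, k + seq_len(b$cohort_n))
    k <- k + b$cohort_n
    p <- rep((b$lo + b$hi) / 2, b$cohort_n)
    reviewed <- seq_len(b$cohort_n) <= b$reviewed_n
    infected <- seq_len(b$cohort_n) <= b$infections_n
    scores[[i]] <- data.frame(procedure_id = ids, probability = p,
                              stringsAsFactors = FALSE)
    labels[[i]] <- data.frame(procedure_id = ids, reviewed = reviewed,
                              infection = infected & reviewed,
                              stringsAsFactors = FALSE)
  }
  list(scores = do.call(rbind, scores), labels = do.call(rbind, labels))
}
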