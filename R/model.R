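#' Covariates of the triage model
#'
#' The final infection-flagging model's covariate set: 90-day mortality,
#' congestive heart failure, solid tumor without metastasis, the CIED and
#' SSI diagnosis-code flags, the antibiotic course class (entering as two
#' indicators against reference `none`), a cardiac microbiology specimen
#' with positive susceptibility-tested culture, and the two clinical-note
#' keyword flags (postprocedure infection documentation as a positive
#' predictor, preprocedure history as a negative one).
#'
#' @return Character vector of `flag_table` column names.
#' @export
triage_covariates <- function() {
  c("died_90d", "congestive_heart_failure", "solid_tumor_without_metastasis",
    "icd_cied_infection", "icd_ssi", "antibiotic_class", "micro_cardiac_pos",
    "note_infection_post", "note_infection_pre")
}

# expand a flag table into the numeric design matrix (no intercept column);
# antibiotic_class becomes two indicators against reference "none"
triage_design <- function(flags, covariates) {
  missing <- setdiff(covariates, names(flags))
  if (length(missing)) {
    stop("flag vector is missing covariate(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cols <- list()
  for (cv in covariates) {
    if (cv == "antibiotic_class") {
      cols[["abx_staph_directed"]] <-
        as.numeric(flags$antibiotic_class == "staph_directed")
      cols[["abx_non_staph"]] <-
        as.numeric(flags$antibiotic_class == "non_staph")
    } else {
      cols[[cv]] <- as.numeric(flags[[cv]])
    }
  }
  if (!length(cols)) return(matrix(numeric(0), nrow = nrow(flags), ncol = 0))
  do.call(cbind, cols)
}

#' Fit the logistic triage model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via `stats::glm`) of reviewed infection labels on the flag
#' covariates, with optional Firth bias-reduction for the near-separated
#' sparse-flag case. Reports odds ratios with Wald 95% CIs and the model
#' C-statistic (concordance of fitted probabilities, identical to the AUC).
#'
#' @param flags A `flag_table` (or data frame with the covariate columns).
#' @param labels Logical vector (or data frame with `procedure_id` and
#'   `infection`, matched to `flags$procedure_id`).
#' @param covariates Covariate names, default [triage_covariates()].
#' @param firth Use Firth-penalized likelihood instead of plain ML.
#' @param threshold Review threshold stored with the model (default 0.10:
#'   in development most true infections occur at predicted probability
#'   10% or more, and the threshold keeps the review workload near 3% of
#'   procedures).
#' @param max_iter,tol IRLS iteration cap (100) and log-likelihood
#'   convergence tolerance (1e-8).
#' @return Object of class `triage_model`: `coefficients` (named, incl.
#'   `(Intercept)`), `vcov`, `covariates`, `threshold`, `or_table` (OR +
#'   Wald 95% CI), and `diagnostics` (`converged`, `iterations`, `logLik`,
#'   `c_statistic`, `n`, `n_events`, `firth`).
#' @export
triage_fit <- function(flags, labels, covariates = triage_covariates(),
                       firth = FALSE, threshold = 0.10, max_iter = 100L,
                       tol = 1e-8) {
  if (is.data.frame(labels)) {
    idx <- match(flags$procedure_id, labels$procedure_id)
    if (anyNA(idx)) stop("labels missing for some procedures", call. = FALSE)
    y <- as.numeric(labels$infection[idx])
  } else {
    y <- as.numeric(labels)
  }
  if (length(y) != nrow(flags)) stop("labels length mismatch", call. = FALSE)
  if (sum(y) < 1 || sum(1 - y) < 1) {
    stop("need at least one positive and one negative label", call. = FALSE)
  }
  X <- triage_design(flags, covariates)
  if (firth) {
    fit <- firth_logistic(X, y, max_iter = max_iter, tol = tol)
  } else {
    df <- as.data.frame(X)
    df$.y <- y
    wrn <- NULL
    g <- withCallingHandlers(
      stats::glm(.y ~ ., data = df, family = stats::binomial(),
                 control = stats::glm.control(epsilon = tol,
                                              maxit = max_iter)),
      warning = function(w) {
        wrn <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      })
    if (!g$converged) {
      stop(sprintf("logistic fit did not converge in %d IRLS iterations (deviance %.6g)",
                   g$iter, g$deviance), call. = FALSE)
    }
    co <- stats::coef(g)
    if (!is.null(wrn) && grepl("0 or 1", wrn) || any(abs(co[-1]) > 10)) {
      suspect <- names(co)[-1][abs(co[-1]) > 10]
      if (length(suspect)) {
        warning("possible complete/quasi-separation; suspect covariate(s): ",
                paste(suspect, collapse = ", "),
                " (consider firth = TRUE)", call. = FALSE)
      }
    }
    fit <- list(coefficients = co, vcov = stats::vcov(g),
                logLik = as.numeric(stats::logLik(g)), iterations = g$iter,
                converged = g$converged,
                fitted = as.numeric(stats::fitted(g)))
  }
  cstat <- roc_auc(fit$fitted, y == 1)$auc
  est <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  or_table <- data.frame(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    or = exp(unname(est)),
    or_lo = exp(unname(est - 1.96 * se)),
    or_hi = exp(unname(est + 1.96 * se)),
    stringsAsFactors = FALSE
  )
  structure(list(
    coefficients = est, vcov = fit$vcov, covariates = covariates,
    threshold = threshold, or_table = or_table,
    diagnostics = list(converged = fit$converged,
                       iterations = fit$iterations, logLik = fit$logLik,
                       c_statistic = cstat, n = length(y),
                       n_events = sum(y), firth = firth)
  ), class = "triage_model")
}

# Firth-penalized logistic regression: Fisher scoring on the modified score
# U*(b) = X'(y - p + h (1/2 - p)), h = hat diagonal. Penalizes the
# likelihood by |I(b)|^{1/2}, keeping estimates finite under separation.
firth_logistic <- function(X, y, max_iter = 100L, tol = 1e-8) {
  Xd <- cbind(`(Intercept)` = 1, X)
  p_dim <- ncol(Xd)
  b <- rep(0, p_dim)
  ll_pen <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% b)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    XtWX <- crossprod(Xd * W, Xd)
    XtWX_inv <- solve(XtWX)
    h <- rowSums((Xd %*% XtWX_inv) * Xd) * W
    U <- drop(crossprod(Xd, y - p + h * (0.5 - p)))
    step <- drop(XtWX_inv %*% U)
    b_new <- b + step
    eta_new <- drop(Xd %*% b_new)
    p_new <- stats::plogis(eta_new)
    ll_new <- sum(y * log(p_new) + (1 - y) * log1p(-p_new)) +
      0.5 * determinant(crossprod(Xd * (p_new * (1 - p_new)), Xd),
                        logarithm = TRUE)$modulus
    if (abs(ll_new - ll_pen) < tol) {
      b <- b_new
      ll_pen <- ll_new
      converged <- TRUE
      break
    }
    b <- b_new
    ll_pen <- ll_new
  }
  if (!converged) {
    stop(sprintf("Firth fit did not converge in %d iterations (penalized logLik %.6g)",
                 max_iter, ll_pen), call. = FALSE)
  }
  eta <- drop(Xd %*% b)
  p <- stats::plogis(eta)
  names(b) <- colnames(Xd)
  vc <- solve(crossprod(Xd * (p * (1 - p)), Xd))
  dimnames(vc) <- list(names(b), names(b))
  list(coefficients = b, vcov = vc,
       logLik = sum(y * log(p) + (1 - y) * log1p(-p)), iterations = it,
       converged = TRUE, fitted = p)
}

#' @export
print.triage_model <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<triage_model> n=%d (events=%d), %s, C=%.3f, threshold=%.2f\n",
              d$n, d$n_events,
              if (d$firth) "Firth-penalized" else "maximum likelihood",
              d$c_statistic, x$threshold))
  ot <- x$or_table
  ot$or <- sprintf("%.2f (%.2f-%.2f)", ot$or, ot$or_lo, ot$or_hi)
  print(ot[c("term", "estimate", "or")], row.names = FALSE)
  invisible(x)
}

#' Predict infection probability from flag vectors
#'
#' Inverse-logit of the linear predictor under the model's coefficients;
#' deterministic. A covariate missing from the flag table is an error
#' naming the covariate.
#'
#' @param model A `triage_model` (fitted, or loaded via [read_model()]).
#' @param flags A `flag_table` or compatible data frame.
#' @return Data frame of class `triage_scores`: `procedure_id`,
#'   `probability`, `above_threshold` (probability >= model threshold; the
#'   threshold comparison is `>=` so band edges and the review cutoff
#'   agree).
#' @export
triage_predict <- function(model, flags) {
  stopifnot(inherits(model, "triage_model"))
  X <- triage_design(flags, model$covariates)
  terms <- setdiff(names(model$coefficients), "(Intercept)")
  missing <- setdiff(terms, colnames(X))
  if (length(missing)) {
    stop("flag vector is missing covariate(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lp <- model$coefficients[["(Intercept)"]] +
    drop(X[, terms, drop = FALSE] %*% model$coefficients[terms])
  out <- data.frame(
    procedure_id = if ("procedure_id" %in% names(flags)) flags$procedure_id
                   else as.character(seq_len(nrow(flags))),
    probability = stats::plogis(lp),
    stringsAsFactors = FALSE
  )
  out$above_threshold <- out$probability >= model$threshold
  class(out) <- c("triage_scores", "data.frame")
  out
}

#' Sample the manual-review queue
#'
#' Seeded simple random sampling without replacement within the two
#' threshold strata: a fraction of above-threshold cases (default 80%) and
#' a fraction of below-threshold cases (default 1%, a leakage check that
#' the algorithm is not missing true infections). Sample sizes are
#' `round(fraction * stratum size)`; queue membership is reproducible given
#' the seed and does not disturb the caller's RNG state.
#'
#' @param scores A `triage_scores` data frame (or any frame with
#'   `procedure_id` and `probability`).
#' @param threshold Review threshold (default 0.10, `>=`).
#' @param above_fraction,below_fraction Sampling fractions in `[0, 1]`.
#' @param seed Integer seed.
#' @return `scores` with columns `above_threshold` and
#'   `selected_for_review`.
#' @export
triage_queue <- function(scores, threshold = 0.10, above_fraction = 0.8,
                         below_fraction = 0.01, seed = 1L) {
  stopifnot(above_fraction >= 0, above_fraction <= 1,
            below_fraction >= 0, below_fraction <= 1)
  scores$above_threshold <- scores$probability >= threshold
  n <- nrow(scores)
  selected <- logical(n)
  with_seed(seed, {
    for (stratum in c(TRUE, FALSE)) {
      idx <- which(scores$above_threshold == stratum)
      frac <- if (stratum) above_fraction else below_fraction
      k <- round(frac * length(idx))
      if (k > 0) selected[sample(idx, k)] <- TRUE
    }
  })
  scores$selected_for_review <- selected
  scores
}

#' Write / read a triage model as JSON
#'
#' Serializes covariate names, coefficients, threshold and fit diagnostics
#' so a model fitted on one cohort can be applied out-of-sample as fixed
#' coefficients.
#'
#' @param model A `triage_model`.
#' @param path JSON file path.
#' @return `write_model`: `path`, invisibly. `read_model`: a
#'   `triage_model` (without `vcov`/`or_table` if absent from the file).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "triage_model"))
  obj <- list(covariates = model$covariates,
              coefficients = as.list(model$coefficients),
              threshold = model$threshold,
              diagnostics = model$diagnostics,
              vcov = model$vcov)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- unlist(obj$coefficients)
  vc <- obj$vcov
  if (!is.null(vc)) {
    vc <- matrix(unlist(vc), nrow = length(co),
                 dimnames = list(names(co), names(co)))
  }
  structure(list(coefficients = co, vcov = vc,
                 covariates = unlist(obj$covariates),
                 threshold = obj$threshold,
                 diagnostics = obj$diagnostics),
            class = "triage_model")
}
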