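# FRET ratio computation, rank tests, AUC comparisons, on-bead
# quantification, dose-response fitting and the model-falsification
# verdicts.

#' Compute per-well emission ratios
#'
#' Divides each Em480 intensity by its matching Em535 intensity,
#' preserving condition/replicate/ladder labels. Rows with nonpositive
#' intensities are dropped with a warning (they cannot arise from the
#' simulator, but parsed files may contain them).
#'
#' @param dataset a `camnet_plate` data.frame (simulated or read from
#'   CSV) with columns `condition`, `replicate`, `ca_free_uM`, `em480`,
#'   `em535`.
#' @return A data.frame of class `camnet_ratios` with columns
#'   `condition`, `replicate`, `ca_free_uM`, `ratio`.
#' @export
compute_ratios <- function(dataset) {
  need <- c("condition", "replicate", "ca_free_uM", "em480", "em535")
  if (!all(need %in% names(dataset)))
    stop("dataset must have columns: ", paste(need, collapse = ", "))
  bad <- !(dataset$em480 > 0 & dataset$em535 > 0)
  if (any(bad)) {
    warning(sum(bad), " record(s) with nonpositive intensity dropped")
    dataset <- dataset[!bad, , drop = FALSE]
  }
  out <- data.frame(condition = dataset$condition,
                    replicate = dataset$replicate,
                    ca_free_uM = dataset$ca_free_uM,
                    ratio = dataset$em480 / dataset$em535,
                    stringsAsFactors = FALSE)
  class(out) <- c("camnet_ratios", "data.frame")
  out
}

#' One-tailed Mann-Whitney U test
#'
#' Wraps [stats::wilcox.test()] (exact null distribution for small
#' samples without ties; normal approximation with continuity and tie
#' correction otherwise) and reports the U statistic of the first
#' sample.
#'
#' @param sample,baseline numeric vectors (nonempty).
#' @param direction `"greater"` tests whether `sample` is
#'   stochastically greater than `baseline`.
#' @return An object of class `camnet_test`: list with `statistic` (U),
#'   `p_value`, `n1`, `n2`, `direction`.
#' @examples
#' mann_whitney(c(3, 4), c(1, 2))$p_value  # 1/6
#' @export
mann_whitney <- function(sample, baseline,
                         direction = c("greater", "less")) {
  if (length(sample) == 0 || length(baseline) == 0)
    stop("both samples must be nonempty")
  direction <- match.arg(direction)
  wt <- suppressWarnings(
    stats::wilcox.test(sample, baseline, alternative = direction,
                       exact = NULL, correct = TRUE)
  )
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n1 = length(sample), n2 = length(baseline),
                 direction = direction),
            class = "camnet_test")
}

#' @export
print.camnet_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), one-tailed (%s) p = %.4g\n",
              x$statistic, x$n1, x$n2, x$direction, x$p_value))
  invisible(x)
}

#' Trapezoidal area under a curve
#'
#' Trapezoid-rule integral of y over the points with
#' `lo <= x <= hi`.
#'
#' @param x sorted abscissa values.
#' @param y ordinates, same length.
#' @param range `c(lo, hi)`; defaults to the full span of `x`.
#' @return The integral (scalar).
#' @examples
#' auc_trapezoid(c(0, 1, 2), c(0, 1, 0))  # 1
#' @export
auc_trapezoid <- function(x, y, range = NULL) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (is.unsorted(x)) stop("x must be sorted increasing")
  if (!is.null(range)) {
    if (range[1] < min(x) || range[2] > max(x))
      stop("range endpoints must lie within the span of x")
    keep <- x >= range[1] & x <= range[2]
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 2) stop("need at least 2 points inside range")
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

#' Per-replicate areas under the binding curve
#'
#' Computes the trapezoidal AUC of the emission ratio over a Ca2+ range
#' separately for every (condition, replicate) series, for comparing
#' whole curves between a CaM condition and baseline.
#'
#' @param ratios a `camnet_ratios` data.frame.
#' @param range `c(lo, hi)` in uM; default full ladder span.
#' @return A data.frame with columns `condition`, `replicate`, `auc`.
#' @export
replicate_auc <- function(ratios, range = NULL) {
  stopifnot(inherits(ratios, "data.frame"))
  sp <- split(ratios, list(ratios$condition, ratios$replicate), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$ca_free_uM), ]
    data.frame(condition = d$condition[1], replicate = d$replicate[1],
               auc = auc_trapezoid(d$ca_free_uM, d$ratio, range),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Percent binding from on-bead band intensities
#'
#' Background-subtracted bound over (bound + unbound), as a percentage,
#' clipped to `[0, 100]`. Undefined (NA, with a warning) when the total
#' background-corrected signal is nonpositive.
#'
#' @param bound,unbound band intensities (vectorized).
#' @param background gel background intensity.
#' @return Percent bound in `[0, 100]`, NA where undefined.
#' @examples
#' onbead_percent_binding(500, 500, 0)  # 50
#' @export
onbead_percent_binding <- function(bound, unbound, background = 0) {
  if (any(bound < 0) || any(unbound < 0) || any(background < 0))
    stop("intensities must be >= 0")
  b <- bound - background
  u <- unbound - background
  tot <- b + u
  bad <- tot <= 0
  if (any(bad)) warning(sum(bad),
    " record(s) with nonpositive corrected total signal; returned NA")
  out <- ifelse(bad, NA_real_, 100 * b / tot)
  pmin(pmax(out, 0), 100)
}

#' Normalize an on-bead percent-binding series to its 0/39 uM endpoints
#'
#' Affine rescale so that the value at 0 uM free Ca2+ maps to 0% and
#' the value at 39 uM maps to 100%.
#'
#' @param percent percent-binding values.
#' @param ca_free matching free Ca2+ values; must contain 0 and 39.
#' @return Rescaled values, same order as input.
#' @examples
#' normalize_onbead(c(10, 35, 60), c(0, 3, 39))  # 0 50 100
#' @export
normalize_onbead <- function(percent, ca_free) {
  if (length(percent) != length(ca_free)) stop("lengths differ")
  i0 <- which(ca_free == 0); i39 <- which(ca_free == 39)
  if (length(i0) == 0 || length(i39) == 0)
    stop("series must contain entries at 0 and 39 uM")
  v0 <- mean(percent[i0]); v39 <- mean(percent[i39])
  if (v39 == v0) {
    warning("degenerate series: value(39) == value(0); returning NA")
    return(rep(NA_real_, length(percent)))
  }
  100 * (percent - v0) / (v39 - v0)
}

#' Fit a four-parameter Hill (log-logistic) dose-response curve
#'
#' Least-squares fit of
#' `r(x) = bottom + (top - bottom) * x^n / (EC50^n + x^n)` on linear x
#' (x = 0 is admissible), via Levenberg-Marquardt. A flat series is
#' flagged as unidentifiable without fitting.
#'
#' @param ca_free dose values, uM (>= 5 distinct values required).
#' @param response measured values (e.g. mean emission ratio per dose).
#' @return An object of class `camnet_drfit` with fields `coefficients`
#'   (`bottom`, `top`, `ec50`, `hill`), `residuals`, `residual_norm`,
#'   `converged`, `flagged` (and `flag_reason` when flagged), `data`.
#'   Methods: `coef`, `predict`, `residuals`, `print`.
#' @examples
#' x <- c(0, 0.1, 0.3, 1, 3, 10, 39)
#' y <- 0.5 + 0.5 * x^2 / (0.4^2 + x^2)
#' coef(fit_dose_response(x, y))
#' @export
fit_dose_response <- function(ca_free, response) {
  if (length(ca_free) != length(response)) stop("lengths differ")
  if (length(unique(ca_free)) < 5)
    stop("need at least 5 distinct dose values")
  d <- data.frame(x = ca_free, y = response)
  out <- list(data = d, converged = FALSE, flagged = FALSE)
  class(out) <- "camnet_drfit"
  if (stats::sd(response) <= 1e-12 * max(abs(response), 1)) {
    out$flagged <- TRUE
    out$flag_reason <- "flat series: EC50 unidentifiable"
    out$coefficients <- c(bottom = mean(response), top = mean(response),
                          ec50 = NA_real_, hill = NA_real_)
    out$residuals <- response - mean(response)
    out$residual_norm <- sqrt(sum(out$residuals^2))
    return(out)
  }
  xpos <- d$x[d$x > 0]
  half <- (min(response) + max(response)) / 2
  ec50_0 <- d$x[which.min(abs(response - half))]
  if (!is.finite(ec50_0) || ec50_0 <= 0) ec50_0 <- stats::median(xpos)
  fit <- try(minpack.lm::nlsLM(
    y ~ bottom + (top - bottom) * ifelse(x == 0, 0, x^hill / (ec50^hill + x^hill)),
    data = d,
    start = list(bottom = min(response), top = max(response),
                 ec50 = ec50_0, hill = 1),
    lower = c(-Inf, -Inf, 1e-9, 1e-3), upper = c(Inf, Inf, Inf, 20),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    out$flagged <- TRUE
    out$flag_reason <- paste("fit did not converge:",
                             attr(fit, "condition")$message)
    out$coefficients <- c(bottom = NA_real_, top = NA_real_,
                          ec50 = NA_real_, hill = NA_real_)
    out$residuals <- rep(NA_real_, nrow(d))
    out$residual_norm <- NA_real_
    return(out)
  }
  cf <- stats::coef(fit)
  out$converged <- TRUE
  out$coefficients <- c(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
                        ec50 = unname(cf["ec50"]), hill = unname(cf["hill"]))
  out$residuals <- stats::residuals(fit)
  out$residual_norm <- sqrt(sum(out$residuals^2))
  out$fit <- fit
  out
}

#' @export
coef.camnet_drfit <- function(object, ...) object$coefficients

#' @export
residuals.camnet_drfit <- function(object, ...) object$residuals

#' @export
predict.camnet_drfit <- function(object, ca_free = NULL, ...) {
  if (is.null(ca_free)) ca_free <- object$data$x
  cf <- object$coefficients
  ifelse(ca_free == 0, cf["bottom"],
         cf["bottom"] + (cf["top"] - cf["bottom"]) *
           ca_free^cf["hill"] / (cf["ec50"]^cf["hill"] + ca_free^cf["hill"]))
}

#' @export
print.camnet_drfit <- function(x, ...) {
  if (x$flagged) {
    cat("Dose-response fit FLAGGED:", x$flag_reason, "\n")
  } else {
    cf <- x$coefficients
    cat(sprintf("Hill dose-response fit: bottom = %.4g, top = %.4g, EC50 = %.4g uM, hill = %.3g\n",
                cf["bottom"], cf["top"], cf["ec50"], cf["hill"]))
    cat(sprintf("  residual norm %.4g, converged: %s\n", x$residual_norm,
                x$converged))
  }
  invisible(x)
}

#' Observed binding/no-binding calls from a ratio dataset
#'
#' Applies the two-statistic decision rule per (CaM condition, regime):
#' a one-tailed Mann-Whitney U test of the regime's endpoint ratios
#' against the reporter-only baseline, and a second U test of the
#' per-replicate trapezoidal AUCs over the regime's Ca2+ range
#' (`[0, 0.038]` uM for the zero-Ca regime, the full ladder for the
#' high-Ca regime). The call is `"B"` only when both tests are
#' significant at `alpha`.
#'
#' @param ratios a `camnet_ratios` data.frame including a `"baseline"`
#'   condition.
#' @param alpha significance threshold (default 0.05).
#' @param low_range Ca2+ range (uM) for the zero-Ca AUC test.
#' @param baseline name of the reporter-only condition.
#' @return A data.frame with columns `mutant`, `regime`, `call`,
#'   `p_endpoint`, `p_auc`.
#' @export
observed_calls <- function(ratios, alpha = 0.05, low_range = c(0, 0.038),
                           baseline = "baseline") {
  stopifnot(inherits(ratios, "data.frame"))
  if (!baseline %in% ratios$condition)
    stop("no '", baseline, "' condition in dataset")
  conds <- setdiff(unique(ratios$condition), baseline)
  xmax <- max(ratios$ca_free_uM)
  full_range <- c(min(ratios$ca_free_uM), xmax)
  auc_low <- replicate_auc(ratios, low_range)
  auc_full <- replicate_auc(ratios, full_range)
  base_end0 <- ratios$ratio[ratios$condition == baseline &
                            ratios$ca_free_uM == 0]
  base_endH <- ratios$ratio[ratios$condition == baseline &
                            ratios$ca_free_uM == xmax]
  rows <- lapply(conds, function(cond) {
    do.call(rbind, lapply(c("zero_ca", "high_ca"), function(reg) {
      if (reg == "zero_ca") {
        endpt <- ratios$ratio[ratios$condition == cond & ratios$ca_free_uM == 0]
        p1 <- mann_whitney(endpt, base_end0)$p_value
        p2 <- mann_whitney(auc_low$auc[auc_low$condition == cond],
                           auc_low$auc[auc_low$condition == baseline])$p_value
      } else {
        endpt <- ratios$ratio[ratios$condition == cond &
                              ratios$ca_free_uM == xmax]
        p1 <- mann_whitney(endpt, base_endH)$p_value
        p2 <- mann_whitney(auc_full$auc[auc_full$condition == cond],
                           auc_full$auc[auc_full$condition == baseline])$p_value
      }
      data.frame(mutant = cond, regime = reg,
                 call = if (p1 < alpha && p2 < alpha) "B" else "NB",
                 p_endpoint = p1, p_auc = p2, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score models against observed binding calls
#'
#' A model's prediction for a (mutant, regime) condition is falsified
#' when it predicts `"B"` and `"NB"` was observed, or vice versa.
#' Falsifications are counted two ways: per condition (table row), and
#' as distinct structural claims — falsified conditions grouped by
#' (regime, predicted call), since e.g. a mechanism's prediction of
#' apo-state binding at zero Ca2+ is one claim however many CaM
#' variants it is tested on.
#'
#' @param observed data.frame with columns `mutant`, `regime`, `call`
#'   (from [observed_calls()] or entered by hand).
#' @param prediction_table a `camnet_predictions` from
#'   [predict_table()] over the same (mutant, regime) index set.
#' @return An object of class `camnet_report`: list with `calls` (merged
#'   per-condition table with one logical `falsified_*` column per
#'   model) and `summary` (per model: `n_conditions`, `n_correct`,
#'   `n_falsified_conditions`, `n_falsified` distinct claims,
#'   `unfalsified`).
#' @examples
#' obs <- data.frame(
#'   mutant = rep(c("WT", "N", "C"), 2),
#'   regime = rep(c("zero_ca", "high_ca"), each = 3),
#'   call = c("NB", "NB", "NB", "B", "B", "NB"))
#' classify_models(obs, predict_table())$summary
#' @export
classify_models <- function(observed, prediction_table) {
  need <- c("mutant", "regime", "call")
  if (!all(need %in% names(observed)))
    stop("observed must have columns mutant, regime, call")
  pred <- as.data.frame(prediction_table)
  models <- sort(unique(pred$model))
  key_obs <- paste(observed$mutant, observed$regime)
  key_pred <- unique(paste(pred$mutant, pred$regime))
  if (!setequal(key_obs, key_pred))
    stop("observed and predicted (mutant, regime) sets differ")
  calls <- observed[, need]
  summ <- do.call(rbind, lapply(models, function(m) {
    pm <- pred[pred$model == m, ]
    idx <- match(key_obs, paste(pm$mutant, pm$regime))
    predicted <- pm$call[idx]
    fals <- predicted != observed$call
    calls[[paste0("model", m, "_pred")]] <<- predicted
    calls[[paste0("model", m, "_falsified")]] <<- fals
    n_claims <- length(unique(paste(observed$regime, predicted)[fals]))
    data.frame(model = m, n_conditions = length(fals),
               n_correct = sum(!fals),
               n_falsified_conditions = sum(fals),
               n_falsified = n_claims,
               unfalsified = !any(fals))
  }))
  rownames(summ) <- NULL
  structure(list(calls = calls, summary = summ), class = "camnet_report")
}

#' @export
print.camnet_report <- function(x, ...) {
  cat("Model discrimination report\n")
  print(x$calls, row.names = FALSE)
  cat("\nPer-model summary (n_falsified counts distinct falsified claims):\n")
  print(x$summary, row.names = FALSE)
  un <- x$summary$model[x$summary$unfalsified]
  if (length(un) == 1)
    cat(sprintf("\nModel %d is the unique unfalsified model.\n", un))
  else if (length(un) == 0) cat("\nAll models falsified.\n")
  else cat("\nUnfalsified models:", paste(un, collapse = ", "), "\n")
  invisible(x)
}
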