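#' Qualitative binding/no-binding prediction table
#'
#' For each (mutant, regime) condition and each mechanism, computes the
#' limiting binding fraction and classifies it as `"B"` (binding) or
#' `"NB"` (no binding). The call is structural: `"NB"` exactly when the
#' limit is a structural zero — a fraction that vanishes because the
#' network truncation removes every MLCK-competent state, independent of
#' parameter values. Quantitative sub-threshold predictions (small but
#' non-zero fractions) remain `"B"`; see [detection_call()] for the
#' "would the assay see it" annotation.
#'
#' @param params a [camnet_params()] object.
#' @param models integer vector of mechanisms to tabulate.
#' @param mutants character vector of CaM mutant codes.
#' @param conc a [concentrations()] object.
#' @return A data.frame of class `camnet_predictions`, one row per
#'   (mutant, regime, model), with columns `mutant`, `regime`
#'   (`"zero_ca"` or `"high_ca"`), `model`, `fraction`, `call`.
#' @examples
#' tab <- predict_table(camnet_params(), conc = concentrations(0.713, 0.0237))
#' subset(tab, regime == "zero_ca" & model == 1)  # all B via K9
#' @export
predict_table <- function(params = camnet_params(), models = 1:3,
                          mutants = c("WT", "N", "C"),
                          conc = concentrations(0.713, 0.0237)) {
  if (length(models) == 0 || length(mutants) == 0)
    stop("models and mutants must be nonempty")
  grid <- expand.grid(model = models, mutant = mutants,
                      regime = c("zero_ca", "high_ca"),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  frac <- mapply(function(m, mu, reg) {
    limit_binding(params, model_variant(m, mu), conc,
                  end = if (reg == "zero_ca") "low" else "high")
  }, grid$model, grid$mutant, grid$regime)
  out <- data.frame(mutant = grid$mutant, regime = grid$regime,
                    model = grid$model, fraction = frac,
                    call = ifelse(frac == 0, "NB", "B"),
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$regime, c("zero_ca", "high_ca")),
                   match(out$mutant, mutants), out$model), ]
  rownames(out) <- NULL
  class(out) <- c("camnet_predictions", "data.frame")
  out
}

#' @export
print.camnet_predictions <- function(x, ...) {
  cat("Predicted binding calls (B = binding, NB = structural zero)\n")
  wide <- stats::reshape(as.data.frame(x)[, c("mutant", "regime", "model", "call")],
                         idvar = c("regime", "mutant"), timevar = "model",
                         direction = "wide")
  names(wide) <- sub("^call\\.", "model ", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Detection-limited binding call
#'
#' Annotates a predicted fraction with whether it exceeds the measured
#' assay sensitivity (default 9% of MLCK bound, the smallest increase
#' the FRET assay was shown to detect). This is a quantitative
#' annotation only; it never overrides the structural B/NB logic of
#' [predict_table()].
#'
#' @param predicted_fraction numeric in `[0, 1]` (vectorized).
#' @param detection_limit assay sensitivity as a fraction, in `[0, 1]`.
#' @return Character vector, `"B"` where the fraction exceeds the limit,
#'   else `"NB"`.
#' @examples
#' detection_call(c(0.92, 0.052), 0.09)  # "B" "NB"
#' @export
detection_call <- function(predicted_fraction, detection_limit = 0.09) {
  if (detection_limit < 0 || detection_limit > 1)
    stop("detection_limit must be in [0, 1]")
  ifelse(predicted_fraction > detection_limit, "B", "NB")
}

#' Write a prediction table to CSV
#'
#' B/NB calls and numeric fractions side by side.
#' @param table a `camnet_predictions` from [predict_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(table, path) {
  stopifnot(inherits(table, "camnet_predictions"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
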