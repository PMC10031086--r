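#' Construct a Ca2+/CaM/MLCK equilibrium binding model
#'
#' The central model object of the package: a mechanism (Model 1, 2 or
#' 3), a CaM mutant, a thermodynamically consistent parameter set and
#' total concentrations. Free Ca2+ is the clamped independent variable.
#' Methods: [predict.camnet_model()] evaluates the titration curve,
#' [simulate.camnet_model()] draws synthetic plate-reader FRET data,
#' `plot()` draws the curve, `coef()` returns the constants.
#'
#' @param model 1, 2 or 3, or a [model_variant()].
#' @param mutant CaM mutant code (see [model_variant()]).
#' @param params a [camnet_params()] object.
#' @param cam_tot,mlck_tot total CaM and MLCK (or FRET reporter), uM.
#'   Defaults are the main-experiment concentrations (0.713 and
#'   0.0237 uM, a 30-fold CaM excess).
#' @return An object of class `camnet_model`.
#' @examples
#' m <- cam_mlck_model(2, "WT")
#' predict(m, ca_free = c(0, 39))
#' @export
cam_mlck_model <- function(model, mutant = "WT", params = camnet_params(),
                           cam_tot = 0.713, mlck_tot = 0.0237) {
  v <- as_variant(model, mutant)
  stopifnot(inherits(params, "camnet_params"))
  conc <- concentrations(cam_tot, mlck_tot)
  obj <- structure(
    list(variant = v, params = params, conc = conc),
    class = "camnet_model"
  )
  # degenerate variants (no MLCK-competent state at any x) are flagged,
  # not errors: their curve is a structural zero everywhere
  obj$structural_zero_curve <-
    limit_binding(params, v, conc, "low") == 0 &&
    limit_binding(params, v, conc, "high") == 0 &&
    effective_affinity(params, v, 1) == 0
  obj
}

#' @export
print.camnet_model <- function(x, ...) {
  print(x$variant)
  cat(sprintf("  [CaM]_tot = %g uM, [MLCK]_tot = %g uM\n",
              x$conc$cam_tot, x$conc$mlck_tot))
  lo <- limit_binding(x$params, x$variant, x$conc, "low")
  hi <- limit_binding(x$params, x$variant, x$conc, "high")
  cat(sprintf("  fraction MLCK bound: %.4f at zero Ca2+, %.4f at saturating Ca2+\n",
              lo, hi))
  if (x$structural_zero_curve)
    cat("  (structural zero: no MLCK-competent state at any free Ca2+)\n")
  invisible(x)
}

#' @export
coef.camnet_model <- function(object, ...) {
  p <- object$params
  c(K9 = unname(p$k_mlck["apo"]), K4 = unname(p$k_mlck["C"]),
    K2 = unname(p$k_mlck["NC"]), K_M_N = unname(p$k_mlck["N"]),
    ca_assoc_N = p$ca_assoc_N, ca_assoc_C = p$ca_assoc_C,
    hill_exp = p$hill_exp,
    cam_tot = object$conc$cam_tot, mlck_tot = object$conc$mlck_tot)
}

#' Predict fraction of MLCK bound at given free Ca2+
#'
#' @param object a [cam_mlck_model()].
#' @param ca_free vector of clamped free Ca2+ values, uM.
#' @param ... unused.
#' @return Numeric vector of fractions bound, one per `ca_free`.
#' @export
predict.camnet_model <- function(object, ca_free = default_ladder(), ...) {
  k <- effective_affinity(object$params, object$variant, ca_free)
  fraction_bound(k, object$conc$cam_tot, object$conc$mlck_tot)
}

#' Titration curve: fraction of MLCK bound versus free Ca2+
#'
#' Evaluates [fraction_bound()] at [effective_affinity()] pointwise over
#' a Ca2+ grid. The endpoints converge to the [limit_binding()] values
#' as x -> 0 and x -> large.
#'
#' @param model a [cam_mlck_model()].
#' @param ca_grid nonempty, nonnegative, sorted Ca2+ grid, uM.
#' @return A data.frame of class `camnet_curve` with columns
#'   `ca_free_uM`, `fraction_bound`, `model`, `mutant`, carrying the
#'   model as attribute `"model"`.
#' @examples
#' titration_curve(cam_mlck_model(2, "WT"), default_ladder())
#' @export
titration_curve <- function(model, ca_grid = default_ladder()) {
  stopifnot(inherits(model, "camnet_model"))
  if (length(ca_grid) == 0 || any(!is.finite(ca_grid)) || any(ca_grid < 0))
    stop("ca_grid must be nonempty, finite and >= 0")
  if (is.unsorted(ca_grid, strictly = FALSE))
    stop("ca_grid must be sorted increasing")
  f <- predict(model, ca_grid)
  out <- data.frame(ca_free_uM = ca_grid, fraction_bound = f,
                    model = model$variant$model_id,
                    mutant = model$variant$mutant)
  class(out) <- c("camnet_curve", "data.frame")
  attr(out, "model") <- model
  out
}

#' @export
plot.camnet_model <- function(x, ca_grid = NULL, ...) {
  if (is.null(ca_grid))
    ca_grid <- c(0, exp(seq(log(1e-3), log(39), length.out = 100)))
  f <- predict(x, ca_grid)
  graphics::plot(ca_grid, f, type = "l", log = "", xlab = "free [Ca2+] (uM)",
                 ylab = "fraction MLCK bound", ylim = c(0, 1),
                 main = sprintf("Model %d, CaM %s", x$variant$model_id,
                                x$variant$mutant), ...)
  invisible(x)
}

#' Write a titration curve to CSV
#'
#' Columns: `ca_free_uM`, `fraction_bound`, `model`, `mutant`.
#' @param curve a `camnet_curve` from [titration_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "camnet_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
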