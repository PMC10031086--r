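# Robustness analyses: K9 concentration/parameter sweeps, the
# two-parameter Monte-Carlo for the N-lobe-mutant prediction, and the
# assay-sensitivity margin.

#' Zero-calcium binding fraction over a K9 x CaM grid
#'
#' The fraction of MLCK bound at zero free Ca2+ under Model 1 depends
#' only on K9 and the totals, and increases with both K9 and the
#' CaM:MLCK ratio. This sweep evaluates the closed form on a grid.
#'
#' @param k9_values apo-CaM MLCK association constants, uM^-1.
#' @param cam_values total CaM concentrations, uM.
#' @param mlck_tot total MLCK, uM.
#' @return A data.frame with columns `k9`, `cam_tot`, `fraction`.
#' @examples
#' k9_sweep(c(0.0078, 0.078), 35.65)  # ~0.218, ~0.735
#' @export
k9_sweep <- function(k9_values, cam_values, mlck_tot = 0.0237) {
  if (any(k9_values < 0) || any(cam_values < 0) || mlck_tot < 0)
    stop("inputs must be >= 0")
  grid <- expand.grid(k9 = k9_values, cam_tot = cam_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$fraction <- fraction_bound(grid$k9, grid$cam_tot, mlck_tot)
  grid
}

#' Monte-Carlo sensitivity of the N-lobe-mutant Model 2 prediction
#'
#' The Model 2 prediction of non-zero binding of the N-lobe-knockout
#' CaM at high Ca2+ depends on two parameters: K4 (MLCK association to
#' C-lobe-loaded CaM) and K6 (the C-lobe Ca2+ association weight).
#' Each draw multiplies both reference values by independent random
#' factors from `interval` (default spanning 0.01x to 100x) and
#' recomputes the fraction of MLCK bound at `ca_free` (39 uM, the
#' stated experimental condition, so K6 participates — the analytic
#' limit would not involve it).
#'
#' @param params reference [camnet_params()].
#' @param n_draws number of random parameter pairs.
#' @param interval multiplier range `c(lo, hi)` applied to each
#'   reference value.
#' @param law `"log-uniform"` (default: the interval spans four orders
#'   of magnitude around a scale parameter) or `"uniform"`.
#' @param ca_free free Ca2+ at which the fraction is evaluated, uM.
#' @param conc a [concentrations()] object.
#' @param seed integer; fixed seed gives an identical result.
#' @param keep_draws retain the per-draw parameter pairs and fractions.
#' @return An object of class `camnet_mc`: list with `n_draws`,
#'   `interval`, `law`, `seed`, `minimum`, `quantiles`, `histogram`
#'   (counts over 5%-wide bins), and optionally `draws`.
#' @examples
#' mc <- monte_carlo_f2n(n_draws = 1000, seed = 1)
#' mc$minimum
#' @export
monte_carlo_f2n <- function(params = camnet_params(), n_draws = 200000,
                            interval = c(0.01, 100),
                            law = c("log-uniform", "uniform"),
                            ca_free = 39,
                            conc = concentrations(0.713, 0.0237),
                            seed = NULL, keep_draws = FALSE) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  law <- match.arg(law)
  k4_ref <- params$k_mlck[["C"]]
  k6_ref <- params$ca_assoc_C
  draws <- with_local_seed(seed, {
    mult <- function(n) switch(law,
      "log-uniform" = exp(stats::runif(n, log(interval[1]), log(interval[2]))),
      "uniform" = stats::runif(n, interval[1], interval[2]))
    data.frame(k4 = k4_ref * mult(n_draws), k6 = k6_ref * mult(n_draws))
  })
  f <- f2n_at(draws$k4, draws$k6, params$hill_exp, ca_free,
              conc$cam_tot, conc$mlck_tot)
  qs <- stats::quantile(f, c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99))
  breaks <- seq(0, 1, by = 0.05)
  hist <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                     count = as.vector(table(cut(f, breaks,
                                                 include.lowest = TRUE))))
  out <- list(n_draws = n_draws, interval = interval, law = law,
              seed = seed, minimum = min(f), quantiles = qs,
              histogram = hist)
  if (keep_draws) {
    draws$fraction <- f
    out$draws <- draws
  }
  structure(out, class = "camnet_mc")
}

# vectorized Model 2 N-mutant fraction bound at clamped x for given
# (K4, K6): admissible Ca states are apo and C-occupied only
f2n_at <- function(k4, k6, hill_exp, ca_free, cam_tot, mlck_tot) {
  w_c <- k6 * ca_free^hill_exp
  k_eff <- k4 * w_c / (1 + w_c)
  fraction_bound(k_eff, cam_tot, mlck_tot)
}

#' Deterministic grid scan matching [monte_carlo_f2n()]
#'
#' Evaluates the N-lobe-mutant Model 2 fraction on a regular
#' (log-spaced) K4 x K6 multiplier grid over the same interval; serves
#' as the deterministic cross-check for the Monte-Carlo minimum.
#'
#' @inheritParams monte_carlo_f2n
#' @param n_grid points per axis.
#' @return List with `minimum` and the grid `data.frame` (`k4`, `k6`,
#'   `fraction`).
#' @export
grid_scan_f2n <- function(params = camnet_params(), n_grid = 100,
                          interval = c(0.01, 100), ca_free = 39,
                          conc = concentrations(0.713, 0.0237)) {
  mult <- exp(seq(log(interval[1]), log(interval[2]), length.out = n_grid))
  grid <- expand.grid(k4 = params$k_mlck[["C"]] * mult,
                      k6 = params$ca_assoc_C * mult, KEEP.OUT.ATTRS = FALSE)
  grid$fraction <- f2n_at(grid$k4, grid$k6, params$hill_exp, ca_free,
                          conc$cam_tot, conc$mlck_tot)
  list(minimum = min(grid$fraction), grid = grid)
}

#' @export
print.camnet_mc <- function(x, ...) {
  cat(sprintf("Monte-Carlo sensitivity: %d draws, %s law, multiplier interval [%g, %g]\n",
              x$n_draws, x$law, x$interval[1], x$interval[2]))
  cat(sprintf("  minimum fraction bound: %.4f\n", x$minimum))
  cat("  quantiles:\n")
  print(round(x$quantiles, 4))
  invisible(x)
}

#' Predicted binding margin between two CaM amounts
#'
#' Fraction of MLCK (FRET reporter) bound under Model 2 at a fixed free
#' Ca2+ for two total-CaM values, and their difference in percentage
#' points — the predicted signal increase used to establish the assay's
#' detection sensitivity.
#'
#' @param params a [camnet_params()].
#' @param mlck_tot total MLCK/reporter, uM (default 0.0229, the
#'   sensitivity experiment's reporter concentration).
#' @param cam_pair the two total-CaM values, uM (defaults 0.01145 and
#'   0.01374: reporter:CaM ratios of 2:1 and 2:1.2).
#' @param ca_free free Ca2+, uM.
#' @return List with `f1`, `f2` (fractions bound) and `delta_points`
#'   (difference in percentage points).
#' @examples
#' ratio_margin()  # ~0.462, ~0.547, ~8.5 points
#' @export
ratio_margin <- function(params = camnet_params(), mlck_tot = 0.0229,
                         cam_pair = c(0.01145, 0.01374), ca_free = 39) {
  if (mlck_tot <= 0 || any(cam_pair <= 0)) stop("concentrations must be > 0")
  m <- function(cam) predict(
    cam_mlck_model(2, "WT", params, cam_tot = cam, mlck_tot = mlck_tot),
    ca_free)
  f1 <- m(cam_pair[1]); f2 <- m(cam_pair[2])
  list(f1 = f1, f2 = f2, delta_points = 100 * (f2 - f1))
}
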