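#' Equilibrium parameter set for the CaM/MLCK network
#'
#' The network is parameterized by state weights rather than by the
#' individual edge constants of the reaction cube: each Ca2+ occupancy
#' state of MLCK-free CaM gets a statistical weight, and each occupancy
#' state gets one MLCK association constant. Thermodynamic-cycle
#' consistency then holds by construction, because every edge constant is
#' a ratio of state weights and is never stored independently.
#'
#' Ca2+ binding is lumped: each lobe binds `hill_exp` Ca2+ ions as one
#' cooperative site, so the apo state has weight 1 and the state with
#' lobe L occupied picks up a factor `ca_assoc_L * x^hill_exp`, where `x`
#' is the clamped free Ca2+ concentration in uM.
#'
#' Named aliases used in the field: `K9 = k_mlck["apo"]` (MLCK binding
#' apo-CaM), `K4 = k_mlck["C"]` (C-lobe-loaded CaM), `K2 = k_mlck["NC"]`
#' (fully loaded CaM), `K6 = ca_assoc_C`.
#'
#' @param k_apo MLCK association constant for apo-CaM (K9), uM^-1.
#' @param k_nlobe MLCK association constant for N-lobe-only-loaded CaM,
#'   uM^-1. Not pinned by published limits; defaults to `k_apo` (the
#'   C-lobe dominates MLCK affinity). Only Model 1 uses it.
#' @param k_clobe MLCK association constant for C-lobe-only-loaded CaM
#'   (K4), uM^-1.
#' @param k_both MLCK association constant for fully Ca2+-loaded CaM
#'   (K2), uM^-1.
#' @param ca_assoc_N,ca_assoc_C lumped Ca2+ association weight
#'   coefficients for the N- and C-lobe sites, uM^-hill_exp. The
#'   effective per-lobe dissociation constant is
#'   `ca_assoc^(-1/hill_exp)` uM. Defaults give effective lumped Kd of
#'   2 uM (C-lobe) and 10 uM (N-lobe), within the literature range for
#'   CaM lobes.
#' @param hill_exp positive integer: Ca2+ ions lumped per model site
#'   (default 2, one cooperative EF-hand pair per lobe).
#'
#' @return An object of class `camnet_params`: a list with fields
#'   `ca_assoc_N`, `ca_assoc_C`, `hill_exp` and `k_mlck` (named vector
#'   with entries `apo`, `N`, `C`, `NC`).
#'
#' @details The defaults are the reference set used throughout: K9 =
#'   0.078 uM^-1, K4 = 16.7 uM^-1, K2 = 1000 uM^-1. With the default
#'   lobe weights, evaluation at 39 uM free Ca2+ tracks the analytic
#'   high-Ca limit to within 0.1 percentage point of binding, and
#'   predicted binding below 0.04 uM free Ca2+ is negligible —
#'   consistent with the titration window in which binding is actually
#'   observed.
#'
#' @examples
#' p <- camnet_params()
#' p$k_mlck[["NC"]]  # K2 = 1000
#' @export
camnet_params <- function(k_apo = 0.078, k_nlobe = 0.078, k_clobe = 16.7,
                          k_both = 1000, ca_assoc_N = 0.01, ca_assoc_C = 0.25,
                          hill_exp = 2L) {
  k <- c(apo = k_apo, N = k_nlobe, C = k_clobe, NC = k_both)
  stopifnot(is.numeric(k), length(k) == 4L, all(is.finite(k)))
  if (any(k < 0)) stop("MLCK association constants must be >= 0")
  if (!is.numeric(ca_assoc_N) || ca_assoc_N < 0 ||
      !is.numeric(ca_assoc_C) || ca_assoc_C < 0)
    stop("Ca association weights must be >= 0")
  hill_exp <- as.integer(hill_exp)
  if (is.na(hill_exp) || hill_exp < 1L) stop("hill_exp must be >= 1")
  structure(
    list(ca_assoc_N = as.numeric(ca_assoc_N),
         ca_assoc_C = as.numeric(ca_assoc_C),
         hill_exp = hill_exp,
         k_mlck = k),
    class = "camnet_params"
  )
}

#' @export
print.camnet_params <- function(x, ...) {
  cat("CaM/MLCK network parameters (uM units)\n")
  cat(sprintf("  Ca2+ lobe weights: N = %g, C = %g uM^-%d  (eff. Kd %.3g / %.3g uM)\n",
              x$ca_assoc_N, x$ca_assoc_C, x$hill_exp,
              if (x$ca_assoc_N > 0) x$ca_assoc_N^(-1 / x$hill_exp) else Inf,
              if (x$ca_assoc_C > 0) x$ca_assoc_C^(-1 / x$hill_exp) else Inf))
  cat(sprintf("  MLCK association K_M(state), uM^-1: apo (K9) = %g, N = %g, C (K4) = %g, NC (K2) = %g\n",
              x$k_mlck[["apo"]], x$k_mlck[["N"]], x$k_mlck[["C"]], x$k_mlck[["NC"]]))
  invisible(x)
}

#' Model variant: mechanism plus CaM mutant
#'
#' Combines a mechanism (Model 1, 2 or 3) with a CaM EF-hand mutant.
#' A knocked-out lobe cannot bind Ca2+, so its occupancy is forced to
#' FALSE in every admissible state.
#'
#' @param model 1 (random), 2 (partially ordered: MLCK requires a loaded
#'   C-lobe) or 3 (fully ordered: MLCK requires both lobes loaded).
#' @param mutant one of `"WT"` (both lobes functional), `"N"` (N-lobe
#'   EF hands knocked out, as in CaM D21A/D57A), `"C"` (C-lobe knocked
#'   out, D94A/D130A), `"NC"` (all four EF hands knocked out).
#' @return An object of class `camnet_variant` with fields `model_id`,
#'   `mutant`, `n_lobe_functional`, `c_lobe_functional`.
#' @examples
#' model_variant(2, "N")
#' @export
model_variant <- function(model, mutant = c("WT", "N", "C", "NC")) {
  if (length(model) != 1L || !model %in% c(1, 2, 3))
    stop("model must be 1, 2 or 3")
  mutant <- match.arg(mutant)
  structure(
    list(model_id = as.integer(model),
         mutant = mutant,
         n_lobe_functional = !mutant %in% c("N", "NC"),
         c_lobe_functional = !mutant %in% c("C", "NC")),
    class = "camnet_variant"
  )
}

#' @export
print.camnet_variant <- function(x, ...) {
  mech <- c("random (MLCK binds in any Ca state)",
            "partially ordered (MLCK requires loaded C-lobe)",
            "fully ordered (MLCK requires both lobes loaded)")[x$model_id]
  cat(sprintf("Model %d, %s; CaM mutant: %s (N-lobe %s, C-lobe %s)\n",
              x$model_id, mech, x$mutant,
              if (x$n_lobe_functional) "functional" else "knocked out",
              if (x$c_lobe_functional) "functional" else "knocked out"))
  invisible(x)
}

as_variant <- function(x, mutant = "WT") {
  if (inherits(x, "camnet_variant")) x else model_variant(x, mutant)
}

#' Total concentrations with clamped free calcium
#'
#' Free Ca2+ is treated as an independent, clamped variable (as enforced
#' experimentally by EGTA-buffered calibration solutions); only total CaM
#' and total MLCK are conserved.
#'
#' @param cam_tot total CaM, uM.
#' @param mlck_tot total MLCK (or FRET reporter), uM.
#' @return An object of class `camnet_conc`.
#' @examples
#' concentrations(0.713, 0.0237)  # main FRET experiment
#' @export
concentrations <- function(cam_tot, mlck_tot) {
  stopifnot(is.numeric(cam_tot), is.numeric(mlck_tot),
            length(cam_tot) == 1L, length(mlck_tot) == 1L)
  if (cam_tot < 0 || mlck_tot < 0) stop("concentrations must be >= 0")
  structure(list(cam_tot = cam_tot, mlck_tot = mlck_tot),
            class = "camnet_conc")
}
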