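#' Enumerate admissible binding states of a model variant
#'
#' Each state of the eight-state cube records whether the (lumped)
#' N-lobe and C-lobe Ca2+ sites are filled and whether MLCK is bound.
#' A model truncation removes MLCK-bound states whose Ca occupancy the
#' mechanism forbids; a mutant lobe knockout removes every state with
#' that lobe occupied.
#'
#' @param variant a [model_variant()], or a model id (1, 2, 3) combined
#'   with `mutant`.
#' @param mutant used only when `variant` is a bare model id.
#' @return A data.frame with logical columns `n_occupied`, `c_occupied`,
#'   `mlck_bound`, one row per admissible state.
#' @examples
#' nrow(enumerate_states(model_variant(1, "WT")))  # all 8 states
#' nrow(enumerate_states(model_variant(2, "WT")))  # 6: MLCK needs C-lobe
#' @export
enumerate_states <- function(variant, mutant = "WT") {
  v <- as_variant(variant, mutant)
  states <- expand.grid(n_occupied = c(FALSE, TRUE),
                        c_occupied = c(FALSE, TRUE),
                        mlck_bound = c(FALSE, TRUE),
                        KEEP.OUT.ATTRS = FALSE)
  keep <- (!states$n_occupied | v$n_lobe_functional) &
          (!states$c_occupied | v$c_lobe_functional) &
          (!states$mlck_bound | mlck_admissible(v, states$n_occupied,
                                                states$c_occupied))
  out <- states[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Mechanism rule: in which Ca occupancy states may MLCK be bound?
mlck_admissible <- function(variant, n_occ, c_occ) {
  switch(variant$model_id,
         rep(TRUE, length(n_occ)),       # Model 1: any order
         c_occ,                          # Model 2: C-lobe first
         n_occ & c_occ)                  # Model 3: both lobes first
}

# Statistical weights of the four Ca occupancy states of MLCK-free CaM
# at clamped free Ca2+ x (uM). Knocked-out lobes get weight 0 for the
# occupied column. Rows: apo, N, C, NC.
state_weights <- function(params, variant, ca_free) {
  h <- params$hill_exp
  xh <- ca_free^h
  wN <- if (variant$n_lobe_functional) params$ca_assoc_N * xh else 0
  wC <- if (variant$c_lobe_functional) params$ca_assoc_C * xh else 0
  c(apo = 1, N = wN, C = wC, NC = wN * wC)
}

#' Effective bimolecular MLCK association constant at clamped free Ca2+
#'
#' At fixed free Ca2+ the network collapses to a single bimolecular
#' CaM + MLCK reaction whose association constant is the weight-averaged
#' MLCK constant over the admissible Ca occupancy states of MLCK-free
#' CaM:
#' \deqn{K_{eff}(x) = \sum_s w_s(x) K_M(s) / \sum_s w_s(x)}
#' with \eqn{K_M(s) = 0} for states in which the mechanism forbids MLCK
#' binding. In the zero- and high-Ca limits this reduces the network to
#' a simple bimolecular reaction governed by a single constant (K9 at
#' x = 0 for Model 1; K2 or K4 at saturation).
#'
#' @inheritParams enumerate_states
#' @param params a [camnet_params()] object.
#' @param ca_free clamped free Ca2+ concentration(s), uM (vectorized).
#' @return Effective association constant(s), uM^-1. Exactly 0 when no
#'   admissible MLCK-bound state has weight (a structural zero).
#' @examples
#' effective_affinity(camnet_params(), model_variant(2, "WT"), 0)    # 0
#' effective_affinity(camnet_params(), model_variant(2, "WT"), 1e6)  # ~K2
#' @export
effective_affinity <- function(params, variant, ca_free, mutant = "WT") {
  stopifnot(inherits(params, "camnet_params"))
  v <- as_variant(variant, mutant)
  if (any(!is.finite(ca_free)) || any(ca_free < 0))
    stop("ca_free must be finite and >= 0")
  vapply(ca_free, function(x) {
    w <- state_weights(params, v, x)
    adm <- mlck_admissible(v, c(FALSE, TRUE, FALSE, TRUE),
                              c(FALSE, FALSE, TRUE, TRUE))
    k <- params$k_mlck; k[!adm] <- 0
    num <- sum(w * k)
    if (num == 0) 0 else num / sum(w)
  }, numeric(1))
}

#' Fraction of MLCK bound in a bimolecular equilibrium (closed form)
#'
#' For a bimolecular reaction CaM + MLCK <-> complex with association
#' constant K and conserved totals C (CaM) and M (MLCK), the fraction of
#' total MLCK in complex is
#' \deqn{F = \frac{2KC}{1 + K(C+M) + \sqrt{1 + 2K(C+M) + K^2(C-M)^2}}}
#' This form of the quadratic root is numerically stable (no subtractive
#' cancellation) and applies unchanged in the zero- and high-Ca limits
#' of every model; only the constant K differs (K9, K4 or K2).
#'
#' @param k_eff association constant, uM^-1 (vectorized).
#' @param cam_tot,mlck_tot total concentrations, uM.
#' @return Fraction in `[0, 1]`; exactly 0 when `k_eff` or `cam_tot`
#'   is 0.
#' @examples
#' fraction_bound(0.078, 35.65, 0.0237)  # ~0.735
#' @export
fraction_bound <- function(k_eff, cam_tot, mlck_tot) {
  if (any(!is.finite(k_eff)) || any(k_eff < 0))
    stop("k_eff must be finite and >= 0")
  if (!is.numeric(cam_tot) || !is.numeric(mlck_tot) ||
      any(cam_tot < 0) || any(mlck_tot < 0))
    stop("concentrations must be numeric and >= 0")
  s <- k_eff * (cam_tot + mlck_tot)
  d <- k_eff * (cam_tot - mlck_tot)
  f <- 2 * k_eff * cam_tot / (1 + s + sqrt(1 + 2 * s + d^2))
  # structural zeros must be exact, not merely tiny
  f[k_eff == 0 | cam_tot == 0] <- 0
  f
}

#' Fraction bound by full mass-action equilibrium (numeric oracle)
#'
#' Independent check of [fraction_bound()]: distributes CaM over all
#' admissible states (weights times free-species concentrations),
#' conserves total CaM and total MLCK at clamped free Ca2+, and solves
#' for free MLCK by bracketed one-dimensional root finding. Exists so
#' that the closed form can be verified against an implementation that
#' shares none of its algebra.
#'
#' @inheritParams effective_affinity
#' @param conc a [concentrations()] object.
#' @param tol relative convergence tolerance passed to the root finder.
#' @return Fraction of total MLCK bound; 0 when `mlck_tot` or `cam_tot`
#'   is 0.
#' @export
fraction_bound_numeric <- function(params, variant, conc, ca_free,
                                   mutant = "WT", tol = 1e-12) {
  v <- as_variant(variant, mutant)
  stopifnot(inherits(conc, "camnet_conc"))
  if (!is.finite(ca_free) || ca_free < 0) stop("ca_free must be >= 0")
  C <- conc$cam_tot
  M <- conc$mlck_tot
  if (C == 0 || M == 0) return(0)
  w <- state_weights(params, v, ca_free)
  adm <- mlck_admissible(v, c(FALSE, TRUE, FALSE, TRUE),
                            c(FALSE, FALSE, TRUE, TRUE))
  k <- params$k_mlck; k[!adm] <- 0
  W <- sum(w)            # weight of MLCK-free CaM states
  WK <- sum(w * k)       # weight x K of MLCK-bound states per free MLCK
  if (WK == 0) return(0)
  # unknown: free MLCK m in (0, M]; apo free CaM c0 = C / (W + m*WK);
  # residual increases monotonically in m
  g <- function(m) m + C * m * WK / (W + m * WK) - M
  if (g(M) < 0) stop("failed to bracket free MLCK root; inputs: C=", C,
                     " M=", M, " x=", ca_free)
  m <- stats::uniroot(g, lower = 0, upper = M, tol = tol * max(M, 1e-30))$root
  # Newton polish to machine precision (g is smooth and increasing)
  for (i in 1:4) {
    gp <- 1 + C * W * WK / (W + m * WK)^2
    m_new <- m - g(m) / gp
    if (!is.finite(m_new) || m_new < 0 || m_new > M) break
    m <- m_new
  }
  bound <- C * m * WK / (W + m * WK)
  bound / M
}

#' Binding fraction in the zero- and high-calcium limits
#'
#' At x = 0 only the apo state has weight, so the low-end fraction is
#' governed by K9 where the mechanism admits apo binding (Model 1) and
#' is a structural zero otherwise. At saturating Ca2+ the functional
#' lobes fill, so the high-end fraction is governed by the MLCK constant
#' of the fullest admissible occupancy (K2 for wild type, K4 when the
#' N-lobe is knocked out). Model 3 with a knocked-out N-lobe has no
#' admissible MLCK-bound state at any x and returns exactly 0 at both
#' ends.
#'
#' @inheritParams fraction_bound_numeric
#' @param end `"low"` (x -> 0) or `"high"` (x -> Inf).
#' @return Fraction of total MLCK bound in that limit.
#' @examples
#' p <- camnet_params()
#' conc <- concentrations(0.713, 0.0237)
#' limit_binding(p, model_variant(1, "WT"), conc, "low")   # ~0.052
#' limit_binding(p, model_variant(2, "N"), conc, "high")   # ~0.920
#' @export
limit_binding <- function(params, variant, conc, end = c("low", "high"),
                          mutant = "WT") {
  v <- as_variant(variant, mutant)
  stopifnot(inherits(conc, "camnet_conc"))
  end <- match.arg(end)
  adm <- mlck_admissible(v, c(FALSE, TRUE, FALSE, TRUE),
                            c(FALSE, FALSE, TRUE, TRUE))
  k <- params$k_mlck; k[!adm] <- 0
  # which lobes can fill at saturation (weight coefficient > 0)
  n_sat <- v$n_lobe_functional && params$ca_assoc_N > 0
  c_sat <- v$c_lobe_functional && params$ca_assoc_C > 0
  k_lim <- if (end == "low") {
    k[["apo"]]
  } else {
    idx <- c("apo", "N", "C", "NC")[1 + n_sat + 2 * c_sat]
    k[[idx]]
  }
  fraction_bound(k_lim, conc$cam_tot, conc$mlck_tot)
}
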