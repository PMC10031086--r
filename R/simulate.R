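# Synthetic plate-reader FRET and on-bead densitometry generators.
# These emulate the statistical structure of the study's raw data so the
# whole discrimination pipeline is testable; every dataset carries its
# ground truth for recovery tests.

# run code with a local, restorable RNG state so generators are
# seed-deterministic without clobbering the caller's stream
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Default 14-point free-calcium titration ladder
#'
#' Fourteen clamped free Ca2+ conditions spanning 0 to 39 uM. The seven
#' anchor values used in the study design (0, 0.038, 0.1, 0.35, 1.35, 3
#' and 39 uM) are included verbatim; the remaining seven are filled by
#' approximate geometric interpolation between the anchors (one point
#' below 0.038, where a geometric mean with 0 does not exist, is placed
#' at a third of 0.038).
#'
#' @return Strictly increasing numeric vector of length 14, first 0,
#'   last 39 (uM).
#' @examples
#' default_ladder()
#' @export
default_ladder <- function() {
  anchors <- c(0, 0.038, 0.1, 0.35, 1.35, 3, 39)
  fill <- c(0.038 / 3,
            sqrt(0.038 * 0.1), sqrt(0.1 * 0.35), sqrt(0.35 * 1.35),
            sqrt(1.35 * 3),
            3 * (39 / 3)^(1 / 3), 3 * (39 / 3)^(2 / 3))
  sort(c(anchors, fill))
}

#' Per-channel noise model for simulated plate-reader intensities
#'
#' Noise is multiplicative Gaussian applied independently to each
#' emission channel (Em480, Em535) — not to their ratio — because ratios
#' of noisy channels are what the assay actually measures.
#'
#' @param channel_cv coefficient of variation per channel (default
#'   0.02; the study does not report channel-level noise, so this is a
#'   stand-in at the scale of tight plate-reader replicates).
#' @param baseline_535 mean Em535 intensity of a reporter-only well,
#'   arbitrary units.
#' @param baseline_480 mean Em480 intensity of a reporter-only well;
#'   default `r0 * baseline_535` is filled in at simulation time.
#' @return An object of class `camnet_noise`.
#' @export
noise_model <- function(channel_cv = 0.02, baseline_535 = 10000,
                        baseline_480 = NULL) {
  if (channel_cv < 0) stop("channel_cv must be >= 0")
  if (baseline_535 <= 0) stop("baseline_535 must be > 0")
  structure(list(channel_cv = channel_cv, baseline_535 = baseline_535,
                 baseline_480 = baseline_480),
            class = "camnet_noise")
}

# default replicate counts: the study's per-condition sample sizes
default_replicates <- function() {
  c(WT = 15L, N = 16L, C = 8L, NC = 3L, baseline = 13L)
}

#' Simulate a plate-reader FRET dataset
#'
#' Draws per-well Em480/Em535 intensities for CaM-variant conditions and
#' a reporter-only baseline across a free-Ca2+ ladder. The true fraction
#' bound F(x) comes from the equilibrium model; the expected emission
#' ratio is the affine map `r(x) = r0 + delta_r * F(x)` (the ratio is an
#' explicit, configurable proxy because it need not be 1:1 with fraction
#' bound); channel intensities are drawn so that em480/em535 has mean
#' r(x) (exactly r(x) when `channel_cv = 0`).
#'
#' @param params a [camnet_params()] object.
#' @param model generating mechanism (default 2, the partially ordered
#'   model supported by the study).
#' @param mutants CaM variants to simulate; a reporter-only `"baseline"`
#'   condition (F = 0 at every x) is always included.
#' @param conc a [concentrations()] object.
#' @param ladder free-Ca2+ grid, uM.
#' @param n_replicates named integer vector of replicates per condition;
#'   default `c(WT = 15, N = 16, C = 8, NC = 3, baseline = 13)`.
#' @param ratio_map `c(r0, delta_r)`: ratio at F = 0 and ratio gain per
#'   unit fraction bound (defaults 0.5, 0.5, arbitrary units).
#' @param noise a [noise_model()].
#' @param seed integer; identical seeds give identical datasets.
#' @return A data.frame of class `camnet_plate` with columns
#'   `condition`, `replicate`, `ca_free_uM`, `em480`, `em535`, and
#'   attributes `truth` (per condition x ladder true fractions and
#'   expected ratios), `ratio_map`, `noise`, `seed`.
#' @examples
#' d <- simulate_fret(seed = 1, n_replicates = c(WT = 3, baseline = 3),
#'                    mutants = "WT")
#' head(d)
#' @export
simulate_fret <- function(params = camnet_params(), model = 2,
                          mutants = c("WT", "N", "C", "NC"),
                          conc = concentrations(0.713, 0.0237),
                          ladder = default_ladder(),
                          n_replicates = default_replicates(),
                          ratio_map = c(r0 = 0.5, delta_r = 0.5),
                          noise = noise_model(), seed = NULL) {
  stopifnot(inherits(noise, "camnet_noise"))
  r0 <- unname(ratio_map[1]); delta_r <- unname(ratio_map[2])
  if (delta_r == 0)
    warning("delta_r = 0: the ratio carries no information about the ",
            "bound fraction; recovery from this dataset is unidentifiable")
  conditions <- c(mutants, "baseline")
  reps <- n_replicates[conditions]
  if (anyNA(reps)) stop("n_replicates must name every condition: ",
                        paste(conditions[is.na(reps)], collapse = ", "))
  if (any(reps < 1)) stop("n_replicates must be >= 1")
  truth <- do.call(rbind, lapply(conditions, function(cond) {
    f <- if (cond == "baseline") rep(0, length(ladder))
         else predict(cam_mlck_model(model, cond, params,
                                     conc$cam_tot, conc$mlck_tot), ladder)
    data.frame(condition = cond, ca_free_uM = ladder, true_fraction = f,
               expected_ratio = r0 + delta_r * f, stringsAsFactors = FALSE)
  }))
  b535 <- noise$baseline_535
  rows <- with_local_seed(seed, {
    do.call(rbind, lapply(conditions, function(cond) {
      tr <- truth[truth$condition == cond, ]
      n <- reps[[cond]]
      grid <- tr[rep(seq_len(nrow(tr)), each = n), ]
      grid$replicate <- rep(seq_len(n), times = nrow(tr))
      m535 <- b535
      m480 <- grid$expected_ratio * b535
      cv <- noise$channel_cv
      em480 <- m480 * (1 + cv * stats::rnorm(nrow(grid)))
      em535 <- m535 * (1 + cv * stats::rnorm(nrow(grid)))
      data.frame(condition = grid$condition, replicate = grid$replicate,
                 ca_free_uM = grid$ca_free_uM,
                 em480 = pmax(em480, .Machine$double.eps),
                 em535 = pmax(em535, .Machine$double.eps),
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(rows) <- NULL
  class(rows) <- c("camnet_plate", "data.frame")
  attr(rows, "truth") <- truth
  attr(rows, "ratio_map") <- c(r0 = r0, delta_r = delta_r)
  attr(rows, "noise") <- noise
  attr(rows, "seed") <- seed
  rows
}

#' Simulate draws from a fitted binding model
#'
#' `simulate()` method for [cam_mlck_model()]: returns `nsim` synthetic
#' plate-reader datasets for this variant (plus the reporter-only
#' baseline), drawn with [simulate_fret()].
#'
#' @param object a [cam_mlck_model()].
#' @param nsim number of datasets.
#' @param seed integer seed for the first dataset; dataset i uses
#'   `seed + i - 1`.
#' @param ... passed to [simulate_fret()] (`ladder`, `n_replicates`,
#'   `ratio_map`, `noise`).
#' @return A list of `nsim` `camnet_plate` data.frames (a single
#'   data.frame when `nsim = 1`).
#' @export
simulate.camnet_model <- function(object, nsim = 1, seed = NULL, ...) {
  out <- lapply(seq_len(nsim), function(i) {
    simulate_fret(params = object$params, model = object$variant$model_id,
                  mutants = object$variant$mutant, conc = object$conc,
                  seed = if (is.null(seed)) NULL else seed + i - 1, ...)
  })
  if (nsim == 1) out[[1]] else out
}

#' Simulate an on-bead densitometry dataset
#'
#' Emulates SDS-PAGE band quantification of bound and unbound CaM
#' fractions: for true fraction F at each ladder point, the bound band
#' intensity is `background + F * intensity_scale` and the unbound band
#' `background + (1 - F) * intensity_scale`, each with multiplicative
#' Gaussian noise on the signal part, so the background-corrected ratio
#' recovers F in expectation.
#'
#' @param true_fractions fractions in `[0, 1]`, one per ladder point.
#' @param ca_free ladder of free Ca2+ values, uM.
#' @param intensity_scale total band signal, arbitrary units.
#' @param background constant gel background intensity.
#' @param cv coefficient of variation of the band signal.
#' @param seed integer seed.
#' @return A data.frame of class `camnet_onbead` with columns
#'   `ca_free_uM`, `bound_intensity`, `unbound_intensity`, `background`,
#'   with the true fractions as attribute `truth`.
#' @examples
#' simulate_onbead(c(0, 0.5, 1), c(0, 1, 39), cv = 0, seed = 1)
#' @export
simulate_onbead <- function(true_fractions, ca_free = default_ladder(),
                            intensity_scale = 1000, background = 50,
                            cv = 0.02, seed = NULL) {
  if (any(true_fractions < 0 | true_fractions > 1))
    stop("true_fractions must be in [0, 1]")
  if (length(true_fractions) != length(ca_free))
    stop("true_fractions and ca_free lengths differ")
  out <- with_local_seed(seed, {
    n <- length(true_fractions)
    sb <- true_fractions * intensity_scale *
      pmax(1 + cv * stats::rnorm(n), 0)
    su <- (1 - true_fractions) * intensity_scale *
      pmax(1 + cv * stats::rnorm(n), 0)
    data.frame(ca_free_uM = ca_free,
               bound_intensity = background + sb,
               unbound_intensity = background + su,
               background = background)
  })
  class(out) <- c("camnet_onbead", "data.frame")
  attr(out, "truth") <- true_fractions
  attr(out, "seed") <- seed
  out
}
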