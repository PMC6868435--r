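#' Mechanical model of the lambda-DNA tether and optical trap
#'
#' Bundles the constants that describe the force-transmitting element of the
#' assay: an extensible worm-like-chain (WLC) double-stranded DNA tether in
#' series with a harmonic optical trap, driven by a piezo stage moving at
#' constant speed. The defaults describe a full-length lambda-DNA handle
#' (contour length 16.4 um, persistence length 50 nm, stretch modulus 1200 pN)
#' and a trap/stage combination for which a 14.00 to 16.96 um stage ramp at
#' 455 nm/s takes the tension from about 1 pN to about 28 pN in about 6.5 s.
#'
#' @param contour_length Tether contour length, nm.
#' @param persistence_length WLC persistence length, nm.
#' @param stretch_modulus Enthalpic stretch modulus, pN.
#' @param trap_stiffness Trap stiffness, pN/nm.
#' @param stage_speed Stage translation speed, nm/s.
#' @param kBT Thermal energy, pN nm.
#'
#' @return An object of class `tether_model`.
#' @examples
#' m <- tether_model()
#' force_at_stage(16960, m)
#' @export
tether_model <- function(contour_length = 16400,
                         persistence_length = 50,
                         stretch_modulus = 1200,
                         trap_stiffness = 0.046,
                         stage_speed = 455,
                         kBT = KBT_DEFAULT) {
  stopifnot_scalar_pos(contour_length, "contour_length")
  stopifnot_scalar_pos(persistence_length, "persistence_length")
  stopifnot_scalar_pos(stretch_modulus, "stretch_modulus")
  stopifnot_scalar_pos(trap_stiffness, "trap_stiffness")
  stopifnot_scalar_pos(stage_speed, "stage_speed")
  stopifnot_scalar_pos(kBT, "kBT")
  structure(
    list(
      contour_length = contour_length,
      persistence_length = persistence_length,
      stretch_modulus = stretch_modulus,
      trap_stiffness = trap_stiffness,
      stage_speed = stage_speed,
      kBT = kBT
    ),
    class = "tether_model"
  )
}

#' @export
print.tether_model <- function(x, ...) {
  cat("<tether_model>\n")
  cat(sprintf("  Lc = %g nm, P = %g nm, K = %g pN\n",
              x$contour_length, x$persistence_length, x$stretch_modulus))
  cat(sprintf("  trap = %g pN/nm, stage speed = %g nm/s, kBT = %g pN nm\n",
              x$trap_stiffness, x$stage_speed, x$kBT))
  invisible(x)
}

# The extensible Marko-Siggia relation, written in terms of
# u = x/Lc - F/K:  F * P / kBT = 1/(4 (1-u)^2) - 1/4 + u.
# g() is strictly increasing on [0, 1), so every force maps to a unique u.
ms_g <- function(u) 1 / (4 * (1 - u)^2) - 0.25 + u
ms_gprime <- function(u) 1 / (2 * (1 - u)^3) + 1

ms_u_of_force <- function(force, model) {
  target <- force * model$persistence_length / model$kBT
  vapply(target, function(tg) {
    if (tg <= 0) return(0)
    uniroot(function(u) ms_g(u) - tg,
            lower = 0, upper = 1 - 1e-12,
            tol = .Machine$double.eps^0.75)$root
  }, numeric(1))
}

#' Extension of the extensible worm-like chain at a given force
#'
#' Solves the extensible Marko-Siggia interpolation
#' \deqn{F = (k_B T / P)\,[1/(4 (1 - x/L_c + F/K)^2) - 1/4 + x/L_c - F/K]}
#' for the extension `x`. The relation is strictly monotone, so the solution
#' is unique.
#'
#' @param force Force, pN (vectorised; must be >= 0).
#' @param model A [tether_model()].
#' @return Extension in nm, same length as `force`.
#' @examples
#' wlc_extension(28, tether_model())
#' @export
wlc_extension <- function(force, model = tether_model()) {
  if (any(!is.finite(force)) || any(force < 0)) {
    abort("`force` must be finite and >= 0.")
  }
  u <- ms_u_of_force(force, model)
  (u + force / model$stretch_modulus) * model$contour_length
}

# d(extension)/d(force) of the extensible WLC, nm/pN (analytic).
wlc_compliance <- function(force, model) {
  u <- ms_u_of_force(force, model)
  dudF <- (model$persistence_length / model$kBT) / ms_gprime(u)
  model$contour_length * (dudF + 1 / model$stretch_modulus)
}

#' Equilibrium force at a given stage position
#'
#' The stage displacement is shared between the WLC tether and the trapped
#' bead: `wlc_extension(F) + F / trap_stiffness = stage`. Monotonicity of both
#' terms makes the force unique. A stage position at or behind the zero-force
#' slack point returns 0 pN with a warning.
#'
#' @param stage Stage position(s), nm from the trap origin.
#' @inheritParams wlc_extension
#' @return Force in pN, same length as `stage`.
#' @examples
#' force_at_stage(c(14000, 16960), tether_model())
#' @export
force_at_stage <- function(stage, model = tether_model()) {
  if (any(!is.finite(stage))) abort("`stage` must be finite.")
  vapply(stage, function(s) {
    if (s <= 0) {
      warn("Stage position at or behind the tether slack point; returning 0 pN.")
      return(0)
    }
    # Parametrise by u so that no nested root search is needed:
    # stage(u) = Lc (u + F(u)/K) + F(u)/kappa with F(u) = kBT/P * g(u).
    stage_of_u <- function(u) {
      f <- model$kBT / model$persistence_length * ms_g(u)
      model$contour_length * (u + f / model$stretch_modulus) +
        f / model$trap_stiffness
    }
    u <- uniroot(function(u) stage_of_u(u) - s,
                 lower = 0, upper = 1 - 1e-12,
                 tol = .Machine$double.eps^0.75)$root
    model$kBT / model$persistence_length * ms_g(u)
  }, numeric(1))
}

#' Nominal (stiff-tether) loading rate of the trap
#'
#' `trap_stiffness * stage_speed`, the loading rate the stage ramp would apply
#' if the tether were inextensible. This is the conventional single-number
#' summary of a constant-velocity pulling protocol and the default rate used
#' by [reconstruct_profile()].
#'
#' @inheritParams wlc_extension
#' @return Loading rate, pN/s.
#' @export
nominal_loading_rate <- function(model = tether_model()) {
  model$trap_stiffness * model$stage_speed
}

#' Loading schedule of a constant-velocity stage ramp
#'
#' Converts a stage ramp into the force-versus-time trajectory experienced by
#' the molecule and the instantaneous loading rate
#' `dF/dt = v / (dx_wlc/dF + 1/kappa)`. Force and rate are tabulated once on a
#' fine grid at construction and interpolated afterwards, which keeps
#' downstream likelihood evaluations cheap.
#'
#' @param model A [tether_model()].
#' @param stage_start,stage_end Stage ramp endpoints, nm.
#' @param n_grid Number of grid points used for tabulation.
#' @return An object of class `loading_schedule` with elements
#'   `force_of_time(t)`, `rate_of_force(F)`, `F_min`, `F_max`, `duration`.
#' @examples
#' sched <- loading_schedule(tether_model())
#' sched$force_of_time(6.5)
#' sched$rate_of_force(8)
#' @export
loading_schedule <- function(model = tether_model(),
                             stage_start = 14000,
                             stage_end = 16960,
                             n_grid = 801) {
  if (stage_end <= stage_start) abort("`stage_end` must exceed `stage_start`.")
  duration <- (stage_end - stage_start) / model$stage_speed
  tt <- seq(0, duration, length.out = n_grid)
  stage <- stage_start + model$stage_speed * tt
  ff <- force_at_stage(stage, model)
  F_min <- ff[1]
  F_max <- ff[n_grid]
  rate_tab <- model$stage_speed /
    (wlc_compliance(ff, model) + 1 / model$trap_stiffness)
  force_of_time <- splinefun(tt, ff, method = "hyman")
  rate_spline <- splinefun(ff, rate_tab, method = "hyman")
  structure(
    list(
      type = "wlc",
      model = model,
      stage_start = stage_start,
      stage_end = stage_end,
      duration = duration,
      F_min = F_min,
      F_max = F_max,
      force_of_time = function(t) force_of_time(pmin(pmax(t, 0), duration)),
      rate_of_force = function(f) rate_spline(pmin(pmax(f, F_min), F_max)),
      grid = tibble::tibble(t_s = tt, stage_nm = stage, force_pN = ff,
                            rate_pN_s = rate_tab)
    ),
    class = "loading_schedule"
  )
}

#' Constant-loading-rate schedule
#'
#' An idealised force ramp `F(t) = F_min + rate * t`, the regime in which the
#' Dudko-Szabo rupture-force distribution is usually quoted.
#'
#' @param rate Loading rate, pN/s.
#' @param F_max Maximum force reached, pN.
#' @param F_min Force at the start of the ramp, pN.
#' @return A `loading_schedule` object.
#' @export
constant_schedule <- function(rate, F_max, F_min = 0) {
  stopifnot_scalar_pos(rate, "rate")
  stopifnot_scalar_pos(F_max, "F_max")
  if (F_min < 0 || F_min >= F_max) abort("`F_min` must lie in [0, F_max).")
  duration <- (F_max - F_min) / rate
  structure(
    list(
      type = "constant",
      model = NULL,
      duration = duration,
      F_min = F_min,
      F_max = F_max,
      force_of_time = function(t) F_min + rate * pmin(pmax(t, 0), duration),
      rate_of_force = function(f) rep_len(rate, length(f)),
      grid = tibble::tibble(t_s = c(0, duration), force_pN = c(F_min, F_max),
                            rate_pN_s = rate)
    ),
    class = "loading_schedule"
  )
}

#' @export
print.loading_schedule <- function(x, ...) {
  cat(sprintf("<loading_schedule: %s>\n", x$type))
  cat(sprintf("  F: %.3g -> %.3g pN over %.3g s\n", x$F_min, x$F_max, x$duration))
  invisible(x)
}

#' @rdname loading_schedule
#' @param x A `loading_schedule`.
#' @param ... Unused.
#' @method tidy loading_schedule
#' @export
tidy.loading_schedule <- function(x, ...) {
  x$grid
}

#' Calibrate the stage ramp endpoint for a target peak force
#'
#' Solves for the stage position at which [force_at_stage()] reaches `F_end`.
#'
#' @param model A [tether_model()].
#' @param F_end Target force at the end of the ramp, pN.
#' @return Stage position, nm.
#' @export
calibrate_stage_end <- function(model = tether_model(), F_end = 28) {
  stopifnot_scalar_pos(F_end, "F_end")
  wlc_extension(F_end, model) + F_end / model$trap_stiffness
}

#' Calibrate the trap stiffness for a target force at a given stage position
#'
#' Solves `wlc_extension(F_end) + F_end / kappa = stage_end` for the trap
#' stiffness `kappa`.
#'
#' @inheritParams calibrate_stage_end
#' @param stage_end Stage position at which `F_end` should be reached, nm.
#' @return Trap stiffness, pN/nm.
#' @export
calibrate_trap_stiffness <- function(model = tether_model(), F_end = 28,
                                     stage_end = 16960) {
  slack <- stage_end - wlc_extension(F_end, model)
  if (slack <= 0) {
    abort("Tether alone is longer than `stage_end` at `F_end`; no stiffness fits.")
  }
  F_end / slack
}

#' Freely jointed chain model of single-stranded DNA
#'
#' @param n_nt Number of nucleotides.
#' @param contour_per_nt Contour length per nucleotide, nm.
#' @param kuhn_length Kuhn length, nm.
#' @param forster_radius Forster radius of the dye pair, nm (used only by the
#'   mechanistic post-rupture FRET mode of the simulators).
#' @return An object of class `ssdna_model`.
#' @export
ssdna_model <- function(n_nt, contour_per_nt = 0.63, kuhn_length = 1.5,
                        forster_radius = 5.4) {
  stopifnot_scalar_pos(n_nt, "n_nt")
  stopifnot_scalar_pos(contour_per_nt, "contour_per_nt")
  stopifnot_scalar_pos(kuhn_length, "kuhn_length")
  stopifnot_scalar_pos(forster_radius, "forster_radius")
  structure(
    list(n_nt = n_nt, contour_per_nt = contour_per_nt,
         kuhn_length = kuhn_length, forster_radius = forster_radius),
    class = "ssdna_model"
  )
}

#' Freely-jointed-chain extension of single-stranded DNA
#'
#' `x(F) = L_ss * [coth(F b / kBT) - kBT / (F b)]` with
#' `L_ss = n_nt * contour_per_nt` (the Langevin function of the reduced
#' force). `x(0) = 0` and `x -> L_ss` at high force.
#'
#' @param force Force, pN (vectorised, >= 0).
#' @param model An [ssdna_model()].
#' @param kBT Thermal energy, pN nm.
#' @return Extension, nm.
#' @export
ssdna_extension <- function(force, model, kBT = KBT_DEFAULT) {
  if (any(force < 0)) abort("`force` must be >= 0.")
  L <- model$n_nt * model$contour_per_nt
  y <- force * model$kuhn_length / kBT
  lang <- ifelse(y < 1e-6, y / 3, 1 / tanh(y) - 1 / y)
  L * lang
}
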