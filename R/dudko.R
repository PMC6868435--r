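#' Dudko-Szabo kinetic parameters
#'
#' The three parameters of the Dudko-Szabo force-dependent rupture model:
#' the distance to the transition state `dx_dagger` (nm), the zero-force
#' lifetime `tau0` (s), and the apparent activation free energy `dG_dagger`
#' (in units of kBT), together with the shape parameter `nu` (1/2 for a
#' cusp-shaped free-energy surface, 2/3 for linear-cubic, 1 for the Bell
#' phenomenological limit).
#'
#' @param dx_dagger Distance to the transition state, nm.
#' @param tau0 Zero-force unfolding lifetime, s.
#' @param dG_dagger Apparent activation free energy, multiples of kBT.
#' @param nu Shape parameter; one of 1/2, 2/3, 1.
#' @return An object of class `ds_params`.
#' @examples
#' p <- ds_params(dx_dagger = 4.3, tau0 = 50, dG_dagger = 6.5)
#' critical_force(p)
#' @export
ds_params <- function(dx_dagger, tau0, dG_dagger, nu = 1 / 2) {
  stopifnot_scalar_pos(dx_dagger, "dx_dagger")
  stopifnot_scalar_pos(tau0, "tau0")
  stopifnot_scalar_pos(dG_dagger, "dG_dagger")
  if (!isTRUE(all.equal(nu, 1 / 2)) && !isTRUE(all.equal(nu, 2 / 3)) &&
      !isTRUE(all.equal(nu, 1))) {
    abort("`nu` must be one of 1/2, 2/3, 1.")
  }
  structure(
    list(dx_dagger = dx_dagger, tau0 = tau0, dG_dagger = dG_dagger, nu = nu),
    class = "ds_params"
  )
}

#' @export
print.ds_params <- function(x, ...) {
  cat(sprintf(
    "<ds_params> dx = %.3g nm, tau0 = %.4g s, dG = %.3g kBT, nu = %.3g\n",
    x$dx_dagger, x$tau0, x$dG_dagger, x$nu))
  invisible(x)
}

#' Critical force at which the activation barrier vanishes
#'
#' `F_c = dG_dagger * kBT / (nu * dx_dagger)`. The Dudko-Szabo rate law is
#' defined for forces below `F_c`.
#'
#' @param params A [ds_params()].
#' @param kBT Thermal energy, pN nm.
#' @return Critical force, pN.
#' @export
critical_force <- function(params, kBT = KBT_DEFAULT) {
  params$dG_dagger * kBT / (params$nu * params$dx_dagger)
}

#' Weighted mixture of Dudko-Szabo components
#'
#' @param components A list of [ds_params()] objects.
#' @param weights Mixture weights; non-negative, summing to 1.
#' @return An object of class `ds_mixture`.
#' @export
ds_mixture <- function(components, weights = NULL) {
  if (inherits(components, "ds_params")) components <- list(components)
  if (length(components) < 1L) abort("At least one component is required.")
  ok <- vapply(components, inherits, logical(1), what = "ds_params")
  if (!all(ok)) abort("All `components` must be `ds_params` objects.")
  weights <- weights %||% rep(1 / length(components), length(components))
  if (length(weights) != length(components)) {
    abort("`weights` must have one entry per component.")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    abort("`weights` must be >= 0 and sum to 1 (tolerance 1e-9).")
  }
  structure(list(components = components, weights = weights),
            class = "ds_mixture")
}

as_ds_mixture <- function(x) {
  if (inherits(x, "ds_mixture")) return(x)
  if (inherits(x, "ds_params")) return(ds_mixture(list(x), 1))
  abort("Expected a `ds_params` or `ds_mixture` object.")
}

#' Dudko-Szabo force-dependent rupture rate
#'
#' \deqn{k(F) = \tau_u(0)^{-1}\,(1 - \nu F \Delta x^\ddagger / \Delta
#'   G^\ddagger)^{1/\nu - 1} \exp\{\Delta G^\ddagger [1 - (1 - \nu F \Delta
#'   x^\ddagger/\Delta G^\ddagger)^{1/\nu}]\}}
#' with \eqn{\Delta G^\ddagger} expressed in energy units (`dG_dagger * kBT`).
#' At `nu = 1` this reduces exactly to the Bell rate
#' `exp(F dx / kBT) / tau0`, independent of `dG_dagger`.
#'
#' @param force Force(s), pN; must satisfy `0 <= F < critical_force(params)`.
#' @param params A [ds_params()].
#' @param kBT Thermal energy, pN nm.
#' @return Rupture rate(s), 1/s.
#' @examples
#' ds_rate(4, ds_params(4.3, 50, 6.5))
#' @export
ds_rate <- function(force, params, kBT = KBT_DEFAULT) {
  Fc <- critical_force(params, kBT)
  if (any(force < 0) || any(force >= Fc)) {
    abort(sprintf(
      "`force` must lie in [0, F_c) with F_c = %.4g pN for these parameters.",
      Fc))
  }
  ds_rate_unsafe(force, params, kBT)
}

# No domain check; forces at/above Fc yield 0 (the barrier is gone and the
# (1 - nu F dx / dG)^... factor is clamped). Used on integration grids.
ds_rate_unsafe <- function(force, params, kBT) {
  z <- pmax(0, 1 - params$nu * force * params$dx_dagger /
              (params$dG_dagger * kBT))
  (1 / params$tau0) * z^(1 / params$nu - 1) *
    exp(params$dG_dagger * (1 - z^(1 / params$nu)))
}

# Cumulative hazard in force, Lambda(F) = int_{F_min}^{F} k(f)/Fdot(f) df,
# tabulated on a grid and returned with interpolators. The grid stops at
# min(F_max, F_c) because the component's density is truncated at F_c.
ds_hazard_table <- function(params, schedule, kBT, n_grid = 1501) {
  Fc <- critical_force(params, kBT)
  hi <- min(schedule$F_max, Fc * (1 - 1e-9))
  lo <- schedule$F_min
  if (hi <= lo) {
    abort(sprintf(
      "Critical force (%.4g pN) lies at or below the schedule start (%.4g pN).",
      Fc, lo))
  }
  grid <- seq(lo, hi, length.out = n_grid)
  haz <- ds_rate_unsafe(grid, params, kBT) / schedule$rate_of_force(grid)
  Lam <- cumlogtrapz(grid, haz)
  list(grid = grid, hazard = haz, Lambda = Lam, Fc = Fc,
       truncated = Fc < schedule$F_max,
       # survival past the end of the component's domain; if Fc < F_max the
       # residual survival S(Fc) persists to F_max (the rate is zero beyond).
       S_end = exp(-Lam[n_grid]))
}

#' Rupture-force distribution under a loading schedule
#'
#' Computes the density of rupture forces
#' \deqn{p(F) = \frac{k(F)}{\dot F(F)} \exp\left(-\int_{F_{min}}^{F}
#'   \frac{k(f)}{\dot F(f)}\,df\right)}
#' for a single Dudko-Szabo component or a weighted mixture, together with the
#' survival probability at the end of the ramp (molecules that never rupture
#' are censored at `F_max`). Probability is conserved:
#' `integral(p) + S(F_max) = 1`.
#'
#' @param params A [ds_params()] or [ds_mixture()].
#' @param schedule A [loading_schedule()] or [constant_schedule()].
#' @param n_grid Grid resolution for quadrature.
#' @param kBT Thermal energy, pN nm.
#' @return An object of class `rupture_density` with a per-force tibble
#'   (`$density`), the mixture survival at `F_max` (`$survival`), the refined
#'   modal force (`$mode`) and the mean rupture force among ruptured
#'   molecules (`$mean`).
#' @examples
#' sched <- constant_schedule(rate = 4.2, F_max = 28.3)
#' rd <- rupture_density(ds_params(4.3, 50, 6.5), sched)
#' glance(rd)
#' @export
rupture_density <- function(params, schedule, n_grid = 3001,
                            kBT = KBT_DEFAULT) {
  mix <- as_ds_mixture(params)
  n_comp <- length(mix$components)
  grid <- seq(schedule$F_min, schedule$F_max, length.out = n_grid)
  dens_total <- numeric(n_grid)
  surv_total <- 0
  comp_rows <- vector("list", n_comp)
  for (i in seq_len(n_comp)) {
    tab <- ds_hazard_table(mix$components[[i]], schedule, kBT, n_grid)
    dens_i <- tab$hazard * exp(-tab$Lambda)
    on_grid <- approx(tab$grid, dens_i, xout = grid, yleft = NA,
                      yright = 0)$y
    on_grid[is.na(on_grid)] <- 0
    dens_total <- dens_total + mix$weights[i] * on_grid
    surv_total <- surv_total + mix$weights[i] * tab$S_end
    comp_rows[[i]] <- tibble::tibble(
      component = i,
      force = tab$grid,
      density = dens_i,
      weight = mix$weights[i],
      Fc = tab$Fc,
      survival = tab$S_end
    )
  }
  # log-mean quadrature: the density decays near-exponentially wherever the
  # hazard does, so the logarithmic interval mean integrates it accurately
  total_mass <- tail(cumlogtrapz(grid, dens_total), 1)
  structure(
    list(
      density = tibble::tibble(force = grid, density = dens_total),
      components = dplyr::bind_rows(comp_rows),
      survival = surv_total,
      total_mass = total_mass,
      mode = refine_mode(grid, dens_total),
      mean = sum(grid * dens_total) / sum(dens_total),
      params = mix,
      schedule = schedule,
      kBT = kBT
    ),
    class = "rupture_density"
  )
}

#' @export
print.rupture_density <- function(x, ...) {
  cat("<rupture_density>\n")
  cat(sprintf("  mode = %.3g pN, mean = %.3g pN, S(F_max) = %.3g\n",
              x$mode, x$mean, x$survival))
  cat(sprintf("  mass + survival = %.6f\n", x$total_mass + x$survival))
  invisible(x)
}

#' @rdname rupture_density
#' @param x A `rupture_density`.
#' @param ... Unused.
#' @method tidy rupture_density
#' @export
tidy.rupture_density <- function(x, ...) {
  x$density
}

#' @rdname rupture_density
#' @method glance rupture_density
#' @export
glance.rupture_density <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    mean = x$mean,
    survival = x$survival,
    total_mass = x$total_mass,
    n_components = length(x$params$components)
  )
}

#' Sample rupture forces under a loading schedule
#'
#' Draws rupture forces by inverse-CDF sampling of the time-inhomogeneous
#' hazard implied by the schedule. Draws whose survival extends past the end
#' of the ramp are returned censored at `F_max`.
#'
#' @inheritParams rupture_density
#' @param n Number of pulling cycles to simulate.
#' @param seed Optional integer seed (restores the RNG state afterwards).
#' @return A tibble with columns `force` (pN; `F_max` for censored rows),
#'   `censored` (logical) and `component` (ground-truth component index).
#' @export
sample_ruptures <- function(params, schedule, n, seed = NULL,
                            n_grid = 2001, kBT = KBT_DEFAULT) {
  if (n < 1) abort("`n` must be >= 1.")
  mix <- as_ds_mixture(params)
  tabs <- lapply(mix$components, ds_hazard_table, schedule = schedule,
                 kBT = kBT, n_grid = n_grid)
  with_seed(seed, {
    comp <- sample.int(length(mix$components), n, replace = TRUE,
                       prob = mix$weights)
    u <- runif(n)
    force <- numeric(n)
    censored <- logical(n)
    for (j in seq_along(tabs)) {
      idx <- which(comp == j)
      if (length(idx) == 0L) next
      tab <- tabs[[j]]
      surv <- exp(-tab$Lambda)
      cens <- u[idx] <= tab$S_end
      censored[idx] <- cens
      force[idx[cens]] <- schedule$F_max
      if (any(!cens)) {
        # survival is non-increasing on the grid; invert by interpolation
        # (ties = "ordered": survival can be flat where the hazard is ~0)
        force[idx[!cens]] <- approx(rev(surv), rev(tab$grid),
                                    xout = u[idx[!cens]],
                                    ties = "ordered")$y
      }
    }
    tibble::tibble(force = force, censored = censored, component = comp)
  })
}

#' Reconstruct the force profile implied by fitted kinetic parameters
#'
#' Tabulates the rupture rate `k(F)` up to the critical force and the
#' predicted rupture-force distribution under a pulling protocol, mirroring
#' the step in which fitted Dudko-Szabo parameters are turned back into
#' predicted force profiles. By default the distribution is evaluated at the
#' protocol's nominal constant loading rate `kappa * v`
#' ([nominal_loading_rate()]); `rate = "instantaneous"` uses the full
#' force-dependent loading rate of the compliant tether instead, and
#' `rate = <number>` any fixed rate.
#'
#' @param params A [ds_params()].
#' @param schedule A [loading_schedule()] built from a [tether_model()]
#'   (required for the nominal rate), or any schedule when
#'   `rate = "instantaneous"`.
#' @param rate `"nominal"` (default), `"instantaneous"`, or a numeric constant
#'   loading rate in pN/s.
#' @param n_grid Grid resolution.
#' @param kBT Thermal energy, pN nm.
#' @return An object of class `ds_profile`: tibble of `k(F)` (`$rate_curve`),
#'   the predicted [rupture_density()] (`$density`), and scalars
#'   `modal_force`, `mean_force`, `critical_force`, `survival`.
#' @examples
#' prof <- reconstruct_profile(ds_params(4.3, 50, 6.5),
#'                             loading_schedule(tether_model()))
#' prof$modal_force
#' @export
reconstruct_profile <- function(params, schedule, rate = "nominal",
                                n_grid = 1501, kBT = KBT_DEFAULT) {
  if (!inherits(params, "ds_params")) abort("`params` must be a `ds_params`.")
  dens_schedule <-
    if (identical(rate, "instantaneous")) {
      schedule
    } else if (is.numeric(rate)) {
      constant_schedule(rate, F_max = schedule$F_max)
    } else if (identical(rate, "nominal")) {
      if (is.null(schedule$model)) {
        abort("`rate = \"nominal\"` needs a schedule built from a tether model.")
      }
      constant_schedule(nominal_loading_rate(schedule$model),
                        F_max = schedule$F_max)
    } else {
      abort("`rate` must be \"nominal\", \"instantaneous\", or a number.")
    }
  rd <- rupture_density(params, dens_schedule, n_grid = n_grid, kBT = kBT)
  Fc <- critical_force(params, kBT)
  f_grid <- seq(0, Fc * (1 - 1e-6), length.out = n_grid)
  structure(
    list(
      rate_curve = tibble::tibble(force = f_grid,
                                  rate = ds_rate_unsafe(f_grid, params, kBT)),
      density = rd,
      modal_force = rd$mode,
      mean_force = rd$mean,
      critical_force = Fc,
      survival = rd$survival,
      params = params,
      loading_rate = dens_schedule$rate_of_force(dens_schedule$F_min)
    ),
    class = "ds_profile"
  )
}

#' @export
print.ds_profile <- function(x, ...) {
  cat("<ds_profile>\n")
  print(x$params)
  cat(sprintf("  modal force = %.3g pN, mean = %.3g pN, F_c = %.3g pN\n",
              x$modal_force, x$mean_force, x$critical_force))
  cat(sprintf("  survival past ramp = %.3g\n", x$survival))
  invisible(x)
}
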