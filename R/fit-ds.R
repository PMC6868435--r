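# Censored maximum-likelihood fitting of Dudko-Szabo rupture kinetics.
#
# The likelihood of an observed rupture force F under a loading schedule is
# the first-passage density p(F) = h(F) exp(-Lambda(F)) with hazard (in
# force) h = k(F)/Fdot(F); a cycle that survives the whole ramp contributes
# the survival S(F_max). Mixtures are fitted jointly over component
# parameters and weights.
#
# Parameterization per component: theta = (log dx, log tau0, log dG_excess)
# with dG = nu * dx * F_floor / kBT + dG_excess, where F_floor is the largest
# observed force divided by 0.95. This keeps the critical force above every
# observation by construction (the density would otherwise vanish at data
# points), replacing an explicit penalty with a smooth reparameterization.

ds_loglik_factory <- function(force, censored, schedule, n_components, nu,
                              kBT, F_floor, n_grid = 601) {
  f_obs <- force[!censored]
  n_cens <- sum(censored)
  rate_obs <- schedule$rate_of_force(f_obs)
  function(theta) {
    comps <- ds_theta_to_params(theta, n_components, nu, kBT, F_floor)
    w <- ds_theta_to_weights(theta, n_components)
    dens <- matrix(0, nrow = length(f_obs), ncol = n_components)
    surv <- numeric(n_components)
    for (i in seq_len(n_components)) {
      p <- comps[[i]]
      tab <- try(ds_hazard_table(p, schedule, kBT, n_grid), silent = TRUE)
      if (inherits(tab, "try-error")) return(-Inf)
      Lam_at <- approx(tab$grid, tab$Lambda, xout = f_obs, yright = NA)$y
      # observations above the component's Fc are impossible under it
      Lam_at[is.na(Lam_at)] <- Inf
      dens[, i] <- ds_rate_unsafe(f_obs, p, kBT) / rate_obs * exp(-Lam_at)
      surv[i] <- tab$S_end
    }
    ll <- sum(log(pmax(dens %*% w, 1e-300)))
    if (n_cens > 0) ll <- ll + n_cens * log(max(sum(w * surv), 1e-300))
    if (!is.finite(ll)) return(-Inf)
    ll
  }
}

ds_theta_to_params <- function(theta, n_components, nu, kBT, F_floor) {
  lapply(seq_len(n_components), function(i) {
    th <- theta[(3 * (i - 1) + 1):(3 * i)]
    dx <- exp(th[1])
    dG <- nu * dx * F_floor / kBT + exp(th[3])
    ds_params(dx_dagger = dx, tau0 = exp(th[2]), dG_dagger = dG, nu = nu)
  })
}

ds_theta_to_weights <- function(theta, n_components) {
  if (n_components == 1L) return(1)
  z <- c(theta[(3 * n_components + 1):length(theta)], 0)
  exp(z) / sum(exp(z))
}

ds_params_to_theta <- function(comps, weights, nu, kBT, F_floor) {
  th <- unlist(lapply(comps, function(p) {
    excess <- p$dG_dagger - nu * p$dx_dagger * F_floor / kBT
    c(log(p$dx_dagger), log(p$tau0), log(max(excess, 0.1)))
  }))
  if (length(comps) > 1L) {
    z <- log(pmax(weights, 1e-6))
    th <- c(th, z[-length(z)] - z[length(z)])
  }
  th
}

# Moment-based starting values from a block of rupture forces: Bell-like
# spread sets dx, the Bell modal-force relation sets tau0.
ds_moment_init <- function(f_block, schedule, nu, kBT, F_floor) {
  s <- max(sd(f_block), 0.5)
  dx <- min(max(1.28 * kBT / s, 0.5), 12)
  f_star <- median(f_block)
  rate <- schedule$rate_of_force(f_star)
  tau0 <- kBT / (rate * dx) * exp(f_star * dx / kBT)
  tau0 <- min(max(tau0, 1e-3), 1e8)
  dG <- nu * dx * F_floor / kBT + runif(1, 1, 8)
  ds_params(dx, tau0, dG, nu)
}

#' Fit Dudko-Szabo kinetics to rupture forces by censored maximum likelihood
#'
#' Fits a single component or a mixture of Dudko-Szabo components to raw
#' (unbinned) rupture forces observed under a loading schedule. Cycles that
#' reached the end of the ramp without rupturing enter the likelihood as
#' survival terms. Optimisation is multi-start from quantile-partitioned,
#' moment-based initialisations; uncertainties come from the observed
#' information matrix at the optimum (delta method on the natural scale).
#' Components are ordered by modal force, ties broken by weight.
#'
#' @param data A tibble with columns `force` (pN) and optionally `censored`
#'   (logical), e.g. from [sample_ruptures()] or [rupture_force_table()]; or a
#'   bare numeric vector of uncensored forces.
#' @param schedule A [loading_schedule()] or [constant_schedule()].
#' @param n_components Number of mixture components.
#' @param nu Dudko-Szabo shape parameter (1/2, 2/3 or 1).
#' @param starts Number of random multi-starts.
#' @param seed Optional seed for the start jitter.
#' @param kBT Thermal energy, pN nm.
#' @return An object of class `ds_fit`; see [tidy.ds_fit()] and
#'   [glance.ds_fit()].
#' @export
fit_ds <- function(data, schedule, n_components = 1, nu = 1 / 2,
                   starts = 20, seed = NULL, kBT = KBT_DEFAULT) {
  if (is.numeric(data)) {
    data <- tibble::tibble(force = data, censored = FALSE)
  }
  if (!all(c("force") %in% names(data))) {
    abort("`data` must contain a `force` column.")
  }
  if (!"censored" %in% names(data)) data$censored <- FALSE
  force <- data$force
  censored <- data$censored
  n_unc <- sum(!censored)
  if (n_unc < 20 * n_components) {
    abort(sprintf(
      "Insufficient data: %d uncensored ruptures for %d component(s); need >= %d.",
      n_unc, n_components, 20 * n_components))
  }
  f_obs <- force[!censored]
  F_floor <- max(f_obs) / 0.95
  loglik <- ds_loglik_factory(force, censored, schedule, n_components, nu,
                              kBT, F_floor)

  with_seed(seed, {
    qs <- quantile(f_obs, probs = seq(0, 1, length.out = n_components + 1))
    qs[1] <- qs[1] - 1e-9
    blocks <- cut(f_obs, breaks = qs, labels = FALSE, include.lowest = TRUE)
    best <- NULL
    for (s in seq_len(starts)) {
      comps0 <- lapply(seq_len(n_components), function(i) {
        p <- ds_moment_init(f_obs[blocks == i], schedule, nu, kBT, F_floor)
        # jitter around the moment guess so the starts explore the surface
        ds_params(p$dx_dagger * exp(rnorm(1, 0, 0.3)),
                  p$tau0 * exp(rnorm(1, 0, 0.6)),
                  p$dG_dagger + runif(1, -0.5, 3), nu)
      })
      w0 <- tabulate(blocks, n_components) / length(f_obs)
      th0 <- ds_params_to_theta(comps0, w0, nu, kBT, F_floor)
      fit1 <- try(optim(th0, loglik, method = "Nelder-Mead",
                        control = list(fnscale = -1, maxit = 1500)),
                  silent = TRUE)
      if (inherits(fit1, "try-error") || !is.finite(fit1$value)) next
      fit2 <- try(optim(fit1$par, loglik, method = "BFGS",
                        control = list(fnscale = -1, maxit = 200)),
                  silent = TRUE)
      cand <- if (!inherits(fit2, "try-error") &&
                  is.finite(fit2$value) && fit2$value >= fit1$value) {
        fit2
      } else {
        fit1
      }
      if (is.null(best) || cand$value > best$value) best <- cand
    }
    if (is.null(best)) {
      abort("All optimisation starts failed; check the data and schedule.")
    }

    theta <- best$par
    comps <- ds_theta_to_params(theta, n_components, nu, kBT, F_floor)
    weights <- ds_theta_to_weights(theta, n_components)

    # observed information and delta-method standard errors
    vcov_theta <- tryCatch({
      H <- optimHess(theta, loglik, control = list(fnscale = -1))
      solve(-H)
    }, error = function(e) NULL)
    natural <- function(th) {
      cs <- ds_theta_to_params(th, n_components, nu, kBT, F_floor)
      ws <- ds_theta_to_weights(th, n_components)
      unlist(lapply(seq_len(n_components), function(i) {
        c(cs[[i]]$dx_dagger, log(cs[[i]]$tau0), cs[[i]]$dG_dagger, ws[i])
      }))
    }
    se_nat <- rep(NA_real_, 4 * n_components)
    if (!is.null(vcov_theta) && all(is.finite(vcov_theta)) &&
        all(diag(vcov_theta) > 0)) {
      J <- numeric_jacobian(natural, theta)
      vn <- J %*% vcov_theta %*% t(J)
      dg <- diag(vn)
      se_nat <- ifelse(dg > 0, sqrt(pmax(dg, 0)), NA_real_)
    } else {
      warn("Observed information is singular; standard errors unavailable.")
    }

    # order components by modal force under the fitting schedule
    modes <- vapply(comps, function(p) {
      rupture_density(p, schedule, n_grid = 501, kBT = kBT)$mode
    }, numeric(1))
    ord <- order(modes, -weights)
    se_mat <- matrix(se_nat, nrow = 4)[, ord, drop = FALSE]

    structure(
      list(
        mixture = ds_mixture(comps[ord], weights[ord]),
        modal_forces = modes[ord],
        se = list(dx_dagger = se_mat[1, ], log_tau0 = se_mat[2, ],
                  dG_dagger = se_mat[3, ], weight = se_mat[4, ]),
        logLik = best$value,
        n = length(force),
        n_censored = sum(censored),
        n_components = n_components,
        nu = nu,
        kBT = kBT,
        convergence = best$convergence,
        schedule = schedule,
        data = tibble::tibble(force = force, censored = censored)
      ),
      class = "ds_fit"
    )
  })
}

numeric_jacobian <- function(fn, x, eps = 1e-5) {
  f0 <- fn(x)
  J <- matrix(0, nrow = length(f0), ncol = length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

#' @export
print.ds_fit <- function(x, ...) {
  cat(sprintf("<ds_fit> %d component(s), nu = %.3g, logLik = %.2f\n",
              x$n_components, x$nu, x$logLik))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a Dudko-Szabo fit
#'
#' @param x A `ds_fit` from [fit_ds()].
#' @param ... Unused.
#' @return A tibble with one row per component and term: `dx_dagger` (nm),
#'   `tau0` (s; its standard error is reported on the log scale in
#'   `std.error.log`), `dG_dagger` (kBT) and `weight`.
#' @method tidy ds_fit
#' @export
tidy.ds_fit <- function(x, ...) {
  comps <- x$mixture$components
  purrr::map_dfr(seq_along(comps), function(i) {
    p <- comps[[i]]
    tibble::tibble(
      component = i,
      term = c("dx_dagger", "tau0", "dG_dagger", "weight"),
      estimate = c(p$dx_dagger, p$tau0, p$dG_dagger, x$mixture$weights[i]),
      std.error = c(x$se$dx_dagger[i],
                    p$tau0 * x$se$log_tau0[i],
                    x$se$dG_dagger[i],
                    x$se$weight[i]),
      modal_force = x$modal_forces[i]
    )
  })
}

#' @rdname tidy.ds_fit
#' @method glance ds_fit
#' @export
glance.ds_fit <- function(x, ...) {
  k <- 4 * x$n_components - 1
  tibble::tibble(
    logLik = x$logLik,
    AIC = -2 * x$logLik + 2 * k,
    BIC = -2 * x$logLik + log(x$n) * k,
    n = x$n,
    n_censored = x$n_censored,
    n_components = x$n_components,
    converged = x$convergence == 0
  )
}
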