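# Shared fixtures. The default loading schedule is built once per test run;
# it is deterministic, so sharing it across tests is safe.

default_model <- tether_model()
default_sched <- loading_schedule(default_model)

# Printed kinetic parameter triples used throughout the kinetic tests:
# the sodium-solution five-repeat fit and the two six-repeat E2 clusters.
ds_na <- ds_params(dx_dagger = 4.3, tau0 = 50, dG_dagger = 6.5)
ds_strong <- ds_params(dx_dagger = 4.0, tau0 = 10990, dG_dagger = 11.6)
ds_weak <- ds_params(dx_dagger = 3.7, tau0 = 59.83, dG_dagger = 5.7)

# Independent brute-force oracle for the rupture-force distribution: Euler
# integration of dS/dt = -k(F(t)) S along the schedule at a fine time step.
# Returns survival on a force grid, interpolable to any force.
euler_survival <- function(params, schedule, dt = 1e-4,
                           kBT = fretforce:::KBT_DEFAULT) {
  tt <- seq(0, schedule$duration, by = dt)
  ff <- schedule$force_of_time(tt)
  Fc <- critical_force(params, kBT)
  kk <- ifelse(ff < Fc, fretforce:::ds_rate_unsafe(ff, params, kBT), 0)
  S <- cumprod(1 - pmin(kk * dt, 1))
  list(force = ff, survival = c(1, S[-length(S)]))
}

# Construct a noiseless half-cycle tibble with a prescribed E(F) curve on
# the default stretch ramp (20 ms sampling).
make_stretch_half <- function(E_of_force, molecule_id = "m1", cycle = 1L,
                              sched = default_sched, dt = 0.02) {
  tt <- seq(0, sched$duration, by = dt)
  ff <- sched$force_of_time(tt)
  tibble::tibble(
    molecule_id = molecule_id,
    cycle = cycle,
    t_s = tt,
    stage_nm = sched$stage_start + sched$model$stage_speed * tt,
    force_pN = ff,
    E = E_of_force(ff),
    phase = "stretch",
    partial = FALSE
  )
}
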