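#' Detection / death hazard rate
#'
#' Shifted logistic in total tumour density:
#' `lambda(N) = lambda_max / (1 + exp(-m (N - N_d)))`, half-maximal at the
#' threshold `N_d` and rapidly switching on above it.
#'
#' @param N total tumour density (vectorised).
#' @param side `"detect"` or `"death"`.
#' @param hz a [hazard_params()].
#' @return Event rate(s) per day.
#' @export
hazard_rate <- function(N, side = c("detect", "death"),
                        hz = hazard_params()) {
  side <- match.arg(side)
  stopifnot(all(N >= 0))
  m <- if (side == "detect") hz$m_detect else hz$m_death
  nd <- if (side == "detect") hz$n_detect else hz$n_death
  hz$lambda_max / (1 + exp(-m * (N - nd)))
}

#' Sample an event time along a density trajectory
#'
#' Per-step event probability `1 - exp(-lambda(N) dt)` on the trajectory's
#' time grid (exact for piecewise-constant rates and never above 1); the
#' first success is the event time.
#'
#' @param t time grid (days), equally spaced by `hz$dt`.
#' @param N total density at each grid time.
#' @param side `"detect"` or `"death"`.
#' @param hz a [hazard_params()].
#' @param u optional vector of uniform draws (one per step after the first
#'   grid point); drawn from the current RNG state when `NULL`.
#' @return The event time in days, or `NA` if no event occurs on the grid
#'   (censored).
#' @export
sample_event <- function(t, N, side = c("detect", "death"),
                         hz = hazard_params(), u = NULL) {
  side <- match.arg(side)
  stopifnot(length(t) == length(N), length(t) >= 2)
  steps <- length(t) - 1
  if (is.null(u)) u <- stats::runif(steps)
  if (length(u) < steps) stop("sample_event: too few uniform draws")
  p <- 1 - exp(-hazard_rate(N[-1], side, hz) * diff(t))
  hit <- which(u[seq_len(steps)] < p)
  if (!length(hit)) return(NA_real_)
  t[hit[1] + 1]
}

## internal: derive reproducible sub-stream seeds from one integer seed
derive_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

## internal: untreated growth trajectory on the daily hazard grid
grow_untreated <- function(pp, t_max, s0, hz) {
  hp <- pp$hierarchy
  st0 <- tumor_state(s = s0, v = rep(0, hp$n), B = 0, m = 0, t = 0)
  simulate_tumor(st0, hp, times = seq(0, t_max, by = hz$dt),
                 dp = pp$delivery, rp = pp$response)
}

## internal: post-detection trajectory under one arm's schedule
treat_from <- function(pp, state_detect, arm, dose_m0, t_max, hz) {
  sched <- standard_of_care_schedule(state_detect$t, arm, dose_m0)
  sched <- sched[sched$time <= t_max + 1e-9, , drop = FALSE]
  simulate_tumor(state_detect, pp$hierarchy,
                 times = seq(state_detect$t, t_max, by = hz$dt),
                 dp = pp$delivery, rp = pp$response, rtp = pp$rt,
                 schedule = sched)
}

## internal: assemble the outcome record for one arm
arm_outcome <- function(arm, t_detect, full_t, full_N, hz, u_death, t_max) {
  t_death <- sample_event(full_t, full_N, "death", hz, u = u_death)
  censored <- is.na(t_death)
  if (censored) t_death <- NA_real_
  survival <- if (is.na(t_detect)) NA_real_
    else if (censored) t_max - t_detect
    else t_death - t_detect
  list(arm = arm, t_detect = t_detect, t_death = t_death,
       censored = censored, survival = survival)
}

#' Simulate one virtual patient under several treatment arms
#'
#' Grows the tumour from a microscopic pure-GSC seed, samples a stochastic
#' detection time from the detection hazard, applies the arm-specific
#' standard-of-care schedule at detection, and samples a death time from
#' the death hazard evaluated along the whole density trajectory. All arms
#' of one patient share the growth trajectory, the detection draw and (by
#' default) the death draws, so between-arm differences reflect treatment
#' alone; pass `paired_deaths = FALSE` to give each arm its own death
#' stream (what an actual trial observes).
#'
#' @param pp a [patient_params()].
#' @param arms character vector from `"ctrl"`, `"single"`, `"continuous"`.
#' @param dose_m0 total AMSC amount for the BMP4 arms.
#' @param hz a [hazard_params()].
#' @param seed integer seed for the patient's stochastic draws.
#' @param t_max maximum simulation time (days); surviving patients are
#'   censored at `t_max`.
#' @param s0 initial GSC density.
#' @param paired_deaths share death draws across arms.
#' @param keep_trajectories return the per-arm density trajectories.
#' @return An object of class `patient_outcome`: a list with `outcomes`
#'   (data.frame, one row per arm: `arm`, `t_detect`, `t_death`,
#'   `survival`, `censored`), `seed`, and optionally `trajectories`.
#' @export
simulate_patient <- function(pp, arms = c("ctrl", "single", "continuous"),
                             dose_m0 = default_dose_m0("high"),
                             hz = hazard_params(), seed = 1,
                             t_max = 3650, s0 = 1e-5,
                             paired_deaths = TRUE,
                             keep_trajectories = FALSE) {
  arms <- match.arg(arms, c("ctrl", "single", "continuous"),
                    several.ok = TRUE)
  seeds <- derive_seeds(seed, 2 + length(arms))
  grid <- seq(0, t_max, by = hz$dt)
  steps <- length(grid) - 1

  growth <- grow_untreated(pp, t_max, s0, hz)
  set.seed(seeds[1])
  u_detect <- stats::runif(steps)
  t_detect <- sample_event(growth$t, growth$N, "detect", hz, u = u_detect)

  set.seed(seeds[2])
  u_death_shared <- stats::runif(steps)

  trajs <- list()
  treated_cache <- list()
  rows <- vector("list", length(arms))
  for (a in seq_along(arms)) {
    arm <- arms[a]
    if (paired_deaths) {
      u_death <- u_death_shared
    } else {
      set.seed(seeds[2 + a])
      u_death <- stats::runif(steps)
    }
    if (is.na(t_detect)) {
      full_N <- growth$N
      if (keep_trajectories) trajs[[arm]] <- growth
    } else {
      dose <- if (arm == "ctrl") 0 else dose_m0
      ## a zero dose makes every arm's schedule equivalent to control
      key <- if (dose > 0) arm else "ctrl"
      if (is.null(treated_cache[[key]]))
        treated_cache[[key]] <- treat_from(pp, state_at(growth, t_detect),
                                           arm, dose, t_max, hz)
      treated <- treated_cache[[key]]
      pre <- growth$N[growth$t < t_detect - 1e-9]
      full_N <- c(pre, treated$N)
      if (keep_trajectories) trajs[[arm]] <- treated
    }
    rows[[a]] <- arm_outcome(arm, t_detect, grid, full_N, hz,
                             u_death, t_max)
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  res <- list(outcomes = out, seed = seed, t_detect = t_detect,
              dose_m0 = dose_m0)
  if (keep_trajectories) {
    res$growth <- growth
    res$trajectories <- trajs
  }
  structure(res, class = "patient_outcome")
}

#' @export
print.patient_outcome <- function(x, ...) {
  cat("Virtual patient (seed ", x$seed, "), detection at ",
      if (is.na(x$t_detect)) "never" else paste0(x$t_detect, " d"),
      ":\n", sep = "")
  print(x$outcomes, row.names = FALSE)
  invisible(x)
}

#' Paired schedule comparison for one patient
#'
#' Convenience wrapper: simulates the control, single-dose and continuous
#' arms for one patient with fully shared stochastic draws and returns the
#' per-arm outcome table.
#'
#' @inheritParams simulate_patient
#' @return The `outcomes` data.frame of [simulate_patient()].
#' @export
simulate_patient_arms <- function(pp, dose_m0 = default_dose_m0("high"),
                                  hz = hazard_params(), seed = 1,
                                  t_max = 3650, s0 = 1e-5) {
  simulate_patient(pp, arms = c("ctrl", "single", "continuous"),
                   dose_m0 = dose_m0, hz = hz, seed = seed, t_max = t_max,
                   s0 = s0, paired_deaths = TRUE)$outcomes
}

#' Outcomes of a cohort of virtual patients
#'
#' Samples `n_patients` by Latin hypercube from the given ranges and
#' simulates each under the requested arms with per-patient seeds derived
#' from `seed`.
#'
#' @param ranges a [parameter_ranges()] table.
#' @param n_patients cohort size.
#' @param arms treatment arms to simulate.
#' @param dose_m0 total AMSC amount for BMP4 arms.
#' @param seed integer seed (drives both sampling and outcome draws).
#' @param hz a [hazard_params()].
#' @param t_max maximum simulation time (days).
#' @param paired_deaths share death draws across arms within a patient.
#' @param sampler `"lhs"` (stratified Latin hypercube, the study design)
#'   or `"iid"` (independent uniform draws, used for null calibration).
#' @return A list with `patients` (parameter draws) and `outcomes` (one row
#'   per patient and arm, with `patient` index).
#' @export
simulate_cohort <- function(ranges, n_patients, arms = c("ctrl",
                                                         "continuous"),
                            dose_m0 = default_dose_m0("high"), seed = 1,
                            hz = hazard_params(), t_max = 3650,
                            paired_deaths = TRUE,
                            sampler = c("lhs", "iid")) {
  sampler <- match.arg(sampler)
  seeds <- derive_seeds(seed, n_patients + 1)
  patients <- if (sampler == "lhs")
    lhs_sample(ranges, n_patients, seed = seeds[1])
  else uniform_sample(ranges, n_patients, seed = seeds[1])
  kin <- attr(ranges, "kinetics_unit")
  if (is.null(kin)) kin <- "day"
  res <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    pp <- patient_params(patients[i, ], kinetics_unit = kin)
    sim <- simulate_patient(pp, arms = arms, dose_m0 = dose_m0, hz = hz,
                            seed = seeds[i + 1], t_max = t_max,
                            paired_deaths = paired_deaths)
    out <- sim$outcomes
    out$patient <- i
    res[[i]] <- out
  }
  list(patients = patients, outcomes = do.call(rbind, res))
}

#' Write a cohort outcome table to CSV
#'
#' @param cohort result of [simulate_cohort()].
#' @param path output path.
#' @param seed seed to record alongside each row.
#' @return `path`, invisibly.
#' @export
write_outcomes_csv <- function(cohort, path, seed = NA) {
  out <- cohort$outcomes
  out$seed <- seed
  utils::write.csv(out[, c("patient", "arm", "t_detect", "t_death",
                           "survival", "censored", "seed")],
                   path, row.names = FALSE)
  invisible(path)
}
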