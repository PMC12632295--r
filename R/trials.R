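#' Days-gained fold change
#'
#' Trial endpoint: treated survival time divided by control survival time
#' for the same patient. Values above 1 indicate benefit; a doubling of
#' survival scores 2.
#'
#' @param survival_treatment,survival_ctrl survival times (days), both
#'   positive.
#' @return The fold change (vectorised).
#' @export
dgfc <- function(survival_treatment, survival_ctrl) {
  if (any(survival_treatment <= 0) || any(survival_ctrl <= 0))
    stop("dgfc: survival times must be positive")
  survival_treatment / survival_ctrl
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator honouring right censoring, as a right-continuous
#' non-increasing step function with `S(0) = 1`.
#'
#' @param time survival times (days).
#' @param event logical or 0/1: event observed (`TRUE`) or censored.
#' @return A data.frame of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `surv` (one row per distinct observed time).
#' @export
kaplan_meier <- function(time, event) {
  if (!length(time)) stop("kaplan_meier: empty input")
  stopifnot(length(time) == length(event))
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  structure(out, class = c("km_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km a [kaplan_meier()] curve.
#' @param t times at which to evaluate.
#' @return Survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- which(km$time <= tt + 1e-12)
    if (!length(i)) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' Two-sample log-rank test
#'
#' Two-sided log-rank p-value with censoring. Degenerate inputs (no events,
#' or identical arms) return p = 1.
#'
#' @param time_a,event_a survival times and event indicators, arm A.
#' @param time_b,event_b survival times and event indicators, arm B.
#' @return A list with `chisq` and `p`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b))
    stop("logrank_test: empty arm")
  time <- c(time_a, time_b)
  event <- as.integer(c(event_a, event_b))
  grp <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  if (sum(event) == 0)
    return(list(chisq = 0, p = 1))
  fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chisq <- unname(fit$chisq)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Write a Kaplan-Meier curve as a CSV step table
#'
#' @param km a [kaplan_meier()] curve.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_km_csv <- function(km, path) {
  utils::write.csv(as.data.frame(km), path, row.names = FALSE)
  invisible(path)
}

#' Median survival from a Kaplan-Meier curve
#'
#' First time at which the survival curve drops to 0.5 or below; `t_max`
#' conventions are the caller's (an undefined median, curve never reaching
#' 0.5, returns `Inf`).
#'
#' @param km a [kaplan_meier()] curve.
#' @return Median survival time.
#' @export
km_median <- function(km) {
  i <- which(km$surv <= 0.5)
  if (!length(i)) Inf else km$time[min(i)]
}

#' Run one virtual clinical trial
#'
#' Samples a cohort by Latin hypercube, simulates a control arm and a
#' continuous-BMP4 arm on the same virtual patients (shared growth and
#' detection; each arm observes its own death draws, as a real trial
#' would), and compares arms by the two-sided log-rank test. The trial is
#' successful when `p < 0.05` and the treated arm's median survival is no
#' worse than control's.
#'
#' @param ranges a [parameter_ranges()] table (possibly stratified).
#' @param n_patients patients per arm.
#' @param dose_m0 total AMSC amount in the treated arm.
#' @param seed integer seed.
#' @param hz a [hazard_params()].
#' @param t_max maximum simulation time (days).
#' @param paired_patients if `TRUE` (the trial design used throughout),
#'   both arms contain exactly the same virtual patients, which makes the
#'   unpaired log-rank comparison conservative; `FALSE` draws an
#'   independent cohort for each arm, the design under which the test's
#'   nominal type-I rate applies (used for null calibration).
#' @return An object of class `trial_result`: list with `outcomes` (per
#'   patient and arm), `km` (per-arm curves), `p`, `success`, `medians`,
#'   `n`, `seed`, `dose_m0`.
#' @export
run_virtual_trial <- function(ranges, n_patients = 20,
                              dose_m0 = default_dose_m0("high"), seed = 1,
                              hz = hazard_params(), t_max = 3650,
                              paired_patients = TRUE,
                              sampler = c("lhs", "iid")) {
  sampler <- match.arg(sampler)
  if (paired_patients) {
    cohort <- simulate_cohort(ranges, n_patients,
                              arms = c("ctrl", "continuous"),
                              dose_m0 = dose_m0, seed = seed, hz = hz,
                              t_max = t_max, paired_deaths = FALSE,
                              sampler = sampler)
    out <- cohort$outcomes
    patients <- cohort$patients
  } else {
    seeds <- derive_seeds(seed, 2)
    ca <- simulate_cohort(ranges, n_patients, arms = "ctrl",
                          dose_m0 = 0, seed = seeds[1], hz = hz,
                          t_max = t_max, sampler = sampler)
    cb <- simulate_cohort(ranges, n_patients, arms = "continuous",
                          dose_m0 = dose_m0, seed = seeds[2], hz = hz,
                          t_max = t_max, sampler = sampler)
    cb$outcomes$patient <- cb$outcomes$patient + n_patients
    out <- rbind(ca$outcomes, cb$outcomes)
    patients <- rbind(ca$patients, cb$patients)
  }
  ## undetected patients contribute no survival time to either arm
  keep <- !is.na(out$survival)
  out <- out[keep, , drop = FALSE]
  ctrl <- out[out$arm == "ctrl", ]
  trt <- out[out$arm == "continuous", ]
  if (!nrow(ctrl) || !nrow(trt)) {
    lr <- list(chisq = 0, p = 1)
    km <- list()
    medians <- c(ctrl = NA_real_, continuous = NA_real_)
    success <- FALSE
  } else {
    lr <- logrank_test(ctrl$survival, !ctrl$censored,
                       trt$survival, !trt$censored)
    km <- list(ctrl = kaplan_meier(ctrl$survival, !ctrl$censored),
               continuous = kaplan_meier(trt$survival, !trt$censored))
    medians <- c(ctrl = km_median(km$ctrl),
                 continuous = km_median(km$continuous))
    success <- lr$p < 0.05 && medians["continuous"] >= medians["ctrl"]
  }
  structure(list(outcomes = out, patients = patients, km = km,
                 p = lr$p, chisq = lr$chisq, medians = medians,
                 success = unname(success), n = n_patients, seed = seed,
                 dose_m0 = dose_m0),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("Virtual trial: n =", x$n, "per arm, dose_m0 =", signif(x$dose_m0, 4),
      "\n  log-rank p =", signif(x$p, 3),
      "; medians (ctrl, continuous) =", x$medians[1], ",", x$medians[2],
      "\n  success:", x$success, "\n")
  invisible(x)
}

#' Run a series of virtual trials
#'
#' Repeats [run_virtual_trial()] with independent per-trial seeds and
#' returns the per-trial summary. When `checkpoint_dir` is given, each
#' trial's summary row is written to `trial_<i>.csv` as it completes and
#' existing checkpoints are reused, making an interrupted series resumable.
#'
#' @param ranges a [parameter_ranges()] table.
#' @param n_trials number of trials.
#' @param n_patients patients per arm in each trial.
#' @param dose_m0 total AMSC amount in the treated arm.
#' @param seed integer seed for the series.
#' @param hz a [hazard_params()].
#' @param t_max maximum simulation time (days).
#' @param checkpoint_dir optional directory for per-trial checkpoints.
#' @return A data.frame with one row per trial: `trial`, `p`, `success`,
#'   `median_ctrl`, `median_treatment`, `seed`.
#' @export
run_trial_series <- function(ranges, n_trials = 20, n_patients = 20,
                             dose_m0 = default_dose_m0("high"), seed = 1,
                             hz = hazard_params(), t_max = 3650,
                             checkpoint_dir = NULL) {
  seeds <- derive_seeds(seed, n_trials)
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    ck <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, sprintf("trial_%03d.csv", i)) else NULL
    if (!is.null(ck) && file.exists(ck)) {
      rows[[i]] <- utils::read.csv(ck)
      next
    }
    tr <- run_virtual_trial(ranges, n_patients, dose_m0, seed = seeds[i],
                            hz = hz, t_max = t_max)
    rows[[i]] <- data.frame(trial = i, p = tr$p, success = tr$success,
                            median_ctrl = tr$medians[["ctrl"]],
                            median_treatment = tr$medians[["continuous"]],
                            seed = seeds[i])
    if (!is.null(ck)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(rows[[i]], ck, row.names = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Stratify the virtual-patient population into trial cohorts
#'
#' Splits the GSC proliferation rate `ms` and self-renewal sensitivity
#' `psi` ranges at their midpoints into bottom/top halves and returns the
#' four stratified cohorts plus the unstratified one; all other parameters
#' keep their full ranges.
#'
#' @param ranges the full [parameter_ranges()] table.
#' @return A named list of five `parameter_ranges` tables:
#'   `insensitive_slow`, `insensitive_fast`, `sensitive_slow`,
#'   `sensitive_fast`, `unstratified`.
#' @export
stratify_cohorts <- function(ranges) {
  half <- function(rng, par, which) {
    i <- match(par, rng$parameter)
    if (is.na(i) || rng$lower[i] == rng$upper[i])
      stop("stratify_cohorts: ", par, " must be a sampled parameter")
    mid <- (rng$lower[i] + rng$upper[i]) / 2
    if (which == "low") rng$upper[i] <- mid else rng$lower[i] <- mid
    rng
  }
  list(
    insensitive_slow = half(half(ranges, "ms", "low"), "psi", "low"),
    insensitive_fast = half(half(ranges, "ms", "high"), "psi", "low"),
    sensitive_slow = half(half(ranges, "ms", "low"), "psi", "high"),
    sensitive_fast = half(half(ranges, "ms", "high"), "psi", "high"),
    unstratified = ranges
  )
}

#' Simulate the days-gained cohort
#'
#' Samples a large virtual-patient cohort, simulates the control and
#' continuous-BMP4 arms with fully paired draws, and returns each patient's
#' parameters, per-arm survival and DGFC score. Patients whose tumour is
#' never detected carry `NA` survival and are excluded from the DGFC
#' column's complete cases.
#'
#' @param ranges a [parameter_ranges()] table.
#' @param n_patients cohort size.
#' @param dose_m0 total AMSC amount in the treated arm.
#' @param seed integer seed.
#' @param hz a [hazard_params()].
#' @param t_max maximum simulation time (days).
#' @return A data.frame: one row per patient with the sampled parameters,
#'   `survival_ctrl`, `survival_treatment`, `censored_ctrl`,
#'   `censored_treatment` and `dgfc`.
#' @export
simulate_dgfc_cohort <- function(ranges, n_patients = 1000,
                                 dose_m0 = default_dose_m0("high"),
                                 seed = 1, hz = hazard_params(),
                                 t_max = 3650) {
  cohort <- simulate_cohort(ranges, n_patients,
                            arms = c("ctrl", "continuous"),
                            dose_m0 = dose_m0, seed = seed, hz = hz,
                            t_max = t_max, paired_deaths = TRUE)
  out <- cohort$outcomes
  ctrl <- out[out$arm == "ctrl", ]
  trt <- out[out$arm == "continuous", ]
  df <- cohort$patients
  df$survival_ctrl <- ctrl$survival[order(ctrl$patient)]
  df$survival_treatment <- trt$survival[order(trt$patient)]
  df$censored_ctrl <- ctrl$censored[order(ctrl$patient)]
  df$censored_treatment <- trt$censored[order(trt$patient)]
  ok <- !is.na(df$survival_ctrl) & df$survival_ctrl > 0 &
    !is.na(df$survival_treatment)
  df$dgfc <- NA_real_
  df$dgfc[ok] <- dgfc(df$survival_treatment[ok], df$survival_ctrl[ok])
  df
}
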