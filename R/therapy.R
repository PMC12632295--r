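#' AMSC / BMP4 delivery kinetics
#'
#' Right-hand side of the delivery subsystem: AMSCs decay exponentially
#' (optionally replenished by an infusion), release BMP4 at rate `c_rel`,
#' and BMP4 is taken up by GSCs and decays.
#'
#' @param m AMSC density.
#' @param B BMP4 concentration (ng/mL).
#' @param s GSC density (uptake sink).
#' @param dp a [delivery_params()].
#' @param infusion AMSC source rate (units per day).
#' @return A list with components `dm` and `dB`.
#' @export
bmp4_rhs <- function(m, B, s, dp, infusion = 0) {
  stopifnot(m >= 0, B >= 0, s >= 0, infusion >= 0)
  list(dm = infusion - dp$delta_m * m,
       dB = dp$c_rel * m - dp$u_b * B * s - dp$delta_b * B)
}

#' GSC self-renewal probability under BMP4
#'
#' A decreasing saturating response: `Ps = Psmin + (Psmax - Psmin) /
#' (1 + psi * B)`. Self-renewal is maximal without BMP4 and approaches
#' `Psmin` as the concentration (or the sensitivity `psi`) grows.
#'
#' @param B BMP4 concentration (ng/mL).
#' @param rp a [response_params()].
#' @param psmin,psmax self-renewal bounds.
#' @return Self-renewal probability in `[psmin, psmax]`.
#' @export
self_renewal_probability <- function(B, rp, psmin, psmax) {
  stopifnot(all(B >= 0), psmin <= psmax)
  psmin + (psmax - psmin) / (1 + rp$psi * B)
}

#' Unit triangle weight
#'
#' Piecewise-linear triangle of unit height and half-width: `1 + x` on
#' `[-1, 0)`, `1 - x` on `[0, 1)`, zero elsewhere.
#'
#' @param x numeric vector.
#' @return Triangle weights.
#' @export
triangle_weight <- function(x) {
  ifelse(x >= -1 & x < 0, 1 + x, ifelse(x >= 0 & x < 1, 1 - x, 0))
}

#' Differentiation distribution over progenitor compartments
#'
#' The proportion of GSC divisions differentiating into each compartment
#' `i = 1..n` is a unit triangle centred at `theta = 1 + phi * B`, so that
#' without BMP4 all differentiation enters compartment 1. Mass that would
#' fall past compartment `n` is assigned to the terminal compartment
#' ("straight to TDCs") and the vector is renormalised to sum to 1.
#'
#' @param B BMP4 concentration (ng/mL).
#' @param phi compartment sensitivity (per ng/mL).
#' @param n number of compartments.
#' @return Length-`n` probability vector.
#' @export
compartment_distribution <- function(B, phi, n) {
  stopifnot(B >= 0, phi >= 0)
  if (n < 1) stop("compartment_distribution: n must be at least 1")
  theta <- 1 + phi * B
  r <- triangle_weight(seq_len(n) - theta)
  j <- n + 1
  while (j < theta + 1) {
    r[n] <- r[n] + triangle_weight(j - theta)
    j <- j + 1
  }
  if (sum(r) <= 0) r[n] <- 1
  r / sum(r)
}

#' Linear-quadratic survival of a radiotherapy fraction
#'
#' Surviving fraction after a single dose `d` Gy:
#' `exp(-Pi * (alpha d + beta d^2))` with `beta = alpha / 10` and a
#' compartment-specific radioprotection multiplier `Pi` on the exponent.
#'
#' @param d dose in Gy (non-negative).
#' @param alpha linear kill coefficient (per Gy).
#' @param protection radioprotection multiplier `Pi` (1 for progenitors,
#'   `eta` for GSCs, `mu` for TDCs).
#' @return Surviving fraction in `(0, 1]`.
#' @export
rt_survival_fraction <- function(d, alpha, protection = 1) {
  if (any(d < 0)) stop("rt_survival_fraction: negative dose")
  beta <- alpha / 10
  exp(-protection * (alpha * d + beta * d^2))
}

#' Apply one radiotherapy fraction to a tumour state
#'
#' Instantaneous per-compartment kill: GSCs survive with protection `eta`,
#' proliferative progenitors with protection 1, TDCs with protection `mu`.
#' BMP4 and AMSC concentrations are unchanged.
#'
#' @param state a [tumor_state()].
#' @param rtp an [rt_params()].
#' @param d dose in Gy.
#' @return The post-fraction [tumor_state()].
#' @export
apply_rt_fraction <- function(state, rtp, d) {
  n <- length(state$v)
  v <- state$v
  v[seq_len(n - 1)] <- v[seq_len(n - 1)] *
    rt_survival_fraction(d, rtp$alpha, 1)
  v[n] <- v[n] * rt_survival_fraction(d, rtp$alpha, rtp$mu)
  tumor_state(s = state$s * rt_survival_fraction(d, rtp$alpha, rtp$eta),
              v = v, B = state$B, m = state$m, t = state$t)
}

#' Apply surgical resection
#'
#' Instantaneous removal of a fixed fraction of every cellular compartment
#' (default 91.7%), leaving compartment proportions, BMP4 and AMSCs
#' unchanged.
#'
#' @param state a [tumor_state()].
#' @param extent fraction removed, in `[0, 1)`.
#' @return The post-resection [tumor_state()].
#' @export
apply_resection <- function(state, extent = 0.917) {
  if (extent < 0 || extent >= 1)
    stop("apply_resection: extent must be in [0, 1)")
  tumor_state(s = state$s * (1 - extent), v = state$v * (1 - extent),
              B = state$B, m = state$m, t = state$t)
}

#' Standard-of-care treatment schedule
#'
#' Immediate resection at detection; 30 radiotherapy fractions of 2 Gy in a
#' 5-days-on / 2-days-off pattern starting 30 days after resection (60 Gy
#' total over six weeks). The BMP4 arm adds either a single AMSC bolus of
#' `dose_m0` at resection or a constant infusion from resection to the last
#' fraction delivering the same total amount.
#'
#' @param t_detect detection (resection) time in days.
#' @param arm `"ctrl"`, `"single"` or `"continuous"`.
#' @param dose_m0 total AMSC amount delivered (ignored for `"ctrl"`).
#' @param resection_extent fraction of tumour removed at surgery.
#' @return A data.frame of class `treatment_schedule` with columns `time`,
#'   `kind`, `magnitude`, ordered by time.
#' @export
standard_of_care_schedule <- function(t_detect, arm = c("ctrl", "single",
                                                        "continuous"),
                                      dose_m0 = 0,
                                      resection_extent = 0.917) {
  arm <- match.arg(arm)
  stopifnot(t_detect >= 0, dose_m0 >= 0)
  ## 5 on / 2 off for six weeks: day offsets within the RT course
  offsets <- as.vector(outer(0:4, 7 * (0:5), `+`))
  rt_times <- t_detect + 30 + offsets
  ev <- data.frame(time = c(t_detect, rt_times),
                   kind = c("resection", rep("rt_fraction", 30)),
                   magnitude = c(resection_extent, rep(2, 30)),
                   stringsAsFactors = FALSE)
  t_rt_end <- max(rt_times)
  if (arm == "single" && dose_m0 > 0) {
    ev <- rbind(ev, data.frame(time = t_detect, kind = "bmp4_bolus",
                               magnitude = dose_m0))
  } else if (arm == "continuous" && dose_m0 > 0) {
    rate <- dose_m0 / (t_rt_end - t_detect)
    ev <- rbind(ev,
                data.frame(time = t_detect, kind = "infusion_start",
                           magnitude = rate),
                data.frame(time = t_rt_end, kind = "infusion_stop",
                           magnitude = 0))
  }
  ev <- ev[order(ev$time, ev$kind), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, arm = arm, t_detect = t_detect,
            class = c("treatment_schedule", "data.frame"))
}

#' Serialise a schedule to JSON
#'
#' @param schedule a [standard_of_care_schedule()] or compatible data.frame.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
schedule_to_json <- function(schedule, path = NULL) {
  txt <- jsonlite::toJSON(as.data.frame(schedule), digits = NA,
                          pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a schedule from JSON
#'
#' @param path path to a JSON event list written by [schedule_to_json()].
#' @return A `treatment_schedule` data.frame.
#' @export
schedule_from_json <- function(path) {
  ev <- jsonlite::fromJSON(path)
  stopifnot(all(c("time", "kind", "magnitude") %in% names(ev)))
  ev <- ev[order(ev$time, ev$kind), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("treatment_schedule", "data.frame"))
}

#' Default AMSC dose magnitudes
#'
#' The total AMSC amount equivalent to the in-vitro exposure is not known,
#' so the dose levels are calibrated against the self-renewal response
#' curve: the "high" dose gives, for median delivery kinetics, a
#' quasi-steady BMP4 concentration of `target_b` ng/mL during a continuous
#' infusion over the resection-to-end-of-RT window. The default `target_b`
#' of 10 ng/mL sits in the middle of the response's dynamic range for the
#' sampled sensitivity values (`psi * B` of order 1 at the median `psi`),
#' so patient-to-patient differences in sensitivity translate into
#' differences in outcome rather than saturating. The "low" dose is one
#' tenth of the high dose.
#'
#' @param level `"high"` or `"low"`.
#' @param dp a [delivery_params()] with the kinetics to calibrate against
#'   (defaults to median Table-range values).
#' @param target_b target plateau BMP4 concentration (ng/mL).
#' @param duration infusion window length (days): resection to last
#'   fraction under the standard-of-care layout.
#' @return Total AMSC amount (arbitrary units).
#' @export
default_dose_m0 <- function(level = c("high", "low"),
                            dp = delivery_params(),
                            target_b = 10, duration = 69) {
  level <- match.arg(level)
  ## plateau: B* = c_rel * m* / delta_b with m* = (m0/duration) / delta_m
  m0 <- target_b * duration * dp$delta_m * dp$delta_b / dp$c_rel
  if (level == "low") m0 / 10 else m0
}
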