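#' Tumour state at a time point
#'
#' @param s GSC density (fraction of carrying capacity).
#' @param v numeric vector of progenitor densities, compartments `1..n`;
#'   the last entry is the terminally differentiated (TDC) compartment.
#' @param B BMP4 concentration (ng/mL).
#' @param m AMSC density (arbitrary units).
#' @param t time (days).
#' @return An object of class `tumor_state`.
#' @export
tumor_state <- function(s, v, B = 0, m = 0, t = 0) {
  stopifnot(is.numeric(s), length(s) == 1, is.numeric(v), length(v) >= 2)
  if (!all(is.finite(c(t, s, v, B, m))))
    stop("tumor_state: non-finite components")
  if (s < 0 || any(v < 0) || B < 0 || m < 0)
    stop("tumor_state: negative densities or concentrations")
  structure(list(t = t, s = s, v = as.numeric(v), B = B, m = m),
            class = "tumor_state")
}

#' @export
print.tumor_state <- function(x, ...) {
  cat("Tumour state at t =", x$t, "d: s =", signif(x$s, 4),
      ", N =", signif(total_density(x), 4),
      ", B =", signif(x$B, 4), "ng/mL, m =", signif(x$m, 4), "\n")
  invisible(x)
}

#' Total tumour density
#'
#' `N = s + sum(v)`, the quantity that drives crowding and the detection and
#' death hazards.
#'
#' @param state a [tumor_state()].
#' @return Total cell density.
#' @export
total_density <- function(state) {
  state$s + sum(state$v)
}

#' Hierarchy right-hand side
#'
#' Reference implementation of the hierarchy rate equations for a given
#' self-renewal probability `Ps` and differentiation distribution `r`. The
#' integrator uses a compiled equivalent; this function is the documented
#' contract and is tested against it.
#'
#' @param state a [tumor_state()].
#' @param hp a [hierarchy_params()].
#' @param Ps GSC self-renewal probability in `[0, 1]`.
#' @param r differentiation distribution over compartments (length `n`,
#'   non-negative, summing to 1).
#' @return A list with components `ds` and `dv` (length `n`).
#' @export
hierarchy_rhs <- function(state, hp, Ps, r) {
  n <- hp$n
  if (length(r) != n) stop("hierarchy_rhs: r must have length n")
  if (any(r < 0) || abs(sum(r) - 1) > 1e-8)
    stop("hierarchy_rhs: r must be a distribution (sum 1)")
  if (Ps < 0 || Ps > 1) stop("hierarchy_rhs: Ps outside [0, 1]")
  s <- state$s; v <- state$v
  if (!all(is.finite(c(s, v)))) stop("hierarchy_rhs: non-finite state")
  N <- s + sum(v)
  crowd <- 1 - N / hp$K
  mi <- hp$mis * hp$ms
  d_i <- hp$delta_is * hp$delta_s
  d_n <- hp$delta_ns * d_i
  grow <- hp$ms * s * crowd
  diff <- 2 * (1 - Ps) * grow
  ds <- (2 * Ps - 1) * grow - hp$delta_s * s
  dv <- numeric(n)
  dv[1] <- r[1] * diff - mi * v[1] * crowd - d_i * v[1]
  if (n > 2) {
    i <- 2:(n - 1)
    dv[i] <- r[i] * diff + 2 * mi * v[i - 1] * crowd -
      mi * v[i] * crowd - d_i * v[i]
  }
  dv[n] <- r[n] * diff + 2 * mi * v[n - 1] * crowd - d_n * v[n]
  list(ds = ds, dv = dv)
}

## internal: parameter vector in the layout expected by the compiled RHS
param_vector <- function(hp, dp = NULL, rp = NULL,
                         infusion = 0, ps_fixed = -1, hold_b = FALSE) {
  if (is.null(dp)) dp <- delivery_params(0, 0, 0, 0)
  if (is.null(rp)) rp <- response_params(0, 0)
  c(n = hp$n, ms = hp$ms, mis = hp$mis, delta_s = hp$delta_s,
    delta_is = hp$delta_is, delta_ns = hp$delta_ns, K = hp$K,
    psmax = hp$psmax, psmin = hp$psmin, psi = rp$psi, phi = rp$phi,
    delta_m = dp$delta_m, delta_b = dp$delta_b, c_rel = dp$c_rel,
    u_b = dp$u_b, infusion = infusion, ps_fixed = ps_fixed,
    hold_b = as.numeric(hold_b))
}

state_to_y <- function(state, n) {
  if (length(state$v) != n) stop("state has wrong number of compartments")
  c(state$s, state$v, state$B, state$m)
}

y_to_state <- function(y, n, t) {
  tumor_state(s = max(y[1], 0), v = pmax(y[2:(n + 1)], 0),
              B = max(y[n + 2], 0), m = max(y[n + 3], 0), t = t)
}

## internal: one smooth integration segment (no discontinuities inside)
integrate_segment <- function(y0, times, pv, rtol, atol) {
  if (length(times) == 1) return(matrix(y0, nrow = 1))
  out <- deSolve::ode(y = y0, times = times, func = "gbmtwin_rhs",
                      parms = pv, dllname = "gbmtwin",
                      initfunc = "gbmtwin_init", method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failed (istate = ", attr(out, "istate")[1], ")")
  y <- unname(out[, -1, drop = FALSE])
  ## floor tiny negative values produced by the tolerance of the solver
  y[y < 0 & y > -1e-12] <- 0
  if (any(y < 0)) y[y < 0] <- 0
  y
}

#' Integrate the tumour model
#'
#' Integrates the coupled hierarchy + BMP4 delivery system with a
#' stiff-capable adaptive solver, restarting at every scheduled event so
#' that instantaneous operators (radiotherapy fractions, resection, AMSC
#' boluses) and infusion switches apply cleanly between smooth segments.
#'
#' @param state0 initial [tumor_state()].
#' @param hp a [hierarchy_params()].
#' @param times increasing vector of output times (days), starting at
#'   `state0$t`.
#' @param dp a [delivery_params()] (`NULL` freezes B and m at 0 dynamics).
#' @param rp a [response_params()] (`NULL` means no BMP4 response).
#' @param rtp an [rt_params()]; required when the schedule contains
#'   radiotherapy fractions.
#' @param schedule a [standard_of_care_schedule()] or any data.frame of
#'   events with columns `time`, `kind`, `magnitude`; `NULL` for free growth.
#' @param ps_fixed if non-`NULL`, hold the self-renewal probability at this
#'   value instead of the BMP4 response curve (in-vitro control media).
#' @param hold_b if `TRUE`, freeze the BMP4 and AMSC concentrations (bath
#'   conditions with media exchange).
#' @param rtol,atol solver tolerances.
#' @return A data.frame of class `tumor_trajectory` with columns `t`, `s`,
#'   `v1..vn`, `B`, `m`, `N` at the requested times.
#' @export
simulate_tumor <- function(state0, hp, times, dp = NULL, rp = NULL,
                           rtp = NULL, schedule = NULL, ps_fixed = NULL,
                           hold_b = FALSE, rtol = 1e-8, atol = 1e-10) {
  stopifnot(!is.unsorted(times, strictly = TRUE))
  if (abs(times[1] - state0$t) > 1e-9)
    stop("times must start at state0$t")
  n <- hp$n
  psf <- if (is.null(ps_fixed)) -1 else ps_fixed
  y <- state_to_y(state0, n)

  ev <- if (is.null(schedule) || nrow(schedule) == 0) {
    data.frame(time = numeric(0), kind = character(0),
               magnitude = numeric(0))
  } else {
    schedule[order(schedule$time), , drop = FALSE]
  }
  if (nrow(ev) && (min(ev$time) < times[1] - 1e-9 ||
                   max(ev$time) > times[length(times)] + 1e-9))
    stop("schedule events outside the integration interval")

  bounds <- sort(unique(c(times[1], ev$time, times[length(times)])))
  infusion <- 0
  rows <- matrix(NA_real_, nrow = length(times), ncol = n + 3)
  idx_map <- stats::setNames(seq_along(times), sprintf("%.6f", times))
  place <- function(tt, yy) {
    idx <- idx_map[sprintf("%.6f", tt)]
    idx <- idx[!is.na(idx)]
    if (length(idx)) rows[idx, ] <<- yy
  }
  place(times[1], y)

  for (k in seq_len(length(bounds) - 1)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    ## apply instantaneous events scheduled at t0
    here <- ev[abs(ev$time - t0) < 1e-9, , drop = FALSE]
    for (j in seq_len(nrow(here))) {
      kind <- here$kind[j]; mag <- here$magnitude[j]
      if (kind == "resection") {
        y[1:(n + 1)] <- y[1:(n + 1)] * (1 - mag)
      } else if (kind == "rt_fraction") {
        if (is.null(rtp)) stop("rt_fraction event but no rt_params given")
        st <- y_to_state(y, n, t0)
        st <- apply_rt_fraction(st, rtp, mag)
        y <- state_to_y(st, n)
      } else if (kind == "bmp4_bolus") {
        y[n + 3] <- y[n + 3] + mag
      } else if (kind == "infusion_start") {
        infusion <- mag
      } else if (kind == "infusion_stop") {
        infusion <- 0
      } else stop("unknown schedule event kind: ", kind)
    }
    place(t0, y)
    seg_times <- sort(unique(c(t0, times[times > t0 + 1e-9 &
                                           times < t1 - 1e-9], t1)))
    pv <- param_vector(hp, dp, rp, infusion = infusion, ps_fixed = psf,
                       hold_b = hold_b)
    yseg <- integrate_segment(y, seg_times, pv, rtol, atol)
    idx <- idx_map[sprintf("%.6f", seg_times)]
    keep <- !is.na(idx)
    rows[idx[keep], ] <- yseg[keep, , drop = FALSE]
    y <- yseg[nrow(yseg), ]
  }
  ## events scheduled exactly at the final time
  here <- ev[abs(ev$time - bounds[length(bounds)]) < 1e-9, , drop = FALSE]
  for (j in seq_len(nrow(here))) {
    kind <- here$kind[j]; mag <- here$magnitude[j]
    if (kind == "resection") y[1:(n + 1)] <- y[1:(n + 1)] * (1 - mag)
    if (kind == "rt_fraction") {
      st <- apply_rt_fraction(y_to_state(y, n, bounds[length(bounds)]),
                              rtp, mag)
      y <- state_to_y(st, n)
    }
    if (kind == "bmp4_bolus") y[n + 3] <- y[n + 3] + mag
    place(bounds[length(bounds)], y)
  }

  if (anyNA(rows)) stop("internal error: unfilled output rows")
  if (!all(is.finite(rows))) stop("non-finite trajectory values")
  traj <- as.data.frame(rows)
  names(traj) <- c("s", paste0("v", seq_len(n)), "B", "m")
  traj <- cbind(t = times, traj)
  traj$N <- traj$s + rowSums(traj[, paste0("v", seq_len(n)), drop = FALSE])
  class(traj) <- c("tumor_trajectory", "data.frame")
  traj
}

#' Extract the tumour state at a trajectory row
#'
#' @param traj a trajectory from [simulate_tumor()].
#' @param t time (days); must be one of the trajectory's output times.
#' @return A [tumor_state()].
#' @export
state_at <- function(traj, t) {
  i <- which(abs(traj$t - t) < 1e-9)
  if (!length(i)) stop("time ", t, " not in trajectory")
  i <- i[1]
  n <- sum(grepl("^v[0-9]+$", names(traj)))
  tumor_state(s = traj$s[i],
              v = as.numeric(traj[i, paste0("v", seq_len(n))]),
              B = traj$B[i], m = traj$m[i], t = traj$t[i])
}

#' Write a trajectory to CSV
#'
#' Columns `t`, `s`, `v1..vn`, `B`, `m`, `N`.
#'
#' @param traj a trajectory from [simulate_tumor()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
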