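#' Hierarchy model parameters
#'
#' Parameters of the compartmental hierarchy of glioma stem cells (GSCs),
#' progenitor cells (PCs) with finite replicative capacity, and terminally
#' differentiated cells (TDCs). All rates are per day; densities are
#' fractions of the carrying capacity `K` (normalised to 1 by default).
#'
#' @param ms GSC proliferation rate (per day). For a cell line with doubling
#'   time `d` hours, `ms = log(2) / (d / 24)`.
#' @param mis PC-to-GSC proliferation ratio; every proliferative compartment
#'   uses the same rate `mi = mis * ms`.
#' @param delta_s GSC death rate (per day).
#' @param delta_is PC death multiplier: `delta_i = delta_is * delta_s` for
#'   compartments `1..n-1`.
#' @param delta_ns TDC death multiplier: `delta_n = delta_ns * delta_i`.
#' @param K carrying capacity of the crowding term.
#' @param n proliferative capacity: number of progenitor compartments, the
#'   n-th being the post-mitotic TDC compartment.
#' @param psmax,psmin maximum and minimum GSC self-renewal probabilities.
#'
#' @return An object of class `hierarchy_params`.
#' @export
hierarchy_params <- function(ms, mis = 2, delta_s = 0, delta_is = 1,
                             delta_ns = 1, K = 1, n = 10,
                             psmax = 1, psmin = 0) {
  stopifnot(is.numeric(ms), ms >= 0, mis >= 0,
            delta_s >= 0, delta_is >= 0, delta_ns >= 0,
            K > 0, n >= 2, n == as.integer(n),
            psmin >= 0, psmin <= psmax, psmax <= 1)
  structure(list(ms = ms, mis = mis, delta_s = delta_s,
                 delta_is = delta_is, delta_ns = delta_ns,
                 K = K, n = as.integer(n), psmax = psmax, psmin = psmin),
            class = "hierarchy_params")
}

#' BMP4 delivery (AMSC) kinetic parameters
#'
#' AMSCs decay exponentially after implantation and release BMP4, which is
#' taken up by GSCs and decays. All rates are per day: with the default
#' `delta_m = delta_b = 0.5`/day a bolus of AMSCs yields a BMP4 peak at
#' 48 hours and AMSC persistence of roughly two weeks, matching reported
#' rodent kinetics.
#'
#' @param delta_m AMSC decay rate (per day).
#' @param delta_b BMP4 decay rate (per day).
#' @param c_rel BMP4 release rate per unit AMSC density (per day).
#' @param u_b BMP4 uptake rate by GSCs (per day per unit GSC density).
#' @return An object of class `delivery_params`.
#' @export
delivery_params <- function(delta_m = 0.5, delta_b = 0.5,
                            c_rel = 0.55, u_b = 0.55) {
  stopifnot(delta_m >= 0, delta_b >= 0, c_rel >= 0, u_b >= 0)
  structure(list(delta_m = delta_m, delta_b = delta_b,
                 c_rel = c_rel, u_b = u_b),
            class = "delivery_params")
}

#' BMP4 response parameters
#'
#' `psi` controls how strongly BMP4 suppresses GSC self-renewal; `phi`
#' controls how far down the hierarchy newly differentiated progenitors are
#' placed (larger `phi` pushes GSC daughters closer to the terminal
#' compartment). Both are per ng/mL of BMP4.
#'
#' @param psi GSC self-renewal sensitivity (per ng/mL).
#' @param phi compartment sensitivity (per ng/mL).
#' @return An object of class `response_params`.
#' @export
response_params <- function(psi, phi) {
  stopifnot(psi >= 0, phi >= 0)
  structure(list(psi = psi, phi = phi), class = "response_params")
}

#' Radiotherapy (linear-quadratic) parameters
#'
#' Survival of a 2 Gy-scale fraction follows the linear-quadratic model with
#' the quadratic coefficient fixed at `beta = alpha / 10`. Compartments
#' differ by a multiplicative radioprotection factor on the exponent:
#' GSCs use `eta`, TDCs use `mu`, proliferative progenitors use 1.
#'
#' @param alpha linear kill coefficient (per Gy).
#' @param eta GSC radioprotection factor in (0, 1].
#' @param mu TDC radioprotection factor in (0, 1].
#' @return An object of class `rt_params` with derived read-only `beta`.
#' @export
rt_params <- function(alpha, eta = 0.1376, mu = 0.5) {
  stopifnot(alpha >= 0, eta > 0, eta <= 1, mu > 0, mu <= 1)
  structure(list(alpha = alpha, beta = alpha / 10, eta = eta, mu = mu),
            class = "rt_params")
}

#' Detection and death hazard parameters
#'
#' Event rates follow a shifted logistic in total tumour density `N`:
#' `lambda(N) = lambda_max / (1 + exp(-m (N - N_d)))`, evaluated on a fixed
#' time grid of step `dt` days. The rate is half-maximal at the threshold.
#'
#' @param lambda_max maximal event rate (per day).
#' @param m_detect,m_death logistic steepness for detection and death.
#' @param n_detect,n_death half-maximal density thresholds (fractions of K).
#' @param dt hazard evaluation time step (days).
#' @return An object of class `hazard_params`.
#' @export
hazard_params <- function(lambda_max = 1, m_detect = 100, m_death = 20,
                          n_detect = 0.2, n_death = 0.7, dt = 1) {
  stopifnot(lambda_max > 0, m_detect > 0, m_death > 0,
            n_detect > 0, n_detect < 1, n_death > 0, n_death < 1, dt > 0)
  structure(list(lambda_max = lambda_max, m_detect = m_detect,
                 m_death = m_death, n_detect = n_detect,
                 n_death = n_death, dt = dt),
            class = "hazard_params")
}

#' @export
print.hierarchy_params <- function(x, ...) {
  cat("Hierarchy parameters: ms =", signif(x$ms, 4), "/day, mis =", x$mis,
      ", n =", x$n, ", Ps in [", x$psmin, ",", x$psmax, "], K =", x$K, "\n")
  invisible(x)
}

#' Fitted cell-line records
#'
#' Twelve patient-derived glioma stem cell lines with measured doubling
#' times, primary/recurrent status and sex, and fitted radiosensitivity
#' `alpha` (per Gy), self-renewal sensitivity `psi` and compartment
#' sensitivity `phi` (both per ng/mL).
#'
#' @return A data.frame with one row per cell line.
#' @export
gbm_cell_lines <- function() {
  data.frame(
    name = c("GBM965", "QNS120", "GBM522b", "GBM1a", "GBM626", "GBM549",
             "QNS315", "QNS657", "QNS679", "GBM640", "QNS108", "QNS166"),
    status = c("P", "P", "R", "P", "P", "P", "P", "P", "R", "P", "P", "P"),
    sex = c("F", "M", "M", "M", "M", "F", "F", "F", "F", "F", "M", "F"),
    doubling_time_hours = c(36.1, 43.5, 53.4, 54.7, 57.1, 60.4,
                            63.6, 75.6, 108, 109, 109, 117),
    alpha = c(0.134, 0.116, 0.199, 0.338, 0.328, 0.189,
              0.0841, 0.104, 0.146, 0.108, 0.151, 0.0872),
    psi = c(0.00289, 0.00159, 0, 0.0108, 0.101, 0.00715,
            0, 0.0245, 0.197, 0.192, 0.00311, 0.0116),
    phi = c(0.0789, 0.0975, 0, 0.0737, 0.0635, 0.0494,
            0, 0.0723, 0.0614, 0.0864, 0.0782, 0.0751),
    stringsAsFactors = FALSE
  )
}

#' Virtual-patient parameter ranges
#'
#' Uniform sampling ranges (or fixed values) for the virtual-patient
#' population, in the published units: per-year for the death, proliferation
#' and kinetic rates, per-Gy for `alpha_s`, dimensionless otherwise. Fixed
#' parameters have `lower == upper`. The delivery-kinetics block is read on
#' a per-day basis by default (the reading that reproduces the reported
#' 48-h BMP4 peak and ~14-day AMSC persistence); `kinetics_unit` switches
#' it to the per-year label as printed.
#'
#' @param kinetics_unit `"day"` (default) or `"year"`: how the delivery
#'   kinetics rates (`delta_m`, `delta_b`, `u_b`, `c_rel`) are read.
#' @return An object of class `parameter_ranges`: a data.frame with columns
#'   `parameter`, `lower`, `upper`, `units`, `sampled`.
#' @export
parameter_ranges <- function(kinetics_unit = c("day", "year")) {
  kinetics_unit <- match.arg(kinetics_unit)
  rng <- data.frame(
    parameter = c("delta_s", "delta_is", "delta_ns", "delta_m", "delta_b",
                  "u_b", "c_rel", "n", "ms", "mis", "psi", "phi",
                  "alpha_s", "eta", "mu", "psmax", "psmin"),
    lower = c(0.0001, 1, 1, 0.5, 0.5, 0.1, 0.1, 10, 10, 1, 0, 0,
              0.001, 0.001, 0.2, 0.5, 0.1),
    upper = c(0.002, 20, 10, 0.5, 0.5, 1, 1, 10, 90, 5, 0.2, 0.1,
              0.01, 1, 1, 0.6, 0.3),
    units = c("1/year", "1", "1", "1/year", "1/year", "1/year", "1/year",
              "1", "1/year", "1", "1", "1", "1/Gy", "1", "1", "1", "1"),
    stringsAsFactors = FALSE
  )
  rng$sampled <- rng$lower != rng$upper
  structure(rng, kinetics_unit = kinetics_unit,
            class = c("parameter_ranges", "data.frame"))
}

#' Read parameter ranges from a CSV file
#'
#' Loads a custom sampling-range table with columns `parameter`, `lower`,
#' `upper` (and optionally `units`), validated against the canonical symbol
#' set of [parameter_ranges()]. A packaged example mirroring the published
#' table lives at `system.file("extdata", "parameter_ranges.csv",
#' package = "gbmtwin")`.
#'
#' @param path CSV file path.
#' @param kinetics_unit how delivery-kinetics rates are read (see
#'   [parameter_ranges()]).
#' @return A `parameter_ranges` table.
#' @export
read_ranges_csv <- function(path, kinetics_unit = c("day", "year")) {
  kinetics_unit <- match.arg(kinetics_unit)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("parameter", "lower", "upper")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("read_ranges_csv: missing column(s): ",
         paste(missing, collapse = ", "))
  canon <- parameter_ranges(kinetics_unit)
  unknown <- setdiff(tab$parameter, canon$parameter)
  if (length(unknown))
    stop("read_ranges_csv: unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  absent <- setdiff(canon$parameter, tab$parameter)
  if (length(absent))
    stop("read_ranges_csv: missing parameter(s): ",
         paste(absent, collapse = ", "))
  tab <- tab[match(canon$parameter, tab$parameter), ]
  if (any(tab$lower > tab$upper))
    stop("read_ranges_csv: lower bound above upper bound")
  if (!"units" %in% names(tab)) tab$units <- canon$units
  tab$sampled <- tab$lower != tab$upper
  rownames(tab) <- NULL
  structure(tab[, c("parameter", "lower", "upper", "units", "sampled")],
            kinetics_unit = kinetics_unit,
            class = c("parameter_ranges", "data.frame"))
}

#' Assemble a virtual patient's parameter set
#'
#' Converts one row of sampled parameters (published units) into the
#' internal per-day parameterisation: `ms` and `delta_s` are divided by 365;
#' the delivery kinetics are taken per day (or divided by 365 under the
#' `"year"` switch); the patient's radiosensitivity is derived as
#' `alpha = alpha_s * ms` with `ms` in the printed per-year unit.
#'
#' @param draw a named list or one-row data.frame of Table-range symbols.
#' @param kinetics_unit how delivery kinetics rates are read (see
#'   [parameter_ranges()]).
#' @return An object of class `patient_params`: a list with components
#'   `hierarchy`, `delivery`, `response`, `rt` and the raw `draw`.
#' @export
patient_params <- function(draw, kinetics_unit = c("day", "year")) {
  kinetics_unit <- match.arg(kinetics_unit)
  d <- as.list(draw)
  kin <- if (kinetics_unit == "day") 1 else 365
  hp <- hierarchy_params(
    ms = d$ms / 365, mis = d$mis,
    delta_s = d$delta_s / 365, delta_is = d$delta_is, delta_ns = d$delta_ns,
    K = 1, n = if (is.null(d$n)) 10 else d$n,
    psmax = d$psmax, psmin = d$psmin
  )
  dp <- delivery_params(delta_m = d$delta_m / kin, delta_b = d$delta_b / kin,
                        c_rel = d$c_rel / kin, u_b = d$u_b / kin)
  rp <- response_params(psi = d$psi, phi = d$phi)
  rtp <- rt_params(alpha = d$alpha_s * d$ms, eta = d$eta, mu = d$mu)
  structure(list(hierarchy = hp, delivery = dp, response = rp, rt = rtp,
                 draw = d),
            class = "patient_params")
}

#' @export
print.patient_params <- function(x, ...) {
  cat("Virtual patient: ms =", signif(x$hierarchy$ms, 4), "/day,",
      "psi =", signif(x$response$psi, 3), ", phi =", signif(x$response$phi, 3),
      ", alpha =", signif(x$rt$alpha, 3), "/Gy\n")
  invisible(x)
}
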