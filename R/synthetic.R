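#' Latin hypercube sample of virtual patients
#'
#' Samples every non-fixed parameter of a [parameter_ranges()] table by
#' Latin hypercube: for each sampled dimension exactly one draw falls in
#' each of `n_patients` equal-width strata of its range. Fixed parameters
#' are copied verbatim. Reproducible for a given seed.
#'
#' @param ranges a [parameter_ranges()] table (columns `parameter`, `lower`,
#'   `upper`, `sampled`).
#' @param n_patients number of virtual patients.
#' @param seed integer seed.
#' @return A data.frame with one row per patient and one column per
#'   parameter (published units), with attribute `seed`.
#' @export
lhs_sample <- function(ranges, n_patients, seed) {
  stopifnot(n_patients >= 1)
  if (any(ranges$lower > ranges$upper))
    stop("lhs_sample: invalid range (lower > upper)")
  sampled <- which(ranges$sampled)
  set.seed(seed)
  u <- lhs::randomLHS(n_patients, length(sampled))
  out <- matrix(rep(ranges$lower, each = n_patients),
                nrow = n_patients,
                dimnames = list(NULL, ranges$parameter))
  for (k in seq_along(sampled)) {
    j <- sampled[k]
    out[, j] <- ranges$lower[j] + u[, k] * (ranges$upper[j] - ranges$lower[j])
  }
  out <- as.data.frame(out)
  attr(out, "seed") <- seed
  attr(out, "kinetics_unit") <- attr(ranges, "kinetics_unit")
  out
}

#' Independent uniform sample of virtual patients
#'
#' Plain iid-uniform draws over the same ranges as [lhs_sample()], without
#' the Latin hypercube's per-dimension balancing. Two such cohorts are
#' exchangeable in the iid sense the log-rank test assumes, which is why
#' null-calibration runs use this sampler; stratified LHS cohorts are more
#' alike than iid samples and make between-cohort tests conservative.
#'
#' @inheritParams lhs_sample
#' @return A data.frame with one row per patient, as [lhs_sample()].
#' @export
uniform_sample <- function(ranges, n_patients, seed) {
  stopifnot(n_patients >= 1)
  if (any(ranges$lower > ranges$upper))
    stop("uniform_sample: invalid range (lower > upper)")
  set.seed(seed)
  out <- as.data.frame(lapply(seq_len(nrow(ranges)), function(j)
    stats::runif(n_patients, ranges$lower[j], ranges$upper[j])))
  names(out) <- ranges$parameter
  attr(out, "seed") <- seed
  attr(out, "kinetics_unit") <- attr(ranges, "kinetics_unit")
  out
}

#' Write a virtual-patient parameter table to CSV
#'
#' The sampling seed is recorded in a header comment line.
#'
#' @param patients a table from [lhs_sample()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_patients_csv <- function(patients, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seed: ", attr(patients, "seed")), con)
  utils::write.csv(patients, con, row.names = FALSE)
  invisible(path)
}

#' Read a virtual-patient parameter table from CSV
#'
#' @param path path written by [write_patients_csv()].
#' @return A data.frame of parameter draws with attribute `seed`.
#' @export
read_patients_csv <- function(path) {
  first <- readLines(path, n = 1)
  seed <- if (grepl("^# seed:", first))
    as.integer(sub("^# seed: *", "", first)) else NA_integer_
  out <- utils::read.csv(path, comment.char = "#")
  attr(out, "seed") <- seed
  out
}

#' Generate a synthetic assay dataset with known ground truth
#'
#' Emulates the sextuplicate clonogenic-survival readouts at 0/2/4/6 Gy
#' (control and BMP4 arms) and the day-7 proliferation readouts: model
#' predictions perturbed by multiplicative lognormal noise of the given
#' coefficient of variation (mean-1 noise, so replicate averages converge
#' to the model prediction). The 0 Gy survival replicates of each arm are
#' renormalised to mean 1, as colony counts are in practice.
#'
#' @param alpha,psi,phi generating parameter values.
#' @param doubling_time_hours generating doubling time.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param replicates replicates per condition.
#' @param seed integer seed.
#' @param doses radiotherapy doses (Gy).
#' @param opts an [assay_options()].
#' @return An assay dataset: data.frame with columns `assay`, `dose_gy`,
#'   `arm`, `replicate`, `value`, with the generating truth in attributes.
#' @export
generate_assay_data <- function(alpha, psi, phi, doubling_time_hours,
                                noise_cv = 0.05, replicates = 6, seed = 1,
                                doses = c(0, 2, 4, 6),
                                opts = assay_options()) {
  stopifnot(noise_cv >= 0, replicates >= 1)
  pred <- assay_predictions(alpha, psi, phi, doubling_time_hours, opts,
                            doses)
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  noise <- function(k) stats::rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)

  rt <- pred$rt[rep(seq_len(nrow(pred$rt)), each = replicates), ]
  rt$replicate <- rep(seq_len(replicates), times = nrow(pred$rt))
  rt$value <- rt$pred * noise(nrow(rt))
  for (a in unique(rt$arm)) {
    i0 <- rt$arm == a & rt$dose_gy == 0
    if (any(i0)) {
      f <- mean(rt$value[i0])
      rt$value[rt$arm == a] <- rt$value[rt$arm == a] / f
    }
  }
  rt <- data.frame(assay = "rt", dose_gy = rt$dose_gy, arm = rt$arm,
                   replicate = rt$replicate, value = rt$value,
                   stringsAsFactors = FALSE)

  ## day-7 sizes in arbitrary fluorescence units: control level 1,
  ## treated level the model's treated-to-control ratio
  pl_mean <- c(CTRL = 1, BMP4 = unname(pred$prolif_ratio))
  pl <- expand.grid(arm = c("CTRL", "BMP4"),
                    replicate = seq_len(replicates),
                    stringsAsFactors = FALSE)
  pl$value <- pl_mean[pl$arm] * noise(nrow(pl))
  pl <- data.frame(assay = "prolif", dose_gy = NA_real_, arm = pl$arm,
                   replicate = pl$replicate, value = pl$value,
                   stringsAsFactors = FALSE)

  out <- rbind(rt, pl)
  rownames(out) <- NULL
  attr(out, "truth") <- list(alpha = alpha, psi = psi, phi = phi,
                             doubling_time_hours = doubling_time_hours)
  attr(out, "seed") <- seed
  out
}

#' Write / read an assay dataset as CSV
#'
#' Columns `assay`, `dose_gy`, `arm`, `replicate`, `value`.
#'
#' @param data an assay dataset.
#' @param path file path.
#' @return `path` (write) or the dataset (read).
#' @export
write_assay_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assay_csv
#' @export
read_assay_csv <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("assay", "dose_gy", "arm", "replicate", "value")
  missing <- setdiff(needed, names(data))
  if (length(missing))
    stop("read_assay_csv: missing column(s): ",
         paste(missing, collapse = ", "))
  data
}
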