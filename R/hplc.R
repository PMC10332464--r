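#' Construct a chromatogram
#'
#' @param time_min Strictly increasing sampling times in minutes (default
#'   acquisition is 5 Hz).
#' @param signal Detector response, same length as `time_min`.
#' @param label Optional trace label.
#' @return An object of class `chromatogram` (data.frame `time_min`,
#'   `signal`).
#' @export
chromatogram <- function(time_min, signal, label = NULL) {
  if (length(time_min) != length(signal)) {
    stop("'time_min' and 'signal' must have equal length")
  }
  if (length(time_min) && any(diff(time_min) <= 0)) {
    stop("'time_min' must be strictly increasing")
  }
  structure(data.frame(time_min = time_min, signal = signal),
            label = label, class = c("chromatogram", "data.frame"))
}

#' Chromatogram generator settings
#'
#' @param duration_min Trace length in minutes.
#' @param rate_hz Sampling rate (5 Hz default, matching the acquisition).
#' @param sigma_min Gaussian peak sigma in minutes.
#' @param baseline Constant baseline level.
#' @param drift_per_min Linear baseline drift per minute.
#' @param noise_sd Gaussian noise sd on the signal.
#' @return List of class `chrom_config`.
#' @export
chrom_config <- function(duration_min = 12, rate_hz = 5, sigma_min = 0.08,
                         baseline = 2, drift_per_min = 0.1,
                         noise_sd = 0.02) {
  assert_number(duration_min, "duration_min", positive = TRUE)
  assert_number(rate_hz, "rate_hz", positive = TRUE)
  assert_number(sigma_min, "sigma_min", positive = TRUE)
  assert_number(noise_sd, "noise_sd", nonneg = TRUE)
  structure(list(duration_min = duration_min, rate_hz = rate_hz,
                 sigma_min = sigma_min, baseline = baseline,
                 drift_per_min = drift_per_min, noise_sd = noise_sd),
            class = "chrom_config")
}

#' Default retention times for the catecholamine standards
#'
#' Generator conventions (the elution order DOPAC < DA < HVA on a C-18
#' column is standard; the specific minutes are package defaults and fully
#' configurable).
#'
#' @return Named numeric vector of minutes.
#' @export
default_retention_times <- function() {
  c(DOPAC = 3.5, DA = 5.0, HVA = 8.0)
}

#' Generate a synthetic chromatogram
#'
#' Sum of Gaussian peaks - one per analyte, integrated area exactly equal
#' to the supplied amount (area units) - on a drifting baseline with
#' Gaussian noise.  Peaks whose apexes are closer than 4 sigma are flagged
#' in the `overlap_warning` attribute.
#'
#' @param concentrations Named vector: analyte -> amount (peak area units,
#'   proportional to on-column mass); amounts must be >= 0.
#' @param retention_times Named vector of apex minutes, distinct, covering
#'   the analytes.
#' @param config A [chrom_config].
#' @param seed Optional integer seed for the noise.
#' @param label Trace label.
#' @return A [chromatogram]; attributes `true_areas`, `overlap_warning`.
#' @export
generate_chromatogram <- function(concentrations,
                                  retention_times = default_retention_times(),
                                  config = chrom_config(),
                                  seed = NULL, label = NULL) {
  stopifnot(inherits(config, "chrom_config"))
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  analytes <- names(concentrations)
  if (is.null(analytes) || !all(analytes %in% names(retention_times))) {
    stop("every analyte needs a named retention time")
  }
  rt <- retention_times[analytes]
  if (anyDuplicated(rt)) stop("retention times must be distinct")
  t <- seq(0, config$duration_min, by = 1 / (config$rate_hz * 60))
  sig <- config$baseline + config$drift_per_min * t
  s <- config$sigma_min
  for (a in analytes) {
    if (concentrations[[a]] > 0) {
      amp <- concentrations[[a]] / (s * sqrt(2 * pi))
      sig <- sig + amp * exp(-(t - rt[[a]])^2 / (2 * s^2))
    }
  }
  overlap <- FALSE
  if (length(rt) > 1) {
    pos <- sort(unname(rt[concentrations[analytes] > 0]))
    if (length(pos) > 1 && any(diff(pos) < 4 * s)) {
      overlap <- TRUE
      warning("peaks closer than 4 sigma; integration may merge them",
              call. = FALSE)
    }
  }
  noise_fun <- function() {
    if (config$noise_sd > 0) stats::rnorm(length(t), 0, config$noise_sd)
    else 0
  }
  noise <- if (is.null(seed)) noise_fun() else with_seed(seed, noise_fun())
  out <- chromatogram(t, sig + noise, label = label)
  attr(out, "true_areas") <- concentrations
  attr(out, "overlap_warning") <- overlap
  out
}

#' Detect and integrate chromatographic peaks
#'
#' Peaks are local maxima above `min_height` whose prominence over the
#' local bounds exceeds `min_prominence`.  Bounds are found by descending
#' from the apex until the signal stops falling (within a noise tolerance)
#' or another peak's territory begins; the baseline is the straight line
#' between the bound points and the area is the trapezoidal integral of
#' (signal - baseline) between them, floored at 0.
#'
#' @param chrom A [chromatogram] with >= 10 samples.
#' @param min_height Minimum apex signal.
#' @param min_prominence Minimum apex height above the interpolated
#'   baseline.
#' @param noise_tol Absolute rise tolerated while descending (default: 1%
#'   of the apex prominence scale).
#' @return data.frame of peaks ordered by apex time: `analyte` (NA until
#'   identified), `apex_time`, `t_start`, `t_end`, `height`, `area`.
#' @export
detect_and_integrate <- function(chrom, min_height = 1,
                                 min_prominence = 0.5, noise_tol = NULL) {
  stopifnot(inherits(chrom, "chromatogram"))
  t <- chrom$time_min; y <- chrom$signal
  n <- length(y)
  if (n < 10L) stop("chromatogram too short to integrate (need >= 10 samples)")
  apex <- which(y[c(-1, -n)] > y[seq_len(n - 2)] &
                  y[c(-1, -n)] >= y[-(1:2)]) + 1L
  apex <- apex[y[apex] >= min_height]
  if (length(apex) == 0L) {
    return(data.frame(analyte = character(), apex_time = numeric(),
                      t_start = numeric(), t_end = numeric(),
                      height = numeric(), area = numeric()))
  }
  descend <- function(i, step) {
    # walk away from the apex while the signal keeps falling; tolerate a
    # cumulative rise of `tol` above the running minimum (noise wiggle)
    # before declaring the peak bound
    j <- i
    run_min <- y[i]
    j_min <- i
    tol <- noise_tol %||% (0.005 * max(y[i] - min(y), .Machine$double.eps))
    while (j + step >= 1L && j + step <= n) {
      nxt <- y[j + step]
      if (nxt > run_min + tol) break
      j <- j + step
      if (nxt < run_min) {
        run_min <- nxt
        j_min <- j
      }
    }
    j_min  # the valley, not the tolerated overshoot
  }
  rows <- lapply(apex, function(i) {
    lo <- descend(i, -1L)
    hi <- descend(i, 1L)
    base <- y[lo] + (y[hi] - y[lo]) * (t[lo:hi] - t[lo]) / (t[hi] - t[lo])
    corr <- y[lo:hi] - base
    area <- sum(diff(t[lo:hi]) * (utils::head(corr, -1) + corr[-1]) / 2)
    prominence <- y[i] - max(y[lo], y[hi])
    data.frame(analyte = NA_character_, apex_time = t[i], t_start = t[lo],
               t_end = t[hi], height = y[i], prominence = prominence,
               area = max(area, 0))
  })
  peaks <- do.call(rbind, rows)
  peaks <- peaks[peaks$prominence >= min_prominence, , drop = FALSE]
  peaks <- peaks[order(peaks$apex_time), ]
  rownames(peaks) <- NULL
  peaks
}

#' Identify sample peaks by standard retention times
#'
#' Each sample peak inherits the label of the standard peak with the
#' nearest apex time within `tolerance_min`; ties break toward the smaller
#' time difference, then the earlier-eluting standard.  Unmatched peaks
#' stay unassigned.
#'
#' @param sample_peaks Peak table from [detect_and_integrate()].
#' @param standard_peaks Peak table with an `analyte` column, or a named
#'   numeric vector of retention times.
#' @param tolerance_min Matching window in minutes.
#' @return `sample_peaks` with the `analyte` column filled where matched.
#' @export
identify_peaks <- function(sample_peaks, standard_peaks,
                           tolerance_min = 0.2) {
  if (is.numeric(standard_peaks)) {
    standard_peaks <- data.frame(analyte = names(standard_peaks),
                                 apex_time = unname(standard_peaks))
  }
  std <- standard_peaks[!is.na(standard_peaks$analyte), , drop = FALSE]
  std <- std[order(std$apex_time), ]
  for (i in seq_len(nrow(sample_peaks))) {
    dt <- abs(sample_peaks$apex_time[i] - std$apex_time)
    ok <- which(dt <= tolerance_min)
    if (length(ok)) {
      j <- ok[order(dt[ok], std$apex_time[ok])][1]
      sample_peaks$analyte[i] <- std$analyte[j]
    }
  }
  sample_peaks
}

#' Confirm peak identities by standard spiking
#'
#' Mirrors the spiking protocol: an aliquot of the composite standard is
#' added to the sample and the run repeated; a label is confirmed when its
#' peak area in the spiked run exceeds the area in the plain sample run by
#' more than `min_increase` (relative).
#'
#' @param sample,spiked [chromatogram]s of the plain and spiked runs.
#' @param standard_peaks Labeled standard peak table or named retention
#'   times (see [identify_peaks()]).
#' @param tolerance_min Retention-time matching window.
#' @param min_increase Relative area increase required (default 10%).
#' @param ... Passed to [detect_and_integrate()].
#' @return data.frame per label: `analyte`, `sample_area`, `spiked_area`,
#'   `verdict` (`"confirmed"`, `"not confirmed"`, `"not found"`).
#' @export
confirm_by_spiking <- function(sample, spiked, standard_peaks,
                               tolerance_min = 0.2, min_increase = 0.10,
                               ...) {
  sp <- identify_peaks(detect_and_integrate(sample, ...), standard_peaks,
                       tolerance_min)
  kp <- identify_peaks(detect_and_integrate(spiked, ...), standard_peaks,
                       tolerance_min)
  labels <- if (is.numeric(standard_peaks)) names(standard_peaks) else {
    unique(stats::na.omit(standard_peaks$analyte))
  }
  rows <- lapply(labels, function(a) {
    s_area <- sp$area[match(a, sp$analyte)]
    k_area <- kp$area[match(a, kp$analyte)]
    verdict <- if (is.na(k_area)) {
      "not found"
    } else if (is.na(s_area)) {
      "confirmed"  # appears only once spiked: present in the standard
    } else if (k_area > s_area * (1 + min_increase)) {
      "confirmed"
    } else {
      "not confirmed"
    }
    data.frame(analyte = a, sample_area = s_area, spiked_area = k_area,
               verdict = verdict)
  })
  do.call(rbind, rows)
}
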