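## Whole-protein-normalized (WPN / TPN) densitometry: a target band is
## quantified relative to its lane's total stain-free protein signal, so no
## loading-control band is needed.  Input is a densitometry table (any
## gel-doc export can produce one); image segmentation is out of scope.

validate_lanes <- function(lanes) {
  req <- c("lane_id", "condition", "total_signal", "band", "volume")
  if (!all(req %in% names(lanes))) {
    stop("lane table must have columns: ", paste(req, collapse = ", "))
  }
  if (any(lanes$total_signal <= 0)) stop("lane total_signal must be > 0")
  if (any(lanes$volume < 0)) stop("band volumes must be >= 0")
  if (any(lanes$volume > lanes$total_signal)) {
    stop("a band volume cannot exceed its lane total")
  }
  lanes
}

#' Whole-protein normalization of band volumes
#'
#' Each lane gets a normalization factor `NF = total_ref / total_lane`
#' (reference lane NF = 1); normalized band volume = raw volume x NF.
#' Multiplying one lane's loading (total and bands) by a scalar leaves its
#' normalized volumes unchanged.
#'
#' @param lanes data.frame: `lane_id`, `condition`, `total_signal`,
#'   `band`, `volume` (one row per band per lane).
#' @param reference_lane_id Lane whose loading defines NF = 1.
#' @return `lanes` with `nf` and `volume_norm` columns added.
#' @export
wpn_normalize <- function(lanes, reference_lane_id) {
  lanes <- validate_lanes(lanes)
  totals <- tapply(lanes$total_signal, lanes$lane_id, function(x) x[1])
  if (!reference_lane_id %in% names(totals)) {
    stop(sprintf("reference lane '%s' not present", reference_lane_id))
  }
  ref_total <- totals[[reference_lane_id]]
  lanes$nf <- ref_total / lanes$total_signal
  lanes$volume_norm <- lanes$volume * lanes$nf
  lanes
}

#' Percent change of a normalized band between conditions
#'
#' `(control - treated) / control * 100`; positive = reduction under
#' treatment, negative = increase.
#'
#' @param control_norm,treated_norm Normalized band volumes (scalars).
#' @return Percentage.
#' @export
wpn_percent_change <- function(control_norm, treated_norm) {
  assert_number(control_norm, "control_norm", positive = TRUE)
  assert_number(treated_norm, "treated_norm", nonneg = TRUE)
  (control_norm - treated_norm) / control_norm * 100
}

#' Generate synthetic densitometry tables
#'
#' `config = "paper_default"` emits the two-lane fixture (control lane
#' total 50,000 / TH band 1,200; treated lane total 55,000 / TH band 1,122)
#' whose whole-protein normalization yields exactly a 15.0% TH reduction.
#' A list config generates randomized lanes with unequal loading: each
#' lane's loading multiplier is lognormal with CV `loading_cv`, scaling
#' total and band together so that normalization must undo it.
#'
#' @param config `"paper_default"` or a list with `n_per_group`,
#'   `total_mean`, `band_frac`, `treated_band_factor`, `loading_cv`.
#' @param seed Integer seed for randomized configs.
#' @return data.frame usable with [wpn_normalize()].
#' @export
generate_densitometry <- function(config = "paper_default", seed = 1L) {
  if (identical(config, "paper_default")) {
    return(data.frame(
      lane_id = c("ctrl_1", "trt_1"),
      condition = c("control", "treated"),
      total_signal = c(50000, 55000),
      band = "TH",
      volume = c(1200, 1122)))
  }
  cfg <- utils::modifyList(
    list(n_per_group = 3L, total_mean = 50000, band_frac = 0.024,
         treated_band_factor = 0.85, loading_cv = 0.1),
    config)
  with_seed(seed, {
    n <- cfg$n_per_group
    loading <- exp(stats::rnorm(2 * n, 0, cfg$loading_cv))
    cond <- rep(c("control", "treated"), each = n)
    band_true <- cfg$total_mean * cfg$band_frac *
      ifelse(cond == "treated", cfg$treated_band_factor, 1)
    data.frame(
      lane_id = sprintf("%s_%d", ifelse(cond == "control", "ctrl", "trt"),
                        c(seq_len(n), seq_len(n))),
      condition = cond,
      total_signal = cfg$total_mean * loading,
      band = "TH",
      volume = band_true * loading)
  })
}
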