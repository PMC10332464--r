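## Negative-geotaxis (climbing) metrics.  A fly is tapped to the bottom of
## a column and the height climbed in a 12-s window is recorded; each fly
## is assayed in several trials.  Group statistics use per-fly mean speeds,
## so n = flies, not trials.

#' Mobility generator settings
#'
#' Presets encode the two exposure conditions the assay characterizes:
#' `"pq_24h"` (fractional climbing-speed decline 0.33) and `"pq_48h"`
#' (0.60).  Default geometry: 12 flies per group, 3 trials per fly,
#' control mean height 60 mm, trial noise sd 5 mm, column height 70 mm.
#'
#' @param timepoint `"pq_24h"` or `"pq_48h"` (sets the default `effect`).
#' @param n_flies Flies per group.
#' @param trials_per_fly Trials per fly.
#' @param control_mean_height Mean height (mm) climbed by control flies.
#' @param effect Fractional decline of the treated group mean.
#' @param noise_sd Trial-level Gaussian sd (mm).
#' @param column_height Column top (mm); heights are clamped to
#'   `[0, column_height]`.
#' @return List of class `mobility_config`.
#' @export
mobility_config <- function(timepoint = c("pq_24h", "pq_48h"),
                            n_flies = 12L, trials_per_fly = 3L,
                            control_mean_height = 60, effect = NULL,
                            noise_sd = 5, column_height = 70) {
  timepoint <- match.arg(timepoint)
  effect <- effect %||% switch(timepoint, pq_24h = 0.33, pq_48h = 0.60)
  assert_number(n_flies, "n_flies", positive = TRUE, integer = TRUE)
  assert_number(trials_per_fly, "trials_per_fly", positive = TRUE,
                integer = TRUE)
  assert_number(control_mean_height, "control_mean_height", positive = TRUE)
  assert_number(effect, "effect", nonneg = TRUE)
  assert_number(noise_sd, "noise_sd", nonneg = TRUE)
  assert_number(column_height, "column_height", positive = TRUE)
  structure(list(timepoint = timepoint, n_flies = n_flies,
                 trials_per_fly = trials_per_fly,
                 control_mean_height = control_mean_height,
                 effect = effect, noise_sd = noise_sd,
                 column_height = column_height),
            class = "mobility_config")
}

#' Generate synthetic climbing records
#'
#' Control trial heights are Gaussian about `control_mean_height`; treated
#' heights about `control_mean_height * (1 - effect)`.  Heights are clamped
#' to `[0, column_height]`.
#'
#' @param config A [mobility_config].
#' @param seed Integer seed.
#' @return data.frame `fly_id`, `group`, `trial`, `height` (mm), with the
#'   column height and window attached as attributes.
#' @export
generate_mobility <- function(config = mobility_config(), seed = 7L) {
  stopifnot(inherits(config, "mobility_config"))
  with_seed(seed, {
    groups <- c("control", config$timepoint)
    means <- c(config$control_mean_height,
               config$control_mean_height * (1 - config$effect))
    rows <- lapply(seq_along(groups), function(g) {
      n <- config$n_flies * config$trials_per_fly
      h <- stats::rnorm(n, means[g], config$noise_sd)
      h <- pmin(pmax(h, 0), config$column_height)
      data.frame(
        fly_id = sprintf("%s_fly%02d", groups[g],
                         rep(seq_len(config$n_flies),
                             each = config$trials_per_fly)),
        group = groups[g],
        trial = rep(seq_len(config$trials_per_fly), config$n_flies),
        height = h)
    })
    out <- do.call(rbind, rows)
    attr(out, "column_height") <- config$column_height
    attr(out, "window_s") <- 12
    out
  })
}

#' Per-fly climbing speed
#'
#' Mean of the fly's trial heights divided by the assay window.
#'
#' @param trial_heights Heights climbed in each trial (>= 1 trial, all
#'   >= 0).
#' @param window_s Assay window in seconds (default 12).
#' @return Speed in height units per second.
#' @export
climbing_speed <- function(trial_heights, window_s = 12) {
  if (length(trial_heights) < 1L || any(trial_heights < 0)) {
    stop("need >= 1 non-negative trial height")
  }
  assert_number(window_s, "window_s", positive = TRUE)
  mean(trial_heights) / window_s
}

#' Group climbing statistics
#'
#' Per-fly mean speeds are summarized per group (mean +/- SEM); percent
#' decline is `(mean_ctrl - mean_trt) / mean_ctrl * 100`; the success rate
#' is the fraction of flies whose mean height reaches `column_height`; the
#' two groups are compared with a two-tailed unpaired t-test on per-fly
#' speeds.
#'
#' @param records Long-format data.frame `fly_id`, `group`, `trial`,
#'   `height` (e.g. from [generate_mobility()]).
#' @param control_group,treated_group Group labels to compare.
#' @param column_height Top-of-column threshold (default: the records'
#'   attribute).
#' @param window_s Assay window in seconds.
#' @param alpha Significance level.
#' @return List of class `mobility_stats`: `summary` (per-group n, mean
#'   speed, SEM, success rate), `pct_decline`, `t`, `df`, `p_value`.
#' @export
group_mobility_stats <- function(records, control_group = "control",
                                 treated_group = NULL,
                                 column_height = NULL, window_s = 12,
                                 alpha = 0.05) {
  column_height <- column_height %||% attr(records, "column_height")
  if (is.null(column_height)) {
    stop("'column_height' is required (none attached to the records)")
  }
  treated_group <- treated_group %||%
    setdiff(unique(records$group), control_group)[1]
  per_fly <- aggregate(height ~ fly_id + group, records, mean)
  per_fly$speed <- per_fly$height / window_s
  grp <- function(g) per_fly[per_fly$group == g, , drop = FALSE]
  ctrl <- grp(control_group); trt <- grp(treated_group)
  if (nrow(ctrl) < 2L || nrow(trt) < 2L) {
    stop("need at least 2 flies per group")
  }
  summ <- do.call(rbind, lapply(list(ctrl, trt), function(d) {
    data.frame(group = d$group[1], n_flies = nrow(d),
               mean_speed = mean(d$speed), sem_speed = sem(d$speed),
               success_rate = mean(d$height >= column_height))
  }))
  tt <- unpaired_t_test(ctrl$speed, trt$speed, alpha = alpha)
  structure(
    list(summary = summ,
         pct_decline = (mean(ctrl$speed) - mean(trt$speed)) /
           mean(ctrl$speed) * 100,
         t = tt$statistic, df = tt$df, p_value = tt$p_value,
         significant = tt$significant, window_s = window_s,
         column_height = column_height),
    class = "mobility_stats")
}

#' @export
print.mobility_stats <- function(x, ...) {
  cat(sprintf("<mobility_stats> decline %.1f%% (p = %.3g)\n",
              x$pct_decline, x$p_value))
  print(x$summary, digits = 4, ...)
  invisible(x)
}
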