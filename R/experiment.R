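## End-to-end orchestration: simulate -> quantify -> compare -> report.
## All tables are CSV with headers; configs, ROIs and the run manifest are
## JSON.  Pixel indices are 0-based and z-ranges inclusive throughout.

#' Configure an end-to-end synthetic experiment
#'
#' Defaults are scaled down (2 brains per group) so a smoke run completes
#' in seconds; the full design of the emulated experiment uses 12 + 12
#' brains.  `subtract_background = "median"` is the pipeline default: with
#' a nonzero uniform background, raw ROI sums dilute relative group
#' differences (see the methods vignette), while per-slice median
#' subtraction removes the background without touching the neuron signal.
#'
#' @param brain A [brain_config].
#' @param n_brains_per_group Brains simulated per condition.
#' @param subtract_background `"median"` (default) or `"none"`.
#' @param mobility_24h,mobility_48h [mobility_config]s.
#' @param chrom A [chrom_config].
#' @param hplc_params Named list of catecholamine chain inputs (see
#'   [quantify_catecholamine()]); `A_Std`/`A_Samp` are measured from the
#'   synthetic chromatograms.
#' @param alpha Significance level.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(brain = brain_config(),
                       n_brains_per_group = 2L,
                       subtract_background = c("median", "none"),
                       mobility_24h = mobility_config("pq_24h"),
                       mobility_48h = mobility_config("pq_48h"),
                       chrom = chrom_config(),
                       hplc_params = list(C_Std = 200, I_Std = 20,
                                          I_Samp = 50, N = 15,
                                          P_Samp = 1.0,
                                          extract_volume = 300,
                                          dilution_factor = 2),
                       alpha = 0.05, seed = 1L) {
  structure(list(brain = brain,
                 n_brains_per_group = as.integer(n_brains_per_group),
                 subtract_background = match.arg(subtract_background),
                 mobility_24h = mobility_24h, mobility_48h = mobility_48h,
                 chrom = chrom, hplc_params = hplc_params, alpha = alpha,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_csv0 <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full synthetic experiment and write a report bundle
#'
#' Simulates both conditions of every assay, quantifies them with the
#' package's own pipeline and writes six report files plus a manifest to
#' `out_dir`: `neurons.csv` (per-neuron FI), `brains.csv` (per-brain
#' totals), `fi_comparison.csv`, `mobility.csv`, `hplc_quant.csv`,
#' `wpn.csv`, `manifest.json`.  Two runs with the same config and seed
#' produce byte-identical CSV payloads.
#'
#' @param config A [run_config].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results and file paths.
#' @export
run_experiment <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (missing(out_dir) || is.null(out_dir)) {
    stop("missing input path: 'out_dir' must name an output directory")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  ## --- imaging arm ------------------------------------------------------
  n <- config$n_brains_per_group
  neuron_rows <- list()
  summaries <- list(control = list(), treated = list())
  for (cond in c("control", "treated")) {
    for (b in seq_len(n)) {
      s <- seed + b + if (cond == "treated") n else 0L
      gb <- generate_brain(config$brain, cond, seed = s)
      gb$stack$brain_id <- sprintf("%s_%02d", cond, b)
      med <- if (config$subtract_background == "median") {
        vapply(seq_len(dim(gb$stack$voxels)[1]),
               function(z) stats::median(gb$stack$voxels[z, , ]), 0)
      } else NULL
      ms <- lapply(gb$rois, function(r) {
        measure_neuron(gb$stack, r,
                       subtract_background = config$subtract_background,
                       .slice_medians = med)
      })
      summaries[[cond]][[b]] <- summarize_brain(ms, gb$stack$brain_id, cond)
      neuron_rows[[length(neuron_rows) + 1L]] <- data.frame(
        brain_id = gb$stack$brain_id, condition = cond,
        neuron_id = vapply(ms, `[[`, "", "neuron_id"),
        cluster = vapply(ms, `[[`, "", "cluster"),
        hemisphere = vapply(ms, `[[`, "", "hemisphere"),
        n_slices = vapply(ms, `[[`, 0L, "n_slices"),
        neuron_fi = vapply(ms, `[[`, 0, "neuron_fi"))
    }
  }
  neurons <- do.call(rbind, neuron_rows)
  brains <- do.call(rbind, lapply(c(summaries$control, summaries$treated),
    function(s) data.frame(brain_id = s$brain_id, condition = s$condition,
                           total_neurons = s$total_neurons,
                           total_fi = s$total_fi)))
  comparison <- compare_groups(summaries$control, summaries$treated,
                               alpha = config$alpha)

  ## --- behavior arm -----------------------------------------------------
  mob <- rbind(
    cbind(generate_mobility(config$mobility_24h, seed = seed + 101L),
          timepoint = "24h"),
    cbind(generate_mobility(config$mobility_48h, seed = seed + 102L),
          timepoint = "48h"))
  mob_stats <- lapply(c("24h", "48h"), function(tp) {
    d <- mob[mob$timepoint == tp, ]
    cfg <- if (tp == "24h") config$mobility_24h else config$mobility_48h
    st <- group_mobility_stats(d, "control",
                               setdiff(unique(d$group), "control"),
                               column_height = cfg$column_height)
    data.frame(timepoint = tp, st$summary,
               pct_decline = st$pct_decline, p_value = st$p_value)
  })
  mobility <- do.call(rbind, mob_stats)

  ## --- HPLC arm ---------------------------------------------------------
  hp <- config$hplc_params
  rt <- default_retention_times()
  std_amt <- stats::setNames(rep(100, 3), names(rt))
  samp_amt <- c(DOPAC = 40, DA = 120, HVA = 25)
  std <- generate_chromatogram(std_amt, rt, config$chrom,
                               seed = seed + 201L, label = "standard")
  smp <- generate_chromatogram(samp_amt, rt, config$chrom,
                               seed = seed + 202L, label = "sample")
  std_peaks <- identify_peaks(detect_and_integrate(std), rt)
  smp_peaks <- identify_peaks(detect_and_integrate(smp), rt)
  quant_rows <- lapply(names(rt), function(a) {
    a_std <- std_peaks$area[match(a, std_peaks$analyte)]
    a_smp <- smp_peaks$area[match(a, smp_peaks$analyte)]
    if (is.na(a_std) || is.na(a_smp)) return(NULL)
    q <- quantify_catecholamine(hp$C_Std, a_std, hp$I_Std, a_smp,
                                hp$I_Samp, hp$N, hp$P_Samp,
                                hp$extract_volume, hp$dilution_factor,
                                analyte = a)
    as.data.frame(q)
  })
  hplc <- do.call(rbind, quant_rows)
  hplc$turnover_dopac_hva_over_da <- turnover_ratio(
    hplc$V8[hplc$analyte == "DA"],
    hplc$V8[hplc$analyte == "DOPAC"],
    hplc$V8[hplc$analyte == "HVA"])

  ## --- blot arm ---------------------------------------------------------
  lanes <- generate_densitometry("paper_default")
  wpn <- wpn_normalize(lanes, reference_lane_id = "ctrl_1")
  wpn_change <- wpn_percent_change(
    wpn$volume_norm[wpn$condition == "control"],
    wpn$volume_norm[wpn$condition == "treated"])
  wpn$pct_change_vs_control <- c(NA, wpn_change)

  paths <- c(
    neurons = write_csv0(neurons, file.path(out_dir, "neurons.csv")),
    brains = write_csv0(brains, file.path(out_dir, "brains.csv")),
    comparison = write_csv0(as.data.frame(comparison),
                            file.path(out_dir, "fi_comparison.csv")),
    mobility = write_csv0(mobility, file.path(out_dir, "mobility.csv")),
    hplc = write_csv0(hplc, file.path(out_dir, "hplc_quant.csv")),
    wpn = write_csv0(wpn, file.path(out_dir, "wpn.csv")))

  cfg_file <- tempfile(fileext = ".json")
  writeLines(as.character(jsonlite::serializeJSON(config)), cfg_file)
  manifest <- list(
    package = "daquant",
    version = as.character(utils::packageVersion("daquant")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    alpha = config$alpha,
    subtract_background = config$subtract_background,
    n_brains_per_group = config$n_brains_per_group,
    z_window = config$brain$z_window,
    z_interval_um = config$brain$z_interval_um,
    config_md5 = unname(tools::md5sum(cfg_file)),
    files = as.list(basename(paths)))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(comparison = comparison, mobility = mobility, hplc = hplc,
                 wpn = wpn, paths = c(paths,
                   manifest = file.path(out_dir, "manifest.json"))))
}
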