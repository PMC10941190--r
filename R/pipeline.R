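# Config-driven orchestration of the analysis stages. Results are written
# as versioned CSV/JSON under an output directory; logging goes to stderr
# so result files stay clean and byte-reproducible under a fixed seed.

#' Assemble a pipeline configuration
#'
#' Collects every adjustable constant of the analysis in one validated
#' list. Defaults are the standard choices used throughout the package.
#'
#' @param cutoff_d H-bond heavy-atom distance cutoff, 4.0 or 3.5 Angstrom.
#' @param angle_cutoff `theta_NXH` cutoff in degrees.
#' @param field_eval_mode `"average-CN"`, `"midpoint"` or `"N-only"`.
#' @param level electrostatics level, `"multipoles"` or `"charges"`.
#' @param induction include mutually induced dipoles.
#' @param offsets an [offset_spec] of calibration-transfer offsets.
#' @param calibration_fc,calibration_pol optional [calibration_line]s for
#'   TDM conversion (identity-like defaults: slope 1, intercept 0).
#' @param switching a [switching_params] for the synthetic stage.
#' @param n_frames synthetic trace length.
#' @param geometry list of arguments for [gen_geometry_samples].
#' @param bands list of [band_model]s for the synthetic spectrum stage.
#' @param spectrum_noise_sd,spectrum_grid synthetic spectrum settings.
#' @param field_bin_width field histogram bin width (MV/cm).
#' @param theta_bin,d_bin geometry histogram bin widths (deg, Angstrom).
#' @param dephasing_time vibrational dephasing time (ps) for the exchange
#'   regime diagnostic.
#' @param seed master integer seed.
#' @param output_dir directory for stage outputs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cutoff_d = 4.0, angle_cutoff = 30,
                            field_eval_mode = "average-CN",
                            level = "multipoles", induction = FALSE,
                            offsets = offset_spec(),
                            calibration_fc = calibration_line(1, 0, "FC"),
                            calibration_pol = calibration_line(1, 0, "POL"),
                            switching = switching_params(6, 4),
                            n_frames = 20000L,
                            geometry = list(center_theta = 163,
                                            center_d = 3.00,
                                            sd_theta = 12, sd_d = 0.08,
                                            rho = 0, n = 20000L),
                            bands = list(band_model(2230.1, 8, 1),
                                         band_model(2246.9, 8, 3)),
                            spectrum_noise_sd = 0.002,
                            spectrum_grid = seq(2200, 2280, by = 0.25),
                            field_bin_width = 2,
                            theta_bin = 2, d_bin = 0.05,
                            dephasing_time = 4,
                            seed = 1L, output_dir = tempfile("nfrun")) {
  if (!cutoff_d > 0 || !angle_cutoff > 0) stop("cutoffs must be positive")
  field_eval_mode <- match.arg(field_eval_mode,
                               c("average-CN", "midpoint", "N-only"))
  level <- match.arg(level, c("multipoles", "charges"))
  stopifnot(inherits(offsets, "offset_spec"),
            inherits(switching, "switching_params"))
  structure(list(
    cutoff_d = cutoff_d, angle_cutoff = angle_cutoff,
    field_eval_mode = field_eval_mode, level = level,
    induction = isTRUE(induction), offsets = offsets,
    calibration_fc = calibration_fc, calibration_pol = calibration_pol,
    switching = switching, n_frames = as.integer(n_frames),
    geometry = geometry, bands = bands,
    spectrum_noise_sd = spectrum_noise_sd, spectrum_grid = spectrum_grid,
    field_bin_width = field_bin_width, theta_bin = theta_bin,
    d_bin = d_bin, dephasing_time = dephasing_time,
    seed = as.integer(seed), output_dir = output_dir
  ), class = "pipeline_config")
}

config_hash <- function(config) {
  # rolling polynomial hash over the deparsed configuration; a content
  # fingerprint for the manifest, not a cryptographic hash. The output
  # location is not part of the content.
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  bytes <- utf8ToInt(paste(deparse(cfg, control = "all"),
                           collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

stage_log <- function(stage, t0) {
  message(sprintf("[%s] done in %.2f s", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages and writes their outputs under
#' `config$output_dir`:
#'
#' * `simulate` - synthetic two-state trace + state-conditional fields
#'   (`trace.csv`), or loads `inputs$trace_csv` when supplied;
#' * `populations` - field-distribution deconvolution (`populations.json`)
#'   and per-population histograms (`histograms.csv`);
#' * `kinetics` - dwell times, lifetimes, exchange rate, predicted
#'   fraction, exchange-regime diagnostic (`kinetics.json`);
#' * `geometry` - geometry samples, 2D histogram and Gaussian-surface fit
#'   (`geometry_fit.json`);
#' * `compare` - York regression of the packaged fixture tables per
#'   parameter-set family, variant table, 2-sigma band and
#'   reference-line verdicts (`comparison.json`, `band_<source>.csv`);
#' * `spectra` - synthetic spectrum, band-count selection and band fit
#'   (`spectra.json`, `spectrum.csv`);
#' * `reproduce` - recomputes the fraction-weighted field column from the
#'   printed fractions/medians and the regression constants
#'   (`reproduce.json`).
#'
#' A `manifest.json` records the package version, configuration (with
#' fingerprint) and per-stage output files. Given a fixed seed the output
#' files are byte-identical across runs; timing is logged to stderr only.
#'
#' @param config a [pipeline_config].
#' @param stages character vector of stage names (default: all).
#' @param inputs optional named list of input paths (`trace_csv`).
#' @return (invisibly) list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "populations", "kinetics",
                                    "geometry", "compare", "spectra",
                                    "reproduce"),
                         inputs = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  known <- c("simulate", "populations", "kinetics", "geometry", "compare",
             "spectra", "reproduce")
  stages <- match.arg(stages, known, several.ok = TRUE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  files <- list()
  run_stage <- function(stage, fun) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    stage_log(stage, t0)
    res
  }
  pth <- function(f) file.path(config$output_dir, f)
  wjson <- function(x, f) {
    jsonlite::write_json(x, pth(f), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    f
  }

  states <- NULL
  fields <- NULL
  if ("simulate" %in% stages) {
    out$simulate <- run_stage("simulate", function() {
      if (!is.null(inputs$trace_csv)) {
        if (!file.exists(inputs$trace_csv)) {
          stop(sprintf("input file '%s' not found", inputs$trace_csv))
        }
        tr <- read_trace_csv(inputs$trace_csv)
      } else {
        st <- gen_state_trace(config$switching, config$n_frames,
                              seed = config$seed)
        fl <- gen_field_trace(st, config$switching,
                              seed = config$seed + 1L)
        tr <- list(states = st, fields = fl)
      }
      write_trace_csv(tr$states, tr$fields, pth("trace.csv"))
      tr
    })
    files$simulate <- "trace.csv"
    states <- out$simulate$states
    fields <- out$simulate$fields
  }

  if ("populations" %in% stages) {
    out$populations <- run_stage("populations", function() {
      if (is.null(states)) stop("needs the simulate stage (or trace input)")
      # split the single synthetic run into two pseudo-trajectories so the
      # across-trajectory error convention is exercised
      traj <- rep(1:2, each = ceiling(length(states$states) / 2),
                  length.out = length(states$states))
      ps <- population_summary(fields, states, trajectory = traj)
      hists <- field_histogram(fields, states, config$field_bin_width)
      write_versioned_csv(
        data.frame(mid = hists$mids, total = hists$total, hb = hists$hb,
                   non = hists$non),
        pth("histograms.csv"), "field-histograms")
      list(summary = ps, histograms = hists)
    })
    files$populations <- c("populations.json", "histograms.csv")
    ps <- out$populations$summary
    wjson(list(frac_hb = ps$frac_hb, frac_hb_err = ps$frac_err,
               frac_non = ps$frac_non, median_hb = ps$median_hb,
               median_hb_err = ps$median_hb_err,
               median_non = ps$median_non,
               median_non_err = ps$median_non_err,
               weighted_field = ps$weighted_field,
               weighted_err = ps$weighted_err,
               n_frames = ps$n_frames), "populations.json")
  }

  if ("kinetics" %in% stages) {
    out$kinetics <- run_stage("kinetics", function() {
      if (is.null(states)) stop("needs the simulate stage (or trace input)")
      dw <- extract_dwells(states)
      mdl_mean <- fit_lifetimes(dw, "mean")
      mdl_mle <- fit_lifetimes(dw, "censored-mle")
      list(dwells = dw, mean = mdl_mean, mle = mdl_mle)
    })
    k <- out$kinetics
    files$kinetics <- "kinetics.json"
    wjson(list(
      n_hb_dwells = length(k$dwells$hb),
      n_non_dwells = length(k$dwells$non),
      n_censored = sum(k$dwells$hb_censored, k$dwells$non_censored),
      mean = list(tau_hb = k$mean$tau_hb, tau_non = k$mean$tau_non,
                  k_exchange = k$mean$k_exchange,
                  predicted_frac_hb = predicted_fraction(k$mean)),
      censored_mle = list(tau_hb = k$mle$tau_hb, tau_non = k$mle$tau_non,
                          k_exchange = k$mle$k_exchange,
                          predicted_frac_hb = predicted_fraction(k$mle)),
      exchange_regime = exchange_regime(k$mle, config$dephasing_time)
    ), "kinetics.json")
  }

  if ("geometry" %in% stages) {
    out$geometry <- run_stage("geometry", function() {
      g <- config$geometry
      samples <- gen_geometry_samples(g$center_theta, g$center_d,
                                      g$sd_theta, g$sd_d, g$rho, g$n,
                                      seed = config$seed + 2L)
      h <- hist2d(samples, config$theta_bin, config$d_bin)
      fit <- fit_surface(h)
      list(samples = samples, hist = h, fit = fit)
    })
    f <- out$geometry$fit
    files$geometry <- "geometry_fit.json"
    wjson(list(theta0 = f$theta0, d0 = f$d0,
               sigma_theta = f$sigma_theta, sigma_d = f$sigma_d,
               rho = f$rho, baseline = f$baseline,
               rms_residual = f$rms_residual,
               rejection_fraction =
                 attr(out$geometry$samples, "rejection_fraction")),
          "geometry_fit.json")
  }

  if ("compare" %in% stages) {
    out$compare <- run_stage("compare", function() {
      lapply(c(FC = "FC", POL = "POL"), function(src) {
        pts <- fixture_comparison_points(src)
        fit <- york_regression(pts)
        xs <- seq(min(pts$x) - 2, max(pts$x) + 2, length.out = 101)
        band <- confidence_band(fit, xs)
        ref <- reference_line(config$offsets, src)
        lb <- line_in_band(fit, ref, xs)
        lb_ind <- line_in_band(fit, ref, xs, use_covariance = FALSE)
        write_versioned_csv(band, pth(sprintf("band_%s.csv", src)),
                            sprintf("2-sigma band %s", src))
        list(points = pts, fit = fit, band = band, reference = ref,
             variants = regression_variants(pts),
             reference_inside = lb$verdict,
             reference_inside_independent = lb_ind$verdict)
      })
    })
    files$compare <- c("comparison.json", "band_FC.csv", "band_POL.csv")
    wjson(lapply(out$compare, function(cmp) list(
      slope = cmp$fit$slope, sigma_slope = cmp$fit$sigma_slope,
      intercept = cmp$fit$intercept,
      sigma_intercept = cmp$fit$sigma_intercept,
      covariance = cmp$fit$covariance,
      reference_intercept = cmp$reference$intercept,
      reference_inside_band = cmp$reference_inside,
      reference_inside_band_independent = cmp$reference_inside_independent,
      variants = cmp$variants
    )), "comparison.json")
  }

  if ("spectra" %in% stages) {
    out$spectra <- run_stage("spectra", function() {
      sp <- gen_spectrum(config$bands, config$spectrum_noise_sd,
                         config$spectrum_grid, seed = config$seed + 3L)
      write_spectrum_csv(sp, pth("spectrum.csv"))
      nb <- select_n_bands(sp)
      fit <- attr(nb, "fits")[[if (nb == 2L) "f2" else "f1"]]
      list(spectrum = sp, n_bands = as.integer(nb),
           p_value = attr(nb, "p_value"), fit = fit)
    })
    s <- out$spectra
    files$spectra <- c("spectra.json", "spectrum.csv")
    wjson(list(
      n_bands = s$n_bands, f_test_p = s$p_value,
      bands = lapply(s$fit$bands, function(b) list(
        center = b$center, fwhm = b$fwhm, area = b$area,
        tdm = band_tdm(b))),
      rss = s$fit$rss
    ), "spectra.json")
  }

  if ("reproduce" %in% stages) {
    out$reproduce <- run_stage("reproduce", function() {
      t2 <- load_fixture("table2")
      recomputed <- fraction_weighted(t2$frac_hb, t2$frac_non,
                                      t2$median_hb, t2$median_non)
      fits <- lapply(c(FC = "FC", POL = "POL"), function(src) {
        york_regression(fixture_comparison_points(src))
      })
      list(weighted = data.frame(environment = t2$environment,
                                 source = t2$source,
                                 printed = t2$weighted,
                                 recomputed = recomputed),
           regressions = fits)
    })
    files$reproduce <- "reproduce.json"
    rp <- out$reproduce
    wjson(list(
      weighted = rp$weighted,
      regressions = lapply(rp$regressions, function(f) list(
        slope = f$slope, sigma_slope = f$sigma_slope,
        intercept = f$intercept, sigma_intercept = f$sigma_intercept))
    ), "reproduce.json")
  }

  manifest <- list(
    package = "nitrilefields",
    version = as.character(utils::packageVersion("nitrilefields")),
    format = FORMAT_VERSION,
    config_hash = config_hash(config),
    seed = config$seed,
    stages = stages,
    outputs = files
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
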