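# Packaged reference tables: the published TDM-derived fields, population
# statistics, band centers, calibration-transfer offsets and regression
# constants used for cross-checks and report formatting. Values are typed
# in from the printed tables; each fixture carries a `source` attribute
# naming where it came from.

fixture_registry <- function() {
  variants <- c("F28oCNF", "F62oCNF", "F92oCNF", "F96oCNF")

  table1 <- data.frame(
    environment = variants,
    f_tdm_fc = c(-23, -4, -38, 1),
    f_tdm_fc_err = c(2, 2, 2, 2),
    f_tdm_pol = c(-39, -15, -60, -9),
    f_tdm_pol_err = c(2, 2, 2, 2),
    stringsAsFactors = FALSE
  )
  attr(table1, "source") <- "published Table 1: nitrile TDM-derived fields (MV/cm)"

  table2 <- data.frame(
    environment = rep(variants, each = 2),
    source = rep(c("FC", "POL"), 4),
    frac_hb = c(51.5, 59.8, 1.8, 0, 31.6, 74.0, 3.7, 22.6),
    frac_hb_err = c(1.1, 5.4, 1.8, NA, 3.8, 10.6, 2.4, 7.5),
    frac_non = c(48.5, 40.2, 98.2, 100, 68.4, 26.0, 96.5, 77.4),
    median_hb = c(-24.8, -64.9, -16.3, NA, -44.5, -78.6, -25.3, -49.1),
    median_hb_err = c(0.1, 1.6, NA, NA, 0.6, 1.9, 1.9, 1.5),
    median_non = c(-6.9, -34.3, -2.7, -15.4, -15.4, -33.5, -5.8, -19.5),
    median_non_err = c(0.3, 1.8, 0.4, 1.0, 1.1, 1.0, 0.2, 0.4),
    weighted = c(-16.1, -52.6, -3.0, -15.4, -24.6, -67.0, -6.5, -26.1),
    weighted_err = c(0.3, 0.3, 0.2, 1.0, 0.2, 5.0, 0.3, 1.8),
    stringsAsFactors = FALSE
  )
  attr(table2, "source") <-
    "published Table 2: H-bonding fractions, medians and fraction-weighted fields (MV/cm); the F28oCNF/FC H-bonded median error is printed as '<0.1' and stored as 0.1; the F96oCNF/FC printed fractions sum to 100.2 by rounding"

  fig3 <- data.frame(
    environment = c("F62oCNF", "F92oCNF", "F92oCNF", "F92oCNF"),
    condition = c("100K", "100K", "100K", "room-temperature"),
    band = c("single", "minor", "major", "single"),
    assignment = c("non-H-bonded", "non-H-bonded", "H-bonded",
                   "exchange-averaged"),
    center = c(2230.8, 2230.1, 2246.9, 2241.3),
    stringsAsFactors = FALSE
  )
  attr(fig3, "source") <- "published Fig 3 band centers (cm^-1)"

  fig4_offsets <- data.frame(
    source = c("FC", "POL"),
    offset = c(6.4, 4.1),
    stringsAsFactors = FALSE
  )
  attr(fig4_offsets, "source") <-
    "published Fig 4 caption: calibration-transfer offsets (MV/cm)"

  fig4_regressions <- data.frame(
    source = c("FC", "POL"),
    slope = c(0.56, 1.17),
    slope_err = c(0.04, 0.09),
    intercept = c(-3.5, -5.3),
    intercept_err = c(0.8, 2.7),
    stringsAsFactors = FALSE
  )
  attr(fig4_regressions, "source") <-
    "published Fig 4: weighted-regression constants"

  # Values reported from the original 100-200 ns trajectories; retained as
  # metadata for report formatting only. They are not reproducible from
  # desk-scale synthetic data and no routine in this package recomputes
  # them.
  geometry_averages <- data.frame(
    environment = rep(c("F28oCNF", "F92oCNF"), each = 2),
    source = rep(c("FC", "POL"), 2),
    theta_cnx = c(138, 163, 146, 167),
    d_nx = c(3.08, 3.00, 2.99, 2.93),
    desk_reproducible = FALSE,
    stringsAsFactors = FALSE
  )
  attr(geometry_averages, "source") <-
    "published Gaussian-surface geometry averages (trajectory-derived; metadata only)"

  list(table1 = table1, table2 = table2, fig3_band_centers = fig3,
       fig4_offsets = fig4_offsets, fig4_regressions = fig4_regressions,
       geometry_averages = geometry_averages)
}

#' Load a packaged reference table
#'
#' @param name one of `"table1"` (TDM-derived fields per variant and
#'   parameter-set family), `"table2"` (population fractions, medians and
#'   fraction-weighted fields), `"fig3_band_centers"`,
#'   `"fig4_offsets"`, `"fig4_regressions"`, `"geometry_averages"`.
#' @return a data frame with a `source` attribute describing provenance.
#' @export
load_fixture <- function(name) {
  reg <- fixture_registry()
  if (!name %in% names(reg)) {
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(names(reg), collapse = ", ")))
  }
  reg[[name]]
}

#' Comparison points for one parameter-set family from the fixtures
#'
#' Assembles the four (TDM field, fraction-weighted simulated field) pairs
#' with their uncertainties for York-type regression.
#'
#' @param source `"FC"` or `"POL"`.
#' @return a [comparison_points] data frame.
#' @export
fixture_comparison_points <- function(source = c("FC", "POL")) {
  source <- match.arg(source)
  t1 <- load_fixture("table1")
  t2 <- load_fixture("table2")
  t2 <- t2[t2$source == source, ]
  t2 <- t2[match(t1$environment, t2$environment), ]
  if (source == "FC") {
    comparison_points(t1$f_tdm_fc, t2$weighted, t1$f_tdm_fc_err,
                      t2$weighted_err, label = t1$environment)
  } else {
    comparison_points(t1$f_tdm_pol, t2$weighted, t1$f_tdm_pol_err,
                      t2$weighted_err, label = t1$environment)
  }
}
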