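# H-bond classification and field-distribution deconvolution.
#
# A frame is H-bonded when at least one donor satisfies d_NX < cutoff_d and
# theta_NXH < angle_cutoff. theta_CNX is measured and reported for every
# record but is never a criterion: it describes how head-on the H-bond is.

#' Describe H-bond donor candidates in a frame
#'
#' @param x_index integer vector of donor heavy-atom indices.
#' @param h_indices list of integer vectors, hydrogens attached to each
#'   heavy atom (may be empty for a given donor, which is then skipped with
#'   a warning at detection time).
#' @param donor_class character vector, `"solvent"` or `"protein"`.
#' @param donor_id labels (default `X<i>`).
#' @return data frame of class `donor_set`.
#' @export
donor_set <- function(x_index, h_indices, donor_class = "solvent",
                      donor_id = NULL) {
  x_index <- as.integer(x_index)
  if (!is.list(h_indices)) h_indices <- list(h_indices)
  if (length(h_indices) != length(x_index)) {
    stop("`h_indices` must supply one vector per donor")
  }
  donor_class <- rep_len(donor_class, length(x_index))
  if (!all(donor_class %in% c("solvent", "protein"))) {
    stop("`donor_class` must be 'solvent' or 'protein'")
  }
  if (is.null(donor_id)) donor_id <- paste0("X", x_index)
  out <- data.frame(x_index = x_index, donor_class = donor_class,
                    donor_id = donor_id, stringsAsFactors = FALSE)
  out$h_indices <- h_indices
  class(out) <- c("donor_set", "data.frame")
  out
}

#' Detect H-bonds to the nitrile nitrogen in one frame
#'
#' Applies the geometric criterion: heavy-atom distance `d_NX <  cutoff_d`
#' and hydrogen angle `theta_NXH < angle_cutoff` (minimum over the donor's
#' hydrogens). The default distance cutoff is 4.0 A with 3.5 A as the
#' standard alternate; the angle cutoff defaults to 30 degrees.
#'
#' @param frame an [md_frame].
#' @param donors a [donor_set].
#' @param cutoff_d heavy-atom distance cutoff (Angstrom).
#' @param angle_cutoff `theta_NXH` cutoff (degrees).
#' @param frame_index frame label stored in the records.
#' @return data frame of H-bond records (possibly 0 rows) with columns
#'   `frame_index`, `donor_id`, `donor_class`, `d_nx`, `theta_cnx`,
#'   `theta_nxh`.
#' @export
detect_hbond <- function(frame, donors, cutoff_d = 4.0, angle_cutoff = 30,
                         frame_index = 1L) {
  stopifnot(inherits(frame, "md_frame"), inherits(donors, "donor_set"))
  rows <- lapply(seq_len(nrow(donors)), function(i) {
    hs <- donors$h_indices[[i]]
    if (length(hs) == 0) {
      warning(sprintf("donor %s has no hydrogens; skipped",
                      donors$donor_id[i]))
      return(NULL)
    }
    g <- measure_geometry(frame, donors$x_index[i], hs)
    if (g["d_nx"] < cutoff_d && g["theta_nxh"] < angle_cutoff) {
      data.frame(frame_index = frame_index,
                 donor_id = donors$donor_id[i],
                 donor_class = donors$donor_class[i],
                 d_nx = unname(g["d_nx"]),
                 theta_cnx = unname(g["theta_cnx"]),
                 theta_nxh = unname(g["theta_nxh"]),
                 stringsAsFactors = FALSE)
    } else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    data.frame(frame_index = integer(0), donor_id = character(0),
               donor_class = character(0), d_nx = numeric(0),
               theta_cnx = numeric(0), theta_nxh = numeric(0))
  } else {
    do.call(rbind, rows)
  }
}

#' Classify a frame sequence into an H-bond state trace
#'
#' @param frames list of [md_frame]s with non-decreasing times.
#' @param donors a [donor_set] (shared indexing across frames) or a list of
#'   one `donor_set` per frame.
#' @inheritParams detect_hbond
#' @return A `state_trace` whose `records` element collects all per-frame
#'   H-bond records.
#' @export
classify_trace <- function(frames, donors, cutoff_d = 4.0,
                           angle_cutoff = 30) {
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (is.unsorted(times)) stop("frames must be time-ordered")
  per_frame <- inherits(donors, "donor_set") == FALSE
  recs <- vector("list", length(frames))
  states <- integer(length(frames))
  for (i in seq_along(frames)) {
    dn <- if (per_frame) donors[[i]] else donors
    r <- detect_hbond(frames[[i]], dn, cutoff_d, angle_cutoff,
                      frame_index = i)
    states[i] <- as.integer(nrow(r) > 0)
    recs[[i]] <- r
  }
  structure(list(times = times, states = states,
                 records = do.call(rbind, recs)),
            class = "state_trace")
}

#' Fraction-weighted projected field
#'
#' Occupancy-weighted combination of the H-bonded and non-H-bonded
#' population medians,
#' `(frac_hb * median_hb + frac_non * median_non) / 100`, with the
#' fractions (in percent) used exactly as supplied. An absent H-bonded
#' median (`NA`) is allowed only when its fraction is zero.
#'
#' @param frac_hb,frac_non population fractions in percent, each in
#'   `[0, 100]`.
#' @param median_hb,median_non population medians (MV/cm); `NA` allowed for
#'   an empty population.
#' @return weighted field in MV/cm.
#' @export
fraction_weighted <- function(frac_hb, frac_non, median_hb, median_non) {
  if (any(c(frac_hb, frac_non) < 0) || any(c(frac_hb, frac_non) > 100)) {
    stop("fractions must lie in [0, 100] percent")
  }
  hb_term <- ifelse(frac_hb == 0 & is.na(median_hb), 0, frac_hb * median_hb)
  non_term <- ifelse(frac_non == 0 & is.na(median_non), 0,
                     frac_non * median_non)
  (hb_term + non_term) / 100
}

se_over <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Deconvolve a field trace into H-bonded / non-H-bonded populations
#'
#' Computes population fractions (percent), per-population field medians,
#' and the fraction-weighted field. Uncertainties are standard errors over
#' per-trajectory values: the trace is split by the `trajectory` labels,
#' each statistic is recomputed per trajectory, and the error is
#' `sd / sqrt(n_traj)` (for two trajectories this is half the absolute
#' difference). With a single trajectory all errors are `NA`.
#'
#' @param fields a `field_trace` (or numeric vector of fields in MV/cm).
#' @param states a `state_trace` (or 0/1 integer vector), same length.
#' @param trajectory optional vector of per-frame trajectory labels.
#' @return list of class `population_summary` with elements `frac_hb`,
#'   `frac_non`, `median_hb`, `median_non`, `weighted_field`, their `*_err`
#'   companions, and `n_frames`.
#' @export
population_summary <- function(fields, states, trajectory = NULL) {
  f <- if (inherits(fields, "field_trace")) fields$fields else as.numeric(fields)
  s <- if (inherits(states, "state_trace")) states$states else as.integer(states)
  if (length(f) != length(s)) stop("field and state traces differ in length")
  if (is.null(trajectory)) trajectory <- rep(1L, length(f))
  one <- function(fi, si) {
    hb <- si == 1L
    list(frac_hb = 100 * mean(hb),
         median_hb = if (any(hb)) stats::median(fi[hb]) else NA_real_,
         median_non = if (any(!hb)) stats::median(fi[!hb]) else NA_real_)
  }
  pooled <- one(f, s)
  frac_hb <- pooled$frac_hb
  frac_non <- 100 - frac_hb
  weighted <- fraction_weighted(frac_hb, frac_non, pooled$median_hb,
                                pooled$median_non)
  per <- lapply(split(seq_along(f), trajectory), function(ix) {
    p <- one(f[ix], s[ix])
    p$weighted <- fraction_weighted(p$frac_hb, 100 - p$frac_hb,
                                    p$median_hb, p$median_non)
    p
  })
  getv <- function(name) vapply(per, function(p) {
    v <- p[[name]]
    if (is.null(v) || is.na(v)) NA_real_ else v
  }, numeric(1))
  structure(list(
    frac_hb = frac_hb, frac_non = frac_non,
    frac_err = se_over(getv("frac_hb")),
    median_hb = pooled$median_hb, median_hb_err = se_over(getv("median_hb")),
    median_non = pooled$median_non,
    median_non_err = se_over(getv("median_non")),
    weighted_field = weighted, weighted_err = se_over(getv("weighted")),
    n_frames = length(f), n_trajectories = length(per)
  ), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  fmt <- function(v, e) {
    if (is.na(v)) "N/A"
    else if (is.na(e)) sprintf("%.1f", v)
    else sprintf("%.1f +/- %.1f", v, e)
  }
  cat("population_summary\n")
  cat(sprintf("  H-bonded fraction:    %s %%\n", fmt(x$frac_hb, x$frac_err)))
  cat(sprintf("  non-H-bonded fraction: %.1f %%\n", x$frac_non))
  cat(sprintf("  median field (H-bonded):     %s MV/cm\n",
              fmt(x$median_hb, x$median_hb_err)))
  cat(sprintf("  median field (non-H-bonded): %s MV/cm\n",
              fmt(x$median_non, x$median_non_err)))
  cat(sprintf("  fraction-weighted field:     %s MV/cm\n",
              fmt(x$weighted_field, x$weighted_err)))
  invisible(x)
}

#' Donor-identity fractions of H-bonded frames
#'
#' Attributes each H-bonded frame to donor classes. A frame whose records
#' contain both classes is split fractionally by record share (e.g.
#' 0.5/0.5 for one solvent and one protein record); set
#' `attribution = "protein-wins"` to assign such frames wholly to the
#' protein class instead.
#'
#' @param records H-bond record data frame (from [detect_hbond] /
#'   [classify_trace]).
#' @param attribution `"fractional"` or `"protein-wins"`.
#' @return named numeric vector of percentages over H-bonded frames
#'   (`solvent`, `protein`).
#' @export
donor_identity_fractions <- function(records,
                                     attribution = c("fractional",
                                                     "protein-wins")) {
  attribution <- match.arg(attribution)
  if (nrow(records) == 0) {
    return(c(solvent = NA_real_, protein = NA_real_))
  }
  by_frame <- split(records$donor_class, records$frame_index)
  w <- vapply(by_frame, function(cls) {
    if (attribution == "protein-wins" && any(cls == "protein")) {
      c(0, 1)
    } else {
      c(mean(cls == "solvent"), mean(cls == "protein"))
    }
  }, numeric(2))
  tot <- rowMeans(w) * 100
  c(solvent = tot[1], protein = tot[2])
}

#' Per-population field histograms
#'
#' Builds the total, H-bonded and non-H-bonded histograms of a field trace
#' on a shared bin grid. Counts are divided by `n * bin_width`, so the
#' total histogram integrates to one and the component histograms sum
#' bin-wise to the total.
#'
#' @inheritParams population_summary
#' @param bin_width bin width in MV/cm (default 2).
#' @return list of class `field_histogram` with `breaks`, `mids`, `total`,
#'   `hb`, `non`.
#' @export
field_histogram <- function(fields, states, bin_width = 2) {
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  f <- if (inherits(fields, "field_trace")) fields$fields else as.numeric(fields)
  s <- if (inherits(states, "state_trace")) states$states else as.integer(states)
  if (length(f) != length(s)) stop("field and state traces differ in length")
  lo <- floor(min(f) / bin_width) * bin_width
  hi <- ceiling(max(f) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  cnt <- function(x) {
    if (length(x) == 0) return(numeric(length(breaks) - 1))
    graphics::hist(x, breaks = breaks, plot = FALSE)$counts
  }
  norm <- length(f) * bin_width
  structure(list(breaks = breaks, mids = breaks[-1] - bin_width / 2,
                 total = cnt(f) / norm, hb = cnt(f[s == 1L]) / norm,
                 non = cnt(f[s == 0L]) / norm),
            class = "field_histogram")
}
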