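# Plain-text readers/writers: an extended-XYZ dialect for frames with
# per-atom electrostatic parameters, and 2-3 column CSVs for traces,
# spectra and ESP grids. Every CSV carries a one-line format-version
# comment header.

FORMAT_VERSION <- "nitrilefields-v1"

xyz_columns <- c("element", "x", "y", "z", "charge", "dx", "dy", "dz",
                 "qxx", "qxy", "qxz", "qyy", "qyz", "qzz", "alpha",
                 "damping", "group")

#' Write frames in the extended-XYZ dialect
#'
#' One block per frame: an atom count line, a comment line of
#' `key=value` tokens (`frame`, `time` in ps, `probe` as three
#' 1-based indices, `cols` naming the per-atom columns), then one
#' whitespace-separated line per atom. All electrostatic parameter columns
#' are always written.
#'
#' @param frames an [md_frame] or list of them.
#' @param path output file path.
#' @export
write_frames_xyz <- function(frames, path) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    s <- fr$sites
    writeLines(as.character(nrow(s)), con)
    writeLines(sprintf("frame=%d time=%.10g probe=%d,%d,%d cols=%s", i,
                       fr$time, fr$probe[1], fr$probe[2], fr$probe[3],
                       paste(xyz_columns, collapse = ",")), con)
    writeLines(sprintf(
      "%s %.10g %.10g %.10g %.10g %.10g %.10g %.10g %.10g %.10g %.10g %.10g %.10g %.10g %.10g %.10g %s",
      s$element, s$x, s$y, s$z, s$charge, s$dx, s$dy, s$dz,
      s$qxx, s$qxy, s$qxz, s$qyy, s$qyz, s$qzz, s$alpha, s$damping,
      as.character(s$group)), con)
  }
  invisible(path)
}

#' Read frames written by [write_frames_xyz]
#'
#' @param path input file path.
#' @return list of [md_frame]s.
#' @export
read_frames_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- as.integer(lines[i])
    comment <- lines[i + 1L]
    toks <- strsplit(strsplit(comment, "\\s+")[[1]], "=")
    kv <- stats::setNames(vapply(toks, `[`, "", 2), vapply(toks, `[`, "", 1))
    probe <- as.integer(strsplit(kv[["probe"]], ",")[[1]])
    block <- lines[i + 1L + seq_len(nat)]
    fields <- strsplit(trimws(block), "\\s+")
    m <- do.call(rbind, fields)
    num <- function(j) as.numeric(m[, j])
    sites <- atom_sites(
      element = m[, 1],
      position = cbind(num(2), num(3), num(4)),
      charge = num(5),
      dipole = cbind(num(6), num(7), num(8)),
      quadrupole = cbind(num(9), num(10), num(11), num(12), num(13),
                         num(14)),
      polarizability = num(15),
      damping = num(16),
      group = m[, 17]
    )
    frames[[length(frames) + 1L]] <-
      md_frame(sites, probe = probe, time = as.numeric(kv[["time"]]))
    i <- i + 2L + nat
  }
  frames
}

#' Build a frame from a PDB structure and a parameter table
#'
#' Reads coordinates with `bio3d::read.pdb` and joins per-atom
#' electrostatic parameters from a CSV keyed by atom serial number. The
#' CSV must have a `serial` column plus any of `charge`, `dx`, `dy`, `dz`,
#' `qxx`, `qxy`, `qxz`, `qyy`, `qyz`, `qzz`, `alpha`, `damping`, `group`;
#' missing columns default as in [atom_sites] (group defaults to the PDB
#' residue id). Atoms without a parameter row get zero charge.
#'
#' @param pdb_path path to a PDB file.
#' @param params_path path to the parameter CSV.
#' @param probe indices (into the PDB atom order) of ring C, nitrile C and
#'   nitrile N.
#' @param time frame time stamp (ps).
#' @return an [md_frame].
#' @export
read_frame_pdb <- function(pdb_path, params_path, probe, time = 0) {
  pdb <- bio3d::read.pdb(pdb_path)
  at <- pdb$atom
  n <- nrow(at)
  par <- utils::read.csv(params_path)
  if (!"serial" %in% names(par)) {
    stop("parameter table must have a `serial` column")
  }
  idx <- match(at$eleno, par$serial)
  get_col <- function(name, default) {
    v <- rep(default, n)
    if (name %in% names(par)) {
      hit <- !is.na(idx)
      v[hit] <- par[[name]][idx[hit]]
      v[is.na(v)] <- default
    }
    v
  }
  sites <- atom_sites(
    element = at$elesy,
    position = cbind(at$x, at$y, at$z),
    charge = get_col("charge", 0),
    dipole = cbind(get_col("dx", 0), get_col("dy", 0), get_col("dz", 0)),
    quadrupole = cbind(get_col("qxx", 0), get_col("qxy", 0),
                       get_col("qxz", 0), get_col("qyy", 0),
                       get_col("qyz", 0), get_col("qzz", 0)),
    polarizability = get_col("alpha", 0),
    damping = get_col("damping", 0.39),
    group = if ("group" %in% names(par)) get_col("group", "ungrouped")
            else paste0(at$resid, at$resno)
  )
  md_frame(sites, probe = probe, time = time)
}

write_versioned_csv <- function(df, path, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s %s", FORMAT_VERSION, what), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_versioned_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write a state/field trace as CSV
#'
#' Columns `time` (ps), `state` (0/1), `field` (MV/cm; `NA` when no field
#' trace is supplied).
#'
#' @param states a `state_trace`.
#' @param fields optional `field_trace` of the same length.
#' @param path output path.
#' @export
write_trace_csv <- function(states, fields = NULL, path) {
  f <- if (is.null(fields)) rep(NA_real_, length(states$states))
       else fields$fields
  if (length(f) != length(states$states)) {
    stop("field and state traces differ in length")
  }
  write_versioned_csv(
    data.frame(time = states$times, state = states$states, field = f),
    path, "trace")
}

#' Read a trace CSV written by [write_trace_csv]
#'
#' @param path input path.
#' @return list with `states` (a `state_trace`) and `fields` (a
#'   `field_trace`, or `NULL` when the file has no field column values).
#' @export
read_trace_csv <- function(path) {
  df <- read_versioned_csv(path)
  states <- structure(list(times = df$time, states = as.integer(df$state)),
                      class = "state_trace")
  fields <- if (all(is.na(df$field))) NULL else {
    structure(list(times = df$time, fields = df$field),
              class = "field_trace")
  }
  list(states = states, fields = fields)
}

#' Write / read a spectrum as 2-column CSV
#'
#' @param spectrum an `ir_spectrum`.
#' @param path file path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  write_versioned_csv(
    data.frame(wavenumber = spectrum$wavenumber,
               absorbance = spectrum$absorbance),
    path, "spectrum")
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- read_versioned_csv(path)
  structure(data.frame(wavenumber = df$wavenumber,
                       absorbance = df$absorbance),
            class = c("ir_spectrum", "data.frame"))
}

#' Write an ESP grid as a CSV matrix with a sidecar header
#'
#' The values file holds the nx x ny potential matrix (V, `NA` where
#' masked); the sidecar JSON records the plane specification, spacing and
#' mask so the grid can be rebuilt exactly.
#'
#' @param grid an `esp_grid`.
#' @param path values file path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @export
write_esp_grid <- function(grid, path) {
  utils::write.table(grid$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  sidecar <- list(format = FORMAT_VERSION,
                  origin = grid$plane$origin, e1 = grid$plane$e1,
                  e2 = grid$plane$e2, nx = grid$nx, ny = grid$ny,
                  spacing = grid$spacing,
                  mask = which(grid$mask, arr.ind = TRUE))
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read an ESP grid written by [write_esp_grid]
#'
#' @param path values file path (sidecar expected at
#'   `paste0(path, ".json")`).
#' @return an `esp_grid`.
#' @export
read_esp_grid <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(values) <- NULL
  structure(list(plane = plane_spec(side$origin, side$e1, side$e2),
                 nx = side$nx, ny = side$ny, spacing = side$spacing,
                 values = values, mask = is.na(values)),
            class = "esp_grid")
}
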