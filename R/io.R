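#' Write a waveform to CSV
#'
#' Two columns `time_s,value` preceded by `#`-prefixed header lines recording
#' the quantity kind (flow/pressure), unit and period. Values are written at
#' 9 significant digits, giving full round-trip fidelity.
#'
#' @param w a [flow_waveform()] or [pressure_waveform()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  kind <- if (inherits(w, "flow_waveform")) "flow" else "pressure"
  vals <- if (kind == "flow") w$flow else w$pressure
  header <- c(sprintf("# kind: %s", kind),
              sprintf("# unit: %s", w$unit),
              sprintf("# period_s: %.9g", w$period),
              "time_s,value")
  body <- sprintf("%.9g,%.9g", w$time, vals)
  writeLines(c(header, body), path)
  invisible(path)
}

.parse_header_field <- function(lines, key) {
  pat <- sprintf("^#\\s*%s:\\s*(.+?)\\s*$", key)
  hit <- grep(pat, lines)
  if (length(hit) == 0L)
    stop(sprintf("malformed waveform file: missing '# %s:' header line", key))
  sub(pat, "\\1", lines[hit[1L]])
}

#' Read a waveform from CSV
#'
#' Counterpart of [write_waveform_csv()]. Accepts LF and CRLF line endings.
#' SI-tagged units are converted on read to the package's interface units
#' (`m3/s` -> mL/s; `Pa`/`kPa` -> mmHg).
#'
#' @param path input file path.
#' @return a [flow_waveform()] or [pressure_waveform()] per the `kind` header.
#' @export
read_waveform_csv <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  kind <- .parse_header_field(lines, "kind")
  unit <- .parse_header_field(lines, "unit")
  period <- as.numeric(.parse_header_field(lines, "period_s"))
  if (!is.finite(period)) stop("malformed waveform file: unreadable period_s header")
  data <- lines[!grepl("^#", lines)]
  if (length(data) < 2L || data[1L] != "time_s,value")
    stop("malformed waveform file: expected 'time_s,value' column header")
  m <- utils::read.csv(text = data)
  scale <- switch(unit,
                  "mL/s" = 1, "m3/s" = 1e6,
                  "mmHg" = 1, "Pa" = 1 / 133.322387415, "kPa" = 1000 / 133.322387415,
                  stop(sprintf("unsupported unit '%s' in waveform file", unit)))
  if (kind == "flow") flow_waveform(m$time_s, m$value * scale, period)
  else if (kind == "pressure") pressure_waveform(m$time_s, m$value * scale, period)
  else stop(sprintf("unsupported waveform kind '%s'", kind))
}

#' Write a velocity-field ensemble to a directory
#'
#' One CSV per frame (`x_m,y_m,u_mps,v_mps,valid`) plus a `manifest.json`
#' recording frame rate, period, cycle/phase indexing and grid shape.
#'
#' @param ensemble a [cycle_ensemble()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_field_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "cycle_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("frame_%04d.csv", seq_along(ensemble$frames))
  for (k in seq_along(ensemble$frames)) {
    f <- ensemble$frames[[k]]
    grid <- expand.grid(y = f$y, x = f$x)  # row-major: y varies fastest
    df <- data.frame(x_m = grid$x, y_m = grid$y,
                     u_mps = as.vector(f$u), v_mps = as.vector(f$v),
                     valid = as.integer(as.vector(f$valid)))
    utils::write.csv(format(df, digits = 9, scientific = NA, trim = TRUE),
                     file.path(dir, files[k]), row.names = FALSE, quote = FALSE)
  }
  f1 <- ensemble$frames[[1L]]
  manifest <- list(frame_rate_hz = ensemble$frame_rate,
                   period_s = ensemble$period,
                   frames_per_cycle = ensemble$frames_per_cycle,
                   n_cycles = ensemble$n_cycles,
                   nx = length(f1$x), ny = length(f1$y),
                   frames = files)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read a velocity-field ensemble
#'
#' Counterpart of [write_field_ensemble()]. The manifest's frame count must
#' equal `frames_per_cycle * n_cycles`; a mismatch raises an error naming the
#' expected and found counts.
#'
#' @param manifest_path path to `manifest.json`.
#' @return a [cycle_ensemble()].
#' @export
read_field_ensemble <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  need <- c("frame_rate_hz", "period_s", "frames_per_cycle", "n_cycles",
            "nx", "ny", "frames")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop(sprintf("invalid manifest: missing field(s) %s", paste(miss, collapse = ", ")))
  expected <- man$frames_per_cycle * man$n_cycles
  if (length(man$frames) != expected)
    stop(sprintf("manifest frame count mismatch: expected %d (= %d x %d), found %d",
                 expected, man$frames_per_cycle, man$n_cycles, length(man$frames)))
  dir <- dirname(manifest_path)
  fpc <- man$frames_per_cycle
  frames <- lapply(seq_along(man$frames), function(k) {
    df <- utils::read.csv(file.path(dir, man$frames[k]))
    x <- sort(unique(df$x_m)); y <- sort(unique(df$y_m))
    if (length(x) != man$nx || length(y) != man$ny)
      stop(sprintf("frame %d grid (%d x %d) does not match manifest (%d x %d)",
                   k, length(x), length(y), man$nx, man$ny))
    velocity_field(x, y,
                   matrix(df$u_mps, man$ny, man$nx),
                   matrix(df$v_mps, man$ny, man$nx),
                   matrix(df$valid == 1, man$ny, man$nx),
                   phase = (k - 1L) %% fpc + 1L,
                   cycle = (k - 1L) %/% fpc + 1L)
  })
  cycle_ensemble(frames, man$frame_rate_hz, man$period_s, man$n_cycles)
}

#' Write/read a velocity profile CSV
#'
#' Columns `s_m,un_mps` with the same `#` header convention as waveform CSVs.
#'
#' @param profile a [velocity_profile()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "velocity_profile"))
  writeLines(c("# kind: velocity_profile", "# unit: m/s", "s_m,un_mps",
               sprintf("%.9g,%.9g", profile$s, profile$u_n)), path)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  data <- lines[!grepl("^#", lines)]
  if (length(data) < 2L || data[1L] != "s_m,un_mps")
    stop("malformed profile file: expected 's_m,un_mps' column header")
  m <- utils::read.csv(text = data)
  velocity_profile(m$s_m, m$un_mps)
}

#' Network JSON serialisation
#'
#' Branch list with R1/R2/C/R_s in the clinical units (mmHg s/mL, mL/mmHg)
#' plus the venous reference pressure.
#'
#' @param network an [aortic_network()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "aortic_network"))
  branches <- lapply(network$branches, function(b)
    list(label = b$label, R1 = b$wk$R1, R2 = b$wk$R2, C = b$wk$C, R_s = b$R_s))
  jsonlite::write_json(list(P_v_mmHg = network$P_v, branches = unname(branches)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$branches) || length(doc$branches) == 0L)
    stop("invalid network file: no branches")
  branches <- lapply(doc$branches, function(b) {
    for (k in c("label", "R1", "R2", "C"))
      if (is.null(b[[k]])) stop(sprintf("invalid network file: branch missing '%s'", k))
    branch_spec(b$label, windkessel_params(b$R1, b$R2, b$C),
                R_s = if (is.null(b$R_s)) 0 else b$R_s)
  })
  aortic_network(branches, P_v = if (is.null(doc$P_v_mmHg)) 0 else doc$P_v_mmHg)
}

#' Target-set JSON serialisation
#'
#' @param targets a [target_set()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_targets_json <- function(targets, path) {
  stopifnot(inherits(targets, "target_set"))
  jsonlite::write_json(list(P_sys_mmHg = targets$P_sys, P_dia_mmHg = targets$P_dia,
                            Q_in_mL_s = targets$Q_in,
                            flows_mL_s = as.list(targets$flows)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_targets_json
#' @export
read_targets_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("P_sys_mmHg", "P_dia_mmHg", "flows_mL_s"))
    if (is.null(doc[[k]])) stop(sprintf("invalid targets file: missing '%s'", k))
  flows <- unlist(doc$flows_mL_s)
  target_set(doc$P_sys_mmHg, doc$P_dia_mmHg, flows,
             Q_in = if (is.null(doc$Q_in_mL_s)) sum(flows) else doc$Q_in_mL_s)
}
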