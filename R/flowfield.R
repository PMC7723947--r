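#' Planar gridded velocity field
#'
#' One frame of a planar velocity measurement or simulation: components u, v
#' (m/s) on a regular rectangular grid. Matrices are indexed `[row, col]` =
#' `[y, x]`, with y increasing upward. Invalid points are carried in an
#' explicit logical mask and excluded from all statistics.
#'
#' @param x grid x coordinates, m (length nx, increasing).
#' @param y grid y coordinates, m (length ny, increasing).
#' @param u,v velocity components, ny x nx matrices, m/s.
#' @param valid logical ny x nx mask (default all TRUE).
#' @param phase,cycle optional 1-based phase/cycle indices of the frame.
#' @return object of class `velocity_field`.
#' @export
velocity_field <- function(x, y, u, v, valid = NULL, phase = NA_integer_,
                           cycle = NA_integer_) {
  nx <- length(x); ny <- length(y)
  stopifnot(is.matrix(u), is.matrix(v), all(dim(u) == c(ny, nx)),
            all(dim(v) == c(ny, nx)))
  if (nx > 1 && any(diff(x) <= 0)) stop("x must be increasing")
  if (ny > 1 && any(diff(y) <= 0)) stop("y must be increasing")
  if (is.null(valid)) valid <- matrix(TRUE, ny, nx)
  stopifnot(is.logical(valid), all(dim(valid) == c(ny, nx)))
  structure(list(x = x, y = y, u = u, v = v, valid = valid,
                 phase = phase, cycle = cycle),
            class = "velocity_field")
}

#' Multi-cycle ensemble of velocity frames
#'
#' Ordered frames from a cyclic acquisition: frame k belongs to phase
#' `(k - 1) %% frames_per_cycle + 1` of cycle `(k - 1) %/% frames_per_cycle + 1`,
#' with `frames_per_cycle = round(period * frame_rate)`.
#'
#' @param frames list of [velocity_field()] frames in acquisition order.
#' @param frame_rate acquisition rate f, Hz.
#' @param period cycle length T, s.
#' @param n_cycles number of complete cycles.
#' @return object of class `cycle_ensemble`.
#' @export
cycle_ensemble <- function(frames, frame_rate, period, n_cycles) {
  fpc <- as.integer(round(period * frame_rate))
  if (length(frames) != fpc * n_cycles)
    stop(sprintf("expected %d frames (= %d phases x %d cycles), found %d",
                 fpc * n_cycles, fpc, n_cycles, length(frames)))
  stopifnot(all(vapply(frames, inherits, TRUE, "velocity_field")))
  structure(list(frames = frames, frame_rate = frame_rate, period = period,
                 frames_per_cycle = fpc, n_cycles = as.integer(n_cycles)),
            class = "cycle_ensemble")
}

#' @export
print.cycle_ensemble <- function(x, ...) {
  f1 <- x$frames[[1L]]
  cat(sprintf("<cycle_ensemble> %d frames (%d phases x %d cycles), grid %d x %d, f = %g Hz, T = %g s\n",
              length(x$frames), x$frames_per_cycle, x$n_cycles,
              length(f1$x), length(f1$y), x$frame_rate, x$period))
  invisible(x)
}

#' Phase-averaged velocity statistics
#'
#' Groups the ensemble's frames by phase and computes, per grid point and
#' phase, the mean and standard deviation of each velocity component over
#' cycles, excluding masked points point-wise. Frames beyond the last complete
#' cycle are ignored with a warning.
#'
#' @param ensemble a [cycle_ensemble()] (or a plain list of frames plus the
#'   `frames_per_cycle` attribute via [cycle_ensemble()]).
#' @return object of class `phase_average`: arrays `u_mean`, `v_mean`, `u_sd`,
#'   `v_sd`, `n` of dim (ny, nx, phases) plus the grid. With a single
#'   contributing cycle the SD is reported as 0 and `n` = 1.
#' @export
phase_average <- function(ensemble) {
  stopifnot(inherits(ensemble, "cycle_ensemble"))
  fpc <- ensemble$frames_per_cycle
  nfr <- length(ensemble$frames)
  ncyc <- nfr %/% fpc
  if (nfr %% fpc != 0L) {
    warning(sprintf("ignoring %d frames beyond the last complete cycle", nfr %% fpc))
  }
  f1 <- ensemble$frames[[1L]]
  ny <- length(f1$y); nx <- length(f1$x)
  dims <- c(ny, nx, fpc)
  u_mean <- v_mean <- u_sd <- v_sd <- array(NA_real_, dims)
  n_arr <- array(0L, dims)
  for (p in seq_len(fpc)) {
    ks <- p + fpc * (seq_len(ncyc) - 1L)
    us <- lapply(ensemble$frames[ks], `[[`, "u")
    vs <- lapply(ensemble$frames[ks], `[[`, "v")
    ms <- lapply(ensemble$frames[ks], `[[`, "valid")
    cnt <- Reduce(`+`, lapply(ms, function(m) m * 1L))
    usum <- Reduce(`+`, mapply(function(a, m) ifelse(m, a, 0), us, ms, SIMPLIFY = FALSE))
    vsum <- Reduce(`+`, mapply(function(a, m) ifelse(m, a, 0), vs, ms, SIMPLIFY = FALSE))
    um <- ifelse(cnt > 0, usum / pmax(cnt, 1L), NA_real_)
    vm <- ifelse(cnt > 0, vsum / pmax(cnt, 1L), NA_real_)
    uss <- Reduce(`+`, mapply(function(a, m) ifelse(m, (a - um)^2, 0), us, ms, SIMPLIFY = FALSE))
    vss <- Reduce(`+`, mapply(function(a, m) ifelse(m, (a - vm)^2, 0), vs, ms, SIMPLIFY = FALSE))
    usd <- ifelse(cnt > 1, sqrt(uss / pmax(cnt - 1L, 1L)), ifelse(cnt == 1, 0, NA_real_))
    vsd <- ifelse(cnt > 1, sqrt(vss / pmax(cnt - 1L, 1L)), ifelse(cnt == 1, 0, NA_real_))
    u_mean[, , p] <- um; v_mean[, , p] <- vm
    u_sd[, , p] <- usd; v_sd[, , p] <- vsd
    n_arr[, , p] <- cnt
  }
  structure(list(x = f1$x, y = f1$y, u_mean = u_mean, v_mean = v_mean,
                 u_sd = u_sd, v_sd = v_sd, n = n_arr,
                 n_cycles = ncyc, frames_per_cycle = fpc),
            class = "phase_average")
}

#' Cycle-count convergence of the phase average
#'
#' For n = 2..n_cycles, the variation introduced by adding the n-th cycle:
#' the maximum, over a grid region and all phases, of the running-mean change
#' |mean_n - mean_(n-1)|, normalised by the largest final phase-averaged
#' speed over the region, in percent.
#'
#' @param ensemble a [cycle_ensemble()].
#' @param region optional logical ny x nx matrix selecting the evaluation
#'   region (default: points valid in every frame).
#' @return data.frame with columns `n` and `variation` (percent).
#' @export
convergence_curve <- function(ensemble, region = NULL) {
  stopifnot(inherits(ensemble, "cycle_ensemble"))
  fpc <- ensemble$frames_per_cycle
  ncyc <- ensemble$n_cycles
  f1 <- ensemble$frames[[1L]]
  if (is.null(region))
    region <- Reduce(`&`, lapply(ensemble$frames, `[[`, "valid"))
  if (!any(region)) stop("empty evaluation region")
  # running means per phase over the region
  sel <- which(region)
  um <- array(0, c(length(sel), fpc))
  final <- array(0, c(length(sel), fpc))
  for (p in seq_len(fpc)) {
    ks <- p + fpc * (seq_len(ncyc) - 1L)
    final[, p] <- rowMeans(vapply(ensemble$frames[ks],
                                  function(f) f$u[sel], numeric(length(sel))))
  }
  norm <- max(abs(final))
  out <- data.frame(n = 2:ncyc, variation = NA_real_)
  run <- matrix(0, length(sel), fpc)
  prev <- NULL
  for (n in seq_len(ncyc)) {
    for (p in seq_len(fpc)) {
      k <- p + fpc * (n - 1L)
      run[, p] <- run[, p] + ensemble$frames[[k]]$u[sel]
    }
    cur <- run / n
    if (n >= 2L)
      out$variation[n - 1L] <- max(abs(cur - prev)) / max(norm, 1e-300) * 100
    prev <- cur
  }
  out
}

#' Normalized median test for spurious vectors
#'
#' Universal PIV outlier detector: for each vector and velocity component, the
#' residual to the median of its neighbourhood (excluding the vector itself)
#' is normalised by the median of the neighbours' own residuals plus a noise
#' floor `eps`; the vector is flagged when the normalised residual exceeds
#' `threshold` in either component. The default `half_window = 2` gives the
#' standard 5 x 5 neighbourhood; borders use shrunken neighbourhoods and
#' masked points are excluded.
#'
#' @param field a [velocity_field()].
#' @param half_window neighbourhood half width (default 2, i.e. 5 x 5).
#' @param threshold detection threshold on the normalised residual (default 2).
#' @param eps noise floor in m/s (default 0.02).
#' @param fill if TRUE, also return the field with flagged vectors replaced by
#'   their neighbourhood medians.
#' @return list with `flags` (logical matrix), `residual` (max normalised
#'   residual over components), `unresolved` (points whose neighbourhood was
#'   entirely masked, left unflagged) and optionally `filled`.
#' @export
normalized_median_filter <- function(field, half_window = 2L, threshold = 2,
                                     eps = 0.02, fill = FALSE) {
  stopifnot(inherits(field, "velocity_field"))
  ny <- length(field$y); nx <- length(field$x)
  if (2L * half_window + 1L > min(ny, nx))
    stop("neighbourhood window does not fit in the grid")
  res <- pmax(.nmt_residual(field$u, field$valid, half_window, eps),
              .nmt_residual(field$v, field$valid, half_window, eps))
  unresolved <- is.na(res) & field$valid
  flags <- !is.na(res) & res > threshold & field$valid
  out <- list(flags = flags, residual = res, unresolved = unresolved)
  if (fill) {
    med_u <- .neighbourhood_median(field$u, field$valid & !flags, half_window)
    med_v <- .neighbourhood_median(field$v, field$valid & !flags, half_window)
    u2 <- field$u; v2 <- field$v
    u2[flags] <- med_u[flags]; v2[flags] <- med_v[flags]
    out$filled <- velocity_field(field$x, field$y, u2, v2, field$valid,
                                 field$phase, field$cycle)
  }
  out
}

# stack the (2w+1)^2 - 1 neighbour shifts of a matrix as columns (NA-padded)
.neighbour_stack <- function(m, valid, w) {
  ny <- nrow(m); nx <- ncol(m)
  m[!valid] <- NA_real_
  shifts <- expand.grid(dy = -w:w, dx = -w:w)
  shifts <- shifts[!(shifts$dy == 0 & shifts$dx == 0), ]
  out <- matrix(NA_real_, ny * nx, nrow(shifts))
  for (s in seq_len(nrow(shifts))) {
    dy <- shifts$dy[s]; dx <- shifts$dx[s]
    src_r <- seq_len(ny) - dy; src_c <- seq_len(nx) - dx
    ok_r <- src_r >= 1 & src_r <= ny; ok_c <- src_c >= 1 & src_c <= nx
    shifted <- matrix(NA_real_, ny, nx)
    shifted[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
    out[, s] <- as.vector(shifted)
  }
  out
}

.row_median <- function(m) {
  apply(m, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0L) NA_real_ else stats::median(r)
  })
}

.nmt_residual <- function(comp, valid, w, eps) {
  nb <- .neighbour_stack(comp, valid, w)
  med <- .row_median(nb)
  rm_ <- .row_median(abs(nb - med))
  r <- abs(as.vector(comp) - med) / (rm_ + eps)
  r[!as.vector(valid)] <- NA_real_
  matrix(r, nrow(comp), ncol(comp))
}

.neighbourhood_median <- function(comp, valid, w) {
  matrix(.row_median(.neighbour_stack(comp, valid, w)), nrow(comp), ncol(comp))
}

#' Directed sampling line for profile extraction
#'
#' A directed segment with its unit normal, defined as the +90 degree
#' (counter-clockwise) rotation of the line direction — this fixes the sign
#' convention of the normal velocity u_n.
#'
#' @param p0,p1 numeric length-2 endpoints (x, y) in metres.
#' @param n number of equally spaced samples (default 1000).
#' @return object of class `profile_line` with fields `p0`, `p1`, `normal`,
#'   `n`, `length`.
#' @export
profile_line <- function(p0, p1, n = 1000L) {
  stopifnot(length(p0) == 2L, length(p1) == 2L)
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  if (len <= 0) stop("profile line must have nonzero length")
  dir <- d / len
  structure(list(p0 = p0, p1 = p1, direction = dir,
                 normal = c(-dir[2L], dir[1L]), n = as.integer(n), length = len),
            class = "profile_line")
}

# bilinear interpolation of a matrix field at arbitrary points
.bilinear <- function(x, y, z, valid, xi, yi) {
  nx <- length(x); ny <- length(y)
  jx <- findInterval(xi, x, rightmost.closed = TRUE)
  jy <- findInterval(yi, y, rightmost.closed = TRUE)
  inside <- jx >= 1L & jx < nx & jy >= 1L & jy < ny
  # points exactly on the top/right edge
  on_edge_x <- abs(xi - x[nx]) < 1e-12
  on_edge_y <- abs(yi - y[ny]) < 1e-12
  jx[on_edge_x] <- nx - 1L; jy[on_edge_y] <- ny - 1L
  inside <- (jx >= 1L & jx < nx & jy >= 1L & jy < ny) &
    (xi >= x[1L] - 1e-12) & (yi >= y[1L] - 1e-12) &
    (xi <= x[nx] + 1e-12) & (yi <= y[ny] + 1e-12)
  out <- rep(NA_real_, length(xi))
  ok <- rep(FALSE, length(xi))
  idx <- which(inside)
  if (length(idx)) {
    j <- jx[idx]; i <- jy[idx]
    tx <- (xi[idx] - x[j]) / (x[j + 1L] - x[j])
    ty <- (yi[idx] - y[i]) / (y[i + 1L] - y[i])
    c00 <- z[cbind(i, j)];      c10 <- z[cbind(i, j + 1L)]
    c01 <- z[cbind(i + 1L, j)]; c11 <- z[cbind(i + 1L, j + 1L)]
    v00 <- valid[cbind(i, j)];      v10 <- valid[cbind(i, j + 1L)]
    v01 <- valid[cbind(i + 1L, j)]; v11 <- valid[cbind(i + 1L, j + 1L)]
    out[idx] <- (1 - ty) * ((1 - tx) * c00 + tx * c10) +
      ty * ((1 - tx) * c01 + tx * c11)
    ok[idx] <- v00 & v10 & v01 & v11
  }
  list(value = out, valid = ok)
}

#' Extract a normal-velocity profile along a line
#'
#' Samples the field at N equally spaced points along the directed line by
#' bilinear interpolation and projects the velocity on the line's unit normal:
#' u_n = (u, v) . n_hat. Samples outside the grid or touching masked grid
#' points are marked invalid.
#'
#' @param field a [velocity_field()].
#' @param line a [profile_line()].
#' @return object of class `velocity_profile`: `s` (arc length, m), `u_n`
#'   (m/s, NA where invalid), `valid`, `line`.
#' @export
extract_profile <- function(field, line) {
  stopifnot(inherits(field, "velocity_field"), inherits(line, "profile_line"))
  s <- seq(0, line$length, length.out = line$n)
  xi <- line$p0[1L] + s * line$direction[1L]
  yi <- line$p0[2L] + s * line$direction[2L]
  ui <- .bilinear(field$x, field$y, field$u, field$valid, xi, yi)
  vi <- .bilinear(field$x, field$y, field$v, field$valid, xi, yi)
  if (!any(ui$valid)) stop("profile line lies fully outside the valid grid")
  u_n <- ui$value * line$normal[1L] + vi$value * line$normal[2L]
  ok <- ui$valid & vi$valid
  u_n[!ok] <- NA_real_
  structure(list(s = s, u_n = u_n, valid = ok, line = line),
            class = "velocity_profile")
}

#' Velocity profile from raw samples
#'
#' @param s arc-length coordinates, m.
#' @param u_n normal velocity samples, m/s (NA = invalid).
#' @return object of class `velocity_profile`.
#' @export
velocity_profile <- function(s, u_n) {
  stopifnot(length(s) == length(u_n))
  structure(list(s = s, u_n = u_n, valid = is.finite(u_n), line = NULL),
            class = "velocity_profile")
}

#' Normalised profile-difference metric
#'
#' Mean absolute difference between an experimental and a computational
#' normal-velocity profile, normalised by the peak magnitude of the
#' computational profile and reported in percent:
#' Delta = 100/N * sum_i |u_e,i - u_c,i| / max_j |u_c,j|.
#' Profiles are linearly resampled onto a common N-point grid over the
#' overlapping arc length; only points valid in both profiles are counted and
#' the effective N is reported.
#'
#' @param experimental,computational [velocity_profile()] objects.
#' @param n number of comparison points (default 1000).
#' @return object of class `comparison_report`: `delta` (percent), `n_used`,
#'   `abs_diff` (m/s), `normaliser` (m/s).
#' @export
delta_metric <- function(experimental, computational, n = 1000L) {
  stopifnot(inherits(experimental, "velocity_profile"),
            inherits(computational, "velocity_profile"))
  same_grid <- length(experimental$s) == length(computational$s) &&
    all(abs(experimental$s - computational$s) < 1e-12)
  if (same_grid && length(experimental$s) == n) {
    ue <- experimental$u_n; uc <- computational$u_n
  } else {
    lo <- max(min(experimental$s), min(computational$s))
    hi <- min(max(experimental$s), max(computational$s))
    if (hi <= lo) stop("profiles do not overlap in arc length")
    sg <- seq(lo, hi, length.out = n)
    ue <- stats::approx(experimental$s, experimental$u_n, xout = sg)$y
    uc <- stats::approx(computational$s, computational$u_n, xout = sg)$y
  }
  ok <- is.finite(ue) & is.finite(uc)
  if (!any(ok)) stop("no mutually valid points")
  norm <- max(abs(uc[ok]))
  if (norm <= 0) stop("computational profile is identically zero: normaliser undefined")
  d <- abs(ue[ok] - uc[ok])
  structure(list(delta = mean(d / norm) * 100, n_used = sum(ok),
                 abs_diff = d, normaliser = norm),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> Delta = %.2f%% over %d points (normaliser %.3g m/s)\n",
              x$delta, x$n_used, x$normaliser))
  invisible(x)
}

#' Flow rate from a diametral profile under axial symmetry
#'
#' Folds the two half-profiles about the axis position onto a common radial
#' grid, averages them, and integrates Q = 2 pi int_0^R u(r) r dr by the
#' trapezoid rule (double integration under the axisymmetry assumption).
#'
#' @param profile a [velocity_profile()] spanning the full lumen chord.
#' @param axis_position arc-length position of the symmetry axis on the line, m.
#' @param n_radial radial integration points (default: profile resolution).
#' @return flow rate in mL/s.
#' @export
axisymmetric_flow_rate <- function(profile, axis_position, n_radial = NULL) {
  stopifnot(inherits(profile, "velocity_profile"))
  s <- profile$s; u <- profile$u_n
  if (axis_position <= min(s) || axis_position >= max(s))
    stop("axis position must lie strictly inside the profile span")
  ok <- is.finite(u)
  s <- s[ok]; u <- u[ok]
  left <- s <= axis_position; right <- s >= axis_position
  r_left <- axis_position - s[left]; u_left <- u[left]
  r_right <- s[right] - axis_position; u_right <- u[right]
  R <- min(max(r_left), max(r_right))
  if (is.null(n_radial)) n_radial <- max(16L, floor(length(s) / 2))
  r <- seq(0, R, length.out = n_radial)
  ul <- stats::approx(r_left, u_left, xout = r, rule = 2)$y
  ur <- stats::approx(r_right, u_right, xout = r, rule = 2)$y
  um <- (ul + ur) / 2
  integrand <- um * r
  Q_m3s <- 2 * pi * sum((integrand[-1L] + integrand[-n_radial]) / 2 * diff(r))
  Q_m3s * 1e6
}

#' Inter-section mass-conservation error
#'
#' Spread of the flow rates computed at successive cross sections of a
#' conduit, as a percentage of their mean: (max - min)/mean * 100 by default,
#' or SD/mean * 100 with `method = "sd"`.
#'
#' @param section_flows numeric vector of flow rates (>= 2 sections).
#' @param method "range" (default) or "sd".
#' @return error in percent.
#' @export
mass_conservation_error <- function(section_flows, method = c("range", "sd")) {
  method <- match.arg(method)
  if (length(section_flows) < 2L) stop("at least 2 sections are required")
  m <- mean(section_flows)
  if (abs(m) < 1e-300) stop("mean section flow is zero")
  if (method == "range") (max(section_flows) - min(section_flows)) / m * 100
  else stats::sd(section_flows) / m * 100
}
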