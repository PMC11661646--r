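#' 2D bin specification for phase-space grids
#'
#' @param nx,ny number of bins per axis.
#' @param xlim,ylim axis ranges; default the unit square of the asymmetry
#'   factors.
#' @return a `phase_bins` list with axis break points and bin centres.
#' @export
phase_bins <- function(nx = 50, ny = nx, xlim = c(0, 1), ylim = c(0, 1)) {
  structure(list(
    xbreaks = seq(xlim[1], xlim[2], length.out = nx + 1),
    ybreaks = seq(ylim[1], ylim[2], length.out = ny + 1),
    xmid = (seq_len(nx) - 0.5) / nx * diff(xlim) + xlim[1],
    ymid = (seq_len(ny) - 0.5) / ny * diff(ylim) + ylim[1],
    nx = nx, ny = ny), class = "phase_bins")
}

.bin_index <- function(v, breaks) {
  i <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  i[v < breaks[1] | v > breaks[length(breaks)]] <- NA_integer_
  i
}

#' Time-windowed weighted phase-space histogram
#'
#' Normalized histogram of the weighted (lambda_AC, lambda_BD) points with
#' timestamps in `t_center` +/- `half_window`, the phase-space density
#' snapshot at time `t_center`.
#'
#' @param samples a `weighted_samples` data frame.
#' @param t_center window centre (s).
#' @param half_window half width of the window (s), default 300 (5 min).
#' @param bins a [phase_bins] specification.
#' @return a `field_grid` with layer `density` (matrix nx x ny, sums to 1).
#' @export
weighted_histogram <- function(samples, t_center, half_window = 300,
                               bins = phase_bins()) {
  sel <- abs(samples$t - t_center) <= half_window
  if (!any(sel)) stop("empty time window: no samples in t_center +/- half_window")
  s <- samples[sel, ]
  ix <- .bin_index(s$lambda_AC, bins$xbreaks)
  iy <- .bin_index(s$lambda_BD, bins$ybreaks)
  ok <- !is.na(ix) & !is.na(iy)
  h <- matrix(0, bins$nx, bins$ny)
  for (k in which(ok)) h[ix[k], iy[k]] <- h[ix[k], iy[k]] + s$w[k]
  tot <- sum(h)
  if (tot <= 0) stop("empty time window: all samples carry zero weight")
  structure(list(bins = bins, density = h / tot, t_center = t_center),
            class = "field_grid")
}

#' Pattern survival curve
#'
#' Weighted fraction of trajectory lineages that have never left the region
#' of intact patterns `R_S` up to time t. First exits are detected
#' per-lineage (branch ancestry aware): a lineage contributes, at its first
#' recorded point outside `R_S`, the statistical weight it carries at that
#' moment; descendants of an exited lineage are not counted again. Re-entries
#' are not counted, so S(t) is non-increasing by construction.
#'
#' @param samples a `weighted_samples` data frame (from [reweight()] or
#'   [as_weighted_samples()]).
#' @param thresholds region boundaries passed to [classify_region()].
#' @return a `survival_curve` data frame (t, S) with the exit events in
#'   attribute `"exits"`.
#' @export
survival_probability <- function(samples, thresholds = c(0.45, 0.43)) {
  outside <- classify_region(samples$lambda_AC, samples$lambda_BD,
                             thresholds) != "R_S"
  ev <- .lineage_first_events(samples, outside)
  br <- attr(samples, "branches")
  W0 <- sum(br$w_birth[br$parent == 0])
  tt <- sort(unique(c(0, samples$t)))
  Sv <- vapply(tt, function(x) 1 - sum(ev$w[ev$t <= x]) / W0, 0.0)
  out <- data.frame(t = tt, S = Sv)
  attr(out, "exits") <- ev
  attr(out, "W0") <- W0
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Fit the pattern destruction rate from a survival curve
#'
#' Fits `S(t) = exp(-k_D * (t - t_lag))` (S clipped at 1 before `t_lag`)
#' using the lag-scan protocol: for every candidate `t_start` on a grid the
#' exponential is fitted on `[t_start, t_end]`, and the fit whose estimated
#' `t_lag` is closest to its own `t_start` is selected. A linear control fit
#' `1 - S(t) = k_D * (t - t_lag)` on the same interval is also returned.
#'
#' @param S a `survival_curve` (or data frame with columns t, S).
#' @param t_start_grid candidate fit-start times; default every 900 s from 0
#'   to `t_end / 2`.
#' @return list `k_D` (1/s), `t_lag` (s), `tau_D = 1/k_D` (s), the chosen
#'   `t_start`, the per-candidate scan table, and `linear_k_D` from the
#'   control fit. If S never drops below 1, `k_D = 0` and `tau_D = Inf`.
#' @export
fit_destruction_rate <- function(S, t_start_grid = NULL) {
  S <- S[order(S$t), ]
  t_end <- max(S$t)
  if (all(S$S >= 1 - 1e-12))
    return(list(k_D = 0, t_lag = NA_real_, tau_D = Inf, t_start = NA_real_,
                scan = NULL, linear_k_D = 0))
  if (is.null(t_start_grid))
    t_start_grid <- seq(0, t_end / 2, by = 900)
  scan <- lapply(t_start_grid, function(ts) {
    d <- S[S$t >= ts, ]
    if (nrow(d) < 10 || length(unique(d$S)) < 3) return(NULL)
    k0 <- {
      pos <- d$S > 0
      if (sum(pos) >= 2) {
        sl <- stats::coef(stats::lsfit(d$t[pos], log(d$S[pos])))[2]
        max(-sl, 1e-10)
      } else 1e-4
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(S ~ exp(-k * (t - tlag)), data = d,
                        start = list(k = k0, tlag = ts),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    co <- stats::coef(fit)
    data.frame(t_start = ts, k_D = co[["k"]], t_lag = co[["tlag"]],
               mismatch = abs(co[["tlag"]] - ts))
  })
  scan <- do.call(rbind, scan)
  if (is.null(scan) || nrow(scan) == 0 || all(!is.finite(scan$k_D)))
    stop("destruction-rate fit failed at every candidate t_start")
  scan <- scan[is.finite(scan$k_D) & scan$k_D >= 0, ]
  best <- scan[which.min(scan$mismatch), ]
  # linear control fit on 1 - S over the same interval
  d <- S[S$t >= best$t_start, ]
  lin <- stats::lm(I(1 - S) ~ t, data = d)
  list(k_D = best$k_D, t_lag = best$t_lag,
       tau_D = if (best$k_D > 0) 1 / best$k_D else Inf,
       t_start = best$t_start, scan = scan,
       linear_k_D = unname(stats::coef(lin)[2]))
}

#' Region occupation probability over time
#'
#' Weighted probability mass inside one phase-space region at each
#' measurement time, using the weight present in the region (lineage history
#' is irrelevant here).
#'
#' @param samples a `weighted_samples` data frame.
#' @param region one of [ac_regions].
#' @param thresholds region boundaries.
#' @param t_grid times at which to evaluate; default the distinct measurement
#'   times (crossing records excluded to keep the grid regular).
#' @return data frame (t, P).
#' @export
region_occupation <- function(samples, region,
                              thresholds = c(0.45, 0.43), t_grid = NULL) {
  reg <- classify_region(samples$lambda_AC, samples$lambda_BD, thresholds)
  if (is.null(t_grid))
    t_grid <- sort(unique(samples$t[!samples$at_crossing]))
  inw <- reg == region
  P <- vapply(t_grid, function(x) {
    sel <- abs(samples$t - x) < 1e-6 & !samples$at_crossing
    tot <- sum(samples$w[sel])
    if (tot <= 0) return(NA_real_)
    sum(samples$w[sel & inw]) / tot
  }, 0.0)
  data.frame(t = t_grid, P = P)
}

#' Average probability flux into a region
#'
#' Slope of a linear fit `P_R(t) = J_avg * t + P_0` to the region occupation
#' probability; the intercept is discarded.
#'
#' @param P_R data frame (t, P) from [region_occupation()] (or any table of
#'   occupation probability over time).
#' @param t_start fit window start; default the first time with nonzero
#'   occupation change.
#' @return `J_avg` in 1/s.
#' @export
average_flux <- function(P_R, t_start = NULL) {
  d <- P_R[is.finite(P_R$P), ]
  if (is.null(t_start)) {
    changing <- which(abs(diff(d$P)) > 0)
    t_start <- if (length(changing)) d$t[changing[1]] else d$t[1]
  }
  d <- d[d$t >= t_start, ]
  if (nrow(d) < 2) stop("not enough points for the flux fit")
  unname(stats::coef(stats::lm(P ~ t, data = d))[2])
}

# Branch-aware displacement pairs at lag dt: consecutive measurement records
# of the same branch exactly dt apart (never across branch points, because a
# child is a different branch id). Returns origin coordinates, displacements
# and origin weights.
.displacements <- function(samples, dt) {
  s <- samples[!samples$at_crossing, ]
  s <- s[order(s$tree, s$branch, s$t), ]
  n <- nrow(s)
  if (n < 2) stop("not enough samples")
  same <- s$tree[-1] == s$tree[-n] & s$branch[-1] == s$branch[-n]
  gap <- abs(s$t[-1] - s$t[-n] - dt) < 1e-6
  k <- which(same & gap)
  data.frame(lambda_AC = s$lambda_AC[k], lambda_BD = s$lambda_BD[k],
             dx = s$lambda_AC[k + 1] - s$lambda_AC[k],
             dy = s$lambda_BD[k + 1] - s$lambda_BD[k],
             w = s$w[k])
}

#' Phase-space drift (velocity) field
#'
#' Per-bin weighted mean of the outgoing displacements over one measurement
#' interval, expressed in phase-space units per hour (PSU/h). Displacements
#' are paired within a branch only. Bins without outgoing samples are empty
#' (NA), not zero.
#'
#' @param samples a `weighted_samples` data frame.
#' @param dt displacement lag (s); must match the measurement interval used
#'   when recording.
#' @param bins a [phase_bins] specification.
#' @return a `field_grid` with layers `vx`, `vy` (PSU/h), `n` (pair counts)
#'   and `wsum`.
#' @export
velocity_field <- function(samples, dt, bins = phase_bins()) {
  d <- .displacements(samples, dt)
  ix <- .bin_index(d$lambda_AC, bins$xbreaks)
  iy <- .bin_index(d$lambda_BD, bins$ybreaks)
  ok <- !is.na(ix) & !is.na(iy)
  vx <- vy <- wsum <- matrix(0, bins$nx, bins$ny)
  n <- matrix(0L, bins$nx, bins$ny)
  for (k in which(ok)) {
    i <- ix[k]; j <- iy[k]
    vx[i, j] <- vx[i, j] + d$w[k] * d$dx[k]
    vy[i, j] <- vy[i, j] + d$w[k] * d$dy[k]
    wsum[i, j] <- wsum[i, j] + d$w[k]
    n[i, j] <- n[i, j] + 1L
  }
  empty <- wsum <= 0
  scale <- 3600 / dt
  vx <- ifelse(empty, NA_real_, vx / wsum * scale)
  vy <- ifelse(empty, NA_real_, vy / wsum * scale)
  structure(list(bins = bins, vx = vx, vy = vy, n = n, wsum = wsum, dt = dt),
            class = "field_grid")
}

#' Phase-space diffusion coefficient field
#'
#' Local diffusion coefficient of the overdamped description of the
#' asymmetry-factor dynamics,
#' `D_lambda = (<dl^2> - <dl_AC>^2 - <dl_BD>^2) / (4 dt)` per bin (the
#' variance of the two-component displacement around its mean, divided by
#' 4 dt), in PSU^2/h.
#'
#' @inheritParams velocity_field
#' @return a `field_grid` with layers `D` (PSU^2/h), `n`, `wsum`.
#' @export
phase_diffusion <- function(samples, dt, bins = phase_bins()) {
  d <- .displacements(samples, dt)
  ix <- .bin_index(d$lambda_AC, bins$xbreaks)
  iy <- .bin_index(d$lambda_BD, bins$ybreaks)
  ok <- !is.na(ix) & !is.na(iy)
  sx <- sy <- s2 <- wsum <- matrix(0, bins$nx, bins$ny)
  n <- matrix(0L, bins$nx, bins$ny)
  for (k in which(ok)) {
    i <- ix[k]; j <- iy[k]
    sx[i, j] <- sx[i, j] + d$w[k] * d$dx[k]
    sy[i, j] <- sy[i, j] + d$w[k] * d$dy[k]
    s2[i, j] <- s2[i, j] + d$w[k] * (d$dx[k]^2 + d$dy[k]^2)
    wsum[i, j] <- wsum[i, j] + d$w[k]
    n[i, j] <- n[i, j] + 1L
  }
  empty <- wsum <= 0
  mx <- sx / wsum
  my <- sy / wsum
  D <- (s2 / wsum - mx^2 - my^2) / (4 * dt) * 3600
  D <- ifelse(empty, NA_real_, D)
  structure(list(bins = bins, D = D, n = n, wsum = wsum, dt = dt),
            class = "field_grid")
}

#' 2D median filter with edge replication
#'
#' Square window of `size x size` bins (window anchored so that it is
#' centred for odd sizes and upper-left-of-centre for even sizes); values
#' outside the grid are replicated from the nearest edge. NA cells are
#' ignored within the window.
#'
#' @param m numeric matrix.
#' @param size window side length in bins.
#' @return filtered matrix of the same shape.
#' @export
median_filter2 <- function(m, size = 4) {
  nr <- nrow(m); nc <- ncol(m)
  lo <- -((size - 1L) %/% 2L)
  hi <- size %/% 2L
  out <- m
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- pmin(pmax(i + (lo:hi), 1L), nr)
    jj <- pmin(pmax(j + (lo:hi), 1L), nc)
    v <- m[ii, jj]
    out[i, j] <- stats::median(v, na.rm = TRUE)
  }
  out[!is.finite(out)] <- NA_real_
  out
}

#' Pseudopotential landscape
#'
#' `-log(p~)` of the phase-space density built from the weighted outgoing
#' trajectory counts per bin, smoothed by a 2D median filter over `n_filt`
#' neighbouring bins. Barrier heights relative to the intact-pattern basin
#' are the biophysically meaningful feature of the landscape; the absolute
#' depth of destroyed-pattern basins grows with the simulated time after
#' destruction. Empty bins are masked (NA).
#'
#' @param samples a `weighted_samples` data frame.
#' @param bins a [phase_bins] specification.
#' @param n_filt median filter window size (bins), default 4.
#' @param dt displacement lag defining "outgoing" counts; if `NULL`, all
#'   recorded points are used instead of outgoing displacements.
#' @return a `field_grid` with layers `density`, `potential`.
#' @export
pseudopotential <- function(samples, bins = phase_bins(), n_filt = 4,
                            dt = NULL) {
  if (is.null(dt)) {
    ix <- .bin_index(samples$lambda_AC, bins$xbreaks)
    iy <- .bin_index(samples$lambda_BD, bins$ybreaks)
    w <- samples$w
  } else {
    d <- .displacements(samples, dt)
    ix <- .bin_index(d$lambda_AC, bins$xbreaks)
    iy <- .bin_index(d$lambda_BD, bins$ybreaks)
    w <- d$w
  }
  ok <- !is.na(ix) & !is.na(iy)
  h <- matrix(0, bins$nx, bins$ny)
  for (k in which(ok)) h[ix[k], iy[k]] <- h[ix[k], iy[k]] + w[k]
  h <- h / sum(h)
  hs <- median_filter2(ifelse(h > 0, h, NA_real_), n_filt)
  pot <- -log(hs)
  structure(list(bins = bins, density = h, smoothed = hs, potential = pot,
                 n_filt = n_filt), class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  layers <- setdiff(names(x), c("bins", "t_center", "dt", "n_filt"))
  cat(sprintf("field_grid: %d x %d bins; layers: %s\n",
              x$bins$nx, x$bins$ny, paste(layers, collapse = ", ")))
  invisible(x)
}

#' Export a field-grid layer as TSV plus JSON axis metadata
#'
#' @param grid a `field_grid`.
#' @param layer layer name (e.g. `"density"`, `"vx"`, `"potential"`).
#' @param path output TSV path; axis metadata is written to `paste0(path,
#'   ".json")`.
#' @export
export_grid_tsv <- function(grid, layer, path) {
  m <- grid[[layer]]
  if (is.null(m)) stop("no such layer: ", layer)
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  meta <- list(layer = layer, nx = grid$bins$nx, ny = grid$bins$ny,
               xbreaks = grid$bins$xbreaks, ybreaks = grid$bins$ybreaks)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
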