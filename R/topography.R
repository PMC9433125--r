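# Scalp topography: 2-D electrode layout, exact radial-basis
# interpolation on the head disc, and the diffusion-extent spread metric.

#' 2-D electrode layout for the 16-channel 10--20 montage
#'
#' Standard schematic polar projection onto the unit head disc, nose up
#' (positive y), left ear at negative x. The temporal/occipital ring sits
#' at radius 0.8; central, frontal and parietal electrodes lie inside.
#'
#' @return Tibble with columns `channel`, `x`, `y` (all within the unit
#'   circle), ordered as [montage_channels()].
#' @export
montage_layout <- function() {
  ring <- function(deg, r = 0.8) {
    th <- deg * pi / 180
    c(x = r * sin(th), y = r * cos(th))
  }
  coords <- rbind(
    Fp1 = ring(-18), Fp2 = ring(18),
    F7  = ring(-54), F8  = ring(54),
    F3  = c(x = -0.35, y = 0.35), F4 = c(x = 0.35, y = 0.35),
    C3  = c(x = -0.40, y = 0.00), C4 = c(x = 0.40, y = 0.00),
    P3  = c(x = -0.35, y = -0.35), P4 = c(x = 0.35, y = -0.35),
    T3  = ring(-90), T4 = ring(90),
    T5  = ring(-126), T6 = ring(126),
    O1  = ring(-162), O2 = ring(162)
  )
  tibble::tibble(channel = rownames(coords),
                 x = coords[, "x"], y = coords[, "y"])
}

rbf_kernel <- function(r, kernel) {
  if (kernel == "thin_plate") {
    k <- r^2 * log(r)
    k[r == 0] <- 0
    k
  } else {
    r  # first-order polyharmonic spline
  }
}

tps_fit <- function(x, y, v, kernel = "linear") {
  n <- length(v)
  d <- sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2)
  K <- rbf_kernel(d, kernel)
  P <- cbind(1, x, y)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  sol <- solve(A, c(v, 0, 0, 0))
  list(w = sol[seq_len(n)], a = sol[n + 1:3], x = x, y = y,
       kernel = kernel)
}

tps_eval <- function(fit, gx, gy) {
  d <- sqrt(outer(gx, fit$x, "-")^2 + outer(gy, fit$y, "-")^2)
  as.numeric(rbf_kernel(d, fit$kernel) %*% fit$w) + fit$a[1] +
    fit$a[2] * gx + fit$a[3] * gy
}

# Virtual rim electrodes (inverse-distance average of the k nearest real
# sites) bound the extrapolation between the electrode ring and the head
# circle, keeping frame values close to the data range.
rim_points <- function(layout, values, n_rim = 24, k = 3, radius = 1) {
  th <- seq(0, 2 * pi, length.out = n_rim + 1)[-1]
  rx <- radius * sin(th)
  ry <- radius * cos(th)
  vr <- vapply(seq_along(th), function(i) {
    d <- sqrt((layout$x - rx[i])^2 + (layout$y - ry[i])^2)
    nn <- order(d)[seq_len(k)]
    w <- 1 / pmax(d[nn], 1e-6)
    sum(w * values[nn]) / sum(w)
  }, numeric(1))
  list(x = rx, y = ry, v = vr)
}

#' Interpolate per-channel values onto the head disc
#'
#' Exact radial-basis interpolation of one scalar per electrode (e.g.
#' total power or a band power) over a regular grid, masked to the unit
#' head circle. The interpolant reproduces the electrode values exactly
#' (to solver precision). The default first-order polyharmonic kernel
#' `phi(r) = r`, together with virtual rim electrodes that carry
#' inverse-distance averages of the nearest real sites, keeps the frame
#' within about 10 percent of the electrode value range (the classical
#' thin-plate kernel, available as `kernel = "thin_plate"`, rings far
#' more between sparse electrodes).
#'
#' @param values Named numeric vector, one finite value per channel of
#'   `layout` (names matched; unnamed values are taken in layout order).
#' @param layout Electrode layout, default [montage_layout()].
#' @param grid_n Grid resolution per axis, default 64.
#' @param t_rel Optional time label (seconds relative to onset) carried in
#'   the result.
#' @param scale Optional `c(v_min, v_max)` colour-scale annotation.
#' @param kernel `"linear"` (default) or `"thin_plate"`.
#' @param rim_pad Number of virtual rim electrodes, default 24; 0
#'   disables padding.
#' @return A `topography_frame`: list with `grid` (`grid_n` x `grid_n`
#'   matrix, `NA` outside the head), axes `gx`, `gy`, the input `values`
#'   and `layout`, `t_rel`, and `scale`.
#' @examples
#' v <- stats::setNames(c(1, rep(0, 15)), montage_channels())
#' fr <- interpolate_scalp(v)
#' @export
interpolate_scalp <- function(values, layout = montage_layout(), grid_n = 64,
                              t_rel = NA_real_, scale = NULL,
                              kernel = c("linear", "thin_plate"),
                              rim_pad = 24) {
  kernel <- match.arg(kernel)
  if (any(!is.finite(values))) stop("non-finite channel value", call. = FALSE)
  if (length(values) != nrow(layout)) {
    stop("need one value per channel of the layout", call. = FALSE)
  }
  if (!is.null(names(values))) {
    idx <- match(layout$channel, names(values))
    if (any(is.na(idx))) stop("value names do not match layout channels",
                              call. = FALSE)
    values <- values[idx]
  }
  values <- as.numeric(values)
  px <- layout$x; py <- layout$y; pv <- values
  if (rim_pad > 0) {
    rim <- rim_points(layout, values, n_rim = rim_pad)
    px <- c(px, rim$x); py <- c(py, rim$y); pv <- c(pv, rim$v)
  }
  fit <- tps_fit(px, py, pv, kernel)
  ax <- seq(-1, 1, length.out = grid_n)
  gg <- expand.grid(x = ax, y = ax)
  z <- tps_eval(fit, gg$x, gg$y)
  z[gg$x^2 + gg$y^2 > 1] <- NA_real_
  structure(
    list(grid = matrix(z, nrow = grid_n), gx = ax, gy = ax,
         values = stats::setNames(as.numeric(values), layout$channel),
         layout = layout, t_rel = t_rel,
         scale = scale %||% range(values)),
    class = "topography_frame"
  )
}

#' @export
print.topography_frame <- function(x, ...) {
  cat(sprintf("<topography_frame>  %dx%d grid, t_rel=%s, scale [%g, %g]\n",
              nrow(x$grid), ncol(x$grid), format(x$t_rel),
              x$scale[1], x$scale[2]))
  invisible(x)
}

#' Spatial diffusion extent
#'
#' Counts the channels whose value exceeds `level` — a simple proxy for
#' how widely elevated power has spread over the scalp. Over the course of
#' a seizure whose discharge recruits channels with graded onset delays,
#' this count rises after onset and falls towards offset.
#'
#' @param values Per-channel numeric vector, or a `topography_frame`
#'   (its electrode values are used, not the interpolated grid).
#' @param level Threshold; strictly greater-than counts.
#' @return Integer count in `0..n_channels`.
#' @export
diffusion_extent <- function(values, level) {
  if (inherits(values, "topography_frame")) values <- values$values
  if (!is.finite(level)) stop("level must be finite", call. = FALSE)
  sum(values > level)
}

#' Topographic frames of per-channel power over a seizure
#'
#' Builds one [interpolate_scalp()] frame per epoch from a per-epoch,
#' per-channel value table (e.g. total power), with the dual colour-scale
#' convention: one scale for pre-/post-ictal frames and a wider one for
#' ictal frames, since discharge power dwarfs background power.
#'
#' @param values_tbl Tibble with columns `epoch`, `t_rel`, `state`,
#'   `channel`, `value`.
#' @param layout Electrode layout, default [montage_layout()].
#' @param grid_n Grid resolution, default 64.
#' @param scale_background,scale_ictal Colour scales `c(min, max)` applied
#'   to non-ictal and ictal frames; defaults 0--1000 and 0--5000 uV^2/Hz.
#' @return List of `topography_frame` objects ordered by epoch.
#' @export
topography_frames <- function(values_tbl, layout = montage_layout(),
                              grid_n = 64,
                              scale_background = c(0, 1000),
                              scale_ictal = c(0, 5000)) {
  ord <- order(values_tbl$epoch)
  values_tbl <- values_tbl[ord, , drop = FALSE]
  split(values_tbl, values_tbl$epoch) |>
    purrr::map(function(d) {
      sc <- if (d$state[1] == "ictal") scale_ictal else scale_background
      interpolate_scalp(stats::setNames(d$value, as.character(d$channel)),
                        layout, grid_n, t_rel = d$t_rel[1], scale = sc)
    }) |>
    unname()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
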