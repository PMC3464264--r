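#' Cuboid detector parameters
#'
#' Parameters of the spatiotemporal interest operator: a 2-D spatial Gaussian
#' of scale `sigma_spatial` combined with a temporal quadrature pair of 1-D
#' Gabor filters of scale `tau_temporal` and frequency `omega`. The response
#' is the sum of squares of the two filtered volumes, so it is non-negative
#' and quadratic in image contrast.
#'
#' @param sigma_spatial Spatial Gaussian scale in pixels (default 2).
#' @param tau_temporal Temporal Gabor scale in frames (default 3).
#' @param omega Carrier frequency of the temporal pair in cycles/frame;
#'   defaults to `4 / tau_temporal`, the original cuboid-detector convention.
#' @param max_points Cap on the number of interest points kept per clip.
#' @param min_response_frac Discard maxima below this fraction of the clip's
#'   maximum response (in `[0, 1)`).
#' @param nms_radius Integer vector `(dx, dy, dt)`: a point must be a strict
#'   local maximum within this box neighbourhood.
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(sigma_spatial = 2, tau_temporal = 3,
                            omega = 4 / tau_temporal,
                            max_points = 200L, min_response_frac = 0.05,
                            nms_radius = c(4L, 4L, 3L)) {
  stopifnot(sigma_spatial > 0, tau_temporal > 0,
            min_response_frac >= 0, min_response_frac < 1,
            length(nms_radius) == 3L)
  structure(list(sigma_spatial = sigma_spatial, tau_temporal = tau_temporal,
                 omega = omega, max_points = as.integer(max_points),
                 min_response_frac = min_response_frac,
                 nms_radius = as.integer(nms_radius)),
            class = "detector_params")
}

gaussian_kernel_1d <- function(sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

temporal_quadrature <- function(tau, omega) {
  r <- ceiling(3 * tau)
  t <- seq(-r, r)
  ev <- -cos(2 * pi * omega * t) * exp(-t^2 / tau^2)
  od <- -sin(2 * pi * omega * t) * exp(-t^2 / tau^2)
  # mean-subtract so a temporally constant video yields exactly zero response
  list(ev = ev - mean(ev), od = od - mean(od))
}

# reflect indices 1..n+2p back into 1..n (symmetric half-sample-free reflection)
reflect_idx <- function(n, pad) {
  idx <- seq(1 - pad, n + pad)
  idx <- ifelse(idx < 1, 2 - idx, idx)
  idx <- ifelse(idx > n, 2 * n - idx, idx)
  idx
}

# 1-D convolution of a volume along dimension `along` with reflection padding,
# implemented as shift-and-add over a padded copy (kernel lengths are small)
conv_dim <- function(vol, kernel, along) {
  d <- dim(vol)
  pad <- (length(kernel) - 1L) %/% 2L
  idx <- reflect_idx(d[along], pad)
  padded <- switch(along, vol[idx, , , drop = FALSE],
                   vol[, idx, , drop = FALSE], vol[, , idx, drop = FALSE])
  out <- array(0, dim = d)
  n <- d[along]
  for (k in seq_along(kernel)) {
    sl <- seq.int(k, k + n - 1L)
    shifted <- switch(along, padded[sl, , , drop = FALSE],
                      padded[, sl, , drop = FALSE], padded[, , sl, drop = FALSE])
    out <- out + kernel[length(kernel) - k + 1L] * shifted
  }
  out
}

#' Cuboid detector response volume
#'
#' Computes `R = (V*g*h_ev)^2 + (V*g*h_od)^2`: the video is smoothed with the
#' separable spatial Gaussian `g` and filtered along time with each member of
#' the quadrature Gabor pair; the two outputs are squared and summed. Both
#' temporal filters are mean-subtracted, so any temporally constant video has
#' identically zero response. Borders are handled by reflection padding and
#' the output has the shape of the input.
#'
#' @param v A [video_volume()] (or plain `H x W x T` array).
#' @param p [detector_params()].
#' @return A non-negative `H x W x T` array of responses.
#' @export
cuboid_response <- function(v, p = detector_params()) {
  stopifnot(length(dim(v)) == 3L)
  hq <- temporal_quadrature(p$tau_temporal, p$omega)
  if (dim(v)[3] < length(hq$ev))
    stop("video too short: needs at least ", length(hq$ev),
         " frames for the temporal filter support", call. = FALSE)
  g <- gaussian_kernel_1d(p$sigma_spatial)
  sm <- conv_dim(conv_dim(unclass(v), g, 1L), g, 2L)
  ev <- conv_dim(sm, hq$ev, 3L)
  od <- conv_dim(sm, hq$od, 3L)
  ev^2 + od^2
}

# separable box max-filter (running max along each dimension)
running_max_dim <- function(vol, radius, along) {
  if (radius <= 0L) return(vol)
  d <- dim(vol); n <- d[along]
  idx_clamp <- function(i) pmin(pmax(i, 1L), n)
  out <- vol
  for (s in seq.int(-radius, radius)) {
    if (s == 0L) next
    sl <- idx_clamp(seq_len(n) + s)
    shifted <- switch(along, vol[sl, , , drop = FALSE],
                      vol[, sl, , drop = FALSE], vol[, , sl, drop = FALSE])
    out <- pmax(out, shifted)
  }
  out
}

#' Detect spatiotemporal interest points
#'
#' Interest points are the strict local maxima of the cuboid response within
#' the `nms_radius` box neighbourhood, kept if their response is at least
#' `min_response_frac` of the clip's maximum response and truncated to the
#' strongest `max_points`.
#'
#' @inheritParams cuboid_response
#' @return A tibble with columns `x` (column), `y` (row), `t` (frame), all
#'   1-based, and `response`, sorted by decreasing response. A temporally
#'   constant video yields zero rows.
#' @export
detect_interest_points <- function(v, p = detector_params()) {
  r <- cuboid_response(v, p)
  rmax <- max(r)
  if (rmax <= 0)
    return(tibble::tibble(x = integer(), y = integer(), t = integer(),
                          response = numeric()))
  mf <- running_max_dim(r, p$nms_radius[2], 1L)   # dy along rows
  mf <- running_max_dim(mf, p$nms_radius[1], 2L)  # dx along columns
  mf <- running_max_dim(mf, p$nms_radius[3], 3L)
  cand <- which(r == mf & r >= p$min_response_frac * rmax & r > 0)
  if (length(cand) == 0L)
    return(tibble::tibble(x = integer(), y = integer(), t = integer(),
                          response = numeric()))
  d <- dim(r)
  coord <- arrayInd(cand, d)
  # enforce strictness: reject plateaus (a neighbour attains the same value)
  keep <- vapply(seq_len(nrow(coord)), function(i) {
    yy <- coord[i, 1]; xx <- coord[i, 2]; tt <- coord[i, 3]
    ys <- max(1, yy - p$nms_radius[2]):min(d[1], yy + p$nms_radius[2])
    xs <- max(1, xx - p$nms_radius[1]):min(d[2], xx + p$nms_radius[1])
    ts <- max(1, tt - p$nms_radius[3]):min(d[3], tt + p$nms_radius[3])
    nb <- r[ys, xs, ts]
    sum(nb == r[yy, xx, tt]) == 1L
  }, logical(1))
  coord <- coord[keep, , drop = FALSE]
  if (nrow(coord) == 0L)
    return(tibble::tibble(x = integer(), y = integer(), t = integer(),
                          response = numeric()))
  pts <- tibble::tibble(x = coord[, 2], y = coord[, 1], t = coord[, 3],
                        response = r[coord])
  pts <- dplyr::arrange(pts, dplyr::desc(.data$response), .data$t, .data$y, .data$x)
  dplyr::slice_head(pts, n = p$max_points)
}

#' Write interest points as TSV
#'
#' Coordinates are exported 0-based (documented in the header line).
#'
#' @param points Tibble from [detect_interest_points()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_interest_points <- function(points, path) {
  con <- file(path, "wt"); on.exit(close(con))
  writeLines("# x\ty\tt\tresponse (x = column, y = row, t = frame; 0-based)", con)
  utils::write.table(
    dplyr::mutate(points, x = .data$x - 1L, y = .data$y - 1L, t = .data$t - 1L),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
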