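#' Coupled spatial-temporal scale configuration
#'
#' The three coupled scales pair larger patch diameters with longer durations:
#' 13x13x11, 25x25x21 and 49x49x31 (pixels x pixels x frames). Every scale is
#' reduced to the common 13x13x11 grid by centred strided sampling, which
#' requires the strides `(diameter - 1) / 12` and `(duration - 1) / 10` to be
#' integers.
#'
#' @param diameters Patch diameters in pixels per scale.
#' @param durations Patch durations in frames per scale.
#' @param target `(diameter, duration)` of the common grid after
#'   down-sampling.
#' @return A list of class `scale_config`.
#' @export
scale_config <- function(diameters = c(13L, 25L, 49L),
                         durations = c(11L, 21L, 31L),
                         target = c(13L, 11L)) {
  stopifnot(length(diameters) == length(durations))
  s_stride <- (diameters - 1) / (target[1] - 1)
  t_stride <- (durations - 1) / (target[2] - 1)
  if (any(s_stride != round(s_stride)) || any(t_stride != round(t_stride)) ||
      any(s_stride < 1) || any(t_stride < 1))
    stop("scale strides (diameter-1)/", target[1] - 1, " and (duration-1)/",
         target[2] - 1, " must be positive integers", call. = FALSE)
  structure(list(diameters = as.integer(diameters),
                 durations = as.integer(durations),
                 target = as.integer(target),
                 spatial_stride = as.integer(s_stride),
                 temporal_stride = as.integer(t_stride)),
            class = "scale_config")
}

#' Circular patch mask and its canonical pixel ordering
#'
#' Pixel `(r, c)` of the `d x d` grid is in-mask iff
#' `(r - m)^2 + (c - m)^2 <= (d^2 - 9) / 4` with `m` the centre index: a
#' centred digital disc whose squared radius is 40 for the default diameter
#' 13, giving exactly 129 in-mask pixels and hence flattened vectors of
#' length `129 * 11 = 1419`. The canonical ordering of in-mask pixels is
#' row-major and is frozen with every codebook.
#'
#' @param diameter Odd patch diameter in pixels.
#' @return A list with `mask` (logical `d x d` matrix) and `order` (2-column
#'   matrix of in-mask `(row, col)` indices in canonical order).
#' @export
circular_mask <- function(diameter = 13L) {
  if (diameter %% 2L == 0L) stop("diameter must be odd", call. = FALSE)
  m <- (diameter + 1L) / 2L
  r2 <- (diameter^2 - 9) / 4
  idx <- as.matrix(expand.grid(col = seq_len(diameter), row = seq_len(diameter)))
  inside <- (idx[, "row"] - m)^2 + (idx[, "col"] - m)^2 <= r2
  mask <- matrix(FALSE, diameter, diameter)
  mask[cbind(idx[inside, "row"], idx[inside, "col"])] <- TRUE
  ord <- which(t(mask), arr.ind = TRUE)      # row-major enumeration
  ord <- cbind(row = ord[, 2], col = ord[, 1])
  list(mask = mask, order = ord)
}

#' Centred strided down-sampling to the common grid
#'
#' Picks indices `centre + k * stride` with `k = -6..6` spatially and
#' `k = -5..5` temporally. For the 25x25x21 middle scale (stride 2, 2) this is
#' exactly the even-indexed subgrid counted from the centre; the coarsest
#' 49x49x31 scale uses strides 4 and 3. A block already at the target size is
#' returned unchanged.
#'
#' @param block Numeric `d x d x T` array.
#' @param cfg A [scale_config()] (supplies the target size).
#' @return A `13 x 13 x 11` array (for the default target).
#' @export
centered_downsample <- function(block, cfg = scale_config()) {
  d <- dim(block)
  s_stride <- (d[1] - 1) / (cfg$target[1] - 1)
  t_stride <- (d[3] - 1) / (cfg$target[2] - 1)
  if (s_stride != round(s_stride) || t_stride != round(t_stride))
    stop("block of ", paste(d, collapse = "x"),
         " has non-integral stride to the target grid", call. = FALSE)
  cs <- (d[1] + 1L) / 2L; ct <- (d[3] + 1L) / 2L
  si <- cs + s_stride * seq.int(-(cfg$target[1] - 1L) / 2L, (cfg$target[1] - 1L) / 2L)
  ti <- ct + t_stride * seq.int(-(cfg$target[2] - 1L) / 2L, (cfg$target[2] - 1L) / 2L)
  block[si, si, ti, drop = FALSE]
}

# crop a d x d x D block centred at (y, x, t) with replicate padding
crop_block <- function(v, y, x, t, diameter, duration) {
  dd <- dim(v)
  rs <- (diameter - 1L) / 2L; rt <- (duration - 1L) / 2L
  yi <- pmin(pmax(seq.int(y - rs, y + rs), 1L), dd[1])
  xi <- pmin(pmax(seq.int(x - rs, x + rs), 1L), dd[2])
  ti <- pmin(pmax(seq.int(t - rt, t + rt), 1L), dd[3])
  unclass(v)[yi, xi, ti, drop = FALSE]
}

# flatten a target-size block: frame-major, canonical in-mask row-major order
flatten_masked <- function(block, mask_order) {
  tt <- dim(block)[3]
  out <- numeric(nrow(mask_order) * tt)
  np <- nrow(mask_order)
  for (f in seq_len(tt))
    out[(f - 1L) * np + seq_len(np)] <- block[, , f][mask_order]
  out
}

#' Sample the coupled three-scale patch sequence at one interest point
#'
#' For each scale a `diameter x diameter x duration` block centred at the
#' point (middle frames of all three sequences aligned at `t`) is cropped with
#' replicate padding, reduced to the common grid by [centered_downsample()],
#' circular-masked, flattened frame-major in the canonical in-mask order, and
#' mean-subtracted. All three vectors have identical length
#' `129 * 11 = 1419`, which lets one ICA routine serve all scales.
#'
#' @param v A [video_volume()].
#' @param pt A one-row interest point (list or tibble row with `x`, `y`, `t`).
#' @param cfg A [scale_config()].
#' @return A list of class `patch_triple` with `vectors` (list of 3 numeric
#'   vectors), `center`, `mask_size`.
#' @export
sample_patch_triple <- function(v, pt, cfg = scale_config()) {
  if (any(!is.finite(unclass(v)))) stop("NaN/Inf in source volume", call. = FALSE)
  cm <- circular_mask(cfg$target[1])
  vecs <- lapply(seq_along(cfg$diameters), function(s) {
    block <- crop_block(v, pt$y, pt$x, pt$t, cfg$diameters[s], cfg$durations[s])
    small <- centered_downsample(block, cfg)
    vec <- flatten_masked(small, cm$order)
    vec - mean(vec)
  })
  structure(list(vectors = vecs,
                 center = list(x = pt$x, y = pt$y, t = pt$t),
                 mask_size = nrow(cm$order)),
            class = "patch_triple")
}

#' Sample patch triples for every interest point of a clip
#'
#' @param v A [video_volume()].
#' @param points Tibble from [detect_interest_points()].
#' @param cfg A [scale_config()].
#' @return A list with `matrices`: one `n_points x 1419` matrix per scale, and
#'   `points`: the input tibble.
#' @export
sample_patches <- function(v, points, cfg = scale_config()) {
  cm <- circular_mask(cfg$target[1])
  n <- nrow(points)
  len <- nrow(cm$order) * cfg$target[2]
  mats <- lapply(seq_along(cfg$diameters), function(s) {
    m <- matrix(0, nrow = n, ncol = len)
    for (i in seq_len(n)) {
      block <- crop_block(v, points$y[i], points$x[i], points$t[i],
                          cfg$diameters[s], cfg$durations[s])
      vec <- flatten_masked(centered_downsample(block, cfg), cm$order)
      m[i, ] <- vec - mean(vec)
    }
    m
  })
  list(matrices = mats, points = points)
}
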