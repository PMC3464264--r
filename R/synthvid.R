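#' Construct a video volume
#'
#' A video volume is the universal input of the pipeline: a numeric
#' `H x W x T` array of intensities in `[0, 1]` (rows are the vertical image
#' dimension, columns horizontal, the third dimension time).
#'
#' @param frames Numeric array of dimension `H x W x T` (a matrix is promoted
#'   to a single-frame volume). All values must be finite and in `[0, 1]`.
#' @param frame_rate Frames per second, informational only.
#' @return An object of class `video_volume`.
#' @export
video_volume <- function(frames, frame_rate = 25) {
  if (is.matrix(frames)) dim(frames) <- c(dim(frames), 1L)
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be an H x W x T array", call. = FALSE)
  if (any(!is.finite(frames)))
    stop("video volume contains non-finite values", call. = FALSE)
  if (min(frames) < -1e-9 || max(frames) > 1 + 1e-9)
    stop("intensities must lie in [0, 1]", call. = FALSE)
  structure(frames, frame_rate = frame_rate, class = c("video_volume", "array"))
}

#' @export
print.video_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<video_volume> %d x %d pixels, %d frames (%.4g fps)\n",
              d[1], d[2], d[3], attr(x, "frame_rate") %||% NA_real_))
  invisible(x)
}

n_frames <- function(v) dim(v)[3]

#' @rdname video_volume
#' @param x Object to test.
#' @export
is_video_volume <- function(x) inherits(x, "video_volume")

# ---- frame-directory I/O ----------------------------------------------------

read_pgm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  # header tokens: width height maxval, '#' comments allowed
  tokens <- character(0)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L)
    if (length(ch) == 0L) stop("truncated PGM header: ", path, call. = FALSE)
    if (ch == "#") { repeat { c2 <- readChar(con, 1L); if (!length(c2) || c2 == "\n") break } }
    else if (grepl("[0-9]", ch)) {
      tok <- ch
      repeat {
        c2 <- readChar(con, 1L)
        if (!length(c2) || !grepl("[0-9]", c2)) break
        tok <- paste0(tok, c2)
      }
      tokens <- c(tokens, tok)
    }
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2]); mx <- as.integer(tokens[3])
  if (magic == "P5") {
    raw <- readBin(con, "integer", n = w * h, size = 1L, signed = FALSE)
  } else {
    raw <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  matrix(raw, nrow = h, ncol = w, byrow = TRUE) / mx
}

write_pgm <- function(mat, path, maxval = 255L) {
  vals <- round(pmin(pmax(mat, 0), 1) * maxval)
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(c("P2", paste(ncol(mat), nrow(mat)), as.character(maxval)), con)
  apply(vals, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

rgb_to_luma <- function(a) {
  # ITU-R BT.601 luma weights
  0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
}

#' Load a video from a directory of image frames
#'
#' Reads a lexicographically ordered directory of `.png` or `.pgm` frames into
#' a [video_volume()]. Intensities are mapped linearly to `[0, 1]`; colour
#' frames are converted to BT.601 luma when `to_gray` is `TRUE`.
#'
#' @param path Directory containing the frames.
#' @param to_gray Convert RGB frames to luma (default `TRUE`).
#' @param frame_rate Frames per second recorded on the volume.
#' @return A [video_volume()].
#' @export
load_video <- function(path, to_gray = TRUE, frame_rate = 25) {
  if (!dir.exists(path)) stop("cannot read video input: ", path, call. = FALSE)
  files <- sort(list.files(path, pattern = "\\.(png|pgm)$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L) stop("no frames found under ", path, call. = FALSE)
  frames <- lapply(files, function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) {
        img <- img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE]
        img <- if (dim(img)[3] == 3L && to_gray) rgb_to_luma(img)
               else apply(img, c(1, 2), mean)  # channel mean when luma is off
      }
      img
    } else read_pgm(f)
  })
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("frames under ", path, " have inconsistent dimensions", call. = FALSE)
  vol <- array(unlist(frames, use.names = FALSE), dim = c(d[1], d[2], length(frames)))
  video_volume(pmin(pmax(vol, 0), 1), frame_rate = frame_rate)
}

#' Save a video volume as a directory of frames
#'
#' Writes one file per frame, zero-padded so lexicographic order equals
#' temporal order. PNG is lossless at 16-bit; ASCII PGM gives plain-text
#' fixtures.
#'
#' @param v A [video_volume()].
#' @param path Output directory (created if missing).
#' @param format `"png"` or `"pgm"`.
#' @return `path`, invisibly.
#' @export
save_video <- function(v, path, format = c("png", "pgm")) {
  format <- match.arg(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tt <- n_frames(v)
  for (t in seq_len(tt)) {
    f <- file.path(path, sprintf("frame_%05d.%s", t, format))
    if (format == "png") png::writePNG(v[, , t], f) else write_pgm(v[, , t], f)
  }
  invisible(path)
}

# ---- synthetic action registry ----------------------------------------------

#' Registered synthetic actions
#'
#' @return Character vector of the action labels the generator knows.
#' @export
synth_actions <- function() {
  c("translating_bar", "oscillating_pair", "expanding_blob", "bouncing_dot")
}

# soft-edged drawing primitives on a pixel grid; xx/yy are coordinate matrices
soft_bar <- function(xx, yy, cx, cy, theta, len, width) {
  xr <- (xx - cx) * cos(theta) + (yy - cy) * sin(theta)
  yr <- -(xx - cx) * sin(theta) + (yy - cy) * cos(theta)
  exp(-(xr^2 / (2 * (len / 2)^2) + yr^2 / (2 * (width / 2)^2)))
}

soft_blob <- function(xx, yy, cx, cy, radius) {
  exp(-((xx - cx)^2 + (yy - cy)^2) / (2 * radius^2))
}

#' Specification of one synthetic clip
#'
#' @param action_label One of [synth_actions()].
#' @param subject_seed Integer controlling geometric jitter (position offset,
#'   size within ±15%, speed within ±20%) shared by all clips of a subject.
#' @param clip_seed Integer controlling the additive noise draw and the phase
#'   of the motion.
#' @param n_frames,height,width Clip dimensions; `n_frames` must be at least 31
#'   so the largest temporal patch scale fits.
#' @param snr_db Target signal-to-noise ratio in dB (`Inf` for a noise-free
#'   clip); 20 dB corresponds to a noise/signal standard-deviation ratio of 0.1.
#' @param scale_factor Spatial rescale multiplier applied to the rendered
#'   geometry and frame size (1 renders the nominal clip).
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(action_label, subject_seed = 1L, clip_seed = 1L,
                       n_frames = 60L, height = 60L, width = 60L,
                       snr_db = 20, scale_factor = 1) {
  if (!action_label %in% synth_actions())
    stop("unknown action label '", action_label, "'; see synth_actions()",
         call. = FALSE)
  if (n_frames < 31L)
    stop("n_frames must be >= 31 (largest temporal scale)", call. = FALSE)
  if (is.na(snr_db)) stop("snr_db must be finite or Inf", call. = FALSE)
  structure(list(action_label = action_label, subject_seed = as.integer(subject_seed),
                 clip_seed = as.integer(clip_seed), n_frames = as.integer(n_frames),
                 height = as.integer(height), width = as.integer(width),
                 snr_db = snr_db, scale_factor = scale_factor),
            class = "synth_spec")
}

# deterministic per-subject geometry jitter, independent of the clip noise
subject_jitter <- function(subject_seed) {
  r <- local_rng(as.double(subject_seed) * 7919 + 13)
  list(dx = r(1, -0.1, 0.1), dy = r(1, -0.1, 0.1),   # fractional position offset
       size = 1 + r(1, -0.15, 0.15),                 # ±15 %
       speed = 1 + r(1, -0.2, 0.2))                  # ±20 %
}

# small deterministic uniform generator detached from .Random.seed
local_rng <- function(seed) {
  state <- as.double(seed %% 2147483647L)
  if (state <= 0) state <- state + 2147483646
  function(n, lo = 0, hi = 1) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (state * 16807) %% 2147483647
      out[i] <- lo + (hi - lo) * state / 2147483647
    }
    out
  }
}

render_clean <- function(spec) {
  sf <- spec$scale_factor
  h <- max(8L, as.integer(round(spec$height * sf)))
  w <- max(8L, as.integer(round(spec$width * sf)))
  tt <- spec$n_frames
  jit <- subject_jitter(spec$subject_seed)
  rphase <- local_rng(as.double(spec$clip_seed) * 104729 + 7)
  phase <- rphase(1, 0, 2 * pi)
  xx <- matrix(rep(seq_len(w), each = h), nrow = h)
  yy <- matrix(rep(seq_len(h), times = w), nrow = h)
  cx0 <- w * (0.5 + jit$dx); cy0 <- h * (0.5 + jit$dy)
  amp <- 0.4
  base <- 0.5
  vol <- array(base, dim = c(h, w, tt))
  for (t in seq_len(tt)) {
    tau <- (t - 1) * jit$speed
    fg <- switch(spec$action_label,
      translating_bar = {
        # vertical bar sweeping back and forth across the frame
        cx <- reflect_coord(cx0 + 1.3 * tau, w)
        soft_bar(xx, yy, cx, cy0, pi / 2, 0.6 * h * jit$size, 3 * jit$size)
      },
      oscillating_pair = {
        # two horizontal bars oscillating vertically in antiphase
        off <- 0.18 * h * sin(2 * pi * tau / 16 + phase)
        gap <- 0.22 * h * jit$size
        soft_bar(xx, yy, cx0, cy0 - gap + off, 0, 0.5 * w * jit$size, 3 * jit$size) +
          soft_bar(xx, yy, cx0, cy0 + gap - off, 0, 0.5 * w * jit$size, 3 * jit$size)
      },
      expanding_blob = {
        # soft annulus whose radius breathes, giving a moving contrast edge
        r0 <- h * (0.16 + 0.1 * sin(2 * pi * tau / 20 + phase)) * jit$size
        dist <- sqrt((xx - cx0)^2 + (yy - cy0)^2)
        exp(-(dist - max(r0, 2))^2 / (2 * (2.5 * jit$size)^2))
      },
      bouncing_dot = {
        # compact dot on a reflecting billiard trajectory
        px <- reflect_coord(cx0 + 1.6 * jit$speed * (t - 1), w)
        py <- reflect_coord(cy0 + 1.1 * jit$speed * (t - 1), h)
        soft_blob(xx, yy, px, py, 3 * jit$size)
      })
    vol[, , t] <- base + amp * pmin(fg, 1.2) / 1.2 - amp * 0.25
  }
  pmin(pmax(vol, 0), 1)
}

# reflect a coordinate into [1, n] (billiard boundary rule)
reflect_coord <- function(x, n) {
  p <- (x - 1) %% (2 * (n - 1))
  ifelse(p <= (n - 1), p, 2 * (n - 1) - p) + 1
}

#' Generate one synthetic action clip
#'
#' Renders the clip described by a [synth_spec()] and adds i.i.d. Gaussian
#' pixel noise calibrated so that `sd(noise) / sd(clean signal)` matches the
#' requested `snr_db` (20 dB gives a ratio of 0.1). The result is clipped to
#' `[0, 1]`; the rendering keeps intensities inside `[0.1, 0.9]` so clipping is
#' negligible at the default noise level. Output is a pure function of
#' `(action_label, subject_seed, clip_seed, ...)`.
#'
#' @param spec A [synth_spec()].
#' @return A [video_volume()] with attributes `label` and `clean` (the
#'   noise-free render).
#' @export
generate_clip <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  clean <- render_clean(spec)
  if (is.finite(spec$snr_db)) {
    sd_noise <- stats::sd(clean) * 10^(-spec$snr_db / 20)
    noise <- array(rnorm_seeded(length(clean), as.double(spec$clip_seed) * 6151 +
                                  as.double(spec$subject_seed) * 389 + 1) * sd_noise,
                   dim = dim(clean))
    out <- pmin(pmax(clean + noise, 0), 1)
  } else out <- clean
  v <- video_volume(out)
  attr(v, "label") <- spec$action_label
  attr(v, "clean") <- clean
  v
}

# seeded standard-normal draws on a private RNG stream
rnorm_seeded <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  stats::rnorm(n)
}

#' Generate a balanced multi-subject synthetic dataset
#'
#' Produces `n_subjects * clips_per_subject * length(labels)` clips, balanced
#' across labels, with per-clip subject identifiers for grouped (leave-one-
#' subject-out) cross-validation.
#'
#' @param n_subjects Number of synthetic subjects (>= 2).
#' @param clips_per_subject Clips of each action per subject (>= 1).
#' @param labels Action labels, a subset of [synth_actions()].
#' @param seed Integer master seed; subject and clip seeds are derived from it.
#' @param ... Passed on to [synth_spec()] (clip size, `snr_db`, ...).
#' @return A tibble with columns `video` (list of [video_volume()]), `label`,
#'   `subject_id`, `clip_id`.
#' @export
generate_dataset <- function(n_subjects, clips_per_subject, labels, seed = 1L, ...) {
  if (n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  if (clips_per_subject < 1L) stop("clips_per_subject must be >= 1", call. = FALSE)
  grid <- tidyr::expand_grid(subject = seq_len(n_subjects),
                             label = labels,
                             clip = seq_len(clips_per_subject))
  rows <- purrr::pmap(grid, function(subject, label, clip) {
    spec <- synth_spec(label,
                       subject_seed = seed * 1009L + subject,
                       clip_seed = seed * 31L + subject * 101L +
                         match(label, labels) * 1511L + clip * 7001L,
                       ...)
    v <- generate_clip(spec)
    tibble::tibble(video = list(v), label = label,
                   subject_id = paste0("s", subject),
                   clip_id = sprintf("s%d_%s_%d", subject, label, clip))
  })
  dplyr::bind_rows(rows)
}

#' Rescale a video volume spatially
#'
#' Bilinear per-frame resize used by the scale-robustness protocol
#' (`factor = 1.1` enlarges frames by 10%).
#'
#' @param v A [video_volume()].
#' @param factor Spatial scale multiplier.
#' @return A rescaled [video_volume()].
#' @export
rescale_video <- function(v, factor) {
  d <- dim(v)
  h2 <- max(8L, as.integer(round(d[1] * factor)))
  w2 <- max(8L, as.integer(round(d[2] * factor)))
  out <- array(0, dim = c(h2, w2, d[3]))
  for (t in seq_len(d[3]))
    out[, , t] <- EBImage::resize(v[, , t], w = h2, h = w2)
  video_volume(pmin(pmax(out, 0), 1), frame_rate = attr(v, "frame_rate") %||% 25)
}

#' Add calibrated Gaussian noise to every clip of a dataset
#'
#' Implements the noise-robustness protocol input: white Gaussian pixel noise
#' at the stated SNR added to the (already rendered) clips, after which the
#' classifier is retrained on the noisy data.
#'
#' @param dataset A tibble from [generate_dataset()].
#' @param snr_db Target SNR in dB relative to each clip's own standard
#'   deviation.
#' @param seed Integer seed for the noise draws.
#' @return The dataset with noisy videos.
#' @export
perturb_dataset_noise <- function(dataset, snr_db = 20, seed = 1L) {
  dataset$video <- purrr::imap(dataset$video, function(v, i) {
    sd_noise <- stats::sd(v) * 10^(-snr_db / 20)
    noise <- rnorm_seeded(length(v), as.double(seed) * 52361 + i) * sd_noise
    video_volume(pmin(pmax(unclass(v) + array(noise, dim(v)), 0), 1))
  })
  dataset
}
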