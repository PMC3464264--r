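# Independent oracles used across the suite.

# FFT-based dense 3-D convolution oracle: reflection-pads the volume, builds
# the full (non-separable) 3-D kernel, convolves cyclically in the frequency
# domain and crops. Shares nothing with the package's shift-and-add path.
oracle_cuboid_response <- function(vol, sigma = 2, tau = 3, omega = 4 / tau) {
  reflect <- function(n, pad) {
    idx <- seq(1 - pad, n + pad)
    idx <- ifelse(idx < 1, 2 - idx, idx)
    ifelse(idx > n, 2 * n - idx, idx)
  }
  rs <- ceiling(3 * sigma); rt <- ceiling(3 * tau)
  g <- exp(-(seq(-rs, rs))^2 / (2 * sigma^2)); g <- g / sum(g)
  tsupp <- seq(-rt, rt)
  hev <- -cos(2 * pi * omega * tsupp) * exp(-tsupp^2 / tau^2)
  hod <- -sin(2 * pi * omega * tsupp) * exp(-tsupp^2 / tau^2)
  hev <- hev - mean(hev); hod <- hod - mean(hod)
  d <- dim(vol)
  pv <- vol[reflect(d[1], rs), , ][, reflect(d[2], rs), ][, , reflect(d[3], rt)]
  pd <- dim(pv)
  conv_full <- function(kern3) {
    kb <- array(0, pd)
    kd <- dim(kern3)
    kb[seq_len(kd[1]), seq_len(kd[2]), seq_len(kd[3])] <- kern3
    # centre the kernel so the output is not shifted
    for (ax in 1:3) {
      sh <- (kd[ax] - 1) / 2
      idx <- ((seq_len(pd[ax]) - 1 + sh) %% pd[ax]) + 1
      kb <- switch(ax, kb[idx, , , drop = FALSE], kb[, idx, , drop = FALSE],
                   kb[, , idx, drop = FALSE])
    }
    Re(fft(fft(pv) * fft(kb), inverse = TRUE)) / prod(pd)
  }
  k_ev <- outer(outer(g, g), hev)
  k_od <- outer(outer(g, g), hod)
  ev <- conv_full(k_ev); od <- conv_full(k_od)
  r <- ev^2 + od^2
  r[rs + seq_len(d[1]), rs + seq_len(d[2]), rt + seq_len(d[3])]
}

# brute-force scan for strict local maxima of a response volume
oracle_local_maxima <- function(r, radius = c(4, 4, 3), frac = 0.05) {
  d <- dim(r); out <- NULL
  thr <- frac * max(r)
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) for (t in seq_len(d[3])) {
    v <- r[y, x, t]
    if (v < thr || v <= 0) next
    ys <- max(1, y - radius[2]):min(d[1], y + radius[2])
    xs <- max(1, x - radius[1]):min(d[2], x + radius[1])
    ts <- max(1, t - radius[3]):min(d[3], t + radius[3])
    nb <- r[ys, xs, ts]
    if (sum(nb >= v) == 1L) out <- rbind(out, c(x, y, t, v))
  }
  out
}

# evaluate a 2-D Gabor with the package's geometric convention (x = column)
make_gabor_frame <- function(par, d = 13) {
  xg <- matrix(rep(seq_len(d), each = d), nrow = d, byrow = TRUE)
  xg <- t(xg)  # columns vary along x
  yg <- matrix(rep(seq_len(d), times = d), nrow = d)
  xr <- (xg - par["x0"]) * cos(par["theta"]) + (yg - par["y0"]) * sin(par["theta"])
  yr <- -(xg - par["x0"]) * sin(par["theta"]) + (yg - par["y0"]) * cos(par["theta"])
  exp(-(xr^2 / (2 * par["sigma_x"]^2) + yr^2 / (2 * par["sigma_y"]^2))) *
    cos(2 * pi * par["freq"] * xr + par["phi"])
}

# random well-conditioned canonical Gabor parameters
random_gabor_pars <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    sx <- runif(1, 2, 3.2); sy <- runif(1, 1.2, sx)
    c(x0 = runif(1, 5.5, 8.5), y0 = runif(1, 5.5, 8.5),
      sigma_x = sx, sigma_y = sy,
      theta = runif(1, 0.05, pi - 0.05), phi = runif(1, 0.3, 2 * pi - 0.3),
      freq = runif(1, 0.09, 0.18))
  })
}

# brute-force exhaustive 2-means (all 2-partitions of <= 12 points)
oracle_two_means <- function(x) {
  n <- nrow(x); best <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.integer(intToBits(code))[1:n] + 1L
    if (length(unique(grp)) < 2L) next
    sse <- sum(vapply(1:2, function(g) {
      pts <- x[grp == g, , drop = FALSE]
      sum(sweep(pts, 2, colMeans(pts))^2)
    }, numeric(1)))
    if (is.null(best) || sse < best$sse) best <- list(grp = grp, sse = sse)
  }
  best
}

# small balanced synthetic dataset shared by protocol-shape tests
tiny_dataset <- function(n_subjects = 2, clips = 1, seed = 5) {
  generate_dataset(n_subjects, clips,
                   c("translating_bar", "expanding_blob"), seed = seed,
                   n_frames = 40L, height = 40L, width = 40L)
}

tiny_config <- function(...) {
  pipeline_config("synthetic-small", n_ic = 12L, n_ic_clusters = 6L,
                  n_struct_clusters = 10L, ica_max_samples = 400L,
                  K_topics = 3L, ...)
}
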