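#' Independent component analysis of patch sequences
#'
#' PCA-whitens the patch matrix to `n_ic` dimensions and runs symmetric
#' fixed-point ICA (logcosh contrast) to obtain `n_ic` unit-norm spatial-
#' temporal filters. The variance retained by the PCA step is reported; the
#' filters (rows of `components`) live in the original flattened patch space,
#' so `patch %*% t(components)` gives the IC amplitudes used by the cluster
#' features.
#'
#' @param patches Numeric matrix, rows are flattened patch-sequence vectors.
#' @param n_ic Number of independent components (requires
#'   `nrow(patches) >= 5 * n_ic`).
#' @param seed Integer seed (orthogonal initialisation of the unmixing
#'   matrix).
#' @param max_iter,tol Fixed-point iteration budget and convergence tolerance
#'   on the unmixing rotation.
#' @return A list of class `ic_basis`: `components` (`n_ic x l`, unit-norm
#'   rows), `whitening` (`n_ic x l`), `variance_retained`, `converged`,
#'   `n_ic`.
#' @export
fit_ica <- function(patches, n_ic, seed = 1L, max_iter = 200L, tol = 1e-4) {
  x <- as.matrix(patches)
  n <- nrow(x); l <- ncol(x)
  if (n_ic > l) stop("n_ic exceeds patch dimension", call. = FALSE)
  if (n < 5L * n_ic)
    stop("need at least 5 * n_ic = ", 5L * n_ic, " samples, got ", n,
         call. = FALSE)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-12
  if (sum(pos) < n_ic)
    stop("data rank ", sum(pos), " below n_ic = ", n_ic, call. = FALSE)
  variance_retained <- sum(eg$values[seq_len(n_ic)]) / sum(pmax(eg$values, 0))
  # whitening matrix K: z = K %*% t(xc) has identity covariance
  K <- diag(1 / sqrt(eg$values[seq_len(n_ic)]), n_ic) %*%
    t(eg$vectors[, seq_len(n_ic), drop = FALSE])
  z <- K %*% t(xc)                       # n_ic x n
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  W <- qr.Q(qr(matrix(stats::rnorm(n_ic^2), n_ic)))
  sym_decor <- function(W) {
    s <- W %*% t(W)
    e <- eigen(s, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), n_ic) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decor(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    wz <- W %*% z                        # n_ic x n
    g <- tanh(wz)
    gp <- 1 - g^2
    W1 <- (g %*% t(z)) / n - diag(rowMeans(gp), n_ic) %*% W
    W1 <- sym_decor(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("ICA did not converge in ", max_iter,
            " iterations; returning best iterate")
  filt <- W %*% K                        # unmixing filters in patch space
  filt <- filt / sqrt(rowSums(filt^2))
  structure(list(components = filt, whitening = K, mean = mu,
                 variance_retained = variance_retained,
                 converged = converged, n_ic = n_ic, seed = seed),
            class = "ic_basis")
}

# ---- Gabor fitting ----------------------------------------------------------

# evaluate a unit-amplitude 2-D Gabor on coordinate vectors
gabor_eval <- function(par, xg, yg) {
  xr <- (xg - par["x0"]) * cos(par["theta"]) + (yg - par["y0"]) * sin(par["theta"])
  yr <- -(xg - par["x0"]) * sin(par["theta"]) + (yg - par["y0"]) * cos(par["theta"])
  exp(-(xr^2 / (2 * par["sigma_x"]^2) + yr^2 / (2 * par["sigma_y"]^2))) *
    cos(2 * pi * par["freq"] * xr + par["phi"])
}

# amplitude solved in closed form; residual for the least-squares fit
gabor_residual <- function(par, xg, yg, yv) {
  p <- par
  p["sigma_x"] <- abs(p["sigma_x"]); p["sigma_y"] <- abs(p["sigma_y"])
  g <- gabor_eval(p, xg, yg)
  a <- sum(g * yv) / max(sum(g * g), 1e-12)
  yv - a * g
}

gabor_start_fft <- function(frame, mask) {
  f0 <- frame
  f0[!mask] <- 0
  d <- nrow(frame)
  ft <- stats::fft(f0)
  mod <- Mod(ft)
  freqs <- c(0:(d %/% 2), -((d - (d %/% 2 + 1)):1)) / d
  mod[1, 1] <- 0                          # ignore DC
  pk <- arrayInd(which.max(mod), dim(mod))
  fy <- freqs[pk[1]]; fx <- freqs[pk[2]]
  f <- sqrt(fx^2 + fy^2)
  theta <- atan2(fy, fx) %% pi
  w <- abs(frame); w <- w / max(sum(w), 1e-12)
  xs <- rep(seq_len(d), each = d); ys <- rep(seq_len(d), times = d)
  # weights enumerated column-major to match frame layout
  wv <- as.vector(w)
  xg <- rep(seq_len(d), each = nrow(frame)); yg <- rep(seq_len(nrow(frame)), times = d)
  x0 <- sum(xg * wv); y0 <- sum(yg * wv)
  sx <- sqrt(max(sum((xg - x0)^2 * wv), 0.5))
  sy <- sqrt(max(sum((yg - y0)^2 * wv), 0.5))
  c(x0 = x0, y0 = y0, sigma_x = sx, sigma_y = sy, theta = theta,
    phi = Arg(ft[pk[1], pk[2]]) %% (2 * pi), freq = max(f, 0.02))
}

fit_gabor_frame <- function(frame, mask, seed, n_restarts = 4L) {
  yv <- frame[mask]
  sstot <- sum((yv - mean(yv))^2)
  if (sum(yv^2) < 1e-20 || sstot < 1e-20) {
    return(list(par = c(x0 = NA_real_, y0 = NA_real_, sigma_x = NA_real_,
                        sigma_y = NA_real_, theta = NA_real_, phi = NA_real_,
                        freq = NA_real_),
                amplitude = 0, r2 = 0, degenerate = TRUE))
  }
  idx <- which(mask, arr.ind = TRUE)
  xg <- idx[, 2]; yg <- idx[, 1]
  start0 <- gabor_start_fft(frame, mask)
  rng <- local_rng(as.double(seed) * 2953 + 11)
  starts <- list(start0)
  for (j in seq_len(n_restarts)) {
    s <- start0
    s["theta"] <- (s["theta"] + rng(1, -0.4, 0.4)) %% pi
    s["phi"] <- (s["phi"] + rng(1, -1.5, 1.5)) %% (2 * pi)
    s["freq"] <- s["freq"] * (1 + rng(1, -0.35, 0.35))
    s["x0"] <- s["x0"] + rng(1, -1.5, 1.5)
    s["y0"] <- s["y0"] + rng(1, -1.5, 1.5)
    starts[[j + 1L]] <- s
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = gabor_residual, xg = xg, yg = yg, yv = yv,
                         control = minpack.lm::nls.lm.control(maxiter = 120)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  par <- best$fit$par
  par["sigma_x"] <- abs(par["sigma_x"]); par["sigma_y"] <- abs(par["sigma_y"])
  g <- gabor_eval(par, xg, yg)
  a <- sum(g * yv) / max(sum(g * g), 1e-12)
  if (a < 0) {           # negative amplitude is a phase shift of pi
    a <- -a
    par["phi"] <- par["phi"] + pi
  }
  r2 <- 1 - best$ssr / sstot
  can <- canonicalize_gabor(par)
  list(par = can, amplitude = a, r2 = r2, degenerate = FALSE)
}

#' Fit Gabor functions to an independent component
#'
#' Reconstructs the IC as a masked `13 x 13 x 11` sequence and least-squares
#' fits each frame with a 2-D Gabor
#' `G(x, y) = exp(-(x'^2/(2*sx^2) + y'^2/(2*sy^2))) * cos(2*pi*f*x' + phi)`
#' (rotated coordinates about the envelope centre; amplitude solved in closed
#' form). Each fit is multi-start: an FFT-derived initial guess plus seeded
#' jittered restarts. The summary fit is the fit of the highest-energy frame,
#' whose 6 canonical parameters (`x0, y0, sigma_x, sigma_y, theta, phi`) drive
#' IC clustering; the 7th fitted parameter, the carrier frequency, is reported
#' but excluded from clustering.
#'
#' @param component Numeric vector of length `129 * 11` (one row of an
#'   [fit_ica()] basis), or a `13 x 13 x 11` array.
#' @param seed Integer seed for the jittered restarts.
#' @param frames `"all"` fits all 11 frames; `"best"` fits only the
#'   highest-energy frame (sufficient for the clustering summary).
#' @param cfg A [scale_config()] (mask geometry).
#' @return A list of class `gabor_fit` with `frames` (tibble of per-frame
#'   parameters, `r2`, `amplitude`, `degenerate`) and `summary` (one row, the
#'   highest-energy frame).
#' @export
fit_gabor <- function(component, seed = 1L, frames = c("all", "best"),
                      cfg = scale_config()) {
  frames <- match.arg(frames)
  cm <- circular_mask(cfg$target[1])
  d <- cfg$target[1]; tt <- cfg$target[2]
  if (is.array(component) && length(dim(component)) == 3L) {
    vol <- component
  } else {
    vol <- array(0, dim = c(d, d, tt))
    np <- nrow(cm$order)
    for (f in seq_len(tt)) {
      fr <- matrix(0, d, d)
      fr[cm$order] <- component[(f - 1L) * np + seq_len(np)]
      vol[, , f] <- fr
    }
  }
  if (sum(vol^2) < 1e-20) stop("component has zero energy", call. = FALSE)
  energy <- vapply(seq_len(tt), function(f) sum(vol[, , f][cm$mask]^2), numeric(1))
  best_f <- which.max(energy)
  fit_ids <- if (frames == "all") seq_len(tt) else best_f
  rows <- lapply(fit_ids, function(f) {
    res <- fit_gabor_frame(vol[, , f], cm$mask, seed = seed + 977L * f)
    tibble::tibble(frame = f, x0 = res$par[["x0"]], y0 = res$par[["y0"]],
                   sigma_x = res$par[["sigma_x"]], sigma_y = res$par[["sigma_y"]],
                   theta = res$par[["theta"]], phi = res$par[["phi"]],
                   freq = res$par[["freq"]], amplitude = res$amplitude,
                   r2 = res$r2, degenerate = res$degenerate)
  })
  frames_tbl <- dplyr::bind_rows(rows)
  structure(list(frames = frames_tbl,
                 summary = frames_tbl[frames_tbl$frame == best_f, ]),
            class = "gabor_fit")
}

#' Canonicalize Gabor parameters
#'
#' Maps equivalent parameterizations to a canonical representative: the
#' orientation is reduced to `[0, pi)` with the compensating phase flip
#' `phi -> 2*pi - phi` when the orientation crosses `pi`; the phase is reduced
#' to `[0, 2*pi)`; envelope scales are made positive and `sigma_x >= sigma_y`
#' is enforced by an axis swap (`theta -> theta + pi/2 mod pi`, carried by the
#' same phase rule). The envelope location is left unconverted. Idempotent.
#'
#' @param par Named numeric vector with elements `x0, y0, sigma_x, sigma_y,
#'   theta, phi` and optionally `freq`.
#' @return The canonical parameter vector.
#' @export
canonicalize_gabor <- function(par) {
  p <- par
  p["sigma_x"] <- abs(p["sigma_x"]); p["sigma_y"] <- abs(p["sigma_y"])
  if (!is.na(p["freq"]) && "freq" %in% names(p) && p["freq"] < 0) {
    # negative carrier equals orientation flip of the carrier phase
    p["freq"] <- -p["freq"]; p["phi"] <- -p["phi"]
  }
  # reduce theta mod pi, flipping phi sign once per half-turn crossed
  k <- floor(p["theta"] / pi)
  p["theta"] <- p["theta"] - k * pi
  if (k %% 2 != 0) p["phi"] <- -p["phi"]
  if (p["sigma_x"] < p["sigma_y"]) {
    tmp <- p["sigma_x"]; p["sigma_x"] <- p["sigma_y"]; p["sigma_y"] <- tmp
    p["theta"] <- p["theta"] + pi / 2
    if (p["theta"] >= pi) { p["theta"] <- p["theta"] - pi; p["phi"] <- -p["phi"] }
  }
  p["phi"] <- p["phi"] %% (2 * pi)
  p
}

#' Cluster independent components by their Gabor descriptions
#'
#' K-means (k-means++ initialisation, seeded restarts, plain Euclidean
#' distance) on the 6-vector `(x0, y0, sigma_x, sigma_y, theta, phi)` of each
#' IC's summary Gabor fit. No standardization is applied and the angular
#' parameters are treated as plain coordinates, following the literal
#' procedure; empty clusters are repaired by splitting the largest.
#'
#' @param fits List of [fit_gabor()] results (or a data frame of summary
#'   rows).
#' @param n_clusters Number of IC clusters.
#' @param seed Integer seed.
#' @param n_restarts K-means restarts (minimum-SSE run kept).
#' @return A list of class `ic_cluster_model` with `centroids`
#'   (`n_clusters x 6`), `assignment` (IC index -> cluster), `sse`.
#' @export
cluster_ics <- function(fits, n_clusters, seed = 1L, n_restarts = 10L) {
  tbl <- if (is.data.frame(fits)) fits
         else dplyr::bind_rows(lapply(fits, function(f) f$summary))
  x <- as.matrix(tbl[, c("x0", "y0", "sigma_x", "sigma_y", "theta", "phi")])
  x[!is.finite(x)] <- 0                   # degenerate fits at a sentinel
  if (n_clusters > nrow(x))
    stop("more clusters than ICs", call. = FALSE)
  km <- seeded_kmeans(x, n_clusters, seed = seed, n_restarts = n_restarts)
  structure(list(centroids = km$centers, assignment = km$cluster,
                 sse = km$tot.withinss, n_clusters = n_clusters),
            class = "ic_cluster_model")
}
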