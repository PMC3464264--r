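# Seeded k-means with k-means++ initialisation, restarts, and empty-cluster
# repair (split the largest cluster), shared by IC clustering and structural
# clustering. Lloyd iterations via stats::kmeans.

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  first <- sample.int(n, 1L)
  centers[1, ] <- x[first, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L)) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
    nxt <- sample.int(n, 1L, prob = p)
    centers[j + 1L, ] <- x[nxt, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[nxt, ])^2))
  }
  centers
}

seeded_kmeans <- function(x, k, seed, n_restarts = 5L, iter_max = 100L) {
  x <- as.matrix(x)
  if (k > nrow(unique(x)))
    stop("fewer distinct points (", nrow(unique(x)), ") than clusters (", k, ")",
         call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- kmeanspp_init(x, k)
    init <- init + 1e-12 * matrix(stats::rnorm(length(init)), nrow(init))
    km <- suppressWarnings(
      stats::kmeans(x, centers = init, iter.max = iter_max, algorithm = "Lloyd"))
    km <- repair_empty(x, km, iter_max)
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

# split the largest cluster to refill any emptied one, then re-run Lloyd
repair_empty <- function(x, km, iter_max) {
  sizes <- tabulate(km$cluster, nbins = nrow(km$centers))
  guard <- 0L
  while (any(sizes == 0L) && guard < 20L) {
    guard <- guard + 1L
    empty <- which(sizes == 0L)[1]
    big <- which.max(sizes)
    members <- which(km$cluster == big)
    far <- members[which.max(rowSums(sweep(x[members, , drop = FALSE], 2,
                                           km$centers[big, ])^2))]
    km$centers[empty, ] <- x[far, ]
    km <- suppressWarnings(
      stats::kmeans(x, centers = km$centers, iter.max = iter_max,
                    algorithm = "Lloyd"))
    sizes <- tabulate(km$cluster, nbins = nrow(km$centers))
  }
  km
}

nearest_center <- function(x, centers) {
  # squared Euclidean distances; ties broken toward the lowest index
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) + outer(rep(1, nrow(x)), rowSums(centers^2))
  max.col(-d2, ties.method = "first")
}
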