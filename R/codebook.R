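#' Per-IC-cluster RMS feature vector of a patch sequence
#'
#' For IC cluster `i` containing filters `A_j`, the feature of a flattened
#' patch sequence `P` is the root mean square of the projections:
#' `a_i = sqrt(mean_j (P . A_j)^2)`. With `N` IC clusters this yields a
#' length-`N` non-negative feature vector per scale. The map is positively
#' homogeneous: `feature_vector(c * P) = c * feature_vector(P)` for `c >= 0`.
#'
#' @param p Numeric patch vector of length `l`, or an `n x l` matrix for batch
#'   evaluation.
#' @param basis An [fit_ica()] `ic_basis`.
#' @param clusters An [cluster_ics()] `ic_cluster_model`.
#' @return A numeric vector of length `n_clusters` (or an `n x n_clusters`
#'   matrix for matrix input).
#' @export
feature_vector <- function(p, basis, clusters) {
  single <- is.null(dim(p))
  pm <- if (single) matrix(p, nrow = 1) else as.matrix(p)
  if (ncol(pm) != ncol(basis$components))
    stop("patch length ", ncol(pm), " does not match basis dimension ",
         ncol(basis$components), call. = FALSE)
  proj2 <- (pm %*% t(basis$components))^2      # n x n_ic squared amplitudes
  k <- clusters$n_clusters
  sizes <- tabulate(clusters$assignment, nbins = k)
  member <- outer(clusters$assignment, seq_len(k), "==") * 1  # n_ic x k
  out <- sqrt(sweep(proj2 %*% member, 2, pmax(sizes, 1L), "/"))
  out[, sizes == 0L] <- 0
  if (single) out[1, ] else out
}

#' Cluster feature vectors into structural clusters
#'
#' Seeded k-means++ (Euclidean distance, minimum-SSE restart kept) on the
#' per-scale RMS feature vectors; the resulting regions are the per-scale
#' digits of the NAS index.
#'
#' @param features `n x N` matrix of [feature_vector()] rows (or a list of
#'   vectors).
#' @param n_clusters Number of structural clusters at this scale.
#' @param seed Integer seed.
#' @param n_restarts K-means restarts (default 5).
#' @return A list of class `structural_cluster_model` with non-negative
#'   `centroids` and `sse`.
#' @export
fit_structural_clusters <- function(features, n_clusters, seed = 1L,
                                    n_restarts = 5L) {
  x <- if (is.list(features) && !is.data.frame(features))
    do.call(rbind, features) else as.matrix(features)
  if (nrow(x) < n_clusters)
    stop("need at least n_clusters = ", n_clusters, " samples", call. = FALSE)
  km <- seeded_kmeans(x, n_clusters, seed = seed, n_restarts = n_restarts)
  structure(list(centroids = km$centers, assignment = km$cluster,
                 sse = km$tot.withinss, n_clusters = n_clusters),
            class = "structural_cluster_model")
}

#' Assign patch triples to their NAS index
#'
#' Each scale's feature vector is mapped to its nearest structural-cluster
#' centroid (ties to the lowest index); the NAS index is the triple of the
#' three per-scale cluster indices, encoded as the string `"c1.c2.c3"`.
#'
#' @param features_by_scale List of three `n x N_s` feature matrices (one per
#'   scale, same row order).
#' @param models List of three [fit_structural_clusters()] models.
#' @return Character vector of `n` NAS indices.
#' @export
assign_nas <- function(features_by_scale, models) {
  stopifnot(length(features_by_scale) == length(models))
  if (any(vapply(models, function(m) is.null(m$centroids), logical(1))))
    stop("structural cluster models must be fitted", call. = FALSE)
  idx <- lapply(seq_along(models), function(s) {
    x <- features_by_scale[[s]]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    nearest_center(as.matrix(x), models[[s]]$centroids)
  })
  do.call(paste, c(idx, sep = "."))
}

#' Per-video NAS count table
#'
#' @param assignments Tibble with columns `video_id`, `label`, `nas` (one row
#'   per retained interest point).
#' @return A long tibble `(video_id, label, nas, count)`.
#' @export
nas_count_table <- function(assignments) {
  dplyr::count(assignments, .data$video_id, .data$label, .data$nas,
               name = "count")
}

# mean per-video relative frequency of every NAS within each class
class_frequencies <- function(counts) {
  counts |>
    dplyr::group_by(.data$video_id) |>
    dplyr::mutate(rel = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    tidyr::complete(tidyr::nesting(!!rlang::sym("video_id"), !!rlang::sym("label")),
                    nas = unique(.data$nas), fill = list(rel = 0)) |>
    dplyr::group_by(.data$label, .data$nas) |>
    dplyr::summarise(freq = mean(.data$rel), .groups = "drop")
}

#' Select discriminative NAS code words
#'
#' Two-step selection: (1) NASs with total training occurrences `<= Mc` are
#' dropped ("more than Mc" semantics, so a NAS occurring exactly `Mc` times is
#' excluded); (2) for every ordered class pair `(A, B)` the survivors are
#' ranked by `s = f_A - f_B` descending, where `f` is the mean per-video
#' relative frequency in a class, with ties broken by smaller `f_B` then by
#' smaller NAS id; the top `Nc` per ordered pair are taken and the union over
#' all ordered pairs is the selected set.
#'
#' @param counts A [nas_count_table()] (needs >= 2 classes).
#' @param Mc Minimum-occurrence threshold.
#' @param Nc Per-ordered-pair selection budget (>= 1).
#' @return A list of class `nas_selection` with `selected` (character vector,
#'   ordered), `provenance` (tibble of `(class_a, class_b, nas, rank, score)`),
#'   `Mc`, `Nc`.
#' @export
select_nas <- function(counts, Mc, Nc) {
  if (Nc < 1) stop("Nc must be >= 1", call. = FALSE)
  classes <- sort(unique(counts$label))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  totals <- counts |>
    dplyr::group_by(.data$nas) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  survivors <- totals$nas[totals$total > Mc]
  if (length(survivors) == 0L)
    return(structure(list(selected = character(), provenance = tibble::tibble(),
                          Mc = Mc, Nc = Nc), class = "nas_selection"))
  freq <- class_frequencies(dplyr::filter(counts, .data$nas %in% survivors))
  wide <- tidyr::pivot_wider(freq, names_from = "label", values_from = "freq",
                             values_fill = 0)
  prov <- list()
  for (a in classes) for (b in setdiff(classes, a)) {
    fa <- wide[[a]] %||% rep(0, nrow(wide))
    fb <- wide[[b]] %||% rep(0, nrow(wide))
    ord <- order(-(fa - fb), fb, wide$nas)
    take <- ord[seq_len(min(Nc, length(ord)))]
    prov[[paste(a, b)]] <- tibble::tibble(
      class_a = a, class_b = b, nas = wide$nas[take],
      rank = seq_along(take), score = (fa - fb)[take])
  }
  prov <- dplyr::bind_rows(prov)
  selected <- unique(prov$nas)
  structure(list(selected = selected, provenance = prov, Mc = Mc, Nc = Nc),
            class = "nas_selection")
}

#' Grid-pooled NAS histogram of one video
#'
#' The video is partitioned into `n x m x k` equal-width bands (`n` vertical,
#' `m` horizontal, `k` temporal; half-open intervals, last band closed) and
#' each retained interest point increments the count of its NAS in the cell
#' containing its `(y, x, t)`. Points whose NAS is not in the selection are
#' dropped. The pooled vector concatenates cells vertically-major (y band,
#' then x band, then t band), each cell in selection order.
#'
#' @param assignments Tibble with columns `x`, `y`, `t` (1-based), `nas` for
#'   one video.
#' @param selection A [select_nas()] result (or character vector of NAS ids).
#' @param grid Integer vector `(n, m, k)`.
#' @param dims Video dimensions `(H, W, T)`.
#' @return A list of class `nas_histogram`: `counts` (named integer vector of
#'   length `n*m*k*length(selected)`), `grid`, `selected`, `n_retained`.
#' @export
nas_histogram <- function(assignments, selection, grid = c(3L, 1L, 1L),
                          dims) {
  sel <- if (inherits(selection, "nas_selection")) selection$selected else selection
  if (prod(grid) < 1) stop("grid cell count must be >= 1", call. = FALSE)
  pts <- dplyr::filter(assignments, .data$nas %in% sel)
  band <- function(coord, extent, nb) pmin(floor((coord - 1) / (extent / nb)), nb - 1) + 1L
  cy <- band(pts$y, dims[1], grid[1])
  cx <- band(pts$x, dims[2], grid[2])
  ct <- band(pts$t, dims[3], grid[3])
  cell <- (cy - 1L) * grid[2] * grid[3] + (cx - 1L) * grid[3] + ct
  ncell <- prod(grid)
  lev <- paste(rep(seq_len(ncell), each = length(sel)),
               rep(seq_along(sel), times = ncell), sep = ":")
  key <- factor(paste(cell, match(pts$nas, sel), sep = ":"), levels = lev)
  counts <- as.integer(table(key))
  names(counts) <- paste0("cell", rep(seq_len(prod(grid)), each = length(sel)),
                          "_", rep(sel, times = prod(grid)))
  structure(list(counts = counts, grid = as.integer(grid), selected = sel,
                 n_retained = nrow(pts)),
            class = "nas_histogram")
}

#' Pool NAS histograms of many videos into a matrix
#'
#' @param assignment_list Named list of per-video assignment tibbles
#'   (`x, y, t, nas`).
#' @param selection A [select_nas()] result.
#' @param grid Integer `(n, m, k)` grid.
#' @param dims Video dimensions `(H, W, T)` shared by the clips.
#' @return Numeric matrix, rows = videos (named), columns = grid cells x
#'   selected NASs.
#' @export
pool_histograms <- function(assignment_list, selection, grid, dims) {
  rows <- lapply(assignment_list, function(a)
    nas_histogram(a, selection, grid, dims)$counts)
  out <- do.call(rbind, rows)
  rownames(out) <- names(assignment_list)
  out
}

#' Sharing of NASs across action classes
#'
#' A NAS "occurs" in a class iff its total count there is at least 1; the
#' sharing level of a NAS is the number of classes it occurs in. Returns both
#' per-NAS levels and the percentage distribution over levels (summing to
#' 100).
#'
#' @param counts A [nas_count_table()].
#' @return A list with `per_nas` (tibble `nas`, `n_classes`) and
#'   `distribution` (tibble `n_classes`, `percent`).
#' @export
nas_sharing_stats <- function(counts) {
  per_nas <- counts |>
    dplyr::filter(.data$count > 0) |>
    dplyr::distinct(.data$nas, .data$label) |>
    dplyr::count(.data$nas, name = "n_classes")
  k <- length(unique(counts$label))
  dist <- per_nas |>
    dplyr::count(.data$n_classes, name = "n_nas") |>
    tidyr::complete(n_classes = seq_len(k), fill = list(n_nas = 0L)) |>
    dplyr::mutate(percent = 100 * .data$n_nas / sum(.data$n_nas))
  list(per_nas = per_nas, distribution = dist)
}

#' Pearson correlation between NAS occurrence profiles
#'
#' Correlates per-video count vectors of every pair of NASs. A NAS whose
#' counts have zero variance across videos gets correlation 0 with everything
#' (and with itself).
#'
#' @param counts A [nas_count_table()] covering at least 3 videos.
#' @return Symmetric correlation matrix with NAS ids as dimnames.
#' @export
nas_correlation <- function(counts) {
  wide <- counts |>
    dplyr::select("video_id", "nas", "count") |>
    tidyr::pivot_wider(names_from = "nas", values_from = "count",
                       values_fill = 0)
  if (nrow(wide) < 3L) stop("need at least 3 videos", call. = FALSE)
  m <- as.matrix(wide[, -1, drop = FALSE])
  sds <- apply(m, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(m))
  cc[sds == 0, ] <- 0
  cc[, sds == 0] <- 0
  cc
}

#' Information content of individual NASs
#'
#' For each NAS and each class, univariate Gaussians (variance floored at
#' 1e-6) are fitted to the per-video relative frequency of the NAS in the
#' class and in the rest; each video is classified leave-one-video-out by the
#' higher likelihood under equal priors, and the one-vs-rest accuracy is
#' reported.
#'
#' @param counts A [nas_count_table()] with at least 2 videos per class.
#' @param var_floor Variance floor of the Gaussian model.
#' @return Tibble `(nas, label, accuracy)`.
#' @export
nas_info_content <- function(counts, var_floor = 1e-6) {
  classes <- sort(unique(counts$label))
  videos <- dplyr::distinct(counts, .data$video_id, .data$label)
  small <- classes[vapply(classes, function(cl)
    sum(videos$label == cl) < 2L, logical(1))]
  if (length(small)) {
    warning("skipping classes with < 2 videos: ", paste(small, collapse = ", "))
    classes <- setdiff(classes, small)
  }
  rel <- counts |>
    dplyr::group_by(.data$video_id) |>
    dplyr::mutate(rel = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  nases <- unique(counts$nas)
  wide <- rel |>
    dplyr::select("video_id", "nas", "rel") |>
    tidyr::pivot_wider(names_from = "nas", values_from = "rel", values_fill = 0)
  vids <- wide$video_id
  lab <- videos$label[match(vids, videos$video_id)]
  m <- as.matrix(wide[, -1, drop = FALSE])
  out <- list()
  for (cl in classes) {
    is_cl <- lab == cl
    acc <- vapply(nases, function(nn)
      gaussian_loo_accuracy(m[, nn], is_cl, var_floor), numeric(1))
    out[[cl]] <- tibble::tibble(nas = nases, label = cl, accuracy = acc)
  }
  dplyr::bind_rows(out)
}

# leave-one-out accuracy of the two-Gaussian (equal-prior) Bayes classifier
# on a scalar feature; the core of the NAS information-content statistic
gaussian_loo_accuracy <- function(x, is_cl, var_floor = 1e-6) {
  correct <- vapply(seq_along(x), function(i) {
    tr_in <- x[is_cl & seq_along(x) != i]
    tr_out <- x[!is_cl & seq_along(x) != i]
    ll <- function(v, s) stats::dnorm(v, mean(s),
                                      sqrt(max(stats::var(s), var_floor)),
                                      log = TRUE)
    pred_in <- ll(x[i], tr_in) >= ll(x[i], tr_out)
    pred_in == is_cl[i]
  }, logical(1))
  mean(correct)
}
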