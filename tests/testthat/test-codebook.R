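make_basis <- function(mat) {
  structure(list(components = mat, n_ic = nrow(mat)), class = "ic_basis")
}
make_ic_clusters <- function(assignment) {
  structure(list(assignment = assignment,
                 n_clusters = max(assignment)), class = "ic_cluster_model")
}

test_that("RMS cluster features match their closed forms", {
  basis <- make_basis(diag(1, 2, 5))
  one_cluster <- make_ic_clusters(c(1L, 1L))
  expect_equal(feature_vector(c(3, 4, 0, 0, 0), basis, one_cluster),
               sqrt(12.5), tolerance = 1e-12)
  # singleton cluster: |projection|
  two_clusters <- make_ic_clusters(c(1L, 2L))
  expect_equal(feature_vector(c(-3, 4, 0, 0, 0), basis, two_clusters),
               c(3, 4), tolerance = 1e-12)
  # orthogonal patch: zero feature
  expect_equal(feature_vector(c(0, 0, 1, 2, 3), basis, one_cluster), 0,
               tolerance = 1e-12)
  # positive homogeneity
  set.seed(3)
  p <- stats::rnorm(5)
  expect_equal(feature_vector(2.5 * p, basis, two_clusters),
               2.5 * feature_vector(p, basis, two_clusters), tolerance = 1e-12)
  expect_error(feature_vector(1:4, basis, one_cluster), "length")
})

test_that("structural clustering recovers well-separated rays", {
  set.seed(23)
  rays <- rbind(matrix(rep(c(10, 0, 0), each = 8), 8) ,
                matrix(rep(c(0, 10, 0), each = 8), 8),
                matrix(rep(c(0, 0, 10), each = 8), 8)) +
    matrix(stats::rnorm(72, sd = 0.05), 24)
  m <- fit_structural_clusters(abs(rays), 3, seed = 2)
  truth <- rep(1:3, each = 8)
  expect_equal(length(unique(paste(m$assignment, truth))), 3L)
  # single cluster centroid is the mean
  m1 <- fit_structural_clusters(abs(rays), 1, seed = 2)
  expect_equal(as.vector(m1$centroids), colMeans(abs(rays)), tolerance = 1e-10)
  # seeded: same data, same model
  m2 <- fit_structural_clusters(abs(rays), 3, seed = 2)
  expect_identical(m$assignment, m2$assignment)
})

test_that("NAS assignment is nearest-centroid with lowest-index tie-break", {
  models <- lapply(1:3, function(s)
    structure(list(centroids = rbind(c(0, 0), c(2, 0), c(1, 0)),
                   n_clusters = 3L), class = "structural_cluster_model"))
  feats <- lapply(1:3, function(s) rbind(c(0.1, 0), c(1.9, 0)))
  expect_equal(assign_nas(feats, models), c("1.1.1", "2.2.2"))
  # equidistant between centroids 1 (at 0) and 3 (at 1): lowest index wins
  feats_tie <- lapply(1:3, function(s) matrix(c(0.5, 0), 1))
  expect_equal(assign_nas(feats_tie, models), "1.1.1")
  # batch equals map of singles
  single <- vapply(1:2, function(i)
    assign_nas(lapply(feats, function(f) f[i, , drop = FALSE]), models),
    character(1))
  expect_equal(assign_nas(feats, models), single)
})

test_that("NAS selection matches exhaustive enumeration of the rule", {
  # hand table: 5 NASs, 2 classes, 2 videos each
  counts <- tibble::tibble(
    video_id = rep(c("a1", "a2", "b1", "b2"), each = 5),
    label = rep(c("A", "A", "B", "B"), each = 5),
    nas = rep(paste0("n", 1:5), 4),
    count = c(6, 2, 1, 0, 1,   4, 4, 1, 1, 0,
              0, 1, 5, 3, 1,   1, 0, 3, 5, 1))
  counts <- dplyr::filter(counts, count > 0)
  sel <- select_nas(counts, Mc = 0, Nc = 2)
  # independent oracle: explicit frequency table and double loop
  rel <- counts |>
    dplyr::group_by(video_id) |>
    dplyr::mutate(rel = count / sum(count)) |>
    dplyr::ungroup()
  f <- function(cl, nn) {
    vids <- unique(rel$video_id[rel$label == cl])
    mean(vapply(vids, function(v) {
      r <- rel$rel[rel$video_id == v & rel$nas == nn]
      if (length(r)) r else 0
    }, numeric(1)))
  }
  want <- character(0)
  for (pair in list(c("A", "B"), c("B", "A"))) {
    tab <- data.frame(nas = paste0("n", 1:5))
    tab$fa <- vapply(tab$nas, f, 1, cl = pair[1])
    tab$fb <- vapply(tab$nas, f, 1, cl = pair[2])
    tab <- tab[order(-(tab$fa - tab$fb), tab$fb, tab$nas), ]
    want <- union(want, tab$nas[1:2])
  }
  expect_setequal(sel$selected, want)
  expect_true(all(table(paste(sel$provenance$class_a,
                              sel$provenance$class_b)) <= 2))
})

test_that("Mc is an exclusive threshold and Nc degenerates gracefully", {
  counts <- tibble::tibble(
    video_id = rep(c("a1", "b1"), each = 2),
    label = rep(c("A", "B"), each = 2),
    nas = rep(c("n1", "n2"), 2),
    count = c(3, 2, 3, 2))
  # n2 occurs exactly 4 times in total: excluded at Mc = 4
  sel <- select_nas(counts, Mc = 4, Nc = 10)
  expect_identical(sel$selected, "n1")
  # Nc larger than survivor count selects all survivors
  sel2 <- select_nas(counts, Mc = 0, Nc = 10)
  expect_setequal(sel2$selected, c("n1", "n2"))
  expect_error(select_nas(counts, 0, 0), "Nc")
  expect_error(select_nas(dplyr::mutate(counts, label = "A"), 0, 1), "classes")
})

test_that("grid pooling uses half-open bands and conserves totals", {
  asg <- tibble::tibble(x = c(5L, 5L, 5L), y = c(1L, 41L, 120L),
                        t = c(1L, 1L, 1L), nas = c("a", "a", "b"))
  h <- nas_histogram(asg, c("a", "b"), grid = c(3L, 1L, 1L),
                     dims = c(120L, 10L, 10L))
  expect_equal(sum(h$counts), 3L)
  expect_equal(h$n_retained, 3L)
  # 0-based y = 40 lies in the second band [40, 80)
  expect_equal(unname(h$counts[["cell2_a"]]), 1L)
  expect_equal(unname(h$counts[["cell3_b"]]), 1L)
  # moving a point across the boundary moves exactly one count
  asg2 <- asg; asg2$y[2] <- 40L   # 0-based 39 -> band 1
  h2 <- nas_histogram(asg2, c("a", "b"), c(3L, 1L, 1L), c(120L, 10L, 10L))
  expect_equal(sum(abs(h2$counts - h$counts)), 2L)
  # points outside the selection are dropped
  h3 <- nas_histogram(asg, c("a"), c(1L, 1L, 1L), c(120L, 10L, 10L))
  expect_equal(sum(h3$counts), 2L)
})

test_that("sharing statistics enumerate a toy table correctly", {
  counts <- tibble::tibble(
    video_id = c("a", "a", "b", "b", "c"),
    label = c("A", "A", "B", "B", "C"),
    nas = c("n1", "n2", "n1", "n2", "n1"),
    count = c(2, 1, 1, 3, 4))
  st <- nas_sharing_stats(counts)
  expect_equal(st$per_nas$n_classes[st$per_nas$nas == "n1"], 3L)
  expect_equal(st$per_nas$n_classes[st$per_nas$nas == "n2"], 2L)
  expect_equal(sum(st$distribution$percent), 100)
  expect_equal(st$distribution$n_nas[st$distribution$n_classes == 3], 1L)
})

test_that("NAS correlations handle self, duplicates, and independence", {
  set.seed(31)
  n <- 200
  base <- stats::rpois(n, 6)
  counts <- dplyr::bind_rows(lapply(seq_len(n), function(i)
    tibble::tibble(video_id = paste0("v", i), label = "A",
                   nas = c("n1", "n2", "n3", "n4"),
                   count = c(base[i], base[i], stats::rpois(1, 6) + 1,
                             stats::rpois(1, 6) + 1))))
  cc <- nas_correlation(counts)
  expect_equal(unname(diag(cc)), rep(1, 4))
  expect_equal(unname(cc["n1", "n2"]), 1, tolerance = 1e-12)
  expect_lt(abs(cc["n3", "n4"]), 0.25)   # independent rows at n = 200
  # zero-variance row gets correlation 0 by convention
  counts0 <- dplyr::mutate(counts,
                           count = ifelse(nas == "n4", 5, count))
  cc0 <- nas_correlation(counts0)
  expect_true(all(cc0["n4", ] == 0))
  expect_error(nas_correlation(counts[1:8, ]), "3 videos")
})

test_that("information content is at chance for identical classes and 1 for separated ones", {
  set.seed(37)
  n <- 50
  mk <- function(label, ids, mu)
    dplyr::bind_rows(lapply(ids, function(i)
      tibble::tibble(video_id = paste0(label, i), label = label,
                     nas = c("n1", "n2"),
                     count = c(stats::rpois(1, mu) + 1, stats::rpois(1, 10) + 1))))
  same <- dplyr::bind_rows(mk("A", 1:n, 10), mk("B", 1:n, 10))
  acc_same <- nas_info_content(same)
  expect_lt(abs(acc_same$accuracy[acc_same$nas == "n1" &
                                  acc_same$label == "A"] - 0.5), 0.12)
  sep <- dplyr::bind_rows(mk("A", 1:10, 2), mk("B", 1:10, 200))
  acc_sep <- nas_info_content(sep)
  expect_equal(unname(acc_sep$accuracy[acc_sep$nas == "n1" &
                                       acc_sep$label == "A"]), 1)
})
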