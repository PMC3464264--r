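test_that("chi-squared kernel matches its closed forms", {
  set.seed(41)
  x <- stats::runif(10); x <- x / sum(x)
  expect_equal(chi2_kernel(x, x), 1, tolerance = 1e-12)
  expect_equal(chi2_kernel(c(0.5, 0.5, 0), c(0, 0, 1)), 0, tolerance = 1e-12)
  expect_equal(chi2_kernel(c(0.5, 0.5), c(1, 0)), 2 / 3, tolerance = 1e-12)
  expect_equal(chi2_kernel(x, rev(x)), chi2_kernel(rev(x), x))
  expect_error(chi2_kernel(c(-0.1, 1.1), c(0.5, 0.5)), "non-negative")
})

test_that("chi-squared Gram matrices are positive semi-definite", {
  set.seed(43)
  h <- matrix(stats::runif(50 * 12), 50); h <- h / rowSums(h)
  g <- nasrec:::chi2_gram(h)
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("SVM separates disjoint-support classes and is deterministic", {
  h <- rbind(c(5, 1, 0, 0), c(4, 2, 0, 0), c(6, 1, 0, 0),
             c(0, 0, 5, 1), c(0, 0, 4, 2), c(0, 0, 6, 1))
  y <- rep(c("a", "b"), each = 3)
  m <- train_svm(h, y, C = 0.125)
  pr <- predict_svm(m, h)
  expect_equal(pr$label, y)
  pr2 <- predict_svm(m, h)
  expect_identical(pr, pr2)                       # repeated calls identical
  # all-zero histogram still yields a valid prediction
  z <- predict_svm(m, rep(0, 4))
  expect_true(z$label %in% c("a", "b"))
  expect_error(train_svm(h, rep("a", 6)), "2 classes")
})

test_that("duplicating a non-support training point leaves decisions unchanged", {
  h <- rbind(c(10, 0, 0, 0), c(9, 1, 0, 0), c(8, 2, 0, 0), c(7, 3, 0, 0),
             c(0, 0, 10, 0), c(0, 0, 9, 1), c(0, 0, 8, 2), c(0, 0, 7, 3))
  y <- rep(c("a", "b"), each = 4)
  m1 <- train_svm(h, y, C = 2)
  sv <- unique(unlist(lapply(m1$machines, function(m)
    kernlab::SVindex(m$machine))))
  non_sv <- setdiff(seq_len(nrow(h)), sv)
  expect_gt(length(non_sv), 0L)       # the construction leaves interior points
  m2 <- train_svm(rbind(h, h[non_sv[1], ]), c(y, y[non_sv[1]]), C = 2)
  p1 <- predict_svm(m1, h); p2 <- predict_svm(m2, h)
  expect_equal(as.matrix(p1[, -1]), as.matrix(p2[, -1]), tolerance = 1e-6)
})

test_that("vanishing C degrades training accuracy on imbalanced separable data", {
  # as C -> 0 the bias dominates and everything collapses to the majority
  h <- rbind(matrix(c(8, 2, 1, 1), 8, 4, byrow = TRUE),
             matrix(c(1, 1, 8, 2), 4, 4, byrow = TRUE))
  y <- rep(c("a", "b"), c(8, 4))
  accs <- vapply(c(0.5, 1e-3, 1e-6), function(C)
    mean(predict_svm(train_svm(h, y, C = C), h)$label == y), numeric(1))
  expect_true(all(diff(accs) <= 0))
  expect_lt(accs[3], accs[1])
})

test_that("LDA with one topic collapses to the empirical word distribution", {
  set.seed(51)
  docs <- lapply(1:60, function(i)
    sample.int(6, 500, TRUE, prob = c(.35, .25, .15, .12, .08, .05)))
  m <- fit_lda(docs, K = 1, C = 6, seed = 2, n_restarts = 1)
  emp <- tabulate(unlist(docs), 6) / length(unlist(docs))
  expect_lt(max(abs(m$beta - emp)), 1e-6)
  expect_true(all(diff(m$elbo) > -1e-6 * abs(m$elbo[-1])))
  expect_equal(rowSums(m$beta), 1, tolerance = 1e-8)
})

test_that("two near-disjoint topics are recovered by variational EM", {
  set.seed(53)
  beta_true <- rbind(c(rep(0.2, 5), rep(0, 5)), c(rep(0, 5), rep(0.2, 5)))
  docs <- lapply(1:150, function(i) {
    th <- stats::rgamma(2, 0.5); th <- th / sum(th)
    z <- sample(1:2, 50, TRUE, th)
    vapply(z, function(k) sample.int(10, 1, prob = beta_true[k, ]), 1L)
  })
  m <- fit_lda(docs, K = 2, C = 10, seed = 5, n_restarts = 2)
  tv <- function(a, b) 0.5 * sum(abs(a - b))
  perm <- min(max(tv(m$beta[1, ], beta_true[1, ]), tv(m$beta[2, ], beta_true[2, ])),
              max(tv(m$beta[1, ], beta_true[2, ]), tv(m$beta[2, ], beta_true[1, ])))
  expect_lt(perm, 0.1)
  expect_true(all(diff(m$elbo) > -1e-6 * abs(m$elbo[-1])))
  # model selection sanity: K = 2 beats K = 1 in held-out bound
  m1 <- fit_lda(docs[1:100], K = 1, C = 10, seed = 5, n_restarts = 1)
  m2 <- fit_lda(docs[1:100], K = 2, C = 10, seed = 5, n_restarts = 2)
  held <- docs[101:150]
  s1 <- sum(vapply(held, lda_score, 1, model = m1))
  s2 <- sum(vapply(held, lda_score, 1, model = m2))
  expect_gt(s2, s1)
})

test_that("per-class LDA scoring assigns class-specific vocabulary correctly", {
  set.seed(57)
  docs_a <- lapply(1:25, function(i) sample.int(4, 40, TRUE))        # words 1-4
  docs_b <- lapply(1:25, function(i) sample.int(4, 40, TRUE) + 4L)   # words 5-8
  models <- list(A = fit_lda(docs_a, K = 2, C = 8, seed = 1, n_restarts = 1),
                 B = fit_lda(docs_b, K = 2, C = 8, seed = 1, n_restarts = 1))
  out_a <- classify_lda(models, sample.int(4, 20, TRUE))
  out_b <- classify_lda(models, sample.int(4, 20, TRUE) + 4L)
  expect_equal(out_a$label, "A")
  expect_equal(out_b$label, "B")
  expect_true(all(is.finite(as.matrix(out_a[, -1]))))
  # identical models: tie broken by class order
  same <- list(A = models$A, B = models$A)
  expect_equal(classify_lda(same, sample.int(4, 10, TRUE))$label, "A")
})

test_that("topic assignment of a code word is the argmax column rule", {
  m <- list(beta = rbind(c(0.1, 0.5), c(0.2, 0.3), c(0.7, 0.2)), K = 3, C = 2)
  class(m) <- "nas_lda"
  expect_equal(topic_of_word(m, 1), 3L)
  expect_equal(topic_of_word(m, 2), 1L)
  # uniform column: lowest topic wins
  mu <- list(beta = matrix(1 / 3, 3, 2), K = 3, C = 2); class(mu) <- "nas_lda"
  expect_equal(topic_of_word(mu, 1), 1L)
  expect_error(topic_of_word(m, 3))
})

test_that("empty documents are dropped with a warning and bad K rejected", {
  docs <- list(c(1L, 2L), integer(0), c(2L, 2L))
  expect_warning(m <- fit_lda(docs, K = 1, C = 2, seed = 1, n_restarts = 1),
                 "empty")
  expect_equal(m$C, 2L)
  expect_error(fit_lda(docs[1], K = 0, C = 2), "K")
})

test_that("the protocol builds leak-free folds with conserved confusion totals", {
  ds <- tiny_dataset(n_subjects = 3, clips = 1, seed = 5)
  pr <- run_protocol(ds, tiny_config(), classifier = "svm", seed = 2)
  expect_equal(nrow(dplyr::filter(pr$folds, condition == "base")), 3L)
  cm <- pr$confusion[["svm base"]]
  expect_equal(unname(rowSums(cm)),
               unname(as.vector(table(ds$label))))
  # determinism end to end
  pr2 <- run_protocol(ds, tiny_config(), classifier = "svm", seed = 2)
  expect_identical(pr$confusion, pr2$confusion)
  expect_error(run_protocol(dplyr::select(ds, -subject_id), tiny_config()),
               "subject")
})
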