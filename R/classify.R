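#' The 1 - chi-squared histogram kernel
#'
#' `K(x, y) = 1 - 0.5 * sum_i (x_i - y_i)^2 / (x_i + y_i)`, with terms whose
#' denominator is zero contributing nothing. On L1-normalized non-negative
#' histograms the kernel is symmetric, takes values in `[0, 1]`, satisfies
#' `K(x, x) = 1`, and is positive semi-definite.
#'
#' @param x,y Non-negative numeric vectors of equal length.
#' @return Scalar similarity.
#' @export
chi2_kernel <- function(x, y) {
  if (any(x < 0) || any(y < 0))
    stop("histograms must be non-negative", call. = FALSE)
  s <- x + y
  d <- (x - y)^2
  1 - 0.5 * sum(ifelse(s > 0, d / s, 0))
}

chi2_gram <- function(a, b = a) {
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      out[i, j] <- chi2_kernel(a[i, ], b[j, ])
  out
}

# L1-normalize each grid cell's sub-histogram to equal weight, then rescale
# the concatenation to total mass exactly 1 (all-zero vectors stay 0). Equal
# total masses keep the 1-chi^2 kernel inside [0, 1] and PSD; equal per-cell
# weights keep the grid cells comparable.
normalize_cells <- function(h, n_cells) {
  m <- if (is.null(dim(h))) matrix(h, nrow = 1) else h
  per_cell <- ncol(m) / n_cells
  for (c in seq_len(n_cells)) {
    cols <- (c - 1L) * per_cell + seq_len(per_cell)
    tot <- rowSums(m[, cols, drop = FALSE])
    m[, cols] <- m[, cols, drop = FALSE] / ifelse(tot > 0, tot, 1)
  }
  mass <- rowSums(m)
  m <- m / ifelse(mass > 0, mass, 1)
  if (is.null(dim(h))) m[1, ] else m
}

#' Train a one-vs-rest SVM on NAS histograms
#'
#' Histograms are L1-normalized per grid cell, the Gram matrix is computed
#' with [chi2_kernel()], and one binary C-SVC (precomputed-kernel, via
#' kernlab) is trained per class against the rest. Training is deterministic
#' given the inputs.
#'
#' @param histograms `n x d` matrix of raw (count) histograms, one row per
#'   video.
#' @param labels Class labels of length `n` (>= 2 distinct classes).
#' @param C Regularization constant (default 0.125).
#' @param n_cells Number of grid cells the columns are blocked into.
#' @return A list of class `nas_svm` with per-class machines, the stored
#'   (normalized) training histograms, `classes`, `C`.
#' @export
train_svm <- function(histograms, labels, C = 0.125, n_cells = 1L) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  x <- normalize_cells(as.matrix(histograms), n_cells)
  gram <- chi2_gram(x)
  ev_min <- min(eigen(gram, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    warning("chi-squared Gram not PSD (min eigenvalue ", signif(ev_min, 3),
            "); adding diagonal jitter")
    gram <- gram + diag(2 * abs(ev_min), nrow(gram))
  }
  machines <- lapply(classes, function(cl) {
    y <- factor(ifelse(labels == cl, "pos", "rest"), levels = c("pos", "rest"))
    m <- kernlab::ksvm(kernlab::as.kernelMatrix(gram), y, type = "C-svc",
                       C = C, tol = 1e-7)
    # orient the decision function so larger values mean "pos": kernlab's sign
    # convention depends on the order classes are met, so calibrate on the
    # training rows
    sv <- kernlab::SVindex(m)
    dec <- drop(kernlab::predict(m, kernlab::as.kernelMatrix(
      gram[, sv, drop = FALSE]), type = "decision"))
    flip <- if (mean(dec[y == "pos"]) >= mean(dec[y == "rest"])) 1 else -1
    list(machine = m, flip = flip)
  })
  names(machines) <- classes
  structure(list(machines = machines, train_x = x, classes = classes, C = C,
                 n_cells = n_cells),
            class = "nas_svm")
}

#' Predict with a one-vs-rest NAS SVM
#'
#' The label is the argmax of the per-class decision values (signed distance
#' toward the "class" side); ties are broken by class order.
#'
#' @param model A [train_svm()] fit.
#' @param histograms Raw histogram vector or matrix (normalized internally
#'   exactly as in training).
#' @return A tibble with `label` and one `decision_<class>` column per class.
#' @export
predict_svm <- function(model, histograms) {
  x <- normalize_cells(
    if (is.null(dim(histograms))) matrix(histograms, nrow = 1)
    else as.matrix(histograms), model$n_cells)
  dec <- vapply(model$classes, function(cl) {
    m <- model$machines[[cl]]
    sv <- kernlab::SVindex(m$machine)
    ktest <- chi2_gram(x, model$train_x[sv, , drop = FALSE])
    val <- kernlab::predict(m$machine, kernlab::as.kernelMatrix(ktest),
                            type = "decision")
    drop(val) * m$flip
  }, numeric(nrow(x)))
  dec <- matrix(dec, nrow = nrow(x),
                dimnames = list(NULL, paste0("decision_", model$classes)))
  lab <- model$classes[max.col(dec, ties.method = "first")]
  dplyr::bind_cols(tibble::tibble(label = lab), tibble::as_tibble(dec))
}

# ---- variational LDA --------------------------------------------------------

# docs: list of integer count vectors of length C (word counts per document)
lda_e_step <- function(doc_counts, alpha, log_beta, max_iter = 100L, tol = 1e-6) {
  k <- length(alpha)
  words <- which(doc_counts > 0)
  cnt <- doc_counts[words]
  gamma <- alpha + sum(cnt) / k
  phi <- matrix(1 / k, length(words), k)
  for (it in seq_len(max_iter)) {
    dig <- digamma(gamma)
    lp <- sweep(t(log_beta[, words, drop = FALSE]), 2, dig, "+")
    lp <- lp - apply(lp, 1, max)
    phi_new <- exp(lp)
    phi_new <- phi_new / rowSums(phi_new)
    gamma_new <- alpha + colSums(phi_new * cnt)
    delta <- max(abs(gamma_new - gamma))
    phi <- phi_new; gamma <- gamma_new
    if (delta < tol * mean(gamma)) break
  }
  list(gamma = gamma, phi = phi, words = words, cnt = cnt)
}

lda_doc_elbo <- function(es, alpha, log_beta) {
  gamma <- es$gamma; phi <- es$phi
  dig <- digamma(gamma) - digamma(sum(gamma))
  e1 <- lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * dig)
  e2 <- sum((phi * es$cnt) %*% dig)
  lw <- t(log_beta[, es$words, drop = FALSE])
  e3 <- sum(es$cnt * rowSums(phi * lw))
  e4 <- -(lgamma(sum(gamma)) - sum(lgamma(gamma)) + sum((gamma - 1) * dig))
  e5 <- -sum(es$cnt * rowSums(phi * log(pmax(phi, 1e-300))))
  e1 + e2 + e3 + e4 + e5
}

# Newton update of the Dirichlet parameter alpha (linear-time inversion),
# with step-halving so the alpha-objective never decreases
lda_update_alpha <- function(alpha, suff, M, max_iter = 50L) {
  obj <- function(a) M * (lgamma(sum(a)) - sum(lgamma(a))) + sum((a - 1) * suff)
  for (it in seq_len(max_iter)) {
    g <- M * (digamma(sum(alpha)) - digamma(alpha)) + suff
    h <- -M * trigamma(alpha)
    z <- M * trigamma(sum(alpha))
    c0 <- sum(g / h) / (1 / z + sum(1 / h))
    step <- (g - c0) / h
    if (any(!is.finite(step))) break
    eta <- 1
    repeat {
      cand <- alpha - eta * step
      ok <- all(is.finite(cand)) && all(cand > 1e-8)
      if (ok && is.finite(obj(cand)) && obj(cand) >= obj(alpha) - 1e-12) break
      eta <- eta / 2
      if (eta < 1e-6) { cand <- alpha; break }
    }
    if (max(abs(cand - alpha)) < 1e-8) { alpha <- cand; break }
    alpha <- cand
  }
  alpha
}

#' Fit a latent Dirichlet allocation model by variational EM
#'
#' Standard variational Bayes for LDA: per-document mean-field E-step over
#' `(gamma, phi)` and M-step over the topic-word matrix `beta` and the
#' Dirichlet parameter `alpha` (Newton with linear-time Hessian inversion).
#' `beta` is smoothed with a symmetric pseudo-count `0.01 / C` treated as a
#' Dirichlet MAP prior folded into the optimised bound, so the reported
#' objective is monotone. Iterates until the relative bound change is below
#' `tol` or `max_iter` EM iterations. Initialisation of `beta` is a seeded
#' perturbed-uniform draw; `n_restarts` independent runs are made and the
#' best-bound run kept.
#'
#' @param docs List of documents. Each document is either an integer vector
#'   of word ids (tokens, 1-based) or a length-`C` count vector when
#'   `as_counts = TRUE`.
#' @param K Number of topics (>= 1).
#' @param C Vocabulary size.
#' @param seed Integer seed.
#' @param max_iter,tol EM budget and relative-ELBO tolerance.
#' @param n_restarts Independent seeded initialisations (best kept).
#' @param as_counts Set when `docs` are already count vectors.
#' @return A list of class `nas_lda`: `beta` (`K x C`, rows on the simplex),
#'   `alpha`, `elbo` (per-iteration trace of the kept run), `K`, `C`.
#' @export
fit_lda <- function(docs, K, C, seed = 1L, max_iter = 200L, tol = 1e-5,
                    n_restarts = 3L, as_counts = FALSE) {
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  counts <- if (as_counts) docs else lapply(docs, function(d) {
    tabulate(d, nbins = C)
  })
  empty <- vapply(counts, sum, numeric(1)) == 0
  if (any(empty)) {
    warning(sum(empty), " empty document(s) dropped")
    counts <- counts[!empty]
  }
  M <- length(counts)
  if (M == 0L) stop("no non-empty documents", call. = FALSE)
  eta <- 0.01 / C
  best <- NULL
  for (r in seq_len(n_restarts)) {
    rng <- local_rng(as.double(seed) * 331 + r * 7907)
    beta <- matrix(1 + 0.05 * rng(K * C), K, C)
    beta <- beta / rowSums(beta)
    alpha <- rep(1, K)
    elbo_trace <- numeric(0)
    prev <- -Inf
    for (it in seq_len(max_iter)) {
      log_beta <- log(beta)
      suff <- rep(0, K)
      beta_new <- matrix(eta, K, C)
      bound <- 0
      esl <- vector("list", M)
      for (d in seq_len(M)) {
        es <- lda_e_step(counts[[d]], alpha, log_beta)
        esl[[d]] <- es
        bound <- bound + lda_doc_elbo(es, alpha, log_beta)
        suff <- suff + digamma(es$gamma) - digamma(sum(es$gamma))
        beta_new[, es$words] <- beta_new[, es$words] +
          t(es$phi * es$cnt)
      }
      bound <- bound + sum(eta * log_beta)   # MAP prior term on beta
      elbo_trace <- c(elbo_trace, bound)
      if (is.finite(prev) && abs(bound - prev) < tol * abs(prev)) break
      prev <- bound
      beta <- beta_new / rowSums(beta_new)
      alpha <- lda_update_alpha(alpha, suff, M)
    }
    if (is.null(best) || elbo_trace[length(elbo_trace)] > best$final) {
      best <- list(beta = beta, alpha = alpha, elbo = elbo_trace,
                   final = elbo_trace[length(elbo_trace)])
    }
  }
  structure(list(beta = best$beta, alpha = best$alpha, elbo = best$elbo,
                 K = K, C = C, eta = eta),
            class = "nas_lda")
}

#' Variational bound of a document under an LDA model
#'
#' Runs the converged E-step for the document and returns the per-document
#' ELBO, the tractable surrogate for `log p(doc | model)` used as the
#' classification score.
#'
#' @param model A [fit_lda()] model.
#' @param doc Integer word-id vector (or count vector with
#'   `as_counts = TRUE`).
#' @param as_counts Whether `doc` is a count vector.
#' @return Scalar bound.
#' @export
lda_score <- function(model, doc, as_counts = FALSE) {
  cnt <- if (as_counts) doc else tabulate(doc, nbins = model$C)
  if (sum(cnt) == 0) stop("empty document", call. = FALSE)
  log_beta <- log(model$beta)
  es <- lda_e_step(cnt, model$alpha, log_beta)
  lda_doc_elbo(es, model$alpha, log_beta)
}

#' Classify a document with per-class LDA models
#'
#' One LDA model is fitted per action class; a document is assigned to the
#' class whose model gives the highest variational bound (ties broken by
#' class order).
#'
#' @param models Named list of [fit_lda()] models sharing the code book.
#' @param doc Document as in [lda_score()].
#' @param as_counts Whether `doc` is a count vector.
#' @return A tibble with `label` and one `score_<class>` column per class.
#' @export
classify_lda <- function(models, doc, as_counts = FALSE) {
  scores <- vapply(models, lda_score, numeric(1), doc = doc,
                   as_counts = as_counts)
  lab <- names(models)[which.max(scores)]
  out <- tibble::as_tibble(as.list(stats::setNames(scores,
                                                   paste0("score_", names(models)))))
  dplyr::bind_cols(tibble::tibble(label = lab), out)
}

#' Dominant topic of a code word
#'
#' The topic of word `w` is `argmax_z beta[z, w]` (ties to the lowest topic
#' id).
#'
#' @param model A [fit_lda()] model.
#' @param w Word id (1-based, `<= C`).
#' @return Integer topic id.
#' @export
topic_of_word <- function(model, w) {
  stopifnot(w >= 1, w <= model$C)
  which.max(model$beta[, w])
}
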