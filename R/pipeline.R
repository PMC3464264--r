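#' Pipeline configuration profiles
#'
#' Bundles every stage parameter. Profiles: `"kth-paper"` and
#' `"weizmann-paper"` record the parameter settings used for the two public
#' benchmarks (1200 ICs; 480 vs 440 IC clusters; 1000 vs 700 structural
#' clusters per scale; SVM selection Mc/Nc 2/400 vs 1/500; LDA selection 3/300
#' vs 0/100; grids 3-1-1 vs 1-1-1; C = 0.125; 50 vs 30 topics).
#' `"synthetic-small"` is a down-scaled profile for synthetic clips (64 ICs,
#' 32 IC clusters, 64 structural clusters, Mc = 1, Nc = 50, grid 3-1-1, 8
#' topics).
#'
#' @param profile Profile name.
#' @param ... Named overrides of individual fields.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(profile = c("synthetic-small", "kth-paper",
                                        "weizmann-paper"), ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    "kth-paper" = list(n_ic = 1200L, n_ic_clusters = 480L,
                       n_struct_clusters = 1000L,
                       Mc_svm = 2L, Nc_svm = 400L, Mc_lda = 3L, Nc_lda = 300L,
                       grid = c(3L, 1L, 1L), C = 0.125, K_topics = 50L,
                       ica_max_samples = 20000L),
    "weizmann-paper" = list(n_ic = 1200L, n_ic_clusters = 440L,
                            n_struct_clusters = 700L,
                            Mc_svm = 1L, Nc_svm = 500L, Mc_lda = 0L,
                            Nc_lda = 100L, grid = c(1L, 1L, 1L), C = 0.125,
                            K_topics = 30L, ica_max_samples = 20000L),
    "synthetic-small" = list(n_ic = 64L, n_ic_clusters = 32L,
                             n_struct_clusters = 64L,
                             Mc_svm = 1L, Nc_svm = 50L, Mc_lda = 1L,
                             Nc_lda = 50L, grid = c(3L, 1L, 1L), C = 0.125,
                             K_topics = 8L, ica_max_samples = 2500L))
  cfg <- utils::modifyList(
    c(base, list(profile = profile,
                 detector = if (profile == "synthetic-small")
                   detector_params(min_response_frac = 0.01)
                 else detector_params(),
                 scales = scale_config(),
                 struct_max_samples = 20000L,
                 seed = 1L)),
    list(...))
  structure(cfg, class = "pipeline_config")
}

# detect interest points and sample patch triples for one clip
extract_clip_features <- function(v, config) {
  pts <- detect_interest_points(v, config$detector)
  ps <- sample_patches(v, pts, config$scales)
  list(points = pts, matrices = ps$matrices, dims = dim(v))
}

# stage over a dataset; returns a named list keyed by clip_id
extract_stage <- function(dataset, config) {
  out <- purrr::map(dataset$video, extract_clip_features, config = config)
  names(out) <- dataset$clip_id
  out
}

#' Build a NAS codebook from training clips
#'
#' Runs the compilation recipe on the training set: detect interest points,
#' sample coupled three-scale patch sequences, fit a per-scale IC basis on a
#' seeded subsample, fit Gabor summaries and cluster the ICs in Gabor
#' parameter space, compute the RMS feature vectors of the training patches,
#' and partition each scale's feature space into structural clusters. The
#' returned bundle carries a manifest echoing every parameter and seed.
#'
#' @param dataset Tibble with columns `video`, `label`, `clip_id` (e.g. from
#'   [generate_dataset()]).
#' @param config A [pipeline_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param features Optional precomputed [extract_stage] output (reused to
#'   avoid recomputing detection across folds).
#' @return A list of class `nas_codebook` with `bases`, `ic_models`,
#'   `struct_models` (one per scale), `config`, `manifest`.
#' @export
build_codebook <- function(dataset, config = pipeline_config(), seed = NULL,
                           features = NULL) {
  seed <- seed %||% config$seed
  if (length(unique(dataset$label)) < 1L)
    stop("need at least one training class", call. = FALSE)
  if (is.null(features)) features <- extract_stage(dataset, config)
  n_scales <- length(config$scales$diameters)
  pooled <- lapply(seq_len(n_scales), function(s)
    do.call(rbind, lapply(features, function(f) f$matrices[[s]])))
  rng <- local_rng(as.double(seed) * 97 + 5)
  bases <- vector("list", n_scales)
  ic_models <- vector("list", n_scales)
  struct_models <- vector("list", n_scales)
  for (s in seq_len(n_scales)) {
    x <- pooled[[s]]
    n_take <- min(nrow(x), config$ica_max_samples)
    take <- order(rng(nrow(x)))[seq_len(n_take)]     # seeded subsample
    bases[[s]] <- fit_ica(x[take, , drop = FALSE], config$n_ic,
                          seed = seed + 11L * s)
    fits <- lapply(seq_len(config$n_ic), function(i)
      fit_gabor(bases[[s]]$components[i, ], seed = seed + 1000L * s + i,
                frames = "best", cfg = config$scales)$summary)
    ic_models[[s]] <- cluster_ics(dplyr::bind_rows(fits),
                                  config$n_ic_clusters,
                                  seed = seed + 29L * s)
    n_sf <- min(nrow(x), config$struct_max_samples)
    take2 <- order(rng(nrow(x)))[seq_len(n_sf)]
    feats <- feature_vector(x[take2, , drop = FALSE], bases[[s]], ic_models[[s]])
    struct_models[[s]] <- fit_structural_clusters(
      feats, config$n_struct_clusters, seed = seed + 53L * s)
  }
  mask <- circular_mask(config$scales$target[1])
  structure(list(bases = bases, ic_models = ic_models,
                 struct_models = struct_models, config = config,
                 mask_order = mask$order,
                 manifest = codebook_manifest(config, seed, dataset)),
            class = "nas_codebook")
}

codebook_manifest <- function(config, seed, dataset) {
  list(seed = seed,
       profile = config$profile,
       parameters = unclass(config)[c("n_ic", "n_ic_clusters",
                                      "n_struct_clusters", "Mc_svm", "Nc_svm",
                                      "Mc_lda", "Nc_lda", "grid", "C",
                                      "K_topics", "ica_max_samples")],
       n_clips = nrow(dataset),
       classes = sort(unique(dataset$label)),
       input_hash = rlang::hash(dataset$clip_id))
}

#' Assign every interest point of a clip to its NAS
#'
#' @param codebook A [build_codebook()] bundle.
#' @param clip_features One element of the extraction stage (list with
#'   `points` and `matrices`).
#' @return Tibble `(x, y, t, nas)`.
#' @export
codebook_assign <- function(codebook, clip_features) {
  if (nrow(clip_features$points) == 0L)
    return(tibble::tibble(x = integer(), y = integer(), t = integer(),
                          nas = character()))
  feats <- lapply(seq_along(codebook$bases), function(s)
    feature_vector(clip_features$matrices[[s]], codebook$bases[[s]],
                   codebook$ic_models[[s]]))
  nas <- assign_nas(feats, codebook$struct_models)
  dplyr::mutate(clip_features$points[, c("x", "y", "t")], nas = nas)
}

# pooled histogram rows for a set of clips with per-clip dimensions
pooled_rows <- function(assignments, dims_list, selection, grid) {
  rows <- lapply(names(assignments), function(id)
    nas_histogram(assignments[[id]], selection, grid, dims_list[[id]])$counts)
  out <- do.call(rbind, rows)
  rownames(out) <- names(assignments)
  out
}

lda_docs_from_assignments <- function(assignments, selection) {
  lapply(assignments, function(a) {
    w <- match(a$nas, selection$selected)
    w[!is.na(w)]
  })
}

#' Run the grouped cross-validation and robustness protocol
#'
#' Leave-one-subject-out evaluation: for each fold the NAS codebook, the
#' discriminative selection, and the classifiers are fitted on the training
#' subjects only, and the held-out subject's clips are scored. Optional
#' test-time spatial rescalings re-extract interest points and patches from
#' the transformed test clips and score them with the fold's unchanged
#' codebook and classifier (the noise variant instead perturbs the whole
#' dataset and retrains; see [perturb_dataset_noise()]).
#'
#' @param dataset Tibble with columns `video`, `label`, `subject_id`,
#'   `clip_id`.
#' @param config A [pipeline_config()].
#' @param classifier `"svm"`, `"lda"`, or `"both"`.
#' @param scale_factors Numeric vector of test-time rescale factors (e.g.
#'   `c(1.1, 0.9)`), or `NULL` for none.
#' @param seed Integer seed for every stochastic stage.
#' @return A list of class `nas_protocol`: `results` (tibble with `condition`,
#'   `classifier`, `accuracy`), `confusion` (named list of confusion
#'   matrices), `folds` (per-fold per-condition accuracies),
#'   `n_selected_svm`, `n_selected_lda` (mean over folds).
#' @export
run_protocol <- function(dataset, config = pipeline_config(),
                         classifier = c("svm", "lda", "both"),
                         scale_factors = NULL, seed = 1L) {
  classifier <- match.arg(classifier)
  use_svm <- classifier %in% c("svm", "both")
  use_lda <- classifier %in% c("lda", "both")
  if (!"subject_id" %in% names(dataset))
    stop("subject ids required", call. = FALSE)
  subjects <- sort(unique(dataset$subject_id))
  classes <- sort(unique(dataset$label))
  base_feat <- extract_stage(dataset, config)
  pert_feat <- list()
  for (f in scale_factors %||% numeric(0)) {
    key <- sprintf("scale_%g", f)
    scaled <- dataset
    scaled$video <- purrr::map(dataset$video, rescale_video, factor = f)
    pert_feat[[key]] <- extract_stage(scaled, config)
  }
  conditions <- c("base", names(pert_feat))
  preds <- list(); truth <- list(); fold_acc <- list()
  n_sel <- c(svm = 0, lda = 0)
  for (fold_i in seq_along(subjects)) {
    held <- subjects[fold_i]
    tr <- dataset$subject_id != held
    if (!any(tr) || !all(classes %in% dataset$label[tr]))
      stop("protocol error: fold ", held, " leaves a class without training data",
           call. = FALSE)
    train_ids <- dataset$clip_id[tr]
    test_ids <- dataset$clip_id[!tr]
    cb <- build_codebook(dataset[tr, ], config, seed = seed + fold_i,
                         features = base_feat[train_ids])
    assign_one <- function(feats, ids)
      stats::setNames(lapply(ids, function(id)
        codebook_assign(cb, feats[[id]])), ids)
    train_asg <- assign_one(base_feat, train_ids)
    counts <- nas_count_table(dplyr::bind_rows(
      purrr::imap(train_asg, function(a, id)
        dplyr::mutate(a, video_id = id,
                      label = dataset$label[dataset$clip_id == id]))))
    dims_of <- function(feats, ids) stats::setNames(
      lapply(ids, function(id) feats[[id]]$dims), ids)
    models <- list()
    if (use_svm) {
      sel_svm <- select_nas(counts, config$Mc_svm, config$Nc_svm)
      n_sel["svm"] <- n_sel["svm"] + length(sel_svm$selected) / length(subjects)
      htrain <- pooled_rows(train_asg, dims_of(base_feat, train_ids),
                            sel_svm, config$grid)
      models$svm <- train_svm(htrain, dataset$label[tr], C = config$C,
                              n_cells = prod(config$grid))
      models$sel_svm <- sel_svm
    }
    if (use_lda) {
      sel_lda <- select_nas(counts, config$Mc_lda, config$Nc_lda)
      n_sel["lda"] <- n_sel["lda"] + length(sel_lda$selected) / length(subjects)
      docs <- lda_docs_from_assignments(train_asg, sel_lda)
      lab_tr <- dataset$label[tr]
      models$lda <- lapply(stats::setNames(classes, classes), function(cl) {
        cls_docs <- docs[lab_tr == cl & vapply(docs, length, 1L) > 0]
        fit_lda(cls_docs, K = config$K_topics, C = length(sel_lda$selected),
                seed = seed + 100L * fold_i + match(cl, classes))
      })
      models$sel_lda <- sel_lda
    }
    for (cond in conditions) {
      feats <- if (cond == "base") base_feat else pert_feat[[cond]]
      test_asg <- assign_one(feats, test_ids)
      lab_true <- dataset$label[!tr]
      if (use_svm) {
        htest <- pooled_rows(test_asg, dims_of(feats, test_ids),
                             models$sel_svm, config$grid)
        p <- predict_svm(models$svm, htest)$label
        key <- paste("svm", cond)
        preds[[key]] <- c(preds[[key]], p)
        truth[[key]] <- c(truth[[key]], lab_true)
        fold_acc[[length(fold_acc) + 1L]] <- tibble::tibble(
          subject = held, condition = cond, classifier = "svm",
          accuracy = mean(p == lab_true))
      }
      if (use_lda) {
        docs <- lda_docs_from_assignments(test_asg, models$sel_lda)
        p <- vapply(docs, function(d) {
          if (length(d) == 0L) return(classes[1])   # tie-break on empty doc
          classify_lda(models$lda, d)$label
        }, character(1))
        key <- paste("lda", cond)
        preds[[key]] <- c(preds[[key]], p)
        truth[[key]] <- c(truth[[key]], lab_true)
        fold_acc[[length(fold_acc) + 1L]] <- tibble::tibble(
          subject = held, condition = cond, classifier = "lda",
          accuracy = mean(p == lab_true))
      }
    }
  }
  confusion <- lapply(stats::setNames(names(preds), names(preds)), function(k)
    table(truth = factor(truth[[k]], classes),
          predicted = factor(preds[[k]], classes)))
  results <- dplyr::bind_rows(lapply(names(preds), function(k) {
    parts <- strsplit(k, " ")[[1]]
    tibble::tibble(classifier = parts[1], condition = parts[2],
                   accuracy = mean(preds[[k]] == truth[[k]]))
  }))
  structure(list(results = results, confusion = confusion,
                 folds = dplyr::bind_rows(fold_acc),
                 n_selected_svm = unname(n_sel["svm"]),
                 n_selected_lda = unname(n_sel["lda"]),
                 classes = classes, seed = seed),
            class = "nas_protocol")
}

#' @export
print.nas_protocol <- function(x, ...) {
  cat("<nas_protocol> leave-one-subject-out evaluation\n")
  print(as.data.frame(x$results), row.names = FALSE)
  invisible(x)
}

#' Train on one dataset and report the evaluation metrics
#'
#' Thin orchestration wrapper: runs [run_protocol()] and formats a metrics
#' report (per-fold and mean accuracy, confusion matrices, selected-NAS
#' counts).
#'
#' @inheritParams run_protocol
#' @return A list of class `nas_report` with `protocol`, `mean_accuracy`
#'   (named by classifier/condition), `confusion`, `manifest`.
#' @export
train_eval <- function(dataset, config = pipeline_config(),
                       classifier = "both", scale_factors = NULL, seed = 1L) {
  prot <- run_protocol(dataset, config, classifier = classifier,
                       scale_factors = scale_factors, seed = seed)
  acc <- stats::setNames(prot$results$accuracy,
                         paste(prot$results$classifier, prot$results$condition))
  structure(list(protocol = prot, mean_accuracy = acc,
                 confusion = prot$confusion,
                 manifest = list(seed = seed, config = unclass(config),
                                 n_clips = nrow(dataset))),
            class = "nas_report")
}
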