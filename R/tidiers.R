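#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Gabor fit
#'
#' @param x A [fit_gabor()] result.
#' @param ... Unused.
#' @return The per-frame parameter tibble.
#' @method tidy gabor_fit
#' @export
tidy.gabor_fit <- function(x, ...) x$frames

#' @rdname tidy.gabor_fit
#' @method glance gabor_fit
#' @export
glance.gabor_fit <- function(x, ...) {
  dplyr::select(x$summary, "frame", "theta", "phi", "freq", "sigma_x",
                "sigma_y", "r2")
}

#' Tidy an LDA model
#'
#' @param x A [fit_lda()] model.
#' @param ... Unused.
#' @return Long tibble `(topic, word, beta)`.
#' @method tidy nas_lda
#' @export
tidy.nas_lda <- function(x, ...) {
  tibble::tibble(topic = rep(seq_len(x$K), times = x$C),
                 word = rep(seq_len(x$C), each = x$K),
                 beta = as.vector(x$beta))
}

#' @rdname tidy.nas_lda
#' @method glance nas_lda
#' @export
glance.nas_lda <- function(x, ...) {
  tibble::tibble(K = x$K, C = x$C, n_iter = length(x$elbo),
                 elbo = x$elbo[length(x$elbo)])
}

#' Tidy a protocol run
#'
#' @param x A [run_protocol()] result.
#' @param ... Unused.
#' @return Per-fold accuracy tibble.
#' @method tidy nas_protocol
#' @export
tidy.nas_protocol <- function(x, ...) x$folds

#' @rdname tidy.nas_protocol
#' @method glance nas_protocol
#' @export
glance.nas_protocol <- function(x, ...) {
  tidyr::pivot_wider(x$results,
                     names_from = c("classifier", "condition"),
                     values_from = "accuracy")
}
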