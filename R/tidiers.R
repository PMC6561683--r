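#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the length-model coefficients
#'
#' @param x A `kferq_length_fit` object from [fit_length_model()].
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic` and
#'   `p.value` for the intercept and slope.
#' @method tidy kferq_length_fit
#' @export
tidy.kferq_length_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(term = rownames(cf), estimate = cf[, 1], std.error = cf[, 2],
         statistic = cf[, 3], p.value = cf[, 4])
}

#' One-row summary of the length-model fit
#'
#' @inheritParams tidy.kferq_length_fit
#' @return A tibble with `r.squared`, `adj.r.squared`, `sigma`, `slope`,
#'   `intercept`, `n` (proteins in the final fit) and `n_removed` (Cook's
#'   distance outliers).
#' @method glance kferq_length_fit
#' @export
glance.kferq_length_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  # a response with zero variance has no explainable variation: R^2 = 0
  r2 <- if (stats::var(x$fit$model$log2_count) == 0) 0
        else if (is.finite(s$r.squared)) s$r.squared else 0
  tibble(r.squared = r2, adj.r.squared = s$adj.r.squared,
         sigma = s$sigma,
         slope = stats::coef(x$fit)[["length"]],
         intercept = stats::coef(x$fit)[["(Intercept)"]],
         n = nrow(x$data), n_removed = x$n_removed)
}
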