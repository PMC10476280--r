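#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Kaplan-Meier fit
#'
#' @param x A `km_fit` from [km_estimate()].
#' @param ... Unused.
#' @return Tibble with one row per distinct event/censor time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `estimate`, `conf.low`, `conf.high`.
#' @export
tidy.km_fit <- function(x, ...) {
  dplyr::rename(x$curve, estimate = "surv", conf.low = "lower",
                conf.high = "upper")
}

#' @rdname tidy.km_fit
#' @return `glance()` returns a one-row tibble: `n`, `n_censored`,
#'   `median_s`, `events`.
#' @export
glance.km_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_censored = x$n_censored,
                 median_s = x$median_s, events = sum(x$curve$n_event))
}

#' Tidy a rate estimate
#' @param x A `rate_estimate` tibble.
#' @param ... Unused.
#' @export
tidy.rate_estimate <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.rate_estimate
#' @export
glance.rate_estimate <- function(x, ...) {
  tibble::tibble(pool = x$pool, k_per_h = x$k_per_h, se_k = x$se_k,
                 n_off = x$n_off)
}
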