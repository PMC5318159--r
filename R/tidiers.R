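#' @exportS3Method generics::tidy
tidy.spearman_boot <- function(x, ...) {
  tibble(estimate = x$rho, conf.low = x$conf_low, conf.high = x$conf_high,
         method = "spearman (bootstrap percentile CI)")
}

#' @exportS3Method generics::glance
glance.spearman_boot <- function(x, ...) {
  tibble(n = x$n, reps = x$reps, conf = x$conf)
}

#' @exportS3Method generics::tidy
tidy.te_stepwise <- function(x, ...) {
  x$steps
}

#' @exportS3Method generics::glance
glance.te_stepwise <- function(x, ...) {
  tibble(r_squared = tail(x$steps$r_squared, 1),
         n = x$n, n_features = nrow(x$steps))
}

#' @exportS3Method generics::tidy
tidy.roc_reference <- function(x, ...) {
  x$curve
}

#' @exportS3Method generics::glance
glance.roc_reference <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @exportS3Method generics::tidy
tidy.gini_result <- function(x, ...) {
  x$lorenz
}

#' @exportS3Method generics::glance
glance.gini_result <- function(x, ...) {
  tibble(id = x$id, gini = x$gini, n_positions = x$n_positions)
}
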