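#' Spearman correlation with bootstrap confidence interval
#'
#' Case-resampling bootstrap of Spearman's rank correlation (average ranks
#' for ties, which are frequent in count data), with a percentile confidence
#' interval.
#'
#' @param x,y Paired numeric vectors, n >= 5.
#' @param reps Bootstrap replicates.
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return Object of class `spearman_boot`: `rho`, `conf_low`, `conf_high`,
#'   `boot` (replicate rhos), `n`, `conf`.
#' @export
spearman_bootstrap <- function(x, y, reps = 1000L, seed = 1, conf = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 5L) abort("need at least 5 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("constant vector: rho undefined")
  rho <- cor(x, y, method = "spearman")
  boot <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      i <- sample.int(n, n, replace = TRUE)
      suppressWarnings(cor(x[i], y[i], method = "spearman"))
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- quantile(boot, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
  structure(
    list(rho = rho, conf_low = ci[1], conf_high = ci[2], boot = boot,
         n = n, conf = conf, reps = reps),
    class = "spearman_boot"
  )
}

#' @export
print.spearman_boot <- function(x, ...) {
  cat("<spearman_boot> rho = ", format(x$rho, digits = 3), " [",
      format(x$conf_low, digits = 3), ", ", format(x$conf_high, digits = 3),
      "] (", x$conf * 100, "% CI, n = ", x$n, ", ", x$reps,
      " replicates)\n", sep = "")
  invisible(x)
}

#' Compare two bootstrap correlation distributions
#'
#' Two-sample Kolmogorov-Smirnov test between the bootstrap distributions of
#' two correlation coefficients.
#'
#' @param boot1,boot2 Numeric vectors of bootstrap replicates (or
#'   `spearman_boot` objects).
#' @return Tibble: `statistic` (D), `p_value`.
#' @export
ks_compare_rho <- function(boot1, boot2) {
  b1 <- if (inherits(boot1, "spearman_boot")) boot1$boot else boot1
  b2 <- if (inherits(boot2, "spearman_boot")) boot2$boot else boot2
  if (!length(b1) || !length(b2)) abort("empty bootstrap distribution")
  ks <- suppressWarnings(ks.test(b1, b2))
  tibble(statistic = unname(ks$statistic), p_value = ks$p.value)
}

#' ROC benchmark of reactivity against a reference structure
#'
#' Evaluates unpaired-base calls against a reference secondary structure with
#' accessibility labels. Only A/C bases are tested; positives are bases both
#' unpaired in the reference and solvent-accessible, negatives are paired
#' bases, and everything else (e.g. unpaired but buried) is excluded.
#' Accuracy at a threshold is (true positives + true negatives) / tested,
#' with "unpaired" predicted when the signal exceeds the threshold.
#'
#' @param values Normalized reactivities of the tested bases.
#' @param paired Logical, reference paired status per base.
#' @param accessible Logical, solvent accessibility per base.
#' @param bases Optional base identities; non-A/C bases are dropped.
#' @return Object of class `roc_reference`: `curve` (tibble `threshold`,
#'   `tpr`, `fpr`, `accuracy`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_reference <- function(values, paired, accessible, bases = NULL) {
  if (!is.null(bases)) {
    keep <- toupper(bases) %in% c("A", "C")
    values <- values[keep]
    paired <- paired[keep]
    accessible <- accessible[keep]
  }
  pos <- !paired & accessible
  neg <- paired
  tested <- pos | neg
  values <- values[tested]
  label <- pos[tested]
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0 || n_neg == 0) {
    abort("single-class reference: AUC undefined")
  }
  # AUC by the rank-sum (probability of correct ordering) formula
  r <- rank(values)
  auc <- (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thresholds <- sort(unique(c(0, values, 1)))
  curve <- purrr::map(thresholds, function(t) {
    pred <- values > t
    tibble(
      threshold = t,
      tpr = sum(pred & label) / n_pos,
      fpr = sum(pred & !label) / n_neg,
      accuracy = (sum(pred & label) + sum(!pred & !label)) / (n_pos + n_neg)
    )
  })
  structure(
    list(curve = bind_rows(curve), auc = auc, n_pos = n_pos, n_neg = n_neg),
    class = "roc_reference"
  )
}

#' @export
print.roc_reference <- function(x, ...) {
  cat("<roc_reference> AUC = ", format(x$auc, digits = 4), " (",
      x$n_pos, " positives, ", x$n_neg, " negatives)\n", sep = "")
  invisible(x)
}

#' Accuracy of unpaired calls at one threshold
#'
#' @param roc A [roc_reference()] object.
#' @param threshold Signal threshold (default 0.2).
#' @return Accuracy value.
#' @export
roc_accuracy <- function(roc, threshold = 0.2) {
  cv <- roc$curve
  i <- max(which(cv$threshold <= threshold))
  cv$accuracy[i]
}

#' Stepwise linear regression of log TE on mRNA features
#'
#' Adds features in the given order to a least-squares model of log TE,
#' reporting each step's R-squared and the nested-model ANOVA F-test for the
#' addition, with the usual significance codes. Zero-variance features are
#' rejected with a warning; near-collinear designs raise a condition-number
#' warning.
#'
#' @param data Data frame of complete cases.
#' @param response Name of the TE column (log is taken internally).
#' @param features Character vector of feature column names, in addition
#'   order.
#' @param log_response Take log of the response (default TRUE; TE spans
#'   orders of magnitude).
#' @return Object of class `te_stepwise`: `steps` tibble (`feature`,
#'   `r_squared`, `f_statistic`, `p_value`, `signif`), `fits` (list of lm
#'   objects), `n`.
#' @export
stepwise_te_regression <- function(data, response = "te", features,
                                   log_response = TRUE) {
  df <- as.data.frame(data)[, c(response, features)]
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 10 * length(features)) {
    abort("need at least 10 complete cases per feature")
  }
  keep <- vapply(features, function(f) sd(df[[f]]) > 0, logical(1))
  if (any(!keep)) {
    warn(paste0("zero-variance feature(s) rejected: ",
                paste(features[!keep], collapse = ", ")))
    features <- features[keep]
  }
  y <- if (log_response) log(df[[response]]) else df[[response]]
  df$.y <- y
  X <- as.matrix(df[, features, drop = FALSE])
  if (length(features) > 1 && kappa(cor(X)) > 1e6) {
    warn("near-collinear features: condition number > 1e6")
  }
  fits <- list()
  steps <- list()
  prev <- lm(.y ~ 1, data = df)
  for (k in seq_along(features)) {
    fml <- stats::reformulate(features[seq_len(k)], response = ".y")
    fit <- lm(fml, data = df)
    a <- anova(prev, fit)
    p <- a$`Pr(>F)`[2]
    steps[[k]] <- tibble(
      feature = features[k],
      r_squared = summary(fit)$r.squared,
      f_statistic = a$F[2],
      p_value = p,
      signif = signif_code(p)
    )
    fits[[k]] <- fit
    prev <- fit
  }
  structure(
    list(steps = bind_rows(steps), fits = fits, n = nrow(df),
         response = response),
    class = "te_stepwise"
  )
}

signif_code <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' @export
print.te_stepwise <- function(x, ...) {
  cat("<te_stepwise> n =", x$n, "\n")
  print(as.data.frame(x$steps))
  invisible(x)
}

#' Bonferroni outlier test on a scatter relationship
#'
#' Externally studentized residuals from the least-squares regression of `y`
#' on `x`; each point's two-sided p-value is Bonferroni-adjusted by the
#' cohort size. Flags points (e.g. a gene whose structure changed in a
#' mutant) that fall off the cohort trend.
#'
#' @param x,y Paired numeric vectors (n >= 10).
#' @param ids Point identifiers.
#' @param candidate Optional id; its row is returned first and its absence is
#'   an error.
#' @return Tibble sorted by adjusted p: `id`, `residual` (studentized),
#'   `p_value`, `p_bonferroni`.
#' @export
outlier_test <- function(x, y, ids = seq_along(x), candidate = NULL) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  ids <- ids[keep]
  n <- length(x)
  if (n < 10L) abort("need at least 10 points")
  if (!is.null(candidate) && !candidate %in% ids) {
    abort("candidate not among ids")
  }
  fit <- lm(y ~ x)
  rs <- stats::rstudent(fit)
  p <- 2 * pt(-abs(rs), df = n - 3)
  out <- tibble(
    id = ids,
    residual = unname(rs),
    p_value = unname(p),
    p_bonferroni = pmin(1, unname(p) * n)
  )
  out <- arrange(out, .data$p_bonferroni)
  if (!is.null(candidate)) {
    out <- bind_rows(out[out$id == candidate, ], out[out$id != candidate, ])
  }
  out
}
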