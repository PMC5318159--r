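#' Gini index of a signal vector
#'
#' Inequality of per-base chemical reactivity over a region, used here as a
#' structure score: DMS reactivity concentrated on a few A/C bases (high Gini)
#' indicates a well-structured region, while evenly spread reactivity (low
#' Gini) indicates an unstructured one.
#'
#' Computed from the ascending-sorted values as
#' \eqn{G = 2 \sum_i i x_{(i)} / (n \sum_i x_i) - (n+1)/n}, which equals both
#' the normalized area between the trapezoidal Lorenz curve and the diagonal,
#' and the mean-absolute-difference form
#' \eqn{\sum_{ij} |x_i - x_j| / (2 n^2 \mu)}.
#'
#' @param values Non-negative numeric vector (at least 2 values).
#' @return A single number in `[0, (n-1)/n]`, or `NA_real_` when all values
#'   are zero (inequality is undefined for an empty distribution).
#' @seealso [gini_result()] for the Lorenz-curve object, [windowed_gini()].
#' @export
#' @examples
#' gini(c(1, 1, 1, 1)) # 0: perfect equality
#' gini(c(0, 0, 0, 1)) # 0.75: all signal on one base
gini <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) abort("gini() needs at least 2 non-missing values")
  if (any(values < 0)) abort("gini() requires non-negative values")
  s <- sum(values)
  if (s == 0) return(NA_real_)
  x <- sort(values)
  2 * sum(seq_len(n) * x) / (n * s) - (n + 1) / n
}

#' Gini index with its Lorenz curve
#'
#' Returns the Gini index of a region together with the Lorenz-curve points
#' it is computed from, so the ratio of areas a/(a+b) (area between the
#' diagonal and the curve over the area below the diagonal) can be inspected
#' or plotted.
#'
#' @param values Non-negative numeric vector.
#' @param id Optional region identifier carried through to output.
#' @return An object of class `gini_result` with elements `id`, `gini`,
#'   `n_positions` and `lorenz` (a tibble with columns `p` and `L`, the
#'   cumulative position and signal fractions).
#' @export
gini_result <- function(values, id = NA_character_) {
  values <- values[!is.na(values)]
  g <- gini(values)
  n <- length(values)
  x <- sort(values)
  s <- sum(x)
  lor <- tibble(
    p = seq(0, 1, length.out = n + 1L),
    L = if (s > 0) c(0, cumsum(x) / s) else rep(NA_real_, n + 1L)
  )
  structure(
    list(id = id, gini = g, n_positions = n, lorenz = lor),
    class = "gini_result"
  )
}

#' @export
print.gini_result <- function(x, ...) {
  cat("<gini_result>", if (!is.na(x$id)) x$id else "", "\n")
  cat("  gini:", format(x$gini, digits = 4), " n_positions:", x$n_positions, "\n")
  invisible(x)
}

#' Gini indices of the two halves of an ORF
#'
#' Splits a per-base reactivity/count profile at `floor(L/2)` nucleotides
#' (transcript coordinates) and scores each half over its A/C positions.
#' Consistent per-ORF structure shows up as strongly correlated half scores
#' across a cohort.
#'
#' @param values Per-base numeric vector over the ORF, 5' to 3'.
#' @param bases Per-base nucleotide identities (characters "A","C","G","T"/"U").
#' @param min_positions Minimum A/C positions required per half.
#' @return A tibble with one row: `gini_first`, `gini_second`, `n_first`,
#'   `n_second` and a logical `flagged` set when a half has too few A/C bases
#'   or no signal.
#' @export
orf_half_ginis <- function(values, bases, min_positions = 2L) {
  stopifnot(length(values) == length(bases))
  L <- length(values)
  half <- floor(L / 2)
  idx1 <- seq_len(half)
  idx2 <- seq.int(half + 1L, L)
  ac1 <- idx1[bases[idx1] %in% c("A", "C")]
  ac2 <- idx2[bases[idx2] %in% c("A", "C")]
  g1 <- if (length(ac1) >= min_positions) gini(values[ac1]) else NA_real_
  g2 <- if (length(ac2) >= min_positions) gini(values[ac2]) else NA_real_
  tibble(
    gini_first = g1, gini_second = g2,
    n_first = length(ac1), n_second = length(ac2),
    flagged = is.na(g1) || is.na(g2)
  )
}

#' Rolling-window Gini scan
#'
#' Gini indices within fixed-width windows scanning a region, reported at the
#' window center. Windows truncated at the region ends are dropped rather than
#' shrunk, so every reported value is computed from the same number of
#' nucleotides. When `bases` is supplied only A/C positions are scored.
#'
#' @param values Per-base numeric vector.
#' @param window Window width in nt (e.g. 80, 100 or 300).
#' @param step Step between window starts in nt.
#' @param bases Optional per-base nucleotide identities for A/C-only scoring.
#' @param offset0 Coordinate of the first element of `values`; window centers
#'   are reported on this scale (use a negative value to center a scan on an
#'   ORF boundary).
#' @return Tibble with columns `center`, `gini`, `n_positions`.
#' @export
windowed_gini <- function(values, window, step = 1L, bases = NULL, offset0 = 0L) {
  L <- length(values)
  if (window > L) abort("window is larger than the region")
  if (window < 2L) abort("window must span at least 2 nt")
  starts <- seq.int(1L, L - window + 1L, by = step)
  res <- purrr::map(starts, function(s) {
    idx <- s:(s + window - 1L)
    if (!is.null(bases)) idx <- idx[bases[idx] %in% c("A", "C")]
    g <- if (length(idx) >= 2L) gini(values[idx]) else NA_real_
    tibble(
      center = offset0 + s - 1L + window / 2,
      gini = g,
      n_positions = length(idx)
    )
  })
  bind_rows(res)
}

#' Translation-dependent Gini difference
#'
#' Normalized difference between the structure score of untranslated mRNA and
#' the same ORF's score under active translation:
#' `(g_untranslated - g_translated) / mean(g_untranslated, g_translated)`.
#' Positive values indicate more structure once ribosomes are removed.
#'
#' @param g_untranslated,g_translated Gini indices of the same region.
#' @return Normalized difference; `NA` when both inputs are zero or missing.
#' @export
delta_gini <- function(g_untranslated, g_translated) {
  out <- (g_untranslated - g_translated) / ((g_untranslated + g_translated) / 2)
  out[(g_untranslated + g_translated) == 0] <- NA_real_
  out
}

#' Per-ORF Gini table from a DMS-seq track
#'
#' Scores every ORF of an annotation: mean raw coverage, whole-ORF Gini over
#' A/C positions, and first/second-half Ginis. Raw counts are used directly;
#' the Gini index is invariant to the positive rescaling that reactivity
#' normalization applies.
#'
#' @param track A [count_track()] of DMS-seq counts.
#' @param annotation A [genome_annotation()].
#' @param min_mean Coverage filter threshold in mean raw reads/nt (ORFs below
#'   it are kept in the table but flagged `included = FALSE`).
#' @return Tibble with one row per ORF: `orf_id`, `operon_id`, `coverage`,
#'   `included`, `gini`, `gini_first`, `gini_second`, `n_ac`.
#' @export
orf_gini_table <- function(track, annotation, min_mean = 15) {
  orfs <- annotation$orfs
  rows <- purrr::map(seq_len(nrow(orfs)), function(i) {
    orf <- orfs[i, ]
    prof <- orf_profile(track, orf)
    bases <- strsplit(orf_seq(annotation, orf$orf_id), "")[[1]]
    ac <- bases %in% c("A", "C")
    halves <- orf_half_ginis(prof, bases)
    tibble(
      orf_id = orf$orf_id,
      operon_id = orf$operon_id,
      coverage = mean(prof),
      included = mean(prof) >= min_mean,
      gini = if (sum(ac) >= 2L) gini(prof[ac]) else NA_real_,
      gini_first = halves$gini_first,
      gini_second = halves$gini_second,
      n_ac = sum(ac)
    )
  })
  bind_rows(rows)
}
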