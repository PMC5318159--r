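#' Normalize raw DMS-seq counts to reactivities in [0, 1]
#'
#' Values above the region's 95th percentile are capped at that percentile
#' (95% Winsorization), then everything is divided by the resulting maximum,
#' so the most highly reactive residue after outlier removal scores 1.
#' Quantiles use linear interpolation between order statistics (R type 7);
#' the percentile definition matters at small n, so it is fixed and
#' documented here. An all-zero region returns an all-zero profile.
#'
#' @param counts Per-base raw counts over a region (transcript orientation).
#' @param bases Per-base nucleotide identities ("A","C","G","T"/"U").
#' @param winsor_q Winsorization quantile (default 0.95).
#' @return A tibble of class `reactivity_profile` with columns `offset`
#'   (1-based position in the region), `base`, `value` (normalized
#'   reactivity) and `unpaired` (all `NA` until [call_unpaired()] is applied);
#'   attribute `coverage` holds the mean raw count.
#' @export
normalize_reactivity <- function(counts, bases, winsor_q = 0.95) {
  stopifnot(length(counts) == length(bases))
  if (!length(counts)) abort("empty region")
  if (any(counts < 0)) abort("counts must be non-negative")
  cap <- quantile(counts, winsor_q, names = FALSE, type = 7)
  v <- pmin(counts, cap)
  m <- max(v)
  if (m > 0) v <- v / m
  out <- tibble(
    offset = seq_along(counts),
    base = toupper(chartr("T", "U", bases)),
    value = v,
    unpaired = NA
  )
  attr(out, "coverage") <- mean(counts)
  class(out) <- c("reactivity_profile", class(out))
  out
}

#' Call unpaired bases from normalized reactivity
#'
#' A and C bases with reactivity strictly greater than `threshold` (fraction
#' of the most reactive residue) are called unpaired; G and U bases carry no
#' call because DMS only reports on adenine and cytosine.
#'
#' @param profile A [normalize_reactivity()] profile.
#' @param threshold Call threshold in (0, 1); default 0.2.
#' @return The profile with its `unpaired` column filled: logical at A/C
#'   positions, `NA` elsewhere.
#' @export
call_unpaired <- function(profile, threshold = 0.2) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  ac <- profile$base %in% c("A", "C")
  profile$unpaired <- ifelse(ac, profile$value > threshold, NA)
  profile
}

#' Coverage filter for structure analysis
#'
#' ORFs qualify when their mean raw DMS-seq reads per nucleotide across the
#' whole ORF is at least `min_mean` (inclusive).
#'
#' @param track A [count_track()] of raw DMS-seq counts.
#' @param annotation A [genome_annotation()].
#' @param min_mean Minimum mean reads/nt (default 15).
#' @return Character vector of qualifying `orf_id`s.
#' @export
coverage_filter <- function(track, annotation, min_mean = 15) {
  orfs <- annotation$orfs
  cov <- vapply(seq_len(nrow(orfs)), function(i) {
    mean(orf_profile(track, orfs[i, ]))
  }, numeric(1))
  orfs$orf_id[cov >= min_mean]
}

#' Replicate reproducibility as a function of coverage cutoff
#'
#' For each coverage cutoff, computes the Pearson correlation of two
#' replicates' raw DMS-seq signal over the first `region_len` nt of every
#' qualifying ORF (ORFs shorter than `region_len` use their full length), and
#' reports the median correlation. ORFs must pass the cutoff in both
#' replicates.
#'
#' @param rep1,rep2 Two [count_track()]s of the same sample type.
#' @param annotation A [genome_annotation()].
#' @param cutoffs Numeric vector of mean reads/nt cutoffs.
#' @param region_len Length of the 5' region compared (default 200 nt).
#' @return Tibble: `cutoff`, `median_r`, `n_orfs`. Cutoffs with no
#'   qualifying ORFs give `NA` medians.
#' @export
reproducibility_curve <- function(rep1, rep2, annotation, cutoffs,
                                  region_len = 200L) {
  orfs <- annotation$orfs
  prof <- purrr::map(seq_len(nrow(orfs)), function(i) {
    p1 <- orf_profile(rep1, orfs[i, ])
    p2 <- orf_profile(rep2, orfs[i, ])
    k <- min(length(p1), region_len)
    list(cov1 = mean(p1), cov2 = mean(p2),
         r = suppressWarnings(cor(p1[seq_len(k)], p2[seq_len(k)])))
  })
  cov1 <- vapply(prof, `[[`, numeric(1), "cov1")
  cov2 <- vapply(prof, `[[`, numeric(1), "cov2")
  r <- vapply(prof, `[[`, numeric(1), "r")
  out <- purrr::map(cutoffs, function(ct) {
    keep <- cov1 >= ct & cov2 >= ct & !is.na(r)
    tibble(cutoff = ct,
           median_r = if (any(keep)) median(r[keep]) else NA_real_,
           n_orfs = sum(keep))
  })
  bind_rows(out)
}
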