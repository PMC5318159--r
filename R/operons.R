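#' Calibrate the mRNA level-equivalence cutoff
#'
#' Most ORFs sit on a single transcript, so the log2 ratio of mean mRNA-seq
#' density between the first and second half of an ORF measures pure
#' within-message variability. The cutoff for calling two adjacent ORFs
#' "equal level" is two standard deviations of that distribution, reported
#' both on the log2 scale and as a fold change.
#'
#' @param track mRNA-seq [count_track()].
#' @param annotation A [genome_annotation()].
#' @param min_mean Minimum mean reads/nt for an ORF to enter the calibration.
#' @return List: `sigma_log2`, `cutoff_log2` (= 2 sigma), `cutoff_fold`,
#'   `n_orfs`.
#' @export
calibrate_level_cutoff <- function(track, annotation, min_mean = 5) {
  orfs <- annotation$orfs
  ratios <- c()
  for (i in seq_len(nrow(orfs))) {
    prof <- orf_profile(track, orfs[i, ])
    if (mean(prof) < min_mean) next
    half <- floor(length(prof) / 2)
    m1 <- mean(prof[seq_len(half)])
    m2 <- mean(prof[(half + 1L):length(prof)])
    if (m1 <= 0 || m2 <= 0) next
    ratios <- c(ratios, log2(m1 / m2))
  }
  if (length(ratios) < 30L) abort("fewer than 30 ORFs with coverage")
  sigma <- sd(ratios)
  list(sigma_log2 = sigma, cutoff_log2 = 2 * sigma,
       cutoff_fold = 2^(2 * sigma), n_orfs = length(ratios))
}

#' Calibrate the mRNA continuity cutoff
#'
#' Gini indices of mRNA-seq signal in fixed windows tiling ORF bodies measure
#' within-message signal roughness; the continuity cutoff is the mean plus
#' two standard deviations of that distribution. Intergenic windows rougher
#' than this indicate a transcript boundary.
#'
#' @param track mRNA-seq [count_track()].
#' @param annotation A [genome_annotation()].
#' @param window Window width in nt.
#' @param step Step between window starts (half-overlap by default).
#' @param min_mean Minimum ORF mean coverage to enter the calibration.
#' @return List: `mean_gini`, `sd_gini`, `cutoff` (= mean + 2 sd),
#'   `n_windows`.
#' @export
calibrate_continuity_cutoff <- function(track, annotation, window = 80L,
                                        step = 40L, min_mean = 5) {
  orfs <- annotation$orfs
  ginis <- c()
  any_fit <- FALSE
  for (i in seq_len(nrow(orfs))) {
    orf <- orfs[i, ]
    if (orf$end - orf$start < window) next
    any_fit <- TRUE
    prof <- orf_profile(track, orf)
    if (mean(prof) < min_mean) next
    wg <- windowed_gini(prof, window = window, step = step)
    ginis <- c(ginis, wg$gini[!is.na(wg$gini)])
  }
  if (!any_fit) abort("window larger than every ORF")
  if (length(ginis) < 30L) abort("fewer than 30 calibration windows")
  list(mean_gini = mean(ginis), sd_gini = sd(ginis),
       cutoff = mean(ginis) + 2 * sd(ginis), n_windows = length(ginis))
}

junction_windows <- function(up, down, strand, window, step) {
  # genome-coordinate starts of continuity windows over the junction
  if (strand == "+") {
    gap_lo <- up$end
    gap_hi <- down$start
  } else {
    gap_lo <- down$end
    gap_hi <- up$start
  }
  gap <- gap_hi - gap_lo
  # only windows fully inside the intergenic region are tested; pairs closer
  # than one window (including overlapping pairs) rely on the level criterion
  if (gap < window) return(integer(0))
  # union of forward and backward tilings keeps the window set symmetric
  # under genome reverse-complementation
  unique(c(seq.int(gap_lo, gap_hi - window, by = step),
           rev(seq.int(gap_hi - window, gap_lo, by = -step))))
}

#' Identify adjacent ORF pairs on the same message
#'
#' A pair of adjacent ORFs within an operon is accepted as residing on a
#' single mRNA when (1) their mean mRNA-seq levels differ by at most the
#' calibrated 2-sigma fold change, and (2) no continuity window spanning the
#' junction has a Gini index above the calibrated cutoff. Intergenic gaps
#' shorter than the window are tested with a single window centered on the
#' junction; overlapping pairs have no gap to test and rely on the level
#' criterion alone.
#'
#' @param track mRNA-seq [count_track()].
#' @param annotation A [genome_annotation()].
#' @param level_cutoff Output of [calibrate_level_cutoff()] (or `NULL` to
#'   calibrate from `track`).
#' @param continuity_cutoff Output of [calibrate_continuity_cutoff()] (or
#'   `NULL`).
#' @param window,step Continuity window geometry, nt.
#' @return The [adjacent_pairs()] table with `level_log2_ratio`,
#'   `max_window_gini`, `level_ok`, `continuity_ok` and `same_message`
#'   columns.
#' @export
same_message_pairs <- function(track, annotation, level_cutoff = NULL,
                               continuity_cutoff = NULL, window = 80L,
                               step = 40L) {
  if (is.null(level_cutoff)) {
    level_cutoff <- calibrate_level_cutoff(track, annotation)
  }
  if (is.null(continuity_cutoff)) {
    continuity_cutoff <- calibrate_continuity_cutoff(track, annotation,
                                                     window, step)
  }
  pairs <- adjacent_pairs(annotation)
  orfs <- annotation$orfs
  n <- nrow(pairs)
  lev <- rep(NA_real_, n)
  wg <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    up <- orfs[orfs$orf_id == pairs$upstream_id[k], ]
    down <- orfs[orfs$orf_id == pairs$downstream_id[k], ]
    m_up <- mean(orf_profile(track, up))
    m_down <- mean(orf_profile(track, down))
    lev[k] <- if (m_up > 0 && m_down > 0) log2(m_down / m_up) else Inf
    starts <- junction_windows(up, down, pairs$strand[k], window, step)
    glen <- nchar(annotation$sequence[[pairs$replicon[k]]])
    starts <- pmax(0L, pmin(starts, glen - window))
    if (length(starts)) {
      g <- vapply(starts, function(s) {
        prof <- region_profile(track, pairs$replicon[k], s, s + window,
                               pairs$strand[k])
        gi <- gini(prof)
        if (is.na(gi)) 1 else gi # zero-coverage gap: maximal discontinuity
      }, numeric(1))
      wg[k] <- max(g)
    }
  }
  pairs$level_log2_ratio <- lev
  pairs$max_window_gini <- wg
  pairs$level_ok <- abs(lev) <= level_cutoff$cutoff_log2
  pairs$continuity_ok <- is.na(wg) | wg <= continuity_cutoff$cutoff
  pairs$same_message <- pairs$level_ok & pairs$continuity_ok
  attr(pairs, "level_cutoff") <- level_cutoff
  attr(pairs, "continuity_cutoff") <- continuity_cutoff
  pairs
}

#' Overlap classification and spacing distribution
#'
#' Classifies pairs as overlapping (spacing <= 0: the upstream stop codon
#' overlaps or is 3' of the downstream start) and attaches the empirical CDF
#' of spacings.
#'
#' @param pairs A pair table with a `spacing` column.
#' @return The table with `overlap_class` (re)computed; attribute
#'   `spacing_cdf` holds a tibble (`spacing`, `cdf`).
#' @export
classify_overlap <- function(pairs) {
  pairs$overlap_class <- ifelse(pairs$spacing <= 0, "overlapping",
                                "non_overlapping")
  sp <- sort(unique(pairs$spacing))
  f <- ecdf(pairs$spacing)
  attr(pairs, "spacing_cdf") <- tibble(spacing = sp, cdf = f(sp))
  pairs
}

#' Flag genes with discontinuous mRNA-seq coverage
#'
#' Genes whose whole-gene mRNA-seq Gini index exceeds the cohort mean by more
#' than two standard deviations show an internal coverage break (early
#' termination or an internal promoter) and are excluded from structure
#' analyses.
#'
#' @param track mRNA-seq [count_track()].
#' @param annotation A [genome_annotation()].
#' @param min_mean Minimum mean coverage for a gene to be evaluated.
#' @return Tibble: `orf_id`, `mrna_gini`, `flagged`.
#' @export
flag_discontinuous_genes <- function(track, annotation, min_mean = 5) {
  orfs <- annotation$orfs
  g <- vapply(seq_len(nrow(orfs)), function(i) {
    prof <- orf_profile(track, orfs[i, ])
    if (mean(prof) < min_mean) return(NA_real_)
    gini(prof)
  }, numeric(1))
  mu <- mean(g, na.rm = TRUE)
  sdev <- sd(g, na.rm = TRUE)
  tibble(
    orf_id = orfs$orf_id,
    mrna_gini = g,
    flagged = !is.na(g) & g > mu + 2 * sdev
  )
}
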