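#' Genomic window around a downstream ORF start, in transcript orientation
#'
#' @param annotation A [genome_annotation()].
#' @param down_orf Row of the ORF table for the downstream gene of a pair.
#' @param flank Half-width in nt; the window covers transcript offsets
#'   `-flank .. flank-1` with offset 0 at the first nucleotide of the start
#'   codon.
#' @return List with `replicon`, `start`, `end` (genome, 0-based half-open),
#'   `strand`, or `NULL` when the context does not fit in the replicon.
#' @export
boundary_window <- function(annotation, down_orf, flank = 250L) {
  L <- nchar(annotation$sequence[[down_orf$replicon]])
  if (down_orf$strand == "+") {
    s <- down_orf$start - flank
    e <- down_orf$start + flank
  } else {
    s <- down_orf$end - flank
    e <- down_orf$end + flank
  }
  if (s < 0 || e > L) return(NULL)
  list(replicon = down_orf$replicon, start = s, end = e,
       strand = down_orf$strand)
}

#' Fold the boundary regions of adjacent ORF pairs
#'
#' For each pair, extracts the sequence from -flank to +flank around the
#' downstream start codon, optionally derives unpaired constraints from a
#' DMS-seq track (window-normalized reactivity, unpaired call at `threshold`),
#' and computes the base-pairing probability matrix. The folding engine is
#' pluggable through `fold_fun`; the downstream statistics only consume the
#' returned matrices.
#'
#' @param annotation A [genome_annotation()].
#' @param pairs Pair table from [adjacent_pairs()] (or any tibble with
#'   `upstream_id`, `downstream_id`).
#' @param dms_track Optional [count_track()] of DMS-seq counts used to
#'   constrain folding; `NULL` folds unconstrained.
#' @param flank Half-width of the boundary window in nt.
#' @param beta Inverse temperature for [pair_probabilities()].
#' @param threshold Unpaired-call threshold on normalized reactivity.
#' @param fold_fun Function `(seq, unpaired) -> probability matrix`;
#'   defaults to the internal engine.
#' @return List with `probs` (named list of matrices) and `skipped`
#'   (character vector of pairs lacking context).
#' @export
boundary_pair_probs <- function(annotation, pairs, dms_track = NULL,
                                flank = 250L, beta = 2, threshold = 0.2,
                                fold_fun = NULL) {
  if (is.null(fold_fun)) {
    fold_fun <- function(seq, unpaired) {
      pair_probabilities(seq, unpaired, beta = beta)
    }
  }
  probs <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(pairs))) {
    pid <- paste0(pairs$upstream_id[i], "|", pairs$downstream_id[i])
    down <- annotation$orfs[annotation$orfs$orf_id == pairs$downstream_id[i], ]
    win <- boundary_window(annotation, down, flank)
    if (is.null(win)) {
      skipped <- c(skipped, pid)
      next
    }
    seq <- region_seq(annotation, win$replicon, win$start, win$end, win$strand)
    unp <- integer(0)
    if (!is.null(dms_track)) {
      counts <- region_profile(dms_track, win$replicon, win$start, win$end,
                               win$strand)
      prof <- normalize_reactivity(counts, strsplit(seq, "")[[1]])
      calls <- call_unpaired(prof, threshold)
      unp <- calls$offset[!is.na(calls$unpaired) & calls$unpaired]
    }
    probs[[pid]] <- fold_fun(seq, unp)
  }
  list(probs = probs, skipped = skipped, flank = flank)
}

#' Folding directionality across ORF boundaries
#'
#' For every position in the boundary window, sums its pairing probability
#' into the downstream `window` nt and into the upstream `window` nt, averages
#' each across pairs, and reports the downstream/upstream ratio per position.
#' A ratio above 1 means the position preferentially folds downstream (into
#' its own ORF when just past a start codon); below 1, upstream. Positions
#' without a full window on either side are not reported; positions where the
#' cross-pair mean of either sum is zero give `NA` ratios.
#'
#' @inheritParams boundary_pair_probs
#' @param window Width in nt of the upstream/downstream windows.
#' @param probs Optional precomputed result of [boundary_pair_probs()].
#' @return Tibble of class `directionality_profile`: `position` (offset from
#'   the downstream start codon), `down_mean`, `up_mean`, `ratio`, `n_pairs`.
#' @export
boundary_directionality <- function(annotation, pairs, dms_track = NULL,
                                    flank = 250L, window = 60L, beta = 2,
                                    threshold = 0.2, probs = NULL) {
  if (is.null(probs)) {
    probs <- boundary_pair_probs(annotation, pairs, dms_track, flank, beta,
                                 threshold)
  }
  flank <- probs$flank
  n <- 2L * flank
  idx <- (window + 1L):(n - window)
  down_sum <- matrix(0, length(idx), length(probs$probs))
  up_sum <- matrix(0, length(idx), length(probs$probs))
  for (k in seq_along(probs$probs)) {
    P <- probs$probs[[k]]
    for (m in seq_along(idx)) {
      i <- idx[m]
      down_sum[m, k] <- sum(P[i, (i + 1L):(i + window)])
      up_sum[m, k] <- sum(P[i, (i - window):(i - 1L)])
    }
  }
  dm <- rowMeans(down_sum)
  um <- rowMeans(up_sum)
  out <- tibble(
    position = idx - flank - 1L,
    down_mean = dm,
    up_mean = um,
    ratio = ifelse(dm > 0 & um > 0, dm / um, NA_real_),
    n_pairs = length(probs$probs)
  )
  class(out) <- c("directionality_profile", class(out))
  out
}

#' Metagene base-pairing probability across ORF boundaries
#'
#' Per-position total pairing probability (`sum_j P[i,j]`), averaged across
#' adjacent ORF pairs and aligned at the downstream start codon. Reproduces
#' the characteristic dip of structure over the first ~25 nt of ORFs when the
#' underlying structures leave start regions unpaired.
#'
#' @inheritParams boundary_directionality
#' @return Tibble: `position`, `mean_pairing`, `n_pairs`.
#' @export
metagene_pairing <- function(annotation, pairs, dms_track = NULL,
                             flank = 250L, beta = 2, threshold = 0.2,
                             probs = NULL) {
  if (is.null(probs)) {
    probs <- boundary_pair_probs(annotation, pairs, dms_track, flank, beta,
                                 threshold)
  }
  flank <- probs$flank
  if (!length(probs$probs)) {
    return(tibble(position = integer(0), mean_pairing = numeric(0),
                  n_pairs = integer(0)))
  }
  tot <- vapply(probs$probs, function(P) rowSums(P), numeric(2L * flank))
  tibble(
    position = seq_len(2L * flank) - flank - 1L,
    mean_pairing = rowMeans(tot),
    n_pairs = length(probs$probs)
  )
}
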