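winsorize <- function(x, lower = 0.05, upper = 0.95) {
  if (!length(x)) return(x)
  q <- quantile(x, c(lower, upper), names = FALSE, type = 7)
  pmin(pmax(x, q[1]), q[2])
}

#' Correction configuration for footprint densities and TE
#'
#' Bundles the filters and corrections applied when turning raw tracks into
#' translation efficiencies: edge-codon masking, the initiation ramp span,
#' optional anti-Shine-Dalgarno pause weights, central Winsorization, the
#' minimum footprint read count, and genes excluded for unconventional
#' translation (selenoproteins and near-identical paralog families).
#'
#' @param edge_codons Codons masked at each ORF end (translation
#'   initiation/termination effects).
#' @param ramp_codons Length of the elevated initiation ramp, in codons
#'   (densities over these codons are divided by the dataset-wide ramp ratio).
#' @param winsor Central fraction kept by Winsorization of footprint signal
#'   (0.90 caps the top and bottom 5%).
#' @param min_reads Minimum footprint reads mapped to a gene.
#' @param excluded_genes Gene ids excluded from TE analysis.
#' @param asd_weights Optional per-position weight vector (same layout as an
#'   ORF profile) dividing out aSD-site pausing; `NULL` disables.
#' @return A list of class `correction_config`.
#' @export
correction_config <- function(edge_codons = 5L, ramp_codons = 50L,
                              winsor = 0.90, min_reads = 128L,
                              excluded_genes = default_excluded_genes(),
                              asd_weights = NULL) {
  if (winsor <= 0 || winsor > 1) abort("winsor must be in (0, 1]")
  if (min_reads < 0) abort("min_reads must be >= 0")
  structure(
    list(edge_codons = as.integer(edge_codons),
         ramp_codons = as.integer(ramp_codons), winsor = winsor,
         min_reads = as.integer(min_reads), excluded_genes = excluded_genes,
         asd_weights = asd_weights),
    class = "correction_config"
  )
}

#' Genes excluded from TE analysis by default
#'
#' Selenoprotein genes and near-identical paralog pairs whose reads cannot be
#' uniquely assigned.
#'
#' @return Character vector of gene ids.
#' @export
default_excluded_genes <- function() {
  c("fdhF", "fdoG", "fdnG",
    "gadA", "gadB", "ynaE", "ydfK", "ldrA", "ldrC",
    "ybfD", "yhhI", "tfaR", "tfaQ", "rzoD", "rzoR", "pinR", "pinQ")
}

#' mRNA abundance (RPKM) of one ORF
#'
#' Per-base mRNA-seq counts are Winsorized at the 5th/95th percentiles within
#' the ORF (trimming coverage spikes), summed, and scaled to reads per
#' kilobase of message per million sequenced reads.
#'
#' @param profile Per-base mRNA-seq counts over the ORF.
#' @param library_size Total assigned reads of the mRNA-seq library.
#' @return RPKM value.
#' @export
mrna_rpkm <- function(profile, library_size) {
  L <- length(profile)
  if (L == 0L) abort("zero-length ORF")
  if (library_size <= 0) abort("library_size must be positive")
  sum(winsorize(profile)) * 1e9 / (L * library_size)
}

#' Dataset-wide initiation ramp ratio
#'
#' Ratio of mean footprint density over the ramp span (after edge masking) to
#' mean density over the plateau, averaged across genes with enough reads and
#' a long enough plateau. Dividing ramp positions by this ratio flattens the
#' elevated density of the first ~50 codons.
#'
#' @param ribo A center-weighted footprint [count_track()].
#' @param annotation A [genome_annotation()].
#' @param cfg A [correction_config()].
#' @return Scalar ratio (1 when no gene qualifies).
#' @export
estimate_ramp_ratio <- function(ribo, annotation, cfg = correction_config()) {
  orfs <- annotation$orfs
  ratios <- c()
  for (i in seq_len(nrow(orfs))) {
    orf <- orfs[i, ]
    prof <- orf_profile(ribo, orf)
    L <- length(prof)
    n_codons <- L %/% 3L
    if (n_codons < cfg$ramp_codons + cfg$edge_codons * 2L + 20L) next
    if (sum(prof) < cfg$min_reads) next
    ramp_idx <- (cfg$edge_codons * 3L + 1L):(cfg$ramp_codons * 3L)
    plateau_idx <- (cfg$ramp_codons * 3L + 1L):(L - cfg$edge_codons * 3L)
    pl <- mean(prof[plateau_idx])
    if (pl <= 0) next
    ratios <- c(ratios, mean(prof[ramp_idx]) / pl)
  }
  if (!length(ratios)) 1 else mean(ratios)
}

#' Corrected average ribosome footprint density of one ORF
#'
#' Applies, in order: masking of the first and last `edge_codons` codons,
#' division of the initiation-ramp span by the dataset-wide ramp ratio,
#' optional anti-Shine-Dalgarno per-position weights, and central
#' Winsorization (default 90%, capping the top and bottom 5% of the per-base
#' signal). Density is the corrected signal summed over the corrected length.
#'
#' @param profile Per-base footprint counts over the ORF (center-weighted),
#'   transcript orientation.
#' @param cfg A [correction_config()].
#' @param ramp_ratio Dataset-wide ramp ratio from [estimate_ramp_ratio()].
#' @return Corrected reads/nt, or `NA` when too few positions survive
#'   masking.
#' @export
footprint_density <- function(profile, cfg = correction_config(),
                              ramp_ratio = 1) {
  L <- length(profile)
  mask <- cfg$edge_codons * 3L
  if (L - 2L * mask < 30L) return(NA_real_)
  idx <- (mask + 1L):(L - mask)
  v <- profile
  ramp_nt <- min(L, cfg$ramp_codons * 3L)
  if (ramp_nt >= 1L && ramp_ratio > 0) {
    v[seq_len(ramp_nt)] <- v[seq_len(ramp_nt)] / ramp_ratio
  }
  if (!is.null(cfg$asd_weights)) {
    w <- rep(cfg$asd_weights, length.out = L)
    v <- v / w
  }
  x <- v[idx]
  tail_q <- (1 - cfg$winsor) / 2
  x <- winsorize(x, tail_q, 1 - tail_q)
  mean(x)
}

#' Per-ORF expression table: RPKM, footprint density, TE
#'
#' Computes mRNA abundance, corrected ribosome footprint density and their
#' ratio (translation efficiency) for every ORF, with QC flags: genes with
#' fewer than `min_reads` raw footprint reads, excluded genes, genes flagged
#' discontinuous, or missing mRNA signal carry flags instead of TEs.
#'
#' @param ribo,mrna Footprint and mRNA-seq [count_track()]s.
#' @param annotation A [genome_annotation()].
#' @param cfg A [correction_config()].
#' @param discontinuous Character vector of ORF ids flagged by
#'   [flag_discontinuous_genes()].
#' @return Tibble: `orf_id`, `operon_id`, `length`, `raw_reads`, `rpkm`,
#'   `density`, `te`, `low_reads`, `excluded_gene`, `discontinuous`,
#'   `no_mrna`.
#' @export
expression_table <- function(ribo, mrna, annotation,
                             cfg = correction_config(),
                             discontinuous = character(0)) {
  orfs <- annotation$orfs
  ramp_ratio <- estimate_ramp_ratio(ribo, annotation, cfg)
  rows <- purrr::map(seq_len(nrow(orfs)), function(i) {
    orf <- orfs[i, ]
    rprof <- orf_profile(ribo, orf)
    mprof <- orf_profile(mrna, orf)
    tibble(
      orf_id = orf$orf_id,
      operon_id = orf$operon_id,
      length = orf$end - orf$start,
      raw_reads = sum(rprof),
      rpkm = mrna_rpkm(mprof, mrna$total_assigned),
      density = footprint_density(rprof, cfg, ramp_ratio)
    )
  })
  tbl <- bind_rows(rows)
  tbl$density_rpm <- tbl$density * 1e6 / ribo$total_assigned
  tbl$low_reads <- tbl$raw_reads < cfg$min_reads
  tbl$excluded_gene <- tbl$orf_id %in% cfg$excluded_genes
  tbl$discontinuous <- tbl$orf_id %in% discontinuous
  tbl$no_mrna <- !(tbl$rpkm > 0)
  attr(tbl, "ramp_ratio") <- ramp_ratio
  translation_efficiency(tbl)
}

#' Translation efficiency from density and RPKM
#'
#' TE is the corrected footprint density normalized by mRNA abundance. The
#' density is first put on a per-million-footprint-reads scale (column
#' `density_rpm`), so TE does not change when both libraries are sequenced
#' deeper or when library sizes are rescaled jointly. Defined only for rows
#' with positive RPKM and no disqualifying flag.
#'
#' @param tbl Expression table with `density_rpm`, `rpkm` and flag columns.
#' @return The table with a `te` column (NA where flagged).
#' @export
translation_efficiency <- function(tbl) {
  ok <- !tbl$low_reads & !tbl$excluded_gene & !tbl$discontinuous &
    !tbl$no_mrna & !is.na(tbl$density)
  tbl$te <- ifelse(ok, tbl$density_rpm / tbl$rpkm, NA_real_)
  tbl
}

#' TE ratios of adjacent ORF pairs
#'
#' Downstream/upstream TE ratio per pair; pairs with a missing TE are
#' dropped.
#'
#' @param pairs Pair table from [adjacent_pairs()] or [same_message_pairs()].
#' @param expr Expression table from [expression_table()].
#' @return Tibble: pair ids, `spacing`, `overlap_class`, `te_up`, `te_down`,
#'   `te_ratio`.
#' @export
adjacent_te_ratios <- function(pairs, expr) {
  te <- setNames(expr$te, expr$orf_id)
  out <- pairs
  out$te_up <- unname(te[out$upstream_id])
  out$te_down <- unname(te[out$downstream_id])
  out <- out[!is.na(out$te_up) & !is.na(out$te_down), ]
  out$te_ratio <- out$te_down / out$te_up
  out
}

#' Compare TE-ratio distributions of overlapping vs non-overlapping pairs
#'
#' Two-sample Kolmogorov-Smirnov test between the log TE-ratio distributions
#' of the two overlap classes.
#'
#' @param ratios Output of [adjacent_te_ratios()].
#' @return Tibble: `statistic`, `p_value`, `n_overlapping`,
#'   `n_non_overlapping`.
#' @export
compare_te_ratio_classes <- function(ratios) {
  a <- log(ratios$te_ratio[ratios$overlap_class == "overlapping"])
  b <- log(ratios$te_ratio[ratios$overlap_class == "non_overlapping"])
  if (!length(a) || !length(b)) {
    return(tibble(statistic = NA_real_, p_value = NA_real_,
                  n_overlapping = length(a), n_non_overlapping = length(b)))
  }
  ks <- suppressWarnings(ks.test(a, b))
  tibble(statistic = unname(ks$statistic), p_value = ks$p.value,
         n_overlapping = length(a), n_non_overlapping = length(b))
}

#' Relative ribosome occupancy per codon
#'
#' For every in-frame codon instance, footprint signal over the codon divided
#' by the ORF's mean per-codon signal; instance values are averaged within
#' each ORF and then across ORFs. Optionally normalized to a control sample.
#'
#' @param ribo A footprint [count_track()].
#' @param annotation A [genome_annotation()].
#' @param codons Codon triplets (DNA alphabet) to report; default all codons
#'   observed.
#' @param control Optional occupancy table of a control sample to normalize
#'   against (matched by codon).
#' @return Tibble: `codon`, `occupancy`, `n_orfs`, `n_instances` (and
#'   `occupancy_rel_control` when `control` is given).
#' @export
codon_occupancy <- function(ribo, annotation, codons = NULL, control = NULL) {
  orfs <- annotation$orfs
  acc <- list()
  for (i in seq_len(nrow(orfs))) {
    orf <- orfs[i, ]
    L <- orf$end - orf$start
    if (L %% 3L != 0L) next
    prof <- orf_profile(ribo, orf)
    cs <- colSums(matrix(prof, nrow = 3L))
    m <- mean(cs)
    if (m == 0) next
    seq <- orf_seq(annotation, orf$orf_id)
    trip <- substring(seq, seq(1, L - 2, 3), seq(3, L, 3))
    acc[[length(acc) + 1L]] <- tibble(orf_id = orf$orf_id, codon = trip,
                                      rel = cs / m)
  }
  if (!length(acc)) {
    return(tibble(codon = character(0), occupancy = numeric(0),
                  n_orfs = integer(0), n_instances = integer(0)))
  }
  inst <- bind_rows(acc)
  if (!is.null(codons)) inst <- inst[inst$codon %in% codons, ]
  per_orf <- inst %>%
    group_by(.data$codon, .data$orf_id) %>%
    summarise(rel = mean(.data$rel), n_inst = n(), .groups = "drop")
  out <- per_orf %>%
    group_by(.data$codon) %>%
    summarise(occupancy = mean(.data$rel), n_orfs = n(),
              n_instances = sum(.data$n_inst), .groups = "drop")
  if (!is.null(control)) {
    ctl <- setNames(control$occupancy, control$codon)
    out$occupancy_rel_control <- out$occupancy / unname(ctl[out$codon])
  }
  out
}

#' Center-weight raw footprint intervals into a per-base track
#'
#' Implements the 1/N center-assignment rule for ribosome footprints: within
#' each read, positions at least 12 nt from either end each receive `1/N`,
#' where N is the number of such center positions.
#'
#' @param reads Tibble of read intervals: `replicon`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @param annotation A [genome_annotation()].
#' @param trim Distance from the read ends excluded, nt (default 12).
#' @param sample_id Sample label.
#' @return A [count_track()] with `total_assigned` equal to the number of
#'   reads contributing at least one center position.
#' @export
center_weight_track <- function(reads, annotation, trim = 12L,
                                sample_id = "ribo") {
  track <- count_track(annotation, sample_id)
  n_used <- 0
  for (i in seq_len(nrow(reads))) {
    s <- reads$start[i]
    e <- reads$end[i]
    lo <- s + trim
    hi <- e - trim
    if (hi <= lo) next
    N <- hi - lo
    v <- track$counts[[reads$replicon[i]]][[reads$strand[i]]]
    v[(lo + 1L):hi] <- v[(lo + 1L):hi] + 1 / N
    track$counts[[reads$replicon[i]]][[reads$strand[i]]] <- v
    n_used <- n_used + 1
  }
  track$total_assigned <- n_used
  track
}
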