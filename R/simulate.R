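# sample() treats a scalar first argument as 1:n; guard degenerate ranges
sample_range <- function(lo, hi, n = 1) {
  v <- seq.int(lo, hi)
  if (length(v) == 1L) rep(v, n) else sample(v, n, replace = TRUE)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic operon genome
#'
#' Lays out operons of consecutive same-strand ORFs on a single replicon with
#' a realistic spacing distribution: a configurable fraction of adjacent pairs
#' overlap (spacing <= 0, as for stop/start-overlapping bacterial gene pairs)
#' and most non-overlapping pairs sit within 25 nt, matching the dense packing
#' of bacterial operons. Sequence is random A/C filler at this stage; ORF
#' bodies are written by [make_structures()].
#'
#' @param n_operons Number of operons.
#' @param orfs_per_operon Integer range `c(lo, hi)` of ORFs per operon.
#' @param orf_len Range of ORF lengths in nt (rounded to codon multiples).
#' @param overlap_fraction Fraction of adjacent pairs with spacing <= 0.
#' @param p_short_gap Among positive gaps, probability of a 1-25 nt gap.
#' @param long_gap Range of the remaining positive gaps in nt.
#' @param operon_gap Range of gaps between operons in nt.
#' @param pad Unannotated sequence at the replicon ends (provides folding
#'   context for boundary windows).
#' @param seed Integer seed; the result is bit-reproducible per seed.
#' @return A [genome_annotation()] with `operon_id` set for every ORF.
#' @export
make_genome <- function(n_operons = 60, orfs_per_operon = c(1, 4),
                        orf_len = c(300, 900), overlap_fraction = 0.2,
                        p_short_gap = 0.55, long_gap = c(26, 150),
                        operon_gap = c(150, 400), pad = 300, seed = 1) {
  if (any(orf_len <= 0) || any(orfs_per_operon <= 0)) {
    abort("ranges must be positive")
  }
  if (orf_len[1] < 60) abort("infeasible packing: ORFs shorter than 60 nt")
  with_seed(seed, {
    orf_rows <- list()
    cursor <- pad
    for (op in seq_len(n_operons)) {
      k <- sample_range(orfs_per_operon[1], orfs_per_operon[2])
      strand <- sample(c("+", "-"), 1)
      lens <- 3L * sample_range(ceiling(orf_len[1] / 3), floor(orf_len[2] / 3), k)
      gaps <- if (k > 1) {
        vapply(seq_len(k - 1), function(i) {
          if (runif(1) < overlap_fraction) {
            sample(c(-4L, -1L), 1)
          } else if (runif(1) < p_short_gap) {
            sample_range(1L, 25L)
          } else {
            sample_range(long_gap[1], long_gap[2])
          }
        }, integer(1))
      } else {
        integer(0)
      }
      # block coordinates in transcript orientation
      starts <- integer(k)
      ends <- integer(k)
      pos <- 0L
      for (i in seq_len(k)) {
        starts[i] <- pos
        ends[i] <- pos + lens[i]
        if (i < k) pos <- ends[i] + gaps[i]
      }
      blocklen <- max(ends)
      opid <- sprintf("op%03d", op)
      for (i in seq_len(k)) {
        if (strand == "+") {
          gs <- cursor + starts[i]
          ge <- cursor + ends[i]
        } else {
          gs <- cursor + blocklen - ends[i]
          ge <- cursor + blocklen - starts[i]
        }
        orf_rows[[length(orf_rows) + 1L]] <- tibble(
          orf_id = sprintf("%s_g%d", opid, i),
          replicon = "chr", start = gs, end = ge,
          strand = strand, operon_id = opid
        )
      }
      cursor <- cursor + blocklen + sample_range(operon_gap[1], operon_gap[2])
    }
    glen <- cursor + pad
    seq <- paste(sample(c("A", "C"), glen, replace = TRUE), collapse = "")
    orfs <- arrange(bind_rows(orf_rows), .data$start)
    genome_annotation(c(chr = seq), orfs)
  })
}

#' Adjacent ORF pairs within operons
#'
#' Consecutive ORFs in transcript order within each operon. Spacing is the
#' distance from the 3' end of the upstream stop codon to the 5' start of the
#' downstream start codon in half-open coordinates, so overlapping pairs have
#' spacing <= 0.
#'
#' @param annotation A [genome_annotation()].
#' @return Tibble: `upstream_id`, `downstream_id`, `replicon`, `strand`,
#'   `operon_id`, `spacing`, `overlap_class`.
#' @export
adjacent_pairs <- function(annotation) {
  orfs <- annotation$orfs
  orfs <- orfs[!is.na(orfs$operon_id), ]
  out <- list()
  for (opid in unique(orfs$operon_id)) {
    sub <- orfs[orfs$operon_id == opid, ]
    sub <- sub[order(sub$start, decreasing = (sub$strand[1] == "-")), ]
    if (nrow(sub) < 2L) next
    for (i in seq_len(nrow(sub) - 1L)) {
      up <- sub[i, ]
      down <- sub[i + 1L, ]
      spacing <- if (up$strand == "+") down$start - up$end else up$start - down$end
      out[[length(out) + 1L]] <- tibble(
        upstream_id = up$orf_id, downstream_id = down$orf_id,
        replicon = up$replicon, strand = up$strand, operon_id = opid,
        spacing = as.integer(spacing),
        overlap_class = ifelse(spacing <= 0, "overlapping", "non_overlapping")
      )
    }
  }
  if (!length(out)) {
    return(tibble(upstream_id = character(0), downstream_id = character(0),
                  replicon = character(0), strand = character(0),
                  operon_id = character(0), spacing = integer(0),
                  overlap_class = character(0)))
  }
  bind_rows(out)
}

# Design one ORF body: tiled hairpins reaching a target fraction of A/C bases
# paired. Every Watson-Crick pair contributes exactly one A/C, so the realized
# fraction is s*n / (#A/C in ORF). Loops/filler are A/C (DMS-callable) unless
# the target is infeasible that way, in which case loops switch to G/U.
design_orf <- function(L, pf, stem, loop, start_clear, end_clear) {
  D <- L - start_clear - end_clear
  pick <- NULL
  for (alph in c("AC", "GU")) {
    for (s in seq(stem, 30L)) {
      n <- if (alph == "AC") {
        round(pf * L / (s * (1 + pf)))
      } else {
        round(pf * L / (s + pf * (s + loop)))
      }
      if (n < 0) n <- 0L
      if (n * (2 * s + loop) > D) next
      realized <- if (alph == "AC") {
        s * n / (L - s * n)
      } else {
        if (L - s * n - loop * n <= 0) next
        s * n / (L - s * n - loop * n)
      }
      if (abs(realized - pf) <= 0.05) {
        pick <- list(s = s, n = as.integer(n), alph = alph)
        break
      }
    }
    if (!is.null(pick)) break
  }
  if (is.null(pick)) {
    # saturate: as many long-stem hairpins as fit
    s <- 30L
    n <- floor(D / (2 * s + loop))
    pick <- list(s = s, n = as.integer(n), alph = "GU")
  }
  pick
}

rand_filler <- function(n) sample(c("A", "C"), n, replace = TRUE)

build_orf_sequence <- function(L, design, loop, start_clear, end_clear) {
  s <- design$s
  n <- design$n
  unit <- 2L * s + loop
  D <- L - start_clear - end_clear
  chars <- rand_filler(L)
  paired <- rep(FALSE, L)
  db <- rep(".", L)
  if (n > 0) {
    leftover <- D - n * unit
    gaps <- tabulate(sample.int(n + 1L, leftover, replace = TRUE), n + 1L)
    pos <- start_clear
    wc5 <- c("A", "U", "C", "G")
    wc3 <- c("U", "A", "G", "C")
    for (h in seq_len(n)) {
      pos <- pos + gaps[h]
      idx5 <- (pos + 1L):(pos + s)
      idxl <- (pos + s + 1L):(pos + s + loop)
      idx3 <- (pos + s + loop + 1L):(pos + unit)
      t <- sample.int(4L, s, replace = TRUE)
      chars[idx5] <- wc5[t]
      chars[idx3] <- rev(wc3[t])
      chars[idxl] <- if (design$alph == "AC") {
        rand_filler(loop)
      } else {
        sample(c("G", "U"), loop, replace = TRUE)
      }
      paired[c(idx5, idx3)] <- TRUE
      db[idx5] <- "("
      db[idx3] <- ")"
      pos <- pos + unit
    }
  }
  list(chars = chars, paired = paired, dotbracket = paste(db, collapse = ""))
}

#' Write ground-truth structures into a synthetic genome
#'
#' Rewrites each ORF body (in transcript orientation) as tiled hairpins whose
#' per-base paired status is exact ground truth, hitting a per-ORF target
#' fraction of A/C bases paired. The first `start_clear` nt of every ORF and
#' all intergenic sequence stay unpaired A/C filler, emulating the
#' unstructured zone at translation starts; hairpins never span ORF
#' boundaries unless `boundary_violation` junctions are requested.
#'
#' @param annotation A [genome_annotation()] from [make_genome()].
#' @param paired_fraction Either a range `c(lo, hi)` sampled uniformly per
#'   ORF, or a named vector of per-ORF targets (fraction of A/C bases paired).
#' @param stem Minimum stem length in bp (lengthened automatically for high
#'   targets).
#' @param loop Hairpin loop length in nt.
#' @param start_clear Unstructured zone after each start codon, nt.
#' @param end_clear Unstructured zone before each stop codon, nt.
#' @param boundary_violation If `TRUE`, every non-overlapping junction also
#'   receives one hairpin whose arms sit on opposite sides of the downstream
#'   start codon (for boundary-disruption experiments).
#' @param seed Integer seed.
#' @return List with elements `annotation` (sequence rewritten) and `truth`
#'   (a `simulation_truth`: per-ORF realized paired fractions, per-base paired
#'   labels in genome coordinates, per-ORF dot-bracket strings).
#' @export
make_structures <- function(annotation, paired_fraction = c(0, 0.8),
                            stem = 6L, loop = 4L, start_clear = 25L,
                            end_clear = 9L, boundary_violation = FALSE,
                            seed = 1) {
  orfs <- annotation$orfs
  with_seed(seed, {
    targets <- if (!is.null(names(paired_fraction))) {
      paired_fraction[orfs$orf_id]
    } else if (length(paired_fraction) == 2L) {
      runif(nrow(orfs), paired_fraction[1], paired_fraction[2])
    } else {
      rep(paired_fraction, length.out = nrow(orfs))
    }
    if (any(targets < 0 | targets > 1)) abort("paired_fraction must be in [0, 1]")
    genome <- strsplit(annotation$sequence[["chr"]], "")[[1]]
    glen <- length(genome)
    paired_genome <- rep(FALSE, glen)
    db <- character(nrow(orfs))
    rows <- list()
    for (i in seq_len(nrow(orfs))) {
      orf <- orfs[i, ]
      L <- orf$end - orf$start
      des <- design_orf(L, targets[i], stem, loop, start_clear, end_clear)
      built <- build_orf_sequence(L, des, loop, start_clear, end_clear)
      idx <- (orf$start + 1L):orf$end
      if (orf$strand == "+") {
        genome[idx] <- built$chars
        paired_genome[idx] <- built$paired
      } else {
        comp <- c(A = "U", C = "G", G = "C", U = "A")
        genome[idx] <- rev(unname(comp[built$chars]))
        paired_genome[idx] <- rev(built$paired)
      }
      n_ac_paired <- sum(built$paired & built$chars %in% c("A", "C"))
      n_ac <- sum(built$chars %in% c("A", "C"))
      db[i] <- built$dotbracket
      rows[[i]] <- tibble(
        orf_id = orf$orf_id, target_pf = unname(targets[i]),
        paired_fraction = if (n_ac > 0) n_ac_paired / n_ac else 0,
        n_hairpins = des$n, stem = des$s, loop_alphabet = des$alph,
        true_te = NA_real_
      )
    }
    truth <- structure(
      list(
        orfs = bind_rows(rows),
        paired = list(chr = paired_genome),
        dotbracket = setNames(db, orfs$orf_id),
        pairs = NULL
      ),
      class = "simulation_truth"
    )
    if (boundary_violation) {
      pr <- adjacent_pairs(annotation)
      pr <- pr[pr$spacing > 0, ]
      comp <- c(A = "U", C = "G", G = "C", U = "A")
      s_b <- 6L
      for (k in seq_len(nrow(pr))) {
        up <- orfs[orfs$orf_id == pr$upstream_id[k], ]
        down <- orfs[orfs$orf_id == pr$downstream_id[k], ]
        arm <- sample(c("A", "U", "C", "G"), s_b, replace = TRUE)
        # transcript offsets: last s_b nt of the upstream end_clear zone and
        # nt 10..15 of the downstream start_clear zone
        upL <- up$end - up$start
        up_off <- (upL - s_b + 1L):upL
        down_off <- 10L:(10L + s_b - 1L)
        gidx <- function(orf, off) {
          if (orf$strand == "+") orf$start + off else orf$end - off + 1L
        }
        ui <- gidx(up, up_off)
        di <- gidx(down, down_off)
        if (up$strand == "+") {
          genome[ui] <- arm
          genome[di] <- rev(unname(comp[arm]))
        } else {
          genome[ui] <- rev(unname(comp[arm]))
          genome[di] <- arm
        }
        paired_genome[c(ui, di)] <- TRUE
      }
      truth$paired$chr <- paired_genome
    }
    seqstr <- paste(genome, collapse = "")
    seqstr <- chartr("U", "T", seqstr)
    ann2 <- genome_annotation(c(chr = seqstr),
                              orfs[, c("orf_id", "replicon", "start", "end",
                                       "strand", "operon_id")])
    list(annotation = ann2, truth = truth)
  })
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("<simulation_truth> ", nrow(x$orfs), " ORFs, mean paired fraction ",
      format(mean(x$orfs$paired_fraction), digits = 3), "\n", sep = "")
  invisible(x)
}

operon_spans <- function(annotation, utr5 = 50L, utr3 = 30L) {
  orfs <- annotation$orfs
  orfs <- orfs[!is.na(orfs$operon_id), ]
  glen <- nchar(annotation$sequence)
  spans <- orfs %>%
    group_by(.data$operon_id) %>%
    summarise(replicon = .data$replicon[1], strand = .data$strand[1],
              lo = min(.data$start), hi = max(.data$end), .groups = "drop")
  spans$lo <- pmax(0L, spans$lo - ifelse(spans$strand == "+", utr5, utr3))
  spans$hi <- pmin(as.integer(glen[spans$replicon]),
                   spans$hi + ifelse(spans$strand == "+", utr3, utr5))
  spans
}

# expected DMS-seq count at each position of a transcribed span
dms_mean_vector <- function(annotation, truth, span, depth, k_unpaired,
                            paired_leak, background) {
  idx <- (span$lo + 1L):span$hi
  gb <- strsplit(substr(annotation$sequence[[span$replicon]],
                        span$lo + 1L, span$hi), "")[[1]]
  base <- if (span$strand == "+") {
    gb
  } else {
    unname(c(A = "T", C = "G", G = "C", T = "A")[gb])
  }
  ac <- base %in% c("A", "C")
  paired <- truth$paired[[span$replicon]][idx]
  mu <- rep(depth * background, length(idx))
  mu[ac & !paired] <- depth * k_unpaired
  mu[ac & paired] <- depth * k_unpaired * paired_leak
  mu
}

rnb <- function(mu, size) {
  if (is.infinite(size)) stats::rpois(length(mu), mu) else {
    rnbinom(length(mu), mu = mu, size = size)
  }
}

#' Per-base DMS modification rates for one sample
#'
#' The latent Poisson rates behind a DMS-seq library: the structural means
#' (unpaired A/C at `depth * k_unpaired`, paired A/C scaled by `paired_leak`,
#' G/U at background) times per-position gamma noise with shape `dispersion`.
#' The gamma noise models sample-level variability (local modification and
#' fragmentation biases), so sequencing replicates of the same sample should
#' share one rate track and differ only in Poisson counting noise — this is
#' what makes replicate agreement improve with read depth.
#'
#' @param annotation,truth Output of [make_structures()].
#' @param depth Depth scale; with the default `k_unpaired` the ORF-average
#'   raw coverage is about `depth` reads/nt for a typically structured ORF.
#' @param dispersion Gamma shape of the rate noise; counts drawn from these
#'   rates are negative binomial with this size parameter (variance
#'   `mu + mu^2/size`); `Inf` disables overdispersion.
#' @param k_unpaired Reactivity of unpaired A/C relative to `depth`.
#' @param paired_leak Residual reactivity of paired A/C; its true value is
#'   not well established, so it is an explicit knob.
#' @param background Reactivity of G/U bases relative to `depth`.
#' @param abundance Optional named per-operon coverage multipliers (see
#'   [operon_abundance()]).
#' @param seed Integer seed.
#' @return A [count_track()] whose values are Poisson rates.
#' @export
dms_rate_track <- function(annotation, truth, depth = 30, dispersion = 8,
                           k_unpaired = 3, paired_leak = 0.1,
                           background = 0.1, abundance = NULL, seed = 1) {
  if (depth <= 0) abort("depth must be positive")
  with_seed(seed, {
    track <- count_track(annotation, "dms_rates")
    spans <- operon_spans(annotation)
    for (k in seq_len(nrow(spans))) {
      span <- spans[k, ]
      mult <- if (is.null(abundance)) 1 else abundance[[span$operon_id]]
      mu <- mult * dms_mean_vector(annotation, truth, span, depth, k_unpaired,
                                   paired_leak, background)
      if (is.finite(dispersion)) {
        mu <- mu * stats::rgamma(length(mu), shape = dispersion,
                                 rate = dispersion)
      }
      v <- track$counts[[span$replicon]][[span$strand]]
      v[(span$lo + 1L):span$hi] <- mu
      track$counts[[span$replicon]][[span$strand]] <- v
    }
    track$total_assigned <- track_total(track)
    track
  })
}

#' Simulate a DMS-seq count track
#'
#' Draws per-base counts over every transcribed operon span from a
#' negative-binomial (Poisson-gamma) law: unpaired A/C bases of the mRNA get
#' mean `depth * k_unpaired`, paired A/C bases the same scaled by
#' `paired_leak`, and G/U bases a low background, emulating DMS chemistry's
#' specificity for unpaired adenine and cytosine. Pass a shared
#' [dms_rate_track()] through `rates` to generate sequencing replicates of
#' one sample.
#'
#' @inheritParams dms_rate_track
#' @param rates Optional precomputed [dms_rate_track()]; when `NULL`, rates
#'   are drawn internally (seed-derived), giving a single-replicate track.
#' @param seed Integer seed for the counting noise.
#' @return A [count_track()].
#' @export
simulate_dms_counts <- function(annotation, truth, depth = 30, dispersion = 8,
                                k_unpaired = 3, paired_leak = 0.1,
                                background = 0.1, abundance = NULL,
                                rates = NULL, seed = 1) {
  if (is.null(rates)) {
    rates <- dms_rate_track(annotation, truth, depth, dispersion, k_unpaired,
                            paired_leak, background, abundance,
                            seed = seed + 500000L)
  }
  with_seed(seed, {
    track <- count_track(annotation, "dms")
    for (rep in names(rates$counts)) {
      for (str in c("+", "-")) {
        r <- rates$counts[[rep]][[str]]
        v <- numeric(length(r))
        nz <- which(r > 0)
        if (length(nz)) v[nz] <- stats::rpois(length(nz), r[nz])
        track$counts[[rep]][[str]] <- v
      }
    }
    track$total_assigned <- track_total(track)
    track
  })
}

#' Per-operon transcript abundance multipliers
#'
#' Lognormal coverage multipliers emulating the spread of transcript
#' abundance across operons; feed the same vector to replicate
#' [simulate_dms_counts()] calls so replicates share biology and differ only
#' in counting noise.
#'
#' @param annotation A [genome_annotation()].
#' @param sdlog Lognormal sd of the multipliers.
#' @param seed Integer seed.
#' @return Named numeric vector, one multiplier per operon.
#' @export
operon_abundance <- function(annotation, sdlog = 1, seed = 1) {
  ops <- unique(annotation$orfs$operon_id)
  with_seed(seed, setNames(stats::rlnorm(length(ops), 0, sdlog), ops))
}

#' Noiseless DMS reactivity means (ground truth)
#'
#' The expected-value version of [simulate_dms_counts()]; useful for tests
#' that need calls to recover the truth exactly.
#'
#' @inheritParams simulate_dms_counts
#' @return A [count_track()] whose "counts" are the per-base means.
#' @export
truth_reactivity <- function(annotation, truth, depth = 30, k_unpaired = 3,
                             paired_leak = 0.1, background = 0.1) {
  track <- count_track(annotation, "dms_truth")
  spans <- operon_spans(annotation)
  for (k in seq_len(nrow(spans))) {
    span <- spans[k, ]
    mu <- dms_mean_vector(annotation, truth, span, depth, k_unpaired,
                          paired_leak, background)
    v <- track$counts[[span$replicon]][[span$strand]]
    v[(span$lo + 1L):span$hi] <- mu
    track$counts[[span$replicon]][[span$strand]] <- v
  }
  track$total_assigned <- track_total(track)
  track
}

#' Simulate mRNA-seq and ribosome-profiling tracks
#'
#' Latent translation efficiency per ORF follows
#' `log(TE) = a - b * paired_fraction + Normal(0, sigma)`: structure
#' suppresses translation log-linearly. mRNA levels are uniform along each
#' message (one level per transcription unit, lognormal across units) and a
#' fraction of operon junctions is broken by an internal terminator/promoter,
#' giving the downstream sub-message an independent level and a near-zero
#' coverage dip in the intergenic gap. Ribosome footprint density is
#' proportional to mRNA level times TE, with an elevated ramp over the first
#' `ramp_codons` codons, all with negative-binomial noise.
#'
#' @param annotation,truth Output of [make_structures()].
#' @param te_model Named vector `c(a, b, sigma)` of the log-TE model.
#' @param depth Mean reads/nt scale for both tracks.
#' @param dispersion Negative-binomial size parameter.
#' @param ramp_mult Footprint density multiplier over the initial ramp.
#' @param ramp_codons Ramp length in codons.
#' @param break_fraction Fraction of all junctions carrying an internal
#'   terminator/promoter (only junctions with spacing >= `min_break_spacing`
#'   are eligible: breaks need intergenic sequence).
#' @param min_break_spacing Minimum spacing for a breakable junction, nt.
#' @param break_fold Range of the fold change a break imposes on the
#'   downstream sub-message's level (direction random); internal promoters
#'   and terminators change levels severalfold.
#' @param level_sdlog Lognormal sd of baseline message levels (0 puts every
#'   message at the `depth` scale).
#' @param seed Integer seed.
#' @return List: `mrna` and `ribo` [count_track()]s, and `truth` updated with
#'   `true_te` per ORF and a `pairs` tibble carrying `same_message` ground
#'   truth per junction.
#' @export
simulate_expression <- function(annotation, truth,
                                te_model = c(a = 0, b = 4, sigma = 0.3),
                                depth = 50, dispersion = 8, ramp_mult = 2,
                                ramp_codons = 50L, break_fraction = 0.2,
                                min_break_spacing = 40L, break_fold = c(3, 10),
                                level_sdlog = 1, seed = 1) {
  if (te_model[["b"]] < 0) abort("te_model slope b must be >= 0")
  with_seed(seed, {
    orfs <- annotation$orfs
    pairs <- adjacent_pairs(annotation)
    eligible <- which(pairs$spacing >= min_break_spacing)
    n_break <- min(length(eligible), round(break_fraction * nrow(pairs)))
    broken <- rep(FALSE, nrow(pairs))
    if (n_break > 0) broken[sample(eligible, n_break)] <- TRUE

    # split operons into messages at broken junctions
    msg_of <- setNames(orfs$operon_id, orfs$orf_id)
    for (k in which(broken)) {
      opid <- pairs$operon_id[k]
      sub <- pairs[pairs$operon_id == opid, ]
      # transcript order of ORFs in this operon
      ids <- c(sub$upstream_id[1], sub$downstream_id)
      at <- match(pairs$downstream_id[k], ids)
      downstream_ids <- ids[at:length(ids)]
      msg_of[downstream_ids] <- paste0(msg_of[downstream_ids], ".",
                                       pairs$downstream_id[k])
    }
    messages <- unique(msg_of)
    level <- setNames(stats::rlnorm(length(messages), 0, level_sdlog), messages)
    # a break changes the downstream sub-message's level severalfold
    for (k in which(broken)) {
      dm <- msg_of[pairs$downstream_id[k]]
      fold <- exp(runif(1, log(break_fold[1]), log(break_fold[2])))
      if (runif(1) < 0.5) fold <- 1 / fold
      level[dm] <- level[dm] * fold
    }

    pf <- setNames(truth$orfs$paired_fraction, truth$orfs$orf_id)
    te <- exp(te_model[["a"]] - te_model[["b"]] * pf[orfs$orf_id] +
                rnorm(nrow(orfs), 0, te_model[["sigma"]]))
    te <- setNames(unname(te), orfs$orf_id)

    # normalize so the ORF-position-weighted mean mRNA level is `depth`
    lens <- orfs$end - orfs$start
    lv_orf <- level[msg_of[orfs$orf_id]]
    scale_m <- depth / stats::weighted.mean(lv_orf, lens)
    scale_r <- depth / stats::weighted.mean(lv_orf * te[orfs$orf_id], lens)

    mrna <- count_track(annotation, "mrna")
    ribo <- count_track(annotation, "ribo")
    glen <- nchar(annotation$sequence[["chr"]])

    # mRNA mean vector per strand
    for (str in c("+", "-")) {
      mu <- rep(0, glen)
      sub <- orfs[orfs$strand == str, ]
      for (i in seq_len(nrow(sub))) {
        orf <- sub[i, ]
        mu[(orf$start + 1L):orf$end] <- level[msg_of[orf$orf_id]] * scale_m
      }
      # covered intergenic regions and UTRs
      pr <- pairs[pairs$strand == str, ]
      for (k in seq_len(nrow(pr))) {
        if (pr$spacing[k] <= 0) next
        up <- orfs[orfs$orf_id == pr$upstream_id[k], ]
        down <- orfs[orfs$orf_id == pr$downstream_id[k], ]
        gap <- if (str == "+") (up$end + 1L):down$start else (down$end + 1L):up$start
        kbroken <- broken[which(pairs$upstream_id == pr$upstream_id[k] &
                                  pairs$downstream_id == pr$downstream_id[k])]
        if (!kbroken) {
          mu[gap] <- level[msg_of[up$orf_id]] * scale_m
        } else {
          # terminator shortly after the upstream stop, promoter shortly
          # before the downstream start; near-zero coverage between
          g <- length(gap)
          upn <- min(10L, g)
          dnn <- min(15L, g - upn)
          gap_t <- if (str == "+") gap else rev(gap)
          if (upn > 0) mu[gap_t[seq_len(upn)]] <- level[msg_of[up$orf_id]] * scale_m
          if (dnn > 0) {
            mu[gap_t[(g - dnn + 1L):g]] <- level[msg_of[down$orf_id]] * scale_m
          }
          mid <- setdiff(seq_len(g), c(seq_len(upn), if (dnn > 0) (g - dnn + 1L):g))
          if (length(mid)) mu[gap_t[mid]] <- 0.02 * depth
        }
      }
      # short UTRs at message ends
      spans <- operon_spans(annotation)
      spans <- spans[spans$strand == str, ]
      for (k in seq_len(nrow(spans))) {
        span <- spans[k, ]
        members <- orfs[orfs$operon_id == span$operon_id, ]
        first_id <- if (str == "+") {
          members$orf_id[which.min(members$start)]
        } else {
          members$orf_id[which.max(members$end)]
        }
        idx <- (span$lo + 1L):span$hi
        zero <- idx[mu[idx] == 0]
        if (length(zero)) mu[zero] <- level[msg_of[first_id]] * scale_m
      }
      v <- rnb(mu, dispersion)
      mrna$counts[["chr"]][[str]] <- as.numeric(v)
    }

    # ribosome footprints: ORF bodies only, ramp over the first codons
    for (str in c("+", "-")) {
      mu <- rep(0, glen)
      sub <- orfs[orfs$strand == str, ]
      for (i in seq_len(nrow(sub))) {
        orf <- sub[i, ]
        L <- orf$end - orf$start
        m <- rep(level[msg_of[orf$orf_id]] * scale_r * te[orf$orf_id], L)
        ramp_nt <- min(L, ramp_codons * 3L)
        m[seq_len(ramp_nt)] <- m[seq_len(ramp_nt)] * ramp_mult
        if (str == "-") m <- rev(m)
        mu[(orf$start + 1L):orf$end] <- m
      }
      ribo$counts[["chr"]][[str]] <- as.numeric(rnb(mu, dispersion))
    }
    mrna$total_assigned <- track_total(mrna)
    ribo$total_assigned <- track_total(ribo)

    truth$orfs$true_te <- unname(te[truth$orfs$orf_id])
    pairs$same_message <- !broken
    pairs$true_te_ratio <- unname(te[pairs$downstream_id] / te[pairs$upstream_id])
    truth$pairs <- pairs
    list(mrna = mrna, ribo = ribo, truth = truth)
  })
}

#' Simulate a complete synthetic study
#'
#' Chains [make_genome()], [make_structures()], two replicate
#' [simulate_dms_counts()] draws and [simulate_expression()] with shared
#' defaults, deriving sub-seeds from one master seed.
#'
#' @param seed Master integer seed.
#' @param n_operons,orfs_per_operon,overlap_fraction Passed to [make_genome()].
#' @param paired_fraction Passed to [make_structures()].
#' @param depth_dms,depth_expr Depth scales of the DMS and expression tracks.
#' @param dispersion NB size parameter for all tracks.
#' @param te_model,break_fraction Passed to [simulate_expression()].
#' @param dms_abundance_sdlog Lognormal sd of per-operon DMS coverage
#'   multipliers, shared between the two replicates (0 keeps every operon at
#'   `depth_dms`).
#' @param ... Further arguments to [simulate_expression()].
#' @return A list of class `ribostruct_sim`: `annotation`, `truth`, and
#'   `tracks` (`dms`, `dms_rep2`, `mrna`, `ribo`).
#' @export
simulate_study <- function(seed = 1, n_operons = 60,
                           orfs_per_operon = c(1, 4), overlap_fraction = 0.2,
                           paired_fraction = c(0, 0.8), depth_dms = 30,
                           depth_expr = 50, dispersion = 8,
                           te_model = c(a = 0, b = 4, sigma = 0.3),
                           break_fraction = 0.2, dms_abundance_sdlog = 0,
                           ...) {
  ann <- make_genome(n_operons = n_operons, orfs_per_operon = orfs_per_operon,
                     overlap_fraction = overlap_fraction, seed = seed)
  st <- make_structures(ann, paired_fraction = paired_fraction,
                        seed = seed + 1000L)
  ab <- if (dms_abundance_sdlog > 0) {
    operon_abundance(st$annotation, dms_abundance_sdlog, seed = seed + 1500L)
  } else {
    NULL
  }
  rates <- dms_rate_track(st$annotation, st$truth, depth = depth_dms,
                          dispersion = dispersion, abundance = ab,
                          seed = seed + 1600L)
  dms <- simulate_dms_counts(st$annotation, st$truth, rates = rates,
                             seed = seed + 2000L)
  dms2 <- simulate_dms_counts(st$annotation, st$truth, rates = rates,
                              seed = seed + 3000L)
  expr <- simulate_expression(st$annotation, st$truth, te_model = te_model,
                              depth = depth_expr, dispersion = dispersion,
                              break_fraction = break_fraction,
                              seed = seed + 4000L, ...)
  structure(
    list(annotation = st$annotation, truth = expr$truth,
         tracks = list(dms = dms, dms_rep2 = dms2, mrna = expr$mrna,
                       ribo = expr$ribo),
         seed = seed),
    class = "ribostruct_sim"
  )
}

#' @export
print.ribostruct_sim <- function(x, ...) {
  cat("<ribostruct_sim> seed ", x$seed, ": ", nrow(x$annotation$orfs),
      " ORFs, ", length(x$tracks), " tracks\n", sep = "")
  invisible(x)
}

#' Write a simulated study to a fixture directory
#'
#' Serializes annotation (GFF3 + FASTA), all tracks (per-strand bedGraph +
#' library-size sidecars), and the ground truth (`truth.tsv`,
#' `truth_pairs.tsv`, plus a 0/1 `paired_truth` bedGraph of per-base paired
#' labels). [read_fixture()] round-trips the bundle.
#'
#' @param bundle A `ribostruct_sim` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation(bundle$annotation, file.path(dir, "annotation.gff3"),
                   file.path(dir, "genome.fa"))
  for (nm in names(bundle$tracks)) {
    write_track(bundle$tracks[[nm]], file.path(dir, nm))
  }
  truth <- bundle$truth
  write.table(truth$orfs, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(truth$pairs)) {
    write.table(truth$pairs, file.path(dir, "truth_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  db <- tibble(orf_id = names(truth$dotbracket),
               dotbracket = unname(truth$dotbracket))
  write.table(db, file.path(dir, "truth_dotbracket.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ptrack <- count_track(bundle$annotation, "paired_truth")
  ptrack$counts[["chr"]][["+"]] <- as.numeric(truth$paired[["chr"]])
  ptrack$total_assigned <- track_total(ptrack)
  write_track(ptrack, file.path(dir, "paired_truth"))
  invisible(dir)
}

#' Read a fixture directory back into a study bundle
#'
#' @param dir Directory written by [write_fixture()].
#' @return A `ribostruct_sim` (without the generator seed).
#' @export
read_fixture <- function(dir) {
  ann <- read_annotation(file.path(dir, "annotation.gff3"),
                         file.path(dir, "genome.fa"))
  track_names <- c("dms", "dms_rep2", "mrna", "ribo")
  tracks <- list()
  for (nm in track_names) {
    pp <- file.path(dir, paste0(nm, "_plus.bedGraph"))
    mp <- file.path(dir, paste0(nm, "_minus.bedGraph"))
    if (file.exists(pp) || file.exists(mp)) {
      tracks[[nm]] <- read_track(if (file.exists(pp)) pp else NULL,
                                 if (file.exists(mp)) mp else NULL,
                                 ann, nm)
    }
  }
  torfs <- as_tibble(read.delim(file.path(dir, "truth.tsv")))
  db <- read.delim(file.path(dir, "truth_dotbracket.tsv"))
  pairs_path <- file.path(dir, "truth_pairs.tsv")
  tpairs <- if (file.exists(pairs_path)) {
    as_tibble(read.delim(pairs_path))
  } else {
    NULL
  }
  pt <- read_track(file.path(dir, "paired_truth_plus.bedGraph"), NULL, ann,
                   "paired_truth")
  truth <- structure(
    list(orfs = torfs,
         paired = list(chr = pt$counts[["chr"]][["+"]] > 0),
         dotbracket = setNames(db$dotbracket, db$orf_id),
         pairs = tpairs),
    class = "simulation_truth"
  )
  structure(
    list(annotation = ann, truth = truth, tracks = tracks, seed = NA_integer_),
    class = "ribostruct_sim"
  )
}
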