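# cohort of uniform-coverage ORFs with controlled half-to-half level jitter
level_test_genome <- function(n_orfs = 40, L = 402L, jitter = 0,
                              depth = 50) {
  orfs <- tibble::tibble(
    orf_id = sprintf("g%02d", seq_len(n_orfs)),
    replicon = "chr",
    start = as.integer(seq(100, by = L + 100, length.out = n_orfs)),
    strand = "+",
    operon_id = sprintf("op%02d", seq_len(n_orfs))
  )
  orfs$end <- orfs$start + L
  glen <- max(orfs$end) + 200L
  ann <- genome_annotation(
    c(chr = strrep("A", glen)),
    orfs[, c("orf_id", "replicon", "start", "end", "strand", "operon_id")]
  )
  track <- count_track(ann, "mrna")
  v <- rep(0, glen)
  half <- L %/% 2L
  # alternating +/- jitter gives a known sd of log2 half-ratios
  delta <- rep(c(jitter, -jitter), length.out = n_orfs)
  for (i in seq_len(n_orfs)) {
    v[(orfs$start[i] + 1):(orfs$start[i] + half)] <- depth * 2^delta[i]
    v[(orfs$start[i] + half + 1):orfs$end[i]] <- depth
  }
  track <- set_track_counts(track, "chr", "+", v)
  list(annotation = ann, track = track, delta = delta)
}

test_that("noiseless uniform coverage calibrates a fold-change cutoff of 1", {
  g <- level_test_genome(jitter = 0)
  cut <- calibrate_level_cutoff(g$track, g$annotation)
  expect_equal(cut$sigma_log2, 0)
  expect_equal(cut$cutoff_fold, 1)
  cc <- calibrate_continuity_cutoff(g$track, g$annotation)
  expect_equal(cc$cutoff, 0)
})

test_that("jitter with 2 sigma = log2(1.5) reports a 1.5-fold cutoff", {
  n <- 40
  target_sd <- log2(1.5) / 2
  x <- target_sd * sqrt((n - 1) / n) # sd of an alternating +/-x vector
  g <- level_test_genome(n_orfs = n, jitter = x)
  cut <- calibrate_level_cutoff(g$track, g$annotation)
  expect_equal(cut$cutoff_fold, 1.5, tolerance = 1e-6)
})

test_that("the level cutoff grows monotonically with intra-ORF noise", {
  cuts <- vapply(c(0.05, 0.15, 0.3), function(j) {
    calibrate_level_cutoff(level_test_genome(jitter = j)$track,
                           level_test_genome(jitter = j)$annotation)$cutoff_fold
  }, numeric(1))
  expect_true(all(diff(cuts) > 0))
})

test_that("continuity calibration needs windows that fit inside ORFs", {
  g <- level_test_genome(L = 60L)
  expect_error(calibrate_continuity_cutoff(g$track, g$annotation, window = 80L),
               "window larger")
})

test_that("same-message calling accepts continuity and rejects steps and gaps", {
  set.seed(40)
  # two-ORF operons: one continuous, one with a 3x step, one with a dead gap
  orfs <- tibble::tibble(
    orf_id = c(sprintf("bg%02d", 1:30), "contA", "contB", "stepA", "stepB",
               "gapA", "gapB"),
    replicon = "chr", strand = "+",
    operon_id = c(sprintf("bgop%02d", 1:30), "cont", "cont", "step", "step",
                  "gap", "gap")
  )
  L <- 402L
  starts <- as.integer(seq(100, by = 600, length.out = nrow(orfs)))
  # pair members placed adjacently with a 100 nt gap
  starts[32] <- starts[31] + L + 100L
  starts[34] <- starts[33] + L + 100L
  starts[36] <- starts[35] + L + 100L
  orfs$start <- starts
  orfs$end <- orfs$start + L
  orfs <- dplyr::arrange(orfs, start)
  glen <- max(orfs$end) + 200L
  ann <- genome_annotation(c(chr = strrep("A", glen)), orfs)
  mu <- rep(0, glen)
  depth <- 60
  for (i in seq_len(nrow(orfs))) mu[(orfs$start[i] + 1):orfs$end[i]] <- depth
  fill_gap <- function(a, b, value) {
    ea <- orfs$end[orfs$orf_id == a]
    sb <- orfs$start[orfs$orf_id == b]
    mu[(ea + 1):sb] <<- value
  }
  fill_gap("contA", "contB", depth)
  fill_gap("stepA", "stepB", depth * 2)
  fill_gap("gapA", "gapB", 0)
  mu[(orfs$start[orfs$orf_id == "stepB"] + 1):orfs$end[orfs$orf_id == "stepB"]] <- depth * 3
  track <- count_track(ann, "mrna")
  track <- set_track_counts(track, "chr", "+", rnb_test(mu, 8))
  pairs <- same_message_pairs(track, ann)
  expect_true(pairs$same_message[pairs$upstream_id == "contA"])
  expect_false(pairs$level_ok[pairs$upstream_id == "stepA"])
  expect_false(pairs$continuity_ok[pairs$upstream_id == "gapA"])
  expect_false(pairs$same_message[pairs$upstream_id == "gapA"])
})

test_that("overlap classification and the spacing CDF use sign conventions", {
  pairs <- tibble::tibble(
    upstream_id = c("a", "b"), downstream_id = c("x", "y"),
    spacing = c(25L, -4L)
  )
  cls <- classify_overlap(pairs)
  expect_equal(cls$overlap_class, c("non_overlapping", "overlapping"))
  cdf <- attr(cls, "spacing_cdf")
  expect_equal(cdf$cdf[cdf$spacing == 25], 1)
  # half-open arithmetic: upstream end 100, downstream start 125
  orfs <- tibble::tibble(
    orf_id = c("p", "q"), replicon = "chr",
    start = c(10L, 125L), end = c(100L, 200L), strand = "+",
    operon_id = "op"
  )
  ann <- genome_annotation(c(chr = strrep("A", 300)), orfs)
  pr <- adjacent_pairs(ann)
  expect_equal(pr$spacing, 25L)
  expect_equal(pr$overlap_class, "non_overlapping")
})

test_that("generated genomes recover the requested overlap fraction", {
  ann <- make_genome(n_operons = 70, orfs_per_operon = c(3, 4),
                     overlap_fraction = 0.2, seed = 41)
  pr <- classify_overlap(adjacent_pairs(ann))
  frac <- mean(pr$overlap_class == "overlapping")
  expect_equal(frac, 0.2, tolerance = 0.35) # binomial noise at ~200 pairs
})

test_that("discontinuous genes are flagged against the cohort distribution", {
  g <- level_test_genome(n_orfs = 40)
  ann <- g$annotation
  v <- g$track$counts$chr$`+`
  # kill the second half of one gene
  orf <- ann$orfs[5, ]
  half <- (orf$start + orf$end) %/% 2
  v[(half + 1):orf$end] <- 0
  track <- set_track_counts(count_track(ann), "chr", "+", v)
  fl <- flag_discontinuous_genes(track, ann)
  expect_true(fl$flagged[fl$orf_id == orf$orf_id])
  expect_equal(sum(fl$flagged), 1L)
  # all-uniform cohort flags nothing
  fl0 <- flag_discontinuous_genes(g$track, ann)
  expect_equal(sum(fl0$flagged), 0L)
})

test_that("pair acceptance is symmetric under genome reverse-complementation", {
  sim <- cached_sim("operon_small",
                    simulate_study(seed = 77, n_operons = 15,
                                   orfs_per_operon = c(2, 3)))
  ann <- sim$annotation
  track <- sim$tracks$mrna
  pairs <- same_message_pairs(track, ann)
  rc <- revcomp_annotation(ann)
  glen <- nchar(ann$sequence[["chr"]])
  rc_track <- count_track(rc, "mrna")
  rc_track <- set_track_counts(rc_track, "chr", "+",
                               rev(track$counts$chr$`-`))
  rc_track <- set_track_counts(rc_track, "chr", "-",
                               rev(track$counts$chr$`+`))
  rc_pairs <- same_message_pairs(rc_track, rc)
  key <- function(p) p[order(p$upstream_id), c("upstream_id", "same_message")]
  expect_equal(as.data.frame(key(rc_pairs)), as.data.frame(key(pairs)))
})
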