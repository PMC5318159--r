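test_that("generators are bit-reproducible for fixed seeds", {
  a1 <- make_genome(n_operons = 5, seed = 9)
  a2 <- make_genome(n_operons = 5, seed = 9)
  expect_identical(a1$sequence, a2$sequence)
  expect_identical(as.data.frame(a1$orfs), as.data.frame(a2$orfs))
  s1 <- simulate_study(seed = 9, n_operons = 5)
  s2 <- simulate_study(seed = 9, n_operons = 5)
  expect_identical(s1$tracks$dms$counts, s2$tracks$dms$counts)
  expect_identical(s1$tracks$ribo$counts, s2$tracks$ribo$counts)
  expect_identical(s1$truth$orfs, s2$truth$orfs)
})

test_that("overlap_fraction controls the sign of spacings", {
  ann0 <- make_genome(n_operons = 20, orfs_per_operon = c(2, 4),
                      overlap_fraction = 0, seed = 3)
  expect_true(all(adjacent_pairs(ann0)$spacing > 0))
  ann1 <- make_genome(n_operons = 60, orfs_per_operon = c(3, 4),
                      overlap_fraction = 0.2, seed = 4)
  pr <- adjacent_pairs(ann1)
  frac <- mean(pr$spacing <= 0)
  expect_gt(frac, 0.1)
  expect_lt(frac, 0.3)
})

test_that("single-ORF operons emit no adjacent pairs", {
  ann <- make_genome(n_operons = 5, orfs_per_operon = c(1, 1), seed = 2)
  expect_equal(nrow(adjacent_pairs(ann)), 0L)
})

test_that("structure designs hit target paired fractions and edge cases", {
  ann <- make_genome(n_operons = 4, orfs_per_operon = c(2, 2),
                     orf_len = c(450, 900), overlap_fraction = 0, seed = 6)
  ids <- ann$orfs$orf_id
  targets <- setNames(rep(c(0, 0.2, 0.45, 0.8), length.out = length(ids)), ids)
  st <- make_structures(ann, paired_fraction = targets, seed = 6)
  expect_equal(st$truth$orfs$paired_fraction[st$truth$orfs$target_pf == 0],
               rep(0, sum(targets == 0)))
  expect_true(all(grepl("^\\.+$",
                        st$truth$dotbracket[names(targets)[targets == 0]])))
  expect_true(all(abs(st$truth$orfs$paired_fraction -
                        st$truth$orfs$target_pf) <= 0.05))
})

test_that("hairpins stay inside ORFs unless boundary violation is requested", {
  ann <- make_genome(n_operons = 6, orfs_per_operon = c(2, 2),
                     overlap_fraction = 0, seed = 7)
  st <- make_structures(ann, paired_fraction = c(0.3, 0.5), seed = 7)
  paired <- st$truth$paired$chr
  in_orf <- rep(FALSE, length(paired))
  for (i in seq_len(nrow(ann$orfs))) {
    in_orf[(ann$orfs$start[i] + 1):ann$orfs$end[i]] <- TRUE
  }
  expect_true(all(!paired[!in_orf]))

  stv <- make_structures(ann, paired_fraction = c(0.3, 0.5),
                         boundary_violation = TRUE, seed = 7)
  pr <- adjacent_pairs(stv$annotation)
  pr <- pr[pr$spacing > 0, ]
  # at least one junction has paired bases on both sides of the downstream start
  found <- FALSE
  for (k in seq_len(nrow(pr))) {
    down <- stv$annotation$orfs[stv$annotation$orfs$orf_id == pr$downstream_id[k], ]
    up <- stv$annotation$orfs[stv$annotation$orfs$orf_id == pr$upstream_id[k], ]
    p <- stv$truth$paired$chr
    up_tail <- if (up$strand == "+") p[(up$end - 8):(up$end)] else p[(up$start + 1):(up$start + 9)]
    down_head <- if (down$strand == "+") p[(down$start + 1):(down$start + 25)] else p[(down$end - 24):down$end]
    if (any(up_tail) && any(down_head)) found <- TRUE
  }
  expect_true(found)
})

test_that("simulated DMS count means match the stated formulas", {
  ann <- make_genome(n_operons = 22, orfs_per_operon = c(3, 3),
                     orf_len = c(600, 900), overlap_fraction = 0, seed = 8)
  st <- make_structures(ann, paired_fraction = c(0.4, 0.4), seed = 8)
  depth <- 20
  track <- simulate_dms_counts(st$annotation, st$truth, depth = depth,
                               dispersion = 8, k_unpaired = 3,
                               paired_leak = 0.1, background = 0.1, seed = 1)
  truth_mu <- truth_reactivity(st$annotation, st$truth, depth = depth)
  mu <- c(truth_mu$counts$chr$`+`, truth_mu$counts$chr$`-`)
  x <- c(track$counts$chr$`+`, track$counts$chr$`-`)
  for (level in c(depth * 3, depth * 3 * 0.1, depth * 0.1)) {
    sel <- which(mu == level)
    expect_gt(length(sel), 1e4)
    m <- mean(x[sel])
    se <- sd(x[sel]) / sqrt(length(sel))
    expect_lt(abs(m - level), 3 * se)
  }
})

test_that("DMS limits: no leak and no background give exact zeros", {
  ann <- make_genome(n_operons = 4, orfs_per_operon = c(2, 2), seed = 12)
  st <- make_structures(ann, paired_fraction = c(0.4, 0.6), seed = 12)
  tr <- simulate_dms_counts(st$annotation, st$truth, depth = 200,
                            dispersion = Inf, paired_leak = 0,
                            background = 0, seed = 3)
  mu <- truth_reactivity(st$annotation, st$truth, depth = 200,
                         paired_leak = 0, background = 0)
  for (str in c("+", "-")) {
    zero_mu <- mu$counts$chr[[str]] == 0
    expect_true(all(tr$counts$chr[[str]][zero_mu] == 0))
  }
})

test_that("ground-truth Gini increases with paired fraction on a noiseless grid", {
  ann <- make_genome(n_operons = 8, orfs_per_operon = c(2, 2),
                     orf_len = c(450, 900), overlap_fraction = 0, seed = 13)
  ids <- ann$orfs$orf_id
  grid <- setNames(seq(0.05, 0.8, length.out = length(ids)), ids)
  st <- make_structures(ann, paired_fraction = grid, seed = 13)
  mu <- truth_reactivity(st$annotation, st$truth)
  g <- orf_gini_table(mu, st$annotation, min_mean = 0)
  ord <- match(st$truth$orfs$orf_id, g$orf_id)
  expect_gt(cor(g$gini[ord], st$truth$orfs$paired_fraction,
                method = "spearman"), 0.99)
})

test_that("expression simulator reflects its generative model", {
  # te ratio of a constructed 100x pair shows up in raw footprint densities
  ann <- make_genome(n_operons = 1, orfs_per_operon = c(2, 2),
                     orf_len = c(600, 600), overlap_fraction = 0, seed = 21)
  st <- make_structures(ann, paired_fraction = c(0.2, 0.2), seed = 21)
  st$truth$orfs$paired_fraction <- c(0, log(100) / 4)
  ex <- simulate_expression(st$annotation, st$truth,
                            te_model = c(a = 0, b = 4, sigma = 0),
                            depth = 200, dispersion = Inf, ramp_mult = 1,
                            break_fraction = 0, seed = 21)
  orfs <- st$annotation$orfs
  d1 <- mean(orf_profile(ex$ribo, orfs[orfs$orf_id == "op001_g1", ]))
  d2 <- mean(orf_profile(ex$ribo, orfs[orfs$orf_id == "op001_g2", ]))
  expect_equal(ex$truth$orfs$true_te[1] / ex$truth$orfs$true_te[2], 100)
  expect_gt(d1 / d2, 80)
  expect_lt(d1 / d2, 125)
  # sigma = 0, b = 0 collapses all TEs
  ex0 <- simulate_expression(st$annotation, st$truth,
                             te_model = c(a = 0.5, b = 0, sigma = 0),
                             depth = 50, break_fraction = 0, seed = 3)
  expect_true(all(ex0$truth$orfs$true_te == exp(0.5)))
  # 2x ramp over the first 50 codons before correction
  exr <- simulate_expression(st$annotation, st$truth,
                             te_model = c(a = 0, b = 0, sigma = 0),
                             depth = 300, dispersion = Inf, ramp_mult = 2,
                             ramp_codons = 50L, break_fraction = 0, seed = 4)
  prof <- orf_profile(exr$ribo, orfs[1, ])
  ramp <- mean(prof[1:150])
  plateau <- mean(prof[151:length(prof)])
  expect_equal(ramp / plateau, 2, tolerance = 0.05)
})

test_that("fixtures round-trip annotation, tracks and truth", {
  sim <- simulate_study(seed = 31, n_operons = 6)
  dir <- withr::local_tempdir()
  write_fixture(sim, dir)
  back <- read_fixture(dir)
  expect_equal(back$annotation$sequence, sim$annotation$sequence)
  expect_equal(back$tracks$dms$counts, sim$tracks$dms$counts)
  expect_equal(back$tracks$mrna$counts, sim$tracks$mrna$counts)
  expect_equal(back$truth$paired$chr, sim$truth$paired$chr)
  expect_equal(back$truth$orfs$paired_fraction, sim$truth$orfs$paired_fraction)
  expect_equal(back$truth$pairs$same_message, sim$truth$pairs$same_message)
  expect_equal(unname(back$truth$dotbracket), unname(sim$truth$dotbracket))
})
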