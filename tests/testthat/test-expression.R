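test_that("RPKM follows the direct formula and its scaling laws", {
  prof <- rep(1, 1000)
  expect_equal(mrna_rpkm(prof, 1e6), 1000)
  expect_equal(mrna_rpkm(prof, 2e6), 500)
  set.seed(30)
  spiky <- rpois(999, 5)
  expect_equal(mrna_rpkm(rep(3, 300), 1e6),
               sum(rep(3, 300)) * 1e9 / (300 * 1e6)) # Winsorization no-op on uniform
  expect_error(mrna_rpkm(numeric(0), 1e6), "zero-length")
})

test_that("footprint corrections are no-ops on flat signal", {
  prof <- rep(4, 600)
  cfg <- correction_config()
  expect_equal(footprint_density(prof, cfg, ramp_ratio = 1), 4)
  # flat cohort estimates a ramp ratio of 1
  ann <- make_genome(n_operons = 6, orfs_per_operon = c(1, 1),
                     orf_len = c(600, 900), seed = 31)
  tr <- count_track(ann, "flat")
  for (str in c("+", "-")) {
    tr <- set_track_counts(tr, "chr", str, rep(2, nchar(ann$sequence)))
  }
  expect_equal(estimate_ramp_ratio(tr, ann, cfg), 1)
})

test_that("a known 2x initiation ramp is corrected to within 2% of plateau", {
  ann <- make_genome(n_operons = 10, orfs_per_operon = c(1, 1),
                     orf_len = c(600, 900), seed = 32)
  st <- make_structures(ann, paired_fraction = c(0.3, 0.3), seed = 32)
  ex <- simulate_expression(st$annotation, st$truth,
                            te_model = c(a = 0, b = 0, sigma = 0),
                            depth = 300, dispersion = Inf, ramp_mult = 2,
                            ramp_codons = 50L, break_fraction = 0, seed = 32)
  cfg <- correction_config()
  ratio <- estimate_ramp_ratio(ex$ribo, ann, cfg)
  expect_equal(ratio, 2, tolerance = 0.03)
  orf <- ann$orfs[1, ]
  prof <- orf_profile(ex$ribo, orf)
  corrected <- footprint_density(prof, cfg, ramp_ratio = ratio)
  plateau <- mean(prof[151:(length(prof) - 15)])
  expect_equal(corrected, plateau, tolerance = 0.02)
})

test_that("90% Winsorization caps an extreme pause spike", {
  prof <- rep(2, 600)
  prof[300] <- 200
  d <- footprint_density(prof, correction_config(), ramp_ratio = 1)
  expect_equal(d, 2, tolerance = 0.05)
})

test_that("corrections apply in the canonical order (mask, ramp, winsorize)", {
  set.seed(33)
  prof <- rpois(450, 10) + 1
  cfg <- correction_config(ramp_codons = 50L)
  ratio <- 1.8
  # independent re-derivation of the documented order
  v <- prof
  v[1:150] <- v[1:150] / ratio
  x <- v[16:(450 - 15)]
  q <- quantile(x, c(0.05, 0.95), names = FALSE)
  x <- pmin(pmax(x, q[1]), q[2])
  expect_equal(footprint_density(prof, cfg, ramp_ratio = ratio), mean(x))
})

test_that("TE applies the read-count and exclusion filters", {
  sim <- default_sim()
  expr <- expression_table(sim$tracks$ribo, sim$tracks$mrna, sim$annotation)
  expect_true(all(is.na(expr$te[expr$low_reads])))
  expect_true(all(!is.na(expr$te[!expr$low_reads & !expr$no_mrna &
                                   !expr$excluded_gene & !expr$discontinuous &
                                   !is.na(expr$density)])))
  # a density of 2 against RPKM 100 gives TE 0.02 on the density_rpm scale
  row <- tibble::tibble(density = 2, density_rpm = 2, rpkm = 100,
                        low_reads = FALSE, excluded_gene = FALSE,
                        discontinuous = FALSE, no_mrna = FALSE)
  expect_equal(translation_efficiency(row)$te, 0.02)
  # 127 raw reads is below the 128-read filter
  row2 <- row
  row2$low_reads <- 127 < correction_config()$min_reads
  expect_true(is.na(translation_efficiency(row2)$te))
  # named exclusion list
  cfg <- correction_config(excluded_genes = sim$annotation$orfs$orf_id[1])
  expr2 <- expression_table(sim$tracks$ribo, sim$tracks$mrna, sim$annotation,
                            cfg)
  expect_true(is.na(expr2$te[1]))
  expect_true(expr2$excluded_gene[1])
})

test_that("TE is invariant to joint library rescaling", {
  sim <- default_sim()
  expr <- expression_table(sim$tracks$ribo, sim$tracks$mrna, sim$annotation)
  ribo2 <- sim$tracks$ribo
  mrna2 <- sim$tracks$mrna
  ribo2$total_assigned <- ribo2$total_assigned * 7
  mrna2$total_assigned <- mrna2$total_assigned * 7
  expr2 <- expression_table(ribo2, mrna2, sim$annotation)
  expect_equal(expr2$te, expr$te)
})

test_that("TE recovers the latent translation efficiencies on synthetic data", {
  sim <- default_sim()
  expr <- expression_table(sim$tracks$ribo, sim$tracks$mrna, sim$annotation)
  j <- dplyr::left_join(expr, sim$truth$orfs, by = "orf_id")
  ok <- !is.na(j$te)
  expect_gte(sum(ok), 50)
  expect_gte(cor(j$te[ok], j$true_te[ok], method = "spearman"), 0.95)
})

test_that("log TE regressed on Gini recovers the generative slope", {
  sim <- default_sim()
  expr <- expression_table(sim$tracks$ribo, sim$tracks$mrna, sim$annotation)
  g <- orf_gini_table(sim$tracks$dms, sim$annotation)
  j <- dplyr::left_join(dplyr::left_join(expr, g, by = "orf_id"),
                        sim$truth$orfs, by = "orf_id")
  j <- j[!is.na(j$te) & !is.na(j$gini) & j$included, ]
  slope <- coef(lm(log(j$te) ~ j$gini))[2]
  dgini_dpf <- coef(lm(j$gini ~ j$paired_fraction))[2]
  expected <- -4 * (1 / dgini_dpf)
  expect_lt(slope, 0)
  expect_lt(abs(slope - expected) / abs(expected), 0.25)
})

test_that("adjacent TE ratios and the overlap-class comparison behave", {
  pairs <- tibble::tibble(
    upstream_id = c("u1", "u2"), downstream_id = c("d1", "d2"),
    spacing = c(25L, -4L),
    overlap_class = c("non_overlapping", "overlapping")
  )
  expr <- tibble::tibble(orf_id = c("u1", "d1", "u2", "d2"),
                         te = c(0.02, 2.06, 1, 1))
  r <- adjacent_te_ratios(pairs, expr)
  expect_equal(r$te_ratio, c(103, 1))
  # identical class distributions give a non-significant K-S p
  set.seed(34)
  x <- exp(rnorm(150))
  big <- tibble::tibble(
    upstream_id = paste0("a", 1:300), downstream_id = paste0("b", 1:300),
    spacing = rep(c(10L, -1L), each = 150),
    overlap_class = rep(c("non_overlapping", "overlapping"), each = 150)
  )
  expr_big <- tibble::tibble(orf_id = c(big$upstream_id, big$downstream_id),
                             te = c(rep(1, 300), rep(exp(rnorm(150)), 2)))
  rb <- adjacent_te_ratios(big, expr_big)
  ks <- compare_te_ratio_classes(rb)
  expect_gt(ks$p_value, 0.01)
  expect_equal(ks$n_overlapping, 150L)
})

test_that("codon occupancy is 1 on uniform signal and detects pauses", {
  ann <- make_genome(n_operons = 6, orfs_per_operon = c(1, 1),
                     orf_len = c(300, 600), seed = 35)
  st <- make_structures(ann, paired_fraction = c(0.2, 0.4), seed = 35)
  ann <- st$annotation
  uniform <- count_track(ann, "u")
  for (str in c("+", "-")) {
    uniform <- set_track_counts(uniform, "chr", str,
                                rep(3, nchar(ann$sequence)))
  }
  occ <- codon_occupancy(uniform, ann)
  expect_true(all(abs(occ$occupancy - 1) < 1e-9))

  # triple the footprint signal at every CTA codon
  paused <- uniform
  orfs <- ann$orfs
  for (i in seq_len(nrow(orfs))) {
    orf <- orfs[i, ]
    seq <- orf_seq(ann, orf$orf_id)
    L <- orf$end - orf$start
    trip <- substring(seq, seq(1, L - 2, 3), seq(3, L, 3))
    hit <- which(trip == "CTA")
    for (h in hit) {
      off <- (h - 1) * 3 + 1:3
      gidx <- if (orf$strand == "+") orf$start + off else orf$end - off + 1L
      v <- paused$counts$chr[[orf$strand]]
      v[gidx] <- v[gidx] * 3
      paused$counts$chr[[orf$strand]] <- v
    }
  }
  occ2 <- codon_occupancy(paused, ann, codons = c("CTA", "CTG"))
  cta <- occ2$occupancy[occ2$codon == "CTA"]
  ctg <- occ2$occupancy[occ2$codon == "CTG"]
  expect_gt(cta, 2.5)
  expect_lt(abs(ctg - 1), 0.1)
  # control normalization of identical samples is 1
  occ3 <- codon_occupancy(uniform, ann, control = occ)
  expect_true(all(abs(occ3$occupancy_rel_control - 1) < 1e-9))
})

test_that("center weighting assigns 1/N to read centers", {
  ann <- toy_annotation()
  reads <- tibble::tibble(replicon = "chr", start = c(0L, 50L),
                          end = c(28L, 70L), strand = "+")
  tr <- center_weight_track(reads, ann, trim = 12L)
  v <- tr$counts$chr$`+`
  expect_equal(sum(v[13:16]), 1)      # 28 nt read: 4 center positions at 1/4
  expect_equal(v[13], 1 / 4)
  expect_true(all(v[1:12] == 0))
  expect_true(all(v[51:70] == 0))     # 20 nt read has no center positions
  expect_equal(tr$total_assigned, 1)
})
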