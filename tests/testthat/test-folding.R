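test_that("MFE folding matches enumeration on the worked hairpin", {
  s <- fold_constrained("GCGAAACGC")
  expect_equal(s$dotbracket, "(((...)))")
  expect_equal(s$n_pairs, 3)
  expect_equal(s$energy, -3)
  expect_equal(mfe_by_enumeration("GCGAAACGC"), 3)

  s2 <- fold_constrained("GCGAAACGC", unpaired = 1)
  expect_lte(s2$n_pairs, 2)
  expect_equal(substr(s2$dotbracket, 1, 1), ".")
  expect_equal(mfe_by_enumeration("GCGAAACGC", unpaired = 1), s2$n_pairs)

  s3 <- fold_constrained("GCGAAACGC", unpaired = 1:9)
  expect_equal(s3$dotbracket, ".........")
  expect_equal(s3$energy, 0)
})

test_that("internal MFE equals brute-force enumeration on random short sequences", {
  set.seed(20)
  for (i in 1:300) {
    n <- sample(5:14, 1)
    s <- random_rna(n)
    unp <- if (runif(1) < 0.3) sample(n, sample(0:2, 1)) else integer(0)
    expect_equal(fold_constrained(s, unp)$n_pairs,
                 mfe_by_enumeration(s, unp),
                 info = paste(s, paste(unp, collapse = ",")))
  }
})

test_that("pair probabilities match enumeration-weighted frequencies", {
  set.seed(21)
  for (i in 1:60) {
    n <- sample(6:12, 1)
    s <- random_rna(n)
    for (beta in c(0, 1, 2)) {
      P <- pair_probabilities(s, beta = beta)
      Pe <- pairprob_by_enumeration(s, beta)
      expect_lt(max(abs(P - Pe)), 1e-9)
    }
  }
})

test_that("single-pair sequences follow the two-state closed form", {
  # GAAAC admits exactly the G-C pair across a 3 nt loop
  for (beta in c(0.5, 1, 2)) {
    P <- pair_probabilities("GAAAC", beta = beta)
    w <- exp(beta)
    expect_equal(P[1, 5], w / (1 + w), tolerance = 1e-12)
    expect_equal(sum(P) - 2 * P[1, 5], 0)
  }
  expect_true(all(pair_probabilities("AAAAAA") == 0))
})

test_that("probability matrices satisfy ensemble invariants and constraints", {
  set.seed(22)
  for (i in 1:20) {
    s <- random_rna(40)
    unp <- sample(40, 5)
    P <- pair_probabilities(s, unpaired = unp)
    expect_equal(P, t(P))
    expect_true(all(P >= 0 & P <= 1))
    expect_true(all(rowSums(P) <= 1 + 1e-9))
    expect_true(all(P[unp, ] == 0))
  }
})

test_that("adding unpaired constraints never increases the MFE pair count", {
  set.seed(23)
  for (i in 1:50) {
    s <- random_rna(30)
    base <- fold_constrained(s)$n_pairs
    cons <- sample(30, 4)
    prev <- base
    for (k in 1:4) {
      np <- fold_constrained(s, cons[1:k])$n_pairs
      expect_lte(np, prev)
      prev <- np
    }
  }
})

test_that("energy per nucleotide behaves like a concentration-free structure score", {
  expect_equal(energy_per_nt("GCGAAACGC"), 3 / 9)
  expect_equal(energy_per_nt("AAAAAA"), 0)
  set.seed(24)
  for (i in 1:25) {
    s <- random_rna(20)
    expect_gte(energy_per_nt(paste0(s, s)) + 1e-12, energy_per_nt(s))
  }
})

test_that("co-optimal traceback is deterministic", {
  s <- "GGGAAACCCAAAGGGAAACCC"
  a <- fold_constrained(s)
  b <- fold_constrained(s)
  expect_identical(a$dotbracket, b$dotbracket)
  expect_identical(dotbracket_to_pairs(a$dotbracket), a$partner)
})

test_that("boundary statistics are engine-agnostic", {
  sim <- cached_sim("fold_small", simulate_study(seed = 55, n_operons = 8,
                                                 orfs_per_operon = c(2, 2),
                                                 paired_fraction = c(0.3, 0.5)))
  pairs <- head(sim$truth$pairs[sim$truth$pairs$spacing > 0, ], 2)
  p_int <- boundary_pair_probs(sim$annotation, pairs, sim$tracks$dms,
                               flank = 100L)
  custom_engine <- function(seq, unpaired) {
    pair_probabilities(seq, unpaired, beta = 2)
  }
  p_fun <- boundary_pair_probs(sim$annotation, pairs, sim$tracks$dms,
                               flank = 100L, fold_fun = custom_engine)
  d1 <- boundary_directionality(sim$annotation, pairs, probs = p_int,
                                window = 30L)
  d2 <- boundary_directionality(sim$annotation, pairs, probs = p_fun,
                                window = 30L)
  expect_equal(d1, d2)
  m <- metagene_pairing(sim$annotation, pairs, probs = p_int)
  expect_equal(nrow(m), 200L)
  # shared profile: mean equals the single profile when one pair is used
  single <- boundary_pair_probs(sim$annotation, pairs[1, ], sim$tracks$dms,
                                flank = 100L)
  m1 <- metagene_pairing(sim$annotation, pairs[1, ], probs = single)
  expect_equal(m1$mean_pairing, rowSums(single$probs[[1]]))
})

test_that("empty pair sets and insufficient context degrade gracefully", {
  sim <- cached_sim("fold_small", simulate_study(seed = 55, n_operons = 8,
                                                 orfs_per_operon = c(2, 2),
                                                 paired_fraction = c(0.3, 0.5)))
  empty <- sim$truth$pairs[0, ]
  m <- metagene_pairing(sim$annotation, empty, flank = 100L)
  expect_equal(nrow(m), 0L)
  # a flank larger than the genome pad forces skips
  p <- boundary_pair_probs(sim$annotation, head(sim$truth$pairs, 1),
                           flank = 10000L)
  expect_equal(length(p$probs), 0L)
  expect_equal(length(p$skipped), 1L)
})

test_that("the ViennaRNA adapter honors the structure_model contract", {
  skip_if(Sys.which("RNAfold") == "", "RNAfold not installed")
  s <- fold_vienna("GGGGGAAAACCCCC", unpaired = c(1, 2))
  expect_s3_class(s, "structure_model")
  expect_true(startsWith(s$dotbracket, ".."))
  expect_lt(s$energy, 0)
  expect_equal(nchar(s$dotbracket), 14)
})
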