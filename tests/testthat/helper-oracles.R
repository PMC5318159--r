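# Independent oracles, deliberately written without reusing package internals.

# Gini as the normalized mean absolute pairwise difference
gini_mad <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# maximum pair count over the brute-force structure enumeration
mfe_by_enumeration <- function(seq, unpaired = integer(0)) {
  st <- enumerate_structures(seq, unpaired)
  max(vapply(st, function(p) sum(!is.na(p)) / 2, numeric(1)))
}

# Boltzmann-weighted pair frequencies over the brute-force enumeration
pairprob_by_enumeration <- function(seq, beta, unpaired = integer(0)) {
  st <- enumerate_structures(seq, unpaired)
  n <- nchar(seq)
  w <- vapply(st, function(p) exp(beta * sum(!is.na(p)) / 2), numeric(1))
  P <- matrix(0, n, n)
  for (k in seq_along(st)) {
    p <- st[[k]]
    for (a in seq_len(n)) {
      if (!is.na(p[a]) && p[a] > a) P[a, p[a]] <- P[a, p[a]] + w[k]
    }
  }
  (P + t(P)) / sum(w)
}

all_codons_test <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

rnb_test <- function(mu, size) {
  rnbinom(length(mu), mu = mu, size = size)
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# a cohort simulation shared across test files (built once per session)
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

default_sim <- function() {
  cached_sim("default", simulate_study(seed = 101, n_operons = 30,
                                       orfs_per_operon = c(2, 4)))
}

# tiny hand-built annotation: two "+" ORFs and one "-" ORF on a 160 nt replicon
toy_annotation <- function() {
  set.seed(5)
  seq <- paste(sample(c("A", "C", "G", "T"), 160, replace = TRUE),
               collapse = "")
  genome_annotation(
    c(chr = seq),
    tibble::tibble(
      orf_id = c("a", "b", "c"),
      replicon = "chr",
      start = c(9L, 45L, 99L),
      end = c(18L, 90L, 150L),
      strand = c("+", "+", "-"),
      operon_id = c("op1", "op1", "op2")
    )
  )
}
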