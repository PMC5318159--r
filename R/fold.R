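encode_seq <- function(seq) {
  x <- strsplit(toupper(seq), "")[[1]]
  x[x == "T"] <- "U"
  code <- c(A = 0L, C = 1L, G = 2L, U = 3L)
  if (any(!x %in% names(code))) abort("sequence must be over A/C/G/T/U")
  unname(code[x])
}

pairs_to_dotbracket <- function(partner) {
  # partner is 0-based from C++
  db <- rep(".", length(partner))
  for (i in seq_along(partner)) {
    j <- partner[i]
    if (j >= 0 && j + 1L > i) {
      db[i] <- "("
      db[j + 1L] <- ")"
    }
  }
  paste(db, collapse = "")
}

#' Constrained minimum-free-energy structure
#'
#' Predicts the optimal secondary structure of a sequence under the package's
#' base-pair-counting energy model: every Watson-Crick or GU pair contributes
#' -1, hairpin loops span at least `min_loop` nucleotides, and `unpaired`
#' positions (e.g. bases called unpaired from DMS reactivity) are forced
#' single-stranded. Ties among co-optimal structures are broken
#' deterministically by preferring the pair with the smaller opening index
#' during traceback.
#'
#' @param seq Nucleotide string over A/C/G/T/U.
#' @param unpaired Integer vector of 1-based positions constrained unpaired.
#' @param min_loop Minimum hairpin loop length in nt.
#' @return An object of class `structure_model`: `seq`, `dotbracket`,
#'   `energy` (in engine units, -1 per pair), `n_pairs`, `partner` (1-based,
#'   NA when unpaired), `constraints`.
#' @seealso [pair_probabilities()], [energy_per_nt()], [fold_vienna()]
#' @export
fold_constrained <- function(seq, unpaired = integer(0), min_loop = 3L) {
  enc <- encode_seq(seq)
  n <- length(enc)
  if (length(unpaired) && (min(unpaired) < 1L || max(unpaired) > n)) {
    abort("unpaired constraints out of bounds")
  }
  cons <- rep(FALSE, n)
  cons[unpaired] <- TRUE
  partner0 <- nussinov_pairs(enc, cons, as.integer(min_loop))
  npairs <- sum(partner0 > seq_len(n) - 1L)
  structure(
    list(
      seq = seq,
      dotbracket = pairs_to_dotbracket(partner0),
      energy = -npairs,
      n_pairs = npairs,
      partner = ifelse(partner0 < 0, NA_integer_, partner0 + 1L),
      constraints = sort(unique(as.integer(unpaired))),
      min_loop = as.integer(min_loop)
    ),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", nchar(x$seq), " nt, ", x$n_pairs,
      " pairs, energy ", x$energy, "\n", sep = "")
  if (nchar(x$seq) <= 80) cat(" ", x$seq, "\n ", x$dotbracket, "\n")
  invisible(x)
}

#' Base-pairing probability matrix
#'
#' McCaskill-style partition function over the base-pair-counting energy
#' model: each pair carries Boltzmann weight `exp(beta)`, so `beta` plays the
#' role of an inverse temperature (beta -> 0 gives the uniform ensemble over
#' legal structures). Constrained positions have zero pairing probability.
#'
#' @inheritParams fold_constrained
#' @param beta Inverse temperature; the default 2 makes losing one pair cost
#'   a factor `exp(-2)`, comparable to one helix stack at growth temperature.
#' @return Symmetric `n x n` matrix `P` with `0 <= P[i,j] <= 1` and
#'   `rowSums(P) <= 1`.
#' @export
pair_probabilities <- function(seq, unpaired = integer(0), beta = 2,
                               min_loop = 3L) {
  enc <- encode_seq(seq)
  n <- length(enc)
  if (length(unpaired) && (min(unpaired) < 1L || max(unpaired) > n)) {
    abort("unpaired constraints out of bounds")
  }
  cons <- rep(FALSE, n)
  cons[unpaired] <- TRUE
  pair_prob_matrix(enc, cons, beta, as.integer(min_loop))
}

#' Structure score of a sequence: -MFE energy per nucleotide
#'
#' Under the internal engine this is simply (number of MFE pairs)/length;
#' with an external thermodynamic engine, pass its energy through `energy`
#' to get kcal/mol/nt.
#'
#' @inheritParams fold_constrained
#' @param energy Optional externally computed free energy to use instead of
#'   the internal model's.
#' @return A non-negative scalar; 0 for an unfoldable sequence.
#' @export
energy_per_nt <- function(seq, unpaired = integer(0), min_loop = 3L,
                          energy = NULL) {
  n <- nchar(seq)
  if (n == 0L) abort("empty sequence")
  if (!is.null(energy)) return(-energy / n)
  -fold_constrained(seq, unpaired, min_loop)$energy / n
}

#' Enumerate all legal secondary structures (oracle)
#'
#' Exhaustive recursion over every nested structure of a short sequence under
#' the same pairing rules as the engine. Intended as an independent
#' brute-force oracle for tests and sanity checks; cost grows exponentially,
#' keep sequences under ~16 nt.
#'
#' @inheritParams fold_constrained
#' @return A list of integer partner vectors (1-based, NA = unpaired), one
#'   per structure, including the empty structure.
#' @export
enumerate_structures <- function(seq, unpaired = integer(0), min_loop = 3L) {
  x <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  n <- length(x)
  cons <- rep(FALSE, n)
  cons[unpaired] <- TRUE
  ok <- function(a, b) {
    paste0(x[a], x[b]) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  }
  rec <- function(i, j) {
    if (i > j || j - i < min_loop + 1L) {
      return(list(integer(0)))
    }
    out <- list()
    # j unpaired
    for (s in rec(i, j - 1L)) out[[length(out) + 1L]] <- s
    # k pairs j
    for (k in i:(j - min_loop - 1L)) {
      if (cons[k] || cons[j] || !ok(k, j)) next
      left <- rec(i, k - 1L)
      inner <- rec(k + 1L, j - 1L)
      for (a in left) {
        for (b in inner) {
          out[[length(out) + 1L]] <- c(a, b, k * 1000000L + j)
        }
      }
    }
    out
  }
  encoded <- rec(1L, n)
  lapply(encoded, function(s) {
    partner <- rep(NA_integer_, n)
    for (code in s) {
      k <- code %/% 1000000L
      j <- code %% 1000000L
      partner[k] <- j
      partner[j] <- k
    }
    partner
  })
}

#' Constrained MFE via ViennaRNA (optional external engine)
#'
#' Thin adapter around the `RNAfold` command-line tool for a
#' nearest-neighbor thermodynamic model. Returns the same `structure_model`
#' contract as [fold_constrained()] (energies in kcal/mol), so downstream
#' boundary statistics are engine-agnostic. Requires `RNAfold` on the PATH.
#'
#' @inheritParams fold_constrained
#' @return A `structure_model` with an `engine` element recording the tool
#'   and version, or an error if RNAfold is unavailable.
#' @export
fold_vienna <- function(seq, unpaired = integer(0)) {
  exe <- Sys.which("RNAfold")
  if (exe == "") abort("RNAfold not found on PATH")
  n <- nchar(seq)
  cstr <- rep(".", n)
  cstr[unpaired] <- "x"
  infile <- tempfile(fileext = ".fa")
  writeLines(c(chartr("T", "U", toupper(seq)), paste(cstr, collapse = "")), infile)
  out <- system2(exe, c("-C", "--noPS"), stdin = infile, stdout = TRUE)
  line <- out[2]
  db <- sub("^(\\S+).*$", "\\1", line)
  energy <- as.numeric(sub("^.*\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1", line))
  ver <- tryCatch(system2(exe, "--version", stdout = TRUE)[1],
                  error = function(e) "RNAfold")
  partner <- dotbracket_to_pairs(db)
  structure(
    list(seq = seq, dotbracket = db, energy = energy,
         n_pairs = sum(!is.na(partner)) / 2,
         partner = partner,
         constraints = sort(unique(as.integer(unpaired))),
         engine = ver),
    class = "structure_model"
  )
}

#' Parse a dot-bracket string into a partner vector
#'
#' @param db Balanced dot-bracket string.
#' @return Integer vector of 1-based partners (NA when unpaired).
#' @export
dotbracket_to_pairs <- function(db) {
  x <- strsplit(db, "")[[1]]
  partner <- rep(NA_integer_, length(x))
  stack <- integer(0)
  for (i in seq_along(x)) {
    if (x[i] == "(") {
      stack <- c(stack, i)
    } else if (x[i] == ")") {
      if (!length(stack)) abort("unbalanced dot-bracket")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack)) abort("unbalanced dot-bracket")
  partner
}
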