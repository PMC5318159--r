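GENETIC_CODE_STOPS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

revcomp_codon <- function(codon) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(codon, ""), function(x) {
    paste(rev(unname(comp[x])), collapse = "")
  }, character(1))
}

#' Default wobble-inefficiency parameters
#'
#' Selective constraints on codon-anticodon pairing at the wobble position,
#' following the classical tRNA-adaptation-index parameterization: 0 for
#' Watson-Crick reading, and fitted penalties for G:U (anticodon G34 reading
#' codon U3... rule `gu`), I:C (`ic`), I:A (`ia`) and U:G (`ug`) wobble
#' reading. Fully overridable.
#'
#' @return Named numeric vector with entries `wc`, `gu`, `ic`, `ia`, `ug`.
#' @export
default_wobble_s <- function() {
  c(wc = 0, gu = 0.41, ic = 0.28, ia = 0.9999, ug = 0.68)
}

#' Relative adaptiveness of each sense codon
#'
#' Absolute adaptiveness sums `(1 - s) * tGCN` over the anticodons able to
#' decode a codon (Watson-Crick plus one wobble reading per codon family),
#' then scales so the best codon has weight 1. Codons with zero absolute
#' adaptiveness receive the geometric mean of the nonzero weights, so a
#' missing anticodon never zeroes out a gene's score.
#'
#' Decoding rules by codon third base: U is read by anticodon-34 A
#' (Watson-Crick) and G (`gu` penalty); C by G (WC) and inosine from A34
#' (`ic`); A by U (WC) and inosine (`ia`); G by C (WC) and U (`ug`).
#'
#' @param tgcn Tibble/data.frame with columns `anticodon` (DNA alphabet,
#'   5'->3') and `copies` (tRNA gene copy number).
#' @param s Wobble penalties, as [default_wobble_s()].
#' @return An object of class `codon_weights`: tibble `codon`, `W`
#'   (absolute), `w` (relative, max 1), `imputed`.
#' @export
relative_adaptiveness <- function(tgcn, s = default_wobble_s()) {
  if (any(tgcn$copies < 0)) abort("tGCN must be non-negative")
  if (any(s < 0 | s > 1)) abort("s parameters must be in [0, 1]")
  cn <- setNames(rep(0, 64), all_codons())
  counts <- setNames(tgcn$copies, toupper(chartr("U", "T", tgcn$anticodon)))
  cn[names(counts)] <- counts
  sense <- setdiff(all_codons(), GENETIC_CODE_STOPS)
  wobble34 <- c(T = "G", C = "A", A = "A", G = "T")
  wobble_s <- c(T = s[["gu"]], C = s[["ic"]], A = s[["ia"]], G = s[["ug"]])
  W <- vapply(sense, function(codon) {
    third <- substr(codon, 3, 3)
    wc_anti <- revcomp_codon(codon)
    wob_anti <- paste0(wobble34[[third]], substr(wc_anti, 2, 3))
    (1 - s[["wc"]]) * cn[[wc_anti]] + (1 - wobble_s[[third]]) * cn[[wob_anti]]
  }, numeric(1))
  if (all(W == 0)) abort("all-zero tGCN")
  w <- W / max(W)
  zero <- w == 0
  if (any(zero)) w[zero] <- exp(mean(log(w[!zero])))
  out <- tibble(codon = sense, W = unname(W), w = unname(w),
                imputed = unname(zero))
  class(out) <- c("codon_weights", class(out))
  out
}

#' tRNA adaptation index of a gene
#'
#' Geometric mean of the relative adaptiveness weights of a gene's codons,
#' excluding the start and stop codons. Computed in log space to avoid
#' underflow on long genes.
#'
#' @param seq Coding sequence (DNA alphabet, length a multiple of 3, at
#'   least 3 codons).
#' @param weights A `codon_weights` table from [relative_adaptiveness()].
#' @return tAI in (0, 1], or `NA` (with attribute `flag = "internal_stop"`)
#'   when the body contains a stop codon.
#' @export
tai <- function(seq, weights) {
  seq <- toupper(chartr("U", "T", seq))
  L <- nchar(seq)
  if (L %% 3L != 0L || L < 9L) {
    abort("coding sequence must be >= 3 codons and a multiple of 3")
  }
  trip <- substring(seq, seq(1, L - 2, 3), seq(3, L, 3))
  body <- trip[2:(length(trip) - 1L)]
  if (any(body %in% GENETIC_CODE_STOPS)) {
    return(structure(NA_real_, flag = "internal_stop"))
  }
  w <- setNames(weights$w, weights$codon)
  exp(mean(log(unname(w[body]))))
}

#' Per-gene tAI table
#'
#' @param annotation A [genome_annotation()].
#' @param weights A `codon_weights` table; defaults to weights built from the
#'   bundled synthetic tGCN table.
#' @return Tibble: `orf_id`, `tai`, `flag`.
#' @export
tai_table <- function(annotation, weights = NULL) {
  if (is.null(weights)) {
    weights <- relative_adaptiveness(read_tgcn())
  }
  orfs <- annotation$orfs
  rows <- purrr::map(seq_len(nrow(orfs)), function(i) {
    res <- tryCatch(tai(orf_seq(annotation, orfs$orf_id[i]), weights),
                    error = function(e) structure(NA_real_, flag = "length"))
    tibble(orf_id = orfs$orf_id[i], tai = as.numeric(res),
           flag = attr(res, "flag") %||% NA_character_)
  })
  bind_rows(rows)
}

#' Read a tRNA gene copy number table
#'
#' The bundled default (`synthetic_tgcn.tsv`) is an illustrative,
#' non-biological table constructed so that every codon family is decodable;
#' supply your organism's tGCN for real analyses.
#'
#' @param path TSV with columns `anticodon`, `copies`; default the bundled
#'   synthetic table.
#' @return Tibble.
#' @export
read_tgcn <- function(path = system.file("extdata", "synthetic_tgcn.tsv",
                                         package = "ribostruct")) {
  as_tibble(read.delim(path))
}
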