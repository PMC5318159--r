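#' Genome annotation container
#'
#' Holds replicon sequences plus an ORF table with optional operon grouping.
#' Internal coordinates are 0-based half-open and strand-aware: `start` is the
#' first nucleotide of the start codon on the transcript strand ("+" ORFs) or
#' `end - 1` is ("-" ORFs); all window arithmetic in the package is done on
#' this scale.
#'
#' @param sequence Named character vector of replicon sequences (DNA alphabet,
#'   upper case).
#' @param orfs Tibble/data.frame with columns `orf_id`, `replicon`, `start`,
#'   `end` (0-based half-open), `strand` ("+"/"-") and optionally `operon_id`.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(sequence, orfs) {
  orfs <- as_tibble(orfs)
  if (!"operon_id" %in% names(orfs)) orfs$operon_id <- NA_character_
  orfs <- orfs[, c("orf_id", "replicon", "start", "end", "strand", "operon_id")]
  orfs$start <- as.integer(orfs$start)
  orfs$end <- as.integer(orfs$end)
  ann <- structure(list(sequence = sequence, orfs = orfs),
                   class = "genome_annotation")
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  orfs <- ann$orfs
  if (anyDuplicated(orfs$orf_id)) abort("duplicate orf_id in annotation")
  bad_rep <- setdiff(unique(orfs$replicon), names(ann$sequence))
  if (length(bad_rep)) {
    abort(paste0("ORFs reference unknown replicon(s): ",
                 paste(bad_rep, collapse = ", ")))
  }
  lens <- nchar(ann$sequence)
  for (i in seq_len(nrow(orfs))) {
    L <- lens[[orfs$replicon[i]]]
    if (orfs$start[i] < 0 || orfs$end[i] > L || orfs$start[i] >= orfs$end[i]) {
      abort(paste0("ORF ", orfs$orf_id[i], " outside replicon bounds"))
    }
  }
  if (!all(orfs$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  frame_ok <- (orfs$end - orfs$start) %% 3L == 0L
  if (!all(frame_ok)) {
    warn(paste0(sum(!frame_ok), " ORF(s) have length not a multiple of 3"))
  }
  ann$orfs$frame_ok <- frame_ok
  # operon members must be same-strand and position-sorted
  ops <- split(seq_len(nrow(orfs)), orfs$operon_id)
  for (idx in ops) {
    if (length(idx) > 1L) {
      if (length(unique(orfs$strand[idx])) != 1L) {
        abort("operon members must share a strand")
      }
      if (is.unsorted(orfs$start[idx])) {
        abort("operon members must be sorted by position")
      }
    }
  }
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", length(x$sequence), " replicon(s), ",
      nrow(x$orfs), " ORFs, ",
      dplyr::n_distinct(x$orfs$operon_id, na.rm = TRUE), " operons\n", sep = "")
  invisible(x)
}

#' Read annotation from GFF3 + FASTA
#'
#' Parses CDS features (with `ID` and optional `operon` attributes) and the
#' genome sequence. GFF3 1-based inclusive coordinates are converted to the
#' internal 0-based half-open convention.
#'
#' @param gff_path Path to a GFF3 file with CDS features.
#' @param fasta_path Path to the genome FASTA.
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(gff_path, fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) abort("no CDS features in GFF3")
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) abort("GFF3 CDS features must carry ID attributes")
  operon <- if (!is.null(gr$operon)) as.character(gr$operon) else NA_character_
  orfs <- tibble(
    orf_id = as.character(ids),
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    operon_id = operon
  )
  orfs <- arrange(orfs, .data$replicon, .data$start)
  genome_annotation(setNames(as.character(seqs), names(seqs)), orfs)
}

#' Write annotation to GFF3 + FASTA
#'
#' Inverse of [read_annotation()]; round-trips losslessly.
#'
#' @param annotation A [genome_annotation()].
#' @param gff_path,fasta_path Output paths.
#' @return Invisibly, the input annotation.
#' @export
write_annotation <- function(annotation, gff_path, fasta_path) {
  orfs <- annotation$orfs
  gr <- GenomicRanges::GRanges(
    seqnames = orfs$replicon,
    ranges = IRanges::IRanges(start = orfs$start + 1L, end = orfs$end),
    strand = orfs$strand
  )
  gr$source <- "ribostruct"
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- orfs$orf_id
  gr$operon <- orfs$operon_id
  rtracklayer::export(gr, gff_path, format = "gff3")
  seqs <- Biostrings::DNAStringSet(annotation$sequence)
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(annotation)
}

#' ORF sequence in transcript orientation
#'
#' @param annotation A [genome_annotation()].
#' @param orf_id ORF identifier.
#' @return Character string, 5' to 3' of the mRNA (reverse-complemented for
#'   "-" strand ORFs), DNA alphabet.
#' @export
orf_seq <- function(annotation, orf_id) {
  orf <- annotation$orfs[annotation$orfs$orf_id == orf_id, ]
  if (nrow(orf) != 1L) abort(paste0("unknown orf_id: ", orf_id))
  region_seq(annotation, orf$replicon, orf$start, orf$end, orf$strand)
}

#' Genomic region sequence in transcript orientation
#'
#' @param annotation A [genome_annotation()].
#' @param replicon Replicon name.
#' @param start,end 0-based half-open coordinates.
#' @param strand "+" or "-".
#' @return Character string 5' to 3' on `strand`.
#' @export
region_seq <- function(annotation, replicon, start, end, strand = "+") {
  s <- substr(annotation$sequence[[replicon]], start + 1L, end)
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

#' Reverse-complement an annotation (with any tracks)
#'
#' Flips every replicon and all coordinates/strands; used for
#' strand-symmetry property checks.
#'
#' @param annotation A [genome_annotation()].
#' @return A [genome_annotation()] on the flipped genome.
#' @export
revcomp_annotation <- function(annotation) {
  lens <- nchar(annotation$sequence)
  seqs <- vapply(annotation$sequence, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1))
  orfs <- annotation$orfs
  L <- lens[orfs$replicon]
  new_start <- L - orfs$end
  new_end <- L - orfs$start
  orfs$start <- as.integer(new_start)
  orfs$end <- as.integer(new_end)
  orfs$strand <- ifelse(orfs$strand == "+", "-", "+")
  orfs <- arrange(orfs, .data$replicon, .data$start)
  genome_annotation(seqs, orfs[, c("orf_id", "replicon", "start", "end",
                                   "strand", "operon_id")])
}
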