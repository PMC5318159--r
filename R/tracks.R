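#' Per-base count track
#'
#' One sample's per-base non-negative counts over the genome, stranded.
#' Positions use the same 0-based half-open convention as
#' [genome_annotation()]: element `i + 1` of a strand vector is the count at
#' 0-based position `i`.
#'
#' @param annotation A [genome_annotation()] supplying replicon lengths.
#' @param sample_id Sample label.
#' @return An object of class `count_track` with all-zero counts; fill via
#'   `set_track_counts()` or the simulators.
#' @export
count_track <- function(annotation, sample_id = "sample") {
  lens <- nchar(annotation$sequence)
  counts <- lapply(lens, function(L) {
    list(`+` = numeric(L), `-` = numeric(L))
  })
  structure(
    list(sample_id = sample_id, counts = counts, total_assigned = 0),
    class = "count_track"
  )
}

#' @export
print.count_track <- function(x, ...) {
  cat("<count_track> ", x$sample_id, ": total_assigned = ",
      format(x$total_assigned), "\n", sep = "")
  invisible(x)
}

#' Replace counts on one replicon/strand
#'
#' @param track A [count_track()].
#' @param replicon Replicon name.
#' @param strand "+" or "-".
#' @param values Numeric vector of the replicon's length, counts >= 0.
#' @return The updated track with `total_assigned` recomputed.
#' @export
set_track_counts <- function(track, replicon, strand, values) {
  if (any(values < 0)) abort("counts must be non-negative")
  if (length(values) != length(track$counts[[replicon]][[strand]])) {
    abort("values length does not match replicon length")
  }
  track$counts[[replicon]][[strand]] <- values
  track$total_assigned <- track_total(track)
  track
}

track_total <- function(track) {
  sum(vapply(track$counts, function(r) sum(r$`+`) + sum(r$`-`), numeric(1)))
}

#' Tidy view of a count track
#'
#' @param x A [count_track()].
#' @param ... Unused.
#' @param drop_zero Drop zero-count positions (default TRUE).
#' @return Tibble with `replicon`, `pos` (0-based), `strand`, `count`.
#' @importFrom tibble as_tibble
#' @exportS3Method tibble::as_tibble
as_tibble.count_track <- function(x, ..., drop_zero = TRUE) {
  rows <- purrr::imap(x$counts, function(str, rep) {
    purrr::imap(str, function(v, sname) {
      keep <- if (drop_zero) which(v != 0) else seq_along(v)
      tibble(replicon = rep, pos = keep - 1L, strand = sname, count = v[keep])
    }) %>% bind_rows()
  })
  bind_rows(rows)
}

#' Read a per-base count track from bedGraph
#'
#' One bedGraph file per strand (the format is unstranded). Intervals are
#' expanded to per-base counts; a `<prefix>.libsize` sidecar, when present,
#' overrides the library size with the sequenced total (per-base tracks alone
#' cannot reconstruct RPKM denominators once reads are filtered).
#'
#' @param plus_path bedGraph for "+" strand counts (0-based half-open, as the
#'   format specifies). `NULL` for none.
#' @param minus_path bedGraph for "-" strand counts. `NULL` for none.
#' @param annotation A [genome_annotation()].
#' @param sample_id Sample label.
#' @return A [count_track()].
#' @export
read_track <- function(plus_path, minus_path, annotation, sample_id = "sample") {
  track <- count_track(annotation, sample_id)
  load_one <- function(path, strand) {
    if (is.null(path)) return()
    info <- file.info(path)
    if (!is.na(info$size) && info$size == 0) return()
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0L) return()
    if (any(gr$score < 0)) abort("negative value in bedGraph")
    for (rep in unique(as.character(GenomicRanges::seqnames(gr)))) {
      if (!rep %in% names(track$counts)) {
        abort(paste0("bedGraph replicon not in annotation: ", rep))
      }
      sub <- gr[as.character(GenomicRanges::seqnames(gr)) == rep]
      L <- length(track$counts[[rep]][[strand]])
      if (max(GenomicRanges::end(sub)) > L) {
        abort("bedGraph interval beyond replicon bounds")
      }
      v <- track$counts[[rep]][[strand]]
      st <- GenomicRanges::start(sub) # 1-based after import of 0-based bedGraph
      en <- GenomicRanges::end(sub)
      for (k in seq_along(sub)) {
        v[st[k]:en[k]] <- v[st[k]:en[k]] + sub$score[k]
      }
      track$counts[[rep]][[strand]] <<- v
    }
  }
  load_one(plus_path, "+")
  load_one(minus_path, "-")
  track$total_assigned <- track_total(track)
  any_path <- plus_path %||% minus_path
  if (!is.null(any_path)) {
    sidecar <- paste0(sub("_(plus|minus)\\.bedGraph$", "", any_path), ".libsize")
    if (file.exists(sidecar)) {
      track$total_assigned <- as.numeric(readLines(sidecar)[1])
    }
  }
  track
}

#' Write a count track as per-strand bedGraph files
#'
#' Runs of equal counts are collapsed into intervals; zero positions are
#' omitted. A `<prefix>.libsize` sidecar records `total_assigned`.
#'
#' @param track A [count_track()].
#' @param prefix Output path prefix; writes `<prefix>_plus.bedGraph`,
#'   `<prefix>_minus.bedGraph` and `<prefix>.libsize`.
#' @return Invisibly, the paths written.
#' @export
write_track <- function(track, prefix) {
  paths <- c(plus = paste0(prefix, "_plus.bedGraph"),
             minus = paste0(prefix, "_minus.bedGraph"))
  for (strand in c("+", "-")) {
    path <- paths[[if (strand == "+") "plus" else "minus"]]
    grs <- list()
    for (rep in names(track$counts)) {
      v <- track$counts[[rep]][[strand]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values != 0
      if (any(keep)) {
        grs[[rep]] <- GenomicRanges::GRanges(
          seqnames = rep,
          ranges = IRanges::IRanges(start = starts[keep], end = ends[keep]),
          score = r$values[keep]
        )
      }
    }
    if (length(grs)) {
      rtracklayer::export(do.call(c, unname(grs)), path, format = "bedGraph")
    } else {
      file.create(path)
    }
  }
  writeLines(format(track$total_assigned, scientific = FALSE),
             paste0(prefix, ".libsize"))
  invisible(c(paths, libsize = paste0(prefix, ".libsize")))
}

#' Per-base profile of an ORF in transcript orientation
#'
#' @param track A [count_track()].
#' @param orf One row of the annotation's `orfs` tibble (or a list with
#'   `replicon`, `start`, `end`, `strand`).
#' @return Numeric vector of length `end - start`; element 1 is the first
#'   nucleotide of the start codon.
#' @export
orf_profile <- function(track, orf) {
  region_profile(track, orf$replicon, orf$start, orf$end, orf$strand)
}

#' Per-base profile of an arbitrary region in transcript orientation
#'
#' @param track A [count_track()].
#' @param replicon Replicon name.
#' @param start,end 0-based half-open coordinates.
#' @param strand "+" or "-" (profile reversed for "-").
#' @return Numeric vector of length `end - start`.
#' @export
region_profile <- function(track, replicon, start, end, strand = "+") {
  v <- track$counts[[replicon]][[strand]][(start + 1L):end]
  if (strand == "-") rev(v) else v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
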