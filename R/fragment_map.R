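#' In-silico restriction digestion of a genome
#'
#' Scans each chromosome for the recognition site of a restriction enzyme and
#' returns the resulting fragment map: ordered, non-overlapping fragments
#' that exactly tile `[0, chromosome length)` in 0-based half-open
#' coordinates. The default is HindIII (`AAGCTT`, cutting after the first
#' base: `A^AGCTT`). Matching is case-insensitive and ambiguous bases (`N`)
#' never match, so runs of unknown sequence are treated as uncuttable.
#'
#' @param genome a named character vector of sequences, a
#'   [Biostrings::DNAStringSet], or the path to a FASTA file.
#' @param site recognition sequence (A/C/G/T only).
#' @param cut_offset 0-based offset of the cut within the site
#'   (`1` for HindIII's `A^AGCTT`).
#'
#' @return A tibble with columns `chrom`, `start`, `end`, `index`
#'   (0-based ordinal along the chromosome) and `fragment_id`
#'   (`"<chrom>_<index>"`), carrying chromosome lengths in the
#'   `chrom_lengths` attribute.
#' @examples
#' digest_genome(c(chr = paste0(strrep("G", 20), "AAGCTT", strrep("G", 34))))
#' @export
digest_genome <- function(genome, site = "AAGCTT", cut_offset = 1) {
  seqs <- as_dna_set(genome)
  if (length(seqs) == 0) abort("empty sequence set")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "") ||
      anyDuplicated(names(seqs))) {
    abort("genome sequences must have unique non-empty names")
  }
  site <- toupper(site)
  if (!grepl("^[ACGT]+$", site)) abort("recognition site must contain only A, C, G, T")
  if (cut_offset < 0 || cut_offset > nchar(site)) {
    abort("cut_offset must lie within the recognition site")
  }
  maps <- purrr::map2(as.character(names(seqs)), as.list(seqs), function(nm, s) {
    len <- length(s)
    if (len < 1) abort(paste0("chromosome '", nm, "' has zero length"))
    hits <- Biostrings::matchPattern(site, s, fixed = TRUE)
    cuts <- BiocGenerics::start(hits) - 1L + as.integer(cut_offset)
    cuts <- cuts[cuts > 0 & cuts < len]
    bounds <- c(0L, sort(unique(cuts)), len)
    tibble(
      chrom = nm,
      start = bounds[-length(bounds)],
      end = bounds[-1],
      index = seq_len(length(bounds) - 1L) - 1L
    )
  })
  map <- dplyr::bind_rows(maps)
  map$fragment_id <- paste0(map$chrom, "_", map$index)
  attr(map, "chrom_lengths") <- setNames(
    vapply(as.list(seqs), length, integer(1)), names(seqs)
  )
  map
}

as_dna_set <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && is.null(names(genome)) &&
      file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome)) return(Biostrings::DNAStringSet(toupper(genome)))
  abort("genome must be a DNAStringSet, a named character vector, or a FASTA path")
}

#' Merge overlapping or bookended genomic intervals
#'
#' Interval union in the style of `bedtools merge`: intervals on the same
#' chromosome that overlap or touch end-to-start are collapsed, and labels of
#' merged inputs are concatenated (comma-separated, duplicates kept once).
#'
#' @param intervals tibble with `chrom`, `start`, `end` and optionally
#'   `label` (0-based half-open).
#' @return A tibble sorted by `(chrom, start)` with no two intervals on one
#'   chromosome overlapping or touching.
#' @examples
#' merge_intervals(tibble::tibble(chrom = "chr1", start = c(0, 5), end = c(10, 20)))
#' @export
merge_intervals <- function(intervals) {
  check_intervals(intervals)
  if (nrow(intervals) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  label = character()))
  }
  has_label <- "label" %in% names(intervals)
  if (!has_label) intervals$label <- NA_character_
  intervals |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      grp = cumsum(dplyr::lag(cummax(as.numeric(.data$end)),
                              default = -Inf) < .data$start)
    ) |>
    dplyr::group_by(.data$chrom, .data$grp) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      label = paste(unique(stats::na.omit(.data$label)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::mutate(label = dplyr::na_if(.data$label, "")) |>
    dplyr::select(!"grp") |>
    dplyr::arrange(.data$chrom, .data$start)
}

check_intervals <- function(intervals) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) && any(intervals$start >= intervals$end)) {
    abort("malformed interval: start must be < end")
  }
  invisible(intervals)
}

#' Fragments overlapping an interval
#'
#' Returns, in coordinate order, every restriction fragment sharing at least
#' one base with the half-open query interval. An interval ending exactly at
#' a fragment start does not overlap that fragment.
#'
#' @param map a fragment map from [digest_genome()].
#' @param chrom chromosome name (must exist in the map).
#' @param start,end 0-based half-open query coordinates.
#' @return The overlapping rows of `map`.
#' @export
fragments_overlapping <- function(map, chrom, start, end) {
  if (!chrom %in% map$chrom) abort(paste0("unknown chromosome: ", chrom))
  if (start >= end) abort("malformed interval: start must be < end")
  map |>
    dplyr::filter(.data$chrom == !!chrom, .data$start < !!end, .data$end > !!start) |>
    dplyr::arrange(.data$start)
}

fragment_midpoints <- function(map) {
  (map$start + map$end) / 2
}
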