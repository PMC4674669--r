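#' Read / write BED intervals
#'
#' BED3+ with 0-based half-open coordinates. Columns beyond the third are
#' read into `label` (column 4) and ignored otherwise. Malformed lines
#' (missing columns, non-integer coordinates, `start >= end`) raise an error
#' naming the offending line numbers.
#'
#' @param path file path.
#' @return tibble with `chrom`, `start`, `end` and (if present) `label`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    abort(paste0("BED line(s) with fewer than 3 columns: line ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    abort(paste0("non-integer coordinates at line ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  bad <- which(start >= end)
  if (length(bad)) {
    abort(paste0("start >= end at line ", paste(head(bad, 5), collapse = ", ")))
  }
  out <- tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = start,
    end = end
  )
  if (any(lengths(fields) >= 4)) {
    out$label <- vapply(fields, function(f) {
      if (length(f) >= 4) f[[4]] else NA_character_
    }, "")
  }
  out
}

#' @rdname read_bed
#' @param intervals tibble with `chrom`, `start`, `end` and optional further
#'   columns (written as BED columns 4+).
#' @export
write_bed <- function(intervals, path) {
  check_intervals(intervals)
  df <- as.data.frame(intervals)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Write a fragment map as BED4
#'
#' `chrom  start  end  fragment_id`.
#'
#' @param map fragment map from [digest_genome()].
#' @param path file path.
#' @export
write_fragment_map <- function(map, path) {
  write_bed(map[, c("chrom", "start", "end", "fragment_id")], path)
}

#' Read / write di-tag tables
#'
#' Two on-disk formats are supported. The fragment-id format is
#' `frag1_id  frag2_id  count` with an optional fourth `replicate` column;
#' [read_ditags()] reads it. The BEDPE-like format is
#' `chrom1 start1 end1 chrom2 start2 end2 count`;
#' [read_ditags_bedpe()] reads it, assigning each end to the fragment
#' containing its midpoint.
#'
#' @param path file path.
#' @param replicate replicate label applied when the file carries none.
#' @return tibble with `frag1_id`, `frag2_id`, `count`, `replicate`.
#' @export
read_ditags <- function(path, replicate = "rep1") {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  if (ncol(df) < 3) abort("di-tag file needs at least 3 columns")
  out <- tibble(
    frag1_id = as.character(df[[1]]),
    frag2_id = as.character(df[[2]]),
    count = as.integer(df[[3]]),
    replicate = if (ncol(df) >= 4) as.character(df[[4]]) else replicate
  )
  bad <- which(is.na(out$count) | out$count < 1)
  if (length(bad)) {
    abort(paste0("invalid count at line ", paste(head(bad, 5), collapse = ", ")))
  }
  out
}

#' @rdname read_ditags
#' @param map fragment map used to assign coordinates to fragments.
#' @export
read_ditags_bedpe <- function(path, map, replicate = "rep1") {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  if (ncol(df) < 7) abort("BEDPE di-tag file needs 7 columns")
  assign_end <- function(chrom, start, end) {
    mid <- (start + end) / 2
    purrr::map_chr(seq_along(chrom), function(i) {
      fr <- fragments_overlapping(map, chrom[i], floor(mid[i]),
                                  floor(mid[i]) + 1)
      if (nrow(fr) == 0) abort(paste0("coordinate outside fragment map: ",
                                      chrom[i], ":", mid[i]))
      fr$fragment_id[1]
    })
  }
  tibble(
    frag1_id = assign_end(as.character(df[[1]]), df[[2]], df[[3]]),
    frag2_id = assign_end(as.character(df[[4]]), df[[5]], df[[6]]),
    count = as.integer(df[[7]]),
    replicate = replicate
  )
}

#' @rdname read_ditags
#' @param ditags di-tag tibble.
#' @export
write_ditags <- function(ditags, path) {
  readr::write_tsv(
    as.data.frame(ditags[, c("frag1_id", "frag2_id", "count", "replicate")]),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Export calls as a WashU longrange track
#'
#' One line per call direction:
#' `chrom<TAB>start<TAB>end<TAB>mateChrom:mateStart-mateEnd,score` with
#' `score = -log10(q)` rounded to 2 decimals (capped at `score_cap` when
#' `q = 0`), sorted by coordinate. Both directions of each pair are emitted.
#'
#' @param calls tibble with `bait_id`, `prey_id`, `q_value`.
#' @param map fragment map giving fragment coordinates.
#' @param path output file.
#' @param score_cap maximum score.
#' @return `path`, invisibly.
#' @export
write_longrange <- function(calls, map, path, score_cap = 300) {
  if (nrow(calls) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  coords <- map[, c("fragment_id", "chrom", "start", "end")]
  j <- function(ids) {
    i <- match(ids, coords$fragment_id)
    if (anyNA(i)) abort("call references fragment ids absent from the map")
    coords[i, ]
  }
  a <- j(calls$bait_id)
  b <- j(calls$prey_id)
  score <- sprintf("%.2f", pmin(-log10(calls$q_value), score_cap))
  fmt <- function(x) sprintf("%.0f", x)
  fwd <- tibble(
    chrom = a$chrom, start = a$start, end = a$end,
    mate = paste0(b$chrom, ":", fmt(b$start), "-", fmt(b$end), ",", score)
  )
  rev <- tibble(
    chrom = b$chrom, start = b$start, end = b$end,
    mate = paste0(a$chrom, ":", fmt(a$start), "-", fmt(a$end), ",", score)
  )
  out <- dplyr::bind_rows(fwd, rev) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end, .data$mate)
  writeLines(paste(out$chrom, fmt(out$start), fmt(out$end), out$mate,
                   sep = "\t"), path)
  invisible(path)
}

#' @rdname write_longrange
#' @export
read_longrange <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  mate_chrom = character(), mate_start = integer(),
                  mate_end = integer(), score = double()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 4)) abort("malformed longrange line")
  mate <- vapply(fields, `[[`, "", 4)
  m <- regmatches(mate, regexec("^([^:]+):([0-9]+)-([0-9]+),([0-9.]+)$", mate))
  if (any(lengths(m) != 5)) abort("malformed longrange mate field")
  tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = as.integer(vapply(fields, `[[`, "", 2)),
    end = as.integer(vapply(fields, `[[`, "", 3)),
    mate_chrom = vapply(m, `[[`, "", 2),
    mate_start = as.integer(vapply(m, `[[`, "", 3)),
    mate_end = as.integer(vapply(m, `[[`, "", 4)),
    score = as.numeric(vapply(m, `[[`, "", 5))
  )
}
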