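#' Define region-capture target fragments
#'
#' Targets every restriction fragment overlapping each (pre-merged)
#' associated region. Where a region edge lies closer than `extension_gap`
#' (default 500 bp) to the nearest cut site of its first/last overlapping
#' fragment, the adjacent fragment is also targeted, so that the capturable
#' sequence flanking the region edge is not lost. Fragments already targeted
#' by a promoter design are excluded.
#'
#' @param regions tibble of merged associated regions (`chrom`, `start`,
#'   `end`, optional `label`).
#' @param map fragment map from [digest_genome()].
#' @param promoter_fragments character vector of fragment ids already
#'   targeted elsewhere; removed from the result.
#' @param extension_gap edge-to-cut-site distance (bp) below which the
#'   neighbouring fragment is added.
#' @return tibble with `fragment_id`, `source = "region"` and `labels`.
#' @export
define_region_targets <- function(regions, map, promoter_fragments = character(),
                                  extension_gap = 500) {
  check_intervals(regions)
  if (!"label" %in% names(regions)) regions$label <- NA_character_
  picked <- purrr::pmap(regions, function(chrom, start, end, label, ...) {
    frs <- fragments_overlapping(map, chrom, start, end)
    ids <- frs$fragment_id
    first <- frs[1, ]
    last <- frs[nrow(frs), ]
    if (start - first$start < extension_gap && first$index > 0) {
      ids <- c(paste0(chrom, "_", first$index - 1L), ids)
    }
    chrom_max <- max(map$index[map$chrom == chrom])
    if (last$end - end < extension_gap && last$index < chrom_max) {
      ids <- c(ids, paste0(chrom, "_", last$index + 1L))
    }
    tibble(fragment_id = ids, labels = label)
  })
  dplyr::bind_rows(picked) |>
    dplyr::filter(!.data$fragment_id %in% promoter_fragments) |>
    dplyr::group_by(.data$fragment_id) |>
    dplyr::summarise(
      source = "region",
      labels = paste(unique(stats::na.omit(.data$labels)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::mutate(labels = dplyr::na_if(.data$labels, ""))
}

#' Define promoter-capture target fragments
#'
#' Builds windows of `snp_window` (default 500 kb) up- and downstream of each
#' lead SNP, extends any window to the bounds of an associated region it
#' overlaps, merges the windows, and then targets every restriction fragment
#' within `tss_pad` (default 500 bp) of each transcription start site falling
#' inside a window. Overlapping targets are collapsed at the fragment level.
#'
#' @param lead_snps tibble with `chrom`, `pos` (0-based) and optional `label`.
#' @param regions tibble of associated regions used for window extension
#'   (may be empty).
#' @param tss tibble with `chrom`, `pos` and `gene`.
#' @param map fragment map.
#' @param snp_window half-width of the SNP window in bp.
#' @param tss_pad distance from the TSS within which fragments are targeted.
#' @return tibble with `fragment_id`, `source = "promoter"` and `labels`
#'   (gene names).
#' @export
define_promoter_targets <- function(lead_snps, regions, tss, map,
                                    snp_window = 5e5, tss_pad = 500) {
  stopifnot(all(c("chrom", "pos") %in% names(lead_snps)),
            all(c("chrom", "pos", "gene") %in% names(tss)))
  if (nrow(lead_snps) == 0) {
    return(tibble(fragment_id = character(), source = character(),
                  labels = character()))
  }
  windows <- tibble(
    chrom = lead_snps$chrom,
    start = pmax(lead_snps$pos - snp_window, 0),
    end = lead_snps$pos + snp_window
  )
  if (!is.null(regions) && nrow(regions)) {
    check_intervals(regions)
    windows <- purrr::pmap(windows, function(chrom, start, end) {
      hit <- regions$chrom == chrom & regions$start < end & regions$end > start
      if (any(hit)) {
        start <- min(start, regions$start[hit])
        end <- max(end, regions$end[hit])
      }
      tibble(chrom = chrom, start = start, end = end)
    }) |> dplyr::bind_rows()
  }
  windows <- merge_intervals(windows)
  in_window <- purrr::map_lgl(seq_len(nrow(tss)), function(i) {
    any(windows$chrom == tss$chrom[i] &
          windows$start <= tss$pos[i] & tss$pos[i] < windows$end)
  })
  tss_in <- tss[in_window, , drop = FALSE]
  if (nrow(tss_in) == 0) {
    return(tibble(fragment_id = character(), source = character(),
                  labels = character()))
  }
  picked <- purrr::map(seq_len(nrow(tss_in)), function(i) {
    # bases within tss_pad of the TSS: [pos - pad, pos + pad] inclusive
    frs <- fragments_overlapping(map, tss_in$chrom[i],
                                 max(tss_in$pos[i] - tss_pad, 0),
                                 tss_in$pos[i] + tss_pad + 1)
    tibble(fragment_id = frs$fragment_id, labels = tss_in$gene[i])
  })
  dplyr::bind_rows(picked) |>
    dplyr::group_by(.data$fragment_id) |>
    dplyr::summarise(
      source = "promoter",
      labels = paste(unique(stats::na.omit(.data$labels)), collapse = ","),
      .groups = "drop"
    )
}

#' Design capture oligos for one restriction fragment
#'
#' For each fragment end independently, 120-bp candidate windows are scanned
#' inward from the end in 1-bp steps; the first window whose
#' boundary-proximal edge lies within `window` bp of the fragment end and
#' which satisfies the GC and N constraints is chosen. Fragments shorter than
#' the oligo fail both ends; when both chosen oligos would overlap on a
#' fragment shorter than two oligo lengths, only the left oligo is emitted
#' and the fragment is captured at one end.
#'
#' @param fragment one-row tibble (`chrom`, `start`, `end`, `fragment_id`).
#' @param sequence the fragment's own sequence (length must equal
#'   `end - start`).
#' @param oligo_length,window,gc_min,gc_max,max_n design constraints: oligo
#'   size (bp), maximal distance of the proximal oligo edge from the fragment
#'   boundary (bp), inclusive GC-fraction bounds, and the maximal number of N
#'   bases allowed.
#' @return tibble of 0-2 baits (`fragment_id`, `fragment_end`, `chrom`,
#'   `start`, `end`, `gc_fraction`, `n_count`) with the fragment's
#'   `capture_status` (`both_ends`, `one_end` or `failed`) as an attribute.
#' @export
design_baits <- function(fragment, sequence, oligo_length = 120, window = 400,
                         gc_min = 0.25, gc_max = 0.65, max_n = 2) {
  stopifnot(nrow(fragment) == 1)
  len <- fragment$end - fragment$start
  if (nchar(sequence) != len) abort("sequence length does not match fragment length")
  empty <- tibble(
    fragment_id = character(), fragment_end = character(), chrom = character(),
    start = integer(), end = integer(), gc_fraction = double(), n_count = integer()
  )
  if (len < oligo_length) {
    attr(empty, "capture_status") <- "failed"
    return(empty)
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  is_gc <- cumsum(c(0L, chars %in% c("G", "C")))
  is_n <- cumsum(c(0L, !chars %in% c("A", "C", "G", "T")))
  window_stats <- function(off) { # 0-based window start within fragment
    gc <- (is_gc[off + oligo_length + 1L] - is_gc[off + 1L]) / oligo_length
    n <- is_n[off + oligo_length + 1L] - is_n[off + 1L]
    c(gc, n)
  }
  pick <- function(offsets) {
    for (off in offsets) {
      st <- window_stats(off)
      if (st[1] >= gc_min && st[1] <= gc_max && st[2] <= max_n) {
        return(list(off = off, gc = st[1], n = as.integer(st[2])))
      }
    }
    NULL
  }
  max_shift <- min(window, len - oligo_length)
  left <- pick(0:max_shift)
  right <- pick(len - oligo_length - (0:max_shift))
  oligo_row <- function(sel, side) {
    tibble(
      fragment_id = fragment$fragment_id, fragment_end = side,
      chrom = fragment$chrom,
      start = fragment$start + sel$off,
      end = fragment$start + sel$off + oligo_length,
      gc_fraction = sel$gc, n_count = sel$n
    )
  }
  baits <- list()
  if (!is.null(left)) baits <- c(baits, list(oligo_row(left, "left")))
  if (!is.null(right)) baits <- c(baits, list(oligo_row(right, "right")))
  if (length(baits) == 2 && len < 2 * oligo_length &&
      baits[[2]]$start < baits[[1]]$end) {
    baits <- baits[1]
  }
  out <- if (length(baits)) dplyr::bind_rows(baits) else empty
  attr(out, "capture_status") <-
    c("failed", "one_end", "both_ends")[nrow(out) + 1L]
  out
}

#' Design capture oligos for a set of target fragments
#'
#' Runs [design_baits()] over every targeted fragment, extracting fragment
#' sequences from the genome.
#'
#' @param targets tibble with `fragment_id` (e.g. from
#'   [define_region_targets()]).
#' @param map fragment map.
#' @param genome the digested genome (same object passed to
#'   [digest_genome()]).
#' @param ... constraint overrides passed to [design_baits()].
#' @return list with `baits` (all designed oligos) and `targets` (input plus
#'   `capture_status`).
#' @export
design_capture <- function(targets, map, genome, ...) {
  seqs <- as_dna_set(genome)
  frs <- dplyr::inner_join(map, targets["fragment_id"], by = "fragment_id")
  if (nrow(frs) < nrow(targets)) abort("some target fragment ids are not in the map")
  res <- purrr::map(seq_len(nrow(frs)), function(i) {
    fr <- frs[i, ]
    s <- as.character(Biostrings::subseq(seqs[[fr$chrom]], fr$start + 1L, fr$end))
    b <- design_baits(fr, s, ...)
    list(baits = b, status = attr(b, "capture_status"))
  })
  baits <- dplyr::bind_rows(purrr::map(res, "baits"))
  status <- tibble(
    fragment_id = frs$fragment_id,
    capture_status = purrr::map_chr(res, "status")
  )
  list(
    baits = baits,
    targets = dplyr::left_join(targets, status, by = "fragment_id")
  )
}

#' Summarise a capture design
#'
#' Computes the accounting identities of a bait design: total targeted
#' fragments, failures, one- vs both-end captures, the total captured bases
#' (`oligo_length * (2 * both + one)`), the genomic span of the captured
#' fragments and their mean size.
#'
#' @param targets tibble with `fragment_id` and `capture_status`.
#' @param map fragment map (used for the genomic span; optional).
#' @param oligo_length bait size in bp.
#' @return One-row tibble (see [design_summary()] for the column set).
#' @export
summarize_design <- function(targets, map = NULL, oligo_length = 120) {
  n_both <- sum(targets$capture_status == "both_ends")
  n_one <- sum(targets$capture_status == "one_end")
  n_failed <- sum(targets$capture_status == "failed")
  span <- NA_real_
  if (!is.null(map)) {
    captured <- targets$fragment_id[targets$capture_status != "failed"]
    frs <- map[map$fragment_id %in% captured, ]
    span <- sum(frs$end - frs$start)
  }
  design_summary(n_both, n_one, n_failed, genomic_span_bases = span,
                 oligo_length = oligo_length)
}

#' Design summary from capture counts
#'
#' The arithmetic core of [summarize_design()], usable directly from
#' published per-status counts.
#'
#' @param n_both,n_one,n_failed fragment counts by capture status.
#' @param genomic_span_bases total length (bp) of the captured fragments.
#' @param oligo_length bait size in bp.
#' @return One-row tibble with `n_fragments_total`, `n_failed`,
#'   `n_both_ends`, `n_one_end`, `n_captured`, `target_capture_bases`,
#'   `genomic_span_bases`, `mean_fragment_size`.
#' @examples
#' design_summary(n_both = 1096, n_one = 1035, n_failed = 1028,
#'                genomic_span_bases = 7.46e6)
#' @export
design_summary <- function(n_both, n_one, n_failed = 0,
                           genomic_span_bases = NA_real_, oligo_length = 120) {
  n_captured <- n_both + n_one
  tibble(
    n_fragments_total = n_both + n_one + n_failed,
    n_failed = n_failed,
    n_both_ends = n_both,
    n_one_end = n_one,
    n_captured = n_captured,
    target_capture_bases = oligo_length * (2 * n_both + n_one),
    genomic_span_bases = genomic_span_bases,
    mean_fragment_size = ifelse(n_captured > 0, genomic_span_bases / n_captured,
                                NA_real_)
  )
}
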