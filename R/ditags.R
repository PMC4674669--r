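#' Filter fragment-level di-tags
#'
#' Applies the pre-analysis filters: di-tags where neither end maps to a
#' baited fragment are removed as off-target; self-ligations are removed; and
#' cis di-tags whose fragment midpoints are separated by less than
#' `min_distance` (default 20 kb) are removed, since contact frequency below
#' that distance is dominated by polymer proximity rather than looping.
#' A per-rule removal tally is attached as the `filter_report` attribute
#' (see [filter_report()]).
#'
#' Filtering is a pure row predicate: it is order-independent and idempotent.
#'
#' @param ditags tibble with `frag1_id`, `frag2_id`, `count` and optionally
#'   `replicate`.
#' @param baited character vector of baited fragment ids.
#' @param map fragment map resolving every fragment id.
#' @param min_distance minimum retained cis midpoint distance in bp.
#' @return The retained di-tags, with ends reordered so `frag1_id` precedes
#'   `frag2_id` in genome order.
#' @export
filter_ditags <- function(ditags, baited, map, min_distance = 20000) {
  d <- normalize_ditags(ditags, map)
  off_target <- !(d$frag1_id %in% baited | d$frag2_id %in% baited)
  self_lig <- d$frag1_id == d$frag2_id
  short_cis <- !is.na(d$distance) & d$distance < min_distance
  keep <- !(off_target | self_lig | short_cis)
  report <- tibble(
    rule = c("off_target", "self_ligation", paste0("cis_lt_", min_distance),
             "retained"),
    ditags = c(sum(off_target), sum(self_lig & !off_target),
               sum(short_cis & !off_target & !self_lig), sum(keep))
  )
  out <- d[keep, , drop = FALSE]
  attr(out, "filter_report") <- report
  out
}

#' @rdname filter_ditags
#' @param filtered the result of `filter_ditags()`.
#' @export
filter_report <- function(filtered) {
  attr(filtered, "filter_report")
}

# Resolve fragment ids against the map, order each pair by genome position
# and annotate chromosome/midpoint/distance columns.
normalize_ditags <- function(ditags, map) {
  stopifnot(all(c("frag1_id", "frag2_id", "count") %in% names(ditags)))
  if (!"replicate" %in% names(ditags)) ditags$replicate <- "rep1"
  idx <- setNames(seq_len(nrow(map)), map$fragment_id)
  i1 <- idx[ditags$frag1_id]
  i2 <- idx[ditags$frag2_id]
  if (anyNA(i1) || anyNA(i2)) {
    bad <- unique(c(ditags$frag1_id[is.na(i1)], ditags$frag2_id[is.na(i2)]))
    abort(paste0("unknown fragment id(s): ", paste(head(bad, 5), collapse = ", ")))
  }
  swap <- i1 > i2
  a <- ifelse(swap, i2, i1)
  b <- ifelse(swap, i1, i2)
  mids <- fragment_midpoints(map)
  tibble(
    frag1_id = map$fragment_id[a],
    frag2_id = map$fragment_id[b],
    chrom1 = map$chrom[a],
    chrom2 = map$chrom[b],
    distance = ifelse(map$chrom[a] == map$chrom[b], abs(mids[b] - mids[a]),
                      NA_real_),
    replicate = ditags$replicate,
    count = ditags$count
  )
}

#' Classify di-tags into ligation categories
#'
#' Assigns each retained di-tag to exactly one of the four ligation
#' categories: `trans` (ends on different chromosomes, whether one or both
#' ends are baited), `cis_double` (both ends baited, same chromosome),
#' `cis_single_le5Mb` and `cis_single_gt5Mb` (one end baited, split at the
#' `cis_limit`, with the boundary case assigned to the near class).
#'
#' @param ditags filtered di-tags from [filter_ditags()].
#' @param baited baited fragment ids.
#' @param map fragment map.
#' @param cis_limit distance (bp) separating the two single-baited cis
#'   classes.
#' @return The input with a `category` column added.
#' @export
classify_ditags <- function(ditags, baited, map, cis_limit = 5e6) {
  d <- if (!"distance" %in% names(ditags)) normalize_ditags(ditags, map) else ditags
  b1 <- d$frag1_id %in% baited
  b2 <- d$frag2_id %in% baited
  d$category <- dplyr::case_when(
    d$chrom1 != d$chrom2 ~ "trans",
    b1 & b2 ~ "cis_double",
    d$distance <= cis_limit ~ "cis_single_le5Mb",
    TRUE ~ "cis_single_gt5Mb"
  )
  d
}

#' Aggregate di-tags to pair counts and per-fragment totals
#'
#' Collapses classified di-tags to one row per (bait, prey, replicate) with
#' summed counts, and tallies per-baited-fragment totals: all di-tags
#' involving the fragment and, separately, its trans di-tags (the raw
#' material of the interactability estimate). For double-baited pairs the
#' lower-coordinate end is reported as the bait; a trans di-tag between two
#' baited fragments contributes to both fragments' trans totals.
#'
#' @param ditags classified di-tags from [classify_ditags()].
#' @param baited baited fragment ids.
#' @return list with `pairs` (bait_id, prey_id, distance, category,
#'   replicate, count) and `fragments` (fragment_id, total_count,
#'   trans_count), pooled over replicates.
#' @export
aggregate_counts <- function(ditags, baited) {
  stopifnot("category" %in% names(ditags))
  b1 <- ditags$frag1_id %in% baited
  b2 <- ditags$frag2_id %in% baited
  bait_id <- ifelse(b1, ditags$frag1_id, ditags$frag2_id)
  prey_id <- ifelse(b1, ditags$frag2_id, ditags$frag1_id)
  key <- paste(bait_id, prey_id, ditags$replicate)
  first <- !duplicated(key)
  sums <- rowsum(ditags$count, key)
  pairs <- tibble(
    bait_id = bait_id[first],
    prey_id = prey_id[first],
    distance = ditags$distance[first],
    category = ditags$category[first],
    replicate = ditags$replicate[first],
    count = as.vector(sums[match(key[first], rownames(sums)), ])
  ) |>
    dplyr::arrange(.data$bait_id, .data$prey_id, .data$replicate)
  end_id <- c(ditags$frag1_id, ditags$frag2_id)
  end_count <- rep(ditags$count, 2)
  end_trans <- rep(ditags$category == "trans", 2)
  keep <- end_id %in% baited
  tot <- rowsum(end_count[keep], end_id[keep])
  trn <- rowsum(end_count[keep] * end_trans[keep], end_id[keep])
  fragments <- tibble(
    fragment_id = rownames(tot),
    total_count = as.vector(tot),
    trans_count = as.vector(trn)
  )
  missing <- setdiff(baited, fragments$fragment_id)
  if (length(missing)) {
    fragments <- dplyr::bind_rows(
      fragments,
      tibble(fragment_id = missing, total_count = 0, trans_count = 0)
    )
  }
  list(pairs = pairs, fragments = fragments)
}

#' Combine replicate pair counts
#'
#' Sums counts across replicates per (bait, prey) pair. Pairs observed in
#' only one replicate keep their count and are flagged; optionally they can
#' be dropped entirely.
#'
#' @param pairs pair counts from [aggregate_counts()] (with a `replicate`
#'   column).
#' @param require_both drop pairs seen in fewer than two replicates.
#' @return tibble with summed `count`, `n_replicates` and
#'   `single_replicate` flag.
#' @export
combine_replicates <- function(pairs, require_both = FALSE) {
  key <- paste(pairs$bait_id, pairs$prey_id)
  first <- !duplicated(key)
  sums <- rowsum(pairs$count, key)
  nrep <- rowsum(as.integer(!duplicated(paste(key, pairs$replicate))), key)
  ord <- match(key[first], rownames(sums))
  out <- tibble(
    bait_id = pairs$bait_id[first],
    prey_id = pairs$prey_id[first],
    distance = pairs$distance[first],
    category = pairs$category[first],
    count = as.vector(sums[ord, ]),
    n_replicates = as.vector(nrep[ord, ])
  ) |>
    dplyr::mutate(single_replicate = .data$n_replicates < 2) |>
    dplyr::arrange(.data$bait_id, .data$prey_id)
  if (require_both) out <- dplyr::filter(out, !.data$single_replicate)
  out
}
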