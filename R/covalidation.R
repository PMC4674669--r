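#' Reciprocal matching of region- and promoter-capture calls
#'
#' A region-capture call is *validatable* when its prey fragment is targeted
#' in the promoter design, so that the same contact could have been observed
#' from the other side. A validatable call is *matched* when the promoter
#' experiment calls the identical fragment pair with bait and prey roles
#' swapped (promoter bait = region prey and promoter prey = region bait).
#' Matching is exact at the restriction-fragment level by default; `slack`
#' allows the promoter-side fragments to differ by up to that many fragment
#' indices.
#'
#' @param region_calls,promoter_calls tibbles with `bait_id`, `prey_id`
#'   (typically [significant_calls()] output).
#' @param promoter_targeted promoter-design fragment ids.
#' @param slack fragment-index slack for matching (0 = exact).
#' @return The validatable region calls with a `matched` flag.
#' @export
reciprocal_match <- function(region_calls, promoter_calls, promoter_targeted,
                             slack = 0) {
  validatable <- dplyr::filter(region_calls,
                               .data$prey_id %in% promoter_targeted)
  if (slack == 0) {
    keys <- paste(promoter_calls$bait_id, promoter_calls$prey_id)
    validatable$matched <-
      paste(validatable$prey_id, validatable$bait_id) %in% keys
  } else {
    validatable$matched <- purrr::map2_lgl(
      validatable$prey_id, validatable$bait_id,
      function(b, p) any(id_near(promoter_calls$bait_id, b, slack) &
                           id_near(promoter_calls$prey_id, p, slack))
    )
  }
  validatable
}

id_near <- function(ids, target, slack) {
  split_t <- split_fragment_id(target)
  split_i <- split_fragment_id(ids)
  split_i$chrom == split_t$chrom & abs(split_i$index - split_t$index) <= slack
}

split_fragment_id <- function(id) {
  m <- regmatches(id, regexpr("_[0-9]+$", id))
  list(chrom = sub("_[0-9]+$", "", id), index = as.integer(sub("_", "", m)))
}

#' Cross-experiment enrichment grid X\[i, j\]
#'
#' Quantifies whether interactions called in both capture experiments are
#' enriched as FDR thresholds tighten. Conditioning on the validatable region
#' calls at the reference FDR (default 20%), the statistic is
#' \deqn{X[i,j] = \frac{P(\mathrm{region}\ q \le i \wedge \mathrm{promoter\
#' match}\ q \le j \mid \mathrm{region}\ q \le \mathrm{ref})}
#' {P(\mathrm{region}\ q \le i \mid \mathrm{region}\ q \le \mathrm{ref})}}
#' estimated by empirical proportions: among region calls at FDR `i`, the
#' fraction reciprocally called in the promoter experiment at FDR `j`.
#' Values near the promoter call rate indicate independence; values rising as
#' `i` tightens indicate shared true interactions.
#'
#' @param region_tests,promoter_tests full test tables (with `q_value`) from
#'   [call_interactions()].
#' @param promoter_targeted promoter-design fragment ids (defines the
#'   validatable set).
#' @param i_grid,j_grid FDR thresholds for the region (rows) and promoter
#'   (columns) experiments; `i_grid` must not exceed `reference_fdr`.
#' @param reference_fdr region-side conditioning threshold.
#' @return tibble of class `chic_enrichment`: `i`, `j`, `x`, `n_region`
#'   (denominator count), `n_matched` (numerator count). Plot with
#'   [autoplot()].
#' @export
enrichment_grid <- function(region_tests, promoter_tests, promoter_targeted,
                            i_grid = c(0.01, 0.05, 0.10, 0.20),
                            j_grid = c(0.01, 0.05, 0.10, 0.20),
                            reference_fdr = 0.20) {
  stopifnot(all(i_grid <= reference_fdr))
  s <- region_tests |>
    dplyr::filter(.data$q_value <= reference_fdr,
                  .data$prey_id %in% promoter_targeted)
  if (nrow(s) == 0) abort("empty conditioning set at the reference FDR")
  # best promoter q-value of the role-swapped pair, Inf if never tested
  pq <- promoter_tests |>
    dplyr::group_by(key = paste(.data$bait_id, .data$prey_id)) |>
    dplyr::summarise(q = min(.data$q_value), .groups = "drop")
  match_q <- setNames(pq$q, pq$key)[paste(s$prey_id, s$bait_id)]
  match_q[is.na(match_q)] <- Inf
  grid <- tidyr::expand_grid(i = sort(i_grid), j = sort(j_grid))
  out <- grid |>
    dplyr::mutate(
      n_region = purrr::map_int(.data$i, ~ sum(s$q_value <= .x)),
      n_matched = purrr::map2_int(.data$i, .data$j,
                                  ~ sum(s$q_value <= .x & match_q <= .y)),
      x = ifelse(.data$n_region > 0, .data$n_matched / .data$n_region,
                 NA_real_)
    )
  class(out) <- c("chic_enrichment", class(out))
  attr(out, "reference_fdr") <- reference_fdr
  out
}

#' Cell-line sharing of called interactions
#'
#' Fragment-level overlap between the significant calls of two cell lines
#' from the same capture design.
#'
#' @param calls_a,calls_b significant-call tibbles with `bait_id`, `prey_id`.
#' @return one-row tibble with the pair counts, the shared count, the
#'   Jaccard fraction `shared / union` and per-cell shared fractions.
#' @export
cell_overlap <- function(calls_a, calls_b) {
  key <- function(x) unique(paste(pmin(x$bait_id, x$prey_id),
                                  pmax(x$bait_id, x$prey_id)))
  a <- key(calls_a)
  b <- key(calls_b)
  shared <- length(intersect(a, b))
  uni <- length(union(a, b))
  tibble(
    n_a = length(a), n_b = length(b), n_shared = shared, n_union = uni,
    fraction_union = ifelse(uni > 0, shared / uni, NA_real_),
    fraction_a = ifelse(length(a) > 0, shared / length(a), NA_real_),
    fraction_b = ifelse(length(b) > 0, shared / length(b), NA_real_)
  )
}
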