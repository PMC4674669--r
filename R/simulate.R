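#' Simulation parameters
#'
#' Study conditions for the synthetic Capture Hi-C generator. Defaults mirror
#' the assay the pipeline targets: HindIII-scale fragments (mean 3.5 kb),
#' lognormal per-fragment interactability, a bimodal trans-count structure
#' (30% noise fragments with mean 100 pooled trans di-tags vs signal
#' fragments with mean 5,000; a fragment's capture efficiency scales its cis
#' and trans propensity consistently, so noise fragments are weak
#' everywhere), power-law cis distance decay anchored at the 20-kb filter
#' boundary, negative binomial pair counts of size 5, two independent
#' replicates and a deep-capture count scale (expected 1,000 di-tags per
#' replicate for a unit-interactability pair at 20 kb).
#'
#' @param seed integer seed; all randomness of [simulate_design()] and
#'   [simulate_counts()] derives from it.
#' @param n_chromosomes,fragments_per_chromosome genome shape.
#' @param mean_fragment_size,min_fragment_size fragment-length distribution
#'   (shifted exponential), bp.
#' @param n_region_baits,n_promoter_baits sizes of the two disjoint bait
#'   sets.
#' @param preys_per_bait cis preys sampled per bait, log-uniform in distance
#'   over the tested range.
#' @param decay_exponent power-law exponent `alpha` of the distance decay.
#' @param library_scale expected count per replicate at `min_distance` for a
#'   unit-interactability pair.
#' @param interactability_sigma lognormal SD (log scale) of per-fragment
#'   interactability.
#' @param nb_dispersion NB size of pair counts.
#' @param noise_fragment_fraction fraction of baited fragments whose trans
#'   profile is pure noise.
#' @param noise_trans_mean,signal_trans_mean pooled (two-replicate) expected
#'   trans totals of the two fragment classes.
#' @param noise_trans_dispersion NB size of noise-fragment trans totals.
#' @param trans_partners number of trans partner fragments over which each
#'   fragment's trans total is spread.
#' @param n_loops,loop_fold spiked true loops between region and promoter
#'   baits: count and fold-change(s) `phi >= 1` (recycled over loops).
#' @param min_distance,cis_limit tested distance range, bp.
#' @return list of class `chic_sim_params`.
#' @export
sim_params <- function(seed = 1,
                       n_chromosomes = 4,
                       fragments_per_chromosome = 1250,
                       mean_fragment_size = 3500,
                       min_fragment_size = 150,
                       n_region_baits = 2000,
                       n_promoter_baits = 1000,
                       preys_per_bait = 25,
                       decay_exponent = 1,
                       library_scale = 1000,
                       interactability_sigma = 0.35,
                       nb_dispersion = 5,
                       noise_fragment_fraction = 0.3,
                       noise_trans_mean = 100,
                       signal_trans_mean = 5000,
                       noise_trans_dispersion = 2,
                       trans_partners = 20,
                       n_loops = 50,
                       loop_fold = 8,
                       min_distance = 20000,
                       cis_limit = 5e6) {
  p <- as.list(environment())
  stopifnot(
    p$seed == round(p$seed),
    p$n_chromosomes >= 1, p$fragments_per_chromosome >= 1,
    p$mean_fragment_size > p$min_fragment_size, p$min_fragment_size >= 1,
    p$decay_exponent > 0, p$library_scale > 0, p$interactability_sigma >= 0,
    p$nb_dispersion > 0, p$noise_fragment_fraction >= 0,
    p$noise_fragment_fraction < 1,
    p$noise_trans_mean > 0, p$signal_trans_mean > 0,
    all(p$loop_fold >= 1), p$min_distance > 0, p$cis_limit > p$min_distance
  )
  structure(p, class = "chic_sim_params")
}

#' Simulate a fragment map and paired capture designs
#'
#' Draws fragment lengths from a shifted exponential (mimicking restriction
#' fragment size dispersion), tiles them into chromosomes, and selects two
#' disjoint bait sets — region-capture and promoter-capture targets — so
#' that loops spiked between them by [simulate_counts()] are reciprocally
#' observable.
#'
#' @param params a [sim_params()] list.
#' @return list of class `chic_sim_design` with `map`, `region_targets`,
#'   `promoter_targets`, `params`.
#' @export
simulate_design <- function(params = sim_params()) {
  stopifnot(inherits(params, "chic_sim_params"))
  set.seed(params$seed)
  n <- params$fragments_per_chromosome
  maps <- purrr::map(seq_len(params$n_chromosomes), function(ci) {
    lens <- params$min_fragment_size +
      round(stats::rexp(n, 1 / (params$mean_fragment_size -
                                  params$min_fragment_size)))
    ends <- cumsum(lens)
    tibble(
      chrom = paste0("chr", ci),
      start = c(0, head(ends, -1)),
      end = ends,
      index = seq_len(n) - 1L
    )
  })
  map <- dplyr::bind_rows(maps)
  map$fragment_id <- paste0(map$chrom, "_", map$index)
  attr(map, "chrom_lengths") <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$end)) |>
    (\(d) setNames(d$len, d$chrom))()
  n_total <- nrow(map)
  if (params$n_region_baits + params$n_promoter_baits >= n_total) {
    abort("bait sets must leave some fragments unbaited (trans partners)")
  }
  region_ids <- sort(sample(map$fragment_id, params$n_region_baits))
  promoter_ids <- sort(sample(setdiff(map$fragment_id, region_ids),
                              params$n_promoter_baits))
  structure(
    list(
      map = map,
      region_targets = tibble(fragment_id = region_ids, source = "region"),
      promoter_targets = tibble(fragment_id = promoter_ids,
                                source = "promoter"),
      params = params
    ),
    class = "chic_sim_design"
  )
}

#' Simulate replicate di-tag tables with known ground truth
#'
#' For each experiment (region and promoter capture), every bait receives
#' `preys_per_bait` cis preys at log-uniform distances within the tested
#' range; the expected count of a pair per replicate is
#' \deqn{\mu = s\,\iota_{bait}\,\iota_{prey}^{[baited]}\,(d/d_{min})^{-\alpha}\,\phi}
#' where interactability multiplies only captured ends (the other end's
#' interactability is observable only when it is itself baited, exactly as in
#' the downstream regression), and `phi` is the spiked loop fold (1
#' otherwise). Counts are drawn independently per replicate from a negative
#' binomial; only non-zero counts become di-tags. Loops are spiked between
#' signal-class region and promoter baits (a loop on a pure-noise fragment
#' would be unobservable by construction) and injected into both
#' experiments with roles swapped.
#'
#' Trans totals are drawn per baited fragment — Poisson around
#' `interactability * signal_trans_mean` for signal fragments, negative
#' binomial with mean `noise_trans_mean` for noise fragments — and spread
#' over `trans_partners` non-baited fragments on other chromosomes.
#'
#' @param design a [simulate_design()] result.
#' @param params a [sim_params()] list (defaults to the design's own).
#' @return list of class `chic_sim`: `ditags` (tibble with `experiment`,
#'   `replicate`, `frag1_id`, `frag2_id`, `count`), `truth` (list with
#'   `pairs` — per-pair expectation, loop membership, fold — and
#'   `fragments` — interactability and noise/signal class) and `params`.
#' @export
simulate_counts <- function(design, params = design$params) {
  stopifnot(inherits(design, "chic_sim_design"),
            inherits(params, "chic_sim_params"))
  set.seed(params$seed + 1L)
  map <- design$map
  mids <- setNames(fragment_midpoints(map), map$fragment_id)
  chrom_of <- setNames(map$chrom, map$fragment_id)
  baited <- list(region = design$region_targets$fragment_id,
                 promoter = design$promoter_targets$fragment_id)
  all_baited <- c(baited$region, baited$promoter)

  frag_truth <- tibble(
    fragment_id = all_baited,
    design = rep(c("region", "promoter"),
                 c(length(baited$region), length(baited$promoter))),
    interactability = rlnorm(length(all_baited),
                             -params$interactability_sigma^2 / 2,
                             params$interactability_sigma),
    class = ifelse(runif(length(all_baited)) < params$noise_fragment_fraction,
                   "noise", "signal")
  )
  # capture efficiency drives cis AND trans propensity consistently: a
  # noise-class fragment interacts poorly everywhere, which is why its trans
  # total sits in the low mode
  frag_truth$efficiency <- frag_truth$interactability *
    ifelse(frag_truth$class == "noise",
           params$noise_trans_mean / params$signal_trans_mean, 1)
  iota <- setNames(frag_truth$efficiency, frag_truth$fragment_id)

  loops <- sample_loops(frag_truth, mids, chrom_of, params)

  cis <- purrr::map(names(baited)[lengths(baited) > 0], function(exp_name) {
    grid <- sample_prey_grid(baited[[exp_name]], map, mids, chrom_of, params)
    # a double-baited contact can be drawn from either side; it is one
    # physical pair, so keep a single draw per unordered pair
    unordered <- paste(pmin(grid$bait_id, grid$prey_id),
                       pmax(grid$bait_id, grid$prey_id))
    grid <- grid[!duplicated(unordered), , drop = FALSE]
    exp_loops <- if (exp_name == "region") {
      loops
    } else {
      tibble(bait_id = loops$prey_id, prey_id = loops$bait_id,
             fold = loops$fold)
    }
    if (nrow(exp_loops)) {
      grid <- grid |>
        dplyr::anti_join(exp_loops, by = c("bait_id", "prey_id")) |>
        dplyr::bind_rows(
          tibble(bait_id = exp_loops$bait_id, prey_id = exp_loops$prey_id,
                 distance = unname(abs(mids[exp_loops$prey_id] -
                                         mids[exp_loops$bait_id])),
                 fold = exp_loops$fold, is_loop = TRUE)
        )
    }
    grid$experiment <- exp_name
    grid$distance <- unname(grid$distance)
    prey_baited <- grid$prey_id %in% baited[[exp_name]]
    grid$mu <- unname(
      params$library_scale * iota[grid$bait_id] *
        ifelse(prey_baited, iota[grid$prey_id], 1) *
        (grid$distance / params$min_distance)^(-params$decay_exponent) *
        grid$fold
    )
    grid
  }) |> dplyr::bind_rows()

  cis_ditags <- purrr::map(c("rep1", "rep2"), function(r) {
    y <- rnbinom(nrow(cis), mu = cis$mu, size = params$nb_dispersion)
    keep <- y >= 1
    tibble(
      experiment = cis$experiment[keep],
      replicate = r,
      frag1_id = cis$bait_id[keep],
      frag2_id = cis$prey_id[keep],
      count = y[keep]
    )
  }) |> dplyr::bind_rows()

  trans_ditags <- simulate_trans(frag_truth, map, chrom_of, all_baited, params)

  structure(
    list(
      ditags = dplyr::bind_rows(cis_ditags, trans_ditags),
      truth = list(pairs = cis, fragments = frag_truth),
      params = params
    ),
    class = "chic_sim"
  )
}

# Spiked loops between signal-class region and promoter baits on the same
# chromosome at a testable distance.
sample_loops <- function(frag_truth, mids, chrom_of, params) {
  empty <- tibble(bait_id = character(), prey_id = character(),
                  fold = double())
  if (params$n_loops == 0) return(empty)
  rb <- frag_truth |>
    dplyr::filter(.data$design == "region", .data$class == "signal")
  pb <- frag_truth |>
    dplyr::filter(.data$design == "promoter", .data$class == "signal")
  cand <- dplyr::inner_join(
    tibble(bait_id = rb$fragment_id, chrom = chrom_of[rb$fragment_id]),
    tibble(prey_id = pb$fragment_id, chrom = chrom_of[pb$fragment_id]),
    by = "chrom", relationship = "many-to-many"
  ) |>
    dplyr::mutate(distance = abs(mids[.data$prey_id] - mids[.data$bait_id])) |>
    dplyr::filter(.data$distance >= params$min_distance,
                  .data$distance <= params$cis_limit)
  if (nrow(cand) < params$n_loops) {
    abort("not enough candidate fragment pairs for the requested loops")
  }
  picked <- cand[sample(nrow(cand), params$n_loops), ]
  tibble(
    bait_id = picked$bait_id,
    prey_id = picked$prey_id,
    fold = rep_len(params$loop_fold, params$n_loops)
  )
}

# For each bait, preys at log-uniform target distances snapped to the
# nearest fragment midpoint on the same chromosome.
sample_prey_grid <- function(bait_ids, map, mids, chrom_of, params) {
  k <- params$preys_per_bait
  by_chrom <- split(bait_ids, chrom_of[bait_ids])
  purrr::imap(by_chrom, function(ids, chrom) {
    cmids <- mids[names(chrom_of)[chrom_of == chrom]]
    n <- length(ids) * k
    bait_mid <- rep(mids[ids], each = k)
    d <- exp(runif(n, log(params$min_distance * 1.25), log(params$cis_limit)))
    pos <- bait_mid + d * sample(c(-1, 1), n, replace = TRUE)
    idx <- findInterval(pos, cmids)
    idx_up <- pmin(idx + 1L, length(cmids))
    idx <- pmax(idx, 1L)
    snapped <- ifelse(abs(cmids[idx] - pos) <= abs(cmids[idx_up] - pos),
                      idx, idx_up)
    tibble(
      bait_id = rep(ids, each = k),
      prey_id = names(cmids)[snapped],
      distance = unname(abs(cmids[snapped] - bait_mid))
    ) |>
      dplyr::filter(.data$prey_id != .data$bait_id,
                    .data$distance >= params$min_distance,
                    .data$distance <= params$cis_limit) |>
      dplyr::distinct(.data$bait_id, .data$prey_id, .keep_all = TRUE) |>
      dplyr::mutate(fold = 1, is_loop = FALSE)
  }) |> dplyr::bind_rows()
}

# Bimodal per-fragment trans totals spread over non-baited partner fragments
# on other chromosomes, drawn independently per replicate. Per-partner counts
# are drawn directly (Poisson for signal, NB with size split across partners
# for noise), so per-fragment totals follow exactly the intended marginal.
simulate_trans <- function(frag_truth, map, chrom_of, all_baited, params) {
  pool <- map$fragment_id[!map$fragment_id %in% all_baited]
  pool_chrom <- chrom_of[pool]
  k <- params$trans_partners
  frag_chrom <- chrom_of[frag_truth$fragment_id]
  rows <- purrr::map(unique(frag_chrom), function(cc) {
    frs <- frag_truth[frag_chrom == cc, , drop = FALSE]
    comp <- pool[pool_chrom != cc]
    if (length(comp) == 0) abort("no trans partner fragments available")
    n_rows <- nrow(frs) * k * 2
    d <- tibble(
      experiment = rep(frs$design, each = 2 * k),
      fragment_id = rep(frs$fragment_id, each = 2 * k),
      class = rep(frs$class, each = 2 * k),
      iota = rep(frs$interactability, each = 2 * k),
      replicate = rep(rep(c("rep1", "rep2"), each = k), nrow(frs)),
      frag2_id = sample(comp, n_rows, replace = TRUE)
    )
    sig <- d$class == "signal"
    d$count <- 0L
    # signal fragments: conditionally Poisson trans totals around
    # efficiency * signal mean (deep-sequencing regime); noise fragments:
    # overdispersed junk around efficiency * signal mean = iota * noise mean
    d$count[sig] <- rpois(sum(sig),
                          d$iota[sig] * params$signal_trans_mean / (2 * k))
    d$count[!sig] <- rnbinom(sum(!sig),
                             mu = d$iota[!sig] * params$noise_trans_mean /
                               (2 * k),
                             size = params$noise_trans_dispersion / k)
    d[d$count >= 1, c("experiment", "replicate", "fragment_id", "frag2_id",
                      "count")]
  })
  dplyr::bind_rows(rows) |>
    dplyr::rename(frag1_id = "fragment_id") |>
    dplyr::filter(.data$frag1_id != .data$frag2_id)
}

#' Simulate a complete synthetic experiment
#'
#' Runs [simulate_design()] then [simulate_counts()].
#'
#' @param params a [sim_params()] list.
#' @return list with `design`, `ditags`, `truth`, `params`.
#' @export
simulate_chic <- function(params = sim_params()) {
  design <- simulate_design(params)
  sim <- simulate_counts(design, params)
  list(design = design, ditags = sim$ditags, truth = sim$truth,
       params = params)
}

#' Evaluate interaction calls against simulation ground truth
#'
#' @param calls a `chic_calls` object or a tests tibble with `significant`.
#' @param truth the `truth` element of a [simulate_counts()] result.
#' @param experiment which experiment's truth to evaluate against; defaults
#'   to the calls' own label.
#' @return list with `summary` (one row: `n_loops`, `n_called`,
#'   `n_true_called`, `sensitivity`, `fdp`, `fdp_defined`), `power`
#'   (per-fold detection rates, both unconditional and among testable loops
#'   whose fragments survived the noise filter) and `power_distance`
#'   (detection by distance stratum).
#' @export
evaluate_calls <- function(calls, truth, experiment = NULL) {
  tests <- if (inherits(calls, "chic_calls")) calls$tests else calls
  if (is.null(experiment)) {
    experiment <- if (inherits(calls, "chic_calls")) calls$experiment
    else unique(tests$experiment)
  }
  pair_key <- function(b, p) paste(pmin(b, p), pmax(b, p))
  loops <- truth$pairs |>
    dplyr::filter(.data$is_loop, .data$experiment == !!experiment)
  called <- dplyr::filter(tests, .data$significant)
  called_keys <- unique(pair_key(called$bait_id, called$prey_id))
  loop_keys <- pair_key(loops$bait_id, loops$prey_id)
  n_true_called <- sum(loop_keys %in% called_keys)
  n_false_called <- length(setdiff(called_keys, loop_keys))
  summary <- tibble(
    n_loops = nrow(loops),
    n_called = length(called_keys),
    n_true_called = n_true_called,
    sensitivity = ifelse(nrow(loops) > 0, n_true_called / nrow(loops),
                         NA_real_),
    fdp = ifelse(length(called_keys) > 0,
                 n_false_called / length(called_keys), 0),
    fdp_defined = length(called_keys) > 0
  )
  tested_keys <- unique(pair_key(tests$bait_id, tests$prey_id))
  power <- loops |>
    dplyr::mutate(
      detected = loop_keys %in% called_keys,
      # a loop whose fragments fell below the noise threshold never reaches
      # the test stage; power_testable conditions on assay observability
      testable = loop_keys %in% tested_keys
    ) |>
    dplyr::group_by(fold = .data$fold) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_testable = sum(.data$testable),
      n_detected = sum(.data$detected),
      power = mean(.data$detected),
      power_testable = ifelse(sum(.data$testable) > 0,
                              sum(.data$detected) / sum(.data$testable),
                              NA_real_),
      .groups = "drop"
    )
  power_distance <- loops |>
    dplyr::mutate(
      detected = loop_keys %in% called_keys,
      distance_bin = cut(.data$distance, c(0, 1e5, 1e6, Inf),
                         labels = c("<100kb", "100kb-1Mb", ">1Mb"))
    ) |>
    dplyr::group_by(.data$distance_bin) |>
    dplyr::summarise(n = dplyr::n(), power = mean(.data$detected),
                     .groups = "drop")
  list(summary = summary, power = power, power_distance = power_distance)
}
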