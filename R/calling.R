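#' Fit the negative binomial regression background
#'
#' Models the expected di-tag count of a bait-prey pair as a log-linear
#' function of genomic distance and bait interactability,
#' `log E[count] = b0 + b1 log(distance) + b2 log(interactability_bait)`,
#' with negative binomial errors and maximum-likelihood dispersion. For
#' double-baited pairs the other end also carries a trans-count estimate, so
#' its interactability enters as an additional covariate. Only cis pairs
#' with distance inside `[min_distance, cis_limit]` whose baited ends passed
#' the noise filter are eligible.
#'
#' @param pairs combined pair counts ([combine_replicates()]).
#' @param profile interactability profile restricted to retained fragments.
#' @param double_baited if `TRUE`, both ends must be retained baits and the
#'   other end's interactability is included.
#' @param min_distance,cis_limit tested distance range in bp.
#' @return object of class `chic_bg` wrapping the `MASS::glm.nb` fit, with
#'   `theta` (NB size), `coefficients` and `n`. Supports [tidy()] and
#'   [glance()].
#' @export
fit_background_glm <- function(pairs, profile, double_baited = FALSE,
                               min_distance = 20000, cis_limit = 5e6) {
  df <- glm_frame(pairs, profile, double_baited, min_distance, cis_limit)
  low_n <- nrow(df) < 100
  if (low_n) {
    warn(paste0("only ", nrow(df), " pairs available for the background fit"))
  }
  form <- if (double_baited) {
    count ~ log_distance + log_i_bait + log_i_other
  } else {
    count ~ log_distance + log_i_bait
  }
  fit_warnings <- character()
  fit <- withCallingHandlers(
    MASS::glm.nb(form, data = df),
    warning = function(w) {
      fit_warnings <<- c(fit_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  structure(
    list(
      fit = fit,
      coefficients = coef(fit),
      theta = fit$theta,
      double_baited = double_baited,
      min_distance = min_distance,
      cis_limit = cis_limit,
      n = nrow(df),
      low_n = low_n,
      fit_warnings = fit_warnings
    ),
    class = "chic_bg"
  )
}

glm_frame <- function(pairs, profile, double_baited, min_distance, cis_limit) {
  iota <- setNames(profile$interactability, profile$fragment_id)
  ok_dist <- !is.na(pairs$distance) &
    pairs$distance >= min_distance & pairs$distance <= cis_limit
  p <- pairs[ok_dist, , drop = FALSE]
  i_bait <- iota[p$bait_id]
  if (anyNA(i_bait)) {
    abort("pairs reference bait fragments absent from the (retained) profile")
  }
  df <- data.frame(
    count = p$count,
    log_distance = log(p$distance),
    log_i_bait = log(i_bait)
  )
  if (double_baited) {
    i_other <- iota[p$prey_id]
    if (anyNA(i_other)) {
      abort("double-baited pairs reference prey fragments absent from the profile")
    }
    df$log_i_other <- log(i_other)
  }
  if (any(!is.finite(df$log_i_bait)) ||
      (double_baited && any(!is.finite(df$log_i_other)))) {
    abort("zero interactability among model covariates; filter low-signal fragments first")
  }
  df
}

#' @export
print.chic_bg <- function(x, ...) {
  cat(sprintf("Negative binomial background regression (%s-baited, n = %d)\n",
              if (x$double_baited) "double" else "single", x$n))
  print(round(x$coefficients, 4))
  cat(sprintf("  dispersion (size) %.3f\n", x$theta))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.chic_bg <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "z value"],
    p.value = s[, "Pr(>|z|)"]
  )
}

#' @exportS3Method generics::glance
glance.chic_bg <- function(x, ...) {
  tibble(theta = x$theta, nobs = x$n, double_baited = x$double_baited,
         deviance = x$fit$deviance, logLik = as.numeric(stats::logLik(x$fit)),
         AIC = stats::AIC(x$fit))
}

#' Test observed pair counts against the fitted background
#'
#' Computes the expected count of each pair under the background model and
#' an upper-tail p-value `P(X >= observed)` under the negative binomial with
#' that expectation and the model's dispersion. An observed count of zero
#' has p-value 1.
#'
#' @param model a `chic_bg` fit.
#' @param pairs pair counts to test (same covariate requirements as the
#'   model).
#' @param profile interactability profile used for the fit.
#' @return tibble of tests: `bait_id`, `prey_id`, `distance`, `category`,
#'   `observed`, `expected`, `p_value`.
#' @export
test_interactions <- function(model, pairs, profile) {
  stopifnot(inherits(model, "chic_bg"))
  df <- glm_frame(pairs, profile, model$double_baited,
                  model$min_distance, model$cis_limit)
  keep <- !is.na(pairs$distance) &
    pairs$distance >= model$min_distance & pairs$distance <= model$cis_limit
  p <- pairs[keep, , drop = FALSE]
  mu <- predict(model$fit, newdata = df, type = "response")
  tibble(
    bait_id = p$bait_id,
    prey_id = p$prey_id,
    distance = p$distance,
    category = if ("category" %in% names(p)) p$category else NA_character_,
    observed = p$count,
    expected = as.numeric(mu),
    p_value = pnbinom(p$count - 1, mu = mu, size = model$theta,
                      lower.tail = FALSE)
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: with p-values sorted ascending,
#' `q_(i) = min over j >= i of p_(j) * n / j`, capped at 1 and mapped back to
#' the input order.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return q-values in input order.
#' @export
fdr_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Call significant interactions
#'
#' Adds Benjamini-Hochberg q-values (one multiple-testing family per call)
#' and flags pairs with `q <= fdr` as significant (inclusive threshold).
#'
#' @param tests tibble from [test_interactions()] (q-values are recomputed
#'   from `p_value` unless already present).
#' @param fdr FDR threshold.
#' @param recompute_q recompute q-values even if a `q_value` column exists.
#' @return `tests` with `q_value` and `significant` columns; the count of
#'   calls is attached as the `call_summary` attribute.
#' @export
call_significant <- function(tests, fdr = 0.05, recompute_q = TRUE) {
  if (recompute_q || !"q_value" %in% names(tests)) {
    tests$q_value <- fdr_adjust(tests$p_value)
  }
  tests$significant <- tests$q_value <= fdr
  attr(tests, "call_summary") <- tibble(
    n_tested = nrow(tests), n_called = sum(tests$significant), fdr = fdr
  )
  tests
}

#' Run the full interaction-calling stage for one experiment
#'
#' Chains di-tag filtering, ligation classification, aggregation, replicate
#' combination, the trans-count background ([fit_background()]), the
#' negative binomial regressions (fitted separately for single- and
#' double-baited cis pairs, since only the latter carry an other-end
#' interactability) and upper-tail testing, then adjusts all p-values as one
#' family and calls interactions at `config$fdr`.
#'
#' Pairs are tested only if cis within `[min_distance, cis_limit]`, the bait
#' passed the noise filter, and — for double-baited pairs — the other end
#' passed it too (noise fragments are excluded symmetrically, as bait and as
#' prey).
#'
#' @param ditags di-tag table for one experiment (both replicates).
#' @param baited baited fragment ids of the experiment.
#' @param map fragment map.
#' @param config a [chic_config()].
#' @param experiment label (`"region"` or `"promoter"`).
#' @param cell_line label carried through to the output.
#' @return list of class `chic_calls`: `tests` (with q-values and
#'   significance), `models`, `background`, `filter_report`, `experiment`,
#'   `cell_line`.
#' @export
call_interactions <- function(ditags, baited, map, config = chic_config(),
                              experiment = "region", cell_line = NA_character_) {
  filtered <- filter_ditags(ditags, baited, map,
                            min_distance = config$min_distance)
  classified <- classify_ditags(filtered, baited, map,
                                cis_limit = config$cis_limit)
  agg <- aggregate_counts(classified, baited)
  combined <- combine_replicates(agg$pairs)
  background <- fit_background(agg$fragments,
                               truncation = config$truncation_signal,
                               quantile = config$noise_quantile)
  retained <- filter_low_signal(background$profile)
  retained_ids <- retained$fragment_id
  testable <- combined |>
    dplyr::filter(
      .data$category %in% c("cis_single_le5Mb", "cis_double"),
      .data$distance >= config$min_distance,
      .data$distance <= config$cis_limit,
      .data$bait_id %in% retained_ids,
      !(.data$prey_id %in% baited) | .data$prey_id %in% retained_ids
    )
  strata <- list(
    single = dplyr::filter(testable, .data$category == "cis_single_le5Mb"),
    double = dplyr::filter(testable, .data$category == "cis_double")
  )
  models <- list()
  tests <- list()
  for (nm in names(strata)) {
    s <- strata[[nm]]
    if (nrow(s) == 0) next
    mod <- fit_background_glm(s, retained, double_baited = nm == "double",
                              min_distance = config$min_distance,
                              cis_limit = config$cis_limit)
    models[[nm]] <- mod
    tests[[nm]] <- test_interactions(mod, s, retained)
  }
  if (length(tests) == 0) abort("no testable cis pairs in this experiment")
  tests <- dplyr::bind_rows(tests) |>
    call_significant(fdr = config$fdr) |>
    dplyr::mutate(experiment = experiment, cell_line = cell_line)
  structure(
    list(
      tests = tests,
      models = models,
      background = background,
      filter_report = filter_report(filtered),
      experiment = experiment,
      cell_line = cell_line,
      config = config
    ),
    class = "chic_calls"
  )
}

#' @export
print.chic_calls <- function(x, ...) {
  cat(sprintf("Capture Hi-C interaction calls (%s capture%s)\n", x$experiment,
              if (is.na(x$cell_line)) "" else paste0(", ", x$cell_line)))
  cat(sprintf("  %d pairs tested, %d called at FDR <= %.2f\n",
              nrow(x$tests), sum(x$tests$significant), x$config$fdr))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.chic_calls <- function(x, ...) {
  x$tests
}

#' @exportS3Method generics::glance
glance.chic_calls <- function(x, ...) {
  tibble(
    experiment = x$experiment,
    cell_line = x$cell_line,
    n_tested = nrow(x$tests),
    n_called = sum(x$tests$significant),
    fdr = x$config$fdr,
    noise_threshold = x$background$threshold,
    n_fragments_retained = sum(x$background$profile$retained)
  )
}

#' Significant calls from a `chic_calls` object
#'
#' @param calls a `chic_calls` object or a tests tibble with a `significant`
#'   column.
#' @return The significant rows of the tests tibble.
#' @export
significant_calls <- function(calls) {
  tests <- if (inherits(calls, "chic_calls")) calls$tests else calls
  dplyr::filter(tests, .data$significant)
}
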