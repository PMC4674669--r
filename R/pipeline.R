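#' Run the full Capture Hi-C analysis pipeline
#'
#' Chains the analysis stages for a paired Region/Promoter capture
#' experiment: di-tag filtering and ligation classification, the trans-count
#' background model, negative binomial regression and FDR-controlled
#' interaction calling per experiment ([call_interactions()]), followed by
#' reciprocal co-validation ([reciprocal_match()], [enrichment_grid()]).
#' All stage outputs, per-stage tallies and the exact configuration are
#' written to `out_dir` for provenance.
#'
#' @param ditags di-tag tibble with an `experiment` column (`"region"` /
#'   `"promoter"`), or for a single experiment without one.
#' @param map fragment map.
#' @param region_targets,promoter_targets target tibbles with `fragment_id`
#'   (either may be `NULL` to skip that experiment).
#' @param out_dir output directory (created if missing); `NULL` to skip
#'   writing.
#' @param config a [chic_config()].
#' @param cell_line label recorded in the outputs.
#' @return list of class `chic_pipeline` with per-experiment `chic_calls`,
#'   the co-validation results (`matches`, `enrichment`) when both
#'   experiments ran, and a `summary` tibble.
#' @export
run_pipeline <- function(ditags, map, region_targets = NULL,
                         promoter_targets = NULL, out_dir = NULL,
                         config = chic_config(), cell_line = NA_character_) {
  targets <- list(region = region_targets, promoter = promoter_targets)
  targets <- targets[!vapply(targets, is.null, logical(1))]
  if (length(targets) == 0) abort("pipeline stage 'design': no target sets supplied")
  if (!"experiment" %in% names(ditags)) {
    if (length(targets) > 1) {
      abort("pipeline stage 'input': di-tags need an 'experiment' column when both designs are supplied")
    }
    ditags$experiment <- names(targets)[1]
  }
  calls <- purrr::imap(targets, function(tg, nm) {
    dt <- dplyr::filter(ditags, .data$experiment == nm)
    if (nrow(dt) == 0) abort(paste0("pipeline stage 'input': no di-tags for the ",
                                    nm, " experiment"))
    withCallingHandlers(
      call_interactions(dt, tg$fragment_id, map, config = config,
                        experiment = nm, cell_line = cell_line),
      error = function(e) abort(paste0("pipeline stage 'call/", nm, "': ",
                                       conditionMessage(e)))
    )
  })
  result <- list(calls = calls, config = config, cell_line = cell_line)
  if (all(c("region", "promoter") %in% names(calls))) {
    promoter_ids <- targets$promoter$fragment_id
    result$matches <- reciprocal_match(
      significant_calls(calls$region),
      significant_calls(calls$promoter),
      promoter_ids
    )
    result$enrichment <- tryCatch(
      enrichment_grid(calls$region$tests, calls$promoter$tests, promoter_ids,
                      reference_fdr = config$reference_fdr),
      error = function(e) NULL
    )
  }
  result$summary <- dplyr::bind_rows(purrr::map(calls, glance))
  class(result) <- "chic_pipeline"
  if (!is.null(out_dir)) write_pipeline_outputs(result, map, out_dir)
  result
}

write_pipeline_outputs <- function(result, map, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(result$config, file.path(out_dir, "config.yaml"))
  write_fragment_map(map, file.path(out_dir, "fragments.bed"))
  for (nm in names(result$calls)) {
    cl <- result$calls[[nm]]
    readr::write_tsv(cl$tests, file.path(out_dir, paste0(nm, "_tests.tsv")))
    readr::write_tsv(cl$background$profile,
                     file.path(out_dir, paste0(nm, "_interactability.tsv")))
    readr::write_tsv(filter_report(cl) %||% cl$filter_report,
                     file.path(out_dir, paste0(nm, "_filter_report.tsv")))
    write_longrange(significant_calls(cl), map,
                    file.path(out_dir, paste0(nm, "_calls.longrange")),
                    score_cap = result$config$score_cap)
  }
  if (!is.null(result$matches)) {
    readr::write_tsv(result$matches, file.path(out_dir, "reciprocal_matches.tsv"))
  }
  if (!is.null(result$enrichment)) {
    readr::write_tsv(as_tibble(result$enrichment),
                     file.path(out_dir, "enrichment_grid.tsv"))
  }
  summary <- list(
    cell_line = result$cell_line,
    experiments = purrr::map(result$calls, function(cl) {
      g <- glance(cl)
      as.list(g)
    })
  )
  if (!is.null(result$matches)) {
    summary$covalidation <- list(
      n_validatable = nrow(result$matches),
      n_matched = sum(result$matches$matched)
    )
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.chic_pipeline <- function(x, ...) {
  cat("Capture Hi-C pipeline result\n")
  print(x$summary)
  if (!is.null(x$matches)) {
    cat(sprintf("  co-validation: %d / %d validatable region calls matched\n",
                sum(x$matches$matched), nrow(x$matches)))
  }
  invisible(x)
}
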