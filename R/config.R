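#' Pipeline configuration
#'
#' Collects every numeric constant of the pipeline in one overridable list.
#' Defaults follow the published Capture Hi-C protocol this package
#' implements: di-tags closer than 20 kb are discarded, cis interactions are
#' tested out to 5 Mb, the signal mode of the trans-count distribution is
#' fitted above a truncation of 3,000 di-tags (diagnostic noise-mode
#' truncations of 1,500 for promoter capture and 600 for region capture),
#' the noise threshold is the 5% quantile of the non-truncated fit,
#' interactions are called at FDR 0.05 and co-validation is normalised at a
#' reference FDR of 0.20. Capture oligos are 120 bp with 25-65% GC, fewer
#' than 3 N bases, placed within 400 bp of a fragment end; promoter windows
#' span +/-500 kb of each lead SNP and +/-500 bp of each TSS; regions are
#' extended by one fragment when a cut site lies within 500 bp of a region
#' edge.
#'
#' @param ... named overrides of any default listed above.
#'
#' @return A named list of class `chic_config`.
#' @examples
#' cfg <- chic_config(fdr = 0.1)
#' cfg$fdr
#' @export
chic_config <- function(...) {
  defaults <- list(
    min_distance = 20000,
    cis_limit = 5e6,
    truncation_signal = 3000,
    truncation_noise_promoter = 1500,
    truncation_noise_region = 600,
    noise_quantile = 0.05,
    fdr = 0.05,
    reference_fdr = 0.20,
    oligo_length = 120,
    oligo_window = 400,
    gc_min = 0.25,
    gc_max = 0.65,
    max_n_bases = 2,
    snp_window = 5e5,
    tss_pad = 500,
    extension_gap = 500,
    score_cap = 300
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
    }
    defaults[names(over)] <- over
  }
  structure(defaults, class = "chic_config")
}

#' Write / read a pipeline configuration
#'
#' Configurations are serialised as YAML so that every output directory can
#' carry the exact parameters that produced it.
#'
#' @param config a [chic_config()] list.
#' @param path file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` a
#'   `chic_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "chic_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(chic_config, vals)
}

#' @export
print.chic_config <- function(x, ...) {
  cat("<chic_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
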