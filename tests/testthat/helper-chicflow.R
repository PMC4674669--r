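# Shared fixtures: all built in code, no files.

# Fragment map from explicit cut positions on one or more chromosomes.
# cuts: named list, one integer vector of 0-based cut positions per chrom;
# lens: named vector of chromosome lengths.
map_from_cuts <- function(cuts, lens) {
  rows <- lapply(names(lens), function(ch) {
    bounds <- c(0L, sort(unique(as.integer(cuts[[ch]]))), as.integer(lens[[ch]]))
    tibble::tibble(
      chrom = ch,
      start = bounds[-length(bounds)],
      end = bounds[-1],
      index = seq_len(length(bounds) - 1L) - 1L
    )
  })
  map <- dplyr::bind_rows(rows)
  map$fragment_id <- paste0(map$chrom, "_", map$index)
  attr(map, "chrom_lengths") <- lens
  map
}

# Random DNA sequence with controllable GC content.
random_seq <- function(n, gc = 0.5, n_frac = 0) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- sample(names(probs), n, replace = TRUE, prob = probs)
  if (n_frac > 0) {
    idx <- sample(n, round(n * n_frac))
    s[idx] <- "N"
  }
  paste(s, collapse = "")
}

# Independent string-scan digestion oracle (fixed pattern, no regex overlap
# subtleties beyond what HindIII needs).
digest_oracle <- function(seq, site = "AAGCTT", cut_offset = 1) {
  seq <- toupper(seq)
  hits <- c()
  for (i in seq_len(nchar(seq) - nchar(site) + 1)) {
    if (substr(seq, i, i + nchar(site) - 1) == site) hits <- c(hits, i)
  }
  cuts <- hits - 1 + cut_offset
  cuts <- cuts[cuts > 0 & cuts < nchar(seq)]
  bounds <- c(0, sort(unique(cuts)), nchar(seq))
  cbind(start = bounds[-length(bounds)], end = bounds[-1])
}

# Brute-force Benjamini-Hochberg by definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  ps <- p[o]
  for (i in seq_len(n)) {
    q_sorted[i] <- min(ps[i:n] * n / (i:n), 1)
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Base-coverage interval-union oracle on small coordinates.
merge_oracle <- function(intervals) {
  out <- list()
  for (ch in sort(unique(intervals$chrom))) {
    iv <- intervals[intervals$chrom == ch, ]
    maxend <- max(iv$end)
    covered <- rep(FALSE, maxend)
    for (k in seq_len(nrow(iv))) covered[(iv$start[k] + 1):iv$end[k]] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- c(0, head(ends, -1))
    keep <- r$values
    out[[ch]] <- tibble::tibble(chrom = ch, start = starts[keep],
                                end = ends[keep])
  }
  dplyr::bind_rows(out)
}

# Small, fast simulation preset for unit tests.
quick_params <- function(seed = 1, ...) {
  defaults <- list(
    seed = seed, n_chromosomes = 2, fragments_per_chromosome = 400,
    n_region_baits = 250, n_promoter_baits = 120, preys_per_bait = 12,
    n_loops = 20, loop_fold = 8
  )
  over <- list(...)
  defaults[names(over)] <- over
  do.call(sim_params, defaults)
}
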