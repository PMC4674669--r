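frag_row <- function(len, chrom = "c1", start = 0, id = "c1_0") {
  tibble::tibble(chrom = chrom, start = start, end = start + len,
                 index = 0L, fragment_id = id)
}

test_that("bait design respects oligo length, window and sequence constraints", {
  # fragment shorter than the oligo fails both ends
  b <- design_baits(frag_row(100), random_seq(100))
  expect_equal(nrow(b), 0)
  expect_equal(attr(b, "capture_status"), "failed")

  # clean balanced-GC fragment: first windows at both ends
  s <- strrep("GCAT", 250)
  b2 <- design_baits(frag_row(1000), s)
  expect_equal(attr(b2, "capture_status"), "both_ends")
  expect_equal(b2$start, c(0, 880))
  expect_equal(b2$end, c(120, 1000))
  expect_equal(b2$fragment_end, c("left", "right"))

  # poly-A head: no left window with proximal edge within 400 bp reaches
  # 25% GC, right end still designable
  s3 <- paste0(strrep("A", 520), strrep("GCAT", 120))
  b3 <- design_baits(frag_row(1000), s3)
  expect_equal(attr(b3, "capture_status"), "one_end")
  expect_equal(b3$fragment_end, "right")

  # three Ns kill the boundary window; one step inward leaves two (allowed)
  s4 <- paste0("NNN", strrep("GCAT", 250))
  b4 <- design_baits(frag_row(1003), s4)
  expect_equal(b4$start[b4$fragment_end == "left"], 1)
})

test_that("short fragments yield a single oligo when the two would overlap", {
  s <- strrep("GCAT", 50) # 200 bp, both candidate oligos overlap
  b <- design_baits(frag_row(200), s)
  expect_equal(nrow(b), 1)
  expect_equal(attr(b, "capture_status"), "one_end")
})

test_that("bait design matches exhaustive valid-window enumeration", {
  oracle_end <- function(seq, side, len = nchar(seq)) {
    offs <- 0:min(400, len - 120)
    for (off in offs) {
      st <- if (side == "left") off + 1 else len - 120 - off + 1
      w <- substr(seq, st, st + 119)
      gc <- sum(strsplit(w, "")[[1]] %in% c("G", "C")) / 120
      nn <- sum(strsplit(w, "")[[1]] == "N")
      if (gc >= 0.25 && gc <= 0.65 && nn <= 2) return(st - 1)
    }
    NA_integer_
  }
  set.seed(91)
  for (rep in 1:12) {
    len <- sample(300:1500, 1)
    s <- random_seq(len, gc = sample(c(0.15, 0.4, 0.7), 1), n_frac = 0.02)
    b <- design_baits(frag_row(len), s)
    left <- oracle_end(s, "left")
    right <- oracle_end(s, "right")
    expect_equal(b$start[b$fragment_end == "left"],
                 if (is.na(left)) numeric(0) else left)
    expect_equal(b$start[b$fragment_end == "right"],
                 if (is.na(right)) numeric(0) else right)
    if (nrow(b)) {
      expect_true(all(b$gc_fraction >= 0.25 & b$gc_fraction <= 0.65))
      expect_true(all(b$n_count < 3))
      prox <- ifelse(b$fragment_end == "left", b$start - 0, len - b$end)
      expect_true(all(prox <= 400))
    }
  }
})

test_that("region targets extend across near-boundary cut sites and exclude promoter fragments", {
  map <- map_from_cuts(list(c1 = c(2000, 4000, 6000, 8000)), c(c1 = 10000))
  # region strictly inside one fragment, >500 bp from both cut sites
  t1 <- define_region_targets(
    tibble::tibble(chrom = "c1", start = 4600, end = 5300), map)
  expect_equal(t1$fragment_id, "c1_2")
  # region starting 300 bp after a cut site pulls in the preceding fragment
  t2 <- define_region_targets(
    tibble::tibble(chrom = "c1", start = 4300, end = 5300), map)
  expect_setequal(t2$fragment_id, c("c1_1", "c1_2"))
  # region ending 300 bp before a cut site pulls in the following fragment
  t3 <- define_region_targets(
    tibble::tibble(chrom = "c1", start = 4600, end = 5700), map)
  expect_setequal(t3$fragment_id, c("c1_2", "c1_3"))
  # promoter-targeted fragments are excluded
  t4 <- define_region_targets(
    tibble::tibble(chrom = "c1", start = 4600, end = 5300), map,
    promoter_fragments = "c1_2")
  expect_equal(nrow(t4), 0)
  expect_error(define_region_targets(
    tibble::tibble(chrom = "c9", start = 0, end = 10), map), "unknown")
})

test_that("promoter targets follow the SNP-window and TSS-proximity rules", {
  cuts <- seq(5000, 1995000, by = 5000)
  map <- map_from_cuts(list(c1 = cuts), c(c1 = 2e6))
  snps <- tibble::tibble(chrom = "c1", pos = 600000)
  regions <- tibble::tibble(chrom = character(), start = integer(),
                            end = integer())
  # TSS 100 kb from the SNP, its +/-500 bp window inside one fragment
  tss1 <- tibble::tibble(chrom = "c1", pos = 701000, gene = "G1")
  p1 <- define_promoter_targets(snps, regions, tss1, map)
  expect_equal(p1$fragment_id, "c1_140")
  expect_equal(p1$labels, "G1")
  # TSS exactly on a cut site targets both flanking fragments
  tss2 <- tibble::tibble(chrom = "c1", pos = 700000, gene = "G2")
  p2 <- define_promoter_targets(snps, regions, tss2, map)
  expect_setequal(p2$fragment_id, c("c1_139", "c1_140"))
  # TSS 600 kb from the only SNP and outside all regions is not targeted
  tss3 <- tibble::tibble(chrom = "c1", pos = 1200000, gene = "G3")
  expect_equal(nrow(define_promoter_targets(snps, regions, tss3, map)), 0)
  # ... unless an associated region overlapping the window extends it
  reg <- tibble::tibble(chrom = "c1", start = 1050000, end = 1250000)
  p3 <- define_promoter_targets(snps, reg, tss3, map)
  expect_true(nrow(p3) >= 1)
})

test_that("design summaries reproduce the capture arithmetic identities", {
  region <- design_summary(n_both = 1096, n_one = 1035, n_failed = 1028,
                           genomic_span_bases = 7.46e6)
  expect_equal(region$target_capture_bases, 387240) # 387.24 kb
  expect_equal(region$n_fragments_total, 3159)
  expect_equal(round(region$mean_fragment_size / 1000, 1), 3.5)

  promoter <- design_summary(n_both = 2986, n_one = 2518, n_failed = 792,
                             genomic_span_bases = 38.76e6)
  expect_equal(promoter$target_capture_bases, 1018800) # ~1.02 Mb
  expect_equal(promoter$n_captured, 5504)
  expect_equal(round(promoter$mean_fragment_size / 1000, 2), 7.04)

  hba <- design_summary(n_both = 26, n_one = 0, genomic_span_bases = 174570)
  expect_equal(round(hba$mean_fragment_size / 1000, 2), 6.71)

  empty <- summarize_design(tibble::tibble(fragment_id = character(),
                                           capture_status = character()))
  expect_equal(empty$n_fragments_total, 0)
  expect_equal(empty$target_capture_bases, 0)
})

test_that("design_capture ties bait status back to targets and satisfies totals", {
  set.seed(3)
  seqs <- c(c1 = random_seq(6000, gc = 0.45))
  map <- digest_genome(seqs)
  # fall back to a synthetic multi-fragment map if no cut site was drawn
  if (nrow(map) < 3) {
    seqs <- c(c1 = paste0(random_seq(2000, 0.45), "AAGCTT",
                          random_seq(1500, 0.45), "AAGCTT",
                          random_seq(2000, 0.45)))
    map <- digest_genome(seqs)
  }
  targets <- tibble::tibble(fragment_id = map$fragment_id)
  dc <- design_capture(targets, map, seqs)
  expect_equal(nrow(dc$targets), nrow(map))
  sm <- summarize_design(dc$targets, map)
  expect_equal(sm$n_fragments_total, sm$n_failed + sm$n_both_ends + sm$n_one_end)
  expect_equal(sm$target_capture_bases,
               120 * (2 * sm$n_both_ends + sm$n_one_end))
  # every bait lies inside its fragment
  if (nrow(dc$baits)) {
    j <- match(dc$baits$fragment_id, map$fragment_id)
    expect_true(all(dc$baits$start >= map$start[j]))
    expect_true(all(dc$baits$end <= map$end[j]))
  }
})
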