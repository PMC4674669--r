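# 5 kb fragments tiling two chromosomes; midpoint spacing is 5 kb
tag_map <- map_from_cuts(
  list(c1 = seq(5000, 9995000, by = 5000), c2 = seq(5000, 995000, by = 5000)),
  c(c1 = 1e7, c2 = 1e6)
)

dt <- function(f1, f2, count = 1, replicate = "rep1") {
  tibble::tibble(frag1_id = f1, frag2_id = f2, count = count,
                 replicate = replicate)
}

test_that("di-tag filtering removes off-target, self-ligated and short-range pairs", {
  baited <- c("c1_10", "c1_100")
  tags <- dplyr::bind_rows(
    dt("c1_10", "c1_13"),   # 15 kb < 20 kb: removed
    dt("c1_10", "c1_14"),   # exactly 20 kb: retained (strict <)
    dt("c1_10", "c1_10"),   # self-ligation: removed
    dt("c1_300", "c1_400"), # neither end baited: removed
    dt("c1_100", "c2_5")    # trans, baited: retained
  )
  out <- filter_ditags(tags, baited, tag_map)
  expect_equal(nrow(out), 2)
  expect_true(all(out$frag1_id %in% c("c1_10", "c1_100")))
  rep <- filter_report(out)
  expect_equal(rep$ditags[rep$rule == "off_target"], 1)
  expect_equal(rep$ditags[rep$rule == "self_ligation"], 1)
  expect_equal(rep$ditags[rep$rule == "cis_lt_20000"], 1)
  expect_equal(rep$ditags[rep$rule == "retained"], 2)
  expect_error(filter_ditags(dt("c1_10", "nope"), baited, tag_map),
               "unknown fragment id")
})

test_that("filtering is idempotent and order-independent", {
  set.seed(5)
  baited <- paste0("c1_", sample(0:1999, 50))
  tags <- dt(paste0("c1_", sample(0:1999, 200, TRUE)),
             paste0("c1_", sample(0:1999, 200, TRUE)),
             count = sample(1:4, 200, TRUE))
  strip <- function(x) {
    x <- x[c("frag1_id", "frag2_id", "replicate", "count")]
    attr(x, "filter_report") <- NULL
    x
  }
  f1 <- filter_ditags(tags, baited, tag_map)
  f2 <- filter_ditags(f1, baited, tag_map)
  expect_equal(strip(f1), strip(f2))
  shuffled <- filter_ditags(tags[sample(nrow(tags)), ], baited, tag_map)
  expect_equal(dplyr::arrange(strip(f1), frag1_id, frag2_id, count),
               dplyr::arrange(strip(shuffled), frag1_id, frag2_id, count))
})

test_that("ligation categories follow the four-way rule table and partition the data", {
  baited <- c("c1_10", "c1_100", "c1_300", "c1_1300")
  tags <- dplyr::bind_rows(
    dt("c1_10", "c2_5"),    # different chromosomes: trans
    dt("c1_100", "c1_300"), # both baited, 1 Mb: cis_double
    dt("c1_10", "c1_500"),  # one baited, 2.45 Mb: cis_single_le5Mb
    dt("c1_10", "c1_1010"), # one baited, exactly 5 Mb: near class (boundary)
    dt("c1_10", "c1_1500"), # one baited, 7.45 Mb: cis_single_gt5Mb
    dt("c1_300", "c1_1300") # both baited, 5 Mb: cis_double regardless
  )
  cl <- classify_ditags(filter_ditags(tags, baited, tag_map), baited, tag_map)
  expect_equal(cl$category,
               c("trans", "cis_double", "cis_single_le5Mb",
                 "cis_single_le5Mb", "cis_single_gt5Mb", "cis_double"))
  expect_equal(sum(table(cl$category)), nrow(cl))
})

test_that("aggregation sums duplicates and tallies per-fragment trans totals", {
  baited <- c("c1_10", "c1_20")
  tags <- dplyr::bind_rows(
    dt("c1_10", "c1_100", 2),
    dt("c1_100", "c1_10", 3), # same unordered pair
    dt("c1_10", "c2_5", 7),   # trans
    dt("c1_20", "c1_200", 4)  # cis only for c1_20
  )
  cl <- classify_ditags(filter_ditags(tags, baited, tag_map), baited, tag_map)
  agg <- aggregate_counts(cl, baited)
  pair <- agg$pairs[agg$pairs$prey_id == "c1_100", ]
  expect_equal(pair$count, 5)
  expect_equal(agg$fragments$trans_count[agg$fragments$fragment_id == "c1_10"],
               7)
  expect_equal(agg$fragments$trans_count[agg$fragments$fragment_id == "c1_20"],
               0)
  # conservation of di-tag mass
  expect_equal(sum(agg$pairs$count), sum(cl$count))
})

test_that("aggregation matches a brute-force tally on random tables", {
  set.seed(11)
  baited <- paste0("c1_", 0:60)
  ids <- c(paste0("c1_", 0:200), paste0("c2_", 0:150))
  tags <- dt(sample(ids, 300, TRUE), sample(ids, 300, TRUE),
             count = sample(1:5, 300, TRUE),
             replicate = sample(c("rep1", "rep2"), 300, TRUE))
  f <- filter_ditags(tags, baited, tag_map)
  cl <- classify_ditags(f, baited, tag_map)
  agg <- aggregate_counts(cl, baited)
  expect_equal(sum(agg$pairs$count), sum(f$count))
  # brute-force trans totals
  for (b in sample(baited, 10)) {
    trans_rows <- cl$category == "trans" & (cl$frag1_id == b | cl$frag2_id == b)
    expect_equal(
      agg$fragments$trans_count[agg$fragments$fragment_id == b],
      sum(cl$count[trans_rows])
    )
  }
})

test_that("replicate combination sums counts and flags single-replicate pairs", {
  p1 <- tibble::tibble(bait_id = c("a", "b"), prey_id = c("x", "y"),
                       distance = c(3e4, 4e4), category = "cis_single_le5Mb",
                       replicate = "rep1", count = c(2, 5))
  # empty second replicate leaves counts unchanged
  comb <- combine_replicates(p1)
  expect_equal(comb$count, c(2, 5))
  expect_true(all(comb$single_replicate))
  # identical replicates double every count
  both <- combine_replicates(dplyr::bind_rows(
    p1, dplyr::mutate(p1, replicate = "rep2")))
  expect_equal(both$count, c(4, 10))
  expect_true(all(!both$single_replicate))
  expect_equal(nrow(combine_replicates(dplyr::bind_rows(
    p1, dplyr::mutate(p1, replicate = "rep2")), require_both = TRUE)), 2)
  # random tables match a brute-force sum
  set.seed(2)
  rnd <- tibble::tibble(
    bait_id = sample(letters[1:5], 40, TRUE),
    prey_id = sample(LETTERS[1:5], 40, TRUE),
    distance = 5e4, category = "cis_single_le5Mb",
    replicate = sample(c("rep1", "rep2"), 40, TRUE),
    count = sample(1:9, 40, TRUE)
  )
  got <- combine_replicates(rnd)
  want <- tapply(rnd$count, paste(rnd$bait_id, rnd$prey_id), sum)
  expect_equal(got$count,
               as.vector(want[paste(got$bait_id, got$prey_id)]))
})
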