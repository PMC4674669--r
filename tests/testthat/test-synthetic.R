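test_that("simulation is deterministic given the seed", {
  a <- simulate_chic(quick_params(seed = 5))
  b <- simulate_chic(quick_params(seed = 5))
  expect_identical(a$ditags, b$ditags)
  expect_identical(a$truth$pairs, b$truth$pairs)
  expect_identical(a$design$map, b$design$map)
  c <- simulate_chic(quick_params(seed = 6))
  expect_false(identical(a$ditags, c$ditags))
})

test_that("fragment maps tile chromosomes with the requested size distribution", {
  d <- simulate_design(sim_params(seed = 2, n_chromosomes = 1,
                                  fragments_per_chromosome = 5000,
                                  mean_fragment_size = 7000,
                                  n_region_baits = 10, n_promoter_baits = 0))
  sizes <- d$map$end - d$map$start
  expect_lt(abs(mean(sizes) - 7000) / 7000, 0.1)
  expect_equal(d$map$start[-1], d$map$end[-nrow(d$map)])
  expect_equal(d$map$start[1], 0)
  # degenerate case: one fragment spans the whole chromosome
  d1 <- simulate_design(sim_params(seed = 2, n_chromosomes = 2,
                                   fragments_per_chromosome = 1,
                                   n_region_baits = 1, n_promoter_baits = 0))
  expect_equal(nrow(d1$map), 2)
  expect_equal(d1$map$start, c(0, 0))
})

test_that("bait sets are disjoint and loops are reciprocally placed", {
  sim <- simulate_chic(quick_params(seed = 9))
  r <- sim$design$region_targets$fragment_id
  p <- sim$design$promoter_targets$fragment_id
  expect_equal(length(intersect(r, p)), 0)
  loops <- dplyr::filter(sim$truth$pairs, is_loop)
  reg_loops <- dplyr::filter(loops, experiment == "region")
  pro_loops <- dplyr::filter(loops, experiment == "promoter")
  expect_true(all(reg_loops$bait_id %in% r))
  expect_true(all(reg_loops$prey_id %in% p))
  expect_setequal(paste(reg_loops$bait_id, reg_loops$prey_id),
                  paste(pro_loops$prey_id, pro_loops$bait_id))
  expect_true(all(loops$distance >= 20000 & loops$distance <= 5e6))
})

test_that("expected pair counts follow the anchored power-law decay", {
  # unit interactability, no noise fragments, no loops: mu depends on
  # distance alone
  p <- quick_params(seed = 31, interactability_sigma = 0, n_loops = 0,
                    noise_fragment_fraction = 0)
  sim <- simulate_chic(p)
  pairs <- sim$truth$pairs
  expect_equal(pairs$mu,
               p$library_scale * (pairs$distance / 20000)^(-p$decay_exponent))
  # observed counts agree with mu within Monte-Carlo error, by distance bin
  dt <- dplyr::filter(sim$ditags, experiment == "region")
  agg <- dplyr::summarise(
    dplyr::group_by(dt, frag1_id, frag2_id),
    count = sum(count), .groups = "drop"
  )
  reg <- dplyr::filter(pairs, experiment == "region")
  obs <- setNames(agg$count, paste(agg$frag1_id, agg$frag2_id))[
    paste(reg$bait_id, reg$prey_id)]
  obs[is.na(obs)] <- 0
  bin <- cut(log10(reg$distance), 5)
  ratio <- tapply(obs, bin, mean) / tapply(2 * reg$mu, bin, mean)
  expect_true(all(abs(ratio - 1) < 0.1))
})

test_that("spiked loops multiply the expected count by their fold", {
  p <- quick_params(seed = 12, n_loops = 15, loop_fold = 8)
  sim <- simulate_chic(p)
  loops <- dplyr::filter(sim$truth$pairs, is_loop, experiment == "region")
  base <- p$library_scale *
    setNames(sim$truth$fragments$efficiency,
             sim$truth$fragments$fragment_id)[loops$bait_id] *
    (loops$distance / 20000)^(-p$decay_exponent)
  expect_equal(unname(loops$mu / base), rep(8, nrow(loops)))
})

test_that("trans counts are bimodal and consistent with fragment class", {
  p <- quick_params(seed = 3)
  sim <- simulate_chic(p)
  reg_baited <- sim$design$region_targets$fragment_id
  f <- filter_ditags(dplyr::filter(sim$ditags, experiment == "region"),
                     reg_baited, sim$design$map)
  cl <- classify_ditags(f, reg_baited, sim$design$map)
  agg <- aggregate_counts(cl, reg_baited)
  truth_class <- setNames(sim$truth$fragments$class,
                          sim$truth$fragments$fragment_id)
  tc <- agg$fragments
  tc$class <- truth_class[tc$fragment_id]
  noise_mean <- mean(tc$trans_count[tc$class == "noise"])
  signal_mean <- mean(tc$trans_count[tc$class == "signal"])
  expect_lt(noise_mean, 200)
  expect_gt(signal_mean, 3000)
})

test_that("call evaluation matches a brute-force confusion matrix", {
  truth <- list(pairs = tibble::tibble(
    experiment = "region",
    bait_id = c("a", "b", "c", "d"),
    prey_id = c("x", "y", "z", "w"),
    distance = c(5e4, 2e5, 1e6, 3e6),
    is_loop = c(TRUE, TRUE, FALSE, FALSE),
    fold = c(8, 4, 1, 1)
  ))
  tests <- tibble::tibble(
    experiment = "region",
    bait_id = c("a", "b", "c", "d"),
    prey_id = c("x", "y", "z", "w"),
    significant = c(TRUE, FALSE, TRUE, FALSE)
  )
  ev <- evaluate_calls(tests, truth)
  expect_equal(ev$summary$sensitivity, 0.5) # a called, b missed
  expect_equal(ev$summary$fdp, 0.5)         # c is a false call
  expect_equal(ev$power$power[ev$power$fold == 8], 1)
  expect_equal(ev$power$power[ev$power$fold == 4], 0)
  # calls exactly the loop set: sensitivity 1, FDP 0
  perfect <- dplyr::mutate(tests, significant = c(TRUE, TRUE, FALSE, FALSE))
  evp <- evaluate_calls(perfect, truth)
  expect_equal(evp$summary$sensitivity, 1)
  expect_equal(evp$summary$fdp, 0)
  # empty call set: sensitivity 0, FDP reported 0 with flag
  none <- dplyr::mutate(tests, significant = FALSE)
  evn <- evaluate_calls(none, truth)
  expect_equal(evn$summary$sensitivity, 0)
  expect_equal(evn$summary$fdp, 0)
  expect_false(evn$summary$fdp_defined)
})
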