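test_that("event sampling honors degenerate probabilities", {
  map <- small_map()
  set.seed(1)
  params <- repair_params(p_crossover = 0)
  pathways <- replicate(200, sample_event(params, map)$pathway)
  expect_false(any(pathways == "crossover"))

  params2 <- repair_params(p_crossover = 0,
                           p_bidirectional_given_NCO = 0,
                           p_downstream_given_unidirectional = 1,
                           tract_dist = list(name = "fixed", value = 100))
  ev <- replicate(50, sample_event(params2, map), simplify = FALSE)
  expect_true(all(vapply(ev, function(e) e$pathway, "") == "SDSA_down"))
  expect_true(all(vapply(ev, function(e) e$tract_extent_down, 0) == 100))
  expect_true(all(vapply(ev, function(e) e$tract_extent_up, 0) == 0))
})

test_that("SDSA events engage one side, dissolution both", {
  map <- small_map()
  set.seed(42)
  params <- repair_params()
  ev <- replicate(500, sample_event(params, map), simplify = FALSE)
  for (e in ev) {
    nonzero <- (e$tract_extent_up > 0) + (e$tract_extent_down > 0)
    if (e$pathway %in% c("SDSA_up", "SDSA_down")) expect_equal(nonzero, 1)
    if (e$pathway == "dissolution") expect_equal(nonzero, 2)
    expect_lte(e$tract_extent_up, map$homology_span / 2)
    expect_lte(e$tract_extent_down, map$homology_span / 2)
  }
})

test_that("product realization places hetDNA and conversion patches correctly", {
  map <- build_marker_map(0, 4, spacing = 50, first_offset_down = 22)
  # SDSA_down, extent 130: SNPs 22, 72, 122 het; 172 untouched
  p <- realize_product(fixed_event("SDSA_down", extent_down = 130), map)
  het <- p$strand_top != p$strand_bottom
  expect_identical(unname(het), c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(p$strand_top[!het] == "R" & p$strand_bottom[!het] == "R"))

  # with downstream proofreading the terminal SNP becomes a conversion
  p2 <- realize_product(fixed_event("SDSA_down", extent_down = 130,
                                    proofread_down = TRUE), map)
  expect_equal(unname(p2$strand_top[1]), "D")
  expect_equal(unname(p2$strand_bottom[1]), "D")
  expect_identical(unname(p2$strand_top[2:3] != p2$strand_bottom[2:3]),
                   c(TRUE, TRUE))

  # dissolution with short symmetric extents marks only the proximal SNPs
  map2 <- build_marker_map(2, 2, spacing = 50, first_offset_up = 22,
                           first_offset_down = 22)
  p3 <- realize_product(fixed_event("dissolution", extent_up = 60,
                                    extent_down = 60), map2)
  het3 <- p3$strand_top != p3$strand_bottom
  expect_identical(unname(het3), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("every SNP of every product is RR, heterozygous, or DD", {
  map <- small_map()
  ch <- simulate_cohort(300, repair_params(seed = 7), map)
  for (p in ch$products) {
    expect_true(all(p$strand_top %in% c("R", "D")))
    expect_true(all(p$strand_bottom %in% c("R", "D")))
  }
})

test_that("cohort simulation is deterministic and truth-aligned", {
  map <- small_map()
  a <- simulate_cohort(50, repair_params(seed = 99), map)
  b <- simulate_cohort(50, repair_params(seed = 99), map)
  expect_identical(a$truth, b$truth)
  expect_identical(a$products, b$products)
  expect_equal(nrow(a$truth), 50)
  expect_identical(a$truth$is_CO, a$truth$pathway == "crossover")
})

test_that("category counts match an exact multinomial oracle", {
  # zero proofreading and a degenerate tract length: the only randomness
  # is the pathway draw, so category counts are multinomial with the
  # configured probabilities; check observed counts within 3 binomial SE
  map <- small_map()
  pc <- 0.2; pb <- 0.3; pd <- 0.6
  params <- repair_params(p_crossover = pc, p_bidirectional_given_NCO = pb,
                          p_downstream_given_unidirectional = pd,
                          tract_dist = list(name = "fixed", value = 100),
                          proofread_lookup = list(`22` = c(up = 0, down = 0)),
                          seed = 123)
  n <- 4000
  ch <- simulate_cohort(n, params, map)
  tab <- table(factor(ch$truth$pathway,
                      levels = c("crossover", "dissolution",
                                 "SDSA_down", "SDSA_up")))
  expected_p <- c(pc, (1 - pc) * pb, (1 - pc) * (1 - pb) * pd,
                  (1 - pc) * (1 - pb) * (1 - pd))
  for (i in 1:4) {
    se <- sqrt(expected_p[i] * (1 - expected_p[i]) / n)
    expect_lt(abs(tab[[i]] / n - expected_p[i]), 3 * se)
  }
})

test_that("terminal proofreading frequency is recovered at scale", {
  # p_proofread = 0.83 at an 8-nt terminal SNP: the observed
  # terminal-conversion fraction over 10,000 events must have a 95% CI
  # covering the input
  map <- build_marker_map(4, 4, spacing = 50, first_offset_up = 8,
                          first_offset_down = 8)
  params <- repair_params(seed = 31)
  ch <- simulate_cohort(10000, params, map)
  obs <- mean(ch$truth$proofread_up)
  ci <- proportion_ci(sum(ch$truth$proofread_up), nrow(ch$truth))
  expect_true(ci["lower"] <= 0.83 && 0.83 <= ci["upper"])
  # conversion is visible in the realized strands
  conv <- vapply(ch$products, function(p) {
    unname(p$strand_top["-8"] == "D" & p$strand_bottom["-8"] == "D")
  }, NA)
  expect_equal(mean(conv), obs)
})

test_that("papillation classifies CO/NCO by the more-than-three rule", {
  expect_true(classify_CO(4))
  expect_false(classify_CO(3))

  map <- small_map()
  co <- realize_product(fixed_event("crossover", extent_up = 100,
                                    extent_down = 100), map)
  nco <- realize_product(fixed_event("SDSA_down", extent_down = 100), map)
  set.seed(5)
  # popout_rate = 0 -> never classified CO
  counts0 <- replicate(50, simulate_papillation(co, popout_rate = 0,
                                                background_rate = 0))
  expect_true(all(!classify_CO(counts0)))
  co_counts <- replicate(200, simulate_papillation(co))
  nco_counts <- replicate(200, simulate_papillation(nco))
  expect_gt(mean(classify_CO(co_counts)), 0.99)
  expect_lt(mean(classify_CO(nco_counts)), 0.05)
})
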