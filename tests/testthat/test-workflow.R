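# end-to-end drivers on a scaled-down configuration (8 SNPs) so the full
# simulate -> map -> stats chain runs in seconds
small_config <- function(seed = 1L, n_products = 30L, per_base_error = 0) {
  cfg <- default_config(seed)
  cfg$substrate$n_up <- 4L
  cfg$substrate$n_down <- 4L
  cfg$repair$n_products <- n_products
  cfg$reads$per_base_error <- per_base_error
  cfg
}

test_that("run_simulate writes aligned, reproducible artifacts", {
  cfg <- small_config(seed = 21, n_products = 50)
  d1 <- withr::local_tempdir()
  sim <- run_simulate(cfg, d1)
  truth <- utils::read.delim(sim$paths$truth, comment.char = "#")
  expect_equal(nrow(truth), 50)
  products <- utils::read.delim(sim$paths$products, comment.char = "#")
  expect_identical(products$id, truth$id)
  # one barcode pair per sequenced (NCO) product
  barcodes <- read_barcode_table(sim$paths$barcodes)
  expect_equal(nrow(barcodes), sum(!truth$is_CO))
  reads <- read_fasta(sim$paths$reads)
  expect_equal(nrow(reads), cfg$reads$n_reads * nrow(barcodes))
  # seed recorded in the headers
  expect_match(readLines(sim$paths$truth, n = 1), "seed: 21")

  # byte-identical rerun under the same seed
  d2 <- withr::local_tempdir()
  run_simulate(cfg, d2)
  for (f in c("products.tsv", "truth.tsv", "reads.fasta", "barcodes.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }

  # n = 0 is legal: empty truth, no reads
  d3 <- withr::local_tempdir()
  sim0 <- run_simulate(small_config(n_products = 0), d3)
  expect_equal(nrow(utils::read.delim(sim0$paths$truth, comment.char = "#")), 0)
  expect_equal(nrow(read_fasta(sim0$paths$reads)), 0)
})

test_that("run_map accounts for every barcode pair and matches truth at error 0", {
  cfg <- small_config(seed = 33, n_products = 40)
  d <- withr::local_tempdir()
  sim <- run_simulate(cfg, d)
  res <- run_map(cfg, sim$paths$reads, sim$paths$barcodes,
                 file.path(d, "map"))
  prof <- res$profiles
  barcodes <- read_barcode_table(sim$paths$barcodes)
  expect_equal(nrow(prof), nrow(barcodes))
  expect_equal(sum(prof$pass) + sum(!prof$pass), nrow(barcodes))
  expect_true(all(prof$reason[!prof$pass] %in%
                  c("too_few_reads", "uncallable", "single_species",
                    "multi_species", "minor_below_10pct")))

  # oracle case: with error 0 every passing profile equals its truth
  map <- build_marker_map(cfg$substrate$n_up, cfg$substrate$n_down,
                         cfg$substrate$spacing,
                         cfg$substrate$first_offset_up,
                         cfg$substrate$first_offset_down)
  truth <- sim$cohort$truth
  id_of <- setNames(barcodes$product_id, barcodes$sample_id)
  for (i in which(prof$pass)) {
    k <- match(id_of[prof$sample_id[i]], truth$id)
    tp <- truth_profile(sim$cohort$products[[k]], map)
    expect_identical(prof$direction[i], tp$direction)
    expect_identical(prof$tract_length_up[i], tp$tract_length_up)
    expect_identical(prof$tract_length_down[i], tp$tract_length_down)
  }
  # summary JSON exists and parses
  js <- jsonlite::read_json(res$paths$summary)
  expect_equal(js$n_profiles, sum(prof$pass))

  # filter log covers all reasons seen
  flog <- utils::read.delim(res$paths$filter_log, comment.char = "#")
  expect_equal(sum(flog$n_groups), nrow(prof))
})

test_that("all groups below the read threshold leave an empty profile set", {
  cfg <- small_config(seed = 44, n_products = 10)
  cfg$reads$n_reads <- 5L   # below the 20-read inclusion threshold
  d <- withr::local_tempdir()
  sim <- run_simulate(cfg, d)
  res <- run_map(cfg, sim$paths$reads, sim$paths$barcodes, file.path(d, "map"))
  expect_true(all(!res$profiles$pass))
  expect_true(all(res$profiles$reason == "too_few_reads"))
  expect_equal(res$summary$n_profiles, 0)
})

test_that("run_stats emits the comparison battery and handles degenerate input", {
  cfg <- small_config(seed = 55, n_products = 60)
  d <- withr::local_tempdir()
  sim <- run_simulate(cfg, d)
  res <- run_map(cfg, sim$paths$reads, sim$paths$barcodes, file.path(d, "map"))
  cmp <- run_stats(cfg, res$summary, res$summary,
                   co_a = c(5, 60), co_b = c(5, 60), outdir = file.path(d, "stats"))
  expect_true(file.exists(file.path(d, "stats", "comparisons.tsv")))
  # identical cohorts: every testable chi-square comparison has p = 1
  chis <- cmp[cmp$testable & cmp$comparison != "tract_length_mann_whitney", ]
  expect_true(all(chis$p_value == 1))
  mw <- cmp[cmp$comparison == "tract_length_mann_whitney", ]
  expect_gt(mw$p_value, 0.95)

  # an empty category is untestable but the run continues
  empty <- summarize_cohort(list())
  cmp2 <- compare_cohorts(empty, res$summary)
  expect_true(any(!cmp2$testable))
  expect_true(all(c("bidirectional_vs_unidirectional",
                    "tract_length_mann_whitney") %in% cmp2$comparison))
})

test_that("configuration files round-trip with validation", {
  cfg <- default_config(seed = 9)
  f <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(list(seed = 9L,
                        substrate = list(n_up = 4, n_down = 4),
                        reads = list(per_base_error = 0.001)), f)
  got <- read_run_config(f)
  expect_equal(got$substrate$n_up, 4)
  expect_equal(got$reads$per_base_error, 0.001)
  expect_equal(got$pipeline$min_reads, 20L)  # defaults survive

  yaml::write_yaml(list(pipeline = list(min_minor_fraction = 0.9)), f)
  expect_error(read_run_config(f), "min_minor_fraction")
})
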