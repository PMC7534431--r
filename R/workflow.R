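# End-to-end drivers: simulate -> reads -> map -> summarize -> stats,
# configured by a single YAML document. Every output table carries a
# header with the seed and a hash of the configuration.

#' Default run configuration
#'
#' Nested list mirroring the full pipeline: substrate geometry, repair
#' model, read emission, pipeline thresholds and stats flags. Defaults
#' are the I-SceI SNP22 study conditions: 4.2-kb substrates, 84 SNPs at
#' 50-bp spacing with the break-proximal SNP 22 nt from the break.
#'
#' @param seed Top-level seed.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    substrate = list(enzyme = "I-SceI", n_up = 42L, n_down = 42L,
                     spacing = 50L, first_offset_up = 22L,
                     first_offset_down = 22L, seed = 100L),
    repair = list(n_products = 100L, p_crossover = 0.09,
                  p_bidirectional_given_NCO = 0.13,
                  p_downstream_given_unidirectional = 0.73,
                  tract_median_bp = 900, tract_sdlog = 0.6,
                  popout_rate = 0.5, papillation_sectors = 30L,
                  papillation_background = 0.02),
    reads = list(n_reads = 30L, minor_fraction = 0.5,
                 per_base_error = 0.002, indel_rate = 0),
    pipeline = list(min_reads = 20L, min_minor_fraction = 0.10,
                    barcode_mismatch = 0L, ambig_exclude = 0.2),
    stats = list(continuity_correction = TRUE)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults; thresholds are
#' validated against their documented ranges.
#'
#' @param path YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_config())
  for (sec in names(user)) {
    if (is.list(cfg[[sec]]) && is.list(user[[sec]])) {
      for (k in names(user[[sec]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
    } else {
      cfg[[sec]] <- user[[sec]]
    }
  }
  validate_config(structure(cfg, class = "run_config"))
}

validate_config <- function(cfg) {
  p <- cfg$pipeline
  if (p$min_reads < 1L) stop("min_reads must be >= 1")
  if (p$min_minor_fraction < 0 || p$min_minor_fraction > 0.5) {
    stop("min_minor_fraction must be in [0, 0.5]")
  }
  if (p$ambig_exclude < 0 || p$ambig_exclude > 1) {
    stop("ambig_exclude must be in [0, 1]")
  }
  if (cfg$reads$minor_fraction > 0.5) stop("minor_fraction must be <= 0.5")
  probs <- with(cfg$repair, c(p_crossover, p_bidirectional_given_NCO,
                              p_downstream_given_unidirectional, popout_rate))
  if (any(probs < 0 | probs > 1)) stop("repair probabilities must be in [0, 1]")
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}

config_substrate <- function(cfg) {
  s <- cfg$substrate
  enzyme <- switch(s$enzyme,
                   "I-SceI" = enzyme_isce1(),
                   "ZFN" = enzyme_zfn(),
                   stop("unknown enzyme '", s$enzyme,
                        "' (expected I-SceI or ZFN)"))
  map <- build_marker_map(s$n_up, s$n_down, s$spacing,
                          s$first_offset_up, s$first_offset_down)
  substrate_pair(map, enzyme, seed = s$seed)
}

config_repair_params <- function(cfg) {
  r <- cfg$repair
  repair_params(p_crossover = r$p_crossover,
                p_bidirectional_given_NCO = r$p_bidirectional_given_NCO,
                p_downstream_given_unidirectional = r$p_downstream_given_unidirectional,
                tract_dist = list(name = "lognormal",
                                  meanlog = log(r$tract_median_bp),
                                  sdlog = r$tract_sdlog))
}

std_header <- function(cfg) {
  c(paste0("seed: ", cfg$seed), paste0("config_hash: ", config_hash(cfg)))
}

#' Simulate a cohort and write all artifacts
#'
#' Simulates `n_products` repair events, scores papillation for every
#' product, emits barcoded reads for the noncrossover products (crossover
#' hetDNA is not sequenced, matching the assay), and writes: a products
#' TSV (with papillation and CO classification), a truth TSV, a reads
#' FASTA and a barcode TSV. Byte-identical for a fixed seed.
#'
#' @param config A `run_config`.
#' @param outdir Output directory (created if needed).
#' @param seed Overrides `config$seed`.
#' @return Invisibly, a list with the file paths and the simulated
#'   objects (`pair`, `cohort`, `barcodes`, `reads`).
#' @export
run_simulate <- function(config, outdir, seed = config$seed) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- as.integer(seed)
  set.seed(config$seed)
  pair <- config_substrate(config)
  params <- config_repair_params(config)
  n <- config$repair$n_products
  cohort <- simulate_cohort(n, params, pair$marker_map, seed = NULL)
  r <- config$repair
  papillae <- vapply(cohort$products, simulate_papillation, 0,
                     popout_rate = r$popout_rate,
                     n_sectors = r$papillation_sectors,
                     background_rate = r$papillation_background)
  products <- cbind(cohort$truth,
                    papillae = as.integer(papillae),
                    classified_CO = classify_CO(papillae),
                    sequenced = !cohort$truth$is_CO)
  nco_idx <- which(!cohort$truth$is_CO)
  barcodes <- make_barcode_table(length(nco_idx),
                                 seed = config$seed + 7L)
  barcodes$product_id <- cohort$truth$id[nco_idx]
  rp <- config$reads
  emission <- read_emission_params(rp$n_reads, rp$minor_fraction,
                                   rp$per_base_error, rp$indel_rate)
  set.seed(config$seed + 13L)
  reads_list <- lapply(seq_along(nco_idx), function(j) {
    bc <- barcode_pair(barcodes$forward_barcode[j],
                       barcodes$reverse_barcode[j])
    emit_reads(cohort$products[[nco_idx[j]]], bc, emission, pair,
               id_prefix = barcodes$sample_id[j], seed = NULL)
  })
  reads <- if (length(reads_list) > 0) {
    do.call(rbind, reads_list)
  } else {
    data.frame(id = character(0), sequence = character(0))
  }
  hdr <- std_header(config)
  paths <- list(products = file.path(outdir, "products.tsv"),
                truth = file.path(outdir, "truth.tsv"),
                reads = file.path(outdir, "reads.fasta"),
                barcodes = file.path(outdir, "barcodes.tsv"))
  write_tsv_with_header(products, paths$products, hdr)
  write_tsv_with_header(cohort$truth, paths$truth, hdr)
  write_fasta(reads, paths$reads)
  write_barcode_table(barcodes, paths$barcodes, hdr)
  invisible(list(paths = paths, pair = pair, cohort = cohort,
                 barcodes = barcodes, reads = reads))
}

#' Run the hetDNA mapping pipeline over a read set
#'
#' Demultiplexes, genotypes, calls species, filters and maps every
#' barcode group; writes a per-recombinant profile TSV (one row per
#' barcode pair with pass/fail and reason), a cohort summary JSON and a
#' filter log.
#'
#' @param config A `run_config` (the substrate section must match the one
#'   used to generate the reads).
#' @param reads_fasta Path to the reads FASTA.
#' @param barcode_tsv Path to the barcode table TSV.
#' @param outdir Output directory.
#' @return Invisibly, a list with `profiles` (data.frame), `summary`
#'   (`cohort_summary`), `calls`, and the output paths.
#' @export
run_map <- function(config, reads_fasta, barcode_tsv, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pair <- config_substrate(config)
  reads <- read_fasta(reads_fasta)
  barcodes <- read_barcode_table(barcode_tsv)
  pl <- config$pipeline
  dm <- demultiplex(reads, barcodes, max_mismatch = pl$barcode_mismatch)
  if (nrow(dm$unassigned) > 0) {
    warning(nrow(dm$unassigned), " reads did not match any barcode pair")
  }
  # genotype all assigned reads in one pass, then split by group
  all_assigned <- do.call(rbind, lapply(dm$groups, function(g) g$reads))
  all_seqs <- if (is.null(all_assigned)) character(0) else all_assigned$sequence
  G_all <- genotype_reads(strip_barcodes(all_seqs), pair)
  offsets <- cumsum(c(0, vapply(dm$groups, function(g) g$n_reads, 0)))
  rows <- list()
  profiles <- list()
  calls <- list()
  for (j in seq_along(dm$groups)) {
    g <- dm$groups[[j]]
    Gj <- G_all[seq(offsets[j] + 1, length.out = g$n_reads), , drop = FALSE]
    call <- call_species(g, pair, min_fraction = pl$min_minor_fraction,
                         genotypes = Gj)
    filt <- apply_filters(call, min_reads = pl$min_reads,
                          min_minor = pl$min_minor_fraction)
    calls[[g$sample_id]] <- call
    prof <- NULL
    if (filt$pass) {
      prof <- map_hetdna(call, pair$marker_map)
      profiles[[g$sample_id]] <- prof
    }
    rows[[j]] <- data.frame(
      sample_id = g$sample_id,
      n_reads = g$n_reads,
      pass = filt$pass,
      reason = filt$reason,
      n_species = call$n_species_detected,
      minor_fraction = round(call$minor_fraction, 4),
      direction = if (is.null(prof)) NA_character_ else prof$direction,
      tract_length_up = if (is.null(prof)) NA_integer_ else prof$tract_length_up,
      tract_length_down = if (is.null(prof)) NA_integer_ else prof$tract_length_down,
      terminal_removed_up = if (is.null(prof)) NA else prof$terminal_removed_up,
      terminal_removed_down = if (is.null(prof)) NA else prof$terminal_removed_down,
      snp_states = if (is.null(prof)) NA_character_ else
        paste(substr(prof$per_snp_state, 1, 1), collapse = "")
    )
  }
  profile_df <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(sample_id = character(0), n_reads = integer(0),
               pass = logical(0), reason = character(0),
               n_species = integer(0), minor_fraction = numeric(0),
               direction = character(0), tract_length_up = integer(0),
               tract_length_down = integer(0),
               terminal_removed_up = logical(0),
               terminal_removed_down = logical(0),
               snp_states = character(0))
  }
  summ <- summarize_cohort(profiles, ambig_exclude = pl$ambig_exclude)
  hdr <- std_header(config)
  paths <- list(profiles = file.path(outdir, "profiles.tsv"),
                summary = file.path(outdir, "summary.json"),
                filter_log = file.path(outdir, "filter_log.tsv"))
  write_tsv_with_header(profile_df, paths$profiles, hdr)
  jsonlite::write_json(summary_as_list(summ, config), paths$summary,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  flog <- as.data.frame(table(reason = profile_df$reason))
  names(flog) <- c("reason", "n_groups")
  write_tsv_with_header(flog, paths$filter_log, hdr)
  invisible(list(profiles = profile_df, summary = summ, calls = calls,
                 paths = paths, n_unassigned = nrow(dm$unassigned)))
}

summary_as_list <- function(s, config = NULL) {
  out <- list(
    seed = if (!is.null(config)) config$seed else NULL,
    config_hash = if (!is.null(config)) config_hash(config) else NULL,
    n_profiles = s$n_profiles,
    n_excluded_ambig = s$n_excluded_ambig,
    counts = as.list(s$counts),
    frac_bidirectional = s$frac_bidirectional,
    frac_downstream_of_unidirectional = s$frac_downstream_of_unidirectional,
    terminal_up = s$terminal_up,
    terminal_down = s$terminal_down,
    median_length = s$median_length,
    cum_points = s$cum_points
  )
  out[!vapply(out, is.null, NA)]
}

#' Compare two cohorts with the study's statistical battery
#'
#' Emits one row per comparison: crossover vs noncrossover proportions
#' (when CO counts are supplied), bidirectional vs unidirectional hetDNA,
#' downstream vs upstream position among unidirectional tracts, terminal
#' SNP removal on each side (all 2x2 chi-square, corrected and
#' uncorrected P reported), and pooled tract lengths (Mann-Whitney).
#' Comparisons with an empty category are flagged untestable and the run
#' continues.
#'
#' @param summary_a,summary_b `cohort_summary` objects.
#' @param co_a,co_b Optional `c(k, n)` crossover counts per cohort.
#' @param continuity_correction Yates correction for the reported
#'   `p_value`.
#' @return A data.frame with columns `comparison`, `a`, `b`, `c`, `d`,
#'   `statistic`, `p_value`, `p_uncorrected`, `testable`, `note`.
#' @export
compare_cohorts <- function(summary_a, summary_b, co_a = NULL, co_b = NULL,
                            continuity_correction = TRUE) {
  rows <- list()
  add_chisq <- function(name, a, b, c, d) {
    testable <- all(c(a + b, c + d, a + c, b + d) > 0) && sum(a, b, c, d) > 0
    if (testable) {
      t1 <- chisq_2x2(a, b, c, d, continuity_correction)
      t0 <- chisq_2x2(a, b, c, d, FALSE)
      rows[[length(rows) + 1]] <<- data.frame(
        comparison = name, a = a, b = b, c = c, d = d,
        statistic = t1$statistic, p_value = t1$p_value,
        p_uncorrected = t0$p_value, testable = TRUE, note = "")
    } else {
      rows[[length(rows) + 1]] <<- data.frame(
        comparison = name, a = a, b = b, c = c, d = d,
        statistic = NA_real_, p_value = NA_real_,
        p_uncorrected = NA_real_, testable = FALSE,
        note = "empty category")
    }
  }
  if (!is.null(co_a) && !is.null(co_b)) {
    add_chisq("co_vs_nco", co_a[1], co_a[2] - co_a[1],
              co_b[1], co_b[2] - co_b[1])
  }
  ca <- summary_a$counts; cb <- summary_b$counts
  uni_a <- ca[["unidirectional_down"]] + ca[["unidirectional_up"]]
  uni_b <- cb[["unidirectional_down"]] + cb[["unidirectional_up"]]
  add_chisq("bidirectional_vs_unidirectional",
            ca[["bidirectional"]], uni_a, cb[["bidirectional"]], uni_b)
  add_chisq("downstream_vs_upstream",
            ca[["unidirectional_down"]], ca[["unidirectional_up"]],
            cb[["unidirectional_down"]], cb[["unidirectional_up"]])
  add_chisq("terminal_removed_up",
            summary_a$terminal_up$k,
            summary_a$terminal_up$n - summary_a$terminal_up$k,
            summary_b$terminal_up$k,
            summary_b$terminal_up$n - summary_b$terminal_up$k)
  add_chisq("terminal_removed_down",
            summary_a$terminal_down$k,
            summary_a$terminal_down$n - summary_a$terminal_down$k,
            summary_b$terminal_down$k,
            summary_b$terminal_down$n - summary_b$terminal_down$k)
  la <- summary_a$pooled_lengths; lb <- summary_b$pooled_lengths
  if (length(la) > 0 && length(lb) > 0) {
    mw <- mann_whitney(la, lb)
    rows[[length(rows) + 1]] <- data.frame(
      comparison = "tract_length_mann_whitney",
      a = length(la), b = NA, c = length(lb), d = NA,
      statistic = mw$U, p_value = mw$p_value, p_uncorrected = NA_real_,
      testable = TRUE, note = mw$method)
  } else {
    rows[[length(rows) + 1]] <- data.frame(
      comparison = "tract_length_mann_whitney",
      a = length(la), b = NA, c = length(lb), d = NA,
      statistic = NA_real_, p_value = NA_real_, p_uncorrected = NA_real_,
      testable = FALSE, note = "empty length set")
  }
  do.call(rbind, rows)
}

#' Run the statistical comparisons and write a TSV
#'
#' @param config A `run_config` (supplies the continuity-correction
#'   flag, the seed and the header hash).
#' @param summary_a,summary_b `cohort_summary` objects to compare.
#' @param co_a,co_b Optional crossover counts `c(k, n)`.
#' @param outdir Output directory.
#' @return Invisibly, the comparisons data.frame (also written to
#'   `comparisons.tsv`).
#' @export
run_stats <- function(config, summary_a, summary_b, co_a = NULL, co_b = NULL,
                      outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cmp <- compare_cohorts(summary_a, summary_b, co_a, co_b,
                         config$stats$continuity_correction)
  write_tsv_with_header(cmp, file.path(outdir, "comparisons.tsv"),
                        std_header(config))
  invisible(cmp)
}
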