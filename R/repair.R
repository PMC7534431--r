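# Generative model of DSB repair products. Noncrossovers arise by SDSA
# (hetDNA on one side of the break) or double-Holliday-junction
# dissolution (hetDNA on both sides); crossovers arise by dHJ cleavage.
# In a mismatch-repair-deficient (mlh1) background hetDNA mismatches are
# never corrected, so each SNP of a product is RR, RD/DR (heteroduplex)
# or DD (conversion via polymerase proofreading of the break-proximal
# mismatch).

#' Repair-model parameters
#'
#' Event-level probabilities and the hetDNA tract-length distribution.
#' Defaults reproduce the I-SceI profile: 9% crossovers, 13% of
#' noncrossovers bidirectional, 73% of unidirectional tracts downstream,
#' tract lengths lognormal with median 900 bp, and proofreading
#' probabilities keyed by the distance of the break-proximal SNP from the
#' enzyme-created 3' end (8 nt: 0.83 upstream / 0.35 downstream; 22 nt:
#' 0.08 / 0.07). Which physical end (invading vs annealing) each side's
#' probability describes is deliberately left free: the parameters are
#' per side of the break.
#'
#' @param p_crossover Probability that an event resolves as a crossover.
#' @param p_bidirectional_given_NCO Probability that a noncrossover has
#'   hetDNA on both sides (dissolution) rather than one (SDSA).
#' @param p_downstream_given_unidirectional Probability that a
#'   unidirectional (SDSA) tract lies downstream of the break.
#' @param tract_dist Named list describing the tract-length distribution
#'   measured in bp from the break: `list(name = "lognormal", meanlog,
#'   sdlog)` or `list(name = "fixed", value)`.
#' @param proofread_lookup Named list keyed by first-SNP offset (nt, as a
#'   string) giving `c(up =, down =)` probabilities that the
#'   break-proximal mismatch on that side is excised by proofreading.
#' @param seed Default seed used by [simulate_cohort()].
#' @return An object of class `repair_params`.
#' @export
repair_params <- function(p_crossover = 0.09,
                          p_bidirectional_given_NCO = 0.13,
                          p_downstream_given_unidirectional = 0.73,
                          tract_dist = list(name = "lognormal",
                                            meanlog = log(900), sdlog = 0.6),
                          proofread_lookup = list(
                            `8` = c(up = 0.83, down = 0.35),
                            `22` = c(up = 0.08, down = 0.07)),
                          seed = NULL) {
  probs <- c(p_crossover, p_bidirectional_given_NCO,
             p_downstream_given_unidirectional,
             unlist(proofread_lookup, use.names = FALSE))
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  tract_dist$name <- match.arg(tract_dist$name, c("lognormal", "fixed"))
  if (tract_dist$name == "fixed" && tract_dist$value <= 0) {
    stop("tract length must be positive")
  }
  structure(list(p_crossover = p_crossover,
                 p_bidirectional_given_NCO = p_bidirectional_given_NCO,
                 p_downstream_given_unidirectional = p_downstream_given_unidirectional,
                 tract_dist = tract_dist,
                 proofread_lookup = proofread_lookup,
                 seed = seed),
            class = "repair_params")
}

proofread_probs <- function(params, offset_up, offset_down) {
  look <- function(off) {
    key <- as.character(off)
    if (!is.null(params$proofread_lookup[[key]])) {
      params$proofread_lookup[[key]]
    } else {
      c(up = 0, down = 0)  # offsets beyond the calibrated range: no removal
    }
  }
  c(up = unname(look(offset_up)["up"]),
    down = unname(look(offset_down)["down"]))
}

# tract lengths in bp; a tract that would run past the end of the shared
# homology is bounded by it (clamped at max_bp = homology_span/2)
draw_tract <- function(n, dist, max_bp) {
  if (n == 0L) return(numeric(0))
  if (dist$name == "fixed") {
    if (dist$value > max_bp) stop("fixed tract length exceeds homology span/2")
    return(rep(dist$value, n))
  }
  pmin(stats::rlnorm(n, dist$meanlog, dist$sdlog), max_bp)
}

#' Sample one repair event
#'
#' Draws the pathway (crossover, dissolution, or SDSA up/down), the
#' hetDNA tract extent on each engaged side, and the two per-side
#' proofreading flags. Uses the current RNG state; seed at the cohort
#' level for reproducibility.
#'
#' @param params A `repair_params`.
#' @param map A `marker_map`; supplies the first-SNP offsets (which select
#'   the proofreading probabilities) and the homology span (which caps
#'   tract extents at span/2).
#' @return An object of class `repair_event` with fields `pathway`,
#'   `tract_extent_up`, `tract_extent_down`, `proofread_up`,
#'   `proofread_down`.
#' @export
sample_event <- function(params, map) {
  stopifnot(inherits(params, "repair_params"), inherits(map, "marker_map"))
  max_bp <- map$homology_span / 2
  u <- stats::runif(3)
  pathway <- if (u[1] < params$p_crossover) {
    "crossover"
  } else if (u[2] < params$p_bidirectional_given_NCO) {
    "dissolution"
  } else if (u[3] < params$p_downstream_given_unidirectional) {
    "SDSA_down"
  } else {
    "SDSA_up"
  }
  two_sided <- pathway %in% c("crossover", "dissolution")
  ext <- draw_tract(if (two_sided) 2L else 1L, params$tract_dist, max_bp)
  extent_up <- extent_down <- 0
  if (two_sided) {
    extent_up <- ext[1]; extent_down <- ext[2]
  } else if (pathway == "SDSA_up") {
    extent_up <- ext[1]
  } else {
    extent_down <- ext[1]
  }
  pp <- proofread_probs(params, map$first_offset_up, map$first_offset_down)
  structure(list(pathway = pathway,
                 tract_extent_up = extent_up,
                 tract_extent_down = extent_down,
                 proofread_up = stats::runif(1) < pp["up"],
                 proofread_down = stats::runif(1) < pp["down"]),
            class = "repair_event")
}

#' Realize a repair event as a two-strand genotype product
#'
#' SNPs within a side's tract extent (`|position| <= extent`) become
#' heteroduplex: one strand carries the donor allele. If the side's
#' proofreading flag is set, the break-proximal SNP on that side becomes
#' donor on both strands (a gene-conversion patch); proofreading acts at
#' both ends of the break independently of which side retains hetDNA, as
#' the newly synthesized terminal segment is copied from the donor
#' template after mismatch excision.
#'
#' @param event A `repair_event`.
#' @param map A `marker_map`.
#' @return An object of class `repair_product` with `strand_top` and
#'   `strand_bottom` ("R"/"D" vectors named by SNP position), `truth`
#'   (the event), `is_CO` and `lys_plus`.
#' @export
realize_product <- function(event, map) {
  stopifnot(inherits(event, "repair_event"), inherits(map, "marker_map"))
  max_bp <- map$homology_span / 2
  if (event$tract_extent_up > max_bp || event$tract_extent_down > max_bp) {
    stop("tract extent exceeds homology span/2")
  }
  pos <- map$positions
  n <- length(pos)
  top <- bottom <- rep("R", n)
  in_up <- pos < 0L & abs(pos) <= event$tract_extent_up
  in_down <- pos > 0L & pos <= event$tract_extent_down
  # hetDNA: donor genotype on one strand; upstream and downstream tracts
  # sit on opposite strands of the repaired duplex
  top[in_up] <- "D"
  bottom[in_down] <- "D"
  if (event$proofread_up) {
    i <- match(first_snp_position(map, "up"), pos)
    if (!is.na(i)) top[i] <- bottom[i] <- "D"
  }
  if (event$proofread_down) {
    i <- match(first_snp_position(map, "down"), pos)
    if (!is.na(i)) top[i] <- bottom[i] <- "D"
  }
  names(top) <- names(bottom) <- pos
  structure(list(strand_top = top,
                 strand_bottom = bottom,
                 truth = event,
                 is_CO = event$pathway == "crossover",
                 lys_plus = TRUE),
            class = "repair_product")
}

#' Simulate a cohort of repair products
#'
#' @param n Number of products.
#' @param params A `repair_params`.
#' @param map A `marker_map`.
#' @param seed Seed (defaults to `params$seed`); the cohort is fully
#'   reproducible for a fixed seed.
#' @return A list with `products` (list of `repair_product`) and `truth`
#'   (data.frame row-aligned with `products`: `id`, `pathway`,
#'   `tract_extent_up`, `tract_extent_down`, `proofread_up`,
#'   `proofread_down`, `is_CO`).
#' @export
simulate_cohort <- function(n, params, map, seed = params$seed) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  products <- vector("list", n)
  for (i in seq_len(n)) {
    products[[i]] <- realize_product(sample_event(params, map), map)
  }
  truth <- data.frame(
    id = sprintf("prod%05d", seq_len(n)),
    pathway = vapply(products, function(p) p$truth$pathway, ""),
    tract_extent_up = vapply(products, function(p) p$truth$tract_extent_up, 0),
    tract_extent_down = vapply(products, function(p) p$truth$tract_extent_down, 0),
    proofread_up = vapply(products, function(p) p$truth$proofread_up, NA),
    proofread_down = vapply(products, function(p) p$truth$proofread_down, NA),
    is_CO = vapply(products, function(p) p$is_CO, NA)
  )
  list(products = products, truth = truth)
}

#' Papillation assay for crossover classification
#'
#' Crossover products carry the URA3 marker between hisG direct repeats;
#' secondary recombination pops the marker out, so colonies of CO
#' recombinants throw 5FOA-resistant papillae at a high per-sector rate
#' while NCO colonies show only rare background papillae. A recombinant
#' producing more than three papillae is scored as a crossover.
#'
#' @param product A `repair_product` (or a logical `is_CO`).
#' @param popout_rate Per-sector probability of marker loss in a CO
#'   colony.
#' @param n_sectors Number of colony sectors scored.
#' @param background_rate Per-sector false-papilla rate in NCO colonies.
#' @return Integer papilla count.
#' @export
simulate_papillation <- function(product, popout_rate = 0.5, n_sectors = 30L,
                                 background_rate = 0.02) {
  if (popout_rate < 0 || popout_rate > 1) stop("popout_rate must be in [0, 1]")
  is_co <- if (inherits(product, "repair_product")) product$is_CO else isTRUE(product)
  stats::rbinom(1L, n_sectors, if (is_co) popout_rate else background_rate)
}

#' @rdname simulate_papillation
#' @param count Papilla count.
#' @return `classify_CO`: TRUE iff `count > 3`.
#' @export
classify_CO <- function(count) {
  count > 3
}
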