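# hetDNA mapping pipeline: demultiplex barcoded reads, genotype each read
# at the marker SNPs against the two known alleles, cluster reads into
# sequence species, apply the inclusion filters (>= 20 reads, exactly two
# distinct species, minor species >= 10%), classify each SNP as
# RR/HET/DD, and delineate hetDNA tract direction and lengths.

#' Demultiplex reads by barcode pair
#'
#' Matches the first 16 nt of each read against the forward barcodes and
#' the reverse-complemented last 16 nt against the reverse barcodes.
#' Matching is exact by default; a Hamming tolerance can be configured.
#' Every read lands in exactly one group or the unassigned bin.
#'
#' @param reads A data.frame with columns `id`, `sequence`.
#' @param barcode_table Data.frame with `sample_id`, `forward_barcode`,
#'   `reverse_barcode`; pairs must be unique.
#' @param max_mismatch Maximum Hamming distance per barcode (default 0 =
#'   exact).
#' @return A list with `groups` (named list of `barcode_group`: fields
#'   `sample_id`, `forward_barcode`, `reverse_barcode`, `reads`,
#'   `n_reads`) and `unassigned` (data.frame of unmatched reads). Groups
#'   are present for every table row, including empty ones.
#' @export
demultiplex <- function(reads, barcode_table, max_mismatch = 0L) {
  key <- paste(barcode_table$forward_barcode, barcode_table$reverse_barcode)
  if (anyDuplicated(key)) stop("duplicate barcode pair in table")
  len <- nchar(reads$sequence)
  fwd <- substr(reads$sequence, 1L, 16L)
  rev_obs <- revcomp(substr(reads$sequence, len - 15L, len))
  idx <- match(paste(fwd, rev_obs), key)
  if (max_mismatch > 0L) {
    for (i in which(is.na(idx))) {
      df <- hamming(fwd[i], barcode_table$forward_barcode)
      dr <- hamming(rev_obs[i], barcode_table$reverse_barcode)
      ok <- which(df <= max_mismatch & dr <= max_mismatch)
      if (length(ok) > 0L) idx[i] <- ok[which.min(df[ok] + dr[ok])]
    }
  }
  groups <- lapply(seq_len(nrow(barcode_table)), function(j) {
    r <- reads[!is.na(idx) & idx == j, , drop = FALSE]
    rownames(r) <- NULL
    structure(list(sample_id = barcode_table$sample_id[j],
                   forward_barcode = barcode_table$forward_barcode[j],
                   reverse_barcode = barcode_table$reverse_barcode[j],
                   reads = r, n_reads = nrow(r)),
              class = "barcode_group")
  })
  names(groups) <- barcode_table$sample_id
  list(groups = groups,
       unassigned = reads[is.na(idx), , drop = FALSE])
}

hamming <- function(x, ys) {
  xs <- strsplit(x, "")[[1]]
  vapply(strsplit(ys, ""), function(y) sum(xs != y), 0L)
}

# strip the barcode layout from read sequences
strip_barcodes <- function(seqs) {
  substr(seqs, 17L, nchar(seqs) - 16L)
}

#' Genotype reads at the marker SNPs
#'
#' For each SNP, a read is called `R` if its 11-nt window centred on the
#' SNP equals the recipient base embedded in the 5-nt reference flanking
#' context on both sides, `D` for the donor base in the same context, and
#' `N` otherwise (sequencing error in the window, or window out of
#' range). Reads shorter than the amplicon span are called `N` at the
#' missing positions with a warning.
#'
#' @param seqs Character vector of barcode-stripped read sequences.
#' @param pair A `substrate_pair`.
#' @return A character matrix (reads x SNPs, columns named by signed
#'   position) over `R`/`D`/`N`.
#' @export
genotype_reads <- function(seqs, pair) {
  map <- pair$marker_map
  m <- length(map$positions)
  G <- matrix("N", nrow = length(seqs), ncol = m,
              dimnames = list(NULL, as.character(map$positions)))
  if (length(seqs) == 0L || m == 0L) return(G)
  if (any(nchar(seqs) < nchar(pair$repaired_sequence))) {
    warning("some reads are shorter than the amplicon span; ",
            "out-of-range SNPs called N")
  }
  ref <- pair$repaired_sequence
  idx <- pos_to_index(pair, map$positions)
  for (j in seq_len(m)) {
    ctx_r <- substr(ref, idx[j] - 5L, idx[j] + 5L)
    ctx_d <- ctx_r
    substr(ctx_d, 6L, 6L) <- map$donor_base[j]
    obs <- substr(seqs, idx[j] - 5L, idx[j] + 5L)
    G[obs == ctx_r, j] <- "R"
    G[obs == ctx_d, j] <- "D"
  }
  G
}

# deterministic clustering of genotype vectors:
#  1. unique patterns counted, ordered by decreasing count then pattern
#  2. greedy merge: a pattern joins the first (largest) cluster whose
#     founding pattern it is compatible with (N is a wildcard)
#  3. clusters with >= min_fraction of reads are species seeds
#  4. reads of non-seed clusters are absorbed into the nearest seed by
#     Hamming distance over jointly confident positions (ties -> the
#     larger seed)
cluster_genotypes <- function(G, min_fraction = 0.10) {
  n <- nrow(G)
  pat <- do.call(paste, c(as.data.frame(G, stringsAsFactors = FALSE), sep = ""))
  tab <- table(pat)
  ord <- order(-as.integer(tab), names(tab))
  upat <- names(tab)[ord]
  ucount <- as.integer(tab)[ord]
  umat <- do.call(rbind, strsplit(upat, ""))
  founders <- integer(0)   # row index into umat
  members <- list()        # pattern indices per cluster
  for (i in seq_along(upat)) {
    placed <- FALSE
    for (k in seq_along(founders)) {
      f <- umat[founders[k], ]
      p <- umat[i, ]
      both <- f != "N" & p != "N"
      if (all(f[both] == p[both])) {
        members[[k]] <- c(members[[k]], i); placed <- TRUE; break
      }
    }
    if (!placed) {
      founders <- c(founders, i)
      members[[length(founders)]] <- i
    }
  }
  csize <- vapply(members, function(m) sum(ucount[m]), 0L)
  ord_c <- order(-csize, seq_along(csize))
  members <- members[ord_c]; csize <- csize[ord_c]
  seeds <- which(csize / n >= min_fraction)
  list(umat = umat, ucount = ucount, pat = pat, upat = upat,
       members = members, csize = csize, seeds = seeds)
}

#' Call the sequence species of one barcode group
#'
#' Reads are clustered by genotype vector with `N` treated as a wildcard;
#' clusters holding at least `min_fraction` of the group's reads are the
#' detected species, and reads in smaller clusters (presumed sequencing
#' errors) are absorbed into the nearest species by Hamming distance.
#' The two largest species define the haplotypes by per-position majority
#' over their member reads. Two species are distinct iff they differ at
#' at least one SNP confidently called in both.
#'
#' @param group A `barcode_group`.
#' @param pair A `substrate_pair`.
#' @param min_fraction Minimum read fraction for a cluster to count as a
#'   species (0.10 per the inclusion rule).
#' @param genotypes Optional precomputed genotype matrix for the group's
#'   reads (rows aligned with `group$reads`), to avoid re-genotyping.
#' @return An object of class `species_call`: `haplotype_A`,
#'   `haplotype_B` (or NULL), `count_A`, `count_B`, `minor_fraction`,
#'   `n_species_detected`, `distinct`, `uncallable`, `n_reads`.
#' @export
call_species <- function(group, pair, min_fraction = 0.10,
                         genotypes = NULL) {
  stopifnot(inherits(group, "barcode_group"))
  n <- group$n_reads
  if (n == 0L) {
    return(structure(list(haplotype_A = NULL, haplotype_B = NULL,
                          count_A = 0L, count_B = 0L,
                          minor_fraction = NA_real_,
                          n_species_detected = 0L, distinct = FALSE,
                          uncallable = TRUE, n_reads = 0L),
                     class = "species_call"))
  }
  G <- if (is.null(genotypes)) {
    genotype_reads(strip_barcodes(group$reads$sequence), pair)
  } else genotypes
  if (all(G == "N")) {
    return(structure(list(haplotype_A = NULL, haplotype_B = NULL,
                          count_A = 0L, count_B = 0L,
                          minor_fraction = NA_real_,
                          n_species_detected = 0L, distinct = FALSE,
                          uncallable = TRUE, n_reads = n),
                     class = "species_call"))
  }
  cl <- cluster_genotypes(G, min_fraction)
  seeds <- cl$seeds
  if (length(seeds) == 0L) {
    # no cluster reaches the species threshold: treat the largest as the
    # sole species so the group fails downstream as single-species
    seeds <- 1L
  }
  # consensus of each seed cluster before absorption (used as the
  # reference for distance assignment)
  seed_cons <- lapply(seeds, function(k) {
    consensus_rows(cl$umat, cl$members[[k]], cl$ucount)
  })
  # absorb non-seed clusters' reads into the nearest seed
  counts <- cl$csize[seeds]
  assigned_members <- cl$members[seeds]
  non_seed <- setdiff(seq_along(cl$members), seeds)
  for (k in non_seed) {
    for (i in cl$members[[k]]) {
      p <- cl$umat[i, ]
      d <- vapply(seed_cons, function(cons) {
        both <- cons != "N" & p != "N"
        sum(cons[both] != p[both])
      }, 0L)
      best <- which(d == min(d))[1]  # ties -> larger (earlier) seed
      counts[best] <- counts[best] + cl$ucount[i]
      assigned_members[[best]] <- c(assigned_members[[best]], i)
    }
  }
  ord <- order(-counts, seq_along(counts))
  counts <- counts[ord]
  assigned_members <- assigned_members[ord]
  hap <- lapply(assigned_members, function(m) {
    stats::setNames(consensus_rows(cl$umat, m, cl$ucount), colnames(G))
  })
  hap_A <- hap[[1]]
  hap_B <- if (length(hap) >= 2L) hap[[2]] else NULL
  distinct <- FALSE
  if (!is.null(hap_B)) {
    both <- hap_A != "N" & hap_B != "N"
    distinct <- any(hap_A[both] != hap_B[both])
  }
  count_A <- counts[1]
  count_B <- if (length(counts) >= 2L) counts[2] else 0L
  structure(list(haplotype_A = hap_A, haplotype_B = hap_B,
                 count_A = as.integer(count_A),
                 count_B = as.integer(count_B),
                 minor_fraction = count_B / (count_A + count_B),
                 n_species_detected = length(cl$seeds),
                 distinct = distinct,
                 uncallable = FALSE, n_reads = n),
            class = "species_call")
}

# weighted per-position majority over pattern rows; ties and all-N -> N
consensus_rows <- function(umat, rows, weights) {
  sub <- umat[rows, , drop = FALSE]
  w <- weights[rows]
  apply_cols <- seq_len(ncol(sub))
  vapply(apply_cols, function(j) {
    v <- sub[, j]
    keep <- v != "N"
    if (!any(keep)) return("N")
    tt <- tapply(w[keep], v[keep], sum)
    mx <- names(tt)[tt == max(tt)]
    if (length(mx) > 1L) "N" else mx
  }, "")
}

#' Apply the inclusion filters
#'
#' A barcode group is included iff it has at least 20 CCS reads, exactly
#' two distinct sequence species, and the minor species comprises at
#' least 10% of the reads. Groups with only one species (no evidence of
#' hetDNA) are excluded, as are groups with more than two species at or
#' above the species threshold.
#'
#' @param call A `species_call`.
#' @param n_reads Read count for the group (defaults to `call$n_reads`).
#' @param min_reads Minimum read count (20).
#' @param min_minor Minimum minor-species fraction (0.10); compared in
#'   exact integer arithmetic on the read counts.
#' @return A list `(pass, reason)`; `reason` is one of `pass`,
#'   `too_few_reads`, `uncallable`, `single_species`, `multi_species`,
#'   `minor_below_10pct`.
#' @export
apply_filters <- function(call, n_reads = call$n_reads, min_reads = 20L,
                          min_minor = 0.10) {
  fail <- function(reason) list(pass = FALSE, reason = reason)
  if (n_reads < min_reads) return(fail("too_few_reads"))
  if (isTRUE(call$uncallable)) return(fail("uncallable"))
  if (call$n_species_detected < 2L || !isTRUE(call$distinct)) {
    return(fail("single_species"))
  }
  if (call$n_species_detected > 2L) return(fail("multi_species"))
  # exact comparison on counts: count_B / (count_A + count_B) >= min_minor
  if (call$count_B < min_minor * (call$count_A + call$count_B) - 1e-9) {
    return(fail("minor_below_10pct"))
  }
  list(pass = TRUE, reason = "pass")
}

#' Map the hetDNA profile of a species call
#'
#' Classifies every SNP from the two haplotypes: `RR` (both recipient),
#' `HET` (heteroduplex: one recipient, one donor), `DD` (conversion:
#' both donor), `AMBIG` (any `N`). The break-proximal SNP on a side is
#' recorded as "terminal removed" when it is `DD` (NA when `AMBIG`).
#' Tract length per side is the distance from the break to the most
#' break-distal `HET` SNP on that side (0 if none); interior non-HET
#' positions do not split a tract. Direction is assigned from which sides
#' carry hetDNA.
#'
#' @param call A passing `species_call`.
#' @param map A `marker_map`.
#' @return An object of class `hetdna_profile`: `per_snp_state` (named by
#'   position), `direction` (`unidirectional_up`, `unidirectional_down`,
#'   `bidirectional`, `none`), `tract_length_up`, `tract_length_down`,
#'   `terminal_removed_up`, `terminal_removed_down`, `ambig_fraction`.
#' @export
map_hetdna <- function(call, map) {
  stopifnot(inherits(call, "species_call"), inherits(map, "marker_map"))
  if (is.null(call$haplotype_A) || is.null(call$haplotype_B)) {
    stop("map_hetdna requires a two-species call")
  }
  A <- call$haplotype_A; B <- call$haplotype_B
  pos <- map$positions
  state <- rep("AMBIG", length(pos))
  nn <- A != "N" & B != "N"
  state[nn & A == "R" & B == "R"] <- "RR"
  state[nn & A == "D" & B == "D"] <- "DD"
  state[nn & A != B] <- "HET"
  names(state) <- pos
  term <- function(side) {
    p <- first_snp_position(map, side)
    if (is.na(p)) return(NA)
    s <- state[as.character(p)]
    if (s == "AMBIG") NA else unname(s == "DD")
  }
  tract_len <- function(side) {
    p <- if (side == "up") pos[pos < 0L & state == "HET"] else pos[pos > 0L & state == "HET"]
    if (length(p) == 0L) 0L else max(abs(p))
  }
  len_up <- tract_len("up"); len_down <- tract_len("down")
  direction <- if (len_up > 0L && len_down > 0L) {
    "bidirectional"
  } else if (len_down > 0L) {
    "unidirectional_down"
  } else if (len_up > 0L) {
    "unidirectional_up"
  } else "none"
  structure(list(per_snp_state = state,
                 direction = direction,
                 tract_length_up = as.integer(len_up),
                 tract_length_down = as.integer(len_down),
                 terminal_removed_up = term("up"),
                 terminal_removed_down = term("down"),
                 ambig_fraction = mean(state == "AMBIG")),
            class = "hetdna_profile")
}

#' hetDNA profile straight from a product's true strands
#'
#' Bypasses read emission and species calling: builds the species call
#' directly from the two simulated strands. Used for truth tables and
#' parameter-recovery checks.
#'
#' @param product A `repair_product`.
#' @param map A `marker_map`.
#' @return A `hetdna_profile`.
#' @export
truth_profile <- function(product, map) {
  call <- structure(list(haplotype_A = product$strand_top,
                         haplotype_B = product$strand_bottom,
                         count_A = 1L, count_B = 1L, minor_fraction = 0.5,
                         n_species_detected = 2L, distinct = TRUE,
                         uncallable = FALSE, n_reads = 2L),
                    class = "species_call")
  map_hetdna(call, map)
}

#' Summarize a cohort of hetDNA profiles
#'
#' Category counts and fractions are computed over profiles with hetDNA
#' (direction != none); terminal-removal fractions per side exclude
#' profiles whose terminal state is ambiguous; pooled tract lengths take
#' one length per side from bidirectional profiles and the single side
#' from unidirectional ones. Profiles with more than `ambig_exclude` of
#' their SNPs ambiguous are dropped from the summary.
#'
#' @param profiles List of `hetdna_profile`.
#' @param ambig_exclude Maximum tolerated AMBIG fraction per profile.
#' @return An object of class `cohort_summary`.
#' @export
summarize_cohort <- function(profiles, ambig_exclude = 0.2) {
  keep <- vapply(profiles, function(p) p$ambig_fraction <= ambig_exclude, NA)
  excluded <- sum(!keep)
  profiles <- profiles[keep]
  dirs <- vapply(profiles, function(p) p$direction, "")
  counts <- c(bidirectional = sum(dirs == "bidirectional"),
              unidirectional_down = sum(dirs == "unidirectional_down"),
              unidirectional_up = sum(dirs == "unidirectional_up"),
              none = sum(dirs == "none"))
  n_info <- sum(counts[c("bidirectional", "unidirectional_down",
                         "unidirectional_up")])
  n_uni <- counts[["unidirectional_down"]] + counts[["unidirectional_up"]]
  term_stats <- function(field) {
    v <- vapply(profiles[dirs != "none"], function(p) p[[field]], NA)
    v <- v[!is.na(v)]
    list(k = sum(v), n = length(v),
         frac = if (length(v) > 0) mean(v) else NA_real_)
  }
  pooled <- unlist(lapply(profiles, function(p) {
    out <- c()
    if (p$tract_length_up > 0L) out <- c(out, p$tract_length_up)
    if (p$tract_length_down > 0L) out <- c(out, p$tract_length_down)
    out
  }))
  pooled <- if (is.null(pooled)) integer(0) else sort(pooled)
  cum_points <- if (length(pooled) > 0) {
    u <- unique(pooled)
    data.frame(length = u, cum_fraction = stats::ecdf(pooled)(u))
  } else {
    data.frame(length = integer(0), cum_fraction = numeric(0))
  }
  structure(list(
    n_profiles = length(profiles),
    n_excluded_ambig = excluded,
    counts = counts,
    n_informative = n_info,
    frac_bidirectional = if (n_info > 0) counts[["bidirectional"]] / n_info else NA_real_,
    frac_downstream_of_unidirectional =
      if (n_uni > 0) counts[["unidirectional_down"]] / n_uni else NA_real_,
    terminal_up = term_stats("terminal_removed_up"),
    terminal_down = term_stats("terminal_removed_down"),
    pooled_lengths = pooled,
    median_length = if (length(pooled) > 0) stats::median(pooled) else NA_real_,
    cum_points = cum_points
  ), class = "cohort_summary")
}
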