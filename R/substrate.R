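# Substrate geometry: recipient/donor allele pair, SNP marker map, and
# nuclease cleavage chemistry. Coordinates are signed nt offsets from the
# break: negative = upstream (promoter-proximal) of the inserted cleavage
# cassette, positive = downstream (promoter-distal). There is no position 0.

BASES <- c("A", "C", "G", "T")

#' Nuclease specification
#'
#' Describes the enzyme that creates the initiating double-strand break:
#' the polarity and length of the overhangs it leaves, the size of any gap
#' that end processing creates relative to the donor, and its recognition
#' site. Presets are provided for the two enzymes of interest: I-SceI
#' (4-nt 3' overhangs, no gap) and a zinc-finger nuclease (4-nt 5'
#' overhangs; resection of the duplicated spacer leaves an 8-bp gap
#' relative to the donor).
#'
#' @param name Identifier for the enzyme.
#' @param overhang_polarity One of `"three_prime"`, `"five_prime"`,
#'   `"blunt"`.
#' @param overhang_length Overhang length in nt; must be 0 iff blunt.
#' @param gap_after_processing Gap in bp left after end processing,
#'   relative to the donor allele (0 for I-SceI, 8 for the ZFN).
#' @param site Recognition/cleavage site sequence present in the recipient
#'   allele only.
#' @return An object of class `enzyme_spec`.
#' @export
enzyme_spec <- function(name, overhang_polarity, overhang_length,
                        gap_after_processing = 0L, site) {
  overhang_polarity <- match.arg(overhang_polarity,
                                 c("three_prime", "five_prime", "blunt"))
  overhang_length <- as.integer(overhang_length)
  if (overhang_length < 0L) stop("overhang_length must be >= 0")
  if ((overhang_polarity == "blunt") != (overhang_length == 0L)) {
    stop("blunt ends require overhang_length 0 and vice versa")
  }
  if (gap_after_processing < 0L) stop("gap_after_processing must be >= 0")
  if (!grepl("^[ACGT]+$", site)) stop("site must be an ACGT string")
  if (nchar(site) < 4L) stop("site must be at least 4 nt")
  structure(list(name = name,
                 overhang_polarity = overhang_polarity,
                 overhang_length = overhang_length,
                 gap_after_processing = as.integer(gap_after_processing),
                 site = site),
            class = "enzyme_spec")
}

#' @rdname enzyme_spec
#' @export
enzyme_isce1 <- function() {
  enzyme_spec("I-SceI", "three_prime", 4L, 0L, site = "TAGGGATAACAGGGTAAT")
}

#' @rdname enzyme_spec
#' @details The ZFN preset uses a representative synthetic site (two 9-bp
#'   zinc-finger binding sites flanking a 6-bp spacer); the site sequence
#'   is a configuration input, not data.
#' @export
enzyme_zfn <- function() {
  enzyme_spec("ZFN", "five_prime", 4L, 8L,
              site = "GACGCTGCTATGGCATCCGTTCAG")
}

#' SNP marker map for the recombination substrates
#'
#' Builds the coordinate frame used by everything downstream: SNP positions
#' as signed nt offsets from the break, with the recipient and donor base
#' at each position. Downstream positions are `first_offset_down`,
#' `first_offset_down + spacing`, ...; upstream positions are mirrored
#' with negative sign. Default bases alternate transitions (A<->G, C<->T)
#' so that recipient != donor everywhere; explicit base vectors may be
#' supplied instead.
#'
#' @param n_up,n_down Number of SNPs upstream / downstream of the break.
#' @param spacing Distance between adjacent SNPs on one side, in bp. Must
#'   exceed 11 bp so that the 5-nt genotyping contexts of adjacent SNPs
#'   cannot overlap.
#' @param first_offset_up,first_offset_down Distance of the break-proximal
#'   SNP from the break on each side, in nt (8 or 22 in the systems this
#'   package emulates).
#' @param recipient_bases,donor_bases Optional explicit base vectors
#'   (ordered by ascending position) overriding the deterministic default.
#' @param homology_span Total homology length in bp shared by the two
#'   substrates; defaults to twice the most distal SNP offset plus a 30-bp
#'   flank on each side.
#' @return An object of class `marker_map` with elements `positions`,
#'   `recipient_base`, `donor_base`, `first_offset_up`,
#'   `first_offset_down`, `spacing`, `homology_span`.
#' @examples
#' m <- build_marker_map(2, 3, spacing = 50, first_offset_up = 22,
#'                       first_offset_down = 22)
#' m$positions  # -72 -22 22 72 122
#' @export
build_marker_map <- function(n_up, n_down, spacing = 50L,
                             first_offset_up = 22L, first_offset_down = 22L,
                             recipient_bases = NULL, donor_bases = NULL,
                             homology_span = NULL) {
  n_up <- as.integer(n_up); n_down <- as.integer(n_down)
  if (n_up < 0L || n_down < 0L) stop("n_up and n_down must be >= 0")
  if (spacing <= 0L) stop("spacing must be > 0")
  if (spacing <= 11L) {
    stop("spacing of ", spacing, " bp is too small: the 11-nt genotyping ",
         "windows of adjacent SNPs would overlap (spacing must exceed 11 bp)")
  }
  if (first_offset_up <= 0L || first_offset_down <= 0L) {
    stop("first offsets must be > 0")
  }
  down <- if (n_down > 0L) first_offset_down + spacing * (seq_len(n_down) - 1L) else integer(0)
  up <- if (n_up > 0L) -(first_offset_up + spacing * (seq_len(n_up) - 1L)) else integer(0)
  positions <- as.integer(sort(c(up, down)))
  n <- length(positions)
  if (anyDuplicated(positions)) stop("duplicate SNP positions")
  if (is.null(recipient_bases)) {
    recipient_bases <- rep_len(c("A", "C"), n)
    donor_bases <- rep_len(c("G", "T"), n)  # transition partners
  } else {
    if (is.null(donor_bases)) stop("donor_bases required with recipient_bases")
    if (length(recipient_bases) != n || length(donor_bases) != n) {
      stop("base vectors must have one entry per SNP")
    }
    if (!all(recipient_bases %in% BASES) || !all(donor_bases %in% BASES)) {
      stop("bases must be in A/C/G/T")
    }
  }
  if (n > 0L && any(recipient_bases == donor_bases)) {
    stop("recipient and donor base must differ at every SNP")
  }
  if (is.null(homology_span)) {
    homology_span <- if (n == 0L) 200L else 2L * (max(abs(positions)) + 30L)
  }
  structure(list(positions = positions,
                 recipient_base = recipient_bases,
                 donor_base = donor_bases,
                 first_offset_up = as.integer(first_offset_up),
                 first_offset_down = as.integer(first_offset_down),
                 spacing = as.integer(spacing),
                 homology_span = as.integer(homology_span)),
            class = "marker_map")
}

# Break-proximal SNP position on one side (NA if the side has no SNPs).
first_snp_position <- function(map, side = c("up", "down")) {
  side <- match.arg(side)
  p <- map$positions
  if (side == "up") {
    p <- p[p < 0L]
    if (length(p) == 0L) NA_integer_ else max(p)
  } else {
    p <- p[p > 0L]
    if (length(p) == 0L) NA_integer_ else min(p)
  }
}

#' Recipient/donor substrate pair
#'
#' Renders the two substrate sequences. The recipient allele carries the
#' enzyme's cleavable site (padded so that the insertion is a -1
#' frameshift relative to the surrounding reading frame); the donor
#' carries a non-cleavable version of the site in which the 4-bp region
#' normally flanked by the enzyme nicks is duplicated, plus the donor base
#' at every SNP. The repaired recipient (donor tetramer copied in) is
#' rendered as well and serves as the amplicon reference for genotyping.
#'
#' @param map A `marker_map`.
#' @param enzyme An `enzyme_spec`.
#' @param seed Integer seed for the random homologous backbone.
#' @param arm_pad Extra homologous sequence beyond the most distal SNP on
#'   each side, in bp.
#' @return An object of class `substrate_pair` with the rendered
#'   `recipient_sequence`, `donor_sequence`, `repaired_sequence`,
#'   `duplicated_tetramer`, arm bookkeeping and the inputs.
#' @export
substrate_pair <- function(map, enzyme, seed = 1L, arm_pad = 30L) {
  stopifnot(inherits(map, "marker_map"), inherits(enzyme, "enzyme_spec"))
  max_up <- max(c(abs(map$positions[map$positions < 0L]), 0L))
  max_down <- max(c(map$positions[map$positions > 0L], 0L))
  arm_up_len <- max_up + arm_pad
  arm_down_len <- max_down + arm_pad

  site <- enzyme$site
  # pad the insertion so its length is 2 mod 3: a -1 frameshift that the
  # 4-bp duplication corrects (site_len + pad + 4 is a multiple of 3)
  pad_len <- (2L - nchar(site)) %% 3L
  tet_start <- (nchar(site) - 4L) %/% 2L + 1L
  tetramer <- substr(site, tet_start, tet_start + 3L)
  site_nc <- paste0(substr(site, 1L, tet_start + 3L), tetramer,
                    substr(site, tet_start + 4L, nchar(site)))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  arm_up <- sample(BASES, arm_up_len, replace = TRUE)
  arm_down <- sample(BASES, arm_down_len, replace = TRUE)
  pad <- if (pad_len > 0L) paste(sample(BASES, pad_len, replace = TRUE), collapse = "") else ""

  # place recipient bases at SNP offsets (up: offset -k -> arm_up index
  # arm_up_len - k + 1; down: offset +k -> arm_down index k)
  up_idx <- map$positions < 0L
  recip_up <- arm_up; recip_down <- arm_down
  recip_up[arm_up_len + map$positions[up_idx] + 1L] <- map$recipient_base[up_idx]
  recip_down[map$positions[!up_idx]] <- map$recipient_base[!up_idx]
  donor_up <- recip_up; donor_down <- recip_down
  donor_up[arm_up_len + map$positions[up_idx] + 1L] <- map$donor_base[up_idx]
  donor_down[map$positions[!up_idx]] <- map$donor_base[!up_idx]

  recip_up <- paste(recip_up, collapse = "")
  recip_down <- paste(recip_down, collapse = "")
  donor_up <- paste(donor_up, collapse = "")
  donor_down <- paste(donor_down, collapse = "")

  recipient <- paste0(recip_up, site, pad, recip_down)
  donor <- paste0(donor_up, site_nc, pad, donor_down)
  repaired <- paste0(recip_up, site_nc, pad, recip_down)

  if (lengths(regmatches(recipient, gregexpr(site, recipient, fixed = TRUE))) != 1L) {
    stop("recipient must contain the enzyme site exactly once; ",
         "re-seed the backbone")
  }
  if (grepl(site, donor, fixed = TRUE)) {
    stop("donor accidentally contains a cleavable site; re-seed the backbone")
  }

  structure(list(recipient_sequence = recipient,
                 donor_sequence = donor,
                 repaired_sequence = repaired,
                 marker_map = map,
                 enzyme = enzyme,
                 duplicated_tetramer = tetramer,
                 arm_up_len = arm_up_len,
                 insert_len_recipient = nchar(site) + pad_len,
                 insert_len_repaired = nchar(site_nc) + pad_len,
                 seed = as.integer(seed)),
            class = "substrate_pair")
}

#' Map signed SNP offsets to 1-based indices in the repaired amplicon
#'
#' @param pair A `substrate_pair`.
#' @param positions Signed offsets (no zero).
#' @return Integer indices into `pair$repaired_sequence`.
#' @export
pos_to_index <- function(pair, positions) {
  if (any(positions == 0L)) stop("position 0 does not exist")
  ifelse(positions < 0L,
         pair$arm_up_len + positions + 1L,
         pair$arm_up_len + pair$insert_len_repaired + positions)
}

#' Re-detect SNPs by comparing rendered recipient and donor arms
#'
#' Round-trip check: compares the homologous arms of the rendered
#' recipient and donor sequences (excluding the cleavage-site insertion)
#' and returns the differing positions with their bases, in the signed
#' offset frame.
#'
#' @param pair A `substrate_pair`.
#' @return A data.frame with columns `position`, `recipient_base`,
#'   `donor_base`.
#' @export
detect_snps <- function(pair) {
  a <- pair$arm_up_len
  r_up <- strsplit(substr(pair$recipient_sequence, 1L, a), "")[[1]]
  d_up <- strsplit(substr(pair$donor_sequence, 1L, a), "")[[1]]
  r_down <- strsplit(substr(pair$recipient_sequence,
                            a + pair$insert_len_recipient + 1L,
                            nchar(pair$recipient_sequence)), "")[[1]]
  d_down <- strsplit(substr(pair$donor_sequence,
                            a + pair$insert_len_repaired + 1L,
                            nchar(pair$donor_sequence)), "")[[1]]
  i_up <- which(r_up != d_up)
  i_down <- which(r_down != d_down)
  data.frame(position = c(i_up - a - 1L, i_down),
             recipient_base = c(r_up[i_up], r_down[i_down]),
             donor_base = c(d_up[i_up], d_down[i_down]))
}

#' Cleave the recipient allele
#'
#' Verifies that the enzyme site is present in the recipient and absent
#' from the donor, and returns the two broken-end records with overhang
#' polarity, length and sequence (the duplicated tetramer region lies
#' between the two nicks).
#'
#' @param pair A `substrate_pair`.
#' @return A list of two `broken_end` records (`side` = "up"/"down") with
#'   fields `polarity`, `overhang_length`, `overhang_sequence` and
#'   `gap_after_processing`.
#' @export
apply_cleavage <- function(pair) {
  stopifnot(inherits(pair, "substrate_pair"))
  enz <- pair$enzyme
  if (!grepl(enz$site, pair$recipient_sequence, fixed = TRUE)) {
    stop("enzyme site absent from recipient: mis-built substrate")
  }
  if (grepl(enz$site, pair$donor_sequence, fixed = TRUE)) {
    stop("donor allele is cleavable: mis-built substrate")
  }
  ov <- if (enz$overhang_polarity == "blunt") "" else pair$duplicated_tetramer
  mk <- function(side, seq) {
    structure(list(side = side, polarity = enz$overhang_polarity,
                   overhang_length = enz$overhang_length,
                   overhang_sequence = seq,
                   gap_after_processing = enz$gap_after_processing),
              class = "broken_end")
  }
  list(up = mk("up", if (nzchar(ov)) revcomp(ov) else ""),
       down = mk("down", ov))
}

#' Is the reading frame restored by copying the duplicated tetramer?
#'
#' Position arithmetic only: the cleavage-site insertion shifts the frame
#' by -1 (length = 2 mod 3) and copying the donor's 4 extra bp restores it.
#'
#' @param pair A `substrate_pair`.
#' @return Logical scalar.
#' @export
frame_restored <- function(pair) {
  (pair$insert_len_recipient %% 3L == 2L) &&
    ((pair$insert_len_recipient + 4L) %% 3L == 0L)
}

#' Export the substrate alleles as FASTA
#'
#' Writes two records, `recipient` and `donor`.
#'
#' @param pair A `substrate_pair`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_substrate_fasta <- function(pair, path) {
  x <- Biostrings::DNAStringSet(c(recipient = pair$recipient_sequence,
                                  donor = pair$donor_sequence))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# reverse complement of an ACGTN character string (vectorized)
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(x, ""), function(s) paste(rev(s), collapse = ""), ""))
}
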