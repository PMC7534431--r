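# Shared fixtures: a small substrate (8 SNPs, 50-bp spacing, first SNP
# 22 nt from the break) keeps read-level tests fast; the full-scale
# geometry (84 SNPs, 4.2-kb homology) is built where a test needs it.

small_map <- function(...) {
  build_marker_map(4, 4, spacing = 50, first_offset_up = 22,
                   first_offset_down = 22, ...)
}

small_pair <- function(enzyme = enzyme_isce1(), seed = 3) {
  substrate_pair(small_map(), enzyme, seed = seed)
}

paper_map <- function(first_offset = 22) {
  build_marker_map(42, 42, spacing = 50, first_offset_up = first_offset,
                   first_offset_down = first_offset)
}

# a repair event with everything pinned down
fixed_event <- function(pathway = "SDSA_down", extent_up = 0,
                        extent_down = 0, proofread_up = FALSE,
                        proofread_down = FALSE) {
  structure(list(pathway = pathway, tract_extent_up = extent_up,
                 tract_extent_down = extent_down,
                 proofread_up = proofread_up,
                 proofread_down = proofread_down),
            class = "repair_event")
}

# a species call built directly from two haplotype vectors
manual_call <- function(A, B, count_A = 15L, count_B = 15L, positions) {
  names(A) <- names(B) <- positions
  structure(list(haplotype_A = A, haplotype_B = B,
                 count_A = count_A, count_B = count_B,
                 minor_fraction = count_B / (count_A + count_B),
                 n_species_detected = 2L, distinct = TRUE,
                 uncallable = FALSE, n_reads = count_A + count_B),
            class = "species_call")
}

# emit a full barcode-grouped read set for one product and call it back
roundtrip_call <- function(product, pair, n_reads = 30, per_base_error = 0,
                           minor_fraction = 0.5, seed = 11) {
  bc <- barcode_pair(strrep("A", 16), strrep("G", 16))
  em <- read_emission_params(n_reads = n_reads,
                             minor_fraction = minor_fraction,
                             per_base_error = per_base_error, seed = seed)
  reads <- emit_reads(product, bc, em, pair)
  tab <- data.frame(sample_id = "S1", forward_barcode = strrep("A", 16),
                    reverse_barcode = strrep("G", 16))
  dm <- demultiplex(reads, tab)
  call_species(dm$groups$S1, pair)
}
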