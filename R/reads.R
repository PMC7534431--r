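# Barcoded CCS-like amplicon read emission. Each recombinant colony is
# amplified with a unique 16-nt forward/reverse barcode pair; the two
# strands of its repaired duplex yield (up to) two sequence species among
# the reads. Read layout: forward barcode + amplicon +
# reverse-complement(reverse barcode). Only substitution errors are
# modeled by default; an indel rate exists but defaults to 0.

#' Barcode pair
#'
#' @param forward_barcode,reverse_barcode 16-nt ACGT strings.
#' @return An object of class `barcode_pair`.
#' @export
barcode_pair <- function(forward_barcode, reverse_barcode) {
  for (b in c(forward_barcode, reverse_barcode)) {
    if (nchar(b) != 16L || !grepl("^[ACGT]+$", b)) {
      stop("barcodes must be 16-nt ACGT strings")
    }
  }
  structure(list(forward_barcode = forward_barcode,
                 reverse_barcode = reverse_barcode),
            class = "barcode_pair")
}

#' Generate a table of unique barcode pairs
#'
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return A data.frame with columns `sample_id`, `forward_barcode`,
#'   `reverse_barcode`; pairs are unique.
#' @export
make_barcode_table <- function(n, seed = 1L) {
  set.seed(seed)
  draw <- function(k) {
    vapply(seq_len(k),
           function(i) paste(sample(BASES, 16L, replace = TRUE), collapse = ""),
           "")
  }
  fwd <- draw(n); rev <- draw(n)
  while (anyDuplicated(paste(fwd, rev))) {
    i <- which(duplicated(paste(fwd, rev)))
    fwd[i] <- draw(length(i)); rev[i] <- draw(length(i))
  }
  data.frame(sample_id = sprintf("S%04d", seq_len(n)),
             forward_barcode = fwd, reverse_barcode = rev)
}

#' Read-emission parameters
#'
#' @param n_reads CCS reads per barcode pair.
#' @param minor_fraction Per-read probability of sampling the minor
#'   strand species (must be <= 0.5).
#' @param per_base_error Independent per-base substitution rate.
#' @param indel_rate Optional per-base indel rate (default 0; split
#'   evenly between 1-bp insertions and deletions).
#' @param seed Default seed for [emit_reads()].
#' @return An object of class `read_emission_params`.
#' @export
read_emission_params <- function(n_reads = 30L, minor_fraction = 0.5,
                                 per_base_error = 0.002, indel_rate = 0,
                                 seed = NULL) {
  if (n_reads < 0L) stop("n_reads must be >= 0")
  if (minor_fraction < 0 || minor_fraction > 0.5) {
    stop("minor_fraction must be in [0, 0.5]")
  }
  if (per_base_error < 0 || per_base_error >= 1) {
    stop("per_base_error must be in [0, 1)")
  }
  if (indel_rate < 0 || indel_rate >= 1) stop("indel_rate must be in [0, 1)")
  structure(list(n_reads = as.integer(n_reads),
                 minor_fraction = minor_fraction,
                 per_base_error = per_base_error,
                 indel_rate = indel_rate,
                 seed = seed),
            class = "read_emission_params")
}

# render the amplicon sequence of one strand: repaired backbone with the
# donor base substituted wherever the strand genotype is D
render_strand <- function(pair, genotypes) {
  map <- pair$marker_map
  seq <- pair$repaired_sequence
  d <- which(genotypes == "D")
  if (length(d) > 0L) {
    idx <- pos_to_index(pair, map$positions[d])
    s <- strsplit(seq, "")[[1]]
    s[idx] <- map$donor_base[d]
    seq <- paste(s, collapse = "")
  }
  seq
}

SUB_ALT <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))

# i.i.d. substitution errors; each error replaces the base with a
# uniformly chosen different base
apply_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(n_err > 0L)) {
    r <- charToRaw(seqs[i])
    posn <- sample.int(length(r), n_err[i])
    cur <- strsplit(rawToChar(r[posn]), "")[[1]]
    repl <- vapply(cur, function(b) sample(SUB_ALT[[b]], 1L), "",
                   USE.NAMES = FALSE)
    r[posn] <- charToRaw(paste(repl, collapse = ""))
    seqs[i] <- rawToChar(r)
  }
  seqs
}

apply_indels <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_ev <- stats::rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(n_ev > 0L)) {
    s <- strsplit(seqs[i], "")[[1]]
    for (k in seq_len(n_ev[i])) {
      p <- sample.int(length(s), 1L)
      if (stats::runif(1) < 0.5) {
        s <- s[-p]                                   # deletion
      } else {
        s <- append(s, sample(BASES, 1L), after = p) # insertion
      }
    }
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Emit barcoded reads from one repair product
#'
#' Each read samples the minor strand (by convention `strand_bottom`)
#' with probability `minor_fraction`, renders that strand's amplicon from
#' the substrate, attaches the barcode pair, and applies the error model.
#'
#' @param product A `repair_product`.
#' @param bc A `barcode_pair`.
#' @param params A `read_emission_params`.
#' @param pair A `substrate_pair`.
#' @param id_prefix Prefix for read ids.
#' @param seed Seed (defaults to `params$seed`; NULL uses the current RNG
#'   state).
#' @return A data.frame of class `read_set` with columns `id`,
#'   `sequence`.
#' @export
emit_reads <- function(product, bc, params, pair, id_prefix = "read",
                       seed = params$seed) {
  stopifnot(inherits(product, "repair_product"),
            inherits(bc, "barcode_pair"),
            inherits(params, "read_emission_params"),
            inherits(pair, "substrate_pair"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_reads
  if (n == 0L) {
    return(structure(data.frame(id = character(0), sequence = character(0)),
                     class = c("read_set", "data.frame")))
  }
  amp_major <- render_strand(pair, product$strand_top)
  amp_minor <- render_strand(pair, product$strand_bottom)
  take_minor <- stats::runif(n) < params$minor_fraction
  amp <- ifelse(take_minor, amp_minor, amp_major)
  amp <- apply_substitutions(amp, params$per_base_error)
  amp <- apply_indels(amp, params$indel_rate)
  seqs <- paste0(bc$forward_barcode, amp, revcomp(bc$reverse_barcode))
  structure(data.frame(id = sprintf("%s_%05d", id_prefix, seq_len(n)),
                       sequence = seqs),
            class = c("read_set", "data.frame"))
}

#' Read/write reads as FASTA
#'
#' Lossless round trip of id and sequence using standard FASTA
#' conventions. Sequences must be over the A/C/G/T/N alphabet; a record
#' containing any other character is rejected by name.
#'
#' @param reads A data.frame with columns `id`, `sequence`.
#' @param path File path.
#' @return `write_fasta`: `path`, invisibly. `read_fasta`: a `read_set`
#'   data.frame.
#' @export
write_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    return(structure(data.frame(id = character(0), sequence = character(0)),
                     class = c("read_set", "data.frame")))
  }
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("malformed FASTA '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  seqs <- as.character(x)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("FASTA record '", names(x)[which(bad)[1]],
         "' contains characters outside A/C/G/T/N")
  }
  structure(data.frame(id = names(x), sequence = unname(seqs)),
            class = c("read_set", "data.frame"))
}

#' Write a barcode table as TSV
#'
#' @param table Data.frame with `sample_id`, `forward_barcode`,
#'   `reverse_barcode`.
#' @param path File path.
#' @param header_lines Optional comment lines (prefixed `#`) written
#'   before the table.
#' @return `path`, invisibly.
#' @export
write_barcode_table <- function(table, path, header_lines = character(0)) {
  write_tsv_with_header(table, path, header_lines)
}

#' @rdname write_barcode_table
#' @export
read_barcode_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

write_tsv_with_header <- function(df, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines) > 0) {
    writeLines(paste0("# ", header_lines), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
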