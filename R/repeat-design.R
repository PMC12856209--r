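# Repeat sequence construction and the design arithmetic used to compare
# oligonucleotides at equal potential-G4-unit (and G-tetrad) concentration.

#' Build a tandem-repeat oligonucleotide
#'
#' Constructs a pentanucleotide (or control hexanucleotide) motif repeated
#' `n` times, as used for WGGGW-family repeat series (W = A or T), e.g. the
#' CANVAS-associated AGGGA motif.
#'
#' @param motif Single string over `A,C,G,T` (DNA) or `A,C,G,U` (RNA);
#'   5 or 6 nucleotides long.
#' @param n Positive integer number of repeats.
#' @param nucleic_acid `"DNA"` or `"RNA"`.
#'
#' @return An object of class `repeat_sequence`: a list with elements
#'   `motif`, `n_repeats`, `nucleic_acid` and the concatenated `sequence`.
#' @examples
#' build_repeat("AGGGA", 8)
#' @export
build_repeat <- function(motif, n, nucleic_acid = c("DNA", "RNA")) {
  nucleic_acid <- match.arg(nucleic_acid)
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif)) {
    .ps_abort("`motif` must be a single nonempty string.", "domain_error")
  }
  motif <- toupper(motif)
  if (!nchar(motif) %in% c(5L, 6L)) {
    .ps_abort("`motif` must be 5 or 6 nucleotides long.", "domain_error")
  }
  alphabet <- if (nucleic_acid == "DNA") c("A", "C", "G", "T") else c("A", "C", "G", "U")
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), alphabet)
  if (length(bad) > 0L) {
    .ps_abort(
      sprintf(
        "Invalid %s character(s) in motif: %s (allowed: %s).",
        nucleic_acid, paste(bad, collapse = ", "), paste(alphabet, collapse = "")
      ),
      "alphabet_error"
    )
  }
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != floor(n)) {
    .ps_abort("`n` must be a positive integer.", "domain_error")
  }
  structure(
    list(
      motif = motif,
      n_repeats = as.integer(n),
      nucleic_acid = nucleic_acid,
      sequence = strrep(motif, as.integer(n))
    ),
    class = "repeat_sequence"
  )
}

#' @export
print.repeat_sequence <- function(x, ...) {
  cat(sprintf(
    "<repeat_sequence> %s(%s)_%d  [%d nt]\n",
    tolower(substr(x$nucleic_acid, 1, 1)), x$motif, x$n_repeats,
    nchar(x$sequence)
  ))
  invisible(x)
}

#' @export
as.character.repeat_sequence <- function(x, ...) x$sequence

.seq_string <- function(seq) {
  if (inherits(seq, "repeat_sequence")) seq$sequence
  else if (is.character(seq) && length(seq) == 1L) toupper(seq)
  else .ps_abort("`seq` must be a repeat_sequence or a single string.", "domain_error")
}

#' Count maximal G-runs
#'
#' Number of maximal runs of consecutive guanines of length at least
#' `min_len`, scanning 5' to 3'. A run of length >= `min_len` counts once
#' regardless of how far it exceeds the threshold. G-run content is the
#' discriminant for G-quadruplex folding potential: motifs with only GG runs
#' (e.g. AGGAC) do not supply the G3 tracts needed for three-tetrad G4 units.
#'
#' @param seq A `repeat_sequence` or a plain sequence string.
#' @param min_len Minimum run length (default 3).
#' @return Integer count of qualifying runs.
#' @examples
#' count_g_runs(build_repeat("TGGGT", 16)) # 16
#' count_g_runs(build_repeat("AGGAC", 8)) # 0
#' count_g_runs(build_repeat("AGGAC", 8), min_len = 2) # 8
#' @export
count_g_runs <- function(seq, min_len = 3) {
  if (!is.numeric(min_len) || min_len < 1) {
    .ps_abort("`min_len` must be >= 1.", "domain_error")
  }
  s <- .seq_string(seq)
  r <- rle(strsplit(s, "", fixed = TRUE)[[1]] == "G")
  sum(r$values & r$lengths >= min_len)
}

#' Design summary: potential G4 units and tetrad concentrations
#'
#' Computes the design arithmetic used to compare repeat oligonucleotides at
#' matched structural concentration: the number of potential contiguous G4
#' units (four G3 runs fold one unit, grouped left-to-right), the
#' concentration of potential G4 units, and the concentration of potential
#' G-tetrads (three tetrads per G3-based unit).
#'
#' @param seq A `repeat_sequence` (or sequence string).
#' @param strand_conc_uM Strand concentration in micromolar (> 0).
#' @param min_run Minimum G-run length defining a tetrad-competent tract
#'   (default 3).
#' @return A one-row tibble with columns `motif`, `n_repeats`,
#'   `g3_run_count`, `potential_g4_units`, `strand_conc_uM`, `unit_conc_uM`,
#'   `tetrad_conc_uM`.
#' @examples
#' design_summary(build_repeat("TGGGT", 8), strand_conc_uM = 3)
#' @export
design_summary <- function(seq, strand_conc_uM, min_run = 3) {
  if (!is.numeric(strand_conc_uM) || length(strand_conc_uM) != 1L ||
    is.na(strand_conc_uM) || strand_conc_uM <= 0) {
    .ps_abort("`strand_conc_uM` must be a positive number.", "domain_error")
  }
  runs <- count_g_runs(seq, min_len = min_run)
  units <- runs %/% 4L
  unit_conc <- units * strand_conc_uM
  is_rs <- inherits(seq, "repeat_sequence")
  tibble(
    motif = if (is_rs) seq$motif else NA_character_,
    n_repeats = if (is_rs) seq$n_repeats else NA_integer_,
    g3_run_count = as.integer(runs),
    potential_g4_units = as.integer(units),
    strand_conc_uM = strand_conc_uM,
    unit_conc_uM = unit_conc,
    tetrad_conc_uM = 3 * unit_conc
  )
}

#' Design strand concentration for a repeat series
#'
#' The comparison scheme fixes the product of strand concentration and repeat
#' number: strands of n repeats are prepared at `base_uM / n` micromolar, so
#' that every member of a WGGGW series carries the same concentration of
#' potential G4 units (6 uM with the default base of 24 uM) and of potential
#' G-tetrads (18 uM).
#'
#' @param n Number of repeats (positive integer, vectorized).
#' @param base_uM Base concentration in micromolar (default 24).
#' @return Strand concentration(s) in micromolar.
#' @examples
#' design_strand_concentration(c(4, 8, 12, 16)) # 6 3 2 1.5
#' @export
design_strand_concentration <- function(n, base_uM = 24) {
  if (!is.numeric(n) || any(is.na(n)) || any(n < 1) || any(n != floor(n))) {
    .ps_abort("`n` must contain positive integers.", "domain_error")
  }
  if (!is.numeric(base_uM) || length(base_uM) != 1L || base_uM <= 0) {
    .ps_abort("`base_uM` must be a positive number.", "domain_error")
  }
  base_uM / n
}

#' Predicted species size for electrophoretic interpretation
#'
#' Size (in bp or nt) of the species a repeat strand would form under three
#' idealized arrangements, used to interpret native PAGE mobilities:
#' a full-register two-strand duplex (n_repeats x motif length, in bp), an
#' intramolecular hairpin (half the strand length, floored, in bp), or an
#' intramolecular G4 (the full strand length, in nt).
#'
#' @param seq A `repeat_sequence`.
#' @param species One of `"bimolecular_duplex"`, `"intramolecular_hairpin"`,
#'   `"intramolecular_G4"`.
#' @return Numeric size; bp for duplex/hairpin, nt for the G4.
#' @examples
#' predicted_species_size(build_repeat("AGGGA", 8), "bimolecular_duplex") # 40
#' @export
predicted_species_size <- function(seq,
                                   species = c(
                                     "bimolecular_duplex",
                                     "intramolecular_hairpin",
                                     "intramolecular_G4"
                                   )) {
  species <- match.arg(species)
  if (!inherits(seq, "repeat_sequence")) {
    .ps_abort("`seq` must be a repeat_sequence.", "domain_error")
  }
  total_len <- nchar(seq$sequence)
  switch(species,
    bimolecular_duplex = seq$n_repeats * nchar(seq$motif),
    intramolecular_hairpin = total_len %/% 2L,
    intramolecular_G4 = total_len
  )
}

#' Design table for a repeat series
#'
#' Convenience wrapper applying [design_summary()] across a series of repeat
#' numbers at the matched concentrations of [design_strand_concentration()].
#'
#' @param motif Repeat motif string.
#' @param n_values Integer vector of repeat numbers (default `c(4, 8, 12, 16)`).
#' @param base_uM Base concentration in micromolar (default 24).
#' @param nucleic_acid `"DNA"` or `"RNA"`.
#' @return A tibble with one row per repeat number, the design-summary columns
#'   plus `duplex_size_bp`.
#' @examples
#' design_table("AGGGA")
#' @export
design_table <- function(motif, n_values = c(4L, 8L, 12L, 16L), base_uM = 24,
                         nucleic_acid = "DNA") {
  purrr::map_dfr(n_values, function(n) {
    rs <- build_repeat(motif, n, nucleic_acid)
    design_summary(rs, design_strand_concentration(n, base_uM)) |>
      mutate(duplex_size_bp = predicted_species_size(rs, "bimolecular_duplex"))
  })
}

#' Write a repeat sequence as single-record FASTA
#'
#' @param seq A `repeat_sequence`.
#' @param path Output file path.
#' @param width Line width for the sequence body (default 60).
#' @return `path`, invisibly.
#' @export
write_repeat_fasta <- function(seq, path, width = 60) {
  if (!inherits(seq, "repeat_sequence")) {
    .ps_abort("`seq` must be a repeat_sequence.", "domain_error")
  }
  id <- sprintf("%s_x%d", seq$motif, seq$n_repeats)
  body <- substring(
    seq$sequence,
    seq(1L, nchar(seq$sequence), by = width),
    pmin(seq(width, nchar(seq$sequence) + width - 1L, by = width), nchar(seq$sequence))
  )
  writeLines(c(paste0(">", id), body), path)
  invisible(path)
}
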