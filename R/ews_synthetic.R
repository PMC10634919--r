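# Synthetic stand-in for the EWS low-complexity domain.
#
# The real 264-residue EWS LCD sequence is user input (e.g. UniProt Q01844,
# residues 1-264) and is deliberately not bundled. For self-contained tests
# and worked examples the package constructs a SYNTHETIC sequence that
# reproduces the documented sequence features of the domain without being the
# real sequence.

# Tyrosine placement: four YxxY motifs, the single YxY at (170, 172), and 27
# isolated tyrosines all separated by >= 4 positions, none inside the
# tyrosine-devoid linker 128-157.
.SYN_YXXY <- list(c(31L, 34L), c(66L, 69L), c(97L, 100L), c(226L, 229L))
.SYN_YXY <- c(170L, 172L)
.SYN_Y_ISOLATED <- c(4L, 10L, 16L, 22L, 39L, 44L, 50L, 56L, 62L, 74L, 80L,
                     86L, 92L, 105L, 111L, 117L, 123L, 162L, 166L, 176L,
                     182L, 188L, 194L, 200L, 208L, 214L, 220L)

#' Synthetic EWS-LCD-like sequence
#'
#' Deterministically constructs a 264-residue synthetic low-complexity
#' sequence with the hallmark features of the EWS LCD: 37 tyrosines of which
#' exactly one pair forms a YxY motif (positions 170/172) and exactly four
#' pairs form YxxY motifs, every other tyrosine separated by at least four
#' positions, a tyrosine-devoid linker spanning residues 128-157, and a
#' serine/threonine/glycine/glutamine/alanine/proline background. It is a
#' labelled stand-in, not the real EWS sequence; analyses of the real protein
#' should load it from FASTA via [read_fasta_sequences()].
#'
#' @return a [protein_sequence()] named "synthetic-EWS-LCD".
#' @export
synthetic_ews_lcd <- function() {
  n <- 264L
  background <- strsplit(strrep("STGQAPSGQT", ceiling(n / 10)), "")[[1]][1:n]
  ypos <- sort(c(unlist(.SYN_YXXY), .SYN_YXY, .SYN_Y_ISOLATED))
  background[ypos] <- "Y"
  protein_sequence(paste(background, collapse = ""),
                   name = "synthetic-EWS-LCD", start_index = 1L)
}

#' Synthetic tyrosine-to-serine mutation sets
#'
#' Mutation sets mirroring the tyrosine-depletion constructs studied for the
#' EWS LCD, defined on the synthetic stand-in sequence of
#' [synthetic_ews_lcd()]: `"Y170S/Y172S"` removes the single YxY motif;
#' `"7YS"` additionally disrupts every YxxY motif (7 substitutions); `"13YS"`
#' extends 7YS by six further tyrosines. The real constructs' positions come
#' from external data and can be supplied with [read_mutation_set()].
#'
#' @param which one of "Y170S/Y172S", "7YS", "13YS".
#' @return a [mutation_set()].
#' @export
synthetic_ys_mutations <- function(which = c("Y170S/Y172S", "7YS", "13YS")) {
  which <- match.arg(which)
  specs <- switch(
    which,
    "Y170S/Y172S" = c("Y170S", "Y172S"),
    "7YS" = c("Y170S", "Y172S", "Y31S", "Y34S", "Y66S", "Y97S", "Y226S"),
    "13YS" = c("Y170S", "Y172S", "Y31S", "Y34S", "Y66S", "Y97S", "Y226S",
               "Y69S", "Y100S", "Y229S", "Y39S", "Y44S", "Y208S")
  )
  mutation_set(spec = specs, label = which)
}
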