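#!/usr/bin/env Rscript
# Sequence bookkeeping for the EWS low-complexity domain: amino-acid
# composition, residue distribution, the tyrosine motif scan, and the
# construction of the tyrosine-to-serine mutants.
#
# The package ships a labelled synthetic stand-in with the domain's documented
# sequence features; to analyse the real protein put its FASTA next to this
# script and point `--fasta` at it.

suppressPackageStartupMessages(library(ewsphase))
dir.create("results", showWarnings = FALSE)

args <- commandArgs(trailingOnly = TRUE)
fasta <- if (length(args) >= 2 && args[1] == "--fasta") args[2] else NULL
lcd <- if (is.null(fasta)) synthetic_ews_lcd() else
  read_fasta_sequences(fasta)[[1]]

cat("Sequence:", lcd$name, "-", length(lcd), "residues\n\n")

comp <- composition_profile(lcd)
comp <- comp[order(-comp$percent), ]
cat("Top composition (percent):\n")
print(head(comp, 8), row.names = FALSE)
write_analysis_table(comp, "results/01_composition.csv")

dist <- residue_positions(lcd, c("Y", "S", "G", "Q", "A", "P", "T"))
dist_tab <- do.call(rbind, lapply(names(dist), function(a) {
  if (length(dist[[a]]) == 0) return(NULL)
  data.frame(aa = a, position = dist[[a]])
}))
write_analysis_table(dist_tab, "results/01_residue_positions.csv")

motifs <- find_tyrosine_motifs(lcd)
cat(sprintf("\nTyrosines: %d | YxY motifs: %d | YxxY motifs: %d | isolated: %d\n",
            length(dist$Y), sum(motifs$kind == "YxY"),
            sum(motifs$kind == "YxxY"), sum(motifs$kind == "isolated")))
yxy <- motifs[motifs$kind == "YxY", ]
cat(sprintf("The single YxY motif sits at (%d, %d); mutating it gives the\n",
            yxy$first_position, yxy$second_position))
cat("Y170S/Y172S construct; the 7YS construct removes every YxY/YxxY motif.\n")
write_analysis_table(motifs, "results/01_tyrosine_motifs.csv")

for (lab in c("Y170S/Y172S", "7YS", "13YS")) {
  mut <- synthetic_ys_mutations(lab)
  ms <- apply_mutations(lcd, mut)
  mm <- find_tyrosine_motifs(ms)
  cat(sprintf("%-12s -> %d tyrosines, %d paired motifs left\n", lab,
              sum(strsplit(ms$residues, "")[[1]] == "Y"),
              sum(mm$kind != "isolated")))
  write_fasta_sequences(ms, file.path("results",
                                      paste0("01_", gsub("/", "_", lab),
                                             ".fasta")))
}
write_fasta_sequences(lcd, "results/01_wildtype.fasta")
cat("\nTables and mutant FASTAs written under results/\n")
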