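#!/usr/bin/env Rscript
# Stage 3: ancestral ORF reconstruction. Each classified locus is
# aligned to its closest reference protein with the frameshift-aware
# DP; the table records frameshifts, premature stops, aligned fraction
# and the intact flag. Older insertions should carry more disruptions.

suppressMessages(library(circomine))
simdir <- "results/sim"
out <- "results/orf"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ref_genome <- read_fasta(file.path(simdir, "reference_genome.fa"))
cds <- read.table(file.path(simdir, "reference_cds.tsv"), header = TRUE,
                  stringsAsFactors = FALSE)
ref <- viral_reference("SynCV1", unname(ref_genome$contigs[1]), cds)
loci <- read.table("results/screen/loci.tsv", header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
cls <- read.table("results/screen/classification.tsv", header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)

orf <- orf_report(loci, cls, list(ref))
write.table(orf[, setdiff(names(orf), "peptide")],
            file.path(out, "orf_report.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_fasta(setNames(orf$peptide, paste(orf$locus_id, orf$gene)),
            file.path(out, "reconstructed_peptides.faa"))

cat(sprintf("ORF reports for %d locus-gene pairs: %d intact, mean %.1f frameshifts, %.1f premature stops\n",
            nrow(orf), sum(orf$intact),
            mean(orf$n_frameshifts, na.rm = TRUE),
            mean(orf$n_premature_stops, na.rm = TRUE)))
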