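#!/usr/bin/env Rscript
# Stage 2: translated screening of every assembly with Rep/Cap probes,
# locus extraction with flanks, and best-match classification against
# the reference library.

suppressMessages(library(circomine))
seed <- 42L
simdir <- "results/sim"
out <- "results/screen"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ref_genome <- read_fasta(file.path(simdir, "reference_genome.fa"))
cds <- read.table(file.path(simdir, "reference_cds.tsv"), header = TRUE,
                  stringsAsFactors = FALSE)
ref <- viral_reference("SynCV1", unname(ref_genome$contigs[1]), cds)
probes <- probes_from_references(list(ref))

fastas <- list.files(simdir, pattern = "^[A-E]\\.fa$", full.names = TRUE)
loci <- do.call(rbind, lapply(fastas, function(f) {
  sp <- sub("\\.fa$", "", basename(f))
  screen_assembly(read_fasta(f, species = sp), probes)
}))
cls <- classify_loci(loci, list(ref))

flat <- loci[, !vapply(loci, is.list, logical(1))]
write.table(flat, file.path(out, "loci.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cls[, !vapply(cls, is.list, logical(1))],
            file.path(out, "classification.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
bed <- data.frame(chrom = loci$contig, start = loci$start,
                  end = loci$end, name = loci$locus_id, score = 0L,
                  strand = loci$strand)
write_bed(bed, file.path(out, "loci.bed"))
write_gff3(bed_to_gff3(bed), file.path(out, "loci.gff3"))

truth <- read.table(file.path(simdir, "truth.tsv"), header = TRUE,
                    stringsAsFactors = FALSE)
cat(sprintf("screened %d assemblies: %d loci (%d tandem-flagged) against %d planted copies\n",
            length(fastas), nrow(loci), sum(loci$tandem), nrow(truth)))
print(table(gene = cls$gene))
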