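#!/usr/bin/env Rscript
# Stage 1: build the synthetic study cohort.
#
# Five host species on a dated tree; four insertion scenarios covering
# the situations the screen has to cope with: a clade-wide full-genome
# insertion (orthologs with shared flanks), a tandem rep array, a young
# species-private insertion, and a LINE-adjacent copy-number expansion.
# Assemblies are lightly fragmented to create contig-edge loci.

suppressMessages(library(circomine))
seed <- 42L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tree_txt <- "(((A:10,B:10)ab:10,C:20)abc:10,(D:25,E:25)de:5)root;"
writeLines(tree_txt, file.path(out, "host_tree.nwk"))
tt <- read_newick_with_ages(tree_txt)

scenarios <- list(
  insertion_scenario("anc_full", "abc",
                     rates = decay_rates(sub = 0.002, indel = 5e-5)),
  insertion_scenario("tandem_rep", "de", region = c(60, 963),
                     tandem_copies = 3,
                     rates = decay_rates(sub = 0.001, indel = 0)),
  insertion_scenario("young_private", "A", region = c(60, 963),
                     time = 2, rates = decay_rates(sub = 0.001)),
  insertion_scenario("line_expanded", "ab", region = c(60, 963),
                     rates = decay_rates(sub = 0.002, indel = 2e-5),
                     line = list(node = "A", copies = 5,
                                 cassette_len = 500)))

sim <- simulate_assembly(tt, scenarios, n_contigs = 3,
                         contig_len = 30000, seed = seed)
sim <- fragment_assembly(sim, break_rate = 2e-6, n_run_rate = 2e-6,
                         seed = seed)

for (sp in names(sim$assemblies)) {
  write_fasta(sim$assemblies[[sp]], file.path(out, paste0(sp, ".fa")))
}
write_truth_bed(sim$truth, file.path(out, "truth.bed"))
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_fasta(c(reference = sim$reference$genome),
            file.path(out, "reference_genome.fa"))
write.table(sim$reference$cds_table, file.path(out, "reference_cds.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d species, %d planted viral copies (%d LINE copies)\n",
            length(sim$assemblies), nrow(sim$truth),
            sum(sim$truth$is_line_copy)))
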