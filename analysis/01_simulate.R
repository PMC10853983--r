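#!/usr/bin/env Rscript
# Simulate the study system: a genome with planted Cassandra families and a
# Cassandra-like TRIM, a species 5S rRNA gene, and ground-truth GFF3.
# Writes results/sim/.
#
# The scenario mirrors the Anthemideae situation: the genic 5S promoter
# carries the shifted C-Box (GGCTTGGGTG); the major Cassandra family
# mirrors it with the Cassandra-shifted motif (GGCCTGGGTG) and contains an
# indel-defined variant (a shared 30 bp LTR deletion in two copies); a
# minor canonical-C-Box family coexists — several C-Box populations in one
# genome. Insertion sites are spaced > 2.3 kb apart so that copies of one
# family cannot be cross-paired within the TRIM distance bounds, mimicking
# genome-wide dispersal of the copies.

library(cassandra)

outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
set.seed(20260917)

unit_spec <- five_s_unit_spec(cbox_variant = "anthemideae_rdna")
unit <- make_5s_unit(unit_spec)
gene <- unit$gene

fam_shift <- make_cassandra_family(
  cassandra_spec(cbox_variant = "anthemideae_cassandra", tsd_length = 5),
  five_s = gene, n_copies = 4, copy_divergence = 0.02,
  deletion_copies = 3:4, id_prefix = "shift", unit_spec = unit_spec)
fam_canon <- make_cassandra_family(
  cassandra_spec(cbox_variant = "canonical", tsd_length = 5),
  five_s = gene, n_copies = 3, copy_divergence = 0.02,
  id_prefix = "canon", unit_spec = unit_spec)
trim <- make_cassandra_like_trim(
  cassandra_spec(ltr_length = 220, internal_length = 90, tsd_length = 5),
  id = "trim_01")

elements <- c(fam_shift, fam_canon, list(trim))
planted <- plant_elements(30000, elements, min_gap = 2300)
write_fasta(c(contig_1 = planted$seq, five_s_gene = gene),
            file.path(outdir, "genome.fasta"))
write_gff3(planted$truth, file.path(outdir, "truth.gff3"))

message("genome: ", nchar(planted$seq), " bp, ",
        sum(planted$truth$type == "LTR_retrotransposon"),
        " planted elements (4 shifted + 3 canonical Cassandras + 1 TRIM)")
message("shifted family variants: ",
        paste(vapply(fam_shift, function(e) e$variant, ""), collapse = ", "))
message("genic 5S C-Box: ", iv_seq(gene, five_s_unit_spec()$cbox),
        " (anthemideae_rdna)")
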