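#!/usr/bin/env Rscript
# Promoter annotation of detected elements: the 5S-derived similarity
# region (the ~70 bp core) inside the LTRs, A-Box/IE/C-Box scan, C-Box
# variant classification (promoter mimicry), MotIE/MotC extraction, and the
# Cassandra / Cassandra-like TRIM / other call.
# Reads results/sim + results/detect, writes results/annotate/.

library(cassandra)

outdir <- "results/annotate"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

seqs <- read_fasta("results/sim/genome.fasta")
cands <- read_tsv("results/detect/candidates.tsv")
anns <- annotate_elements(cands, seqs[["contig_1"]], seqs[["five_s_gene"]])
write_tsv(anns, file.path(outdir, "annotations.tsv"))

tally <- tally_cbox_populations(anns)
write_tsv(data.frame(cbox_class = names(tally), count = tally),
          file.path(outdir, "cbox_populations.tsv"))

message("labels: ", paste(names(table(anns$label)), table(anns$label),
                          sep = "=", collapse = ", "))
message("C-Box populations: ",
        paste(names(tally), tally, sep = "=", collapse = ", "))
genic <- scan_boxes(seqs[["five_s_gene"]])
message("genic 5S C-Box class: ", genic$cbox_class,
        " | majority TE class: ", names(which.max(tally)),
        " (promoter mimicry: the TE population mirrors the genic shift)")
cass <- anns[anns$label == "cassandra", ]
message("core regions: length ",
        paste(range(cass$core_end - cass$core_start), collapse = "-"),
        " bp, relative midpoints ",
        paste(sprintf("%.2f", range(cass$relative_midpoint)),
              collapse = "-"))
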