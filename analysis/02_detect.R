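#!/usr/bin/env Rscript
# Structure-based TRIM detection on the simulated genome: direct-repeat
# pairs with LTRs of 30-500 bp, 30-2000 bp apart, >= 70% LTR identity;
# PBS/PPT/TSD annotated but never filtered on (relaxed mode).
# Reads results/sim/, writes results/detect/.

library(cassandra)

outdir <- "results/detect"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

seqs <- read_fasta("results/sim/genome.fasta")
cfg <- detector_config()
cands <- find_ltr_pairs(seqs[["contig_1"]], cfg, contig_id = "contig_1")

write_tsv(cands, file.path(outdir, "candidates.tsv"))
candidates_to_gff3(cands, file.path(outdir, "candidates.gff3"), cfg)

message(nrow(cands), " candidate elements; LTR identities ",
        paste(sprintf("%.1f", range(cands$ltr_identity_pct)),
              collapse = "-"), "%")
message("with TSD: ", sum(!is.na(cands$tsd)),
        "; with PBS: ", sum(!is.na(cands$pbs_offset)),
        "; with PPT: ", sum(!is.na(cands$ppt_start)))
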