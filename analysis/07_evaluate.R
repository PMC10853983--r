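#!/usr/bin/env Rscript
# Score every stage against the planted ground truth: detection
# precision/recall at >= 50% reciprocal overlap, classification accuracy,
# C-Box population recovery, and the arrangement calls.
# Reads results/{sim,detect,annotate,linkage}, writes results/evaluation.tsv.

library(cassandra)

truth <- read_gff3("results/sim/truth.gff3")
cands <- read_tsv("results/detect/candidates.tsv")
anns <- read_tsv("results/annotate/annotations.tsv")
linkage <- read_tsv("results/linkage/linkage_calls.tsv")

ev <- evaluate_against_truth(cands, anns, truth)
arr_acc <- mean(linkage$call == linkage$truth)
ev <- rbind(ev, data.frame(stage = "arrangement", metric = "accuracy",
                           value = arr_acc))

# C-Box population recovery: planted variant labels vs annotated classes
te_truth <- truth[truth$type == "LTR_retrotransposon", ]
planted <- table(sub(".*cbox_variant=([a-z_]+).*", "\\1",
                     te_truth$attributes[grepl("label=cassandra;",
                                               te_truth$attributes)]))
observed <- tally_cbox_populations(anns[anns$label == "cassandra", ])
cbox_ok <- all(names(planted) %in% names(observed)) &&
  all(observed[names(planted)] == as.integer(planted))
ev <- rbind(ev, data.frame(stage = "cbox_populations",
                           metric = "exact_recovery",
                           value = as.numeric(cbox_ok)))

write_tsv(ev, "results/evaluation.tsv")
print(ev)
message("planted C-Box populations: ",
        paste(names(planted), planted, sep = "=", collapse = ", "))
message("observed C-Box populations: ",
        paste(names(observed), observed, sep = "=", collapse = ", "))
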