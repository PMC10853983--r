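# End-to-end orchestration: simulate -> detect -> annotate -> cluster ->
# dotplot -> linkage -> report, plus evaluation against planted truth.
# Every stage is a plain function over files/data frames; the numbered
# scripts under analysis/ are thin drivers over these.

#' Build a pipeline configuration
#'
#' Nested configuration for a full run. Unknown keys are rejected. The
#' resolved configuration is written next to the outputs of every run.
#'
#' @param seed Global integer seed.
#' @param outdir Output directory.
#' @param simulate List: `n_cassandra`, `n_trim`, `background_length`,
#'   `cbox_variant_rdna` (genic 5S variant), `cbox_variant_te` (planted
#'   element variant), `divergence`, `tsd_length`, `ltr_length`,
#'   `internal_length`, `protect_cbox`.
#' @param detect List of [detector_config()] overrides.
#' @param annotate List of [motif_config()] overrides.
#' @param cluster List: `threshold`, `min_indel`.
#' @param dotplot List of [dotplot_config()] overrides.
#' @param linkage List: `enabled`, `linked`, `n_copies`, `coverage`,
#'   `read_length`, `k`, `min_count`, `distance`, `subunit_lengths`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = "results/run",
                            simulate = list(), detect = list(),
                            annotate = list(), cluster = list(),
                            dotplot = list(), linkage = list()) {
  defaults <- list(
    seed = seed, outdir = outdir,
    simulate = list(n_cassandra = 4L, n_trim = 1L,
                    background_length = 8000L,
                    cbox_variant_rdna = "canonical",
                    cbox_variant_te = "canonical",
                    divergence = 0, tsd_length = 5L, ltr_length = 270L,
                    internal_length = 82L, protect_cbox = FALSE),
    detect = list(), annotate = list(),
    cluster = list(threshold = 70, min_indel = 10L),
    dotplot = list(k = 12L, n = 3L),
    linkage = list(enabled = TRUE, linked = TRUE, n_copies = 3L,
                   coverage = 15, read_length = 100L, k = 31L,
                   min_count = 2L, distance = 25L,
                   subunit_lengths = c(s18 = 1800L, s58 = 160L,
                                       s26 = 3400L)))
  user <- list(simulate = simulate, detect = detect, annotate = annotate,
               cluster = cluster, dotplot = dotplot, linkage = linkage)
  for (section in names(user)) {
    known <- names(defaults[[section]])
    extra <- setdiff(names(user[[section]]), known)
    if (section %in% c("detect", "annotate", "dotplot")) {
      ctor <- switch(section, detect = detector_config,
                     annotate = motif_config, dotplot = dotplot_config)
      extra <- setdiff(names(user[[section]]), names(formals(ctor)))
    }
    if (length(extra)) {
      stop("unknown configuration key in '", section, "': ",
           paste(extra, collapse = ", "))
    }
    defaults[[section]][names(user[[section]])] <- user[[section]]
  }
  structure(defaults, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Simulates a genome with planted elements and an rDNA read set, then runs
#' detection, promoter annotation, family clustering, dotplots, and linkage
#' classification, writing every table into `config$outdir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory stage results: `genome`,
#'   `truth`, `five_s_gene`, `candidates`, `annotations`, `families`,
#'   `family_stats`, `variants`, `dotplot`, `linkage_call`, `summary`.
#' @export
run_full <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  writeLines(deparse(unclass(config)),
             file.path(config$outdir, "config_resolved.txt"))
  set.seed(config$seed)
  sim <- config$simulate

  # --- simulate ---
  unit_spec <- five_s_unit_spec(cbox_variant = sim$cbox_variant_rdna)
  unit <- make_5s_unit(unit_spec)
  gene <- unit$gene
  elements <- list()
  n_te <- sim$n_cassandra + sim$n_trim
  if (n_te > 0L) {
    for (i in seq_len(sim$n_cassandra)) {
      spec <- cassandra_spec(ltr_length = sim$ltr_length,
                             internal_length = sim$internal_length,
                             cbox_variant = sim$cbox_variant_te,
                             tsd_length = sim$tsd_length,
                             divergence = sim$divergence)
      elements[[length(elements) + 1L]] <-
        make_cassandra(spec, five_s = gene, id = sprintf("cassandra_%02d", i),
                       unit_spec = unit_spec,
                       protect_cbox = isTRUE(sim$protect_cbox))
    }
    for (i in seq_len(sim$n_trim)) {
      spec <- cassandra_spec(ltr_length = max(54L, sim$ltr_length),
                             internal_length = sim$internal_length,
                             tsd_length = sim$tsd_length,
                             divergence = sim$divergence)
      elements[[length(elements) + 1L]] <-
        make_cassandra_like_trim(spec, id = sprintf("trim_%02d", i))
    }
  }
  planted <- plant_elements(sim$background_length, elements)
  genome <- planted$seq
  truth <- planted$truth
  write_fasta(c(contig_1 = genome, five_s_gene = gene),
              file.path(config$outdir, "genome.fasta"))
  write_gff3(truth, file.path(config$outdir, "truth.gff3"))

  # --- detect ---
  dcfg <- do.call(detector_config, config$detect)
  cands <- find_ltr_pairs(genome, dcfg, contig_id = "contig_1")
  write_tsv(cands, file.path(config$outdir, "candidates.tsv"))
  candidates_to_gff3(cands, file.path(config$outdir, "candidates.gff3"))

  # --- annotate ---
  mcfg <- do.call(motif_config, config$annotate)
  anns <- annotate_elements(cands, genome, gene, mcfg)
  write_tsv(anns, file.path(config$outdir, "annotations.tsv"))

  # --- cluster ---
  fams <- list(); fam_stats <- NULL; variants <- list()
  if (nrow(cands) > 0L) {
    el_seqs <- setNames(substring(genome, cands$element_start + 1L,
                                  cands$element_end), anns$element_id)
    el_parts <- setNames(lapply(seq_len(nrow(cands)), function(i) {
      list(full = el_seqs[[i]],
           ltr = substring(genome, cands$ltr5_start[i] + 1L,
                           cands$ltr5_end[i]),
           internal = substring(genome, cands$internal_start[i] + 1L,
                                cands$internal_end[i]))
    }), anns$element_id)
    m <- identity_matrix(el_seqs)
    fams <- cluster_families(m, threshold = config$cluster$threshold)
    fam_stats <- do.call(rbind, lapply(fams, family_stats,
                                       elements = el_parts))
    variants <- lapply(fams, split_variants, seqs = el_seqs,
                       min_indel = config$cluster$min_indel)
    fam_rows <- NULL
    for (fi in seq_along(fams)) {
      for (vi in seq_along(variants[[fi]])) {
        fam_rows <- rbind(fam_rows, data.frame(
          family_id = fams[[fi]]$family_id,
          variant = sprintf("%s_v%d", fams[[fi]]$family_id, vi),
          element_id = variants[[fi]][[vi]], stringsAsFactors = FALSE))
      }
    }
    write_tsv(fam_rows, file.path(config$outdir, "families.tsv"))
    write_tsv(fam_stats, file.path(config$outdir, "family_stats.tsv"))
    # --- dotplot over 5' LTRs ---
    ltr_seqs <- setNames(substring(genome, cands$ltr5_start + 1L,
                                   cands$ltr5_end), anns$element_id)
    dcfg2 <- do.call(dotplot_config, config$dotplot)
    dp <- all_vs_all(ltr_seqs, dcfg2)
    dotplot_to_tsv(dp, file.path(config$outdir, "dotplot.tsv"))
  } else {
    dp <- NULL
    write_tsv(data.frame(), file.path(config$outdir, "families.tsv"))
  }

  # --- linkage ---
  linkage_call <- NULL
  lk <- config$linkage
  if (isTRUE(lk$enabled)) {
    arr <- make_rdna_array(unit_spec, n_copies = lk$n_copies,
                           linked = isTRUE(lk$linked),
                           subunit_lengths = lk$subunit_lengths)
    reads <- unlist(lapply(names(arr$arrays), function(nm) {
      simulate_reads(arr$arrays[[nm]], lk$read_length, lk$coverage,
                     prefix = nm)
    }))
    linkage_call <- classify_linkage_from_reads(reads, arr$refs, k = lk$k,
                                                min_count = lk$min_count,
                                                distance = lk$distance)
    write_tsv(data.frame(
      label = linkage_call$label, reason = linkage_call$reason,
      components = linkage_call$components,
      cyclic = paste(linkage_call$cyclic, collapse = ","),
      truth_arrangement = arr$arrangement),
      file.path(config$outdir, "linkage.tsv"))
    graph_to_tsv(linkage_call$graph,
                 file.path(config$outdir, "unitigs.tsv"))
  }

  # --- summary: element -> family -> variant -> cbox class ---
  summary_df <- anns[, c("element_id", "element_start", "element_end",
                         "label", "cbox_class")]
  if (nrow(cands) > 0L && !is.null(fam_rows <- tryCatch(
        read_tsv(file.path(config$outdir, "families.tsv")),
        error = function(e) NULL)) && nrow(fam_rows) > 0L) {
    summary_df <- merge(summary_df, fam_rows, by = "element_id",
                        all.x = TRUE, sort = FALSE)
  }
  write_tsv(summary_df, file.path(config$outdir, "summary.tsv"))

  invisible(list(genome = genome, truth = truth, five_s_gene = gene,
                 candidates = cands, annotations = anns, families = fams,
                 family_stats = fam_stats, variants = variants,
                 dotplot = dp, linkage_call = linkage_call,
                 summary = summary_df))
}

.reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2)
  if (ov <= 0) return(0)
  min(ov / (e1 - s1), ov / (e2 - s2))
}

#' Evaluate pipeline outputs against planted truth
#'
#' Detection counts a truth element as recovered when a candidate overlaps
#' it with at least 50% reciprocal overlap. Classification accuracy compares
#' predicted labels with truth labels over matched elements; arrangement
#' accuracy compares the L/S call with the planted arrangement.
#'
#' @param candidates Candidate data frame from [find_ltr_pairs()].
#' @param annotations Data frame from [annotate_elements()] (or `NULL`).
#' @param truth Truth data frame (with `LTR_retrotransposon` rows carrying a
#'   `label=` attribute).
#' @param arrangement_call Optional `arrangement_call`.
#' @param truth_arrangement Optional "L"/"S".
#' @param min_overlap Reciprocal-overlap threshold (default 0.5).
#' @return Data frame with columns `stage`, `metric`, `value` (`NA` where a
#'   metric is not applicable).
#' @export
evaluate_against_truth <- function(candidates, annotations, truth,
                                   arrangement_call = NULL,
                                   truth_arrangement = NULL,
                                   min_overlap = 0.5) {
  te_truth <- truth[truth$type == "LTR_retrotransposon", , drop = FALSE]
  n_truth <- nrow(te_truth)
  n_pred <- if (is.null(candidates)) 0L else nrow(candidates)
  match_of_pred <- rep(NA_integer_, n_pred)
  if (n_pred > 0L && n_truth > 0L) {
    for (i in seq_len(n_pred)) {
      for (j in seq_len(n_truth)) {
        ro <- .reciprocal_overlap(candidates$element_start[i],
                                  candidates$element_end[i],
                                  te_truth$start[j], te_truth$end[j])
        if (ro >= min_overlap) { match_of_pred[i] <- j; break }
      }
    }
  }
  tp <- sum(!is.na(match_of_pred))
  recalled <- length(unique(match_of_pred[!is.na(match_of_pred)]))
  precision <- if (n_pred == 0L) NA_real_ else tp / n_pred
  recall <- if (n_truth == 0L) NA_real_ else recalled / n_truth
  rows <- data.frame(stage = c("detection", "detection"),
                     metric = c("precision", "recall"),
                     value = c(precision, recall), stringsAsFactors = FALSE)
  if (!is.null(annotations) && nrow(annotations) > 0L && n_truth > 0L) {
    truth_label <- sub(".*label=([a-z_]+).*", "\\1", te_truth$attributes)
    correct <- 0L; total <- 0L
    for (i in seq_len(n_pred)) {
      j <- match_of_pred[i]
      if (is.na(j)) next
      total <- total + 1L
      if (annotations$label[i] == truth_label[j]) correct <- correct + 1L
    }
    rows <- rbind(rows, data.frame(
      stage = "classification", metric = "accuracy",
      value = if (total == 0L) NA_real_ else correct / total))
  }
  if (!is.null(arrangement_call) && !is.null(truth_arrangement)) {
    rows <- rbind(rows, data.frame(
      stage = "arrangement", metric = "accuracy",
      value = as.numeric(arrangement_call$label == truth_arrangement)))
  }
  rows
}
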