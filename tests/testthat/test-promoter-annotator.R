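test_that("C-Box classification assigns each reference motif to itself", {
  expect_equal(classify_cbox("AGGATGGGTG"), list(class = "canonical",
                                                 distance = 0L))
  expect_equal(classify_cbox("GGCTTGGGTG"),
               list(class = "anthemideae_rdna", distance = 0L))
  expect_equal(classify_cbox("GGCCTGGGTG"),
               list(class = "anthemideae_cassandra", distance = 0L))
  # far from every reference -> other
  far <- classify_cbox("ACGTACGTAC")
  expect_equal(far$class, "other")
  expect_gt(far$distance, 2)
  expect_error(classify_cbox("ACGT"), "10 nt")
})

test_that("C-Box classification tolerates private substitutions and flags ties", {
  # one substitution away from canonical stays canonical at distance 1
  expect_equal(classify_cbox("AGGATGGGTA"),
               list(class = "canonical", distance = 1L))
  # the rdna and cassandra shifted motifs differ by 1; a midpoint motif at
  # distance 1 from several references... construct an exact tie:
  # GGCTTGGGTG vs GGCCTGGGTG differ at position 4 only; any 10-mer at equal
  # distance from both is ambiguous
  tie <- "GGCATGGGTG" # position 4 = A: distance 1 to both shifted motifs
  expect_equal(hamming(tie, "GGCTTGGGTG"), 1L)
  expect_equal(hamming(tie, "GGCCTGGGTG"), 1L)
  expect_equal(classify_cbox(tie)$class, "ambiguous")
})

test_that("box scanning finds planted promoter boxes at their offsets", {
  spec <- five_s_unit_spec()
  gene <- make_5s_unit(spec, seed = 5)$gene
  ann <- scan_boxes(gene)
  expect_equal(ann$abox$start, spec$abox$start)
  expect_equal(ann$ie$start, spec$ie$start)
  expect_equal(ann$cbox$start, spec$cbox$start)
  expect_equal(ann$cbox_class, "canonical")
  # one substitution inside the C-Box: still found, distance 1
  mut <- gene
  substr(mut, 81, 81) <- if (substr(gene, 81, 81) == "A") "C" else "A"
  ann2 <- scan_boxes(mut)
  expect_equal(ann2$cbox$start, spec$cbox$start)
  expect_equal(ann2$cbox_distance, 1L)
  # seeded-random 120-mer: all boxes absent
  rnd <- random_dna(120, seed = 55)
  cfg <- motif_config()
  # exhaustive confirmation on this seed: no window within the mismatch
  # allowance of any box motif
  min_mm <- function(s, motif) {
    k <- nchar(motif)
    min(vapply(1:(nchar(s) - k + 1),
               function(i) hamming(substr(s, i, i + k - 1), motif),
               integer(1)))
  }
  expect_gt(min_mm(rnd, cfg$abox_seq), cfg$max_mm_abox)
  for (ref in cfg$cbox_refs) expect_gt(min_mm(rnd, ref),
                                       cfg$cbox_assign_max_mm)
  ann3 <- scan_boxes(rnd)
  expect_null(ann3$abox); expect_null(ann3$cbox)
  # the 6 nt IE motif is short enough to chance-match at 2 mismatches;
  # the scan must agree with the exhaustive check either way
  expect_equal(is.null(ann3$ie), min_mm(rnd, cfg$ie_seq) > cfg$max_mm_ie)
})

test_that("MotIE and MotC are the spacers upstream of IE and C-Box", {
  spec <- five_s_unit_spec()
  gene <- make_5s_unit(spec, seed = 5)$gene
  ann <- scan_boxes(gene)
  # the planted 4-mer between A-Box end (64) and IE start (68)
  expect_identical(ann$mot_ie, substr(gene, 65, 68))
  expect_equal(nchar(ann$mot_ie), 4L)
  # the planted 5-mer between IE end (74) and C-Box start (79)
  expect_identical(ann$mot_c, substr(gene, 75, 79))
  expect_equal(nchar(ann$mot_c), 5L)
  # IE absent -> MotIE absent
  ann_no_ie <- ann
  ann_no_ie$ie <- NULL
  mot <- extract_motifs(gene, ann_no_ie)
  expect_true(is.na(mot$mot_ie))
  # degenerate spacing: boxes closer than the motif length warn and yield NA
  ann_tight <- list(abox = interval(0, 15), ie = interval(17, 23),
                    cbox = interval(28, 38))
  expect_warning(mot2 <- extract_motifs(random_dna(60, seed = 6), ann_tight),
                 "MotIE")
  expect_true(is.na(mot2$mot_ie))
})

test_that("the 5S similarity region is found mid-LTR with sane geometry", {
  unit_spec <- five_s_unit_spec()
  gene <- make_5s_unit(unit_spec, seed = 7)$gene
  el <- make_cassandra(cassandra_spec(ltr_length = 280,
                                      core_offset_fraction = 0.48),
                       five_s = gene, seed = 8, unit_spec = unit_spec)
  ltr <- iv_seq(el$seq, interval(0, 280))
  reg <- locate_similarity_region(ltr, gene)
  expect_false(is.null(reg))
  expect_gte(iv_length(reg$ltr_span), 70 - 2) # planted 70 bp core
  expect_equal(reg$identity_pct, 100)
  # strictly inside the LTR, midpoint within the observed 25-75% band
  expect_gt(reg$ltr_span$start, 0)
  expect_lt(reg$ltr_span$end, 280)
  expect_gt(reg$relative_midpoint, 0.25)
  expect_lt(reg$relative_midpoint, 0.75)
  expect_equal(reg$relative_midpoint, 0.48, tolerance = 0.02)
  # a Cassandra-like TRIM LTR has no similarity region
  tr <- make_cassandra_like_trim(cassandra_spec(ltr_length = 280), seed = 9)
  expect_null(locate_similarity_region(iv_seq(tr$seq, interval(0, 280)),
                                       gene))
})

test_that("elements classify as cassandra / cassandra-like TRIM / other", {
  fx <- planted_genome(901, n_elements = 2, with_trim = TRUE)
  cands <- find_ltr_pairs(fx$genome)
  expect_equal(nrow(cands), 3)
  anns <- annotate_elements(cands, fx$genome, fx$gene)
  truth_te <- fx$truth[fx$truth$type == "LTR_retrotransposon", ]
  truth_lab <- sub(".*label=([a-z_]+).*", "\\1", truth_te$attributes)
  expect_identical(anns$label, truth_lab)
  # the TRIM was recognised through its TATA box near offset 48 (detected
  # LTR boundaries can jitter by a base when a flank column chance-matches,
  # hence the tolerance the classifier itself uses)
  expect_lte(abs(anns$tata_offset[anns$label == "cassandra_like_trim"] - 48L),
             5L)
  # a plain direct repeat with neither core nor TATA -> other_trim
  set.seed(902)
  ltr <- random_dna(150)
  plain <- paste0(random_dna(400), ltr, random_dna(120), ltr,
                  random_dna(400))
  pc <- find_ltr_pairs(plain)
  expect_equal(nrow(pc), 1)
  expect_equal(annotate_elements(pc, plain, fx$gene)$label, "other_trim")
})

test_that("C-Box population tallies reproduce planted proportions", {
  set.seed(903)
  unit_spec <- five_s_unit_spec(cbox_variant = "anthemideae_rdna")
  gene <- make_5s_unit(unit_spec)$gene
  mk <- function(variant, n, id0) {
    lapply(seq_len(n), function(i) {
      make_cassandra(cassandra_spec(cbox_variant = variant,
                                    divergence = 0.02),
                     five_s = gene, unit_spec = unit_spec,
                     id = sprintf("%s_%02d", id0, i), protect_cbox = TRUE)
    })
  }
  els <- c(mk("canonical", 7, "can"), mk("anthemideae_cassandra", 3, "ant"))
  anns <- lapply(els, function(e) {
    ltr <- iv_seq(e$seq, interval(0, e$spec$ltr_length))
    suppressWarnings(scan_boxes(ltr))
  })
  tally <- tally_cbox_populations(anns)
  expect_equal(tally[["canonical"]], 7L)
  expect_equal(tally[["anthemideae_cassandra"]], 3L)
  expect_length(tally_cbox_populations(list()), 0)
})
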