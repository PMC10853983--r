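# Programmatic fixtures shared across test files.

# A genome with `n_elements` planted Cassandras (plus optionally one
# Cassandra-like TRIM), all sharing one genic 5S reference.
planted_genome <- function(seed, n_elements = 1L, divergence = 0,
                           ltr_length = 200L, internal_length = 100L,
                           background_length = 3000L, with_trim = FALSE,
                           cbox_variant = "canonical",
                           rdna_variant = "canonical",
                           protect_cbox = FALSE, tsd_length = 5L) {
  set.seed(seed)
  unit_spec <- five_s_unit_spec(cbox_variant = rdna_variant)
  gene <- make_5s_unit(unit_spec)$gene
  elements <- list()
  for (i in seq_len(n_elements)) {
    spec <- cassandra_spec(ltr_length = ltr_length,
                           internal_length = internal_length,
                           cbox_variant = cbox_variant,
                           tsd_length = tsd_length, divergence = divergence)
    elements[[length(elements) + 1L]] <-
      make_cassandra(spec, five_s = gene, id = sprintf("cassandra_%02d", i),
                     unit_spec = unit_spec, protect_cbox = protect_cbox)
  }
  if (with_trim) {
    spec <- cassandra_spec(ltr_length = max(60L, ltr_length),
                           internal_length = internal_length,
                           tsd_length = tsd_length, divergence = divergence)
    elements[[length(elements) + 1L]] <- make_cassandra_like_trim(spec,
                                                                  id = "trim_01")
  }
  planted <- plant_elements(background_length, elements)
  list(genome = planted$seq, truth = planted$truth, gene = gene,
       unit_spec = unit_spec, elements = elements)
}

# A genome whose single element has hand-designed flanks that mismatch the
# extension comparisons for >= 6 positions at every boundary, so the x-drop
# refinement provably stops exactly at the truth boundaries.
designed_boundary_genome <- function(seed = 101L) {
  set.seed(seed)
  gene <- make_5s_unit()$gene
  spec <- cassandra_spec(ltr_length = 200L, internal_length = 100L,
                         tsd_length = 0L)
  el <- make_cassandra(spec, five_s = gene, id = "cassandra_designed")
  # left extension compares bg-left vs the internal end (PPT "GGGAGAGAGG",
  # all purines): "TTTTTT" mismatches every position. Right extension
  # compares the internal start (PBS "TGGTATCAGAGC", no C in the first 6)
  # vs bg-right: "CCCCCC" mismatches every position. The two flank strings
  # differ so no spurious TSD appears either.
  bg_left <- paste0(random_dna(700), "TTTTTT")
  bg_right <- paste0("CCCCCC", random_dna(700))
  genome <- paste0(bg_left, el$seq, bg_right)
  truth <- el$truth
  truth$start <- truth$start + nchar(bg_left)
  truth$end <- truth$end + nchar(bg_left)
  truth$contig_id <- "contig_1"
  list(genome = genome, truth = truth, gene = gene)
}

# k families of diverged copies for the clustering suite
family_seqs <- function(k, copies = 4L, seq_length = 600L, rate = 0.05,
                        seed = 1L) {
  set.seed(seed)
  seqs <- character(0)
  truth <- character(0)
  for (f in seq_len(k)) {
    ancestor <- random_dna(seq_length)
    for (c in seq_len(copies)) {
      id <- sprintf("f%d_c%d", f, c)
      seqs[id] <- mutate(ancestor, substitution_rate = rate)
      truth[id] <- sprintf("f%d", f)
    }
  }
  list(seqs = seqs, truth = truth)
}

# deterministically tiled reads guaranteeing every k-mer occurs >= 2 times
tiled_reads <- function(seq, read_length = 100L, step = 10L) {
  L <- nchar(seq)
  starts <- unique(c(seq(1L, L - read_length + 1L, by = step),
                     L - read_length + 1L))
  reads <- substring(seq, starts, starts + read_length - 1L)
  reads <- c(reads, reads) # duplicate so min_count = 2 is always met
  names(reads) <- sprintf("tile_%04d", seq_along(reads))
  reads
}

# reduced rDNA marker-block sizes: topology and coverage unchanged, sized
# for test runtime
small_subunits <- c(s18 = 600L, s58 = 100L, s26 = 1200L)
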