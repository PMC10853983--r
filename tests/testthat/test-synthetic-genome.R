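test_that("5S units carry the variant C-Box at its offset and are deterministic", {
  u_can <- make_5s_unit(five_s_unit_spec(cbox_variant = "canonical"), seed = 3)
  expect_identical(iv_seq(u_can$gene, interval(79, 89)), "AGGATGGGTG")
  u_rdna <- make_5s_unit(five_s_unit_spec(cbox_variant = "anthemideae_rdna"),
                         seed = 3)
  expect_identical(iv_seq(u_rdna$gene, interval(79, 89)), "GGCTTGGGTG")
  # A-Box and IE land at their configured offsets too
  spec <- five_s_unit_spec()
  expect_identical(iv_seq(u_can$gene, spec$abox), spec$abox_seq)
  expect_identical(iv_seq(u_can$gene, spec$ie), spec$ie_seq)
  # determinism and unit length
  expect_identical(make_5s_unit(spec, seed = 9)$seq,
                   make_5s_unit(spec, seed = 9)$seq)
  expect_equal(nchar(u_can$seq), spec$gene_length + spec$nts_length)
  # invalid layouts rejected
  expect_error(five_s_unit_spec(gene_length = 80), "C-Box")
  expect_error(five_s_unit_spec(abox = interval(49, 70)), "ordered")
})

test_that("rDNA arrays respect the linked/separated arrangement", {
  us <- five_s_unit_spec()
  lk <- make_rdna_array(us, n_copies = 5, linked = TRUE, seed = 2,
                        subunit_lengths = small_subunits)
  expect_length(lk$arrays, 1)
  five_s <- lk$truth[lk$truth$type == "five_S_rRNA_gene", ]
  monomers <- lk$truth[lk$truth$type == "rDNA_monomer", ]
  expect_equal(nrow(five_s), 5)
  # every 5S gene sits inside a monomer interval
  for (i in seq_len(nrow(five_s))) {
    inside <- any(monomers$start <= five_s$start[i] &
                    monomers$end >= five_s$end[i])
    expect_true(inside)
  }
  # total length = n x monomer length (no indels)
  expect_equal(nchar(lk$arrays[[1]]), 5 * unname(lk$monomer_lengths[1]))
  # the planted gene is recoverable from the array
  expect_identical(iv_seq(lk$arrays[[1]],
                          interval(five_s$start[1], five_s$end[1])),
                   lk$five_s_gene)

  sp <- make_rdna_array(us, n_copies = 5, linked = FALSE, seed = 2,
                        subunit_lengths = small_subunits)
  expect_length(sp$arrays, 2)
  five_s2 <- sp$truth[sp$truth$type == "five_S_rRNA_gene", ]
  expect_true(all(five_s2$contig_id == "rdna_5S"))
  expect_true(all(sp$truth$contig_id[sp$truth$type == "35S_region"] ==
                    "rdna_35S"))
  expect_error(make_rdna_array(us, n_copies = 1), ">= 2")
})

test_that("Cassandra elements have identical LTRs at divergence 0 and a 70 bp core", {
  gene <- make_5s_unit(seed = 5)$gene
  el <- make_cassandra(cassandra_spec(), five_s = gene, seed = 6)
  ltr5 <- iv_seq(el$seq, interval(0, 270))
  ltr3 <- iv_seq(el$seq, interval(nchar(el$seq) - 270, nchar(el$seq)))
  expect_identical(ltr5, ltr3)
  expect_equal(global_identity(ltr5, ltr3)$identity_pct, 100)
  core <- el$truth[el$truth$type == "five_S_core", ]
  expect_equal(core$end - core$start, 70)
  # core never touches the LTR termini
  expect_gt(core$start, 0)
  expect_lt(core$end, 270)
  # the Cassandra-shifted variant appears in the LTR C-Box slice
  el2 <- make_cassandra(cassandra_spec(cbox_variant = "anthemideae_cassandra"),
                        five_s = gene, seed = 6)
  cb <- el2$truth[el2$truth$type == "C_box", ]
  expect_identical(iv_seq(el2$seq, interval(cb$start, cb$end)), "GGCCTGGGTG")
  # PBS immediately 3' of the 5' LTR, PPT immediately 5' of the 3' LTR
  expect_identical(iv_seq(el$seq, interval(270, 282)), "TGGTATCAGAGC")
  expect_identical(iv_seq(el$seq, interval(342, 352)), "GGGAGAGAGG")
  # core touching a terminus is a spec error
  expect_error(make_cassandra(cassandra_spec(ltr_length = 70),
                              five_s = gene, seed = 1), "terminus")
})

test_that("Cassandra-like TRIMs carry TATAAA at 48 nt and no 5S core", {
  spec <- cassandra_spec(ltr_length = 200)
  tr <- make_cassandra_like_trim(spec, seed = 8)
  expect_identical(iv_seq(tr$seq, interval(48, 54)), "TATAAA")
  # no 5S similarity at min score 40
  gene <- make_5s_unit(seed = 5)$gene
  ltr <- iv_seq(tr$seq, interval(0, 200))
  expect_null(local_align(ltr, gene, min_score = 40))
  expect_equal(global_identity(ltr, iv_seq(tr$seq, interval(nchar(tr$seq) - 200,
                                                            nchar(tr$seq))))$identity_pct,
               100)
  expect_error(make_cassandra_like_trim(cassandra_spec(ltr_length = 50)),
               "ltr_length")
})

test_that("planting duplicates the target site and keeps truth exact", {
  gene <- make_5s_unit(seed = 5)$gene
  el <- make_cassandra(cassandra_spec(tsd_length = 5), five_s = gene,
                       seed = 6)
  g <- plant_elements(4000, list(el), seed = 7)
  te <- g$truth[g$truth$type == "LTR_retrotransposon", ]
  left <- iv_seq(g$seq, interval(te$start - 5, te$start))
  right <- iv_seq(g$seq, interval(te$end, te$end + 5))
  expect_identical(left, right)
  # planted truth is self-consistent: the truth interval reproduces the
  # element sequence emitted by the generator
  expect_identical(iv_seq(g$seq, interval(te$start, te$end)), el$seq)
  # zero elements -> pure background, empty truth
  g0 <- plant_elements(500, list(), seed = 7)
  expect_equal(nchar(g0$seq), 500)
  expect_equal(nrow(g0$truth), 0)
  # two elements -> disjoint truth intervals
  el2 <- make_cassandra(cassandra_spec(tsd_length = 4), five_s = gene,
                        seed = 9, id = "cassandra_2")
  g2 <- plant_elements(5000, list(el, el2), seed = 8)
  tes <- g2$truth[g2$truth$type == "LTR_retrotransposon", ]
  expect_equal(nrow(tes), 2)
  expect_lte(tes$end[1], tes$start[2])
})

test_that("mutate applies rates as configured and is deterministic", {
  s <- random_dna(10000, seed = 12)
  expect_identical(mutate(s, 0, 0), s)
  m <- mutate(s, substitution_rate = 0.05, seed = 13)
  frac <- hamming(s, m) / nchar(s)
  sd3 <- 3 * sqrt(0.05 * 0.95 / nchar(s))
  expect_lt(abs(frac - 0.05), sd3)
  expect_identical(mutate(s, 0.05, 0.001, seed = 14),
                   mutate(s, 0.05, 0.001, seed = 14))
  # protected intervals are untouched
  p <- mutate(s, substitution_rate = 1, seed = 15,
              protect = list(interval(100, 110)))
  expect_identical(substr(p, 101, 110), substr(s, 101, 110))
})

test_that("read simulation hits the target coverage with exact substrings", {
  g <- random_dna(10000, seed = 16)
  reads <- simulate_reads(g, read_length = 100, coverage = 10, seed = 17)
  expect_length(reads, 1000)
  set.seed(18)
  for (r in sample(reads, 20)) expect_true(grepl(r, g, fixed = TRUE))
  expect_length(simulate_reads(g, 100, 0, seed = 17), 0)
  expect_identical(simulate_reads(g, 100, 5, seed = 19),
                   simulate_reads(g, 100, 5, seed = 19))
})

test_that("cassandra families are amplified copies with optional indel variants", {
  gene <- make_5s_unit(seed = 5)$gene
  fam <- make_cassandra_family(cassandra_spec(), five_s = gene,
                               n_copies = 4, copy_divergence = 0.02,
                               deletion_copies = 3:4, seed = 61)
  expect_length(fam, 4)
  # deletion copies are shorter by 2 x 30 bp (both LTRs)
  lens <- vapply(fam, function(e) nchar(e$seq), numeric(1))
  expect_equal(lens[1] - lens[3], 60)
  expect_equal(lens[3], lens[4])
  # copies stay well above the 70% family threshold
  expect_gt(global_identity(fam[[1]]$seq, fam[[2]]$seq)$identity_pct, 85)
  # the C-Box is protected from divergence in every copy
  for (e in fam) {
    cb <- e$truth[e$truth$type == "C_box", ]
    expect_identical(iv_seq(e$seq, interval(cb$start, cb$end)),
                     cbox_references()[["canonical"]])
  }
  # determinism
  fam2 <- make_cassandra_family(cassandra_spec(), five_s = gene,
                                n_copies = 4, copy_divergence = 0.02,
                                deletion_copies = 3:4, seed = 61)
  expect_identical(fam[[2]]$seq, fam2[[2]]$seq)
  # a deletion through the core is rejected
  expect_error(make_cassandra_family(cassandra_spec(), five_s = gene,
                                     deletion_copies = 1L,
                                     deletion_offset = 120L, seed = 62),
               "core")
})
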