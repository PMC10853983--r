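test_that("a planted zero-divergence element is recovered with exact intervals", {
  fx <- designed_boundary_genome(seed = 101)
  cands <- find_ltr_pairs(fx$genome)
  expect_equal(nrow(cands), 1)
  te <- fx$truth[fx$truth$type == "LTR_retrotransposon", ]
  ltrs <- fx$truth[fx$truth$type == "long_terminal_repeat", ]
  expect_equal(cands$element_start, te$start)
  expect_equal(cands$element_end, te$end)
  expect_equal(cands$ltr5_start, ltrs$start[1])
  expect_equal(cands$ltr5_end, ltrs$end[1])
  expect_equal(cands$ltr3_start, ltrs$start[2])
  expect_equal(cands$ltr3_end, ltrs$end[2])
  expect_equal(cands$ltr_identity_pct, 100)
})

test_that("length bounds and the identity threshold filter candidates", {
  set.seed(201)
  # 25 bp repeats: below min_ltr 30 -> not reported
  rep25 <- random_dna(25)
  g1 <- paste0(random_dna(300), rep25, random_dna(100), rep25,
               random_dna(300))
  expect_equal(nrow(find_ltr_pairs(g1)), 0)
  # a 40%-identity pair: far below the 70% threshold
  a <- random_dna(200)
  b <- mutate(a, substitution_rate = 0.6)
  g2 <- paste0(random_dna(300), a, random_dna(100), b, random_dna(300))
  cands2 <- find_ltr_pairs(g2)
  if (nrow(cands2) > 0) expect_true(all(cands2$ltr_identity_pct >= 70))
  # internal region beyond max_between -> not reported at default bounds
  c0 <- random_dna(100)
  g3 <- paste0(random_dna(100), c0, random_dna(2300), c0, random_dna(100))
  expect_equal(nrow(find_ltr_pairs(g3)), 0)
  # sequence shorter than the minimum feasible element -> empty, no error
  expect_equal(nrow(find_ltr_pairs(random_dna(60))), 0)
})

test_that("random background yields no candidates, in agreement with the scan oracle", {
  for (seed in c(301, 302, 303)) {
    g <- random_dna(2000, seed = seed)
    expect_false(oracle_repeat_signal(g))
    expect_equal(nrow(find_ltr_pairs(g)), 0)
  }
})

test_that("detector agrees with the exhaustive interval-pair oracle on small inputs", {
  cfg <- detector_config(min_ltr = 20, max_ltr = 60, min_between = 10,
                         max_between = 120, seed_word = 10)
  for (seed in 401:406) {
    set.seed(seed)
    plant <- seed %% 2 == 0
    if (plant) {
      ltr <- random_dna(40)
      g <- paste0(random_dna(120), ltr, random_dna(60), ltr,
                  random_dna(120))
    } else {
      g <- random_dna(400)
    }
    oracle <- oracle_repeat_pairs(g, 20, 60, 10, 120)
    cands <- find_ltr_pairs(g, cfg)
    # soundness: anything the detector reports, the oracle also admits
    if (nrow(cands) > 0) expect_false(is.null(oracle),
                                      info = paste("seed", seed))
    if (plant) {
      # completeness on planted repeats: both must find the pair
      expect_false(is.null(oracle), info = paste("seed", seed))
      expect_gt(nrow(cands), 0, label = paste("seed", seed, "candidates"))
    }
    if (plant && !is.null(oracle) && nrow(cands) > 0) {
      # the detector's pair must coincide with the oracle's best-scoring
      # pair (same diagonal, heavily overlapping copy span)
      best <- oracle[which.max(oracle$score), ]
      d_oracle <- best$ltr_len + best$gap
      d_det <- cands$ltr3_start[1] - cands$ltr5_start[1]
      expect_equal(d_det, d_oracle)
      ov <- min(cands$ltr5_end[1], best$start + best$ltr_len) -
        max(cands$ltr5_start[1], best$start)
      expect_gte(ov / best$ltr_len, 0.8)
    }
  }
})

test_that("reported candidates always satisfy the configured bounds", {
  cfg <- detector_config()
  for (seed in 501:505) {
    fx <- planted_genome(seed, n_elements = seed %% 3 + 1,
                         divergence = 0.03)
    cands <- find_ltr_pairs(fx$genome, cfg)
    for (i in seq_len(nrow(cands))) {
      l5 <- cands$ltr5_end[i] - cands$ltr5_start[i]
      l3 <- cands$ltr3_end[i] - cands$ltr3_start[i]
      int <- cands$internal_end[i] - cands$internal_start[i]
      expect_gte(l5, cfg$min_ltr); expect_lte(l5, cfg$max_ltr)
      expect_gte(l3, cfg$min_ltr); expect_lte(l3, cfg$max_ltr)
      expect_gte(int, cfg$min_between); expect_lte(int, cfg$max_between)
      expect_gte(cands$ltr_identity_pct[i], cfg$min_ltr_identity)
      expect_lte(cands$ltr5_end[i], cands$internal_start[i])
      expect_lte(cands$internal_end[i], cands$ltr3_start[i])
    }
  }
})

test_that("TSD detection reports the longest flank duplication", {
  el <- random_dna(300, seed = 601)
  cand <- data.frame(element_start = 100L, element_end = 100L + 300L)
  # 5 bp duplication
  g <- paste0(random_dna(95, seed = 602), "ACGTA", el, "ACGTA",
              random_dna(95, seed = 603))
  expect_identical(detect_tsd(g, cand), "ACGTA")
  # differing flanks -> none
  g2 <- paste0(random_dna(95, seed = 604), "ACGTA", el, "TTTTT",
               random_dna(95, seed = 605))
  expect_null(detect_tsd(g2, cand))
  # 6 bp and 4 bp duplications both present -> the 6 bp one wins
  g3 <- paste0(random_dna(94, seed = 606), "GACGTA", el, "GACGTA",
               random_dna(94, seed = 607))
  cand3 <- data.frame(element_start = 100L, element_end = 400L)
  expect_identical(detect_tsd(g3, cand3), "GACGTA")
})

test_that("PBS detection finds the motif within 20 nt of the 5' LTR", {
  cfg <- detector_config()
  motif <- cfg$pbs_motif
  make_cand <- function(internal) {
    g <- paste0(random_dna(200, seed = 701), internal,
                random_dna(200, seed = 702))
    list(g = g, cand = data.frame(ltr5_end = 200L,
                                  ltr3_start = 200L + nchar(internal)))
  }
  # planted 3 nt after the LTR: offset 3, 0 mismatches
  x <- make_cand(paste0("AAA", motif, random_dna(40, seed = 703)))
  hit <- detect_pbs(x$g, x$cand, cfg)
  expect_equal(hit$offset, 3)
  expect_equal(hit$mismatches, 0)
  # no motif -> none
  y <- make_cand(random_dna(60, seed = 704))
  expect_null(detect_pbs(y$g, y$cand, cfg))
  # 3 mismatches with allowance 2 -> none
  mm3 <- motif
  substr(mm3, 1, 3) <- "CCC" # motif starts TGG, so 3 mismatches
  z <- make_cand(paste0(mm3, random_dna(40, seed = 705)))
  expect_null(detect_pbs(z$g, z$cand, cfg))
})

test_that("PPT detection applies the purine-count window rule", {
  cfg <- detector_config()
  make_cand <- function(internal) {
    g <- paste0(random_dna(200, seed = 801), internal,
                random_dna(200, seed = 802))
    data.frame(g = I(list(g)),
               internal_start = 200L,
               ltr3_start = 200L + nchar(internal))
  }
  # all-purine window planted at the internal end
  int1 <- paste0(strrep("C", 40), "GGGAGAGAGG")
  cand1 <- make_cand(int1)
  hit <- detect_ppt(cand1$g[[1]], cand1, cfg)
  expect_equal(hit$purines, 10)
  expect_equal(hit$start, 200L + 40L)
  # pyrimidine-rich flank -> none
  cand2 <- make_cand(strrep("CT", 25))
  expect_null(detect_ppt(cand2$g[[1]], cand2, cfg))
  # exactly 8 purines in 10 passes at the default threshold
  int3 <- paste0(strrep("C", 40), "GAGAGAGACT")
  cand3 <- make_cand(int3)
  hit3 <- detect_ppt(cand3$g[[1]], cand3, cfg)
  expect_equal(hit3$purines, 8)
})

test_that("strict flags turn annotations into filters", {
  fx <- designed_boundary_genome(seed = 101)
  # the designed element has no TSD (tsd_length 0), so strict TSD mode
  # must drop it while relaxed mode keeps it
  relaxed <- find_ltr_pairs(fx$genome)
  expect_equal(nrow(relaxed), 1)
  strict <- find_ltr_pairs(fx$genome, detector_config(require_tsd = TRUE))
  expect_equal(nrow(strict), 0)
})
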