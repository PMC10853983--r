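# Synthetic genomes with planted ground truth: tandem 5S arrays, 35S
# monomers with or without an internal 5S copy, Cassandra elements whose LTRs
# carry a mid-LTR 5S-derived core, Cassandra-like TRIMs with a TATA box
# instead, copy divergence, and uniform random background.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Uniform random DNA
#' @param n Length in bp.
#' @param seed Optional integer seed (`NULL` = current RNG stream).
#' @return A DNA string of length `n`.
#' @export
random_dna <- function(n, seed = NULL) {
  .with_seed(seed, {
    if (n <= 0) return("")
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  })
}

#' Reference C-Box motifs
#'
#' The three observed 10-mers: the canonical angiosperm C-Box, the shifted
#' variant found in Anthemideae 5S rRNA genes, and the Cassandra-borne
#' mirror of that shift.
#' @return Named character vector of 10-mers.
#' @export
cbox_references <- function() {
  c(canonical             = "AGGATGGGTG",
    anthemideae_rdna      = "GGCTTGGGTG",
    anthemideae_cassandra = "GGCCTGGGTG")
}

.replace_at <- function(seq, iv, replacement) {
  stopifnot(nchar(replacement) == iv_length(iv), iv$end <= nchar(seq))
  paste0(substr(seq, 1L, iv$start), replacement,
         substr(seq, iv$end + 1L, nchar(seq)))
}

#' Specification of a 5S rDNA unit
#'
#' The ~120 bp 5S rRNA gene plus its nontranscribed spacer (NTS). Box layout
#' follows the internal control region of plant 5S genes: a 15 nt A-Box, a
#' 6 nt intermediate element (IE) 4 nt downstream (the MotIE spacer), and the
#' 10 nt C-Box 5 nt further downstream (the MotC spacer). Only the C-Box
#' strings are fixed observations; A-Box/IE defaults are configurable layout
#' parameters, not ground truth.
#'
#' @param gene_length Gene length in bp (default 120).
#' @param nts_length Spacer length in bp (default 300).
#' @param cbox_variant One of `names(cbox_references())`.
#' @param abox,ie,cbox Gene-relative [interval()]s for the three boxes.
#' @param abox_seq,ie_seq Default box strings (lengths must match intervals).
#' @return A list of class `five_s_unit_spec`.
#' @export
five_s_unit_spec <- function(gene_length = 120L, nts_length = 300L,
                             cbox_variant = "canonical",
                             abox = interval(49, 64), ie = interval(68, 74),
                             cbox = interval(79, 89),
                             abox_seq = "GGATGCGATCATACC",
                             ie_seq = "CGAGAG") {
  cbox_variant <- match.arg(cbox_variant, names(cbox_references()))
  if (cbox$end > gene_length) stop("C-Box offsets exceed gene_length")
  if (abox$end > ie$start || ie$end > cbox$start) {
    stop("box intervals must be ordered and non-overlapping: A-Box < IE < C-Box")
  }
  stopifnot(nchar(abox_seq) == iv_length(abox), nchar(ie_seq) == iv_length(ie),
            iv_length(cbox) == 10L)
  structure(list(gene_length = as.integer(gene_length),
                 nts_length = as.integer(nts_length),
                 cbox_variant = cbox_variant, abox = abox, ie = ie,
                 cbox = cbox, abox_seq = abox_seq, ie_seq = ie_seq),
            class = "five_s_unit_spec")
}

.truth_row <- function(contig_id, type, iv, attributes = ".") {
  data.frame(contig_id = contig_id, type = type, start = iv$start,
             end = iv$end, attributes = attributes, stringsAsFactors = FALSE)
}

#' Generate a single 5S rDNA unit (gene + NTS)
#'
#' The gene portion carries the configured A-Box/IE/C-Box strings at their
#' offsets; the C-Box equals the variant's reference motif; the rest of the
#' gene and the NTS are seeded-random.
#'
#' @param spec A [five_s_unit_spec()].
#' @param seed Integer seed.
#' @param id Contig id for the truth records.
#' @return List with `seq`, `gene` (gene portion only), `truth` (data frame),
#'   and `spec`.
#' @export
make_5s_unit <- function(spec = five_s_unit_spec(), seed = NULL,
                         id = "5S_unit") {
  .with_seed(seed, {
    gene <- random_dna(spec$gene_length)
    gene <- .replace_at(gene, spec$abox, spec$abox_seq)
    gene <- .replace_at(gene, spec$ie, spec$ie_seq)
    gene <- .replace_at(gene, spec$cbox, cbox_references()[[spec$cbox_variant]])
    unit <- paste0(gene, random_dna(spec$nts_length))
    truth <- rbind(
      .truth_row(id, "five_S_rRNA_gene", interval(0, spec$gene_length),
                 paste0("cbox_variant=", spec$cbox_variant)),
      .truth_row(id, "A_box", spec$abox),
      .truth_row(id, "IE", spec$ie),
      .truth_row(id, "C_box", spec$cbox,
                 paste0("variant=", spec$cbox_variant)))
    list(seq = unit, gene = gene, truth = truth, spec = spec)
  })
}

#' Generate a tandem rDNA array, linked or separated
#'
#' Linked: each monomer is 18S + 5.8S + 26S marker blocks with a spacer
#' containing one 5S unit, so the 5S gene sits inside the 35S monomer.
#' Separated: two independent arrays, one of 35S-only monomers and one of
#' 5S-only units. Subunits are distinct seeded-random marker blocks
#' (defaults 1.8 kb / 160 bp / 3.4 kb), sufficient for graph coloring
#' without real rRNA sequence.
#'
#' @param unit_spec A [five_s_unit_spec()] for the 5S unit.
#' @param n_copies Monomer copies per array (>= 2).
#' @param linked Logical arrangement flag.
#' @param seed Integer seed.
#' @param subunit_lengths Named lengths for `s18`, `s58`, `s26` blocks.
#' @param its_length,igs_length Internal/intergenic spacer lengths.
#' @return List with `arrays` (named character vector of 1 or 2 contigs),
#'   `truth`, `refs` (named reference blocks: `35S_18S`, `35S_5.8S`,
#'   `35S_26S`, `5S`), `monomer_lengths`, and `arrangement` ("L" or "S").
#' @export
make_rdna_array <- function(unit_spec = five_s_unit_spec(), n_copies = 3L,
                            linked = TRUE, seed = NULL,
                            subunit_lengths = c(s18 = 1800L, s58 = 160L,
                                                s26 = 3400L),
                            its_length = 150L, igs_length = 200L) {
  if (n_copies < 2L) stop("n_copies must be >= 2")
  .with_seed(seed, {
    s18 <- random_dna(subunit_lengths[["s18"]])
    s58 <- random_dna(subunit_lengths[["s58"]])
    s26 <- random_dna(subunit_lengths[["s26"]])
    its1 <- random_dna(its_length); its2 <- random_dna(its_length)
    unit <- make_5s_unit(unit_spec)
    refs <- c(`35S_18S` = s18, `35S_5.8S` = s58, `35S_26S` = s26,
              `5S` = unit$gene)
    arrangement <- if (linked) "L" else "S"
    truth <- NULL
    add <- function(contig, type, start, len, attrs = ".") {
      truth <<- rbind(truth, .truth_row(contig, type,
                                        interval(start, start + len), attrs))
    }
    if (linked) {
      igs1 <- random_dna(igs_length); igs2 <- random_dna(igs_length)
      monomer <- paste0(s18, its1, s58, its2, s26, igs1, unit$seq, igs2)
      contig <- "rdna_linked"
      arr <- paste(rep(monomer, n_copies), collapse = "")
      off35 <- nchar(s18) + its_length + nchar(s58) + its_length + nchar(s26)
      for (i in seq_len(n_copies) - 1L) {
        m0 <- i * nchar(monomer)
        add(contig, "rDNA_monomer", m0, nchar(monomer),
            paste0("arrangement=", arrangement))
        add(contig, "35S_region", m0, off35)
        add(contig, "five_S_rRNA_gene", m0 + off35 + igs_length,
            unit_spec$gene_length,
            paste0("cbox_variant=", unit_spec$cbox_variant))
      }
      arrays <- setNames(arr, contig)
      monomer_lengths <- c(rdna_linked = nchar(monomer))
    } else {
      igs <- random_dna(igs_length)
      monomer35 <- paste0(s18, its1, s58, its2, s26, igs)
      arr35 <- paste(rep(monomer35, n_copies), collapse = "")
      arr5 <- paste(rep(unit$seq, n_copies), collapse = "")
      for (i in seq_len(n_copies) - 1L) {
        add("rdna_35S", "rDNA_monomer", i * nchar(monomer35), nchar(monomer35),
            paste0("arrangement=", arrangement))
        add("rdna_35S", "35S_region", i * nchar(monomer35),
            nchar(monomer35) - igs_length)
        add("rdna_5S", "five_S_rRNA_gene", i * nchar(unit$seq),
            unit_spec$gene_length,
            paste0("cbox_variant=", unit_spec$cbox_variant))
      }
      arrays <- c(rdna_35S = arr35, rdna_5S = arr5)
      monomer_lengths <- c(rdna_35S = nchar(monomer35),
                           rdna_5S = nchar(unit$seq))
    }
    list(arrays = arrays, truth = truth, refs = refs,
         monomer_lengths = monomer_lengths, arrangement = arrangement,
         five_s_gene = unit$gene)
  })
}

#' Specification of a synthetic Cassandra element
#'
#' Two near-identical LTRs of 30-500 bp flanking a short internal region; a
#' ~70 bp 5S-derived core (A-Box through C-Box plus 15 bp flanks) sits
#' mid-LTR, never touching a terminus; a methionine-tRNA PBS directly 3' of
#' the 5' LTR and a polypurine tract directly 5' of the 3' LTR.
#'
#' @param ltr_length LTR length in bp, within [30, 500] (default 270, the
#'   Asteraceae median).
#' @param internal_length Internal-region length within [30, 2000] (default
#'   82, the Asteraceae median); must fit the PBS and PPT.
#' @param core_offset_fraction LTR-relative midpoint of the 5S core.
#' @param cbox_variant C-Box variant planted in the LTR core.
#' @param tsd_length Target-site-duplication length in [4, 6], or 0 for none.
#' @param pbs_motif Primer-binding-site string.
#' @param ppt Polypurine-tract string (>= 8 purines in 10 nt by default).
#' @param divergence Per-site substitution rate applied independently to each
#'   LTR copy (pairwise LTR divergence is therefore about twice this).
#' @param indel_rate Per-site indel rate applied with the substitutions.
#' @param core_flank Flank added on each side of the A-Box..C-Box span to
#'   reach the ~70 bp core (default 15).
#' @return A list of class `cassandra_spec`.
#' @export
cassandra_spec <- function(ltr_length = 270L, internal_length = 82L,
                           core_offset_fraction = 0.5,
                           cbox_variant = "canonical", tsd_length = 5L,
                           pbs_motif = "TGGTATCAGAGC", ppt = "GGGAGAGAGG",
                           divergence = 0, indel_rate = 0, core_flank = 15L) {
  if (ltr_length < 30L || ltr_length > 500L) {
    stop("ltr_length must lie in [30, 500]")
  }
  if (internal_length < 30L || internal_length > 2000L) {
    stop("internal_length must lie in [30, 2000]")
  }
  if (!(tsd_length == 0L || (tsd_length >= 4L && tsd_length <= 6L))) {
    stop("tsd_length must be 0 or in [4, 6]")
  }
  if (core_offset_fraction <= 0 || core_offset_fraction >= 1) {
    stop("core_offset_fraction must lie in (0, 1)")
  }
  if (internal_length < nchar(pbs_motif) + nchar(ppt)) {
    stop("internal_length too short for PBS + PPT")
  }
  cbox_variant <- match.arg(cbox_variant, names(cbox_references()))
  structure(list(ltr_length = as.integer(ltr_length),
                 internal_length = as.integer(internal_length),
                 core_offset_fraction = core_offset_fraction,
                 cbox_variant = cbox_variant, tsd_length = as.integer(tsd_length),
                 pbs_motif = pbs_motif, ppt = ppt, divergence = divergence,
                 indel_rate = indel_rate, core_flank = as.integer(core_flank)),
            class = "cassandra_spec")
}

# core slice of a 5S gene under a unit spec: A-Box..C-Box span plus flanks
.core_interval <- function(unit_spec, flank) {
  interval(max(0L, unit_spec$abox$start - flank),
           min(unit_spec$gene_length, unit_spec$cbox$end + flank))
}

.build_ltr <- function(spec, unit_spec, gene) {
  core_iv <- .core_interval(unit_spec, spec$core_flank)
  core <- iv_seq(gene, core_iv)
  # the LTR copy of the C-Box carries the element's own variant
  cb_in_core <- interval(unit_spec$cbox$start - core_iv$start,
                         unit_spec$cbox$end - core_iv$start)
  core <- .replace_at(core, cb_in_core,
                      cbox_references()[[spec$cbox_variant]])
  clen <- nchar(core)
  start <- as.integer(round(spec$core_offset_fraction * spec$ltr_length -
                              clen / 2))
  if (start < 1L || start + clen > spec$ltr_length - 1L) {
    stop("core would touch an LTR terminus (ltr_length ", spec$ltr_length,
         ", core ", clen, " bp at fraction ", spec$core_offset_fraction, ")")
  }
  ltr <- random_dna(spec$ltr_length)
  ltr <- .replace_at(ltr, interval(start, start + clen), core)
  list(ltr = ltr, core = interval(start, start + clen),
       cbox = interval(start + cb_in_core$start, start + cb_in_core$end))
}

.element_truth <- function(id, label, spec, ltr_len5, ltr_len3, internal_len,
                           core = NULL, cbox = NULL) {
  l5 <- interval(0, ltr_len5)
  int <- interval(ltr_len5, ltr_len5 + internal_len)
  l3 <- interval(int$end, int$end + ltr_len3)
  truth <- rbind(
    .truth_row(id, "LTR_retrotransposon", interval(0, l3$end),
               paste0("label=", label, ";cbox_variant=", spec$cbox_variant,
                      ";tsd_length=", spec$tsd_length)),
    .truth_row(id, "long_terminal_repeat", l5, "which=5prime"),
    .truth_row(id, "long_terminal_repeat", l3, "which=3prime"),
    .truth_row(id, "primer_binding_site",
               interval(int$start, int$start + nchar(spec$pbs_motif))),
    .truth_row(id, "RR_tract", interval(int$end - nchar(spec$ppt), int$end)))
  if (!is.null(core)) {
    truth <- rbind(truth,
      .truth_row(id, "five_S_core", core, "which=5prime"),
      .truth_row(id, "C_box", cbox,
                 paste0("which=5prime;variant=", spec$cbox_variant)))
  }
  truth
}

#' Generate a Cassandra element with planted 5S core
#'
#' Element = 5' LTR + internal + 3' LTR; both LTRs carry the 5S-derived core
#' centered at `core_offset_fraction`; PBS directly after the 5' LTR, PPT
#' directly before the 3' LTR. Divergence is applied independently to the two
#' LTR copies.
#'
#' @param spec A [cassandra_spec()].
#' @param five_s A `make_5s_unit()`-style gene string, or `NULL` to generate
#'   one from `unit_spec`.
#' @param seed Integer seed.
#' @param id Element id for truth records.
#' @param unit_spec The [five_s_unit_spec()] describing the gene layout.
#' @param protect_cbox If `TRUE`, divergence never hits the planted C-Boxes.
#' @return List with `seq`, `truth`, `ltr` (ancestral undiverged LTR),
#'   `label` ("cassandra"), `tsd_length`, and `spec`.
#' @export
make_cassandra <- function(spec = cassandra_spec(), five_s = NULL, seed = NULL,
                           id = "cassandra_1",
                           unit_spec = five_s_unit_spec(),
                           protect_cbox = FALSE) {
  .with_seed(seed, {
    gene <- if (is.null(five_s)) make_5s_unit(unit_spec)$gene else five_s
    built <- .build_ltr(spec, unit_spec, gene)
    protect <- if (protect_cbox) list(built$cbox) else NULL
    ltr5 <- mutate(built$ltr, spec$divergence, spec$indel_rate,
                   protect = protect)
    ltr3 <- mutate(built$ltr, spec$divergence, spec$indel_rate,
                   protect = protect)
    filler <- spec$internal_length - nchar(spec$pbs_motif) - nchar(spec$ppt)
    internal <- paste0(spec$pbs_motif, random_dna(filler), spec$ppt)
    seq <- paste0(ltr5, internal, ltr3)
    truth <- .element_truth(id, "cassandra", spec, nchar(ltr5), nchar(ltr3),
                            nchar(internal), built$core, built$cbox)
    list(seq = seq, truth = truth, ltr = built$ltr, label = "cassandra",
         tsd_length = spec$tsd_length, spec = spec)
  })
}

#' Generate a Cassandra-like TRIM (TATA box, no 5S core)
#'
#' Same two-LTR architecture as a Cassandra but the LTRs carry no 5S-derived
#' region; instead a "TATAAA" box begins 48 nt from the 5' LTR terminus.
#'
#' @inheritParams make_cassandra
#' @param tata_offset Offset of the TATA box from the LTR 5' terminus.
#' @return As [make_cassandra()], with `label` "cassandra_like_trim".
#' @export
make_cassandra_like_trim <- function(spec = cassandra_spec(), seed = NULL,
                                     id = "trim_1", tata_offset = 48L) {
  if (spec$ltr_length < tata_offset + 6L) {
    stop("ltr_length must be >= ", tata_offset + 6L,
         " so the TATA box fits at offset ", tata_offset)
  }
  .with_seed(seed, {
    ltr <- random_dna(spec$ltr_length)
    ltr <- .replace_at(ltr, interval(tata_offset, tata_offset + 6L), "TATAAA")
    ltr5 <- mutate(ltr, spec$divergence, spec$indel_rate)
    ltr3 <- mutate(ltr, spec$divergence, spec$indel_rate)
    filler <- spec$internal_length - nchar(spec$pbs_motif) - nchar(spec$ppt)
    internal <- paste0(spec$pbs_motif, random_dna(filler), spec$ppt)
    seq <- paste0(ltr5, internal, ltr3)
    truth <- .element_truth(id, "cassandra_like_trim", spec, nchar(ltr5),
                            nchar(ltr3), nchar(internal))
    truth <- rbind(truth,
      .truth_row(id, "TATA_box", interval(tata_offset, tata_offset + 6L),
                 "which=5prime"))
    list(seq = seq, truth = truth, ltr = ltr, label = "cassandra_like_trim",
         tsd_length = spec$tsd_length, spec = spec)
  })
}

#' Plant elements into random background with target-site duplications
#'
#' Elements are inserted at non-overlapping seeded positions. When an element
#' carries `tsd_length > 0`, the insertion-site flank of that length is
#' duplicated on both sides of the element.
#'
#' @param background_length Background length in bp.
#' @param elements List of element objects from [make_cassandra()] /
#'   [make_cassandra_like_trim()].
#' @param seed Integer seed.
#' @param contig_id Id of the output contig.
#' @param min_gap Minimum spacing between insertion sites.
#' @return List with `seq`, `truth` (all element-local truth lifted to contig
#'   coordinates, plus one `LTR_retrotransposon` row per element).
#' @export
plant_elements <- function(background_length, elements, seed = NULL,
                           contig_id = "contig_1", min_gap = 50L) {
  .with_seed(seed, {
    bg <- random_dna(background_length)
    if (length(elements) == 0L) {
      return(list(seq = bg, truth = .truth_row(contig_id, "region",
                    interval(0, background_length))[0, ]))
    }
    n <- length(elements)
    max_tsd <- max(vapply(elements, function(e) e$tsd_length, integer(1)))
    lo <- max_tsd + 1L
    hi <- background_length - max_tsd - 1L
    slack <- (hi - lo) - (n - 1L) * min_gap
    if (slack < n) stop("cannot place ", n, " elements without overlap")
    # spacing-guaranteed construction: sample in the compacted space, then
    # re-expand by min_gap per element
    pos <- sort(sample.int(slack, n)) + lo - 1L +
      (seq_len(n) - 1L) * min_gap
    pieces <- character(0)
    truth <- NULL
    prev <- 0L   # background coordinate consumed so far
    offset <- 0L # final-coordinate shift accumulated so far
    for (i in seq_len(n)) {
      e <- elements[[i]]
      t <- e$tsd_length
      p <- pos[i]
      pieces <- c(pieces, substr(bg, prev + 1L, p + t)) # left flank incl. TSD
      el_start <- p + t + offset
      pieces <- c(pieces, e$seq)
      tr <- e$truth
      tr$start <- tr$start + el_start
      tr$end <- tr$end + el_start
      tr$contig_id <- contig_id
      tr$attributes <- paste0(tr$attributes, ";element_id=",
                              e$truth$contig_id[1])
      truth <- rbind(truth, tr)
      offset <- offset + nchar(e$seq) + t
      prev <- p # right flank restarts at p, duplicating bg[p, p+t)
    }
    pieces <- c(pieces, substr(bg, prev + 1L, background_length))
    list(seq = paste(pieces, collapse = ""), truth = truth)
  })
}

#' Generate a family of Cassandra copies from one master element
#'
#' Models amplification: a zero-divergence master element is built once,
#' then each copy receives independent per-site substitutions. A subset of
#' copies can share a variant-defining LTR deletion (applied identically to
#' both LTRs before the substitutions), reproducing indel-based variant
#' formation within a family.
#'
#' @param spec A [cassandra_spec()] (its `divergence` is ignored; copy
#'   divergence is set here).
#' @param five_s The species 5S gene string (or `NULL` to generate one).
#' @param n_copies Number of copies.
#' @param copy_divergence Per-site substitution rate per copy.
#' @param deletion_copies Indices of copies carrying the shared deletion.
#' @param deletion_offset LTR-relative 0-based start of the deletion; must
#'   not intersect the 5S core.
#' @param deletion_length Deletion length in bp (default 30).
#' @param seed Integer seed.
#' @param id_prefix Prefix for copy ids.
#' @param unit_spec The [five_s_unit_spec()] describing the gene layout.
#' @param protect_cbox If `TRUE` (default), substitutions never hit the
#'   planted C-Boxes.
#' @return List of element objects (as [make_cassandra()]), one per copy.
#' @export
make_cassandra_family <- function(spec = cassandra_spec(), five_s = NULL,
                                  n_copies = 4L, copy_divergence = 0.02,
                                  deletion_copies = integer(0),
                                  deletion_offset = NULL,
                                  deletion_length = 30L, seed = NULL,
                                  id_prefix = "cassandra",
                                  unit_spec = five_s_unit_spec(),
                                  protect_cbox = TRUE) {
  .with_seed(seed, {
    spec$divergence <- 0; spec$indel_rate <- 0
    master <- make_cassandra(spec, five_s = five_s, unit_spec = unit_spec,
                             id = paste0(id_prefix, "_master"))
    L <- spec$ltr_length
    internal <- substr(master$seq, L + 1L, nchar(master$seq) - L)
    core <- master$truth[master$truth$type == "five_S_core", ]
    cbox <- master$truth[master$truth$type == "C_box", ]
    if (length(deletion_copies)) {
      if (is.null(deletion_offset)) deletion_offset <- core$end + 10L
      if (deletion_offset < core$end && deletion_offset + deletion_length >
            core$start) {
        stop("variant deletion would intersect the 5S core")
      }
      if (deletion_offset + deletion_length > L) {
        stop("variant deletion exceeds the LTR")
      }
    }
    lapply(seq_len(n_copies), function(i) {
      ltr_c <- master$ltr
      cb <- interval(cbox$start, cbox$end)
      if (i %in% deletion_copies) {
        ltr_c <- paste0(substr(ltr_c, 1L, deletion_offset),
                        substr(ltr_c, deletion_offset + deletion_length + 1L,
                               L))
        if (cb$start >= deletion_offset + deletion_length) {
          cb <- interval(cb$start - deletion_length, cb$end - deletion_length)
        }
      }
      lc <- nchar(ltr_c)
      seq <- paste0(ltr_c, internal, ltr_c)
      protect <- if (protect_cbox) {
        off3 <- lc + nchar(internal)
        list(cb, interval(off3 + cb$start, off3 + cb$end))
      } else NULL
      seq <- mutate(seq, substitution_rate = copy_divergence,
                    protect = protect)
      id <- sprintf("%s_%02d", id_prefix, i)
      truth <- .element_truth(id, "cassandra", spec, lc, lc,
                              nchar(internal),
                              core = NULL, cbox = NULL)
      truth <- rbind(truth,
        .truth_row(id, "C_box", cb,
                   paste0("which=5prime;variant=", spec$cbox_variant)))
      list(seq = seq, truth = truth, ltr = ltr_c, label = "cassandra",
           tsd_length = spec$tsd_length, spec = spec,
           variant = if (i %in% deletion_copies) "deletion" else "base")
    })
  })
}

#' Mutate a sequence with substitutions and indels
#'
#' Per-site independent substitutions to a different base, then indels
#' (insertion or deletion, equal odds) with seeded lengths uniform in
#' `indel_min`..`indel_max`.
#'
#' @param seq DNA string.
#' @param substitution_rate Per-site substitution probability.
#' @param indel_rate Per-site indel-event probability.
#' @param seed Integer seed.
#' @param protect Optional list of [interval()]s never touched by
#'   substitutions nor removed by deletions.
#' @param indel_min,indel_max Indel length bounds (default 1-30 bp, the
#'   variant-defining range observed in Cassandra LTRs).
#' @return The mutated DNA string.
#' @export
mutate <- function(seq, substitution_rate = 0, indel_rate = 0, seed = NULL,
                   protect = NULL, indel_min = 1L, indel_max = 30L) {
  .with_seed(seed, {
    n <- nchar(seq)
    if (n == 0L || (substitution_rate <= 0 && indel_rate <= 0)) return(seq)
    protected <- rep(FALSE, n)
    for (iv in protect) protected[(iv$start + 1L):iv$end] <- TRUE
    chars <- strsplit(seq, "")[[1]]
    if (substitution_rate > 0) {
      hit <- which(runif(n) < substitution_rate & !protected)
      for (i in hit) {
        chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
      }
    }
    if (indel_rate > 0) {
      sites <- which(runif(n) < indel_rate)
      for (p in rev(sites)) { # right-to-left keeps coordinates valid
        len <- sample(indel_min:indel_max, 1L)
        if (runif(1) < 0.5) { # insertion after p
          chars <- append(chars, sample(c("A", "C", "G", "T"), len,
                                        replace = TRUE), after = p)
        } else {              # deletion starting at p
          del <- p:min(n, p + len - 1L)
          del <- del[del <= length(chars)]
          if (any(protected[del[del <= n]])) next
          chars <- chars[-del]
        }
      }
    }
    paste(chars, collapse = "")
  })
}

#' Simulate uniform error-free reads
#'
#' @param genome DNA string.
#' @param read_length Read length in bp.
#' @param coverage Target fold-coverage; the read count is
#'   `round(coverage * length / read_length)`.
#' @param seed Integer seed.
#' @param prefix Read-id prefix.
#' @return Named character vector of reads (possibly empty).
#' @export
simulate_reads <- function(genome, read_length, coverage, seed = NULL,
                           prefix = "read") {
  .with_seed(seed, {
    L <- nchar(genome)
    if (read_length > L) stop("read_length exceeds genome length")
    n <- round(coverage * L / read_length)
    if (n <= 0) return(setNames(character(0), character(0)))
    starts <- sample.int(L - read_length + 1L, n, replace = TRUE)
    reads <- substring(genome, starts, starts + read_length - 1L)
    names(reads) <- sprintf("%s_%06d", prefix, seq_len(n))
    reads
  })
}
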