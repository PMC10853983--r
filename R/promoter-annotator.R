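# Annotation of the 5S internal promoter (A-Box, intermediate element,
# C-Box) inside LTRs or 5S genes, C-Box variant classification (promoter
# mimicry), location of the 5S-derived similarity region, and
# Cassandra / Cassandra-like TRIM / other classification.

#' Motif configuration for promoter annotation
#'
#' @param abox_seq,ie_seq Reference A-Box and IE strings (the defaults match
#'   the synthetic 5S layout; configurable, not ground truth).
#' @param cbox_refs The three reference C-Box 10-mers ([cbox_references()]).
#' @param max_mm_abox,max_mm_ie Mismatch allowances for A-Box/IE search.
#' @param cbox_assign_max_mm Maximum Hamming distance for C-Box class
#'   assignment (default 2: the references are mutually 1-3 apart, so 2 keeps
#'   the classes separable while tolerating one private substitution).
#' @param tata_seq,tata_offset,tata_tol TATA box string, its expected offset
#'   from the 5' LTR terminus (48 nt), and the tolerance.
#' @param min_core_score Minimum local-alignment score for the 5S similarity
#'   region.
#' @param min_core_len Minimum aligned length of the similarity region; the
#'   full core is ~70 bp but its extent beyond the A-Box..C-Box span is
#'   species-specific, hence a parameter.
#' @return A list of class `motif_config`.
#' @export
motif_config <- function(abox_seq = "GGATGCGATCATACC", ie_seq = "CGAGAG",
                         cbox_refs = cbox_references(), max_mm_abox = 2L,
                         max_mm_ie = 2L, cbox_assign_max_mm = 2L,
                         tata_seq = "TATAAA", tata_offset = 48L,
                         tata_tol = 5L, min_core_score = 40,
                         min_core_len = 40L) {
  stopifnot(nzchar(abox_seq), nzchar(ie_seq),
            all(nchar(cbox_refs) == 10L), length(cbox_refs) >= 1L)
  structure(as.list(environment()), class = "motif_config")
}

#' Classify a C-Box 10-mer against the reference variants
#'
#' Nearest reference motif by Hamming distance; farther than
#' `cbox_assign_max_mm` from every reference gives class `other`; an exact
#' tie between references gives `ambiguous`.
#'
#' @param seq10 A 10-mer.
#' @param cfg A [motif_config()].
#' @return List with `class` and `distance` (to the nearest reference).
#' @export
classify_cbox <- function(seq10, cfg = motif_config()) {
  if (nchar(seq10) != 10L) stop("C-Box sequence must be exactly 10 nt")
  d <- vapply(cfg$cbox_refs, hamming, integer(1), a = toupper(seq10))
  dmin <- min(d)
  if (dmin > cfg$cbox_assign_max_mm) {
    return(list(class = "other", distance = dmin))
  }
  hits <- names(d)[d == dmin]
  if (length(hits) > 1L) return(list(class = "ambiguous", distance = dmin))
  list(class = hits, distance = dmin)
}

# best approximate occurrence of `motif` in seq at starts within
# [from, to] (0-based); ties to the leftmost. Returns list(start, mm) or NULL.
.best_occurrence <- function(seq, motif, max_mm, from = 0L,
                             to = nchar(seq) - nchar(motif)) {
  m <- nchar(motif)
  if (to < from) return(NULL)
  starts <- from:to
  if (length(starts) == 0L) return(NULL)
  subs <- substring(seq, starts + 1L, starts + m)
  mm <- vapply(subs, hamming, integer(1), b = motif, USE.NAMES = FALSE)
  i <- which.min(mm)
  if (mm[i] > max_mm) return(NULL)
  list(start = starts[i], mm = mm[i])
}

#' Scan a sequence for the 5S promoter boxes
#'
#' Ordered search: the best approximate A-Box occurrence first, then the IE
#' downstream of it, then the C-Box as the best match (at most
#' `cbox_assign_max_mm` mismatches) to any reference variant downstream of
#' the IE. Absent boxes are data, not errors.
#'
#' @param seq DNA string (an LTR or a 5S gene).
#' @param cfg A [motif_config()].
#' @return A `promoter_annotation` list: `abox`, `ie`, `cbox` (intervals or
#'   `NULL`), `cbox_seq`, `cbox_class`, `cbox_distance`, `mot_ie`, `mot_c`.
#' @export
scan_boxes <- function(seq, cfg = motif_config()) {
  seq <- clean_dna(seq)
  ann <- list(abox = NULL, ie = NULL, cbox = NULL, cbox_seq = NA_character_,
              cbox_class = NA_character_, cbox_distance = NA_integer_,
              mot_ie = NA_character_, mot_c = NA_character_)
  class(ann) <- "promoter_annotation"
  a <- .best_occurrence(seq, cfg$abox_seq, cfg$max_mm_abox)
  if (!is.null(a)) {
    ann$abox <- interval(a$start, a$start + nchar(cfg$abox_seq))
  }
  ie_from <- if (is.null(ann$abox)) 0L else ann$abox$end
  e <- .best_occurrence(seq, cfg$ie_seq, cfg$max_mm_ie, from = ie_from)
  if (!is.null(e)) ann$ie <- interval(e$start, e$start + nchar(cfg$ie_seq))
  cb_from <- if (!is.null(ann$ie)) ann$ie$end else ie_from
  best <- NULL
  for (ref in cfg$cbox_refs) {
    h <- .best_occurrence(seq, ref, cfg$cbox_assign_max_mm, from = cb_from)
    if (!is.null(h) && (is.null(best) || h$mm < best$mm)) best <- h
  }
  if (!is.null(best)) {
    ann$cbox <- interval(best$start, best$start + 10L)
    ann$cbox_seq <- iv_seq(seq, ann$cbox)
    cls <- classify_cbox(ann$cbox_seq, cfg)
    ann$cbox_class <- cls$class
    ann$cbox_distance <- cls$distance
  }
  mot <- extract_motifs(seq, ann)
  ann$mot_ie <- mot$mot_ie
  ann$mot_c <- mot$mot_c
  ann
}

#' Extract the MotIE and MotC polymorphic spacer motifs
#'
#' MotIE is the 4 nt immediately preceding the IE start; MotC the 5 nt
#' immediately preceding the C-Box start. A motif is `NA` when its bounding
#' boxes are absent or closer than the motif length (degenerate spacing,
#' warned).
#'
#' @param seq The annotated sequence.
#' @param ann A `promoter_annotation` from [scan_boxes()].
#' @return List with `mot_ie` (4 nt or `NA`) and `mot_c` (5 nt or `NA`).
#' @export
extract_motifs <- function(seq, ann) {
  mot_ie <- NA_character_; mot_c <- NA_character_
  if (!is.null(ann$ie) && !is.null(ann$abox)) {
    if (ann$ie$start - ann$abox$end >= 4L) {
      mot_ie <- substr(seq, ann$ie$start - 3L, ann$ie$start)
    } else {
      warning("A-Box/IE gap shorter than 4 nt; MotIE undefined")
    }
  }
  if (!is.null(ann$cbox) && !is.null(ann$ie)) {
    if (ann$cbox$start - ann$ie$end >= 5L) {
      mot_c <- substr(seq, ann$cbox$start - 4L, ann$cbox$start)
    } else {
      warning("IE/C-Box gap shorter than 5 nt; MotC undefined")
    }
  }
  list(mot_ie = mot_ie, mot_c = mot_c)
}

#' Locate the 5S-derived similarity region within an LTR
#'
#' Best local alignment of the LTR against the 5S rRNA gene; `NULL` when the
#' score falls below `min_core_score` or the aligned LTR span is shorter than
#' `min_core_len`. The relative midpoint is the center of the LTR span as a
#' fraction of the LTR length.
#'
#' @param ltr LTR DNA string.
#' @param five_s_gene 5S gene DNA string.
#' @param cfg A [motif_config()].
#' @return List with `ltr_span`, `gene_span` ([interval()]s), `identity_pct`,
#'   `relative_midpoint`; or `NULL`.
#' @export
locate_similarity_region <- function(ltr, five_s_gene, cfg = motif_config()) {
  aln <- local_align(ltr, five_s_gene, min_score = cfg$min_core_score)
  if (is.null(aln)) return(NULL)
  if (iv_length(aln$span_a) < cfg$min_core_len) return(NULL)
  list(ltr_span = aln$span_a, gene_span = aln$span_b,
       identity_pct = aln$identity_pct,
       relative_midpoint = (aln$span_a$start + aln$span_a$end) /
         (2 * nchar(ltr)))
}

#' Classify a detected element as Cassandra, Cassandra-like TRIM, or other
#'
#' Cassandra: either LTR yields a 5S similarity region passing the
#' thresholds. Cassandra-like TRIM: no similarity region, but the TATA box
#' occurs at `tata_offset` +/- `tata_tol` from the 5' LTR start. Otherwise:
#' other TRIM. When both LTRs yield a region the 5' one is primary.
#'
#' @param cand One candidate row from [find_ltr_pairs()].
#' @param seq The contig string the candidate lives on.
#' @param five_s_gene The species 5S rRNA gene string.
#' @param cfg A [motif_config()].
#' @return List with `label`, `evidence` ("similarity_region", "tata_box" or
#'   "none"), `core` (primary similarity region or `NULL`), `core3` (3' LTR
#'   region or `NULL`), and `tata_offset` (observed, or `NA`).
#' @export
classify_element <- function(cand, seq, five_s_gene, cfg = motif_config()) {
  ltr5 <- substr(seq, cand$ltr5_start + 1L, cand$ltr5_end)
  ltr3 <- substr(seq, cand$ltr3_start + 1L, cand$ltr3_end)
  r5 <- locate_similarity_region(ltr5, five_s_gene, cfg)
  r3 <- locate_similarity_region(ltr3, five_s_gene, cfg)
  if (!is.null(r5) || !is.null(r3)) {
    primary <- if (!is.null(r5)) r5 else r3
    return(list(label = "cassandra", evidence = "similarity_region",
                core = primary, core3 = r3, tata_offset = NA_integer_))
  }
  lo <- max(0L, cfg$tata_offset - cfg$tata_tol)
  hi <- min(nchar(ltr5) - nchar(cfg$tata_seq), cfg$tata_offset + cfg$tata_tol)
  tata <- if (hi >= lo) .best_occurrence(ltr5, cfg$tata_seq, 0L, lo, hi)
          else NULL
  if (!is.null(tata)) {
    return(list(label = "cassandra_like_trim", evidence = "tata_box",
                core = NULL, core3 = NULL, tata_offset = tata$start))
  }
  list(label = "other_trim", evidence = "none", core = NULL, core3 = NULL,
       tata_offset = NA_integer_)
}

#' Annotate all detected candidates on a contig
#'
#' Runs [classify_element()] and [scan_boxes()] (on the 5' LTR) for every
#' candidate and returns one summary row per element.
#'
#' @param cands Candidate data frame from [find_ltr_pairs()].
#' @param seq Contig string.
#' @param five_s_gene Species 5S gene string.
#' @param cfg A [motif_config()].
#' @return Data frame: element id, label, evidence, cbox fields, MotIE/MotC,
#'   core span and identity, relative midpoint.
#' @export
annotate_elements <- function(cands, seq, five_s_gene, cfg = motif_config()) {
  out <- NULL
  for (i in seq_len(nrow(cands))) {
    cand <- cands[i, ]
    cls <- classify_element(cand, seq, five_s_gene, cfg)
    ltr5 <- substr(seq, cand$ltr5_start + 1L, cand$ltr5_end)
    ann <- suppressWarnings(scan_boxes(ltr5, cfg))
    out <- rbind(out, data.frame(
      element_id = sprintf("%s_te%03d", cand$contig_id, i),
      contig_id = cand$contig_id,
      element_start = cand$element_start, element_end = cand$element_end,
      label = cls$label, evidence = cls$evidence,
      cbox_seq = ann$cbox_seq, cbox_class = ann$cbox_class,
      cbox_distance = ann$cbox_distance,
      mot_ie = ann$mot_ie, mot_c = ann$mot_c,
      core_start = if (is.null(cls$core)) NA_integer_ else cls$core$ltr_span$start,
      core_end = if (is.null(cls$core)) NA_integer_ else cls$core$ltr_span$end,
      core_identity = if (is.null(cls$core)) NA_real_ else cls$core$identity_pct,
      relative_midpoint = if (is.null(cls$core)) NA_real_
                          else cls$core$relative_midpoint,
      tata_offset = cls$tata_offset,
      stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- data.frame(element_id = character(), contig_id = character(),
                      element_start = integer(), element_end = integer(),
                      label = character(), evidence = character(),
                      cbox_seq = character(), cbox_class = character(),
                      cbox_distance = integer(), mot_ie = character(),
                      mot_c = character(), core_start = integer(),
                      core_end = integer(), core_identity = numeric(),
                      relative_midpoint = numeric(), tata_offset = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Tally C-Box variant populations over annotated elements
#'
#' @param annotations Data frame from [annotate_elements()], or a list of
#'   `promoter_annotation` objects.
#' @return Named integer vector of counts per `cbox_class`; elements without
#'   a located C-Box are counted under `none`. Empty input gives an empty
#'   tally.
#' @export
tally_cbox_populations <- function(annotations) {
  if (is.data.frame(annotations)) {
    cls <- annotations$cbox_class
  } else {
    cls <- vapply(annotations, function(a) a$cbox_class, character(1))
  }
  if (length(cls) == 0L) return(integer(0))
  cls[is.na(cls)] <- "none"
  tab <- table(cls)
  setNames(as.integer(tab), names(tab))
}
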