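# Structure-based detection of candidate TRIM elements: two similar direct
# repeats (the LTRs) within TRIM length bounds, with PBS/PPT/TSD evidence.
# Replaces an LTR-Finder + manual-inspection screen; runs in "relaxed" mode
# by default (TSD and TG..CA are annotations, never filters).

#' Detector configuration
#'
#' Defaults encode the TRIM-specific screen: LTR length 30-500 bp, distance
#' between the LTRs (internal region) 30-2000 bp, LTR pairwise identity
#' 70% and above; PBS/PPT are looked for but nothing is filtered on motifs,
#' TG..CA architecture or TSDs unless the strict flags are set.
#'
#' @param min_ltr,max_ltr LTR length bounds in bp.
#' @param min_between,max_between Internal-region length bounds in bp.
#' @param min_ltr_identity Minimum 5'/3' LTR percent identity (inclusive).
#' @param seed_word Exact-match word size used for seeding.
#' @param tsd_min,tsd_max TSD length bounds for annotation.
#' @param require_tg_ca If `TRUE`, only elements starting TG and ending CA
#'   are kept (strict mode).
#' @param require_tsd If `TRUE`, only elements with a detected TSD are kept
#'   (strict mode).
#' @param pbs_motif,pbs_max_mm PBS reference motif and mismatch allowance.
#' @param ppt_window,ppt_min_purines PPT window and purine threshold.
#' @param motif_search_window How far inside the internal region (nt) to look
#'   for PBS/PPT.
#' @param xdrop Score drop terminating the seed-extension phase.
#' @param chain_gap Maximum gap (bp) between seed words merged into one
#'   repeat segment.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(min_ltr = 30L, max_ltr = 500L, min_between = 30L,
                            max_between = 2000L, min_ltr_identity = 70,
                            seed_word = 12L, tsd_min = 4L, tsd_max = 6L,
                            require_tg_ca = FALSE, require_tsd = FALSE,
                            pbs_motif = "TGGTATCAGAGC", pbs_max_mm = 2L,
                            ppt_window = 10L, ppt_min_purines = 8L,
                            motif_search_window = 20L,
                            xdrop = 10, chain_gap = 50L) {
  stopifnot(min_ltr <= max_ltr, min_between <= max_between,
            min_ltr_identity > 0, min_ltr_identity <= 100)
  structure(as.list(environment()), class = "detector_config")
}

.empty_candidates <- function() {
  data.frame(contig_id = character(), element_start = integer(),
             element_end = integer(), ltr5_start = integer(),
             ltr5_end = integer(), ltr3_start = integer(),
             ltr3_end = integer(), internal_start = integer(),
             internal_end = integer(), ltr_identity_pct = numeric(),
             aln_score = numeric(), tsd = character(), pbs_offset = integer(), pbs_mm = integer(),
             ppt_start = integer(), ppt_purines = integer(),
             tg_ca = logical(), stringsAsFactors = FALSE)
}

# Ungapped x-drop extension. Compares seq[a + step*t] vs seq[b + step*t]
# for t = 1, 2, ... (0-based a, b are the last already-included positions);
# returns the number of additional positions at the best-scoring point.
.xdrop_extend <- function(chars, a, b, step, xdrop, lo, hi) {
  best <- 0; score <- 0; best_t <- 0L; t <- 0L
  repeat {
    t <- t + 1L
    pa <- a + step * t; pb <- b + step * t
    if (pa < lo || pb < lo || pa > hi || pb > hi) break
    score <- score + if (chars[pa + 1L] == chars[pb + 1L]) 1 else -2
    if (score > best) { best <- score; best_t <- t }
    if (score < best - xdrop) break
  }
  best_t
}

# Seed-word pairs grouped by diagonal into repeat segments.
.seed_segments <- function(seq, cfg) {
  L <- nchar(seq)
  k <- cfg$seed_word
  if (L < 2L * k) return(NULL)
  starts <- 0:(L - k)
  words <- substring(seq, starts + 1L, starts + k)
  grp <- split(starts, words)
  grp <- grp[lengths(grp) >= 2L]
  dmin <- cfg$min_ltr + cfg$min_between
  dmax <- cfg$max_ltr + cfg$max_between
  seeds_i <- integer(0); seeds_d <- integer(0)
  for (p in grp) {
    if (length(p) > 50L) next # hyper-repetitive word; segments emerge anyway
    cmb <- utils::combn(p, 2L)
    d <- cmb[2L, ] - cmb[1L, ]
    ok <- d >= dmin & d <= dmax
    seeds_i <- c(seeds_i, cmb[1L, ok])
    seeds_d <- c(seeds_d, d[ok])
  }
  if (length(seeds_i) == 0L) return(NULL)
  segs <- NULL
  for (d in unique(seeds_d)) {
    i <- sort(seeds_i[seeds_d == d])
    brk <- c(0L, which(diff(i) > cfg$chain_gap), length(i))
    for (j in seq_len(length(brk) - 1L)) {
      run <- i[(brk[j] + 1L):brk[j + 1L]]
      segs <- rbind(segs, data.frame(s = run[1L],
                                     e = run[length(run)] + k, d = d))
    }
  }
  segs
}

#' Find candidate two-LTR elements by direct-repeat structure
#'
#' Seeds exact word matches between positions at an admissible distance,
#' chains them into repeat segments, extends segment boundaries by x-drop
#' comparison of the two copies, scores the refined copies by global
#' alignment, and keeps candidates meeting all [detector_config()] bounds.
#' Overlapping candidates are resolved by highest LTR identity, then longer
#' element, then leftmost start. Detection is single-strand.
#'
#' @param seq Contig DNA string.
#' @param cfg A [detector_config()].
#' @param contig_id Id recorded in the output.
#' @return Candidate data frame (0-based half-open coordinates), one row per
#'   element: element/LTR/internal intervals, `ltr_identity_pct`, `tsd`,
#'   `pbs_offset`/`pbs_mm`, `ppt_start`/`ppt_purines`, `tg_ca`. Empty (never
#'   an error) when nothing qualifies.
#' @export
find_ltr_pairs <- function(seq, cfg = detector_config(),
                           contig_id = "contig_1") {
  seq <- clean_dna(seq)
  L <- nchar(seq)
  if (L < 2L * cfg$min_ltr + cfg$min_between) return(.empty_candidates())
  segs <- .seed_segments(seq, cfg)
  if (is.null(segs)) return(.empty_candidates())
  chars <- strsplit(seq, "")[[1]]
  out <- .empty_candidates()
  for (r in seq_len(nrow(segs))) {
    s <- segs$s[r]; e <- segs$e[r]; d <- segs$d[r]
    # extend left from position s and s+d, right from e-1 and e+d-1
    ext_l <- .xdrop_extend(chars, s, s + d, -1L, cfg$xdrop, 0L, L - 1L)
    ext_r <- .xdrop_extend(chars, e - 1L, e + d - 1L, +1L, cfg$xdrop, 0L,
                           L - 1L)
    ls <- s - ext_l
    le <- e + ext_r
    ltr_len <- le - ls
    gap <- d - ltr_len
    if (ltr_len < cfg$min_ltr || ltr_len > cfg$max_ltr) next
    if (gap < cfg$min_between || gap > cfg$max_between) next
    if (le + d > L) next
    copy1 <- substr(seq, ls + 1L, le)
    copy2 <- substr(seq, ls + d + 1L, le + d)
    aln <- global_identity(copy1, copy2)
    if (aln$identity_pct < cfg$min_ltr_identity) next
    out <- rbind(out, data.frame(
      contig_id = contig_id, element_start = ls, element_end = le + d,
      ltr5_start = ls, ltr5_end = le, ltr3_start = ls + d, ltr3_end = le + d,
      internal_start = le, internal_end = ls + d,
      ltr_identity_pct = aln$identity_pct, aln_score = aln$score,
      tsd = NA_character_,
      pbs_offset = NA_integer_, pbs_mm = NA_integer_,
      ppt_start = NA_integer_, ppt_purines = NA_integer_,
      tg_ca = NA, stringsAsFactors = FALSE))
  }
  if (nrow(out) == 0L) return(out)
  out <- .resolve_overlaps(out)
  # motif and TSD evidence (annotations; filters only in strict mode)
  for (i in seq_len(nrow(out))) {
    cand <- out[i, ]
    tsd <- detect_tsd(seq, cand, cfg)
    out$tsd[i] <- if (is.null(tsd)) NA_character_ else tsd
    pbs <- detect_pbs(seq, cand, cfg)
    if (!is.null(pbs)) { out$pbs_offset[i] <- pbs$offset
                         out$pbs_mm[i] <- pbs$mismatches }
    ppt <- detect_ppt(seq, cand, cfg)
    if (!is.null(ppt)) { out$ppt_start[i] <- ppt$start
                         out$ppt_purines[i] <- ppt$purines }
    out$tg_ca[i] <- substr(seq, cand$element_start + 1L,
                           cand$element_start + 2L) == "TG" &&
      substr(seq, cand$element_end - 1L, cand$element_end) == "CA"
  }
  if (cfg$require_tg_ca) out <- out[out$tg_ca, , drop = FALSE]
  if (cfg$require_tsd) out <- out[!is.na(out$tsd), , drop = FALSE]
  out <- out[order(out$element_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Overlap resolution. Candidates are accepted greedily by LTR-pair
# alignment score (length-weighted identity), ties by identity then
# leftmost; a candidate overlapping an already-accepted element span by 20
# bp or more is dropped. Score ordering (rather than identity-first with
# longer-element tie-breaks) is essential when distinct elements share an
# identical mid-LTR core: the cross-element core pairing has the same 100%
# identity but a far lower score than the true full-LTR pair.
.resolve_overlaps <- function(cands, min_shared_bp = 20L) {
  ord <- order(-cands$aln_score, -cands$ltr_identity_pct,
               cands$element_start)
  keep <- logical(nrow(cands))
  for (i in ord) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- min(cands$element_end[i], cands$element_end[j]) -
        max(cands$element_start[i], cands$element_start[j])
      if (ov >= min_shared_bp) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  cands[keep, , drop = FALSE]
}

#' Detect a target-site duplication around a candidate
#'
#' Longest identical duplication of the flanks immediately outside the
#' element, with length between `tsd_min` and `tsd_max`.
#'
#' @param seq Contig string.
#' @param cand One candidate row from [find_ltr_pairs()].
#' @param cfg A [detector_config()].
#' @return The TSD string, or `NULL`.
#' @export
detect_tsd <- function(seq, cand, cfg = detector_config()) {
  es <- cand$element_start; ee <- cand$element_end
  for (len in seq(cfg$tsd_max, cfg$tsd_min)) {
    if (es - len < 0L || ee + len > nchar(seq)) next
    left <- substr(seq, es - len + 1L, es)
    right <- substr(seq, ee + 1L, ee + len)
    if (left == right) return(left)
  }
  NULL
}

#' Detect the primer binding site downstream of the 5' LTR
#'
#' Best match to the configured PBS motif within `motif_search_window` nt 3'
#' of the 5' LTR end, at most `pbs_max_mm` mismatches; ties go to the
#' smallest offset.
#'
#' @inheritParams detect_tsd
#' @return List with `offset` (nt after the 5' LTR) and `mismatches`, or
#'   `NULL`.
#' @export
detect_pbs <- function(seq, cand, cfg = detector_config()) {
  m <- nchar(cfg$pbs_motif)
  best <- NULL
  for (off in 0:cfg$motif_search_window) {
    s <- cand$ltr5_end + off
    if (s + m > cand$ltr3_start) break
    mm <- hamming(substr(seq, s + 1L, s + m), cfg$pbs_motif)
    if (mm <= cfg$pbs_max_mm && (is.null(best) || mm < best$mismatches)) {
      best <- list(offset = off, mismatches = mm)
    }
  }
  best
}

#' Detect the polypurine tract upstream of the 3' LTR
#'
#' First window of `ppt_window` nt, walking 5' from the 3' LTR start (the
#' PPT abuts the LTR it primes), within `motif_search_window` nt, that
#' contains at least `ppt_min_purines` purines.
#'
#' @inheritParams detect_tsd
#' @return List with `start` (0-based contig coordinate) and `purines`, or
#'   `NULL`.
#' @export
detect_ppt <- function(seq, cand, cfg = detector_config()) {
  w <- cfg$ppt_window
  lo <- max(cand$internal_start, cand$ltr3_start - cfg$motif_search_window)
  hi <- cand$ltr3_start - w
  if (hi < lo) return(NULL)
  for (s in hi:lo) {
    win <- substr(seq, s + 1L, s + w)
    purines <- sum(strsplit(win, "")[[1]] %in% c("A", "G"))
    if (purines >= cfg$ppt_min_purines) {
      return(list(start = s, purines = purines))
    }
  }
  NULL
}

#' Write detector candidates as GFF3
#'
#' One `LTR_retrotransposon` feature per candidate with
#' `long_terminal_repeat`, `primer_binding_site` and `RR_tract` children.
#'
#' @param cands Candidate data frame from [find_ltr_pairs()].
#' @param path Output GFF3 file.
#' @param cfg The [detector_config()] used (for motif lengths).
#' @export
candidates_to_gff3 <- function(cands, path, cfg = detector_config()) {
  rows <- NULL
  for (i in seq_len(nrow(cands))) {
    c0 <- cands[i, ]
    eid <- sprintf("te%03d", i)
    rows <- rbind(rows,
      data.frame(contig_id = c0$contig_id, type = "LTR_retrotransposon",
                 start = c0$element_start, end = c0$element_end,
                 attributes = sprintf("ID=%s;ltr_identity=%.1f", eid,
                                      c0$ltr_identity_pct)),
      data.frame(contig_id = c0$contig_id, type = "long_terminal_repeat",
                 start = c(c0$ltr5_start, c0$ltr3_start),
                 end = c(c0$ltr5_end, c0$ltr3_end),
                 attributes = sprintf("Parent=%s", eid)))
    if (!is.na(c0$pbs_offset)) {
      s <- c0$ltr5_end + c0$pbs_offset
      rows <- rbind(rows, data.frame(
        contig_id = c0$contig_id, type = "primer_binding_site", start = s,
        end = s + nchar(cfg$pbs_motif),
        attributes = sprintf("Parent=%s;mismatches=%d", eid, c0$pbs_mm)))
    }
    if (!is.na(c0$ppt_start)) {
      rows <- rbind(rows, data.frame(
        contig_id = c0$contig_id, type = "RR_tract", start = c0$ppt_start,
        end = c0$ppt_start + cfg$ppt_window,
        attributes = sprintf("Parent=%s;purines=%d", eid, c0$ppt_purines)))
    }
  }
  if (is.null(rows)) rows <- data.frame(contig_id = character(),
                                        type = character(),
                                        start = integer(), end = integer(),
                                        attributes = character())
  write_gff3(rows, path)
}
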