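# Windowed all-against-all dotplots: window matches (k = 12, allowed
# mismatches n = 3) and longest-common-substring shading.

#' Dotplot configuration
#'
#' @param k Window length (default 12).
#' @param n Allowed mismatches per window (default 3); must satisfy
#'   `0 <= n < k`.
#' @return A list of class `dotplot_config`.
#' @export
dotplot_config <- function(k = 12L, n = 3L) {
  stopifnot(n >= 0L, n < k)
  structure(list(k = as.integer(k), n = as.integer(n)),
            class = "dotplot_config")
}

#' All window matches between two sequences
#'
#' Every pair of 0-based window starts `(i, j)` where the k-mers
#' `a[i, i+k)` and `b[j, j+k)` differ in at most `n` positions. Computed per
#' diagonal with running mismatch sums.
#'
#' @param a,b DNA strings.
#' @param cfg A [dotplot_config()].
#' @return Two-column integer matrix (`i`, `j`), possibly empty. Sequences
#'   shorter than `k` give an empty set with a warning.
#' @export
window_matches <- function(a, b, cfg = dotplot_config()) {
  k <- cfg$k
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  if (nchar(a) < k || nchar(b) < k) {
    warning("sequence shorter than window length k = ", k)
    return(empty)
  }
  av <- charToRaw(a); bv <- charToRaw(b)
  la <- length(av); lb <- length(bv)
  out_i <- integer(0); out_j <- integer(0)
  for (d in (-(la - k)):(lb - k)) {
    # positions along the diagonal: a-index t, b-index t + d (0-based)
    t0 <- max(0L, -d)
    t1 <- min(la - 1L, lb - 1L - d)
    len <- t1 - t0 + 1L
    if (len < k) next
    mism <- as.integer(av[(t0 + 1L):(t1 + 1L)] != bv[(t0 + d + 1L):(t1 + d + 1L)])
    cs <- c(0L, cumsum(mism))
    wm <- cs[(k + 1L):(len + 1L)] - cs[1:(len - k + 1L)]
    hit <- which(wm <= cfg$n) - 1L
    if (length(hit)) {
      out_i <- c(out_i, t0 + hit)
      out_j <- c(out_j, t0 + d + hit)
    }
  }
  cbind(i = out_i, j = out_j)
}

#' Length of the longest common exact substring
#'
#' Row-vectorised dynamic programming.
#'
#' @param a,b DNA strings.
#' @return Integer length (0 when nothing is shared).
#' @export
longest_common_substring <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) return(0L)
  av <- charToRaw(a); bv <- charToRaw(b)
  prev <- integer(length(bv))
  best <- 0L
  for (i in seq_along(av)) {
    match <- bv == av[i]
    cur <- ifelse(match, c(0L, prev[-length(prev)]) + 1L, 0L)
    best <- max(best, max(cur))
    prev <- cur
  }
  as.integer(best)
}

#' All-against-all dotplot grid
#'
#' Computes window matches and the shading metric (longest common substring
#' length normalised by the shorter sequence length) for every ordered pair.
#' Rendering, if any, is done downstream from the returned coordinates and
#' never affects the results.
#'
#' @param seqs Named character vector.
#' @param cfg A [dotplot_config()].
#' @return List with `pairs` (data frame: `id_a`, `id_b`, `n_matches`,
#'   `shade_metric`) and `matches` (named list of match matrices keyed
#'   `"id_a|id_b"`).
#' @export
all_vs_all <- function(seqs, cfg = dotplot_config()) {
  ids <- names(seqs)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  pairs <- NULL
  matches <- list()
  for (ia in ids) for (ib in ids) {
    m <- window_matches(seqs[[ia]], seqs[[ib]], cfg)
    shade <- longest_common_substring(seqs[[ia]], seqs[[ib]]) /
      min(nchar(seqs[[ia]]), nchar(seqs[[ib]]))
    matches[[paste(ia, ib, sep = "|")]] <- m
    pairs <- rbind(pairs, data.frame(id_a = ia, id_b = ib,
                                     n_matches = nrow(m),
                                     shade_metric = shade,
                                     stringsAsFactors = FALSE))
  }
  list(pairs = pairs, matches = matches)
}

#' Write dotplot match coordinates as TSV
#'
#' @param result An [all_vs_all()] result.
#' @param path Output file.
#' @export
dotplot_to_tsv <- function(result, path) {
  rows <- NULL
  for (key in names(result$matches)) {
    m <- result$matches[[key]]
    ids <- strsplit(key, "|", fixed = TRUE)[[1]]
    if (nrow(m) == 0L) next
    rows <- rbind(rows, data.frame(id_a = ids[1], id_b = ids[2],
                                   i = m[, "i"], j = m[, "j"],
                                   stringsAsFactors = FALSE))
  }
  if (is.null(rows)) {
    rows <- data.frame(id_a = character(), id_b = character(),
                       i = integer(), j = integer())
  }
  write_tsv(rows, path)
}
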