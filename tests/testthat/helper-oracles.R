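# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (no Biostrings, no seeding/chaining) so they can serve as
# ground truth for the operations they check.

# Needleman-Wunsch with linear gap cost, small-input only. Returns score and
# the percent identity of the traceback alignment (matched columns over
# columns with at least one residue, terminal overhangs excluded).
oracle_global_align <- function(a, b, match = 1, mismatch = -2, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(
      S[i, j] + if (av[i] == bv[j]) match else mismatch,
      S[i, j + 1] + gap,
      S[i + 1, j] + gap)
  }
  # traceback
  i <- n; j <- m; ra <- character(0); rb <- character(0)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1
    }
  }
  res <- which(ra != "-" & rb != "-")
  ident <- if (length(res) == 0) 0 else {
    keep <- seq(res[1], res[length(res)])
    kra <- ra[keep]; krb <- rb[keep]
    100 * sum(kra == krb & kra != "-") / sum(kra != "-" | krb != "-")
  }
  list(score = S[n + 1, m + 1], identity_pct = ident)
}

# all (i, j) window pairs with <= n mismatches, by direct double loop
oracle_window_matches <- function(a, b, k, n) {
  out <- NULL
  for (i in 0:(nchar(a) - k)) for (j in 0:(nchar(b) - k)) {
    mm <- sum(strsplit(substr(a, i + 1, i + k), "")[[1]] !=
                strsplit(substr(b, j + 1, j + k), "")[[1]])
    if (mm <= n) out <- rbind(out, c(i = i, j = j))
  }
  if (is.null(out)) matrix(integer(0), ncol = 2,
                           dimnames = list(NULL, c("i", "j"))) else out
}

# longest common substring by substring-set intersection, longest first
oracle_lcs <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  for (len in seq(min(la, lb), 1)) {
    sa <- unique(substring(a, 1:(la - len + 1), len:la))
    sb <- unique(substring(b, 1:(lb - len + 1), len:lb))
    if (length(intersect(sa, sb)) > 0) return(len)
  }
  0L
}

# Exhaustive direct-repeat pair oracle. Enumerates EVERY (start, ltr_len,
# gap) triple within the given bounds and scores the two copies by ungapped
# identity; returns all admissible pairs. Vectorised over the diagonal but
# literally exhaustive in the triple space.
oracle_repeat_pairs <- function(seq, min_ltr, max_ltr, min_between,
                                max_between, min_identity = 70) {
  L <- nchar(seq)
  v <- charToRaw(seq)
  out <- NULL
  for (d in (min_ltr + min_between):min(max_ltr + max_between, L - min_ltr)) {
    nn <- L - d
    if (nn < min_ltr) next
    eq <- as.integer(v[1:nn] == v[(d + 1):(d + nn)])
    cs <- c(0L, cumsum(eq))
    for (len in min_ltr:min(max_ltr, nn)) {
      gap <- d - len
      if (gap < min_between || gap > max_between) next
      n_win <- nn - len + 1L
      if (n_win < 1L) next
      matches <- cs[(len + 1L):(len + n_win)] - cs[1:n_win]
      ident <- 100 * matches / len
      hit <- which(ident >= min_identity)
      if (length(hit)) {
        out <- rbind(out, data.frame(start = hit - 1L, ltr_len = len,
                                     gap = gap,
                                     identity = ident[hit],
                                     score = matches[hit] -
                                       2 * (len - matches[hit])))
      }
    }
  }
  out
}

# Sufficient-condition scan at full TRIM bounds: any admissible pair with
# >= `min_identity` ungapped identity implies some `probe`-length window on
# a diagonal in [min_ltr + min_between, max_ltr + max_between] reaching
# >= `min_identity`. Returns TRUE when such signal exists.
oracle_repeat_signal <- function(seq, min_ltr = 30, max_ltr = 500,
                                 min_between = 30, max_between = 2000,
                                 min_identity = 70, probe = 30) {
  L <- nchar(seq)
  v <- charToRaw(seq)
  for (d in (min_ltr + min_between):min(max_ltr + max_between, L - probe)) {
    nn <- L - d
    if (nn < probe) next
    eq <- as.integer(v[1:nn] == v[(d + 1):(d + nn)])
    cs <- c(0L, cumsum(eq))
    wm <- cs[(probe + 1L):(nn + 1L)] - cs[1:(nn - probe + 1L)]
    if (any(100 * wm / probe >= min_identity)) return(TRUE)
  }
  FALSE
}

# enumerate the best local-alignment score between two short strings by
# scoring every (substring of a) x (substring of b) ungapped overlay plus
# the package-independent global DP on the substrings is too costly; for
# the planted-substring cases used in tests an ungapped scan is exact.
oracle_best_ungapped_local <- function(a, b, match = 1, mismatch = -2) {
  best <- 0
  la <- nchar(a); lb <- nchar(b)
  va <- charToRaw(a); vb <- charToRaw(b)
  for (d in (-(la - 1)):(lb - 1)) {
    t0 <- max(0L, -d); t1 <- min(la - 1L, lb - 1L - d)
    if (t1 < t0) next
    sc <- ifelse(va[(t0 + 1):(t1 + 1)] == vb[(t0 + d + 1):(t1 + d + 1)],
                 match, mismatch)
    # maximal subarray = best ungapped local score on this diagonal
    cur <- 0
    for (x in sc) { cur <- max(0, cur + x); best <- max(best, cur) }
  }
  best
}
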