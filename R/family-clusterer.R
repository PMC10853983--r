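# Grouping of elements into families at the inclusive 70% pairwise-identity
# threshold (single linkage), splitting families into indel-defined
# variants, and per-family length/identity statistics.

#' All-pairs global identity matrix
#'
#' @param seqs Named character vector of sequences.
#' @param scoring An [aln_scoring()].
#' @return Symmetric matrix of percent identities with 100 on the diagonal,
#'   dimnames = sequence ids.
#' @export
identity_matrix <- function(seqs, scoring = aln_scoring()) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(m)
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    id <- global_identity(seqs[[i]], seqs[[j]], scoring)$identity_pct
    m[i, j] <- id
    m[j, i] <- id
  }
  m
}

#' Cluster elements into families by single linkage
#'
#' Families are the connected components of the graph whose edges join pairs
#' with identity at or above the threshold ("70% and above" is inclusive).
#' Single linkage keeps indel-bearing variants inside one family despite
#' depressed mean identity. Family ids are assigned by descending size, ties
#' by lexicographically smallest member.
#'
#' @param m Identity matrix from [identity_matrix()].
#' @param threshold Inclusive percent-identity threshold (default 70).
#' @return List of families; each family is a list with `family_id` and
#'   `member_ids` (sorted).
#' @export
cluster_families <- function(m, threshold = 70) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  ids <- rownames(m)
  adj <- m >= threshold
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  groups <- split(ids, comp)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups),
               vapply(groups, function(g) g[1L], character(1)))
  groups <- groups[ord]
  lapply(seq_along(groups), function(i) {
    list(family_id = sprintf("family_%02d", i), member_ids = groups[[i]])
  })
}

#' Per-family length and identity statistics
#'
#' Medians of full/LTR/internal lengths over the members (even counts use
#' the mean-of-middle rule, i.e. `stats::median`), and mean pairwise percent
#' identity over member pairs for full, LTR and internal sequences.
#' Single-member families report `NA` identities.
#'
#' @param family A family from [cluster_families()].
#' @param elements Named list, one entry per element id, each a list with
#'   `full`, `ltr`, `internal` DNA strings.
#' @param scoring An [aln_scoring()].
#' @return One-row data frame of family statistics.
#' @export
family_stats <- function(family, elements, scoring = aln_scoring()) {
  mem <- elements[family$member_ids]
  lens <- function(part) vapply(mem, function(e) nchar(e[[part]]), numeric(1))
  mean_pairwise <- function(part) {
    n <- length(mem)
    if (n < 2L) return(NA_real_)
    vals <- c()
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      vals <- c(vals, global_identity(mem[[i]][[part]], mem[[j]][[part]],
                                      scoring)$identity_pct)
    }
    mean(vals)
  }
  data.frame(
    family_id = family$family_id, n_members = length(mem),
    median_full_length = median(lens("full")),
    median_ltr_length = median(lens("ltr")),
    median_internal_length = median(lens("internal")),
    overall_identity_pct = mean_pairwise("full"),
    ltr_identity_pct = mean_pairwise("ltr"),
    internal_identity_pct = mean_pairwise("internal"),
    stringsAsFactors = FALSE)
}

# indel events of one aligned pair: internal gap runs >= min_indel, as a
# data frame of (type, reference position, length)
.indel_events <- function(ref, qry, min_indel = 10L,
                          scoring = aln_scoring()) {
  aln <- global_identity(ref, qry, scoring)
  a <- strsplit(aln$aligned_a, "")[[1]]
  b <- strsplit(aln$aligned_b, "")[[1]]
  # trim terminal-overhang columns; internal events only
  both <- which(a != "-" & b != "-")
  empty <- data.frame(type = character(), pos = integer(), len = integer())
  if (length(both) == 0L) return(empty)
  keep <- seq(both[1L], both[length(both)])
  a <- a[keep]; b <- b[keep]
  refpos <- cumsum(a != "-") # reference coordinate per column
  gaps <- (a == "-") | (b == "-")
  runs <- rle(gaps)
  idx <- cumsum(runs$lengths)
  out <- empty
  for (r in which(runs$values & runs$lengths >= min_indel)) {
    col0 <- idx[r] - runs$lengths[r] + 1L
    out <- rbind(out, data.frame(
      type = if (a[col0] == "-") "ins" else "del",
      pos = refpos[col0], len = runs$lengths[r]))
  }
  out
}

# two event lists describe the same variant when they pair up one-to-one
# with equal types and positions/lengths within tolerance
.events_compatible <- function(x, y, pos_tol, len_tol) {
  if (nrow(x) != nrow(y)) return(FALSE)
  if (nrow(x) == 0L) return(TRUE)
  all(x$type == y$type) &&
    all(abs(x$pos - y$pos) <= pos_tol) &&
    all(abs(x$len - y$len) <= len_tol)
}

#' Split a family into indel-defined variants
#'
#' Each member is aligned to the family's longest member; internal gap
#' events of at least `min_indel` bp form the member's indel signature.
#' Members whose signatures match event-for-event (same event types,
#' positions within `pos_tol`, lengths within `len_tol` — alignment
#' ambiguity shifts identical planted indels by a few bases) are grouped
#' into one variant; members with no qualifying events form the base
#' variant.
#'
#' @param family A family from [cluster_families()].
#' @param seqs Named character vector holding the member sequences (full or
#'   LTR, as desired).
#' @param min_indel Minimum indel size in bp (default 10).
#' @param pos_tol,len_tol Matching tolerances in bp (defaults 20 and 10).
#' @param scoring An [aln_scoring()].
#' @return List of character vectors of member ids, one per variant, ordered
#'   by descending size then smallest member.
#' @export
split_variants <- function(family, seqs, min_indel = 10L, pos_tol = 20L,
                           len_tol = 10L, scoring = aln_scoring()) {
  mem <- family$member_ids
  if (length(mem) == 0L) return(list())
  ref_id <- mem[which.max(nchar(seqs[mem]))]
  events <- lapply(mem, function(id) {
    if (id == ref_id) {
      data.frame(type = character(), pos = integer(), len = integer())
    } else .indel_events(seqs[[ref_id]], seqs[[id]], min_indel, scoring)
  })
  n <- length(mem)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- .events_compatible(events[[i]], events[[j]], pos_tol,
                                    len_tol)
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  groups <- lapply(split(mem, comp), sort)
  ord <- order(-lengths(groups),
               vapply(groups, function(g) g[1L], character(1)))
  unname(groups[ord])
}
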