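# Pairwise and progressive alignment primitives. These back the probe
# search, read-overlap checks, distance computation and guide-tree stages.
# The dynamic programming core (Gotoh affine-gap, deterministic traceback
# preferring diagonal > up > left) lives in src/dp_align.cpp and operates on
# a precomputed column-score matrix, so the same engine serves residue
# against residue and profile against profile alignment.

#' Alignment scoring scheme
#'
#' Linear gap penalties are the default (`gap_extend` follows `gap_open`);
#' pass a smaller `gap_extend` for affine gaps. A substitution `matrix`
#' (e.g. BLOSUM62) overrides `match`/`mismatch`.
#'
#' @param match,mismatch scores for identical / differing residues
#' @param gap_open penalty for the first residue of a gap (<= 0)
#' @param gap_extend penalty for each further gap residue (<= 0)
#' @param matrix optional substitution matrix with residue dimnames
#' @return object of class `scoring_scheme`
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap_open = -2,
                           gap_extend = gap_open, matrix = NULL) {
  if (is.null(matrix) && mismatch > match)
    stop("mismatch score must not exceed match score")
  if (gap_open > 0 || gap_extend > 0) stop("gap penalties must be <= 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, matrix = matrix),
            class = "scoring_scheme")
}

#' @rdname scoring_scheme
#' @export
dna_scoring <- function(match = 1, mismatch = -1, gap_open = -2,
                        gap_extend = gap_open) {
  scoring_scheme(match, mismatch, gap_open, gap_extend)
}

#' @rdname scoring_scheme
#' @export
protein_scoring <- function(gap_open = -6, gap_extend = gap_open) {
  scoring_scheme(gap_open = gap_open, gap_extend = gap_extend,
                 matrix = blosum62())
}

blosum62_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_cache$m <- e$BLOSUM62
  }
  blosum62_cache$m
}

pair_score_matrix <- function(a_chars, b_chars, scoring) {
  if (!is.null(scoring$matrix)) {
    m <- scoring$matrix
    a2 <- ifelse(a_chars %in% rownames(m), a_chars, "X")
    b2 <- ifelse(b_chars %in% colnames(m), b_chars, "X")
    matrix(m[cbind(rep(a2, times = length(b2)),
                   rep(b2, each = length(a2)))],
           nrow = length(a2))
  } else {
    outer(a_chars, b_chars,
          function(x, y) ifelse(x == y, scoring$match, scoring$mismatch))
  }
}

aligned_strings <- function(a_chars, b_chars, a_idx, b_idx) {
  a_aln <- ifelse(a_idx == 0, "-", a_chars[pmax(a_idx, 1)])
  b_aln <- ifelse(b_idx == 0, "-", b_chars[pmax(b_idx, 1)])
  c(paste(a_aln, collapse = ""), paste(b_aln, collapse = ""))
}

new_alignment <- function(a_aln, b_aln, score, a_start, a_end, b_start, b_end) {
  structure(list(a = a_aln, b = b_aln, score = score,
                 a_start = a_start, a_end = a_end,
                 b_start = b_start, b_end = b_end),
            class = "mads_alignment")
}

#' @export
print.mads_alignment <- function(x, ...) {
  cat(sprintf("Alignment score %.4g  a[%d,%d)  b[%d,%d)\n",
              x$score, x$a_start, x$a_end, x$b_start, x$b_end))
  cat(" ", x$a, "\n ", x$b, "\n")
  invisible(x)
}

#' Global (Needleman-Wunsch) alignment
#'
#' Returns the optimal global alignment of two sequences under the given
#' scoring scheme. Traceback ties are broken deterministically (diagonal
#' over up over left). Coordinates are 0-based half-open.
#'
#' @param a,b sequences (single strings)
#' @param scoring a [scoring_scheme()]
#' @return an object of class `mads_alignment` with elements `a`, `b`
#'   (gapped strings), `score` and start/end coordinates
#' @export
global_align <- function(a, b, scoring = dna_scoring()) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  if (is.null(scoring$matrix) && guess_alphabet(a) != guess_alphabet(b))
    stop("sequences must share an alphabet")
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  S <- pair_score_matrix(ac, bc, scoring)
  r <- dp_global_cpp(S, scoring$gap_open, scoring$gap_extend)
  al <- aligned_strings(ac, bc, r$a_idx, r$b_idx)
  new_alignment(al[1], al[2], r$score, 0L, length(ac), 0L, length(bc))
}

#' Local (Smith-Waterman) alignment with top-N hits
#'
#' Finds up to `top_n` maximal local alignments of `query` against `target`,
#' non-overlapping on the target, sorted by score descending. Mirrors a
#' best-N probe search against a genomic scaffold.
#'
#' @param query,target sequences (single strings)
#' @param scoring a [scoring_scheme()]
#' @param top_n maximum number of hits to return
#' @return list of `mads_alignment` objects (possibly empty)
#' @export
local_align <- function(query, target, scoring = dna_scoring(), top_n = 3L) {
  if (top_n < 1) stop("top_n must be >= 1")
  if (nchar(query) == 0 || nchar(target) == 0) stop("sequences must be non-empty")
  qc <- strsplit(query, "")[[1]]
  tc <- strsplit(target, "")[[1]]
  S <- pair_score_matrix(qc, tc, scoring)
  hits <- list()
  for (i in seq_len(top_n)) {
    r <- dp_local_cpp(S, scoring$gap_open, scoring$gap_extend)
    if (r$score <= 0 || length(r$a_idx) == 0) break
    qi <- r$a_idx[r$a_idx > 0]
    ti <- r$b_idx[r$b_idx > 0]
    al <- aligned_strings(qc, tc, r$a_idx, r$b_idx)
    hits[[length(hits) + 1]] <- new_alignment(
      al[1], al[2], r$score,
      min(qi) - 1L, max(qi), min(ti) - 1L, max(ti))
    S[, min(ti):max(ti)] <- -1e9  # mask target interval: non-overlapping hits
  }
  ord <- order(vapply(hits, function(h) h$score, numeric(1)), decreasing = TRUE)
  hits[ord]
}

# k-mer (word) distance between ungapped sequences: 1 - shared fraction of
# the smaller unique k-mer set. Used only to build the guide tree.
kmer_distance_matrix <- function(seqs, k = 3L) {
  sets <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(s)
    unique(substring(s, 1:(n - k + 1), k:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- length(intersect(sets[[i]], sets[[j]]))
    denom <- min(length(sets[[i]]), length(sets[[j]]))
    d[i, j] <- d[j, i] <- 1 - shared / max(denom, 1)
  }
  d
}

profile_freqs <- function(rows, alphabet) {
  m <- do.call(rbind, strsplit(rows, ""))
  w <- ncol(m)
  f <- matrix(0, nrow = length(alphabet), ncol = w, dimnames = list(alphabet))
  for (a in alphabet) f[a, ] <- colSums(m == a)
  f / nrow(m)  # gaps dilute toward zero
}

merge_profiles <- function(rows_a, rows_b, scoring, alphabet, submat) {
  fa <- profile_freqs(rows_a, alphabet)
  fb <- profile_freqs(rows_b, alphabet)
  S <- t(fa) %*% submat %*% fb
  r <- dp_global_cpp(S, scoring$gap_open, scoring$gap_extend)
  expand <- function(rows, idx) {
    ch <- strsplit(rows, "")
    vapply(ch, function(v) {
      out <- ifelse(idx == 0, "-", v[pmax(idx, 1)])
      paste(out, collapse = "")
    }, character(1))
  }
  c(expand(rows_a, r$a_idx), expand(rows_b, r$b_idx))
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree by neighbor joining on k-mer distances, then aligns
#' profiles up the tree with the same DP engine used for pairwise
#' alignment. Output rows are returned in input order.
#'
#' @param seqs named character vector of (ungapped) sequences, length >= 2
#' @param scoring a [scoring_scheme()]; defaults to BLOSUM62 for proteins
#' @param k word length for the guide-tree distance
#' @return a [msa()] object
#' @export
progressive_align <- function(seqs, scoring = protein_scoring(), k = 3L) {
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (anyDuplicated(names(seqs))) stop("sequence names must be unique")
  alphabet <- if (is.null(scoring$matrix)) DNA_BASES else AA20
  submat <- if (is.null(scoring$matrix)) {
    m <- matrix(scoring$mismatch, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
    diag(m) <- scoring$match
    m
  } else scoring$matrix[alphabet, alphabet]

  if (length(seqs) == 2) {
    al <- global_align(seqs[[1]], seqs[[2]], scoring)
    return(msa(stats::setNames(c(al$a, al$b), names(seqs))))
  }

  d <- kmer_distance_matrix(seqs, k = k)
  guide <- nj_tree(d)
  guide <- ape::root(guide, outgroup = guide$tip.label[1], resolve.root = TRUE)

  ntip <- length(guide$tip.label)
  children <- split(guide$edge[, 2], guide$edge[, 1])
  align_node <- function(node) {
    if (node <= ntip) {
      return(stats::setNames(seqs[guide$tip.label[node]], guide$tip.label[node]))
    }
    kids <- children[[as.character(node)]]
    prof <- align_node(kids[1])
    for (kid in kids[-1]) {
      other <- align_node(kid)
      merged <- merge_profiles(unname(prof), unname(other), scoring,
                               alphabet, submat)
      prof <- stats::setNames(merged, c(names(prof), names(other)))
    }
    prof
  }
  rows <- align_node(ntip + 1L)
  msa(rows[names(seqs)])
}

#' Crop an alignment to well-occupied columns
#'
#' Retains columns whose gap fraction is at most `max_gap_fraction`,
#' preserving column order. Mirrors removing poorly conserved regions before
#' tree building.
#'
#' @param x a [msa()]
#' @param max_gap_fraction columns with a larger gap fraction are dropped
#' @return a cropped [msa()]
#' @export
crop_to_conserved <- function(x, max_gap_fraction = 0.5) {
  if (max_gap_fraction < 0 || max_gap_fraction > 1)
    stop("max_gap_fraction must be in [0, 1]")
  m <- as.matrix(x)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac <= max_gap_fraction
  if (!any(keep)) stop("empty-after-crop: no column satisfies the gap threshold")
  msa(stats::setNames(apply(m[, keep, drop = FALSE], 1, paste, collapse = ""),
                      names(x)))
}

#' Pairwise p-distance matrix from an alignment
#'
#' Proportion of differing sites over columns where neither row is gapped.
#'
#' @param x a [msa()] with at least 3 rows
#' @return symmetric numeric matrix with zero diagonal
#' @export
pairwise_distance_matrix <- function(x) {
  if (length(x) < 3) stop("need at least 3 rows")
  m <- as.matrix(x)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok)) stop(sprintf("incomparable-pair: %s and %s share no ungapped column",
                               rownames(m)[i], rownames(m)[j]))
    d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
  }
  d
}

#' Write/read a PHYLIP square distance matrix
#' @param d symmetric matrix with dimnames
#' @param path file path
#' @export
write_phylip_dist <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste0(formatC(rownames(d)[i], width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = "  ")), con)
  }
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  labs <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    labs[i] <- parts[1]
    d[i, ] <- as.numeric(parts[-1])
  }
  dimnames(d) <- list(labs, labs)
  d
}
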