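# Neighbor-joining tree construction, bootstrap support, low-support
# collapse and reference-guided clade assignment. The NJ agglomeration is
# implemented here (classical Saitou-Nei Q criterion with standard branch
# length formulas and a deterministic smallest-(i,j) tie break); ape
# supplies only the `phylo` container and Newick parsing.

#' Neighbor-joining tree
#'
#' Classical neighbor joining from a symmetric distance matrix. Negative
#' branch lengths are retained (classical behavior) and flagged via the
#' `negative_branch_lengths` attribute. On equal Q values the pair with the
#' smallest (row, column) index in the current matrix is joined, making the
#' output deterministic.
#'
#' @param d symmetric numeric matrix with zero diagonal and dimnames
#'   (or a `dist` object), at least 3 taxa
#' @return an unrooted `ape::phylo` tree
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (any(abs(d - t(d)) > 1e-9)) stop("distance matrix must be symmetric")
  if (any(!is.finite(d))) stop("distances must be finite")

  frag <- rownames(d)  # newick fragment per active cluster
  D <- d
  fmt <- function(x) sprintf("%.10g", x)

  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest (i, j) pair (i < j, row-major) on ties
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (Q[i, j] < best - 1e-12) { best <- Q[i, j]; bi <- i; bj <- j }
    }
    li <- 0.5 * D[bi, bj] + (r[bi] - r[bj]) / (2 * (m - 2))
    lj <- D[bi, bj] - li
    newfrag <- paste0("(", frag[bi], ":", fmt(li), ",", frag[bj], ":", fmt(lj), ")")
    dk <- (D[bi, ] + D[bj, ] - D[bi, bj]) / 2
    keep <- setdiff(seq_len(m), c(bi, bj))
    D2 <- D[keep, keep, drop = FALSE]
    dk <- dk[keep]
    D <- rbind(cbind(D2, dk), c(dk, 0))
    frag <- c(frag[keep], newfrag)
    # put the merged cluster at position bi to keep index-based ties stable
    ord <- append(seq_len(length(frag) - 1), length(frag), after = bi - 1)
    D <- D[ord, ord, drop = FALSE]
    frag <- frag[ord]
  }

  dab <- D[1, 2]; dac <- D[1, 3]; dbc <- D[2, 3]
  la <- (dab + dac - dbc) / 2
  lb <- (dab + dbc - dac) / 2
  lc <- (dac + dbc - dab) / 2
  nwk <- paste0("(", frag[1], ":", fmt(la), ",", frag[2], ":", fmt(lb),
                ",", frag[3], ":", fmt(lc), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "negative_branch_lengths") <- any(tree$edge.length < 0)
  tree
}

# Canonical keys for the non-trivial bipartitions of an unrooted tree:
# each internal edge splits the leaves in two; the key is the sorted side
# that does NOT contain the alphabetically smallest leaf label.
bipartition_keys <- function(tree) {
  labs <- tree$tip.label
  anchor <- min(labs)
  pp <- ape::prop.part(tree)
  keys <- character(0)
  nodes <- integer(0)
  ntip <- length(labs)
  for (i in seq_along(pp)) {
    side <- labs[pp[[i]]]
    if (length(side) == ntip) next  # root clade: all tips
    other <- setdiff(labs, side)
    part <- if (anchor %in% side) other else side
    if (length(part) < 2 || length(part) > ntip - 2) next  # trivial split
    keys <- c(keys, paste(sort(part), collapse = "|"))
    nodes <- c(nodes, ntip + i)  # prop.part order follows node numbering
  }
  stats::setNames(nodes, keys)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement (Felsenstein bootstrap),
#' recomputes p-distances and the NJ tree per replicate, and scores every
#' internal edge of the original tree by the percentage of replicates
#' containing the same bipartition. Seeded and reproducible.
#'
#' @param x a [msa()]
#' @param n_reps number of bootstrap replicates (>= 1)
#' @param seed integer RNG seed
#' @return the NJ tree of the full alignment with per-internal-node support
#'   percentages in `node.label` (NA on the unlabellable root node) and a
#'   named support vector in the `bipartition_support` attribute
#' @export
bootstrap_support <- function(x, n_reps = 1000L, seed = 1L) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  base_tree <- nj_tree(pairwise_distance_matrix(x))
  key_nodes <- bipartition_keys(base_tree)
  counts <- stats::setNames(numeric(length(key_nodes)), names(key_nodes))
  m <- as.matrix(x)
  with_seed(seed, {
    for (rep in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      sub <- msa(stats::setNames(apply(m[, cols, drop = FALSE], 1,
                                       paste, collapse = ""), rownames(m)))
      rep_tree <- tryCatch(nj_tree(pairwise_distance_matrix(sub)),
                           error = function(e) NULL)
      if (is.null(rep_tree)) next
      rep_keys <- names(bipartition_keys(rep_tree))
      hit <- names(counts) %in% rep_keys
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- 100 * counts / n_reps
  ntip <- length(base_tree$tip.label)
  node_label <- rep(NA_real_, base_tree$Nnode)
  node_label[unname(key_nodes) - ntip] <- support
  base_tree$node.label <- ifelse(is.na(node_label), "",
                                 sprintf("%.10g", node_label))
  attr(base_tree, "bipartition_support") <- support
  base_tree
}

node_supports <- function(tree) {
  if (is.null(tree$node.label)) rep(NA_real_, tree$Nnode)
  else suppressWarnings(as.numeric(tree$node.label))
}

#' Collapse internal edges with low bootstrap support
#'
#' Contracts every internal edge whose support is strictly below
#' `threshold` into a polytomy; edges with support equal to the threshold
#' are retained. The leaf set is unchanged.
#'
#' @param tree a `phylo` with support values in `node.label`
#' @param threshold support percentage below which edges are collapsed
#' @return a (possibly multifurcating) `phylo`
#' @export
collapse_low_support <- function(tree, threshold = 50) {
  sup <- node_supports(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(x) sprintf("%.10g", x)
  build <- function(node) {
    # returns vector of newick fragments (without a trailing branch length)
    if (node <= ntip) return(tree$tip.label[node])
    eidx <- children[[as.character(node)]]
    parts <- character(0)
    for (e in eidx) {
      child <- tree$edge[e, 2]
      len <- if (!is.null(tree$edge.length)) tree$edge.length[e] else NA_real_
      if (child > ntip) {
        s <- sup[child - ntip]
        kid_frags <- build(child)
        if (!is.na(s) && s < threshold) {
          # contract: splice grandchildren into this node's child list
          parts <- c(parts, kid_frags)
          next
        }
        lab <- if (is.na(s)) "" else fmt(s)
        frag <- paste0("(", paste(kid_frags, collapse = ","), ")", lab)
      } else {
        frag <- build(child)
      }
      if (!is.na(len)) frag <- paste0(frag, ":", fmt(len))
      parts <- c(parts, frag)
    }
    parts
  }
  # when a contracted child is spliced in, its grandchildren fragments keep
  # their own branch lengths; the contracted edge's length is dropped
  root_parts <- build(root)
  nwk <- paste0("(", paste(root_parts, collapse = ","), ");")
  ape::read.tree(text = nwk)
}

#' Assign query leaves to named clades by reference placement
#'
#' Each unlabeled leaf receives the label of the smallest monophyletic
#' group (a side of some edge of the unrooted tree) that contains the query
#' and at least one labeled reference leaf. Groups whose references carry
#' conflicting labels yield `"unresolved"`.
#'
#' @param tree a `phylo` (typically after [collapse_low_support()])
#' @param reference_labels named character vector: taxon -> clade label
#' @return data.frame with columns `query`, `clade`, `n_references`
#' @export
assign_clade <- function(tree, reference_labels) {
  if (length(reference_labels) == 0) stop("reference label vocabulary is empty")
  labs <- tree$tip.label
  refs <- intersect(names(reference_labels), labs)
  if (length(refs) == 0) stop("no reference taxon present in the tree")
  queries <- setdiff(labs, names(reference_labels))
  pp <- ape::prop.part(tree)
  sides <- list()
  for (i in seq_along(pp)) {
    side <- labs[pp[[i]]]
    if (length(side) == length(labs)) next
    sides[[length(sides) + 1]] <- side
    sides[[length(sides) + 1]] <- setdiff(labs, side)
  }
  sides[[length(sides) + 1]] <- labs  # whole leaf set as fallback group
  out <- data.frame(query = character(0), clade = character(0),
                    n_references = integer(0), stringsAsFactors = FALSE)
  for (q in queries) {
    cand <- Filter(function(s) q %in% s && any(refs %in% s), sides)
    sizes <- vapply(cand, length, integer(1))
    grp <- cand[[which.min(sizes)]]
    grp_refs <- intersect(grp, refs)
    lab <- unique(unname(reference_labels[grp_refs]))
    clade <- if (length(lab) == 1) lab else "unresolved"
    out <- rbind(out, data.frame(query = q, clade = clade,
                                 n_references = length(grp_refs),
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Write a tree to Newick
#' @param tree a `phylo`
#' @param path file path
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
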