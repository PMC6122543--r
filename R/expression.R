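# Relative qPCR expression by the 2^-ddCt method with a housekeeping
# reference gene, replicate-level testing, and hierarchical clustering of
# the gene x sample expression matrix.

#' Relative expression by 2^-ddCt
#'
#' Per sample and gene, dCt = mean Ct(target) - mean Ct(reference); ddCt
#' subtracts the calibrator sample's dCt; fold change = 2^(-ddCt). The SD
#' is propagated from replicate-level dCt values (replicate i of the
#' target paired with replicate i of the reference) and the p-value
#' compares a sample's replicate dCt values against the calibrator's by a
#' pooled-variance t test. Samples with missing reference measurements are
#' flagged, not dropped silently.
#'
#' @param ct a long-format Ct table (sample, gene, replicate, ct), e.g.
#'   from [gen_ct_table()]
#' @param ref_gene reference (housekeeping) gene id; defaults to the
#'   table's `reference_gene` attribute
#' @param calibrator calibrator sample id; defaults to the table's
#'   `calibrator` attribute
#' @return data.frame: gene, sample, fold, log2_fold, sd_dct, p_value,
#'   error ("" or reason)
#' @export
ddct <- function(ct, ref_gene = NULL, calibrator = NULL) {
  if (is.null(ref_gene)) ref_gene <- attr(ct, "reference_gene")
  if (is.null(calibrator)) calibrator <- attr(ct, "calibrator")
  if (is.null(ref_gene) || !ref_gene %in% ct$gene)
    stop("reference gene not present in the Ct table")
  if (is.null(calibrator) || !calibrator %in% ct$sample)
    stop("calibrator sample not present in the Ct table")
  samples <- unique(ct$sample)
  genes <- setdiff(unique(ct$gene), ref_gene)
  # replicate-level dCt per (sample, gene)
  rep_dct <- function(s, g) {
    tgt <- ct[ct$sample == s & ct$gene == g, ]
    ref <- ct[ct$sample == s & ct$gene == ref_gene, ]
    if (nrow(ref) == 0) return(NULL)
    tgt <- tgt[order(tgt$replicate), ]
    ref <- ref[order(ref$replicate), ]
    n <- min(nrow(tgt), nrow(ref))
    tgt$ct[seq_len(n)] - ref$ct[seq_len(n)]
  }
  out <- list()
  for (g in genes) {
    dct_cal <- rep_dct(calibrator, g)
    for (s in samples) {
      dct_s <- rep_dct(s, g)
      if (is.null(dct_s) || length(dct_s) == 0) {
        out[[length(out) + 1]] <- data.frame(
          gene = g, sample = s, fold = NA_real_, log2_fold = NA_real_,
          sd_dct = NA_real_, p_value = NA_real_,
          error = "missing reference measurements", stringsAsFactors = FALSE)
        next
      }
      ddct_val <- mean(dct_s) - mean(dct_cal)
      p <- if (s != calibrator && length(dct_s) >= 2 && length(dct_cal) >= 2 &&
               (stats::var(dct_s) + stats::var(dct_cal)) > 0)
        stats::t.test(dct_s, dct_cal, var.equal = TRUE)$p.value
      else NA_real_
      out[[length(out) + 1]] <- data.frame(
        gene = g, sample = s, fold = 2^(-ddct_val), log2_fold = -ddct_val,
        sd_dct = stats::sd(dct_s), p_value = p, error = "",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-sample pooled-variance Student t test on replicate fold values
#'
#' @param a,b numeric vectors of replicate measurements (each n >= 2)
#' @return list: `t`, `df`, `p_value`, `significant_05`, `significant_01`
#' @export
group_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 replicates")
  res <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value,
       significant_05 = res$p.value <= 0.05,
       significant_01 = res$p.value <= 0.01)
}

#' Expression matrix from a ddCt result
#'
#' @param rel result of [ddct()]
#' @param drop_missing drop genes flagged with errors or NA folds (they
#'   are listed in the `dropped` attribute)
#' @return genes x samples matrix of log2 fold changes
#' @export
expression_matrix <- function(rel, drop_missing = TRUE) {
  m <- stats::reshape(rel[, c("gene", "sample", "log2_fold")],
                      idvar = "gene", timevar = "sample",
                      direction = "wide")
  rn <- m$gene
  m <- as.matrix(m[, -1, drop = FALSE])
  rownames(m) <- rn
  colnames(m) <- sub("^log2_fold\\.", "", colnames(m))
  dropped <- rownames(m)[apply(m, 1, function(r) any(!is.finite(r)))]
  if (drop_missing && length(dropped) > 0)
    m <- m[!rownames(m) %in% dropped, , drop = FALSE]
  attr(m, "dropped") <- dropped
  m
}

#' Hierarchical clustering of an expression matrix
#'
#' Agglomerative average-linkage clustering of genes, with euclidean or
#' correlation (1 - Pearson) distance. Rows containing missing values are
#' dropped and reported; a constant row under correlation distance is an
#' error.
#'
#' @param expr genes x samples numeric matrix (e.g. log2 folds)
#' @param distance "pearson" (1 - correlation) or "euclidean"
#' @param linkage agglomeration method (default "average")
#' @return list of class `expr_clustering`: `hclust`, `merge_heights`,
#'   `leaf_order` (gene ids in dendrogram order), `dropped`
#' @export
hcluster <- function(expr, distance = c("pearson", "euclidean"),
                     linkage = "average") {
  distance <- match.arg(distance)
  keep <- apply(expr, 1, function(r) all(is.finite(r)))
  dropped <- rownames(expr)[!keep]
  expr <- expr[keep, , drop = FALSE]
  if (nrow(expr) < 2) stop("need at least 2 genes with complete values")
  if (distance == "pearson") {
    sds <- apply(expr, 1, stats::sd)
    if (any(sds == 0))
      stop("zero-variance row(s): ",
           paste(rownames(expr)[sds == 0], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(t(expr)))
  } else {
    d <- stats::dist(expr)
  }
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, merge_heights = hc$height,
                 leaf_order = rownames(expr)[hc$order], dropped = dropped),
            class = "expr_clustering")
}

#' @export
print.expr_clustering <- function(x, ...) {
  cat(sprintf("Expression clustering: %d genes, heights %.3g .. %.3g\n",
              length(x$leaf_order), min(x$merge_heights),
              max(x$merge_heights)))
  if (length(x$dropped) > 0)
    cat("  dropped (missing values):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Export a clustering as a Newick dendrogram
#' @param clustering an `expr_clustering`
#' @param path output path
#' @export
write_dendrogram <- function(clustering, path) {
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}
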