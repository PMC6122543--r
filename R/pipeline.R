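# End-to-end pipeline on a seeded synthetic genome: simulate -> domain
# scan -> read walk -> ORF completion -> phylogeny -> cis elements ->
# expression. Every stage writes plain-text outputs into `outdir`, and the
# whole run is byte-deterministic for a fixed seed.

derive_seed <- function(seed, offset) (as.integer(seed) + offset) %% 2147483647L

#' Run the full synthetic-genome pipeline
#'
#' Generates a planted gene family, defective annotations and reads,
#' identifies and classifies family members with the bundled M/K
#' profiles, completes the defective models by read walking, builds a
#' bootstrapped NJ tree and assigns clades, scans promoters and introns
#' for cis elements, and computes relative expression from a simulated Ct
#' table. All outputs are written under `outdir`.
#'
#' @param outdir output directory (created)
#' @param seed master RNG seed; all stage seeds derive from it
#' @param n_genes,n_typeI family composition
#' @param n_truncate number of genes receiving annotation defects (drawn
#'   from the standard panel modes; at most 17)
#' @param depth,read_len,err_rate read simulation parameters
#' @param bootstrap_reps bootstrap replicates for the tree
#' @return invisibly, a list with the main in-memory results and the
#'   output paths
#' @export
run_pipeline <- function(outdir, seed = 1L, n_genes = 12L, n_typeI = 3L,
                         n_truncate = 4L, depth = 30, read_len = 100L,
                         err_rate = 0, bootstrap_reps = 50L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  # 1. simulate
  truth <- gen_gene_family(n_genes, n_typeI, seed = derive_seed(seed, 1L))
  paths <- write_family(truth, outdir)
  panel_full <- default_truncation_panel_n(truth, n_truncate,
                                           seed = derive_seed(seed, 2L))
  annotated <- truncate_models(truth, panel_full, seed = derive_seed(seed, 7L))
  ann_paths <- write_annotated(annotated, outdir)
  reads <- sim_reads(truth$transcripts, depth = depth, read_len = read_len,
                     err_rate = err_rate, seed = derive_seed(seed, 3L))
  write_fastq(unclass(reads), file.path(outdir, "reads.fq"))

  # 2. scan & classify
  profiles <- default_profiles()
  classification <- classify_proteins(truth$proteins, profiles$M, profiles$K)
  utils::write.table(classification, file.path(outdir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # 3. walk + complete the defective models
  index <- build_read_index(unclass(reads), k = 21L)
  defective <- annotated[panel_full$gene_id]
  report <- correct_models(defective, index, profiles$M, profiles$K)
  write_orf_report(report, file.path(outdir, "orf_report.tsv"))
  corrected <- stats::setNames(report$corrected_protein, report$gene_id)
  corrected <- corrected[!is.na(corrected)]
  if (length(corrected) > 0)
    write_fasta(corrected, file.path(outdir, "corrected_proteins.fa"), "AA")

  # 4. phylogeny + clade assignment
  aln <- progressive_align(truth$proteins)
  cropped <- crop_to_conserved(aln, max_gap_fraction = 0.5)
  tree <- bootstrap_support(cropped, n_reps = bootstrap_reps,
                            seed = derive_seed(seed, 4L))
  collapsed <- collapse_low_support(tree, threshold = 50)
  write_newick(collapsed, file.path(outdir, "family_tree.nwk"))
  # every second gene of each clade acts as a labelled reference
  ref_ids <- names(truth$clade_labels)[c(TRUE, FALSE)]
  assignments <- assign_clade(collapsed, truth$clade_labels[ref_ids])
  utils::write.table(assignments, file.path(outdir, "clade_assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # 5. cis elements in promoters and introns
  dict <- load_cis_dictionary()
  hits <- list()
  for (gid in names(truth$genes)) {
    g <- truth$genes[[gid]]
    prom <- extract_promoter(g, truth$scaffolds[[g$scaffold]])
    hits[[length(hits) + 1]] <-
      scan_motifs(prom, dict, seq_id = gid, region = "promoter")
    intr <- extract_introns(g, truth$scaffolds[[g$scaffold]])
    if (length(intr) > 0)
      hits[[length(hits) + 1]] <-
        scan_motifs(paste(intr, collapse = ""), dict, seq_id = gid,
                    region = "intron")
  }
  hit_tab <- do.call(rbind, hits)
  utils::write.table(hit_tab, file.path(outdir, "cis_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cis_summary <- summarize_categories(hit_tab, dict)
  utils::write.table(cis_summary$category_summary,
                     file.path(outdir, "cis_categories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # 6. expression
  samples <- c("leaf", "F1", "F2", "F3", "F4")
  folds <- with_seed(derive_seed(seed, 5L), {
    f <- matrix(2^stats::runif(length(truth$proteins) * length(samples),
                               -3, 3),
                nrow = length(truth$proteins),
                dimnames = list(names(truth$proteins), samples))
    f[, "leaf"] <- 1
    f
  })
  ct <- gen_ct_table(folds, noise_sd = 0.15, seed = derive_seed(seed, 6L))
  utils::write.csv(ct, file.path(outdir, "ct_table.csv"), row.names = FALSE)
  rel <- ddct(ct)
  utils::write.csv(rel, file.path(outdir, "relative_expression.csv"),
                   row.names = FALSE)
  expr <- expression_matrix(rel)
  clustering <- hcluster(expr)
  write_dendrogram(clustering, file.path(outdir, "expression_dendrogram.nwk"))
  utils::write.table(round(expr, 6), file.path(outdir, "expression_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)

  invisible(list(truth = truth, classification = classification,
                 report = report, tree = collapsed,
                 assignments = assignments, cis = cis_summary,
                 expression = rel, clustering = clustering,
                 outdir = outdir))
}

# panel of the first n defect modes (ordering as in the 17-gene panel)
default_truncation_panel_n <- function(truth, n, seed = 1L) {
  stopifnot(n >= 1)
  ids <- names(truth$clade_labels)[truth$clade_labels != "Malpha"]
  modes <- rep(c("lack_K", "lack_M", "corrupt_5prime"), length.out = n)
  reasons <- c(lack_K = "Lack of K-domain", lack_M = "Lack of M-domain",
               corrupt_5prime = "5' region is incorrect")[modes]
  if (length(ids) < n) stop("not enough type II genes")
  ids <- ids[seq_len(n)]
  with_seed(seed, {
    recs <- lapply(seq_len(n), function(i) {
      g <- truth$genes[[ids[i]]]
      true_len <- nchar(g$protein)
      m_end <- g$m_span[2]
      k_start <- g$k_span[1]
      bad_aa <- NA_integer_
      orig <- switch(modes[i],
        lack_K = sample_range(m_end + 10L, k_start + 15L),
        lack_M = sample_range(true_len - k_start, true_len - m_end %/% 2L),
        corrupt_5prime = {
          keep <- sample_range(true_len - k_start, true_len - m_end)
          bad_aa <- sample(30:60, 1)
          keep + bad_aa
        })
      data.frame(gene_id = ids[i], mode = modes[i],
                 original_len_aa = orig, reason = unname(reasons[i]),
                 bad_aa = bad_aa, stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
}
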