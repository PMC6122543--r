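test_that("family generation is byte-deterministic and honors composition", {
  f1 <- gen_gene_family(10, 2, seed = 7)
  f2 <- gen_gene_family(10, 2, seed = 7)
  expect_identical(f1$scaffolds, f2$scaffolds)
  expect_identical(f1$proteins, f2$proteins)
  d1 <- tempfile(); d2 <- tempfile()
  write_family(f1, d1); write_family(f2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_equal(sum(f1$clade_labels == "Malpha"), 2)
  # round trip with the domain scanner: exactly the type I genes lack K
  prof <- default_profiles()
  cl <- classify_proteins(f1$proteins, prof$M, prof$K)
  expect_equal(sum(cl$type == "type_I"), 2)
  expect_identical(cl$id[cl$type == "type_I"],
                   names(f1$clade_labels)[f1$clade_labels == "Malpha"])
  expect_error(gen_gene_family(3, 5), "n_typeI")
})

test_that("an empty family writes valid empty files", {
  f0 <- gen_gene_family(0, 0, seed = 1)
  expect_length(f0$genes, 0)
  d <- tempfile()
  paths <- write_family(f0, d)
  expect_true(all(file.exists(paths)))
  expect_length(read_fasta(paths[["scaffolds"]], "DNA"), 0)
})

test_that("gene-model invariants hold for every planted gene", {
  fam <- gen_gene_family(12, 3, seed = 8)
  for (gid in names(fam$genes)) {
    g <- fam$genes[[gid]]
    sc <- fam$scaffolds[[g$scaffold]]
    spliced <- paste(substring(sc, g$exons[, 1] + 1, g$exons[, 2]),
                     collapse = "")
    if (g$strand == "-") spliced <- revcomp(spliced)
    expect_identical(spliced, unname(fam$transcripts[[gid]]))
    expect_identical(translate_cds(g$cds), paste0(g$protein, "*"))
    # the CDS sits inside the transcript at the recorded offsets
    expect_identical(substr(fam$transcripts[[gid]], g$cds_tx[1] + 1,
                            g$cds_tx[2]), unname(g$cds))
    if (g$type == "type_I") expect_equal(g$n_introns, 0)
  }
})

test_that("long-intron mode plants a >= 10 kb intron", {
  fam <- gen_gene_family(3, 0, seed = 9, long_intron = TRUE)
  g <- fam$genes[[1]]
  gaps <- g$exons[-1, 1] - g$exons[-nrow(g$exons), 2]
  expect_true(max(gaps) >= 10000)
})

test_that("truncation emits the stated lengths and keeps truth intact", {
  fam <- gen_gene_family(5, 0, seed = 10)
  gid <- names(fam$genes)[1]
  true_len <- nchar(fam$proteins[[gid]])
  recs <- data.frame(gene_id = gid, mode = "lack_K",
                     original_len_aa = 90)
  ann <- truncate_models(fam, recs, seed = 2)
  expect_equal(nchar(ann[[gid]]$protein), 90)
  expect_identical(ann[[gid]]$protein, substr(fam$proteins[[gid]], 1, 90))
  expect_equal(nchar(fam$proteins[[gid]]), true_len)
  # unknown ids are rejected; empty record list is the identity
  expect_error(truncate_models(fam, data.frame(gene_id = "nope",
                                               mode = "lack_K",
                                               original_len_aa = 10)),
               "unknown gene_id")
  ident <- truncate_models(fam)
  expect_identical(ident[[gid]]$protein, unname(fam$proteins[[gid]]))
  expect_error(truncate_models(fam, data.frame(gene_id = gid,
                                               mode = "lack_M",
                                               original_len_aa = true_len)),
               "must be <")
})

test_that("lack_M removal maps to the far end of a minus-strand locus", {
  set.seed(11)
  fam <- NULL
  for (s in 1:40) {  # find a seed giving gene 1 on the minus strand
    cand <- gen_gene_family(2, 0, seed = s)
    if (cand$genes[[1]]$strand == "-") { fam <- cand; break }
  }
  expect_false(is.null(fam))
  gid <- names(fam$genes)[1]
  g <- fam$genes[[gid]]
  true_len <- nchar(g$protein)
  orig <- true_len - g$m_span[2] - 5L
  ann <- truncate_models(fam, data.frame(gene_id = gid, mode = "lack_M",
                                         original_len_aa = orig), seed = 3)
  cg <- madswalk:::annotated_cds_genomic(ann[[gid]])
  # removed 5' codons sit 3' of the annotated CDS in genomic coordinates
  # (minus strand: transcript 5' = high genomic coordinates)
  expect_lt(max(cg[, 2]), g$cds_genomic[2])
  expect_equal(min(cg[, 1]), g$cds_genomic[1])
  gene_span_hi <- max(g$exons[, 2])
  expect_true(all(cg[, 2] <= gene_span_hi))
})

test_that("read simulation matches its count formula and error model", {
  tx <- setNames(paste(rep("ACGT", 250), collapse = ""), "t1")  # 1000 nt
  reads <- sim_reads(tx, depth = 10, read_len = 100, err_rate = 0, seed = 4)
  expect_length(reads, 100)  # ceil(10 * 1000 / 100)
  # error-free reads are exact substrings of the transcript on some strand
  set.seed(12)
  tx2 <- setNames(random_dna_str(700), "t2")
  r2 <- sim_reads(tx2, depth = 3, read_len = 80, err_rate = 0, seed = 5)
  for (rd in r2) {
    expect_true(grepl(rd, tx2, fixed = TRUE) ||
                  grepl(revcomp(rd), tx2, fixed = TRUE))
  }
  r2b <- sim_reads(tx2, depth = 3, read_len = 80, err_rate = 0, seed = 5)
  expect_identical(r2, r2b)
  expect_identical(names(r2), names(r2b))
  expect_error(sim_reads(tx2, read_len = 800, seed = 1), "read_len")
  # substitution rate is close to the requested rate
  r3 <- sim_reads(tx2, depth = 30, read_len = 80, err_rate = 0.05, seed = 6)
  mism <- vapply(r3, function(rd) {
    best <- Inf
    for (cand in c(rd, revcomp(rd))) {
      h <- local_align(cand, tx2, dna_scoring(), top_n = 1)
      if (length(h)) best <- min(best, (80 - h[[1]]$score) / 2)
    }
    best
  }, numeric(1))
  expect_gt(mean(mism) / 80, 0.02)
  expect_lt(mean(mism) / 80, 0.08)
})

test_that("Ct tables follow the planted fold model", {
  folds <- matrix(c(1, 16), 1, dimnames = list("g1", c("leaf", "F1")))
  ct <- gen_ct_table(folds, noise_sd = 0, seed = 1)
  expect_s3_class(ct, "ct_table")
  expect_equal(attr(ct, "calibrator"), "leaf")
  # every (sample, gene) pair has 3 replicates; Ct finite and positive
  counts <- table(ct$sample, ct$gene)
  expect_true(all(counts == 3))
  expect_true(all(is.finite(ct$ct) & ct$ct > 0))
  # fold 16 = 4 fewer cycles in the target
  m <- aggregate(ct ~ sample + gene, ct, mean)
  expect_equal(m$ct[m$gene == "g1" & m$sample == "leaf"] -
                 m$ct[m$gene == "g1" & m$sample == "F1"], 4)
  expect_error(gen_ct_table(matrix(-1, 1, 1,
                                   dimnames = list("g", "leaf"))),
               "must be > 0")
  # Monte-Carlo recovery under noise
  errs <- vapply(1:200, function(i) {
    cti <- gen_ct_table(folds, noise_sd = 0.2, seed = 1000 + i)
    r <- ddct(cti)
    r$fold[r$sample == "F1"]
  }, numeric(1))
  expect_lt(abs(mean(errs) / 16 - 1), 0.05)
})
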