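test_that("the CArG consensus matches palindromically with dedupe", {
  dict <- load_cis_dictionary()
  carg <- dict[dict$name == "CArG", ]
  expect_true(is_palindromic_iupac(carg$pattern))
  h <- scan_motifs("TTCCATATATGGTT", carg)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 2)
  expect_equal(h$strand, "±")
  expect_equal(h$match, "CCATATATGG")
})

test_that("empty dictionaries and sequences yield empty tables", {
  dict <- load_cis_dictionary()
  expect_equal(nrow(scan_motifs("ACGTACGT", dict[0, ])), 0)
  expect_error(validate_motif_dict(
    data.frame(name = "bad", pattern = "ACQ", category = "other")),
    "invalid IUPAC")
})

test_that("the scanner equals an independent regex oracle", {
  dict <- load_cis_dictionary()
  set.seed(81)
  for (rep in 1:40) {
    s <- random_dna_str(2000)
    got <- scan_motifs(s, dict, seq_id = "s")
    want <- oracle_scan(s, dict, seq_id = "s")
    got_k <- sort(paste(got$motif, got$start, got$strand))
    want_k <- sort(paste(want$motif, want$start, want$strand))
    expect_identical(got_k, want_k, label = paste("rep", rep))
  }
})

test_that("reverse-complementing a sequence reflects hits exactly", {
  dict <- load_cis_dictionary()
  set.seed(82)
  s <- random_dna_str(1500)
  fwd <- scan_motifs(s, dict, seq_id = "s")
  rev <- scan_motifs(revcomp(s), dict, seq_id = "s")
  L <- nchar(s)
  wid <- setNames(nchar(dict$pattern), dict$name)
  flip <- function(h) {
    strand <- ifelse(h$strand == "±", "±", ifelse(h$strand == "+", "-", "+"))
    start <- L - (h$start + wid[h$motif])
    sort(paste(h$motif, start, strand))
  }
  expect_identical(sort(paste(fwd$motif, fwd$start, fwd$strand)), flip(rev))
})

test_that("promoter extraction respects strand and scaffold edges", {
  fam <- gen_gene_family(6, 1, seed = 83)
  for (gid in names(fam$genes)) {
    g <- fam$genes[[gid]]
    sc <- fam$scaffolds[[g$scaffold]]
    prom <- extract_promoter(g, sc, length = 1500)
    expect_equal(nchar(prom), 1500)
    expect_false(attr(prom, "truncated"))
    # the promoter must abut the start codon: promoter + CDS starts with ATG
    tx <- fam$transcripts[[gid]]
    cds_start_in_tx <- g$cds_tx[1]
    expect_identical(substr(tx, cds_start_in_tx + 1, cds_start_in_tx + 3),
                     "ATG")
    # the last bases of the promoter equal the sequence just upstream of
    # the start codon on the coding strand
    if (g$strand == "+") {
      upstream <- substr(sc, g$cds_genomic[1] - 19, g$cds_genomic[1])
    } else {
      upstream <- revcomp(substr(sc, g$cds_genomic[2] + 1,
                                 g$cds_genomic[2] + 20))
    }
    expect_identical(substr(as.vector(prom), 1481, 1500), unname(upstream))
  }
  # plus-strand arithmetic on a hand-built model
  gene <- list(strand = "+", cds_genomic = c(2000L, 2600L))
  sc <- random_dna_str(2600)
  expect_identical(unclass(extract_promoter(gene, sc, 1500))[1],
                   substr(sc, 501, 2000))
  # truncation at the scaffold edge
  gene2 <- list(strand = "+", cds_genomic = c(100L, 400L))
  p2 <- extract_promoter(gene2, sc, 1500)
  expect_equal(attr(p2, "actual_length"), 100)
  expect_true(attr(p2, "truncated"))
  expect_error(extract_promoter(list(strand = "+"), sc), "start codon")
})

test_that("introns are reported on the coding strand in transcript order", {
  fam <- gen_gene_family(8, 0, seed = 84)
  g <- fam$genes[[1]]
  sc <- fam$scaffolds[[g$scaffold]]
  introns <- extract_introns(g, sc)
  expect_length(introns, g$n_introns)
  # reassembling exons + introns in genomic order recovers the locus
  ex <- g$exons[order(g$exons[, 1]), , drop = FALSE]
  genomic_introns <- vapply(seq_len(nrow(ex) - 1), function(i)
    substr(sc, ex[i, 2] + 1, ex[i + 1, 1]), character(1))
  if (g$strand == "-") {
    expect_identical(unname(introns), unname(rev(revcomp(genomic_introns))))
  } else {
    expect_identical(unname(introns), unname(genomic_introns))
  }
})

test_that("planted motifs are recovered and category sums are conserved", {
  dict <- load_cis_dictionary()
  pm <- plant_motifs(4, 1200, plan = c(CArG = 3, `G-box` = 2), seed = 85)
  expect_true(all(pm$truth_counts[, "CArG"] == 3))
  expect_true(all(pm$truth_counts[, "G-box"] == 2))
  hits <- do.call(rbind, lapply(names(pm$promoters), function(p)
    scan_motifs(pm$promoters[[p]], dict, seq_id = p)))
  # every planted instance is found by the scanner
  planted_k <- paste(pm$planted$seq_id, pm$planted$motif, pm$planted$start)
  hits_k <- paste(hits$seq_id, hits$motif, hits$start)
  expect_true(all(planted_k %in% hits_k))
  # scanner totals = planted + recorded background, per motif
  for (m in c("CArG", "G-box")) {
    expect_equal(sum(hits$motif == m),
                 sum(pm$planted$motif == m) + sum(pm$background$motif == m))
  }
  s <- summarize_categories(hits, dict)
  expect_equal(sum(s$category_summary$count), nrow(hits))
  expect_equal(sum(s$category_summary$proportion), 1)
  expect_equal(sum(s$per_gene$count), nrow(hits))
  # permutation invariance of the aggregates
  s2 <- summarize_categories(hits[sample(nrow(hits)), ], dict)
  expect_identical(s$category_summary, s2$category_summary)
  # unknown motif names are rejected
  bad <- hits
  bad$motif[1] <- "nonexistent"
  expect_error(summarize_categories(bad, dict), "not in dictionary")
})

test_that("an empty plan gives background-only promoters", {
  pm <- plant_motifs(3, 800, plan = c(), seed = 86)
  expect_equal(nrow(pm$planted), 0)
  expect_true(all(pm$truth_counts == 0))
  expect_equal(unique(nchar(pm$promoters)), 800)
  expect_error(plant_motifs(2, 30, plan = c(CArG = 10), seed = 1),
               "infeasible")
})
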