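test_that("profile log-odds match hand computation", {
  # single-row seed: column-1 'A' = log2(((1+1)/(1+20))/0.05)
  p1 <- build_profile(msa(c(s1 = "ACDEF")), pseudocount = 1)
  expect_equal(unname(p1$log_odds["A", 1]), log2(((1 + 1) / (1 + 20)) / 0.05),
               tolerance = 1e-12)
  # two-row seed: column-1 'A' = log2(((2+1)/(2+20))/0.05)
  p2 <- build_profile(msa(c(s1 = "ACDEF", s2 = "ATDEF")), pseudocount = 1)
  expect_equal(unname(p2$log_odds["A", 1]), log2(((2 + 1) / (2 + 20)) / 0.05),
               tolerance = 1e-12)
  # column 2 splits C/T
  expect_equal(unname(p2$log_odds["C", 2]), log2(((1 + 1) / (2 + 20)) / 0.05),
               tolerance = 1e-12)
})

test_that("the consensus scores at least as high as every seed row", {
  prof <- default_profiles()
  for (p in prof) {
    cons <- profile_consensus(p)
    cons_score <- max(scan_protein(p, cons)$score)
    expect_true(all(cons_score >= p$seed_self_scores - 1e-9))
  }
})

test_that("scan_protein equals brute-force window scoring", {
  prof <- default_profiles()$M
  set.seed(21)
  for (rep in 1:25) {
    protein <- random_protein_str(sample(70:150, 1))
    # plant the consensus in a third of the cases
    if (rep %% 3 == 0) {
      off <- sample(1:(nchar(protein) - prof$width), 1)
      protein <- paste0(substr(protein, 1, off - 1), profile_consensus(prof),
                        substr(protein, off + prof$width, nchar(protein)))
    }
    got <- madswalk:::score_windows(prof, strsplit(protein, "")[[1]])
    want <- oracle_window_scores(prof, protein)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("planted consensus is found at the planted offset", {
  prof <- default_profiles()$M
  set.seed(22)
  flank <- random_protein_str(10)
  protein <- paste0(flank, profile_consensus(prof), random_protein_str(30))
  hits <- scan_protein(prof, protein, id = "x")
  expect_true(any(hits$start == 10))
  expect_true(all(hits$end - hits$start == prof$width))
  # shorter than the profile: empty result, not an error
  expect_equal(nrow(scan_protein(prof, "MKLV")), 0)
})

test_that("raising the threshold never adds hits", {
  prof <- default_profiles()$M
  set.seed(23)
  protein <- paste0(random_protein_str(15), profile_consensus(prof),
                    random_protein_str(40))
  lo <- scan_protein(prof, protein)
  hi_prof <- prof
  hi_prof$bit_threshold <- prof$bit_threshold * 1.3
  hi <- scan_protein(hi_prof, protein)
  expect_true(nrow(hi) <= nrow(lo))
  expect_true(all(hi$start %in% lo$start))
})

test_that("six-frame scanning finds planted domains with strand symmetry", {
  prof <- default_profiles()$M
  set.seed(24)
  cons <- profile_consensus(prof)
  choices <- madswalk:::codon_choices()
  cds <- madswalk:::sample_cds_for(cons, choices)
  dna <- paste0(random_dna_str(33), cds, random_dna_str(60))
  fwd <- scan_scaffold_sixframe(prof, dna, id = "s")
  expect_true(nrow(fwd) >= 1)
  expect_true(any(fwd$frame == ((33 %% 3) + 1) & fwd$start == 33))
  rev <- scan_scaffold_sixframe(prof, revcomp(dna), id = "s")
  # same hits up to frame sign and coordinate reflection
  expect_equal(nrow(rev), nrow(fwd))
  L <- nchar(dna)
  expect_setequal(paste(L - rev$end, L - rev$start, -sign(rev$frame),
                        round(rev$score, 6)),
                  paste(fwd$start, fwd$end, sign(fwd$frame),
                        round(fwd$score, 6)))
})

test_that("classification follows the M/K rule table", {
  h <- data.frame(seq_id = "x", start = 0, end = 60, frame = 0, score = 99,
                  domain = "M")
  none <- h[0, ]
  expect_equal(classify_gene(h, h)$type, "type_II")
  expect_equal(classify_gene(h, none)$type, "type_I")
  expect_equal(classify_gene(none, h)$type, "non_MADS")
  expect_false(classify_gene(none, none)$has_M)
})

test_that("family classification recovers planted type labels", {
  fam <- gen_gene_family(14, 4, seed = 31)
  prof <- default_profiles()
  cl <- classify_proteins(fam$proteins, prof$M, prof$K)
  want <- ifelse(fam$clade_labels[cl$id] == "Malpha", "type_I", "type_II")
  expect_identical(cl$type, unname(want))
})

test_that("de-duplication drops identical and contained proteins", {
  p <- c(a = "MKLVRRNG", b = "MKLVRRNG", c = "KLVRR", d = "MACDEF")
  kept <- dedupe_family(p)
  expect_setequal(names(kept), c("a", "d"))
})

test_that("profiles survive TSV serialization", {
  prof <- default_profiles()$K
  f <- tempfile(fileext = ".tsv")
  write_profile(prof, f)
  back <- read_profile(f)
  expect_equal(back$width, prof$width)
  expect_equal(back$bit_threshold, prof$bit_threshold, tolerance = 1e-9)
  expect_equal(back$log_odds, prof$log_odds, tolerance = 1e-9)
  p1 <- scan_protein(prof, profile_consensus(prof))
  p2 <- scan_protein(back, profile_consensus(prof))
  expect_equal(p1$score, p2$score, tolerance = 1e-9)
})
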