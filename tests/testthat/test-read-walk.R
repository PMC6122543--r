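make_tiling_reads <- function(truth, read_len, step) {
  starts <- seq(1, nchar(truth) - read_len + 1, by = step)
  setNames(vapply(starts, function(s) substr(truth, s, s + read_len - 1),
                  character(1)),
           paste0("r", seq_along(starts)))
}

test_that("the index stores every k-mer of every read on both strands", {
  # palindromic 8-mer: two postings, strands + and -
  idx <- build_read_index(c(r1 = "ACGTACGT"), k = 8, enforce_min_k = FALSE)
  expect_equal(nrow(idx$postings), 2)
  expect_setequal(idx$postings$strand, c("+", "-"))
  expect_equal(unique(idx$postings$kmer), "ACGTACGT")

  # completeness on simulated reads
  set.seed(41)
  tx <- setNames(random_dna_str(500), "tx")
  reads <- sim_reads(tx, depth = 5, read_len = 60, seed = 2)
  idx <- build_read_index(unclass(reads), k = 21)
  for (i in seq_along(reads)) {
    for (off in c(1, 17, 40)) {
      km <- substr(reads[[i]], off, off + 20)
      post <- query_index(idx, km)
      expect_true(any(post$read == i & post$offset == off - 1 &
                        post$strand == "+"),
                  info = paste("read", i, "offset", off))
      rc <- revcomp(km)
      expect_true(nrow(query_index(idx, rc)) >= 1)
    }
  }
  # empty read set
  empty <- build_read_index(character(0), k = 21)
  expect_equal(nrow(query_index(empty, "ACGTACGTACGTACGTACGTA")), 0)
  expect_error(build_read_index(c(r1 = "ACGTACGTACGT"), k = 4),
               "enforce_min_k")
})

test_that("overlap candidates obey the threshold, containment and overhang rules", {
  params <- walk_params(k = 4, min_overlap = 5, min_support = 1)
  idx <- build_read_index(c(rd = "CGTACGG"), k = 4, enforce_min_k = FALSE)
  cand <- find_overlapping_reads(idx, "TTACGTAC", "3p", params)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$overlap, 5)          # "CGTAC"
  expect_equal(cand$overhang, "GG")
  # contained read: no overhang, rejected
  idx2 <- build_read_index(c(rd = "TACGT"), k = 4, enforce_min_k = FALSE)
  expect_equal(nrow(find_overlapping_reads(idx2, "TTACGTAC", "3p", params)), 0)
  # overlap below threshold: rejected
  idx3 <- build_read_index(c(rd = "TACGGGG"), k = 3, enforce_min_k = FALSE)
  p3 <- walk_params(k = 3, min_overlap = 5, min_support = 1)
  expect_equal(nrow(find_overlapping_reads(idx3, "TTACGTAC", "3p", p3)), 0)
})

test_that("consensus extension applies majority vote and the tie rule", {
  params <- walk_params(k = 4, min_overlap = 4, min_support = 2)
  cands <- data.frame(read_id = c("a", "b", "c"), strand = "+",
                      shift = 0, overlap = 10, mismatches = 0,
                      overhang = c("AA", "AA", "AA"),
                      stringsAsFactors = FALSE)
  ext <- extend_once("CCCGGGTTTT", cands, "3p", params)
  expect_equal(ext$bases_added, 2)
  expect_equal(ext$contig, "CCCGGGTTTTAA")
  expect_equal(ext$support, 3)
  # 2 vs 2 tie stops before the column
  tie <- data.frame(read_id = letters[1:4], strand = "+", shift = 0,
                    overlap = 10, mismatches = 0,
                    overhang = c("A", "A", "T", "T"), stringsAsFactors = FALSE)
  ext2 <- extend_once("CCCGGGTTTT", tie, "3p", params)
  expect_equal(ext2$bases_added, 0)
  expect_true(ext2$ambiguous)
  # no candidates at all
  ext3 <- extend_once("CCCGGGTTTT", cands[0, ], "3p", params)
  expect_equal(ext3$bases_added, 0)
  expect_false(ext3$ambiguous)
})

test_that("the walk recovers a planted sequence from tiling reads", {
  truth <- "TTTTACGTACGTACAAAA"
  seed_seq <- substr(truth, 5, 14)
  reads <- make_tiling_reads(truth, 8, 2)
  idx <- build_read_index(reads, k = 4, enforce_min_k = FALSE)
  params <- walk_params(k = 4, min_overlap = 4, min_support = 1)
  w <- walk(seed_seq, idx, params)
  expect_identical(w$final, truth)
  expect_equal(unname(w$termination), c("no_new_reads", "no_new_reads"))
  expect_true(grepl(seed_seq, w$final, fixed = TRUE))
  h <- w$history
  expect_equal(sum(h$bases_added), nchar(w$final) - nchar(seed_seq))

  # reads identical to the seed only: no extension either way
  idx2 <- build_read_index(c(r = seed_seq), k = 4, enforce_min_k = FALSE)
  w2 <- walk(seed_seq, idx2, params)
  expect_identical(w2$final, seed_seq)
  expect_error(walk("AC", idx2, params), "min_overlap")
})

test_that("walks are exact on random planted transcripts and safe under noise", {
  set.seed(42)
  txs <- setNames(vapply(sample(400:1200, 6), random_dna_str, character(1)),
                  paste0("tx", 1:6))
  reads <- sim_reads(txs, depth = 10, read_len = 100, err_rate = 0, seed = 3)
  idx <- build_read_index(unclass(reads), k = 21)
  for (tid in names(txs)) {
    L <- nchar(txs[[tid]])
    sd <- substr(txs[[tid]], floor(L * 0.3), floor(L * 0.7))
    w <- walk(sd, idx)
    expect_equal(walk_identity(w$final, txs[[tid]]), 100)
    expect_true(grepl(sd, w$final, fixed = TRUE))
  }
})

test_that("raising min_support or min_overlap never lengthens the result", {
  set.seed(43)
  tx <- setNames(random_dna_str(800), "tx")
  reads <- sim_reads(tx, depth = 8, read_len = 80, err_rate = 0.005, seed = 5)
  idx <- build_read_index(unclass(reads), k = 21)
  sd <- substr(tx, 300, 520)
  base_len <- nchar(walk(sd, idx, walk_params(min_support = 1))$final)
  for (ms in c(2, 4, 8)) {
    len <- nchar(walk(sd, idx, walk_params(min_support = ms))$final)
    expect_lte(len, base_len)
    base_len <- len
  }
  l1 <- nchar(walk(sd, idx, walk_params(min_overlap = 25))$final)
  l2 <- nchar(walk(sd, idx, walk_params(min_overlap = 60))$final)
  expect_lte(l2, l1)
})

test_that("the walk halts under the iteration and length caps", {
  # self-overlapping repeat reads would extend forever without caps
  reads <- setNames(rep(strrep("ACGGT", 8), 4), paste0("r", 1:4))
  idx <- build_read_index(reads, k = 10)
  params <- walk_params(k = 10, min_overlap = 12, min_support = 2,
                        max_iterations = 15, max_length = 500)
  w <- walk(strrep("ACGGT", 6), idx, params)
  expect_true(all(w$termination %in%
                    c("max_iterations", "max_length", "no_new_reads",
                      "ambiguous")))
  expect_true(nchar(w$final) <= 500 + 100)
})

test_that("unsupported seed ends are trimmed before walking", {
  set.seed(44)
  tx <- random_dna_str(600)
  reads <- sim_reads(setNames(tx, "tx"), depth = 20, read_len = 80, seed = 6)
  idx <- build_read_index(unclass(reads), k = 21)
  core <- substr(tx, 200, 400)
  junk <- random_dna_str(60)
  tr <- trim_to_read_support(paste0(junk, core), idx)
  expect_equal(tr$seq, core)
  expect_equal(tr$trimmed_5p, 60)
  clean <- trim_to_read_support(core, idx)
  expect_equal(clean$trimmed_5p + clean$trimmed_3p, 0)
})
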