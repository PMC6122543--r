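# Independent oracles used across the suite. Each is a deliberately
# simple, slow re-derivation that shares no code path with the
# implementation it checks.

# best global alignment score by plain recursive scoring (linear gaps)
oracle_global_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  memo <- matrix(NA_real_, n + 1, m + 1)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    v <- if (i == 0 && j == 0) 0
    else {
      best <- -Inf
      if (i > 0 && j > 0)
        best <- max(best, rec(i - 1, j - 1) +
                      if (ac[i] == bc[j]) match else mismatch)
      if (i > 0) best <- max(best, rec(i - 1, j) + gap)
      if (j > 0) best <- max(best, rec(i, j - 1) + gap)
      best
    }
    memo[i + 1, j + 1] <<- v
    v
  }
  rec(n, m)
}

# best local score = max global score over all substring pairs (>= 1 char)
oracle_local_score <- function(q, t, match = 1, mismatch = -1, gap = -2) {
  best <- 0
  for (qs in seq_len(nchar(q))) for (qe in qs:nchar(q)) {
    sq <- substr(q, qs, qe)
    for (ts in seq_len(nchar(t))) for (te in ts:nchar(t)) {
      st <- substr(t, ts, te)
      best <- max(best, oracle_global_score(sq, st, match, mismatch, gap))
    }
  }
  best
}

# window scores of a profile over a protein, straight double loop
oracle_window_scores <- function(profile, protein) {
  aa <- strsplit(protein, "")[[1]]
  W <- profile$width
  nw <- length(aa) - W + 1
  if (nw < 1) return(numeric(0))
  vapply(seq_len(nw), function(s) {
    tot <- 0
    for (j in seq_len(W)) {
      r <- aa[s + j - 1]
      if (r == "*") return(-Inf)
      if (r %in% rownames(profile$log_odds))
        tot <- tot + profile$log_odds[r, j]
    }
    tot
  }, numeric(1))
}

# regex-based IUPAC motif scan (overlapping matches via lookahead)
IUPAC_REGEX <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                 S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
                 B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
                 N = "[ACGT]")

iupac_regex <- function(pattern) {
  paste(IUPAC_REGEX[strsplit(toupper(pattern), "")[[1]]], collapse = "")
}

oracle_scan <- function(seq, dict, seq_id = "seq") {
  rows <- list()
  for (i in seq_len(nrow(dict))) {
    pat <- toupper(dict$pattern[i])
    rcp <- revcomp_iupac(pat)
    palin <- identical(pat, rcp)
    fwd <- gregexpr(paste0("(?=", iupac_regex(pat), ")"), seq, perl = TRUE)[[1]]
    if (fwd[1] != -1) {
      rows[[length(rows) + 1]] <- data.frame(
        seq_id = seq_id, motif = dict$name[i],
        strand = if (palin) "±" else "+", start = as.integer(fwd) - 1L,
        stringsAsFactors = FALSE)
    }
    if (!palin) {
      rev <- gregexpr(paste0("(?=", iupac_regex(rcp), ")"), seq,
                      perl = TRUE)[[1]]
      if (rev[1] != -1) {
        rows[[length(rows) + 1]] <- data.frame(
          seq_id = seq_id, motif = dict$name[i], strand = "-",
          start = as.integer(rev) - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(seq_id = character(0), motif = character(0),
                      strand = character(0), start = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res[order(res$motif, res$start, res$strand), , drop = FALSE]
}

# all six-frame ATG..stop ORFs by direct string chopping
oracle_orfs <- function(dna, min_len_aa = 1L) {
  gc <- Biostrings::GENETIC_CODE
  translate1 <- function(s) {
    codons <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    paste(ifelse(codons %in% names(gc), gc[codons], "X"), collapse = "")
  }
  out <- list()
  L <- nchar(dna)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else revcomp(dna)
    for (f in 1:3) {
      sub <- substr(s, f, f + 3 * ((L - f + 1) %/% 3) - 1)
      if (nchar(sub) < 6) next
      prot <- translate1(sub)
      pch <- strsplit(prot, "")[[1]]
      for (m in which(pch == "M")) {
        stops <- which(pch == "*")
        stops <- stops[stops > m]
        if (length(stops) == 0) next
        plen <- stops[1] - m
        if (plen >= min_len_aa)
          out[[length(out) + 1]] <- paste(pch[m:(stops[1] - 1)], collapse = "")
      }
    }
  }
  sort(unlist(out))
}

# average-linkage agglomeration by direct search over pair means
oracle_average_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best - 1e-12) { best <- h; bi <- i; bj <- j }
    }
    merged <- c(clusters[[bi]], clusters[[bj]])
    clusters <- c(clusters[-c(bi, bj)], list(merged))
    heights <- c(heights, best)
    partitions[[length(partitions) + 1]] <-
      lapply(clusters, function(x) sort(x))
  }
  list(heights = heights, partitions = partitions)
}

# minimum-evolution fit for the three unrooted 4-taxon topologies
oracle_me_topology <- function(d) {
  taxa <- rownames(d)
  splits <- list(c(1, 2), c(1, 3), c(1, 4))
  pair_rows <- utils::combn(4, 2)
  fits <- vapply(splits, function(sp) {
    a <- sp[1]; b <- sp[2]; cd <- setdiff(1:4, sp)
    # edges: ta, tb, tc, td, internal; design matrix over the 6 pairs
    X <- matrix(0, 6, 5)
    y <- numeric(6)
    leaf_edge <- integer(4)
    leaf_edge[c(a, b)] <- 1:2
    leaf_edge[cd] <- 3:4
    for (p in seq_len(6)) {
      i <- pair_rows[1, p]; j <- pair_rows[2, p]
      X[p, leaf_edge[i]] <- 1
      X[p, leaf_edge[j]] <- 1
      same_side <- (i %in% sp && j %in% sp) || (i %in% cd && j %in% cd)
      if (!same_side) X[p, 5] <- 1
      y[p] <- d[i, j]
    }
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum(beta)  # total tree length
  }, numeric(1))
  sp <- splits[[which.min(fits)]]
  # canonical form: the side not containing the first taxon
  sort(taxa[setdiff(1:4, sp)])
}

# the split containing taxon pair of an unrooted 4-taxon tree
nj4_split <- function(tree) {
  keys <- names(madswalk:::bipartition_keys(tree))
  if (length(keys) == 0) return(NULL)
  sort(strsplit(keys[1], "|", fixed = TRUE)[[1]])
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")

random_protein_str <- function(n) paste(sample(madswalk:::AA20, n,
                                               replace = TRUE), collapse = "")
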