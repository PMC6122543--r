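# Profile construction and scanning for the MADS (M) and keratin-like (K)
# domains, six-frame scaffold scanning, and type I / type II / non-MADS
# classification. Profiles are ungapped per-column log-odds matrices (bits)
# built from a seed alignment — a deliberate, exactly testable
# simplification of full profile HMMs for short, well conserved domains.

#' Build an ungapped log-odds profile from a seed alignment
#'
#' Columns with a gap fraction of 50% or more are dropped first. Each
#' retained column scores residue `a` as
#' `log2(((count_a + pseudocount) / (N + 20 * pseudocount)) / background_a)`
#' where `N` is the number of residues observed in the column. The hit
#' threshold defaults to `threshold_frac` of the minimum self-score of the
#' seed rows.
#'
#' @param seed_msa a [msa()] of aligned seed domain sequences
#' @param label domain label, e.g. "M" or "K"
#' @param pseudocount additive pseudocount weight
#' @param background named amino-acid background frequencies (default
#'   uniform 1/20)
#' @param threshold_frac fraction of the minimum seed self-score used as
#'   the bit-score threshold
#' @return object of class `domain_profile`
#' @export
build_profile <- function(seed_msa, label = "M", pseudocount = 1,
                          background = NULL, threshold_frac = 0.6) {
  m <- as.matrix(seed_msa)
  if (nrow(m) == 0) stop("empty seed alignment")
  keep <- colMeans(m == "-") < 0.5
  m <- m[, keep, drop = FALSE]
  W <- ncol(m)
  if (W < 5) stop("profile width must be >= 5")
  if (is.null(background)) background <- stats::setNames(rep(0.05, 20), AA20)
  counts <- vapply(seq_len(W), function(j) {
    col <- m[, j]
    tab <- table(factor(col[col %in% AA20], levels = AA20))
    as.numeric(tab)
  }, numeric(20))
  rownames(counts) <- AA20
  N <- colSums(counts)
  probs <- sweep(counts + pseudocount, 2, N + 20 * pseudocount, "/")
  log_odds <- log2(probs / background[AA20])
  self <- vapply(seq_len(nrow(m)), function(i) {
    ok <- m[i, ] %in% AA20
    sum(log_odds[cbind(match(m[i, ok], AA20), which(ok))])
  }, numeric(1))
  structure(list(label = label, width = W, log_odds = log_odds,
                 background = background, pseudocount = pseudocount,
                 bit_threshold = threshold_frac * min(self),
                 seed_self_scores = self),
            class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat(sprintf("Domain profile '%s': width %d, bit threshold %.2f\n",
              x$label, x$width, x$bit_threshold))
  invisible(x)
}

#' Consensus sequence of a profile
#' @param profile a `domain_profile`
#' @export
profile_consensus <- function(profile) {
  paste(AA20[apply(profile$log_odds, 2, which.max)], collapse = "")
}

# score every window of a residue vector against the profile; windows
# containing a stop are invalid (-Inf); residues outside the 20-letter
# alphabet contribute 0 bits
score_windows <- function(profile, aa_chars) {
  W <- profile$width
  L <- length(aa_chars)
  nw <- L - W + 1
  if (nw < 1) return(numeric(0))
  idx <- match(aa_chars, AA20)
  contrib <- matrix(0, nrow = L, ncol = 1)
  scores <- numeric(nw)
  for (j in seq_len(W)) {
    pos <- j:(j + nw - 1)
    v <- profile$log_odds[cbind(idx[pos], j)]
    v[is.na(v)] <- 0
    scores <- scores + v
  }
  has_stop <- aa_chars == "*"
  if (any(has_stop)) {
    bad <- unique(unlist(lapply(which(has_stop), function(p)
      max(1, p - W + 1):min(nw, p))))
    scores[bad] <- -Inf
  }
  scores
}

greedy_nonoverlap <- function(starts, ends, scores) {
  ord <- order(-scores, starts)
  taken <- logical(0)
  sel <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (s in sel) {
      if (starts[i] < ends[s] && starts[s] < ends[i]) { ok <- FALSE; break }
    }
    if (ok) sel <- c(sel, i)
  }
  sort(sel)
}

empty_hits <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             frame = integer(0), score = numeric(0), domain = character(0),
             stringsAsFactors = FALSE)
}

#' Scan a protein with a domain profile
#'
#' Scores every window of profile width and reports windows at or above the
#' bit threshold, greedily pruned to a non-overlapping best-first set.
#' Coordinates are 0-based half-open residue positions; proteins shorter
#' than the profile yield an empty result.
#'
#' @param profile a `domain_profile`
#' @param protein protein sequence (single string)
#' @param id sequence identifier recorded in the hits
#' @return data.frame with columns seq_id, start, end, frame (0 for protein
#'   input), score, domain
#' @export
scan_protein <- function(profile, protein, id = "protein") {
  aa <- strsplit(protein, "")[[1]]
  scores <- score_windows(profile, aa)
  hit <- which(is.finite(scores) & scores >= profile$bit_threshold)
  if (length(hit) == 0) return(empty_hits())
  starts <- hit - 1L
  ends <- starts + profile$width
  sel <- greedy_nonoverlap(starts, ends, scores[hit])
  data.frame(seq_id = id, start = starts[sel], end = ends[sel], frame = 0L,
             score = scores[hit][sel], domain = profile$label,
             stringsAsFactors = FALSE)
}

#' Scan a DNA scaffold in all six reading frames
#'
#' Translates the scaffold in frames +1..+3 and -1..-3 (stops break
#' windows) and reports profile hits with the frame and the 0-based
#' half-open DNA coordinates of the window on the forward strand.
#'
#' @param profile a `domain_profile`
#' @param scaffold DNA sequence (single string)
#' @param id scaffold identifier
#' @return data.frame as in [scan_protein()] with `frame` in -3..-1, +1..+3
#'   and DNA coordinates
#' @export
scan_scaffold_sixframe <- function(profile, scaffold, id = "scaffold") {
  L <- nchar(scaffold)
  if (L < 3 * profile$width) return(empty_hits())
  out <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) scaffold else revcomp(scaffold)
    for (f in 1:3) {
      sub_len <- 3 * ((L - f + 1) %/% 3)
      if (sub_len < 3 * profile$width) next
      prot <- translate_cds(substr(s, f, f + sub_len - 1))
      hits <- scan_protein(profile, prot, id = id)
      if (nrow(hits) == 0) next
      dna_start <- (f - 1L) + 3L * hits$start
      dna_end <- (f - 1L) + 3L * hits$end
      if (strand == -1L) {
        tmp <- L - dna_end
        dna_end <- L - dna_start
        dna_start <- tmp
      }
      hits$start <- dna_start
      hits$end <- dna_end
      hits$frame <- strand * f
      out[[length(out) + 1]] <- hits
    }
  }
  if (length(out) == 0) return(empty_hits())
  res <- do.call(rbind, out)
  res[order(res$start, res$frame), , drop = FALSE]
}

#' Classify a protein from its domain hits
#'
#' M and K hits together give type II (MIKC architecture); an M hit without
#' K gives type I; no M hit marks a non-MADS (pseudogene candidate).
#'
#' @param m_hits,k_hits hit data.frames from [scan_protein()] for the same
#'   protein
#' @return list with `type` ("type_II", "type_I" or "non_MADS"), `has_M`,
#'   `has_K`
#' @export
classify_gene <- function(m_hits, k_hits) {
  has_M <- nrow(m_hits) > 0
  has_K <- nrow(k_hits) > 0
  type <- if (has_M && has_K) "type_II" else if (has_M) "type_I" else "non_MADS"
  list(type = type, has_M = has_M, has_K = has_K)
}

#' Classify a set of proteins with M and K profiles
#' @param proteins named character vector of protein sequences
#' @param m_profile,k_profile `domain_profile`s for the M and K domains
#' @return data.frame with columns id, has_M, has_K, type
#' @export
classify_proteins <- function(proteins, m_profile, k_profile) {
  res <- lapply(names(proteins), function(id) {
    cl <- classify_gene(scan_protein(m_profile, proteins[[id]], id),
                        scan_protein(k_profile, proteins[[id]], id))
    data.frame(id = id, has_M = cl$has_M, has_K = cl$has_K, type = cl$type,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Rule-based family de-duplication
#'
#' Drops identical proteins and proteins that are exact sub-sequences of a
#' longer family member (rule-based replacement for manual curation of
#' redundant entries).
#'
#' @param proteins named character vector
#' @return named character vector of retained proteins
#' @export
dedupe_family <- function(proteins) {
  ord <- order(-nchar(proteins), names(proteins))
  kept <- character(0)
  keep_names <- character(0)
  for (i in ord) {
    p <- proteins[[i]]
    if (any(vapply(kept, function(k) grepl(p, k, fixed = TRUE), logical(1)))) next
    kept <- c(kept, p)
    keep_names <- c(keep_names, names(proteins)[i])
  }
  proteins[names(proteins) %in% keep_names]
}

#' Serialize / load a domain profile as TSV
#'
#' A small header block (key-value lines starting with `#`) followed by the
#' W x 20 log-odds matrix.
#' @param profile a `domain_profile`
#' @param path file path
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# label\t%s", profile$label),
               sprintf("# width\t%d", profile$width),
               sprintf("# pseudocount\t%g", profile$pseudocount),
               sprintf("# bit_threshold\t%.10g", profile$bit_threshold),
               paste(c("pos", AA20), collapse = "\t")), con)
  for (j in seq_len(profile$width)) {
    writeLines(paste(c(j, sprintf("%.10g", profile$log_odds[, j])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), "\t"))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  body <- utils::read.delim(text = lines[!grepl("^#", lines)],
                            check.names = FALSE)
  lo <- t(as.matrix(body[, AA20]))
  rownames(lo) <- AA20
  structure(list(label = meta[["label"]], width = as.integer(meta[["width"]]),
                 log_odds = lo,
                 background = stats::setNames(rep(0.05, 20), AA20),
                 pseudocount = as.numeric(meta[["pseudocount"]]),
                 bit_threshold = as.numeric(meta[["bit_threshold"]]),
                 seed_self_scores = NULL),
            class = "domain_profile")
}

#' Load the bundled synthetic seed alignment for a domain
#'
#' The package ships small synthetic seed alignments for the M and K
#' domains (invented consensus sequences with per-column noise), used both
#' by the profile builder and by the synthetic-data generator so that
#' planted domains are guaranteed detectable.
#' @param domain "M" or "K"
#' @return a [msa()]
#' @export
seed_alignment <- function(domain = c("M", "K")) {
  domain <- match.arg(domain)
  f <- system.file("extdata",
                   sprintf("%s_domain_seed_synthetic.fasta", tolower(domain)),
                   package = "madswalk", mustWork = TRUE)
  read_msa(f, type = "AA")
}

#' Build the default M and K profiles from the bundled seed alignments
#' @param threshold_frac passed to [build_profile()]
#' @return list with elements `M` and `K`
#' @export
default_profiles <- function(threshold_frac = 0.6) {
  list(M = build_profile(seed_alignment("M"), label = "M",
                         threshold_frac = threshold_frac),
       K = build_profile(seed_alignment("K"), label = "K",
                         threshold_frac = threshold_frac))
}
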