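# Iterative extension of an incomplete transcript sequence with optimally
# aligned short reads ("read walking"): a k-mer read index, ungapped anchor
# alignment of candidate reads against the contig terminus, majority-vote
# consensus extension, and the outer loop that alternates 5' and 3' rounds
# until no end can be extended further.

#' Walk parameters
#'
#' Free parameters of the extension loop. Defaults are chosen so that
#' error-free recovery is provable and noisy recovery robust; all are
#' configurable.
#'
#' @param k k-mer length for the read index (nt)
#' @param min_overlap minimum ungapped overlap between a read and the
#'   contig terminus (nt); must be >= k
#' @param max_mismatch_rate maximum fraction of mismatches in the overlap
#' @param min_support minimum number of reads supporting each appended
#'   consensus column
#' @param max_iterations cap on extension rounds per walk
#' @param max_length cap on the final contig length (nt)
#' @return list of class `walk_params`
#' @export
walk_params <- function(k = 21L, min_overlap = 31L, max_mismatch_rate = 0.05,
                        min_support = 2L, max_iterations = 200L,
                        max_length = 20000L) {
  if (min_overlap < k) stop("min_overlap must be >= k")
  if (max_mismatch_rate < 0 || max_mismatch_rate >= 0.5)
    stop("max_mismatch_rate must be in [0, 0.5)")
  if (min_support < 1) stop("min_support must be >= 1")
  structure(list(k = as.integer(k), min_overlap = as.integer(min_overlap),
                 max_mismatch_rate = max_mismatch_rate,
                 min_support = as.integer(min_support),
                 max_iterations = as.integer(max_iterations),
                 max_length = as.integer(max_length)),
            class = "walk_params")
}

seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

#' Build a k-mer index over a read set
#'
#' Indexes every k-mer of every read on both strands (k-mers containing N
#' are skipped), so any read position with a valid k-mer is retrievable.
#' Small k causes posting-list blow-up; `k < 8` is rejected unless
#' `enforce_min_k = FALSE` (toy-scale inputs only).
#'
#' @param reads named character vector of read sequences
#' @param k k-mer length
#' @param enforce_min_k reject k < 8
#' @return object of class `read_index`
#' @export
build_read_index <- function(reads, k = 21L, enforce_min_k = TRUE) {
  k <- as.integer(k)
  if (k < 8 && enforce_min_k)
    stop("k < 8 leads to posting-list blow-up; pass enforce_min_k = FALSE ",
         "for toy-scale inputs")
  if (length(reads) > 0 && any(nchar(reads) < k))
    stop("all reads must be at least k nt long")
  if (is.null(names(reads)) && length(reads) > 0)
    names(reads) <- paste0("read", seq_along(reads))
  fwd <- unname(reads)
  rev <- if (length(reads)) unname(revcomp(reads)) else character(0)
  postings <- if (length(reads) == 0) {
    data.table::data.table(kmer = character(0), read = integer(0),
                           offset = integer(0), strand = character(0))
  } else {
    np <- nchar(fwd) - k + 1L
    build_strand <- function(seqs, strand) {
      ridx <- rep.int(seq_along(seqs), np)
      off <- unlist(lapply(np, seq_len), use.names = FALSE)
      km <- substring(seqs[ridx], off, off + k - 1L)
      data.table::data.table(kmer = km, read = ridx, offset = off - 1L,
                             strand = strand)
    }
    dt <- rbind(build_strand(fwd, "+"), build_strand(rev, "-"))
    dt <- dt[!grepl("N", dt$kmer, fixed = TRUE)]
    dt
  }
  data.table::setkey(postings, kmer)
  structure(list(k = k, postings = postings, reads = fwd, reads_rc = rev,
                 ids = names(reads),
                 split_fwd = strsplit(fwd, ""),
                 split_rc = strsplit(rev, "")),
            class = "read_index")
}

#' @export
print.read_index <- function(x, ...) {
  cat(sprintf("Read index: %d reads, k = %d, %d postings\n",
              length(x$reads), x$k, nrow(x$postings)))
  invisible(x)
}

#' Query the index for postings of a k-mer
#' @param index a `read_index`
#' @param kmer k-mer string
#' @return data.table of postings (possibly empty)
#' @export
query_index <- function(index, kmer) {
  .q <- kmer  # avoid masking the postings column inside the join
  index$postings[data.table::J(.q), nomatch = 0L]
}

# Candidate reads for extending the 3' end of `terminus`, via shared k-mer
# anchors and ungapped verification against the terminus.
find_overlapping_3p <- function(index, terminus, params) {
  Lt <- nchar(terminus)
  kms <- seq_kmers(terminus, index$k)
  if (length(kms) == 0) return(empty_candidates())
  tk <- data.table::data.table(kmer = kms, tpos = seq_along(kms) - 1L)
  hits <- index$postings[tk, nomatch = 0L, on = "kmer", allow.cartesian = TRUE]
  if (nrow(hits) == 0) return(empty_candidates())
  hits[, shift := tpos - offset]
  cand <- unique(hits[, c("read", "strand", "shift")])
  tch <- strsplit(terminus, "")[[1]]
  out <- vector("list", nrow(cand))
  n_out <- 0L
  for (i in seq_len(nrow(cand))) {
    ridx <- cand$read[i]
    oriented <- if (cand$strand[i] == "+") index$reads[ridx] else index$reads_rc[ridx]
    rch <- if (cand$strand[i] == "+") index$split_fwd[[ridx]] else index$split_rc[[ridx]]
    rl <- length(rch)
    sh <- cand$shift[i]
    overhang_len <- (sh + rl) - Lt
    os <- max(sh, 0L)
    oe <- min(sh + rl, Lt)
    ov <- oe - os
    if (ov < params$min_overlap) next
    mism <- sum(tch[(os + 1L):oe] != rch[(os - sh + 1L):(oe - sh)])
    if (mism > params$max_mismatch_rate * ov) next
    n_out <- n_out + 1L
    out[[n_out]] <- list(read_id = index$ids[ridx], strand = cand$strand[i],
                         shift = sh, overlap = ov, mismatches = mism,
                         overhang_len = overhang_len,
                         overhang = if (overhang_len >= 1L)
                           substr(oriented, rl - overhang_len + 1L, rl)
                         else "")
  }
  if (n_out == 0L) return(empty_candidates())
  res <- data.frame(
    read_id = vapply(out[1:n_out], `[[`, character(1), "read_id"),
    strand = vapply(out[1:n_out], `[[`, character(1), "strand"),
    shift = vapply(out[1:n_out], `[[`, numeric(1), "shift"),
    overlap = vapply(out[1:n_out], `[[`, numeric(1), "overlap"),
    mismatches = vapply(out[1:n_out], `[[`, numeric(1), "mismatches"),
    overhang_len = vapply(out[1:n_out], `[[`, numeric(1), "overhang_len"),
    overhang = vapply(out[1:n_out], `[[`, character(1), "overhang"),
    stringsAsFactors = FALSE)
  # keep only each read/strand's optimal placement (longest overlap, then
  # fewest mismatches, then smallest shift); a read whose optimal placement
  # is containment offers no extension and is dropped
  res <- res[order(res$read_id, res$strand,
                   -res$overlap, res$mismatches, res$shift), , drop = FALSE]
  res <- res[!duplicated(res[, c("read_id", "strand")]), , drop = FALSE]
  res <- res[res$overhang_len >= 1L, , drop = FALSE]
  res$overhang_len <- NULL
  if (nrow(res) == 0L) return(empty_candidates())
  res[order(-res$overlap, res$mismatches, res$read_id), , drop = FALSE]
}

empty_candidates <- function() {
  data.frame(read_id = character(0), strand = character(0),
             shift = numeric(0), overlap = numeric(0),
             mismatches = numeric(0), overhang = character(0),
             stringsAsFactors = FALSE)
}

#' Find reads overlapping a contig terminus
#'
#' Returns reads that share at least one k-mer with the terminus, whose
#' ungapped anchor alignment has overlap >= `min_overlap` and mismatch rate
#' <= `max_mismatch_rate`, and that overhang beyond the contig end. Sorted
#' by overlap length, then fewer mismatches, then read id. For the 5' end
#' the overhang is reported in contig orientation (the string to prepend).
#'
#' @param index a `read_index`
#' @param terminus the last (3') or first (5') stretch of the contig
#' @param end "3p" or "5p"
#' @param params a [walk_params()]
#' @return data.frame: read_id, strand, shift, overlap, mismatches, overhang
#' @export
find_overlapping_reads <- function(index, terminus, end = c("3p", "5p"),
                                   params = walk_params()) {
  end <- match.arg(end)
  if (nchar(terminus) < params$min_overlap)
    stop("terminus shorter than min_overlap")
  if (end == "3p") return(find_overlapping_3p(index, terminus, params))
  res <- find_overlapping_3p(index, revcomp(terminus), params)
  if (nrow(res) > 0) {
    res$overhang <- unname(revcomp(res$overhang))
    res$strand <- ifelse(res$strand == "+", "-", "+")
  }
  res
}

#' One consensus extension step
#'
#' Builds a per-position majority-vote consensus over the candidate reads'
#' overhanging bases and extends the contig while each column has support
#' >= `min_support` and a strict majority (> 0.5). A strict tie stops the
#' extension at that column with reason "ambiguous".
#'
#' @param contig current contig sequence
#' @param candidates result of [find_overlapping_reads()]
#' @param end "3p" or "5p"
#' @param params a [walk_params()]
#' @return list: `contig`, `bases_added`, `support` (minimum column support
#'   over the added bases), `ambiguous` (TRUE if stopped on a tie)
#' @export
extend_once <- function(contig, candidates, end = c("3p", "5p"),
                        params = walk_params()) {
  end <- match.arg(end)
  if (nrow(candidates) == 0)
    return(list(contig = contig, bases_added = 0L, support = 0L,
                ambiguous = FALSE))
  over <- candidates$overhang
  if (end == "5p") over <- unname(revcomp(over))  # grow left-to-right internally
  och <- strsplit(over, "")
  lens <- lengths(och)
  maxl <- max(lens)
  cons <- character(0)
  min_sup <- Inf
  ambiguous <- FALSE
  for (j in seq_len(maxl)) {
    has <- lens >= j
    support <- sum(has)
    if (support < params$min_support) break
    bases <- vapply(och[has], `[[`, character(1), j)
    tab <- sort(table(bases), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) { ambiguous <- TRUE; break }
    if (tab[1] / support <= 0.5) break
    cons <- c(cons, names(tab)[1])
    min_sup <- min(min_sup, support)
  }
  if (length(cons) == 0)
    return(list(contig = contig, bases_added = 0L, support = 0L,
                ambiguous = ambiguous))
  add <- paste(cons, collapse = "")
  new_contig <- if (end == "3p") paste0(contig, add)
                else paste0(revcomp(add), contig)
  list(contig = new_contig, bases_added = length(cons),
       support = as.integer(min_sup), ambiguous = ambiguous)
}

#' Iterative read walk from a seed sequence
#'
#' Alternates 5' and 3' consensus extension rounds against the read index
#' until both ends terminate (no new reads, an ambiguous column, or the
#' iteration/length caps). Deterministic for fixed inputs.
#'
#' @param seed seed sequence (>= `min_overlap` nt)
#' @param index a `read_index`
#' @param params a [walk_params()]
#' @return object of class `walk_result`: `seed`, `final`, `history`
#'   (per-iteration data.frame), `reads_used`, `termination` (named reasons
#'   for the "5p" and "3p" ends)
#' @export
walk <- function(seed, index, params = walk_params()) {
  if (nchar(seed) < params$min_overlap)
    stop("seed shorter than min_overlap")
  contig <- seed
  active <- c("5p" = TRUE, "3p" = TRUE)
  termination <- c("5p" = NA_character_, "3p" = NA_character_)
  history <- list()
  reads_used <- character(0)
  max_rl <- if (length(index$reads)) max(nchar(index$reads)) else 0L
  iter <- 0L
  while (any(active)) {
    iter <- iter + 1L
    if (iter > params$max_iterations) {
      termination[active] <- "max_iterations"
      break
    }
    for (end in c("5p", "3p")) {
      if (!active[[end]]) next
      Lterm <- min(nchar(contig), max(max_rl, params$min_overlap))
      terminus <- if (end == "3p") substr(contig, nchar(contig) - Lterm + 1L,
                                          nchar(contig))
                  else substr(contig, 1L, Lterm)
      cands <- find_overlapping_reads(index, terminus, end, params)
      ext <- extend_once(contig, cands, end, params)
      history[[length(history) + 1]] <- data.frame(
        iteration = iter, end = end, bases_added = ext$bases_added,
        support = ext$support, stringsAsFactors = FALSE)
      if (ext$bases_added > 0) {
        contig <- ext$contig
        reads_used <- union(reads_used, cands$read_id)
        if (nchar(contig) >= params$max_length) {
          termination[active] <- "max_length"
          active[] <- FALSE
          break
        }
      } else {
        active[[end]] <- FALSE
        termination[[end]] <- if (ext$ambiguous) "ambiguous" else "no_new_reads"
      }
    }
  }
  structure(list(seed = seed, final = contig,
                 history = do.call(rbind, history),
                 reads_used = reads_used, termination = termination),
            class = "walk_result")
}

#' @export
print.walk_result <- function(x, ...) {
  cat(sprintf("Walk: %d nt seed -> %d nt final (5p: %s, 3p: %s; %d reads used)\n",
              nchar(x$seed), nchar(x$final),
              x$termination[["5p"]], x$termination[["3p"]],
              length(x$reads_used)))
  invisible(x)
}

#' Trim seed ends lacking read support
#'
#' Drops leading and trailing seed regions covered by no k-mer present in
#' the read index (e.g. mis-annotated or foreign 5'/3' sequence, which
#' would otherwise block terminus extension). Interior low-coverage gaps
#' are kept.
#'
#' @param seed seed sequence
#' @param index a `read_index`
#' @return list: `seq` (trimmed seed), `offset` (0-based trim offset),
#'   `trimmed_5p`, `trimmed_3p` (nt removed at each end)
#' @export
trim_to_read_support <- function(seed, index) {
  k <- index$k
  kms <- seq_kmers(seed, k)
  if (length(kms) == 0)
    return(list(seq = seed, offset = 0L, trimmed_5p = 0L, trimmed_3p = 0L))
  found <- unique(index$postings[data.table::J(unique(kms)), nomatch = 0L,
                                 on = "kmer"]$kmer)
  present <- kms %in% found
  if (!any(present))
    return(list(seq = seed, offset = 0L, trimmed_5p = 0L, trimmed_3p = 0L))
  first <- which(present)[1]
  last <- which(present)[length(which(present))]
  from <- first                 # 1-based first supported base
  to <- last + k - 1L           # 1-based last supported base
  list(seq = substr(seed, from, to), offset = from - 1L,
       trimmed_5p = from - 1L, trimmed_3p = nchar(seed) - to)
}

#' Percent identity of a walked sequence against the planted truth
#'
#' Anchors the final sequence on the truth via the known seed position and
#' compares base by base over the aligned extent; bases walked beyond the
#' truth boundaries count as mismatches.
#'
#' @param final walked sequence
#' @param truth planted transcript
#' @return identity in percent (0-100)
#' @export
walk_identity <- function(final, truth) {
  # locate the best exact anchor of a central stretch of `final` in `truth`
  anchor_len <- min(nchar(final), 31L)
  mid <- max(1L, (nchar(final) - anchor_len) %/% 2L)
  anchor <- substr(final, mid, mid + anchor_len - 1L)
  p <- regexpr(anchor, truth, fixed = TRUE)
  if (p < 0) {  # fall back: try the seed-sized prefix
    p <- regexpr(substr(final, 1, anchor_len), truth, fixed = TRUE)
    mid <- 1L
    if (p < 0) return(0)
  }
  start_in_truth <- as.integer(p) - (mid - 1L)  # 1-based, may be < 1
  fch <- strsplit(final, "")[[1]]
  tpos <- seq_along(fch) + start_in_truth - 1L
  ok <- tpos >= 1 & tpos <= nchar(truth)
  tch <- strsplit(truth, "")[[1]]
  matches <- sum(fch[ok] == tch[tpos[ok]])
  100 * matches / length(fch)
}

#' Write a tabular walk report
#' @param results named list of `walk_result` objects
#' @param path output TSV path
#' @export
write_walk_report <- function(results, path) {
  rows <- lapply(names(results), function(id) {
    r <- results[[id]]
    h <- r$history
    data.frame(seed_id = id, original_len = nchar(r$seed),
               final_len = nchar(r$final),
               bases_added_5p = sum(h$bases_added[h$end == "5p"]),
               bases_added_3p = sum(h$bases_added[h$end == "3p"]),
               termination_5p = r$termination[["5p"]],
               termination_3p = r$termination[["3p"]],
               reads_used = length(r$reads_used), stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
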