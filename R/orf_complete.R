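# Turning walked transcripts into corrected protein models: ORF
# enumeration on both strands, domain-anchored ORF selection, and the
# before/after completion report.

#' Find all open reading frames
#'
#' Enumerates every ATG-initiated, stop-terminated ORF on both strands with
#' protein length >= `min_len_aa` (standard genetic code). Nested ORFs
#' sharing a stop are all reported. Coordinates are 0-based half-open on
#' the forward strand and include the stop codon.
#'
#' @param transcript DNA sequence over ACGTN
#' @param min_len_aa minimum protein length
#' @return data.frame: start, end, frame (+1..+3 / -1..-3), protein;
#'   sorted by protein length descending
#' @export
find_orfs <- function(transcript, min_len_aa = 1L) {
  L <- nchar(transcript)
  out <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) transcript else revcomp(transcript)
    for (f in 1:3) {
      sub_len <- 3L * ((L - f + 1L) %/% 3L)
      if (sub_len < 6L) next
      prot <- translate_cds(substr(s, f, f + sub_len - 1L))
      pch <- strsplit(prot, "")[[1]]
      stops <- which(pch == "*")
      starts <- which(pch == "M")
      if (length(stops) == 0 || length(starts) == 0) next
      for (m in starts) {
        nxt <- stops[stops > m]
        if (length(nxt) == 0) next
        stop_pos <- nxt[1]
        plen <- stop_pos - m
        if (plen < min_len_aa) next
        nt_start <- (f - 1L) + 3L * (m - 1L)          # 0-based on strand s
        nt_end <- (f - 1L) + 3L * stop_pos            # includes stop codon
        if (strand == -1L) {
          tmp <- L - nt_end
          nt_end <- L - nt_start
          nt_start <- tmp
        }
        out[[length(out) + 1]] <- data.frame(
          start = nt_start, end = nt_end, frame = strand * f,
          protein = substr(prot, m, stop_pos - 1L), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), protein = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(-nchar(res$protein), res$start, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Complete a gene model from a walk result
#'
#' Selects, among the ORFs of the walked sequence, the longest ORF that
#' overlaps the seed's location (forward strand, since the walk preserves
#' transcript orientation) and contains an M-domain hit, then reports
#' before/after lengths and domain flags. If no ORF qualifies, the failure
#' is recorded in the report (`reason_code = "no-orf"`), not thrown.
#'
#' @param seed_model an annotated model (list with at least `gene_id`,
#'   `protein` and `cds`; see [truncate_models()])
#' @param walk_result a [walk()] result whose seed lies within `final`
#' @param m_profile,k_profile `domain_profile`s
#' @param min_len_aa minimum ORF length considered
#' @return one-row data.frame of class `orf_report`
#' @export
complete_model <- function(seed_model, walk_result, m_profile, k_profile,
                           min_len_aa = 30L) {
  original_protein <- seed_model$protein
  before_m <- nrow(scan_protein(m_profile, original_protein)) > 0
  before_k <- nrow(scan_protein(k_profile, original_protein)) > 0
  final <- walk_result$final
  p <- regexpr(walk_result$seed, final, fixed = TRUE)
  seed_start <- if (p > 0) as.integer(p) - 1L else 0L
  seed_end <- seed_start + nchar(walk_result$seed)
  orfs <- find_orfs(final, min_len_aa = min_len_aa)
  ok <- orfs$frame > 0 & orfs$start < seed_end & orfs$end > seed_start
  orfs <- orfs[ok, , drop = FALSE]
  has_m <- vapply(orfs$protein, function(pr)
    nrow(scan_protein(m_profile, pr)) > 0, logical(1))
  orfs <- orfs[has_m, , drop = FALSE]
  if (nrow(orfs) == 0) {
    rep <- data.frame(gene_id = seed_model$gene_id,
                      reason_code = "no-orf",
                      original_len_aa = nchar(original_protein),
                      corrected_len_aa = NA_integer_, frame = NA_integer_,
                      has_M_before = before_m, has_K_before = before_k,
                      has_M_after = NA, has_K_after = NA,
                      corrected_protein = NA_character_,
                      corrected_cds = NA_character_,
                      stringsAsFactors = FALSE)
    class(rep) <- c("orf_report", "data.frame")
    return(rep)
  }
  best <- orfs[1, ]  # already sorted by length descending
  prot <- best$protein
  rep <- data.frame(gene_id = seed_model$gene_id,
                    reason_code = if (!is.null(seed_model$reason))
                      seed_model$reason else "",
                    original_len_aa = nchar(original_protein),
                    corrected_len_aa = nchar(prot),
                    frame = best$frame,
                    has_M_before = before_m, has_K_before = before_k,
                    has_M_after = nrow(scan_protein(m_profile, prot)) > 0,
                    has_K_after = nrow(scan_protein(k_profile, prot)) > 0,
                    corrected_protein = prot,
                    corrected_cds = substr(final, best$start + 1L, best$end),
                    stringsAsFactors = FALSE)
  class(rep) <- c("orf_report", "data.frame")
  rep
}

#' Correct a set of annotated gene models against a read set
#'
#' The full replenishment pipeline for each model: trim seed ends without
#' read support, walk against the read index, and select the corrected
#' domain-anchored ORF.
#'
#' @param models list of annotated models (see [truncate_models()])
#' @param index a `read_index` (or reads, see `reads`)
#' @param m_profile,k_profile `domain_profile`s
#' @param params a [walk_params()]
#' @return data.frame with one [complete_model()] row per model plus
#'   trimming/walk bookkeeping columns
#' @export
correct_models <- function(models, index, m_profile, k_profile,
                           params = walk_params()) {
  rows <- lapply(models, function(mod) {
    tr <- trim_to_read_support(mod$cds, index)
    seed <- tr$seq
    if (nchar(seed) < params$min_overlap) seed <- mod$cds
    w <- walk(seed, index, params)
    rep <- complete_model(mod, w, m_profile, k_profile)
    rep$trimmed_5p <- tr$trimmed_5p
    rep$trimmed_3p <- tr$trimmed_3p
    rep$walked_len <- nchar(w$final)
    rep
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write an ORF completion report as TSV
#' @param report data.frame from [correct_models()]
#' @param path output path
#' @export
write_orf_report <- function(report, path) {
  cols <- setdiff(names(report), c("corrected_protein", "corrected_cds"))
  utils::write.table(report[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
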