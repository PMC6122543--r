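# Enumeration of cis-regulatory elements in promoter and intron sequences
# with an IUPAC degenerate-motif dictionary, and category-level summaries.
# Degenerate matching goes through Biostrings; the palindromic-motif
# convention (a pattern equal to its own IUPAC reverse complement is
# reported once per position with strand "±") is handled here.

IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                H = "D", V = "B", N = "N")

#' Reverse complement of an IUPAC degenerate pattern
#' @param pattern IUPAC string
#' @export
revcomp_iupac <- function(pattern) {
  ch <- rev(strsplit(toupper(pattern), "")[[1]])
  paste(IUPAC_COMP[ch], collapse = "")
}

#' Is a degenerate pattern its own reverse complement?
#' @param pattern IUPAC string
#' @export
is_palindromic_iupac <- function(pattern) {
  identical(toupper(pattern), revcomp_iupac(pattern))
}

#' Load a cis-element dictionary
#'
#' Reads a TSV with columns `name`, `pattern` (IUPAC), `category`. With no
#' path, loads the dictionary bundled with the package (curated consensus
#' patterns for commonly reported plant promoter elements across nine
#' functional categories; the consensus strings are configuration data).
#'
#' @param path optional TSV path
#' @return data.frame of class `motif_dict`
#' @export
load_cis_dictionary <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cis_elements.tsv", package = "madswalk",
                        mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_motif_dict(d)
}

#' Validate a motif dictionary data.frame
#' @param d data.frame with name, pattern, category columns
#' @export
validate_motif_dict <- function(d) {
  stopifnot(all(c("name", "pattern", "category") %in% names(d)))
  if (anyDuplicated(d$name)) stop("motif names must be unique")
  d$pattern <- toupper(d$pattern)
  bad <- !grepl(sprintf("^[%s]+$", paste(names(IUPAC_COMP), collapse = "")),
                d$pattern)
  if (any(bad))
    stop("invalid IUPAC letter in pattern(s): ",
         paste(d$name[bad], collapse = ", "))
  class(d) <- c("motif_dict", "data.frame")
  d
}

empty_motif_hits <- function() {
  data.frame(seq_id = character(0), region = character(0),
             motif = character(0), strand = character(0),
             start = integer(0), match = character(0),
             stringsAsFactors = FALSE)
}

#' Scan a sequence for degenerate motif matches
#'
#' Reports every match position of every dictionary motif. Non-palindromic
#' motifs are searched on both strands when `both_strands` is TRUE (a
#' reverse-strand hit is recorded at its forward-strand 0-based start, with
#' the matched substring given in pattern orientation). Palindromic motifs
#' are reported once per position with strand `"±"`.
#'
#' @param seq DNA sequence (single string)
#' @param motifs a `motif_dict`
#' @param both_strands scan the reverse strand as well
#' @param seq_id identifier recorded in the output
#' @param region region tag ("promoter" or "intron")
#' @return data.frame: seq_id, region, motif, strand, start, match
#' @export
scan_motifs <- function(seq, motifs, both_strands = TRUE,
                        seq_id = "seq", region = "promoter") {
  motifs <- validate_motif_dict(as.data.frame(motifs))
  if (nrow(motifs) == 0 || nchar(seq) == 0) return(empty_motif_hits())
  subject <- Biostrings::DNAString(seq)
  rows <- list()
  for (i in seq_len(nrow(motifs))) {
    pat <- motifs$pattern[i]
    palin <- is_palindromic_iupac(pat)
    fwd <- Biostrings::matchPattern(pat, subject,
                                    fixed = c(pattern = FALSE, subject = TRUE))
    if (length(fwd) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        seq_id = seq_id, region = region, motif = motifs$name[i],
        strand = if (palin) "±" else "+",
        start = Biostrings::start(fwd) - 1L,
        match = as.character(fwd), stringsAsFactors = FALSE)
    }
    if (both_strands && !palin) {
      rcp <- revcomp_iupac(pat)
      rev <- Biostrings::matchPattern(rcp, subject,
                                      fixed = c(pattern = FALSE, subject = TRUE))
      if (length(rev) > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          seq_id = seq_id, region = region, motif = motifs$name[i],
          strand = "-", start = Biostrings::start(rev) - 1L,
          match = unname(revcomp(as.character(rev))), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty_motif_hits())
  res <- do.call(rbind, rows)
  res[order(res$motif, res$start, res$strand), , drop = FALSE]
}

#' Extract the promoter upstream of the translational start
#'
#' Returns the `length` nucleotides immediately 5' of the start codon on
#' the coding strand (reverse-complemented for minus-strand genes),
#' truncated without error at scaffold edges.
#'
#' @param gene a gene model (see [gen_gene_family()]) with `strand` and the
#'   genomic CDS interval
#' @param scaffold the scaffold sequence (single string)
#' @param length promoter length in nt (default 1500)
#' @return single string with attributes `truncated` and `actual_length`
#' @export
extract_promoter <- function(gene, scaffold, length = 1500L) {
  if (is.null(gene$cds_genomic)) stop("gene model lacks a start codon coordinate")
  L <- nchar(scaffold)
  if (gene$strand == "+") {
    s <- gene$cds_genomic[1]  # 0-based position of the A of ATG
    from <- max(s - length, 0L)
    seq <- substr(scaffold, from + 1L, s)
  } else {
    e <- gene$cds_genomic[2]  # half-open end; ATG occupies [e-3, e)
    to <- min(e + length, L)
    seq <- revcomp(substr(scaffold, e + 1L, to))
  }
  attr(seq, "actual_length") <- nchar(seq)
  attr(seq, "truncated") <- nchar(seq) < length
  seq
}

#' Intron sequences of a gene model
#'
#' Introns are the exon complement within the gene span, reported on the
#' coding strand in transcript order.
#' @param gene a gene model
#' @param scaffold the scaffold sequence
#' @return character vector of intron sequences (possibly empty)
#' @export
extract_introns <- function(gene, scaffold) {
  ex <- gene$exons
  if (nrow(ex) < 2) return(character(0))
  ex <- ex[order(ex[, 1]), , drop = FALSE]
  introns <- vapply(seq_len(nrow(ex) - 1), function(i)
    substr(scaffold, ex[i, 2] + 1L, ex[i + 1, 1]), character(1))
  if (gene$strand == "-") introns <- rev(revcomp(introns))
  introns
}

#' Summarize motif hits by functional category
#'
#' @param hits a motif hit table (rows from [scan_motifs()], possibly from
#'   several sequences concatenated with `rbind`)
#' @param motifs the `motif_dict` used for scanning
#' @return list with `category_summary` (category, count, proportion over
#'   non-empty categories) and `per_gene` (seq_id x motif counts)
#' @export
summarize_categories <- function(hits, motifs) {
  motifs <- validate_motif_dict(as.data.frame(motifs))
  unknown <- setdiff(unique(hits$motif), motifs$name)
  if (length(unknown) > 0)
    stop("motif(s) not in dictionary: ", paste(unknown, collapse = ", "))
  cat_of <- stats::setNames(motifs$category, motifs$name)
  if (nrow(hits) == 0) {
    return(list(category_summary = data.frame(category = character(0),
                                              count = integer(0),
                                              proportion = numeric(0)),
                per_gene = data.frame(seq_id = character(0),
                                      motif = character(0),
                                      count = integer(0))))
  }
  categ <- cat_of[hits$motif]
  tab <- table(categ)
  summary <- data.frame(category = names(tab), count = as.integer(tab),
                        proportion = as.numeric(tab) / sum(tab),
                        stringsAsFactors = FALSE)
  summary <- summary[order(-summary$count, summary$category), ]
  rownames(summary) <- NULL
  pg <- as.data.frame(table(seq_id = hits$seq_id, motif = hits$motif),
                      stringsAsFactors = FALSE)
  names(pg)[3] <- "count"
  pg <- pg[pg$count > 0, ]
  pg <- pg[order(pg$seq_id, pg$motif), ]
  rownames(pg) <- NULL
  list(category_summary = summary, per_gene = pg)
}
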