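# Shared sequence utilities: alphabets, reverse complement, translation,
# FASTA/FASTQ I/O and the lightweight multiple-alignment container used by
# the alignment, profile and phylogeny stages.

DNA_BASES <- c("A", "C", "G", "T")

#' Standard 20 amino acids (Biostrings ordering)
#' @keywords internal
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Evaluate an expression under a fixed RNG seed
#'
#' Restores the caller's RNG state afterwards so generators are
#' byte-deterministic without side effects on the session.
#' @param seed integer seed
#' @param code expression to evaluate
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences
#' @return character vector, names preserved
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Translate coding sequences with the standard genetic code
#'
#' Trailing bases that do not fill a codon are ignored; ambiguous codons
#' translate to X and stops to `*`.
#' @param x character vector of DNA sequences
#' @return character vector of protein sequences
#' @export
translate_cds <- function(x) {
  out <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAStringSet(x), if.fuzzy.codon = "solve", no.init.codon = TRUE)))
  names(out) <- names(x)
  out
}

guess_alphabet <- function(x) {
  ch <- unique(strsplit(toupper(gsub("-", "", x)), "")[[1]])
  if (all(ch %in% c(DNA_BASES, "N"))) "DNA" else "AA"
}

#' Read/write FASTA
#'
#' Thin wrappers over Biostrings returning plain named character vectors,
#' the currency of the pipeline.
#' @param path file path
#' @param x named character vector of sequences
#' @param type "DNA" or "AA"
#' @return `read_fasta`: named character vector
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  ss <- if (type == "DNA") Biostrings::readDNAStringSet(path)
        else Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- names(ss)
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  ss <- if (type == "DNA") Biostrings::DNAStringSet(x) else Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Write short reads as FASTQ
#' @param reads named character vector of read sequences
#' @param path output path
#' @param qualities character vector of quality strings (recycled constant
#'   placeholder if NULL)
#' @export
write_fastq <- function(reads, path, qualities = NULL) {
  ss <- Biostrings::DNAStringSet(reads)
  if (is.null(qualities)) qualities <- vapply(nchar(reads), function(n)
    strrep("?", n), character(1))
  q <- Biostrings::BStringSet(qualities)
  Biostrings::writeXStringSet(ss, filepath = path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read FASTQ into a named character vector
#' @param path file path
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(ss)
  names(out) <- sub(" .*$", "", names(ss))
  out
}

#' Multiple sequence alignment container
#'
#' A named character vector of equal-width gapped strings with class
#' `mads_msa`. Row order is meaningful and preserved by every operation.
#' @param x named character vector of aligned (gapped) sequences
#' @return object of class `mads_msa`
#' @export
msa <- function(x) {
  if (length(x) == 0) stop("empty alignment")
  w <- unique(nchar(x))
  if (length(w) != 1) stop("aligned rows must have equal width")
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  structure(x, class = "mads_msa")
}

#' @export
as.matrix.mads_msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(unclass(x), ""))
  rownames(m) <- names(x)
  m
}

#' @export
print.mads_msa <- function(x, ...) {
  cat(sprintf("Multiple alignment: %d sequences x %d columns\n",
              length(x), nchar(x[[1]])))
  show_n <- min(length(x), 8L)
  for (i in seq_len(show_n)) {
    s <- unclass(x)[[i]]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  %-15s %s\n", names(x)[i], s))
  }
  if (length(x) > show_n) cat(sprintf("  ... %d more rows\n", length(x) - show_n))
  invisible(x)
}

#' Number of columns of an alignment
#' @param x a `mads_msa`
#' @export
msa_width <- function(x) nchar(unclass(x)[[1]])

#' Remove gaps from alignment rows
#' @param x a `mads_msa` or character vector of gapped strings
#' @return named character vector of ungapped sequences
#' @export
degap <- function(x) {
  out <- gsub("-", "", unclass(x), fixed = TRUE)
  names(out) <- names(x)
  out
}

#' Read/write aligned FASTA as an `mads_msa`
#' @param path file path
#' @param x a `mads_msa`
#' @param type "AA" or "DNA"
#' @export
read_msa <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  ss <- Biostrings::readBStringSet(path)
  out <- as.character(ss)
  names(out) <- names(ss)
  msa(out)
}

#' @rdname read_msa
#' @export
write_msa <- function(x, path, type = c("AA", "DNA")) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(unclass(x)), filepath = path)
  invisible(path)
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
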