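# Synthetic data with recorded ground truth: a planted gene family
# (scaffolds, multi-exon gene models, transcripts, proteins, clade
# labels), defective annotations mirroring the documented failure modes,
# error-bearing short reads, promoters with planted motifs, and qPCR Ct
# tables generated from known fold changes. Everything is byte
# deterministic under a fixed seed.

GENETIC_CODE_REV <- NULL  # built lazily: amino acid -> codon choices

# sample n values from lo..hi, safe when the range collapses to one value
sample_range <- function(lo, hi, n = 1L) {
  x <- seq(as.integer(lo), as.integer(hi))
  if (length(x) == 1L) rep(x, n) else sample(x, n, replace = TRUE)
}

codon_choices <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

sample_cds_for <- function(protein, choices) {
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    cc <- choices[[a]]
    cc[sample.int(length(cc), 1)]
  }, character(1))
  paste(codons, collapse = "")
}

mutate_protein <- function(protein, rate, keep_first = TRUE) {
  ch <- strsplit(protein, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (keep_first) hit <- setdiff(hit, 1L)
  for (p in hit) ch[p] <- sample(setdiff(AA20, ch[p]), 1)
  paste(ch, collapse = "")
}

TYPE_II_CLADES <- c("AG-like", "SQUA-like", "SVP-like", "TM3-like",
                    "PI-like", "AGL2-like")

#' Generate a synthetic MADS-box gene family with planted truth
#'
#' Plants `n_genes` genes, `n_typeI` of which are type I (M domain only,
#' intronless, clade "Malpha") and the rest type II with the full
#' M-I-K-C protein architecture, multi-exon structure and one gene per
#' scaffold. Planted domain instances are drawn from the bundled seed
#' alignments with per-column substitution noise so that profiles built
#' from the same seeds score them highly. Clade membership is simulated by
#' deriving members of a clade from a shared ancestor protein. Transcripts
#' carry short UTRs; the 5' UTR ends with an in-frame stop immediately
#' before the start codon, as real transcripts typically do, which anchors
#' ORF selection.
#'
#' @param n_genes total number of genes (>= 0)
#' @param n_typeI number of type I genes (0 <= n_typeI <= n_genes)
#' @param intron_len_range intron length range in nt
#' @param seed integer RNG seed
#' @param n_introns_range intron count range for type II genes
#' @param i_len length of the I (intervening) region in aa
#' @param c_len_range length range of the C-terminal region in aa
#' @param utr_len_range UTR length range in nt (each side)
#' @param domain_noise per-column substitution rate applied to planted
#'   domain instances (on top of clade-level noise)
#' @param member_noise substitution rate from clade ancestor to member
#' @param long_intron if TRUE the first type II gene gets one >= 10 kb
#'   intron (long-intron mode)
#' @return object of class `family_truth`: scaffolds, genes, transcripts,
#'   proteins, clade_labels, rng_seed
#' @export
gen_gene_family <- function(n_genes, n_typeI = 0L,
                            intron_len_range = c(80L, 400L), seed = 1L,
                            n_introns_range = c(4L, 7L), i_len = 30L,
                            c_len_range = c(35L, 85L),
                            utr_len_range = c(60L, 100L),
                            domain_noise = 0.10, member_noise = 0.05,
                            long_intron = FALSE) {
  if (n_typeI < 0 || n_typeI > n_genes)
    stop("need 0 <= n_typeI <= n_genes")
  if (intron_len_range[1] > intron_len_range[2] || intron_len_range[1] < 1)
    stop("invalid intron length range")
  empty <- structure(list(scaffolds = character(0), genes = list(),
                          transcripts = character(0), proteins = character(0),
                          clade_labels = character(0), rng_seed = seed),
                     class = "family_truth")
  if (n_genes == 0) return(empty)

  with_seed(seed, {
    choices <- codon_choices()
    m_rows <- degap(seed_alignment("M"))
    k_rows <- degap(seed_alignment("K"))
    n_typeII <- n_genes - n_typeI
    # clade plan: type II genes spread over up to six clades, type I in one
    clades_ii <- if (n_typeII > 0)
      TYPE_II_CLADES[seq_len(min(length(TYPE_II_CLADES),
                                 max(1, ceiling(n_typeII / 7))))]
    else character(0)
    gene_clades <- c(rep_len(clades_ii, n_typeII), rep("Malpha", n_typeI))
    gene_types <- c(rep("type_II", n_typeII), rep("type_I", n_typeI))

    # one ancestor protein per clade
    ancestors <- list()
    for (cl in unique(gene_clades)) {
      m_dom <- mutate_protein(sample(m_rows, 1), domain_noise)
      if (cl == "Malpha") {
        tail_len <- sample_range(60L, 110L)
        prot <- paste0(m_dom, random_protein(tail_len))
        spans <- list(M = c(0L, nchar(m_dom)), K = NULL)
      } else {
        k_dom <- mutate_protein(sample(k_rows, 1), domain_noise,
                                keep_first = FALSE)
        i_reg <- random_protein(i_len)
        c_reg <- random_protein(sample_range(c_len_range[1], c_len_range[2]))
        prot <- paste0(m_dom, i_reg, k_dom, c_reg)
        spans <- list(M = c(0L, nchar(m_dom)),
                      K = c(nchar(m_dom) + i_len,
                            nchar(m_dom) + i_len + nchar(k_dom)))
      }
      ancestors[[cl]] <- list(protein = prot, spans = spans)
    }

    scaffolds <- character(n_genes)
    scaffold_ids <- sprintf("scaffold_%03d", seq_len(n_genes))
    genes <- vector("list", n_genes)
    transcripts <- character(n_genes)
    proteins <- character(n_genes)
    gene_ids <- sprintf("PeM%03d", seq_len(n_genes))

    for (g in seq_len(n_genes)) {
      cl <- gene_clades[g]
      anc <- ancestors[[cl]]
      protein <- mutate_protein(anc$protein, member_noise)
      cds <- sample_cds_for(protein, choices)
      stop_codon <- sample(c("TAA", "TAG", "TGA"), 1)
      cds <- paste0(cds, stop_codon)

      utr5_len <- sample_range(utr_len_range[1], utr_len_range[2])
      utr3_len <- sample_range(utr_len_range[1], utr_len_range[2])
      utr5 <- paste0(random_dna(utr5_len - 3L), "TAA")  # in-frame stop at -1
      utr3 <- random_dna(utr3_len)
      transcript <- paste0(utr5, cds, utr3)
      tx_len <- nchar(transcript)
      cds_tx <- c(utr5_len, utr5_len + nchar(cds))  # 0-based half-open

      # exon structure on the transcript
      if (gene_types[g] == "type_I") {
        n_introns <- 0L
      } else {
        n_introns <- sample_range(n_introns_range[1], n_introns_range[2])
      }
      # keep the M-domain region within the first exon so its genomic frame
      # is intact; splits go after utr5 + M domain
      min_split <- utr5_len + 3L * (anc$spans$M[2] + 2L)
      if (n_introns > 0 && tx_len - min_split > 30L * n_introns) {
        splits <- sort(sample(seq(min_split, tx_len - 20L), n_introns))
        # enforce a minimal exon length of 15 nt
        splits <- splits[c(TRUE, diff(splits) >= 15L)]
      } else splits <- integer(0)
      bounds <- c(0L, splits, tx_len)
      exon_tx <- cbind(bounds[-length(bounds)], bounds[-1])
      intron_lens <- if (nrow(exon_tx) > 1) {
        il <- sample_range(intron_len_range[1], intron_len_range[2],
                           nrow(exon_tx) - 1)
        if (long_intron && g == 1) il[1] <- 10000L + sample(0:500, 1)
        il
      } else integer(0)

      # assemble the plus-strand locus
      pieces <- character(0)
      exon_genomic_plus <- matrix(0L, nrow = nrow(exon_tx), ncol = 2)
      pos <- 0L
      for (e in seq_len(nrow(exon_tx))) {
        ex_seq <- substr(transcript, exon_tx[e, 1] + 1L, exon_tx[e, 2])
        exon_genomic_plus[e, ] <- c(pos, pos + nchar(ex_seq))
        pieces <- c(pieces, ex_seq)
        pos <- pos + nchar(ex_seq)
        if (e < nrow(exon_tx)) {
          pieces <- c(pieces, random_dna(intron_lens[e]))
          pos <- pos + intron_lens[e]
        }
      }
      locus_plus <- paste(pieces, collapse = "")
      up_len <- 2000L
      down_len <- 500L
      flank_up <- random_dna(up_len)
      flank_down <- random_dna(down_len)
      strand <- sample(c("+", "-"), 1)
      region_plus <- paste0(flank_up, locus_plus, flank_down)
      Lr <- nchar(region_plus)
      if (strand == "+") {
        scaffold <- region_plus
        exons <- exon_genomic_plus + up_len
      } else {
        scaffold <- revcomp(region_plus)
        ex <- exon_genomic_plus + up_len
        exons <- cbind(Lr - ex[, 2], Lr - ex[, 1])
        exons <- exons[order(exons[, 1]), , drop = FALSE]
      }
      # genomic CDS interval (positions of first base of ATG / end of stop)
      cds_plus <- tx_to_plus_interval(exon_tx, exon_genomic_plus, cds_tx) + up_len
      cds_genomic <- if (strand == "+") cds_plus
                     else c(Lr - cds_plus[2], Lr - cds_plus[1])

      genes[[g]] <- structure(list(
        gene_id = gene_ids[g], scaffold = scaffold_ids[g], strand = strand,
        exons = exons, cds_tx = cds_tx, cds_genomic = cds_genomic,
        cds = cds, transcript = transcript, protein = protein,
        type = gene_types[g], clade = cl,
        m_span = anc$spans$M, k_span = anc$spans$K,
        n_introns = nrow(exon_tx) - 1L), class = "gene_model")
      scaffolds[g] <- scaffold
      transcripts[g] <- transcript
      proteins[g] <- protein
    }
    names(scaffolds) <- scaffold_ids
    names(genes) <- gene_ids
    names(transcripts) <- gene_ids
    names(proteins) <- gene_ids
    structure(list(scaffolds = scaffolds, genes = genes,
                   transcripts = transcripts, proteins = proteins,
                   clade_labels = stats::setNames(gene_clades, gene_ids),
                   rng_seed = seed),
              class = "family_truth")
  })
}

# map a transcript interval (0-based half-open, contiguous in spliced
# coordinates) to the covering plus-strand genomic interval
tx_to_plus_interval <- function(exon_tx, exon_plus, interval) {
  map_pos <- function(tp) {  # transcript position -> plus position
    for (e in seq_len(nrow(exon_tx))) {
      if (tp >= exon_tx[e, 1] && tp < exon_tx[e, 2])
        return(exon_plus[e, 1] + (tp - exon_tx[e, 1]))
    }
    stop("transcript position out of range")
  }
  c(map_pos(interval[1]), map_pos(interval[2] - 1L) + 1L)
}

#' @export
print.family_truth <- function(x, ...) {
  cat(sprintf("Synthetic gene family: %d genes (%d type I), seed %d\n",
              length(x$genes), sum(x$clade_labels == "Malpha"), x$rng_seed))
  invisible(x)
}

#' Write the family truth to disk
#'
#' Emits scaffolds, transcripts, proteins (FASTA), gene annotations (GFF3)
#' and the clade label table (TSV).
#' @param truth a `family_truth`
#' @param dir output directory (created if missing)
#' @return named vector of file paths
#' @export
write_family <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(scaffolds = file.path(dir, "scaffolds.fa"),
             transcripts = file.path(dir, "transcripts.fa"),
             proteins = file.path(dir, "proteins.fa"),
             gff3 = file.path(dir, "genes.gff3"),
             clades = file.path(dir, "clades.tsv"))
  write_fasta(truth$scaffolds, paths["scaffolds"], "DNA")
  write_fasta(truth$transcripts, paths["transcripts"], "DNA")
  write_fasta(truth$proteins, paths["proteins"], "AA")
  write_family_gff3(truth$genes, paths["gff3"])
  utils::write.table(
    data.frame(gene_id = names(truth$clade_labels),
               clade = unname(truth$clade_labels)),
    paths["clades"], sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}

#' Write gene models as GFF3
#'
#' Internal 0-based half-open coordinates are converted to the 1-based
#' inclusive GFF3 convention.
#' @param genes list of gene models
#' @param path output path
#' @export
write_family_gff3 <- function(genes, path) {
  if (length(genes) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  feats <- list()
  for (g in genes) {
    span <- c(min(g$exons[, 1]), max(g$exons[, 2]))
    feats[[length(feats) + 1]] <- data.frame(
      seqnames = g$scaffold, start = span[1] + 1L, end = span[2],
      strand = g$strand, type = "gene", ID = g$gene_id, Parent = NA,
      stringsAsFactors = FALSE)
    feats[[length(feats) + 1]] <- data.frame(
      seqnames = g$scaffold, start = span[1] + 1L, end = span[2],
      strand = g$strand, type = "mRNA", ID = paste0(g$gene_id, ".t1"),
      Parent = g$gene_id, stringsAsFactors = FALSE)
    for (e in seq_len(nrow(g$exons))) {
      feats[[length(feats) + 1]] <- data.frame(
        seqnames = g$scaffold, start = g$exons[e, 1] + 1L,
        end = g$exons[e, 2], strand = g$strand, type = "exon",
        ID = sprintf("%s.e%d", g$gene_id, e),
        Parent = paste0(g$gene_id, ".t1"), stringsAsFactors = FALSE)
    }
    feats[[length(feats) + 1]] <- data.frame(
      seqnames = g$scaffold, start = g$cds_genomic[1] + 1L,
      end = g$cds_genomic[2], strand = g$strand, type = "CDS",
      ID = paste0(g$gene_id, ".cds"), Parent = paste0(g$gene_id, ".t1"),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand, type = df$type, ID = df$ID,
    Parent = ifelse(is.na(df$Parent), NA_character_, df$Parent),
    phase = ifelse(df$type == "CDS", 0L, NA_integer_))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Plant annotation defects into a family
#'
#' Produces an annotated gene set in which the listed genes carry the
#' documented defect modes: `lack_M` (5'-most codons through part of the M
#' domain removed), `lack_K` (codons from the K domain through the stop
#' removed), `corrupt_5prime` / `corrupt_3prime` (a prefix/suffix replaced
#' by foreign random sequence). `original_len_aa` is the emitted protein
#' length. Genes without a record are passed through unchanged.
#'
#' @param truth a `family_truth`
#' @param records data.frame with columns `gene_id`, `mode`,
#'   `original_len_aa`, and optionally `reason` (free-text reason code) and
#'   `bad_aa` (foreign residues for corrupt modes, default 40)
#' @param seed RNG seed for the foreign sequence of corrupt modes
#' @return list of annotated models (class `annotated_set`); each model
#'   has gene_id, reason, mode, cds, protein, cds_genomic_annotated and
#'   original truth references
#' @export
truncate_models <- function(truth, records = NULL, seed = 1L) {
  with_seed(seed, truncate_models_impl(truth, records))
}

truncate_models_impl <- function(truth, records = NULL) {
  models <- list()
  rec_ids <- if (is.null(records)) character(0) else records$gene_id
  unknown <- setdiff(rec_ids, names(truth$genes))
  if (length(unknown) > 0)
    stop("unknown gene_id(s): ", paste(unknown, collapse = ", "))
  for (gid in names(truth$genes)) {
    g <- truth$genes[[gid]]
    true_len <- nchar(g$protein)
    if (!gid %in% rec_ids) {
      models[[gid]] <- list(gene_id = gid, reason = "complete", mode = "none",
                            cds = substr(g$cds, 1, nchar(g$cds) - 3L),
                            protein = g$protein,
                            original_len_aa = true_len,
                            true_len_aa = true_len,
                            cds_tx_annotated = g$cds_tx,
                            gene = g)
      next
    }
    r <- records[records$gene_id == gid, ][1, ]
    orig <- as.integer(r$original_len_aa)
    reason <- if (!is.null(r$reason) && !is.na(r$reason)) r$reason else r$mode
    bad_aa <- if (!is.null(r$bad_aa) && !is.na(r$bad_aa))
      as.integer(r$bad_aa) else 40L
    cds_nostop <- substr(g$cds, 1, nchar(g$cds) - 3L)
    if (r$mode %in% c("lack_M", "lack_K") && orig >= true_len)
      stop("original_len_aa must be < true protein length for lack_* modes")
    if (r$mode == "lack_K") {
      protein <- substr(g$protein, 1, orig)
      cds <- substr(cds_nostop, 1, 3L * orig)
      cds_tx_ann <- c(g$cds_tx[1], g$cds_tx[1] + 3L * orig)
    } else if (r$mode == "lack_M") {
      protein <- substr(g$protein, true_len - orig + 1L, true_len)
      cds <- substr(cds_nostop, 3L * (true_len - orig) + 1L, 3L * true_len)
      cds_tx_ann <- c(g$cds_tx[1] + 3L * (true_len - orig), g$cds_tx[2])
    } else if (r$mode == "corrupt_5prime") {
      keep <- orig - bad_aa
      if (keep < 10L) stop("corrupt_5prime leaves too little true sequence")
      junk <- random_protein(bad_aa)
      protein <- paste0(junk, substr(g$protein, true_len - keep + 1L, true_len))
      cds <- paste0(sample_cds_for(junk, codon_choices()),
                    substr(cds_nostop, 3L * (true_len - keep) + 1L,
                           3L * true_len))
      cds_tx_ann <- c(g$cds_tx[1] + 3L * (true_len - keep), g$cds_tx[2])
    } else if (r$mode == "corrupt_3prime") {
      keep <- orig - bad_aa
      if (keep < 10L) stop("corrupt_3prime leaves too little true sequence")
      junk <- random_protein(bad_aa)
      protein <- paste0(substr(g$protein, 1, keep), junk)
      cds <- paste0(substr(cds_nostop, 1, 3L * keep),
                    sample_cds_for(junk, codon_choices()))
      cds_tx_ann <- c(g$cds_tx[1], g$cds_tx[1] + 3L * keep)
    } else stop("unknown mode: ", r$mode)
    stopifnot(nchar(protein) == orig)
    models[[gid]] <- list(gene_id = gid, reason = reason, mode = r$mode,
                          cds = cds, protein = protein,
                          original_len_aa = orig, true_len_aa = true_len,
                          cds_tx_annotated = cds_tx_ann, gene = g)
  }
  structure(models, class = "annotated_set")
}

# genomic interval(s) of an annotated (possibly truncated) CDS
annotated_cds_genomic <- function(model) {
  g <- model$gene
  exon_tx <- cbind(c(0L, cumsum(g$exons[, 2] - g$exons[, 1]))[seq_len(nrow(g$exons))],
                   cumsum(g$exons[, 2] - g$exons[, 1]))
  # exon order along the transcript
  ex <- g$exons
  if (g$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  tx_iv <- model$cds_tx_annotated
  out <- NULL
  pos <- 0L
  for (e in seq_len(nrow(ex))) {
    w <- ex[e, 2] - ex[e, 1]
    lo <- max(tx_iv[1] - pos, 0L)
    hi <- min(tx_iv[2] - pos, w)
    if (hi > lo) {
      if (g$strand == "+") iv <- c(ex[e, 1] + lo, ex[e, 1] + hi)
      else iv <- c(ex[e, 2] - hi, ex[e, 2] - lo)
      out <- rbind(out, iv)
    }
    pos <- pos + w
  }
  out[order(out[, 1]), , drop = FALSE]
}

#' Write an annotated (defect-bearing) gene set
#' @param set an `annotated_set` from [truncate_models()]
#' @param dir output directory
#' @return named vector of paths (protein FASTA + GFF3)
#' @export
write_annotated <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prot <- vapply(set, `[[`, character(1), "protein")
  names(prot) <- vapply(set, `[[`, character(1), "gene_id")
  p1 <- file.path(dir, "annotated_proteins.fa")
  write_fasta(prot, p1, "AA")
  genes <- lapply(set, function(m) {
    g <- m$gene
    cg <- annotated_cds_genomic(m)
    g$cds_genomic <- c(min(cg[, 1]), max(cg[, 2]))
    g
  })
  p2 <- file.path(dir, "annotated_genes.gff3")
  write_family_gff3(genes, p2)
  c(proteins = p1, gff3 = p2)
}

#' Simulate error-bearing short reads from transcripts
#'
#' Per transcript, `ceiling(depth * length / read_len)` reads are drawn
#' with uniform start positions and uniform strand; substitution errors
#' are i.i.d. at `err_rate`. Qualities are a constant placeholder.
#'
#' @param transcripts named character vector
#' @param depth fold coverage
#' @param read_len read length (nt); must not exceed the shortest
#'   transcript
#' @param err_rate substitution error probability per base
#' @param seed RNG seed
#' @return named character vector of reads (class `read_set`)
#' @export
sim_reads <- function(transcripts, depth = 10, read_len = 100L,
                      err_rate = 0, seed = 1L) {
  if (err_rate < 0 || err_rate >= 1) stop("err_rate must be in [0, 1)")
  if (length(transcripts) == 0) return(structure(character(0), class = "read_set"))
  if (read_len > min(nchar(transcripts)))
    stop("read_len exceeds the shortest transcript")
  with_seed(seed, {
    all_reads <- character(0)
    for (tid in names(transcripts)) {
      tx <- transcripts[[tid]]
      L <- nchar(tx)
      n <- ceiling(depth * L / read_len)
      starts <- sample.int(L - read_len + 1L, n, replace = TRUE)
      strands <- sample(c("+", "-"), n, replace = TRUE)
      seqs <- substring(tx, starts, starts + read_len - 1L)
      neg <- strands == "-"
      if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
      if (err_rate > 0) {
        n_err <- stats::rbinom(n, read_len, err_rate)
        for (i in which(n_err > 0)) {
          ch <- strsplit(seqs[i], "")[[1]]
          pos <- sample.int(read_len, n_err[i])
          for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
          seqs[i] <- paste(ch, collapse = "")
        }
      }
      names(seqs) <- sprintf("%s_r%04d", tid, seq_len(n))
      all_reads <- c(all_reads, seqs)
    }
    structure(all_reads, class = "read_set")
  })
}

#' Plant motif instances into random promoter sequences
#'
#' Generates `n_promoters` uniform-background promoters and plants, for
#' each motif in `plan`, the requested number of non-overlapping concrete
#' instances at recorded positions. Chance background matches are recorded
#' separately by scanning the emitted sequences and subtracting the
#' planted positions.
#'
#' @param n_promoters number of promoters
#' @param promoter_len promoter length (nt)
#' @param plan named integer vector: motif name -> instances per promoter
#' @param motifs a `motif_dict` containing every planned motif
#' @param seed RNG seed
#' @return list: `promoters` (named character), `planted` (data.frame),
#'   `background` (data.frame of unplanted scanner hits), `truth_counts`
#'   (promoter x motif planted count table)
#' @export
plant_motifs <- function(n_promoters, promoter_len = 1500L, plan = c(),
                         motifs = load_cis_dictionary(), seed = 1L) {
  motifs <- validate_motif_dict(as.data.frame(motifs))
  if (length(plan) > 0) {
    missing <- setdiff(names(plan), motifs$name)
    if (length(missing) > 0)
      stop("plan motifs absent from dictionary: ", paste(missing, collapse = ", "))
    pat_len <- stats::setNames(nchar(motifs$pattern), motifs$name)
    if (sum(unlist(plan) * pat_len[names(plan)]) > 0.5 * promoter_len)
      stop("infeasible packing: planted instances do not fit")
  }
  iupac_sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  realize <- function(pattern) {
    ch <- strsplit(pattern, "")[[1]]
    paste(vapply(ch, function(x) sample(iupac_sets[[x]], 1), character(1)),
          collapse = "")
  }
  with_seed(seed, {
    proms <- stats::setNames(
      vapply(seq_len(n_promoters), function(i) random_dna(promoter_len),
             character(1)),
      sprintf("promoter_%03d", seq_len(n_promoters)))
    planted <- list()
    for (pid in names(proms)) {
      occupied <- matrix(numeric(0), ncol = 2)
      for (mname in names(plan)) {
        pat <- motifs$pattern[motifs$name == mname]
        w <- nchar(pat)
        for (inst in seq_len(plan[[mname]])) {
          placed <- FALSE
          for (try in 1:2000) {
            s <- sample.int(promoter_len - w + 1L, 1) - 1L
            if (nrow(occupied) == 0 ||
                all(s + w <= occupied[, 1] | s >= occupied[, 2])) {
              occupied <- rbind(occupied, c(s, s + w))
              inst_seq <- realize(pat)
              proms[pid] <- paste0(substr(proms[pid], 1, s), inst_seq,
                                   substr(proms[pid], s + w + 1L,
                                          promoter_len))
              planted[[length(planted) + 1]] <- data.frame(
                seq_id = pid, motif = mname, start = s, strand = "+",
                match = inst_seq, stringsAsFactors = FALSE)
              placed <- TRUE
              break
            }
          }
          if (!placed) stop("infeasible packing: could not place ", mname)
        }
      }
    }
    planted <- if (length(planted)) do.call(rbind, planted) else
      data.frame(seq_id = character(0), motif = character(0),
                 start = integer(0), strand = character(0),
                 match = character(0), stringsAsFactors = FALSE)
    # background = scanner hits not explained by a planted instance
    hits <- do.call(rbind, lapply(names(proms), function(pid)
      scan_motifs(proms[[pid]], motifs, both_strands = TRUE, seq_id = pid)))
    if (is.null(hits)) hits <- empty_motif_hits()
    key_planted <- paste(planted$seq_id, planted$motif, planted$start)
    is_planted <- paste(hits$seq_id, hits$motif, hits$start) %in% key_planted
    background <- hits[!is_planted, , drop = FALSE]
    truth_counts <- table(factor(planted$seq_id, levels = names(proms)),
                          factor(planted$motif, levels = motifs$name))
    list(promoters = proms, planted = planted, background = background,
         truth_counts = truth_counts)
  })
}

#' Generate a qPCR Ct table from known fold changes
#'
#' Ct values follow the ddCt model: the reference gene is constant across
#' samples (plus noise); each target's Ct in a sample is its calibrator Ct
#' minus log2(fold change), plus noise. Replicates are generated
#' independently.
#'
#' @param true_folds numeric matrix of fold changes, genes x samples; the
#'   calibrator column must be 1 (it is normalized to be)
#' @param base_ct target-gene Ct in the calibrator sample (cycles)
#' @param noise_sd Gaussian noise SD (cycles)
#' @param seed RNG seed
#' @param reference_gene id of the housekeeping reference gene
#' @param ref_ct reference-gene Ct (cycles)
#' @param calibrator calibrator sample id (defaults to a column named
#'   "leaf", else the first column)
#' @param replicates replicate count per (sample, gene)
#' @return long-format data.frame (sample, gene, replicate, ct) of class
#'   `ct_table` with attributes `reference_gene` and `calibrator`
#' @export
gen_ct_table <- function(true_folds, base_ct = 24, noise_sd = 0, seed = 1L,
                         reference_gene = "NTB", ref_ct = 20,
                         calibrator = NULL, replicates = 3L) {
  if (any(true_folds <= 0)) stop("fold changes must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  samples <- colnames(true_folds)
  genes <- rownames(true_folds)
  if (is.null(calibrator))
    calibrator <- if ("leaf" %in% samples) "leaf" else samples[1]
  if (!calibrator %in% samples) stop("calibrator not among samples")
  folds <- sweep(true_folds, 1, true_folds[, calibrator], "/")
  with_seed(seed, {
    rows <- list()
    for (s in samples) {
      for (g in c(reference_gene, genes)) {
        mu <- if (g == reference_gene) ref_ct
              else base_ct - log2(folds[g, s])
        ct <- mu + stats::rnorm(replicates, 0, noise_sd)
        rows[[length(rows) + 1]] <- data.frame(
          sample = s, gene = g, replicate = seq_len(replicates), ct = ct,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    if (any(out$ct <= 0)) stop("generated Ct values must be positive; ",
                               "reduce noise_sd or raise base_ct")
    structure(out, class = c("ct_table", "data.frame"),
              reference_gene = reference_gene, calibrator = calibrator)
  })
}

#' Build the standard 17-gene defect panel
#'
#' Mirrors the documented composition of incomplete gene models in a draft
#' annotation: six genes lacking the K domain, seven lacking the M domain
#' and four with a corrupted 5' region (foreign sequence replacing the
#' true start). Applied to the first 17 type II genes of the family.
#'
#' @param truth a `family_truth` with at least 17 type II genes
#' @param seed RNG seed for the defect lengths
#' @return records data.frame suitable for [truncate_models()]
#' @export
default_truncation_panel <- function(truth, seed = 1L) {
  ids <- names(truth$clade_labels)[truth$clade_labels != "Malpha"]
  if (length(ids) < 17) stop("need at least 17 type II genes")
  ids <- ids[1:17]
  modes <- c(rep("lack_K", 6), rep("lack_M", 7), rep("corrupt_5prime", 4))
  reasons <- c(rep("Lack of K-domain", 6), rep("Lack of M-domain", 7),
               "5' region is foreign sequence", "M-domain is truncated",
               "5' region is incorrect", "5' region is incorrect")
  with_seed(seed, {
    recs <- lapply(seq_along(ids), function(i) {
      g <- truth$genes[[ids[i]]]
      true_len <- nchar(g$protein)
      m_end <- g$m_span[2]
      k_start <- g$k_span[1]
      bad_aa <- NA_integer_
      orig <- switch(modes[i],
        # keep the full M but at most a sliver of K
        lack_K = sample_range(m_end + 10L, k_start + 15L),
        # remove at least the first half of the M domain, keep K intact
        lack_M = sample_range(true_len - k_start, true_len - m_end %/% 2L),
        corrupt_5prime = {
          keep <- sample_range(true_len - k_start, true_len - m_end)
          bad_aa <- sample(30:60, 1)
          keep + bad_aa
        })
      data.frame(gene_id = ids[i], mode = modes[i],
                 original_len_aa = orig, reason = reasons[i],
                 bad_aa = bad_aa, stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
}
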