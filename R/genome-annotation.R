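# Gene models, transcript anatomy and coding-sequence translation.
#
# Coordinates are 1-based inclusive everywhere (GFF3/VCF convention); BED
# input is converted on read (see load_blacklist).

# Standard genetic code, DNA alphabet, stop rendered "*". Hand-coded on
# purpose: translation is a first-class primitive of this package and is
# cross-checked against an independent lookup table in the test suite.
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

#' Construct a genome assembly from named chromosome sequences
#'
#' @param chromosomes named character vector, one upper-case A/C/G/T string
#'   per chromosome.
#' @return a `genome_assembly`: list with `chromosomes` (sequences) and
#'   `lengths` (named integer vector).
#' @export
genome_assembly <- function(chromosomes) {
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes)))
    stop_ctx("chromosome names must be present and unique")
  if (any(grepl("[^ACGT]", chromosomes)))
    stop_ctx("chromosome sequences must contain only A/C/G/T")
  structure(list(chromosomes = chromosomes,
                 lengths = stats::setNames(nchar(chromosomes),
                                           names(chromosomes))),
            class = "genome_assembly")
}

#' Read a genome assembly from a FASTA file
#'
#' @param path FASTA file.
#' @return a [genome_assembly()].
#' @export
read_assembly <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  genome_assembly(stats::setNames(toupper(as.character(seqs)),
                                  sub("\\s.*$", "", names(seqs))))
}

#' Write a genome assembly to FASTA
#'
#' @param assembly a [genome_assembly()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(assembly, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(assembly$chromosomes), path, width = 70L)
  invisible(path)
}

new_transcript <- function(id, gene_id, chrom, strand, exons, cds) {
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop_ctx("transcript %s: overlapping exons", id)
  if (any(exons$start > exons$end) ||
      (nrow(cds) && any(cds$start > cds$end)))
    stop_ctx("transcript %s: interval start > end", id)
  structure(list(id = id, gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds = cds),
            class = "transcript")
}

new_gene_model <- function(gene_id, public_name, chrom, transcripts) {
  if (!length(transcripts)) stop_ctx("gene %s has no transcripts", gene_id)
  structure(list(gene_id = gene_id, public_name = public_name, chrom = chrom,
                 strand = transcripts[[1L]]$strand, transcripts = transcripts),
            class = "gene_model")
}

#' Total CDS length of a transcript, in bp
#' @param transcript a transcript from a gene model.
#' @return integer.
#' @export
cds_length <- function(transcript) {
  if (!nrow(transcript$cds)) return(0L)
  as.integer(sum(transcript$cds$end - transcript$cds$start + 1L))
}

#' Genomic span of a gene model
#' @param gene a gene model.
#' @return named list with `chrom`, `start`, `end` over all exons.
#' @export
gene_span <- function(gene) {
  starts <- unlist(lapply(gene$transcripts, function(t) t$exons$start))
  ends <- unlist(lapply(gene$transcripts, function(t) t$exons$end))
  list(chrom = gene$chrom, start = min(starts), end = max(ends))
}

#' Load gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features linked by `ID`/`Parent` attributes into
#' a list of gene models, preserving 1-based inclusive coordinates. An mRNA
#' whose Parent gene is absent, or an exon/CDS whose Parent mRNA is absent,
#' is a parse error naming the offending feature.
#'
#' @param gff_path path to a GFF3 file.
#' @return list of gene models.
#' @export
load_gene_models <- function(gff_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- gr$Parent   # CharacterList
  strand <- as.character(GenomicRanges::strand(gr))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr)
  end <- GenomicRanges::end(gr)

  gene_idx <- which(type == "gene")
  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  gene_ids <- ids[gene_idx]
  mrna_ids <- ids[mrna_idx]

  parent1 <- vapply(as.list(parents), function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))

  for (i in mrna_idx) {
    if (is.na(parent1[i]) || !(parent1[i] %in% gene_ids))
      stop_ctx("GFF3 parse error: mRNA '%s' has missing or unknown Parent gene",
               ids[i] %||% "<no ID>")
  }
  for (i in which(type %in% c("exon", "CDS"))) {
    if (is.na(parent1[i]) || !(parent1[i] %in% mrna_ids))
      stop_ctx("GFF3 parse error: %s feature at %s:%d-%d has missing or unknown Parent mRNA",
               type[i], chrom[i], start[i], end[i])
  }
  if (any(!strand[gene_idx] %in% c("+", "-")))
    stop_ctx("unknown strand symbol for gene feature(s): %s",
             paste(ids[gene_idx][!strand[gene_idx] %in% c("+", "-")],
                   collapse = ", "))

  models <- vector("list", length(gene_idx))
  names(models) <- gene_ids
  for (k in seq_along(gene_idx)) {
    gi <- gene_idx[k]
    gid <- ids[gi]
    tx_rows <- mrna_idx[parent1[mrna_idx] == gid]
    txs <- lapply(tx_rows, function(ti) {
      tid <- ids[ti]
      ex <- which(type == "exon" & parent1 == tid)
      cd <- which(type == "CDS" & parent1 == tid)
      if (!length(ex) && length(cd)) ex <- cd  # CDS-only annotation
      new_transcript(
        id = tid, gene_id = gid, chrom = chrom[ti], strand = strand[ti],
        exons = data.frame(start = start[ex], end = end[ex]),
        cds = data.frame(start = start[cd], end = end[cd]))
    })
    names(txs) <- ids[tx_rows]
    name <- gr$Name[gi] %||% NA_character_
    if (is.na(name)) name <- gid
    models[[k]] <- new_gene_model(gid, name, chrom[gi], txs)
  }
  models
}

#' Select a gene's longest transcript
#'
#' "Longest" is measured by total CDS length; ties are broken by
#' lexicographically smallest transcript id so that the choice is
#' deterministic.
#'
#' @param gene a gene model.
#' @return a transcript.
#' @export
longest_transcript <- function(gene) {
  lens <- vapply(gene$transcripts, cds_length, integer(1))
  ids <- vapply(gene$transcripts, function(t) t$id, character(1))
  ord <- order(-lens, ids)
  gene$transcripts[[ord[1L]]]
}

# 1-based index within the spliced CDS of a genomic position, or NA
cds_index_of <- function(transcript, pos) {
  cds <- transcript$cds
  if (!nrow(cds)) return(NA_integer_)
  seg <- which(pos >= cds$start & pos <= cds$end)
  if (!length(seg)) return(NA_integer_)
  w <- cds$end - cds$start + 1L
  if (transcript$strand == "+") {
    before <- if (seg > 1L) sum(w[seq_len(seg - 1L)]) else 0L
    as.integer(before + (pos - cds$start[seg] + 1L))
  } else {
    n <- nrow(cds)
    after <- if (seg < n) sum(w[seq(seg + 1L, n)]) else 0L
    as.integer(after + (cds$end[seg] - pos + 1L))
  }
}

# genomic positions of splice sites: first two and last two bases of each
# intron between consecutive exons
splice_positions <- function(transcript) {
  ex <- transcript$exons
  if (nrow(ex) < 2L) return(integer(0))
  out <- integer(0)
  for (i in seq_len(nrow(ex) - 1L)) {
    is <- ex$end[i] + 1L
    ie <- ex$start[i + 1L] - 1L
    if (ie < is) next
    out <- c(out, unique(pmin(pmax(c(is, is + 1L, ie - 1L, ie), is), ie)))
  }
  sort(unique(out))
}

#' Locate a genomic position within a transcript's anatomy
#'
#' Returns the region a position falls in relative to one transcript:
#' `coding_exon` (with the strand-aware 1-based index within the spliced
#' CDS), `splice_site` (the first two or last two bases of an intron),
#' `intron_interior`, `utr` (exonic but outside the CDS) or `intergenic`
#' (outside the transcript span, always a valid answer).
#'
#' @param transcript a transcript.
#' @param chrom chromosome name of the queried position.
#' @param pos 1-based genomic coordinate.
#' @return list with `region`, `transcript_id`, and `cds_index` (`NA` unless
#'   `region == "coding_exon"`).
#' @export
site_context <- function(transcript, chrom, pos) {
  stopifnot(pos >= 1)
  res <- function(region, idx = NA_integer_)
    list(region = region, transcript_id = transcript$id, cds_index = idx)
  ex <- transcript$exons
  if (chrom != transcript$chrom || pos < min(ex$start) || pos > max(ex$end))
    return(res("intergenic"))
  idx <- cds_index_of(transcript, pos)
  if (!is.na(idx)) return(res("coding_exon", idx))
  in_exon <- any(pos >= ex$start & pos <= ex$end)
  if (in_exon) return(res("utr"))
  if (pos %in% splice_positions(transcript)) return(res("splice_site"))
  res("intron_interior")
}

#' Spliced coding sequence of a transcript
#'
#' Concatenates the CDS segments in transcription order, reverse-complemented
#' for minus-strand transcripts.
#'
#' @param transcript a transcript.
#' @param assembly a [genome_assembly()] containing the transcript's
#'   chromosome.
#' @return nucleotide string.
#' @export
cds_sequence <- function(transcript, assembly) {
  seq <- assembly$chromosomes[[transcript$chrom]]
  if (is.null(seq))
    stop_ctx("chromosome %s not in assembly", transcript$chrom)
  cds <- transcript$cds
  if (any(cds$end > nchar(seq)))
    stop_ctx("transcript %s: CDS segment exceeds chromosome %s length",
             transcript$id, transcript$chrom)
  parts <- substring(seq, cds$start, cds$end)
  s <- paste(parts, collapse = "")
  if (transcript$strand == "-") reverse_complement(s) else s
}

#' Translate a coding sequence
#'
#' Standard genetic code; stop codons are rendered `"*"` and translation does
#' not terminate early (internal stops are rendered and left to the caller
#' to interpret).
#'
#' @param cds nucleotide string whose length is a multiple of 3.
#' @return protein string.
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  n <- nchar(cds)
  if (n == 0L) return("")
  if (n %% 3L != 0L)
    stop_ctx("CDS length %d is not divisible by 3", n)
  if (grepl("[^ACGT]", cds))
    stop_ctx("CDS contains non-ACGT characters")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(unname(CODON_TABLE[codons]), collapse = "")
}
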