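# Hand-built fixtures and independent oracles used across the test files.

# --- deterministic two-exon toy gene --------------------------------------
#
# 201 codons: ATG, then glutamate codons, with codon 62 = CGT (R), codon
# 191 = TGC (C), terminal TAA. Split over two exons by a 100 bp intron.
# The minus-strand twin is the exact mirror image on the reverse-complement
# chromosome, so corresponding variants must annotate identically.

toy_cds <- function() {
  codons <- rep("GAA", 201)
  codons[1] <- "ATG"
  codons[62] <- "CGT"
  codons[191] <- "TGC"
  codons[201] <- "TAA"
  paste(codons, collapse = "")
}

toy_gene_plus <- function() {
  cds <- toy_cds()                      # 603 bp
  intron <- paste0("GT", paste(rep("A", 96), collapse = ""), "AG")
  flank <- paste(rep("C", 50), collapse = "")
  chrom_seq <- paste0(flank, substr(cds, 1, 300), intron,
                      substr(cds, 301, 603), flank)
  assembly <- genome_assembly(c(chrT = chrom_seq))
  exons <- data.frame(start = c(51L, 451L), end = c(350L, 753L))
  tx <- screenmap:::new_transcript("toyg.t1", "toyg", "chrT", "+",
                                   exons, exons)
  gene <- screenmap:::new_gene_model("toyg", "toy-1", "chrT", list(tx))
  list(assembly = assembly, gene = gene, tx = tx, cds = cds)
}

toy_gene_minus <- function() {
  p <- toy_gene_plus()
  L <- nchar(p$assembly$chromosomes[["chrT"]])
  chrom_seq <- screenmap:::reverse_complement(p$assembly$chromosomes[["chrT"]])
  mirror <- function(x) L - x + 1L
  exons <- data.frame(start = mirror(p$tx$exons$end),
                      end = mirror(p$tx$exons$start))
  tx <- screenmap:::new_transcript("toyg.t1", "toyg", "chrT", "-",
                                   exons, exons)
  gene <- screenmap:::new_gene_model("toyg", "toy-1", "chrT", list(tx))
  list(assembly = genome_assembly(c(chrT = chrom_seq)), gene = gene,
       tx = tx, cds = p$cds, mirror = mirror)
}

# genomic position of a CDS index in the plus-strand toy gene
toy_plus_genomic <- function(i) if (i <= 300) 50L + i else 450L + (i - 300L)

# --- independent oracles ---------------------------------------------------

# translation via the Biostrings genetic-code table (independent lookup)
oracle_translate <- function(cds) {
  if (nchar(cds) == 0) return("")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

# exploded-coordinate site map for one transcript: enumerates every genomic
# position and assigns region labels by construction
oracle_site_map <- function(tx) {
  span <- min(tx$exons$start):max(tx$exons$end)
  region <- setNames(rep("intron_interior", length(span)),
                     as.character(span))
  for (k in seq_len(nrow(tx$exons)))
    region[as.character(tx$exons$start[k]:tx$exons$end[k])] <- "utr"
  cds_positions <- integer(0)
  for (k in seq_len(nrow(tx$cds)))
    cds_positions <- c(cds_positions, tx$cds$start[k]:tx$cds$end[k])
  cds_positions <- sort(cds_positions)
  if (tx$strand == "-") cds_positions <- rev(cds_positions)
  region[as.character(cds_positions)] <- "coding_exon"
  if (nrow(tx$exons) > 1) {
    for (k in seq_len(nrow(tx$exons) - 1)) {
      intron <- (tx$exons$end[k] + 1L):(tx$exons$start[k + 1] - 1L)
      ss <- intersect(c(intron[1:2], intron[length(intron) - 1:0]), intron)
      region[as.character(ss)] <- "splice_site"
    }
  }
  list(region = region,
       cds_index = setNames(seq_along(cds_positions),
                            as.character(cds_positions)))
}

# full-retranslation effect oracle for SNVs: apply the variant to the
# chromosome, re-extract and re-translate the whole CDS by hand, and
# classify from the protein diff
oracle_snv_effect <- function(gene, assembly, pos, alt) {
  tx <- longest_transcript(gene)
  seq <- assembly$chromosomes[[gene$chrom]]
  mut <- seq
  substr(mut, pos, pos) <- alt
  extract <- function(s) {
    parts <- substring(s, tx$cds$start, tx$cds$end)
    x <- paste(parts, collapse = "")
    if (tx$strand == "-")
      x <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    x
  }
  map <- oracle_site_map(tx)
  reg <- map$region[as.character(pos)]
  if (is.na(reg)) reg <- "intergenic"
  if (reg != "coding_exon")
    return(list(effect = if (reg == "splice_site") "splice_site"
                         else "noncoding",
                aa_change = NA_character_))
  p_ref <- oracle_translate(extract(seq))
  p_alt <- oracle_translate(extract(mut))
  if (p_ref == p_alt) {
    i <- ceiling(map$cds_index[as.character(pos)] / 3)
    aa <- substr(p_ref, i, i)
    return(list(effect = "synonymous", aa_change = paste0(aa, i, aa)))
  }
  d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])[1]
  ref_aa <- substr(p_ref, d, d)
  alt_aa <- substr(p_alt, d, d)
  eff <- if (d == 1 && ref_aa == "M") "start_loss"
         else if (alt_aa == "*") "nonsense" else "missense"
  list(effect = eff, aa_change = paste0(ref_aa, d, alt_aa))
}

# brute-force hypergeometric upper tail: P(X >= a)
oracle_hyper_tail <- function(a, K, n, N) {
  ks <- a:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# --- small helpers ---------------------------------------------------------

write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

small_sim_config <- function(seed = 7, ...) {
  simulation_config(seed = seed, n_chromosomes = 2, genes_per_chromosome = 4,
                    gene_length_bp = 900, intergenic_bp = 3000, n_groups = 4,
                    background_mutations_per_strain = 40, ...)
}

make_calls <- function(chrom, pos, ref, alt, total, altd) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             total_depth = as.integer(total), alt_depth = as.integer(altd),
             stringsAsFactors = FALSE)
}
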