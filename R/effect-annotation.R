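# Variant-effect annotation against gene models.
#
# Effect classes: missense, nonsense, splice_site, start_loss, frameshift,
# inframe_indel, synonymous, noncoding. Amino-acid numbering always uses the
# gene's longest transcript; splice-site calling considers all transcripts,
# but a coding classification from the longest transcript takes precedence
# (one mutation type per allele, as reported in mutation catalogs).

EFFECT_CLASSES <- c("missense", "nonsense", "splice_site", "start_loss",
                    "frameshift", "inframe_indel", "synonymous", "noncoding")

#' Format an amino-acid change string
#'
#' @param ref_aa single-letter reference residue (or `"*"`).
#' @param position 1-based residue index.
#' @param alt_aa single-letter alternate residue (or `"*"`).
#' @return string such as `"R62C"` or `"Q367*"`.
#' @export
format_aa_change <- function(ref_aa, position, alt_aa) {
  if (any(position < 1)) stop_ctx("residue position must be >= 1")
  ok <- c(unname(CODON_TABLE), "*")
  if (!all(c(ref_aa, alt_aa) %in% ok))
    stop_ctx("residues must be single-letter amino-acid codes or '*'")
  paste0(ref_aa, position, alt_aa)
}

#' Is an effect class a candidate (protein-affecting) class?
#'
#' Candidate classes are the protein-changing or splicing ones kept by the
#' effect filter: missense, nonsense, splice_site, start_loss, frameshift
#' and inframe_indel. Synonymous and noncoding variants are not candidates.
#'
#' @param effect character vector of effect classes.
#' @return logical vector.
#' @export
effect_is_candidate <- function(effect) {
  stopifnot(all(effect %in% EFFECT_CLASSES))
  effect %in% c("missense", "nonsense", "splice_site", "start_loss",
                "frameshift", "inframe_indel")
}

# Precompute per-gene anatomy used to classify many variants quickly.
build_annotation_index <- function(genes, assembly) {
  entries <- lapply(genes, function(g) {
    lt <- longest_transcript(g)
    sp <- sort(unique(unlist(lapply(g$transcripts, splice_positions))))
    sp_tx <- if (length(sp)) {
      vapply(sp, function(p) {
        for (t in g$transcripts) if (p %in% splice_positions(t)) return(t$id)
        NA_character_
      }, character(1))
    } else character(0)
    intr <- if (nrow(lt$exons) > 1L) {
      data.frame(start = lt$exons$end[-nrow(lt$exons)] + 1L,
                 end = lt$exons$start[-1L] - 1L)
    } else data.frame(start = integer(0), end = integer(0))
    span <- gene_span(g)
    list(gene = g, lt = lt, cds = cds_sequence(lt, assembly),
         splice_pos = sp, splice_tx = sp_tx, lt_introns = intr, span = span)
  })
  names(entries) <- vapply(genes, function(g) g$gene_id, character(1))
  spans <- do.call(rbind, lapply(entries, function(e)
    data.frame(chrom = e$span$chrom, start = e$span$start, end = e$span$end)))
  gr <- if (length(entries)) {
    GenomicRanges::GRanges(spans$chrom,
                           IRanges::IRanges(spans$start, spans$end))
  } else GenomicRanges::GRanges()
  structure(list(entries = entries, granges = gr), class = "annotation_index")
}

empty_annotation <- function() {
  data.frame(strain_id = character(0), chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0), gene_id = character(0),
             transcript_id = character(0), effect = character(0),
             aa_change = character(0), cds_index = integer(0),
             total_depth = integer(0), alt_depth = integer(0),
             stringsAsFactors = FALSE)
}

# classify one variant against one indexed gene entry; returns list
classify_against_entry <- function(entry, chrom, pos, ref, alt) {
  lt <- entry$lt
  out <- list(transcript_id = lt$id, effect = "noncoding",
              aa_change = NA_character_, cds_index = NA_integer_)
  is_snv <- nchar(ref) == 1L && nchar(alt) == 1L
  if (is_snv) {
    ctx <- site_context(lt, chrom, pos)
    if (ctx$region == "coding_exon") {
      i <- ctx$cds_index
      cds <- entry$cds
      base <- if (lt$strand == "-") complement_base(alt) else alt
      codon_i <- ((i - 1L) %/% 3L) + 1L
      cstart <- (codon_i - 1L) * 3L + 1L
      ref_codon <- substr(cds, cstart, cstart + 2L)
      off <- i - cstart + 1L
      alt_codon <- ref_codon
      substr(alt_codon, off, off) <- base
      ref_aa <- unname(CODON_TABLE[ref_codon])
      alt_aa <- unname(CODON_TABLE[alt_codon])
      out$cds_index <- i
      out$effect <- if (alt_aa == ref_aa) "synonymous"
        else if (codon_i == 1L && ref_aa == "M") "start_loss"
        else if (alt_aa == "*") "nonsense"
        else "missense"
      out$aa_change <- format_aa_change(ref_aa, codon_i, alt_aa)
    } else if (pos %in% entry$splice_pos) {
      out$effect <- "splice_site"
      out$transcript_id <- entry$splice_tx[match(pos, entry$splice_pos)]
    }
    return(out)
  }
  # indel: interval of affected reference bases
  iv <- c(pos, pos + nchar(ref) - 1L)
  olap <- function(df) nrow(df) > 0L &&
    any(iv[1L] <= df$end & iv[2L] >= df$start)
  in_cds <- olap(lt$cds)
  in_intron <- olap(entry$lt_introns)
  if (in_cds && in_intron) {
    out$effect <- "splice_site"   # indel spanning an exon-intron boundary
  } else if (in_cds) {
    shift <- abs(nchar(ref) - nchar(alt)) %% 3L
    out$effect <- if (shift != 0L) "frameshift" else "inframe_indel"
  } else if (length(entry$splice_pos) &&
             any(entry$splice_pos >= iv[1L] & entry$splice_pos <= iv[2L])) {
    out$effect <- "splice_site"
  }
  out
}

#' Annotate one variant call against gene models
#'
#' Produces one annotation per gene overlapped by the variant. The reference
#' allele is checked against the assembly; a mismatch is an error. Variants
#' overlapping no gene yield a single `noncoding` annotation with `NA`
#' gene id.
#'
#' @param call list or one-row data.frame with `chrom`, `pos`, `ref`, `alt`
#'   (and optionally depths and `strain_id`).
#' @param genes list of gene models (or a prebuilt annotation index).
#' @param assembly a [genome_assembly()].
#' @return data.frame of annotated variants.
#' @export
annotate_variant <- function(call, genes, assembly) {
  idx <- if (inherits(genes, "annotation_index")) genes
         else build_annotation_index(genes, assembly)
  calls <- as.data.frame(call, stringsAsFactors = FALSE)
  set <- list(strain_id = calls$strain_id %||% NA_character_, calls = calls)
  annotate_calls(set, idx, assembly)
}

#' Annotate all calls of a strain variant set
#'
#' @param set a [strain_variant_set()] (or list with `strain_id`, `calls`).
#' @param index annotation index from `build_annotation_index()`, or a list
#'   of gene models.
#' @param assembly a [genome_assembly()].
#' @return data.frame with one row per (call, overlapped gene).
#' @export
annotate_calls <- function(set, index, assembly) {
  if (!inherits(index, "annotation_index"))
    index <- build_annotation_index(index, assembly)
  calls <- set$calls
  n <- nrow(calls)
  if (!n) return(empty_annotation())
  strain <- if (length(set$strain_id) == 1L) set$strain_id else NA_character_

  # reference check, vectorized per chromosome
  for (ch in unique(calls$chrom)) {
    seq <- assembly$chromosomes[[ch]]
    if (is.null(seq)) stop_ctx("chromosome %s not in assembly", ch)
    sel <- which(calls$chrom == ch)
    obs <- substring(seq, calls$pos[sel],
                     calls$pos[sel] + nchar(calls$ref[sel]) - 1L)
    bad <- sel[obs != calls$ref[sel]]
    if (length(bad))
      stop_ctx("reference mismatch for strain %s at %s:%d (expected %s)",
               strain %||% "<unknown>", ch, calls$pos[bad[1L]],
               calls$ref[bad[1L]])
  }

  q <- GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(calls$pos,
                                  calls$pos + nchar(calls$ref) - 1L))
  hits <- GenomicRanges::findOverlaps(q, index$granges)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)

  rows_call <- c(qh, setdiff(seq_len(n), unique(qh)))
  rows_gene <- c(sh, rep(NA_integer_, n - length(unique(qh))))
  m <- length(rows_call)
  gene_id <- transcript_id <- aa_change <- rep(NA_character_, m)
  effect <- rep("noncoding", m)
  cds_index <- rep(NA_integer_, m)
  for (k in seq_len(m)) {
    gi <- rows_gene[k]
    if (is.na(gi)) next
    i <- rows_call[k]
    e <- index$entries[[gi]]
    cls <- classify_against_entry(e, calls$chrom[i], calls$pos[i],
                                  calls$ref[i], calls$alt[i])
    gene_id[k] <- e$gene$gene_id
    transcript_id[k] <- cls$transcript_id
    effect[k] <- cls$effect
    aa_change[k] <- cls$aa_change
    cds_index[k] <- cls$cds_index
  }
  out <- data.frame(
    strain_id = strain, chrom = calls$chrom[rows_call],
    pos = calls$pos[rows_call], ref = calls$ref[rows_call],
    alt = calls$alt[rows_call], gene_id = gene_id,
    transcript_id = transcript_id, effect = effect, aa_change = aa_change,
    cds_index = cds_index,
    total_depth = calls$total_depth[rows_call] %||% NA_integer_,
    alt_depth = calls$alt_depth[rows_call] %||% NA_integer_,
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$alt, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write annotated variants as TSV
#'
#' Columns mirror a printed mutation catalog: strain, position, alleles,
#' gene, numbering transcript, effect class and amino-acid change.
#'
#' @param annotated data.frame from [annotate_calls()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_annotated_tsv <- function(annotated, path) {
  cols <- c("strain_id", "chrom", "pos", "ref", "alt", "gene_id",
            "transcript_id", "effect", "aa_change")
  write_tsv(annotated[, cols, drop = FALSE], path)
}
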