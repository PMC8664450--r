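# Per-strain variant calls: VCF I/O, allele fractions, zygosity, blacklist.

#' Construct a per-strain variant call set
#'
#' @param strain_id strain identifier (unique within a dataset).
#' @param collection mutant-collection label (e.g. `"A"` or `"B"`).
#' @param mapped_chromosome chromosome the strain's mutation was genetically
#'   mapped to.
#' @param calls data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `total_depth`, `alt_depth` and optionally `quality`.
#' @return a `strain_variant_set`.
#' @export
strain_variant_set <- function(strain_id, collection, mapped_chromosome,
                               calls) {
  need <- c("chrom", "pos", "ref", "alt", "total_depth", "alt_depth")
  missing <- setdiff(need, names(calls))
  if (length(missing))
    stop_ctx("strain %s: calls missing column(s) %s", strain_id,
             paste(missing, collapse = ", "))
  if (!"quality" %in% names(calls))
    calls$quality <- rep(NA_real_, nrow(calls))
  bad <- which(calls$alt_depth < 0 | calls$alt_depth > calls$total_depth |
                 calls$pos < 1 | calls$ref == calls$alt)
  if (length(bad))
    stop_ctx("strain %s: invalid call at row %d (%s:%d)", strain_id, bad[1L],
             calls$chrom[bad[1L]], calls$pos[bad[1L]])
  calls <- calls[order(calls$chrom, calls$pos, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(strain_id = strain_id, collection = collection,
                 mapped_chromosome = mapped_chromosome, calls = calls),
            class = "strain_variant_set")
}

#' Read a single-strain VCF into a variant call set
#'
#' One call is produced per ALT allele; multi-allelic records are split.
#' Allele depths are taken from the per-sample `AD` field when present
#' (total depth from `DP`, else the sum of `AD`); otherwise they are derived
#' from the site-level `DP4` read-count tag. A record with neither encoding
#' is an error naming the record.
#'
#' @param path VCF file (plain or bgzipped).
#' @param strain_id strain identifier.
#' @param collection collection label.
#' @param mapped_chromosome mapped chromosome name.
#' @return a [strain_variant_set()].
#' @export
read_strain_vcf <- function(path, strain_id, collection = NA_character_,
                            mapped_chromosome = NA_character_) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fx))) fx <- t(fx)   # single-record files drop to a vector
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0L)
    return(strain_variant_set(strain_id, collection, mapped_chromosome,
                              data.frame(chrom = character(0), pos = integer(0),
                                         ref = character(0), alt = character(0),
                                         total_depth = integer(0),
                                         alt_depth = integer(0),
                                         quality = numeric(0))))
  has_gt <- ncol(vcf@gt) >= 2L
  ad <- if (has_gt) suppressWarnings(
    vcfR::extract.gt(vcf, element = "AD")[, 1L]) else rep(NA_character_, n)
  dp <- if (has_gt) suppressWarnings(
    vcfR::extract.gt(vcf, element = "DP")[, 1L]) else rep(NA_character_, n)
  info <- fix$INFO %||% rep(NA_character_, n)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    if (!is.na(ad[i])) {
      advals <- suppressWarnings(
        as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1L]]))
      total <- if (!is.na(dp[i])) as.integer(dp[i]) else sum(advals)
      alt_d <- advals[seq_along(alts) + 1L]
    } else {
      m <- regmatches(info[i], regexpr("DP4=[0-9,]+", info[i]))
      if (!length(m) || is.na(info[i]))
        stop_ctx("VCF record %s:%s in %s has no depth information (AD or DP4)",
                 fix$CHROM[i], fix$POS[i], path)
      dp4 <- as.integer(strsplit(sub("DP4=", "", m), ",")[[1L]])
      total <- sum(dp4)
      alt_d <- rep(sum(dp4[3:4]), length(alts))
    }
    rows[[i]] <- data.frame(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = fix$REF[i], alt = alts,
      total_depth = total, alt_depth = alt_d,
      quality = suppressWarnings(as.numeric(fix$QUAL[i])),
      stringsAsFactors = FALSE)
  }
  strain_variant_set(strain_id, collection, mapped_chromosome,
                     do.call(rbind, rows))
}

#' Write a strain's calls as a single-sample VCF
#'
#' Emits VCF v4.2 with `GT:AD:DP` per-sample fields; the file round-trips
#' through [read_strain_vcf()].
#'
#' @param set a [strain_variant_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_strain_vcf <- function(set, path) {
  calls <- set$calls
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=screenmap",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", set$strain_id, sep = "\t"))
  gt <- ifelse(calls$alt_depth >= calls$total_depth, "1/1", "0/1")
  sample_col <- sprintf("%s:%d,%d:%d", gt,
                        calls$total_depth - calls$alt_depth,
                        calls$alt_depth, calls$total_depth)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tGT:AD:DP\t%s",
                  calls$chrom, calls$pos, calls$ref, calls$alt,
                  ifelse(is.na(calls$quality), ".",
                         format(calls$quality, trim = TRUE)),
                  sample_col)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Alternate-allele read fraction of calls
#'
#' @param calls data.frame of calls (or a [strain_variant_set()]).
#' @return numeric vector `alt_depth / total_depth` in `[0, 1]`.
#' @export
allele_fraction <- function(calls) {
  if (inherits(calls, "strain_variant_set")) calls <- calls$calls
  if (any(calls$total_depth == 0))
    stop_ctx("allele fraction undefined at zero total depth (%s:%d)",
             calls$chrom[calls$total_depth == 0][1L],
             calls$pos[calls$total_depth == 0][1L])
  calls$alt_depth / calls$total_depth
}

#' Classify call zygosity from the allele read fraction
#'
#' A call is `heterozygous` when its alternate-allele read fraction lies
#' within the band (inclusive at both ends), `homozygous` above it and
#' `low_fraction` below it. The default band is 20%-80% of reads.
#'
#' @param calls data.frame of calls or a [strain_variant_set()].
#' @param band numeric length-2 fraction interval, default `c(0.2, 0.8)`.
#' @return character vector of labels.
#' @export
classify_zygosity <- function(calls, band = c(0.2, 0.8)) {
  if (length(band) != 2L || any(band < 0) || any(band > 1) ||
      band[1L] > band[2L])
    stop_ctx("zygosity band must be an ordered fraction interval within [0,1]")
  f <- allele_fraction(calls)
  ifelse(f > band[2L], "homozygous",
         ifelse(f < band[1L], "low_fraction", "heterozygous"))
}

#' Load a blacklist of excluded genomic positions from BED
#'
#' BED intervals (0-based half-open) are converted to 1-based inclusive and
#' overlapping intervals are merged.
#'
#' @param path BED file; `track`/`browser`/comment lines are ignored.
#' @return a `blacklist` holding a data.frame of merged intervals
#'   (`chrom`, `start`, `end`).
#' @export
load_blacklist <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  empty <- structure(list(intervals = data.frame(
    chrom = character(0), start = integer(0), end = integer(0))),
    class = "blacklist")
  if (!any(keep)) return(empty)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < 3L)
      stop_ctx("malformed BED line %d: fewer than 3 fields", idx[k])
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s)
      stop_ctx("malformed BED line %d: bad interval '%s'-'%s'",
               idx[k], f[2L], f[3L])
  }
  chrom <- vapply(fields, `[`, character(1), 1L)
  start0 <- as.integer(vapply(fields, `[`, character(1), 2L))
  end0 <- as.integer(vapply(fields, `[`, character(1), 3L))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = start0 + 1L, end = end0)))
  structure(list(intervals = data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr))),
    class = "blacklist")
}

blacklist_granges <- function(bl) {
  GenomicRanges::GRanges(bl$intervals$chrom,
                         IRanges::IRanges(bl$intervals$start,
                                          bl$intervals$end))
}

#' Remove calls at blacklisted positions
#'
#' Calls whose position lies inside any excluded interval are removed; all
#' others are preserved in order. Idempotent.
#'
#' @param set a [strain_variant_set()].
#' @param bl a [load_blacklist()] result, or `NULL` for no exclusion.
#' @return filtered [strain_variant_set()].
#' @export
apply_blacklist <- function(set, bl) {
  if (is.null(bl) || !nrow(bl$intervals)) return(set)
  calls <- set$calls
  if (!nrow(calls)) return(set)
  q <- GenomicRanges::GRanges(calls$chrom,
                              IRanges::IRanges(calls$pos, calls$pos))
  hit <- GenomicRanges::countOverlaps(q, blacklist_granges(bl)) > 0L
  set$calls <- calls[!hit, , drop = FALSE]
  rownames(set$calls) <- NULL
  set
}

#' Read a strain metadata table
#'
#' @param path TSV with columns `strain_id`, `allele_name`, `collection`,
#'   `mapped_chromosome`, `complementation_group`.
#' @return data.frame.
#' @export
read_strain_metadata <- function(path) {
  read_tsv_strict(path, c("strain_id", "allele_name", "collection",
                          "mapped_chromosome", "complementation_group"))
}
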