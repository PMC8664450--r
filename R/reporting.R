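# Packaged catalog tables, count summaries, gene-set overrepresentation and
# the expression-pattern rule classifier.
#
# The packaged fixtures under inst/extdata/tables transcribe a published
# catalog of maternal-effect lethal / sterile alleles: the mutant-collection
# summary, the essential-gene allele catalog (with human orthologs), the
# genes-of-interest phenotype table (temperature sensitivity and eggshell
# osmotic-integrity codes), the complementation tests that resolved
# conflicting groups, and the male-fertility mating-rescue table.

#' Path to the packaged catalog tables
#' @return directory path.
#' @export
catalog_dir <- function() {
  system.file("extdata", "tables", package = "screenmap", mustWork = TRUE)
}

parse_pheno_flags <- function(phenotype) {
  list(ts = grepl("\\[(leaky )?ts\\]", phenotype),
       ts_leaky = grepl("\\[leaky ts\\]", phenotype),
       sterile = grepl("Unfertilized oocytes", phenotype, ignore.case = TRUE))
}

#' Load the packaged catalog tables
#'
#' @param dir directory holding the TSV fixtures (defaults to the packaged
#'   copies).
#' @return a `screen_catalog`: list of data.frames `collections`, `alleles`
#'   (essential-gene catalog), `goi` (genes of interest, with derived
#'   logical columns `ts`, `ts_leaky`, `sterile` and a normalized `oid`
#'   code), `conflict_strains`, `conflict_tests`, and `male_fertility`.
#' @export
load_catalog_tables <- function(dir = catalog_dir()) {
  collections <- read_tsv_strict(
    file.path(dir, "collections.tsv"),
    c("collection", "n_groups", "chromosome"))
  alleles <- read_tsv_strict(
    file.path(dir, "essential_genes.tsv"),
    c("comp_group", "strain", "allele", "gene", "chrom", "pos", "ref",
      "alt", "mutation", "mutation_type", "aa_change", "human_orthologs"))
  goi <- read_tsv_strict(
    file.path(dir, "genes_of_interest.tsv"),
    c("strain", "allele", "gene", "aa_change", "mutant_phenotype", "oid"))
  oid_codes <- c(Yes = "yes", No = "no", Some = "some",
                 `N/A` = "not_applicable", `N/T` = "not_tested")
  bad <- !goi$oid %in% names(oid_codes)
  if (any(bad)) stop_ctx("unknown OID code '%s' in genes_of_interest.tsv",
                         goi$oid[bad][1L])
  goi$oid <- unname(oid_codes[goi$oid])
  flags <- parse_pheno_flags(goi$mutant_phenotype)
  goi$ts <- flags$ts
  goi$ts_leaky <- flags$ts_leaky
  goi$sterile <- flags$sterile
  conflict_strains <- read_tsv_strict(
    file.path(dir, "conflict_group_strains.tsv"),
    c("group_id", "strain_id", "allele", "preliminary_candidate",
      "mapped_under"))
  conflict_tests <- read_complementation_tests(
    file.path(dir, "conflict_tests.tsv"))
  male_fertility <- read_tsv_strict(
    file.path(dir, "male_fertility.tsv"),
    c("strain", "allele", "gene", "phenotype", "rescue"))
  structure(list(collections = collections, alleles = alleles, goi = goi,
                 conflict_strains = conflict_strains,
                 conflict_tests = conflict_tests,
                 male_fertility = male_fertility),
            class = "screen_catalog")
}

#' Named count summaries over the catalog tables
#'
#' Available summaries: `distinct_genes` (genes in the essential-gene
#' catalog), `distinct_groups_total` (sum of the collection-table group
#' counts), `goi_alleles`, `sterile_alleles`, `mel_alleles` (maternal-effect
#' lethal, i.e. non-sterile, genes-of-interest alleles), `ortholog_genes`
#' (catalog genes with at least one human ortholog), `ts_alleles`
#' (temperature-sensitive, including leaky), `ts_nonsense_alleles`,
#' `oid_yes_strains`, `oid_some_strains`, `rescue_yes_strains`.
#'
#' @param catalog a [load_catalog_tables()] result.
#' @param query summary name.
#' @return integer count.
#' @export
summarize_catalog <- function(catalog, query) {
  stopifnot(inherits(catalog, "screen_catalog"))
  gene_orthologs <- tapply(catalog$alleles$human_orthologs,
                           catalog$alleles$gene,
                           function(x) any(!x %in% c("None", "", NA)))
  is_nonsense <- grepl("\\*$", catalog$goi$aa_change)
  switch(query,
    distinct_genes = length(unique(catalog$alleles$gene)),
    distinct_groups_total = sum(catalog$collections$n_groups),
    goi_alleles = nrow(catalog$goi),
    sterile_alleles = sum(catalog$goi$sterile),
    mel_alleles = sum(!catalog$goi$sterile),
    ortholog_genes = sum(gene_orthologs),
    ts_alleles = sum(catalog$goi$ts),
    ts_nonsense_alleles = sum(catalog$goi$ts & is_nonsense),
    oid_yes_strains = sum(catalog$goi$oid == "yes"),
    oid_some_strains = sum(catalog$goi$oid == "some"),
    rescue_yes_strains = sum(catalog$male_fertility$rescue == "Yes"),
    stop_ctx("unknown summary '%s'", query))
}

#' Build a gene-annotation table for overrepresentation testing
#'
#' @param gene,term parallel character vectors (one row per annotation).
#' @param universe background gene universe; every annotated gene must be
#'   in it.
#' @return an `annotation_table`.
#' @export
annotation_table <- function(gene, term, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop_ctx("empty gene universe")
  extra <- setdiff(unique(gene), universe)
  if (length(extra))
    stop_ctx("annotated gene(s) not in universe: %s",
             paste(utils::head(extra, 3L), collapse = ", "))
  structure(list(annotations = data.frame(gene = gene, term = term,
                                          stringsAsFactors = FALSE),
                 universe = universe),
            class = "annotation_table")
}

#' One-sided Fisher overrepresentation test with Bonferroni correction
#'
#' For each term, tests overrepresentation of the term among the study set
#' against the background universe with a one-sided Fisher's exact test on
#' the 2x2 table (in-set annotated / in-set not / out-set annotated /
#' out-set not). Adjusted p-values are Bonferroni
#' (`min(1, p * number of tested terms)`).
#'
#' @param study_set character vector of study genes (subset of the
#'   universe).
#' @param annotation an [annotation_table()].
#' @param alpha optional adjusted-p cutoff; when given, only terms with
#'   `p_adjusted < alpha` are returned.
#' @return data.frame with `term`, `n_study`, `n_term`, `n_overlap`,
#'   `fold`, `p_value`, `p_adjusted`, sorted by `p_value`.
#' @export
fisher_overrepresentation <- function(study_set, annotation, alpha = NULL) {
  stopifnot(inherits(annotation, "annotation_table"))
  universe <- annotation$universe
  study_set <- unique(study_set)
  if (!all(study_set %in% universe))
    stop_ctx("study set contains genes outside the universe")
  N <- length(universe)
  n <- length(study_set)
  terms <- sort(unique(annotation$annotations$term))
  rows <- lapply(terms, function(t) {
    genes_t <- unique(annotation$annotations$gene[
      annotation$annotations$term == t])
    K <- length(genes_t)
    a <- length(intersect(study_set, genes_t))
    tab <- matrix(c(a, n - a, K - a, N - n - (K - a)), nrow = 2L)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(term = t, n_study = n, n_term = K, n_overlap = a,
               fold = (a / n) / (K / N), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_value * length(terms))
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(alpha)) out <- out[out$p_adjusted < alpha, , drop = FALSE]
  out
}

#' Classify a gene's life-stage expression pattern
#'
#' A rule-based restatement of visual inspection of stage-resolved
#' expression profiles: a gene is *maternal* when early-embryo and
#' hermaphrodite-gonad levels both exceed a fold multiple of the gene's
#' median stage level (gene products supplied to the embryo by the mother);
#' *maternal_plus_zygotic* when, in addition, some larval stage is also
#' elevated (an additional zygotic role); *male_enriched* when the male
#' level exceeds a fold multiple of every hermaphrodite stage (suggesting a
#' sperm-specific function). Flags are co-reported; the primary class gives
#' male enrichment precedence, then zygotic, then maternal.
#'
#' @param profile named non-negative numeric vector of expression levels;
#'   must include `early_embryo`, `hermaphrodite_gonad`, `male`, and at
#'   least one larval stage (name starting with `"L"` or `"larval"`).
#' @param maternal_fold,zygotic_fold,male_fold rule thresholds (defaults 2,
#'   2 and 2; artifact choices, documented rather than fitted).
#' @return list with `class` (one of `maternal`, `maternal_plus_zygotic`,
#'   `male_enriched`, `other`) and logical `flags` (`maternal`, `zygotic`,
#'   `male_enriched`).
#' @export
classify_expression_pattern <- function(profile, maternal_fold = 2,
                                        zygotic_fold = 2, male_fold = 2) {
  need <- c("early_embryo", "hermaphrodite_gonad", "male")
  missing <- setdiff(need, names(profile))
  if (length(missing))
    stop_ctx("profile missing stage field(s): %s",
             paste(missing, collapse = ", "))
  larval <- names(profile)[grepl("^(L[1-4]|larval)", names(profile))]
  if (!length(larval)) stop_ctx("profile has no larval stage field")
  if (any(profile < 0)) stop_ctx("expression levels must be >= 0")
  med <- stats::median(profile)
  maternal <- profile[["early_embryo"]] > maternal_fold * med &&
    profile[["hermaphrodite_gonad"]] > maternal_fold * med
  zygotic <- maternal && any(profile[larval] > zygotic_fold * med)
  herm <- profile[setdiff(names(profile), "male")]
  male <- profile[["male"]] > male_fold * max(herm)
  cls <- if (male) "male_enriched"
         else if (zygotic) "maternal_plus_zygotic"
         else if (maternal) "maternal" else "other"
  list(class = cls,
       flags = c(maternal = maternal, zygotic = zygotic,
                 male_enriched = male))
}
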