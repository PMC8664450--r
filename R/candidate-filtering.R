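# The four-stage candidate filter cascade:
#   (i)   recurrence: variants seen in more than `max_shared_strains` strains
#         of one collection are removed everywhere (counted on pre-filter,
#         post-blacklist calls);
#   (ii)  zygosity: only heterozygous calls (allele fraction in the band)
#         are kept;
#   (iii) effect: only protein-affecting or splice-site annotations are kept;
#   (iv)  chromosome: only variants on the strain's genetically mapped
#         chromosome are kept.
# Every stage only removes calls, and removals are recorded in an audit
# trail so removed variants can be re-inspected later.

#' Filter cascade configuration
#'
#' @param max_shared_strains recurrence threshold: a variant observed in
#'   strictly more than this many strains of one collection is removed
#'   (default 3, i.e. removed when seen in >= 4 strains).
#' @param het_band heterozygous allele-fraction band, inclusive
#'   (default `c(0.2, 0.8)`).
#' @param candidate_effects effect classes kept by the effect filter.
#' @param enforce_mapped_chromosome apply the mapped-chromosome filter
#'   (default `TRUE`).
#' @return a `filter_config`.
#' @export
filter_config <- function(max_shared_strains = 3L,
                          het_band = c(0.2, 0.8),
                          candidate_effects = EFFECT_CLASSES[
                            effect_is_candidate(EFFECT_CLASSES)],
                          enforce_mapped_chromosome = TRUE) {
  if (max_shared_strains < 1L)
    stop_ctx("max_shared_strains must be >= 1")
  if (length(het_band) != 2L || any(het_band < 0) || any(het_band > 1) ||
      het_band[1L] > het_band[2L])
    stop_ctx("het_band must be an ordered fraction interval within [0,1]")
  if (!all(candidate_effects %in% EFFECT_CLASSES))
    stop_ctx("unknown effect class in candidate_effects")
  structure(list(max_shared_strains = as.integer(max_shared_strains),
                 het_band = het_band,
                 candidate_effects = candidate_effects,
                 enforce_mapped_chromosome = isTRUE(enforce_mapped_chromosome)),
            class = "filter_config")
}

#' Recurrence filter (filter i)
#'
#' Removes, from every strain, variants whose exact (chrom, pos, ref, alt)
#' identity is observed in strictly more than `max_shared_strains` strains
#' of the same collection. Counting is done on the input sets as given.
#'
#' @param sets list of [strain_variant_set()]s from one collection.
#' @param cfg a [filter_config()].
#' @return list of filtered sets, same order.
#' @export
recurrence_filter <- function(sets, cfg = filter_config()) {
  colls <- unique(vapply(sets, function(s) as.character(s$collection),
                         character(1)))
  if (length(colls) > 1L)
    stop_ctx("recurrence_filter: sets span multiple collections (%s)",
             paste(colls, collapse = ", "))
  keys_per_strain <- lapply(sets, function(s)
    unique(variant_key(s$calls$chrom, s$calls$pos, s$calls$ref, s$calls$alt)))
  tab <- table(unlist(keys_per_strain))
  bad <- names(tab)[tab > cfg$max_shared_strains]
  lapply(sets, function(s) {
    k <- variant_key(s$calls$chrom, s$calls$pos, s$calls$ref, s$calls$alt)
    s$calls <- s$calls[!(k %in% bad), , drop = FALSE]
    rownames(s$calls) <- NULL
    s
  })
}

#' Zygosity filter (filter ii)
#'
#' Keeps only calls labelled heterozygous by [classify_zygosity()]; both
#' homozygous and low-fraction calls are removed.
#'
#' @param set a [strain_variant_set()].
#' @param cfg a [filter_config()].
#' @return filtered set.
#' @export
zygosity_filter <- function(set, cfg = filter_config()) {
  if (!nrow(set$calls)) return(set)
  keep <- classify_zygosity(set$calls, cfg$het_band) == "heterozygous"
  set$calls <- set$calls[keep, , drop = FALSE]
  rownames(set$calls) <- NULL
  set
}

#' Effect filter (filter iii)
#'
#' Keeps only annotations whose effect class is in the configured candidate
#' set (by default the protein-affecting and splice-site classes).
#'
#' @param annotated data.frame from [annotate_calls()].
#' @param cfg a [filter_config()].
#' @return filtered data.frame.
#' @export
effect_filter <- function(annotated, cfg = filter_config()) {
  out <- annotated[annotated$effect %in% cfg$candidate_effects, ,
                   drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mapped-chromosome filter (filter iv)
#'
#' Keeps only variants on the chromosome to which the strain's mutation was
#' genetically mapped. A no-op when `enforce_mapped_chromosome` is `FALSE`.
#'
#' @param annotated data.frame of annotated variants.
#' @param mapped_chromosome chromosome name.
#' @param cfg a [filter_config()].
#' @param known_chromosomes optional character vector of valid chromosome
#'   names; if supplied, an unknown `mapped_chromosome` is an error.
#' @return filtered data.frame.
#' @export
chromosome_filter <- function(annotated, mapped_chromosome,
                              cfg = filter_config(),
                              known_chromosomes = NULL) {
  if (!is.null(known_chromosomes) &&
      !(mapped_chromosome %in% known_chromosomes))
    stop_ctx("unknown mapped chromosome '%s'", mapped_chromosome)
  if (!cfg$enforce_mapped_chromosome) return(annotated)
  out <- annotated[annotated$chrom == mapped_chromosome, , drop = FALSE]
  rownames(out) <- NULL
  out
}

call_keys <- function(calls) {
  variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
}

#' Run the full filter cascade over a set of strains
#'
#' Order: blacklist, recurrence (within each collection), zygosity,
#' annotation, effect, mapped chromosome. Removals are audited per strain
#' and per stage, in units of calls; a call survives the effect stage if at
#' least one of its per-gene annotations has a candidate effect class.
#'
#' @param sets list of [strain_variant_set()]s.
#' @param genes list of gene models.
#' @param assembly a [genome_assembly()].
#' @param bl blacklist from [load_blacklist()], or `NULL`.
#' @param cfg a [filter_config()].
#' @return named list of `candidate_list` objects (one per strain), each
#'   with `strain_id`, `variants` (surviving annotated variants), `genes`
#'   (sorted gene ids), and `audit` (`counts` data.frame and `removed`
#'   data.frame of per-variant removals naming the removing filter).
#' @export
run_cascade <- function(sets, genes, assembly, bl = NULL,
                        cfg = filter_config()) {
  index <- build_annotation_index(genes, assembly)
  chroms <- names(assembly$chromosomes)

  removed <- lapply(sets, function(s) list())
  names(removed) <- vapply(sets, function(s) s$strain_id, character(1))
  record <- function(strain, stage, calls) {
    if (!nrow(calls)) return()
    removed[[strain]][[stage]] <<- data.frame(
      strain_id = strain, filter = stage, chrom = calls$chrom,
      pos = calls$pos, ref = calls$ref, alt = calls$alt,
      stringsAsFactors = FALSE)
  }

  # blacklist
  n_in <- stats::setNames(vapply(sets, function(s) nrow(s$calls), integer(1)),
                          names(removed))
  sets <- lapply(sets, function(s) {
    out <- apply_blacklist(s, bl)
    drop <- !(call_keys(s$calls) %in% call_keys(out$calls))
    record(s$strain_id, "blacklist", s$calls[drop, , drop = FALSE])
    out
  })

  # recurrence, per collection
  coll <- vapply(sets, function(s) as.character(s$collection), character(1))
  for (cl in unique(coll)) {
    sel <- which(coll == cl)
    filtered <- recurrence_filter(sets[sel], cfg)
    for (j in seq_along(sel)) {
      s <- sets[[sel[j]]]
      drop <- !(call_keys(s$calls) %in% call_keys(filtered[[j]]$calls))
      record(s$strain_id, "recurrence", s$calls[drop, , drop = FALSE])
      sets[[sel[j]]] <- filtered[[j]]
    }
  }

  out <- vector("list", length(sets))
  names(out) <- names(removed)
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    strain <- s$strain_id

    z <- zygosity_filter(s, cfg)
    drop <- !(call_keys(s$calls) %in% call_keys(z$calls))
    record(strain, "zygosity", s$calls[drop, , drop = FALSE])

    ann <- annotate_calls(z, index, assembly)
    ann_keys <- call_keys(ann)
    keep_ann <- effect_filter(ann, cfg)
    surviving_keys <- unique(call_keys(keep_ann))
    drop_calls <- z$calls[!(call_keys(z$calls) %in% surviving_keys), ,
                          drop = FALSE]
    record(strain, "effect", drop_calls)

    mapped <- s$mapped_chromosome
    final_ann <- chromosome_filter(keep_ann, mapped, cfg,
                                   known_chromosomes = chroms)
    kept_calls <- z$calls[call_keys(z$calls) %in% surviving_keys, ,
                          drop = FALSE]
    if (cfg$enforce_mapped_chromosome) {
      record(strain, "chromosome",
             kept_calls[kept_calls$chrom != mapped, , drop = FALSE])
      kept_calls <- kept_calls[kept_calls$chrom == mapped, , drop = FALSE]
    }

    final_ann <- final_ann[order(final_ann$chrom, final_ann$pos,
                                 final_ann$alt), , drop = FALSE]
    rownames(final_ann) <- NULL
    rem <- removed[[strain]]
    rem_df <- if (length(rem)) do.call(rbind, unname(rem)) else
      data.frame(strain_id = character(0), filter = character(0),
                 chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), stringsAsFactors = FALSE)
    stages <- c("blacklist", "recurrence", "zygosity", "effect", "chromosome")
    counts <- data.frame(
      strain_id = strain, filter = stages,
      removed = vapply(stages, function(st) sum(rem_df$filter == st),
                       integer(1)),
      stringsAsFactors = FALSE)
    stopifnot(sum(counts$removed) == n_in[[strain]] - nrow(kept_calls))
    out[[i]] <- structure(
      list(strain_id = strain, variants = final_ann,
           genes = sort(unique(final_ann$gene_id[!is.na(final_ann$gene_id)])),
           n_input_calls = n_in[[strain]], n_surviving_calls = nrow(kept_calls),
           audit = list(counts = counts, removed = rem_df)),
      class = "candidate_list")
  }
  out
}

#' Write candidate lists and their audit trail as TSV
#'
#' @param candidates list of candidate lists from [run_cascade()].
#' @param variants_path output TSV of surviving variants.
#' @param audit_path optional output TSV of per-stage removal counts.
#' @return `variants_path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, variants_path,
                                 audit_path = NULL) {
  vars <- do.call(rbind, lapply(candidates, function(cl)
    cl$variants[, c("strain_id", "gene_id", "chrom", "pos", "ref", "alt",
                    "effect", "aa_change")]))
  write_tsv(vars, variants_path)
  if (!is.null(audit_path)) {
    audit <- do.call(rbind, lapply(candidates, function(cl) cl$audit$counts))
    write_tsv(audit, audit_path)
  }
  invisible(variants_path)
}
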