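# Candidate intersection within complementation groups, adjudication of
# multi-candidate groups, and group merging / double-mutant detection from
# complementation-test outcomes.

#' Construct a complementation group
#'
#' @param group_id group identifier.
#' @param member_strains character vector of strain ids (singletons are
#'   allowed but cannot be resolved by intersection).
#' @param mapped_chromosome chromosome shared by the member strains.
#' @return a `complementation_group`.
#' @export
complementation_group <- function(group_id, member_strains,
                                  mapped_chromosome = NA_character_) {
  if (!length(member_strains)) stop_ctx("group %s has no members", group_id)
  structure(list(group_id = group_id,
                 member_strains = as.character(member_strains),
                 mapped_chromosome = mapped_chromosome),
            class = "complementation_group")
}

new_resolution <- function(group_id, status, candidate_genes,
                           evidence = character(0),
                           member_strains = character(0)) {
  structure(list(group_id = group_id, status = status,
                 candidate_genes = sort(unique(candidate_genes)),
                 evidence = evidence, member_strains = member_strains),
            class = "group_resolution")
}

#' Intersect candidate gene lists within a complementation group
#'
#' The group's candidate genes are the intersection of its member strains'
#' candidate gene sets. One gene in common designates the putative essential
#' gene (`unique`); several give `multiple` (kept for adjudication); none
#' gives `none` and flags the group for reanalysis. Single-member groups are
#' `unresolved_singleton`: one allele cannot be resolved by intersection.
#'
#' @param group a [complementation_group()].
#' @param lists named list of candidate lists (from [run_cascade()]) keyed
#'   by strain id.
#' @return a `group_resolution`.
#' @export
intersect_candidates <- function(group, lists) {
  members <- group$member_strains
  missing <- setdiff(members, names(lists))
  if (length(missing))
    stop_ctx("group %s: no candidate list for strain(s) %s", group$group_id,
             paste(missing, collapse = ", "))
  gene_sets <- lapply(lists[members], function(cl) cl$genes)
  if (length(members) == 1L)
    return(new_resolution(group$group_id, "unresolved_singleton",
                          gene_sets[[1L]],
                          "single allele; intersection not applicable",
                          members))
  common <- Reduce(intersect, gene_sets)
  status <- if (length(common) == 1L) "unique"
            else if (length(common) > 1L) "multiple" else "none"
  ev <- c(sprintf("members: %s", paste(members, collapse = ", ")),
          sprintf("per-strain candidate counts: %s",
                  paste(vapply(gene_sets, length, integer(1)),
                        collapse = ", ")),
          if (status == "none") "no gene in common; flagged for reanalysis")
  new_resolution(group$group_id, status, common, ev, members)
}

#' Adjudicate a multi-candidate group by mutation severity
#'
#' Optional, disabled by default. When enabled, prefers a candidate gene in
#' which every member strain carries a severe lesion (nonsense, frameshift,
#' splice-site or start-loss) over genes supported only by missense calls.
#' If no single gene stands out the group stays `multiple`; the choice is
#' never forced.
#'
#' @param resolution a `group_resolution` with status `multiple`.
#' @param lists named list of candidate lists keyed by strain id.
#' @param enabled apply the heuristic (default `FALSE`).
#' @return possibly updated `group_resolution`.
#' @export
adjudicate_multiple <- function(resolution, lists, enabled = FALSE) {
  if (!enabled || resolution$status != "multiple") return(resolution)
  severe <- c("nonsense", "frameshift", "splice_site", "start_loss")
  members <- resolution$member_strains
  all_severe <- vapply(resolution$candidate_genes, function(g) {
    all(vapply(members, function(s) {
      v <- lists[[s]]$variants
      any(v$gene_id == g & v$effect %in% severe, na.rm = TRUE)
    }, logical(1)))
  }, logical(1))
  if (sum(all_severe) == 1L) {
    chosen <- resolution$candidate_genes[all_severe]
    resolution$evidence <- c(resolution$evidence, sprintf(
      "adjudicated to %s: severe lesions in all members; alternatives %s",
      chosen, paste(resolution$candidate_genes[!all_severe],
                    collapse = ", ")))
    resolution$candidate_genes <- chosen
    resolution$status <- "unique"
  } else {
    resolution$evidence <- c(resolution$evidence,
                             "severity adjudication inconclusive")
  }
  resolution
}

#' Read complementation-test outcomes from TSV
#'
#' @param path TSV with columns `strain_a`, `strain_b`, `outcome`
#'   (`complements` / `fails_to_complement`).
#' @return data.frame.
#' @export
read_complementation_tests <- function(path) {
  df <- read_tsv_strict(path, c("strain_a", "strain_b", "outcome"))
  bad <- !df$outcome %in% c("complements", "fails_to_complement")
  if (any(bad))
    stop_ctx("unknown complementation outcome '%s'", df$outcome[bad][1L])
  df
}

# per unordered group pair: "fails_to_complement" dominates when both kinds
# of strain-level edges exist between two groups
group_pair_outcomes <- function(tests, strain_group) {
  ga <- strain_group[tests$strain_a]
  gb <- strain_group[tests$strain_b]
  unknown <- is.na(ga) | is.na(gb)
  if (any(unknown))
    stop_ctx("complementation test references unknown strain '%s'",
             c(tests$strain_a, tests$strain_b)[
               c(is.na(ga), is.na(gb))][1L])
  # symmetric-consistency check at strain level
  pair <- paste(pmin(tests$strain_a, tests$strain_b),
                pmax(tests$strain_a, tests$strain_b), sep = "|")
  agg <- tapply(tests$outcome, pair, function(x) length(unique(x)))
  if (any(agg > 1L))
    stop_ctx("inconsistent outcomes for strain pair %s",
             names(agg)[agg > 1L][1L])
  sel <- ga != gb
  if (!any(sel))
    return(data.frame(g1 = character(0), g2 = character(0),
                      outcome = character(0)))
  gp <- data.frame(g1 = pmin(ga[sel], gb[sel]), g2 = pmax(ga[sel], gb[sel]),
                   outcome = tests$outcome[sel], stringsAsFactors = FALSE)
  key <- paste(gp$g1, gp$g2, sep = "|")
  out <- do.call(rbind, lapply(split(gp, key), function(d) {
    d$outcome <- if (any(d$outcome == "fails_to_complement"))
      "fails_to_complement" else "complements"
    d[1L, ]
  }))
  rownames(out) <- NULL
  out
}

#' Merge complementation groups using cross-group test outcomes
#'
#' Builds a failure-to-complement graph over groups. Groups connected by
#' `fails_to_complement` edges that also share a candidate gene are merged
#' into one resolution (status `merged`). A group that fails to complement
#' members of two groups which are known to complement *each other* is a
#' double mutant: it carries lesions in both genes and is flagged
#' `double_mutant` with both groups' candidate genes listed. Without the
#' explicit complements edge between the partners the group is only merged
#' and flagged ambiguous.
#'
#' @param resolutions list of `group_resolution`s.
#' @param tests data.frame of complementation-test outcomes
#'   (see [read_complementation_tests()]).
#' @param group_membership named character vector mapping strain id to
#'   group id.
#' @return list of `group_resolution`s with merged/double-mutant groups
#'   replacing their inputs.
#' @export
merge_groups <- function(resolutions, tests, group_membership) {
  if (is.null(tests) || !nrow(tests)) return(resolutions)
  names(resolutions) <- vapply(resolutions, function(r) r$group_id,
                               character(1))
  gp <- group_pair_outcomes(tests, group_membership)
  fails <- gp[gp$outcome == "fails_to_complement", , drop = FALSE]
  comps <- gp[gp$outcome == "complements", , drop = FALSE]
  comp_key <- paste(comps$g1, comps$g2, sep = "|")

  # double mutants first: g fails both a and b, while a complements b
  double <- character(0)
  for (g in names(resolutions)) {
    partners <- unique(c(fails$g2[fails$g1 == g], fails$g1[fails$g2 == g]))
    partners <- setdiff(partners, double)
    if (length(partners) < 2L) next
    cmb <- utils::combn(sort(partners), 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1L, j]; b <- cmb[2L, j]
      if (paste(a, b, sep = "|") %in% comp_key) {
        r <- resolutions[[g]]
        genes <- unique(c(resolutions[[a]]$candidate_genes,
                          resolutions[[b]]$candidate_genes))
        r$status <- "double_mutant"
        r$candidate_genes <- sort(genes)
        r$evidence <- c(r$evidence, sprintf(
          "fails to complement %s and %s, which complement each other; lesions in two genes (%s)",
          a, b,
          if (length(genes)) paste(genes, collapse = " + ") else
            "partner genes unknown"))
        resolutions[[g]] <- r
        double <- c(double, g)
        break
      }
    }
  }

  # union-find merge over fails edges with a shared candidate gene
  mergeable <- setdiff(names(resolutions), double)
  parent <- stats::setNames(mergeable, mergeable)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (j in seq_len(nrow(fails))) {
    a <- fails$g1[j]; b <- fails$g2[j]
    if (!(a %in% mergeable) || !(b %in% mergeable)) next
    if (length(intersect(resolutions[[a]]$candidate_genes,
                         resolutions[[b]]$candidate_genes)) == 0L) next
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[[rb]] <- ra
  }
  roots <- vapply(mergeable, find, character(1))
  out <- list()
  for (r in unique(roots)) {
    members <- mergeable[roots == r]
    if (length(members) == 1L) {
      out[[members]] <- resolutions[[members]]
      next
    }
    shared <- Reduce(intersect,
                     lapply(members, function(g)
                       resolutions[[g]]$candidate_genes))
    genes <- if (length(shared)) shared else
      unique(unlist(lapply(members, function(g)
        resolutions[[g]]$candidate_genes)))
    merged_id <- paste(sort(members), collapse = "+")
    ev <- c(sprintf("groups %s fail to complement and share candidate gene(s) %s; not distinct",
                    paste(sort(members), collapse = ", "),
                    paste(genes, collapse = ", ")),
            if (!length(shared)) "no gene shared by all merged members; union reported (ambiguous)")
    out[[merged_id]] <- new_resolution(
      merged_id, "merged", genes, ev,
      unlist(lapply(members, function(g) resolutions[[g]]$member_strains)))
  }
  for (g in double) out[[g]] <- resolutions[[g]]
  unname(out[order(names(out))])
}

#' Write group resolutions as TSV
#'
#' @param resolutions list of `group_resolution`s.
#' @param path output TSV (`group_id`, `status`, `genes`, `evidence`).
#' @return `path`, invisibly.
#' @export
write_resolutions_tsv <- function(resolutions, path) {
  df <- do.call(rbind, lapply(resolutions, function(r) data.frame(
    group_id = r$group_id, status = r$status,
    genes = paste(r$candidate_genes, collapse = ","),
    evidence = paste(r$evidence, collapse = "; "),
    stringsAsFactors = FALSE)))
  write_tsv(df, path)
}
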