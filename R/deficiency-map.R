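# Deficiency (chromosomal deletion) intervals with certain and uncertain
# boundaries, and corroboration of gene assignments against deficiency
# mapping outcomes.
#
# A deficiency's inner span is certainly deleted (bounded by the outermost
# gene known to lie inside the deletion); its outer span certainly contains
# the deletion (bounded by the closest gene known to lie outside). A faded
# edge leaves a margin of uncertainty between the two; a sharp edge means
# the two bounds coincide on that side.

#' Construct a deficiency interval
#'
#' @param name deficiency name (e.g. `"tDf5"`).
#' @param chrom chromosome name.
#' @param inner_start,inner_end certainly deleted span (1-based inclusive).
#' @param outer_start,outer_end span certainly containing the deletion;
#'   `NA` means no external anchor gene is known on that side and the span
#'   extends to the chromosome edge (`1` or `chrom_length`).
#' @param left_edge,right_edge `"sharp"` (inner and outer bounds coincide)
#'   or `"faded"`.
#' @param chrom_length chromosome length used for unbounded outer edges
#'   (`Inf` when unknown).
#' @return a `deficiency_interval`.
#' @export
deficiency_interval <- function(name, chrom, inner_start, inner_end,
                                outer_start = NA, outer_end = NA,
                                left_edge = c("faded", "sharp"),
                                right_edge = c("faded", "sharp"),
                                chrom_length = Inf) {
  left_edge <- match.arg(left_edge)
  right_edge <- match.arg(right_edge)
  if (inner_start > inner_end)
    stop_ctx("deficiency %s: inner span start > end", name)
  if (left_edge == "sharp") outer_start <- inner_start
  if (right_edge == "sharp") outer_end <- inner_end
  if (is.na(outer_start)) outer_start <- 1
  if (is.na(outer_end)) outer_end <- chrom_length
  if (outer_start > inner_start || outer_end < inner_end)
    stop_ctx("deficiency %s: inner span not contained in outer span", name)
  structure(list(name = name, chrom = chrom,
                 inner = c(start = inner_start, end = inner_end),
                 outer = c(start = outer_start, end = outer_end),
                 edges = c(left = left_edge, right = right_edge)),
            class = "deficiency_interval")
}

#' Does a deficiency cover a genomic position?
#'
#' @param df a [deficiency_interval()].
#' @param chrom chromosome of the queried position.
#' @param pos 1-based coordinate.
#' @return `"inside"` (within the certainly deleted span), `"outside"`
#'   (wrong chromosome or beyond the outer span), or `"uncertain"` (within
#'   a faded-edge margin).
#' @export
covers <- function(df, chrom, pos) {
  if (chrom != df$chrom || pos < df$outer["start"] || pos > df$outer["end"])
    return("outside")
  if (pos >= df$inner["start"] && pos <= df$inner["end"]) return("inside")
  "uncertain"
}

#' Does a deficiency cover a gene span?
#'
#' A gene partially overlapped by the certainly deleted span counts as
#' inside: deleting any part of an essential gene fails to complement it.
#'
#' @param df a [deficiency_interval()].
#' @param chrom,start,end gene span (1-based inclusive).
#' @return `"inside"`, `"outside"` or `"uncertain"`.
#' @export
covers_span <- function(df, chrom, start, end) {
  if (chrom != df$chrom || end < df$outer["start"] || start > df$outer["end"])
    return("outside")
  if (end >= df$inner["start"] && start <= df$inner["end"]) return("inside")
  "uncertain"
}

#' Read deficiency intervals from TSV
#'
#' @param path TSV with columns `name`, `chrom`, `inner_start`, `inner_end`,
#'   `outer_start`, `outer_end` (empty for unbounded), `left_edge`,
#'   `right_edge`.
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return named list of [deficiency_interval()]s.
#' @export
read_deficiencies <- function(path, chrom_lengths = NULL) {
  df <- read_tsv_strict(path, c("name", "chrom", "inner_start", "inner_end",
                                "outer_start", "outer_end", "left_edge",
                                "right_edge"))
  out <- lapply(seq_len(nrow(df)), function(i) {
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[df$chrom[i]]] else Inf
    deficiency_interval(
      df$name[i], df$chrom[i], df$inner_start[i], df$inner_end[i],
      outer_start = suppressWarnings(as.numeric(df$outer_start[i])),
      outer_end = suppressWarnings(as.numeric(df$outer_end[i])),
      left_edge = df$left_edge[i], right_edge = df$right_edge[i],
      chrom_length = len %||% Inf)
  })
  names(out) <- df$name
  out
}

#' Read deficiency-mapping outcomes from TSV
#'
#' @param path TSV with columns `group_id`, `deficiency`, `result`
#'   (`under` / `not_under` / `untested`).
#' @return data.frame.
#' @export
read_mapping_outcomes <- function(path) {
  df <- read_tsv_strict(path, c("group_id", "deficiency", "result"))
  bad <- !df$result %in% c("under", "not_under", "untested")
  if (any(bad)) stop_ctx("unknown mapping result '%s'", df$result[bad][1L])
  if (anyDuplicated(df[, c("group_id", "deficiency")]))
    stop_ctx("duplicate mapping outcome for a (group, deficiency) pair")
  df
}

#' Corroborate a group's gene assignment against deficiency mapping
#'
#' Consistent when every deficiency the group maps under covers the
#' assigned gene and every deficiency it maps not-under excludes it;
#' conflict when an "under" deficiency excludes the gene or a "not_under"
#' deficiency includes it; uncertain when a decisive comparison falls in a
#' faded-edge margin. Conflicts do not veto the assignment; they set a flag
#' for follow-up complementation tests.
#'
#' @param resolution a `group_resolution` with at least one candidate gene.
#' @param gene_position list with `chrom`, `start`, `end` for the assigned
#'   gene (see [gene_span()]).
#' @param outcomes data.frame of mapping outcomes
#'   (see [read_mapping_outcomes()]); rows for other groups are ignored.
#' @param dfs named list of [deficiency_interval()]s.
#' @return `"consistent"`, `"conflict"` or `"uncertain"`, with a `detail`
#'   attribute giving the per-deficiency comparison.
#' @export
corroborate <- function(resolution, gene_position, outcomes, dfs) {
  if (!length(resolution$candidate_genes))
    stop_ctx("group %s has no candidate gene to corroborate",
             resolution$group_id)
  rows <- outcomes[outcomes$group_id == resolution$group_id &
                     outcomes$result != "untested", , drop = FALSE]
  unknown <- setdiff(rows$deficiency, names(dfs))
  if (length(unknown))
    stop_ctx("unknown deficiency name '%s'", unknown[1L])
  if (!nrow(rows)) {
    out <- "consistent"
    attr(out, "detail") <- data.frame(deficiency = character(0),
                                      result = character(0),
                                      coverage = character(0))
    return(out)
  }
  coverage <- vapply(rows$deficiency, function(nm)
    covers_span(dfs[[nm]], gene_position$chrom, gene_position$start,
                gene_position$end), character(1))
  conflict <- (rows$result == "under" & coverage == "outside") |
    (rows$result == "not_under" & coverage == "inside")
  uncertain <- coverage == "uncertain"
  verdict <- if (any(conflict)) "conflict"
             else if (any(uncertain)) "uncertain" else "consistent"
  attr(verdict, "detail") <- data.frame(
    deficiency = rows$deficiency, result = rows$result, coverage = coverage,
    stringsAsFactors = FALSE, row.names = NULL)
  verdict
}
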