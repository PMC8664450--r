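mk_df <- function(...) deficiency_interval(...)

test_that("coverage distinguishes inside, outside and faded-edge uncertainty", {
  df <- mk_df("tDfX", "III", 1000, 2000, outer_start = 800,
              outer_end = 2300, left_edge = "faded", right_edge = "faded")
  expect_equal(covers(df, "III", 1500), "inside")
  expect_equal(covers(df, "III", 1000), "inside")
  expect_equal(covers(df, "IV", 1500), "outside")
  expect_equal(covers(df, "III", 700), "outside")
  expect_equal(covers(df, "III", 900), "uncertain")
  expect_equal(covers(df, "III", 2200), "uncertain")

  sharp <- mk_df("tDfS", "III", 1000, 2000, left_edge = "sharp",
                 right_edge = "sharp")
  expect_equal(covers(sharp, "III", 999), "outside")
  expect_equal(covers(sharp, "III", 1000), "inside")

  # sharp edges force the outer bound onto the inner bound
  expect_equal(unname(sharp$outer), unname(sharp$inner))
  expect_error(mk_df("bad", "III", 2000, 1000), "start > end")
  expect_error(mk_df("bad", "III", 1000, 2000, outer_start = 1500,
                     left_edge = "faded"), "not contained")
})

test_that("coverage is monotone in the spans", {
  base <- mk_df("d", "III", 1000, 2000, outer_start = 800, outer_end = 2300,
                left_edge = "faded", right_edge = "faded")
  bigger_inner <- mk_df("d", "III", 900, 2100, outer_start = 800,
                        outer_end = 2300, left_edge = "faded",
                        right_edge = "faded")
  bigger_outer <- mk_df("d", "III", 1000, 2000, outer_start = 600,
                        outer_end = 2500, left_edge = "faded",
                        right_edge = "faded")
  rank <- c(outside = 0, uncertain = 1, inside = 2)
  for (pos in seq(600, 2600, by = 50)) {
    expect_gte(rank[covers(bigger_inner, "III", pos)],
               rank[covers(base, "III", pos)])
    expect_gte(rank[covers(bigger_outer, "III", pos)],
               rank[covers(base, "III", pos)])
  }
})

test_that("gene spans partially overlapping the deleted region count as inside", {
  df <- mk_df("d", "III", 1000, 2000, outer_start = 800, outer_end = 2300,
              left_edge = "faded", right_edge = "faded")
  expect_equal(covers_span(df, "III", 1900, 2200), "inside")
  expect_equal(covers_span(df, "III", 2100, 2250), "uncertain")
  expect_equal(covers_span(df, "III", 2400, 2600), "outside")
  expect_equal(covers_span(df, "IV", 1500, 1600), "outside")
})

test_that("corroboration flags consistency, conflicts and uncertainty", {
  dfs <- list(
    tDf5 = mk_df("tDf5", "III", 12000000, 13500000,
                 outer_start = 11800000, outer_end = 13700000,
                 left_edge = "faded", right_edge = "faded"),
    tDf7 = mk_df("tDf7", "III", 1000000, 2000000, left_edge = "sharp",
                 right_edge = "sharp"))
  res <- screenmap:::new_resolution("gA", "unique", "geneA")
  gene_pos <- list(chrom = "III", start = 12969933, end = 12975000)

  ok <- corroborate(res, gene_pos, data.frame(
    group_id = "gA", deficiency = c("tDf5", "tDf7"),
    result = c("under", "not_under")), dfs)
  expect_equal(as.character(ok), "consistent")

  # the conflict mode: a group mapping under none of the tested deficiencies
  # while its assigned gene lies inside one of them
  conflict <- corroborate(res, gene_pos, data.frame(
    group_id = "gA", deficiency = c("tDf5", "tDf7"),
    result = c("not_under", "not_under")), dfs)
  expect_equal(as.character(conflict), "conflict")
  detail <- attr(conflict, "detail")
  expect_equal(detail$coverage[detail$deficiency == "tDf5"], "inside")

  faded <- corroborate(res, list(chrom = "III", start = 11850000,
                                 end = 11900000),
                       data.frame(group_id = "gA", deficiency = "tDf5",
                                  result = "under"), dfs)
  expect_equal(as.character(faded), "uncertain")

  # untested rows and rows for other groups are ignored
  stable <- corroborate(res, gene_pos, data.frame(
    group_id = c("gA", "gA", "gB"),
    deficiency = c("tDf5", "tDf7", "tDf7"),
    result = c("under", "untested", "not_under")), dfs)
  expect_equal(as.character(stable), "consistent")

  expect_error(corroborate(res, gene_pos, data.frame(
    group_id = "gA", deficiency = "nope", result = "under"), dfs),
    "unknown deficiency")
  expect_error(corroborate(screenmap:::new_resolution("gA", "none",
                                                      character(0)),
                           gene_pos, data.frame(group_id = character(0),
                                                deficiency = character(0),
                                                result = character(0)),
                           dfs),
               "no candidate gene")
})

test_that("deficiency and mapping-outcome tables round-trip through TSV", {
  dpath <- tempfile(fileext = ".tsv")
  writeLines(c(
    "name\tchrom\tinner_start\tinner_end\touter_start\touter_end\tleft_edge\tright_edge",
    "tDf5\tIII\t1000\t2000\t800\t2300\tfaded\tfaded",
    "tDf6\tIII\t5000\t6000\t\t\tsharp\tsharp"), dpath)
  dfs <- read_deficiencies(dpath, chrom_lengths = c(III = 10000))
  expect_named(dfs, c("tDf5", "tDf6"))
  expect_equal(unname(dfs$tDf6$outer), unname(dfs$tDf6$inner))
  expect_equal(unname(dfs$tDf5$outer["start"]), 800)

  mpath <- tempfile(fileext = ".tsv")
  writeLines(c("group_id\tdeficiency\tresult",
               "gA\ttDf5\tunder", "gA\ttDf6\tnot_under"), mpath)
  out <- read_mapping_outcomes(mpath)
  expect_equal(nrow(out), 2L)
  writeLines(c("group_id\tdeficiency\tresult", "gA\ttDf5\tmaybe"), mpath)
  expect_error(read_mapping_outcomes(mpath), "unknown mapping result")
})

test_that("simulated deficiencies with exact spans corroborate correct assignments", {
  cfg <- small_sim_config(seed = 12)
  genome <- simulate_genome(cfg)
  screen <- simulate_screen(cfg, genome)
  cand <- run_cascade(screen$strains, genome$genes, genome$assembly)
  genes_by_id <- setNames(genome$genes,
                          vapply(genome$genes, function(g) g$gene_id,
                                 character(1)))
  for (grp in screen$groups) {
    res <- intersect_candidates(grp, cand)
    gene <- screen$truth$groups$causal_gene[
      screen$truth$groups$group_id == grp$group_id]
    sp <- gene_span(genes_by_id[[gene]])
    df <- deficiency_interval(paste0("df_", grp$group_id), sp$chrom,
                              sp$start - 500, sp$end + 500,
                              left_edge = "sharp", right_edge = "sharp")
    verdict <- corroborate(res, sp,
                           data.frame(group_id = grp$group_id,
                                      deficiency = df$name,
                                      result = "under"),
                           setNames(list(df), df$name))
    expect_equal(as.character(verdict), "consistent")
  }
})
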