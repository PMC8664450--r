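mk_cl <- function(strain, genes, variants = NULL) {
  if (is.null(variants))
    variants <- data.frame(gene_id = genes, effect = "missense",
                           stringsAsFactors = FALSE)
  structure(list(strain_id = strain, variants = variants,
                 genes = sort(unique(genes))),
            class = "candidate_list")
}

test_that("candidate intersection resolves unique, multiple, none and singletons", {
  lists <- list(s1 = mk_cl("s1", c("geneA", "geneB")),
                s2 = mk_cl("s2", c("geneB", "geneC")),
                s3 = mk_cl("s3", c("geneA", "geneB")),
                s4 = mk_cl("s4", c("geneD")))
  uni <- intersect_candidates(complementation_group("g1", c("s1", "s2")),
                              lists)
  expect_equal(uni$status, "unique")
  expect_equal(uni$candidate_genes, "geneB")

  multi <- intersect_candidates(complementation_group("g2", c("s1", "s3")),
                                lists)
  expect_equal(multi$status, "multiple")
  expect_equal(multi$candidate_genes, c("geneA", "geneB"))

  none <- intersect_candidates(complementation_group("g3", c("s2", "s4")),
                               lists)
  expect_equal(none$status, "none")
  expect_equal(none$candidate_genes, character(0))
  expect_true(any(grepl("reanalysis", none$evidence)))

  singleton <- intersect_candidates(complementation_group("g4", "s4"), lists)
  expect_equal(singleton$status, "unresolved_singleton")

  expect_error(intersect_candidates(
    complementation_group("g5", c("s1", "missing")), lists), "missing")

  # symmetry/associativity: member order never changes the result
  rev_multi <- intersect_candidates(
    complementation_group("g2", c("s3", "s1")), lists)
  expect_equal(rev_multi$candidate_genes, multi$candidate_genes)
  tri <- intersect_candidates(
    complementation_group("g6", c("s1", "s2", "s3")), lists)
  tri2 <- intersect_candidates(
    complementation_group("g6", c("s3", "s2", "s1")), lists)
  expect_equal(tri$candidate_genes, tri2$candidate_genes)
})

test_that("severity adjudication prefers genes with severe lesions in all members", {
  v1 <- data.frame(gene_id = c("geneX", "geneY"),
                   effect = c("nonsense", "missense"),
                   stringsAsFactors = FALSE)
  v2 <- data.frame(gene_id = c("geneX", "geneY"),
                   effect = c("nonsense", "missense"),
                   stringsAsFactors = FALSE)
  lists <- list(s1 = mk_cl("s1", c("geneX", "geneY"), v1),
                s2 = mk_cl("s2", c("geneX", "geneY"), v2))
  res <- intersect_candidates(complementation_group("g", c("s1", "s2")),
                              lists)
  expect_equal(res$status, "multiple")

  adj <- adjudicate_multiple(res, lists, enabled = TRUE)
  expect_equal(adj$status, "unique")
  expect_equal(adj$candidate_genes, "geneX")
  expect_true(any(grepl("adjudicated", adj$evidence)))

  # both genes nonsense-supported: tie preserved
  v_tie <- data.frame(gene_id = c("geneX", "geneY"),
                      effect = c("nonsense", "nonsense"),
                      stringsAsFactors = FALSE)
  lists_tie <- list(s1 = mk_cl("s1", c("geneX", "geneY"), v_tie),
                    s2 = mk_cl("s2", c("geneX", "geneY"), v_tie))
  res_tie <- intersect_candidates(complementation_group("g", c("s1", "s2")),
                                  lists_tie)
  expect_equal(adjudicate_multiple(res_tie, lists_tie,
                                   enabled = TRUE)$status, "multiple")
  # disabled: unchanged
  expect_equal(adjudicate_multiple(res, lists), res)
})

catalog_conflict_fixture <- function() {
  cat <- load_catalog_tables()
  membership <- setNames(cat$conflict_strains$group_id,
                         cat$conflict_strains$strain_id)
  resolutions <- list(
    screenmap:::new_resolution("gene-28", "unique", "bckd-1A",
                               member_strains = "GE1742"),
    screenmap:::new_resolution("gene-17", "unique", "bckd-1A",
                               member_strains = c("GE2627", "GE2206")),
    screenmap:::new_resolution("gene-15", "unique", "top-3",
                               member_strains = c("GE2220", "GE2399")),
    screenmap:::new_resolution("gene-34", "none", character(0),
                               member_strains = "GE2278"),
    screenmap:::new_resolution("gene-35", "unique", "top-3",
                               member_strains = "GE1735"))
  list(membership = membership, resolutions = resolutions,
       tests = cat$conflict_tests)
}

test_that("groups failing to complement with a shared gene are merged", {
  fx <- catalog_conflict_fixture()
  merged <- merge_groups(fx$resolutions, fx$tests, fx$membership)
  ids <- vapply(merged, function(r) r$group_id, character(1))
  expect_true("gene-17+gene-28" %in% ids)
  m <- merged[[which(ids == "gene-17+gene-28")]]
  expect_equal(m$status, "merged")
  expect_equal(m$candidate_genes, "bckd-1A")
  # merging never splits groups or invents genes
  expect_setequal(m$member_strains, c("GE1742", "GE2627", "GE2206"))
})

test_that("a group failing to complement two mutually complementing groups is a double mutant", {
  fx <- catalog_conflict_fixture()
  merged <- merge_groups(fx$resolutions, fx$tests, fx$membership)
  ids <- vapply(merged, function(r) r$group_id, character(1))
  dm <- merged[[which(ids == "gene-35")]]
  expect_equal(dm$status, "double_mutant")
  expect_true("top-3" %in% dm$candidate_genes)
  expect_true(any(grepl("two genes", dm$evidence)))
  # gene-15 itself must not be absorbed into the double-mutant group
  expect_true("gene-15" %in% ids)
  expect_equal(merged[[which(ids == "gene-15")]]$status, "unique")
})

test_that("inconsistent or empty test sets are handled", {
  fx <- catalog_conflict_fixture()
  expect_equal(merge_groups(fx$resolutions, fx$tests[0, ], fx$membership),
               fx$resolutions)
  bad <- rbind(fx$tests,
               data.frame(strain_a = "GE2206", strain_b = "GE1742",
                          outcome = "complements"))
  expect_error(merge_groups(fx$resolutions, bad, fx$membership),
               "inconsistent|Inconsistent")
  unknown <- data.frame(strain_a = "GEX", strain_b = "GE1742",
                        outcome = "complements")
  expect_error(merge_groups(fx$resolutions, unknown, fx$membership),
               "unknown strain")
})
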