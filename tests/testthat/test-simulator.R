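test_that("simulated genomes carry well-formed genes and honour the geometry", {
  cfg <- small_sim_config(seed = 3)
  genome <- simulate_genome(cfg)
  expect_length(genome$genes, cfg$n_chromosomes * cfg$genes_per_chromosome)
  expect_length(genome$assembly$chromosomes, cfg$n_chromosomes)
  strands <- vapply(genome$genes, function(g) g$strand, character(1))
  expect_setequal(unique(strands), c("+", "-"))
  for (g in genome$genes) {
    prot <- translate_cds(cds_sequence(longest_transcript(g),
                                       genome$assembly))
    expect_equal(substr(prot, 1, 1), "M")
    expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
    # generator bookkeeping agrees with the gene-model route
    expect_equal(prot, genome$anatomy[[g$gene_id]]$protein)
  }
  empty <- simulate_genome(simulation_config(seed = 1, n_chromosomes = 1,
                                             genes_per_chromosome = 0,
                                             n_groups = 0,
                                             intergenic_bp = 5000))
  expect_length(empty$genes, 0L)
  expect_length(empty$assembly$chromosomes, 1L)
})

test_that("identical seeds give byte-identical FASTA, GFF3 and VCF outputs", {
  cfg <- small_sim_config(seed = 9)
  dir1 <- file.path(tempdir(), "run_a")
  dir2 <- file.path(tempdir(), "run_b")
  for (d in c(dir1, dir2)) {
    genome <- simulate_genome(cfg)
    screen <- simulate_screen(cfg, genome)
    write_screen_run(genome, screen, d)
  }
  for (f in c("genome.fa", "genes.gff3", "strain_metadata.tsv",
              "truth_causal.tsv", "truth_background.tsv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
  vcfs <- list.files(file.path(dir1, "strains"))
  expect_identical(
    readLines(file.path(dir1, "strains", vcfs[1])),
    readLines(file.path(dir2, "strains", vcfs[1])))
  # a different seed changes the genome
  other <- simulate_genome(small_sim_config(seed = 10))
  expect_false(identical(other$assembly$chromosomes,
                         simulate_genome(cfg)$assembly$chromosomes))
})

test_that("emitted run directories round-trip through the package readers", {
  cfg <- small_sim_config(seed = 4)
  genome <- simulate_genome(cfg)
  screen <- simulate_screen(cfg, genome)
  dir <- file.path(tempdir(), "run_rt")
  write_screen_run(genome, screen, dir)

  asm <- read_assembly(file.path(dir, "genome.fa"))
  expect_equal(asm$chromosomes, genome$assembly$chromosomes)
  models <- load_gene_models(file.path(dir, "genes.gff3"))
  expect_length(models, length(genome$genes))
  got_cds <- vapply(models, function(g)
    cds_sequence(longest_transcript(g), asm), character(1))
  want_cds <- vapply(genome$genes, function(g)
    cds_sequence(longest_transcript(g), genome$assembly), character(1))
  expect_setequal(got_cds, want_cds)

  meta <- read_strain_metadata(file.path(dir, "strain_metadata.tsv"))
  expect_equal(nrow(meta), length(screen$strains))
  s1 <- screen$strains[[1]]
  back <- read_strain_vcf(file.path(dir, "strains",
                                    paste0(s1$strain_id, ".vcf")),
                          s1$strain_id, s1$collection,
                          s1$mapped_chromosome)
  expect_equal(back$calls[, c("chrom", "pos", "ref", "alt", "total_depth",
                              "alt_depth")],
               s1$calls[, c("chrom", "pos", "ref", "alt", "total_depth",
                            "alt_depth")])
})

test_that("truth tables satisfy the screen's structural invariants", {
  cfg <- small_sim_config(seed = 8)
  genome <- simulate_genome(cfg)
  screen <- simulate_screen(cfg, genome)
  truth <- screen$truth
  expect_equal(nrow(truth$groups), cfg$n_groups)
  for (g in truth$groups$group_id) {
    rows <- truth$causal[truth$causal$group_id == g, ]
    expect_equal(nrow(rows), cfg$strains_per_group)
    expect_length(unique(rows$gene_id), 1L)
    expect_gt(length(unique(rows$pos)), 1L)  # distinct lesions per strain
    f <- rows$alt_depth / rows$total_depth
    expect_true(all(f >= 0.2 & f <= 0.8))    # causal lesions heterozygous
  }
  # causal genes sampled without replacement
  expect_false(anyDuplicated(truth$groups$causal_gene) > 0)
  # the EMS signature dominates the background SNVs
  bg <- truth$background
  snv <- bg[nchar(bg$ref) == 1 & nchar(bg$alt) == 1, ]
  transitions <- (snv$ref == "G" & snv$alt == "A") |
    (snv$ref == "C" & snv$alt == "T")
  expect_gt(mean(transitions), 0.85)
  # recurrent decoys are shared by as many strains of their collection as
  # the configuration allows (all carriers in one collection)
  rec <- bg[bg$class == "recurrent", ]
  coll_of <- setNames(truth$strains$collection, truth$strains$strain_id)
  coll_size <- table(truth$strains$collection)
  for (site in unique(paste(rec$chrom, rec$pos))) {
    carriers <- rec$strain_id[paste(rec$chrom, rec$pos) == site]
    colls <- unique(coll_of[carriers])
    expect_length(colls, 1L)
    expect_equal(length(carriers),
                 min(cfg$recurrent_decoy_strains,
                     unname(coll_size[colls])))
  }
})

test_that("heterozygous depth draws hit the configured coverage model", {
  cfg <- simulation_config(seed = 1)
  set.seed(123)
  draws <- draw_het_depths(cfg, 10000)
  expect_true(all(draws$total_depth >= cfg$depth_min))
  expect_true(all(draws$total_depth <= cfg$depth_max))
  expect_lt(abs(mean(draws$total_depth) - cfg$depth_mean), 1)
  expect_lt(abs(mean(draws$alt_depth / draws$total_depth) - 0.5), 0.01)
})

test_that("configuration contradictions are rejected", {
  expect_error(simulation_config(causal_effect_mix = c(missense = 0.5)),
               "sum to 1")
  expect_error(simulation_config(causal_effect_mix = c(banana = 1)),
               "must be among")
  expect_error(simulation_config(depth_min = 50, depth_mean = 40,
                                 depth_max = 60), "depth_min")
  expect_error(simulation_config(strains_per_group = 1), ">= 2")
  expect_error(simulation_config(n_groups = 1000), "not enough genes")
  expect_error(simulation_config(ems_transition_fraction = 1.2), "\\[0, 1\\]")
})

test_that("evaluation scores resolutions against the truth table", {
  cfg <- small_sim_config(seed = 2)
  run <- run_simulated_screen(cfg)
  ev <- run$evaluation
  expect_equal(ev$recovery, 1)
  expect_true(all(ev$per_group$outcome %in%
                    c("recovered_unique", "recovered_among_multiple")))
  # empty resolutions: everything missed
  none <- lapply(run$screen$groups, function(g)
    screenmap:::new_resolution(g$group_id, "none", character(0)))
  ev0 <- evaluate_against_truth(none, run$screen$truth)
  expect_equal(ev0$recovery, 0)
  expect_true(all(ev0$per_group$outcome == "missed"))
  # mismatched group sets are an error
  expect_error(evaluate_against_truth(none[-1], run$screen$truth),
               "different groups")
})
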