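test_that("engineered codon changes annotate with catalog-style aa strings", {
  p <- toy_gene_plus()
  seq <- p$assembly$chromosomes[["chrT"]]
  ann1 <- annotate_variant(
    list(chrom = "chrT", pos = toy_plus_genomic(184), ref = "C", alt = "T"),
    list(p$gene), p$assembly)          # codon 62 CGT -> TGT
  expect_equal(ann1$effect, "missense")
  expect_equal(ann1$aa_change, "R62C")

  ann2 <- annotate_variant(
    list(chrom = "chrT", pos = toy_plus_genomic(573), ref = "C", alt = "A"),
    list(p$gene), p$assembly)          # codon 191 TGC -> TGA
  expect_equal(ann2$effect, "nonsense")
  expect_equal(ann2$aa_change, "C191*")

  ann3 <- annotate_variant(
    list(chrom = "chrT", pos = toy_plus_genomic(3), ref = "G", alt = "A"),
    list(p$gene), p$assembly)          # ATG -> ATA
  expect_equal(ann3$effect, "start_loss")
  expect_equal(ann3$aa_change, "M1I")

  ann4 <- annotate_variant(
    list(chrom = "chrT", pos = toy_plus_genomic(30), ref = "A", alt = "G"),
    list(p$gene), p$assembly)          # GAA -> GAG
  expect_equal(ann4$effect, "synonymous")

  del <- list(chrom = "chrT", pos = 600L,
              ref = substr(seq, 600, 602), alt = substr(seq, 600, 600))
  ann5 <- annotate_variant(del, list(p$gene), p$assembly)
  expect_equal(ann5$effect, "frameshift")
  expect_true(is.na(ann5$aa_change))

  ann6 <- annotate_variant(
    list(chrom = "chrT", pos = 351L, ref = "G", alt = "A"),
    list(p$gene), p$assembly)          # first intron base
  expect_equal(ann6$effect, "splice_site")

  # indel spanning the exon-intron boundary
  boundary <- list(chrom = "chrT", pos = 349L,
                   ref = substr(seq, 349, 352), alt = substr(seq, 349, 349))
  expect_equal(annotate_variant(boundary, list(p$gene),
                                p$assembly)$effect, "splice_site")

  expect_error(annotate_variant(
    list(chrom = "chrT", pos = toy_plus_genomic(184), ref = "A", alt = "T"),
    list(p$gene), p$assembly), "reference mismatch")
})

test_that("mirror-image minus-strand gene yields identical aa changes", {
  p <- toy_gene_plus()
  m <- toy_gene_minus()
  cases <- list(c(184L, "T"), c(573L, "A"), c(3L, "A"), c(30L, "G"),
                c(250L, "C"))
  for (cs in cases) {
    i <- as.integer(cs[1]); alt <- cs[2]
    pos_p <- toy_plus_genomic(i)
    ann_p <- annotate_variant(
      list(chrom = "chrT", pos = pos_p,
           ref = substr(p$assembly$chromosomes[["chrT"]], pos_p, pos_p),
           alt = alt),
      list(p$gene), p$assembly)
    pos_m <- m$mirror(pos_p)
    ann_m <- annotate_variant(
      list(chrom = "chrT", pos = pos_m,
           ref = substr(m$assembly$chromosomes[["chrT"]], pos_m, pos_m),
           alt = screenmap:::complement_base(alt)),
      list(m$gene), m$assembly)
    expect_equal(ann_m$effect, ann_p$effect)
    expect_equal(ann_m$aa_change, ann_p$aa_change)
    expect_equal(ann_m$cds_index, ann_p$cds_index)
  }
})

test_that("200 random SNVs match the full-retranslation oracle", {
  for (fixture in list(toy_gene_plus(), toy_gene_minus())) {
    seq <- fixture$assembly$chromosomes[["chrT"]]
    set.seed(314)
    positions <- sample(nchar(seq), 100)
    for (pos in positions) {
      ref <- substr(seq, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      got <- annotate_variant(list(chrom = "chrT", pos = pos, ref = ref,
                                   alt = alt),
                              list(fixture$gene), fixture$assembly)
      want <- oracle_snv_effect(fixture$gene, fixture$assembly, pos, alt)
      expect_equal(got$effect, want$effect,
                   label = sprintf("effect at pos %d (%s strand)", pos,
                                   fixture$gene$strand))
      if (got$effect %in% c("missense", "nonsense", "start_loss",
                            "synonymous"))
        expect_equal(got$aa_change, want$aa_change)
    }
  }
})

test_that("annotation against a gene set equals the union over single genes", {
  p <- toy_gene_plus()
  chrom <- paste0(p$assembly$chromosomes[["chrT"]],
                  p$assembly$chromosomes[["chrT"]])
  asm <- genome_assembly(c(chrT = chrom))
  shift <- nchar(p$assembly$chromosomes[["chrT"]])
  ex2 <- data.frame(start = p$tx$exons$start + shift,
                    end = p$tx$exons$end + shift)
  tx2 <- screenmap:::new_transcript("toyh.t1", "toyh", "chrT", "+", ex2, ex2)
  gene2 <- screenmap:::new_gene_model("toyh", "toy-2", "chrT", list(tx2))
  calls <- make_calls("chrT",
                      c(toy_plus_genomic(184), toy_plus_genomic(184) + shift),
                      "C", "T", 38, 19)
  set <- strain_variant_set("s", "A", "chrT", calls)
  both <- annotate_calls(set, list(p$gene, gene2), asm)
  one <- rbind(annotate_calls(set, list(p$gene), asm),
               annotate_calls(set, list(gene2), asm))
  both_genic <- both[!is.na(both$gene_id), ]
  one_genic <- one[!is.na(one$gene_id), ]
  ord <- function(d) { d <- d[order(d$pos, d$gene_id), ]; rownames(d) <- NULL; d }
  expect_equal(ord(both_genic), ord(one_genic))
  expect_equal(both_genic$aa_change, c("R62C", "R62C"))
})

test_that("aa-change formatting and candidate classes follow the catalog conventions", {
  expect_equal(format_aa_change("R", 62, "C"), "R62C")
  expect_equal(format_aa_change("Q", 367, "*"), "Q367*")
  expect_equal(format_aa_change("M", 1, "M"), "M1M")
  expect_error(format_aa_change("R", 0, "C"), ">= 1")
  expect_error(format_aa_change("B", 10, "C"), "amino-acid")

  expect_true(all(effect_is_candidate(c("missense", "nonsense",
                                        "splice_site", "start_loss",
                                        "frameshift", "inframe_indel"))))
  expect_false(any(effect_is_candidate(c("synonymous", "noncoding"))))
  expect_error(effect_is_candidate("banana"))
})
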