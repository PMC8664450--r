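# Synthetic EMS-screen simulator.
#
# Generates a toy genome with multi-exon protein-coding genes, then a
# balancer-style screen: for each complementation group a causal gene is
# chosen and each member strain receives one distinct heterozygous
# protein-affecting lesion in that gene, on top of abundant strain-private
# background mutations with an EMS-biased spectrum (G:C -> A:T transitions),
# planted recurrent decoys shared across strains of a collection, and a
# configurable fraction of homozygous background calls. Read depths emulate
# short-read coverage (21x-65x, mean 38x) with binomial allele sampling.
#
# The generator keeps its own anatomy bookkeeping (exploded genomic->CDS
# maps, splice and intron position sets built during gene construction) and
# derives the truth table from it, independently of the annotation module,
# so pipeline-vs-truth comparisons are dual-route.

NONSTOP_CODONS <- names(CODON_TABLE)[CODON_TABLE != "*"]
STOP_CODONS <- names(CODON_TABLE)[CODON_TABLE == "*"]
HET_BAND <- c(0.2, 0.8)  # canonical heterozygous allele-fraction band

#' Simulation configuration
#'
#' Defaults encode the screen the package models: two or more balancer-
#' maintained heterozygous alleles per complementation group, depth of
#' coverage between 21x and 65x averaging 38x with heterozygous alt
#' fractions near 0.5, an EMS-dominated mutation spectrum, and recurrent
#' decoys shared by more strains than the recurrence filter tolerates.
#'
#' @param seed integer seed; all outputs are deterministic given the config.
#' @param n_chromosomes,genes_per_chromosome toy genome geometry.
#' @param gene_length_bp target CDS length per gene, bp.
#' @param intergenic_bp mean intergenic spacer, bp.
#' @param n_groups number of complementation groups.
#' @param strains_per_group alleles sequenced per group (>= 2).
#' @param background_mutations_per_strain strain-private background variants.
#' @param ems_transition_fraction probability a background mutation is a
#'   G:C -> A:T transition (EMS signature); the remainder are transversions
#'   or, with `indel_fraction`, small deletions.
#' @param indel_fraction fraction of non-transition background mutations
#'   emitted as 1-2 bp deletions.
#' @param causal_effect_mix named probabilities over
#'   `missense`, `nonsense`, `splice_site`, `frameshift`, `start_loss`.
#' @param depth_mean,depth_min,depth_max read-depth model (discrete uniform
#'   on `[depth_min, 2*depth_mean - depth_min]`, clipped at `depth_max`,
#'   which hits `depth_mean` exactly).
#' @param het_alt_probability binomial success probability for heterozygous
#'   alt reads.
#' @param homozygous_decoy_fraction fraction of background mutations emitted
#'   homozygous (alt depth = total depth).
#' @param recurrent_decoy_strains number of strains sharing each planted
#'   recurrent decoy (default 4, one more than the recurrence filter keeps).
#' @param n_recurrent_decoys recurrent decoys planted per collection.
#' @return a `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 3L,
                              genes_per_chromosome = 10L,
                              gene_length_bp = 1200L,
                              intergenic_bp = 80000L,
                              n_groups = 20L,
                              strains_per_group = 2L,
                              background_mutations_per_strain = 150L,
                              ems_transition_fraction = 0.95,
                              indel_fraction = 0.1,
                              causal_effect_mix = c(missense = 0.45,
                                                    nonsense = 0.30,
                                                    splice_site = 0.10,
                                                    frameshift = 0.10,
                                                    start_loss = 0.05),
                              depth_mean = 38L, depth_min = 21L,
                              depth_max = 65L,
                              het_alt_probability = 0.5,
                              homozygous_decoy_fraction = 0.2,
                              recurrent_decoy_strains = 4L,
                              n_recurrent_decoys = 5L) {
  probs <- c(ems_transition_fraction, indel_fraction, het_alt_probability,
             homozygous_decoy_fraction)
  if (any(probs < 0 | probs > 1))
    stop_ctx("probabilities must lie in [0, 1]")
  allowed <- c("missense", "nonsense", "splice_site", "frameshift",
               "start_loss")
  if (!all(names(causal_effect_mix) %in% allowed))
    stop_ctx("causal_effect_mix names must be among %s",
             paste(allowed, collapse = ", "))
  if (abs(sum(causal_effect_mix) - 1) > 1e-8)
    stop_ctx("causal_effect_mix must sum to 1")
  if (!(depth_min <= depth_mean && depth_mean <= depth_max))
    stop_ctx("need depth_min <= depth_mean <= depth_max")
  if (strains_per_group < 2L)
    stop_ctx("strains_per_group must be >= 2")
  if (n_groups > n_chromosomes * genes_per_chromosome)
    stop_ctx("not enough genes (%d) to assign one causal gene per group (%d)",
             n_chromosomes * genes_per_chromosome, n_groups)
  structure(list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    gene_length_bp = as.integer(gene_length_bp),
    intergenic_bp = as.integer(intergenic_bp),
    n_groups = as.integer(n_groups),
    strains_per_group = as.integer(strains_per_group),
    background_mutations_per_strain =
      as.integer(background_mutations_per_strain),
    ems_transition_fraction = ems_transition_fraction,
    indel_fraction = indel_fraction,
    causal_effect_mix = causal_effect_mix,
    depth_mean = as.integer(depth_mean), depth_min = as.integer(depth_min),
    depth_max = as.integer(depth_max),
    het_alt_probability = het_alt_probability,
    homozygous_decoy_fraction = homozygous_decoy_fraction,
    recurrent_decoy_strains = as.integer(recurrent_decoy_strains),
    n_recurrent_decoys = as.integer(n_recurrent_decoys)),
    class = "simulation_config")
}

rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# one gene block in local (block) coordinates; sense construction, then
# mirrored for minus-strand genes
make_gene_block <- function(cfg) {
  n_codons <- max(60L, round(cfg$gene_length_bp / 3 *
                               stats::runif(1, 0.7, 1.3)))
  body <- sample(NONSTOP_CODONS, n_codons - 2L, replace = TRUE)
  cds <- paste0("ATG", paste(body, collapse = ""),
                sample(STOP_CODONS, 1L))
  L <- nchar(cds)
  n_introns <- sample(1:3, 1L)
  repeat {
    cuts <- sort(sample(seq(30L, L - 30L), n_introns))
    if (n_introns == 1L || min(diff(cuts)) >= 30L) break
  }
  piece_start <- c(1L, cuts + 1L)
  piece_end <- c(cuts, L)
  intron_len <- sample(50:90, n_introns, replace = TRUE)
  intron_seq <- vapply(intron_len, function(l)
    paste0("GT", rand_dna(l - 4L), "AG"), character(1))

  cds_off <- integer(L)            # sense offset of each CDS index
  intron_off <- vector("list", n_introns)
  parts <- character(0)
  off <- 0L
  for (k in seq_along(piece_start)) {
    w <- piece_end[k] - piece_start[k] + 1L
    cds_off[piece_start[k]:piece_end[k]] <- (off + 1L):(off + w)
    parts <- c(parts, substr(cds, piece_start[k], piece_end[k]))
    off <- off + w
    if (k <= n_introns) {
      intron_off[[k]] <- (off + 1L):(off + intron_len[k])
      parts <- c(parts, intron_seq[k])
      off <- off + intron_len[k]
    }
  }
  B <- off
  sense_block <- paste(parts, collapse = "")
  strand <- sample(c("+", "-"), 1L)
  f <- if (strand == "+") identity else function(o) B - o + 1L

  exon_segs <- data.frame(t(vapply(seq_along(piece_start), function(k) {
    a <- f(cds_off[piece_start[k]])
    b <- f(cds_off[piece_end[k]])
    c(min(a, b), max(a, b))
  }, integer(2))))
  names(exon_segs) <- c("start", "end")
  intron_segs <- data.frame(t(vapply(intron_off, function(v)
    range(f(v)), integer(2))))
  names(intron_segs) <- c("start", "end")
  splice_local <- sort(unlist(lapply(intron_off, function(v)
    f(c(v[1:2], v[length(v) - 1L], v[length(v)])))))
  intron_all <- unlist(lapply(intron_off, f))

  list(seq = if (strand == "-") reverse_complement(sense_block)
             else sense_block,
       length = B, strand = strand, cds = cds,
       cds_pos = f(cds_off),                    # transcription order
       exon_segs = exon_segs[order(exon_segs$start), , drop = FALSE],
       intron_segs = intron_segs[order(intron_segs$start), , drop = FALSE],
       splice_pos = splice_local,
       intron_interior_pos = sort(setdiff(intron_all, splice_local)))
}

#' Simulate a toy genome with gene models
#'
#' Generates `n_chromosomes` chromosomes carrying non-overlapping multi-exon
#' genes on both strands, every CDS starting with ATG, ending in a single
#' terminal stop codon and free of internal stops. Deterministic under the
#' config seed; the caller's RNG state is untouched.
#'
#' @param cfg a [simulation_config()].
#' @return a `sim_genome`: list with `assembly` ([genome_assembly()]),
#'   `genes` (gene models) and `anatomy` (the generator's own per-gene
#'   bookkeeping: CDS strings, exploded genomic->CDS maps, splice and
#'   intron position sets).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    chrom_names <- paste0("chr", utils::as.roman(seq_len(cfg$n_chromosomes)))
    seqs <- stats::setNames(character(cfg$n_chromosomes), chrom_names)
    genes <- list()
    anatomy <- list()
    gid <- 0L
    for (ci in seq_len(cfg$n_chromosomes)) {
      pieces <- character(0)
      offset <- 0L
      for (gi in seq_len(cfg$genes_per_chromosome)) {
        spacer <- round(stats::runif(1, 0.8, 1.2) * cfg$intergenic_bp)
        pieces <- c(pieces, rand_dna(spacer))
        offset <- offset + spacer
        blk <- make_gene_block(cfg)
        gid <- gid + 1L
        gene_id <- sprintf("sgene%03d", gid)
        tx_id <- paste0(gene_id, ".t1")
        shift <- function(x) x + offset
        exons <- data.frame(start = shift(blk$exon_segs$start),
                            end = shift(blk$exon_segs$end))
        tx <- new_transcript(tx_id, gene_id, chrom_names[ci], blk$strand,
                             exons, exons)
        genes[[gene_id]] <- new_gene_model(gene_id, gene_id,
                                           chrom_names[ci], list(tx))
        anatomy[[gene_id]] <- list(
          gene_id = gene_id, chrom = chrom_names[ci], strand = blk$strand,
          span = c(start = offset + 1L, end = offset + blk$length),
          cds = blk$cds,
          protein = translate_cds(blk$cds),
          cds_pos = shift(blk$cds_pos),
          exon_segs = data.frame(start = shift(blk$exon_segs$start),
                                 end = shift(blk$exon_segs$end)),
          intron_segs = data.frame(start = shift(blk$intron_segs$start),
                                   end = shift(blk$intron_segs$end)),
          splice_pos = shift(blk$splice_pos),
          intron_interior_pos = shift(blk$intron_interior_pos))
        pieces <- c(pieces, blk$seq)
        offset <- offset + blk$length
      }
      pieces <- c(pieces, rand_dna(cfg$intergenic_bp))
      seqs[ci] <- paste(pieces, collapse = "")
    }
    structure(list(assembly = genome_assembly(seqs),
                   genes = unname(genes), anatomy = anatomy),
              class = "sim_genome")
  })
}

draw_depths <- function(cfg, n) {
  hi <- min(cfg$depth_max, 2L * cfg$depth_mean - cfg$depth_min)
  sample(seq(cfg$depth_min, hi), n, replace = TRUE)
}

# heterozygous alt-depth draw truncated to the heterozygous band; used for
# planted causal variants, whose carriers are balanced heterozygotes by
# construction
draw_het_alt <- function(depth, p) {
  for (i in 1:200) {
    a <- stats::rbinom(1L, depth, p)
    f <- a / depth
    if (f >= HET_BAND[1L] && f <= HET_BAND[2L]) return(a)
  }
  round(depth * p)
}

#' Draw heterozygous call depths from the simulator's read-depth model
#'
#' Utility for inspecting the depth model: total depths from the discrete
#' uniform model and alt depths from the band-truncated binomial used for
#' heterozygous carriers.
#'
#' @param cfg a [simulation_config()].
#' @param n number of calls.
#' @return data.frame with `total_depth`, `alt_depth`.
#' @export
draw_het_depths <- function(cfg, n) {
  d <- draw_depths(cfg, n)
  a <- vapply(d, draw_het_alt, integer(1), p = cfg$het_alt_probability)
  data.frame(total_depth = d, alt_depth = a)
}

# generator-side effect classification from anatomy bookkeeping (no use of
# the annotation module)
sim_effect_of <- function(anatomy_by_chrom, chrom, pos, ref, alt) {
  genes <- anatomy_by_chrom[[chrom]]
  iv <- c(pos, pos + nchar(ref) - 1L)
  for (an in genes) {
    if (iv[2L] < an$span["start"] || iv[1L] > an$span["end"]) next
    if (nchar(ref) == 1L && nchar(alt) == 1L) {
      i <- match(pos, an$cds_pos)
      if (!is.na(i)) {
        base <- if (an$strand == "-") complement_base(alt) else alt
        codon_i <- ((i - 1L) %/% 3L) + 1L
        cstart <- (codon_i - 1L) * 3L + 1L
        ref_codon <- substr(an$cds, cstart, cstart + 2L)
        alt_codon <- ref_codon
        substr(alt_codon, i - cstart + 1L, i - cstart + 1L) <- base
        ref_aa <- unname(CODON_TABLE[ref_codon])
        alt_aa <- unname(CODON_TABLE[alt_codon])
        eff <- if (alt_aa == ref_aa) "synonymous"
          else if (codon_i == 1L && ref_aa == "M") "start_loss"
          else if (alt_aa == "*") "nonsense" else "missense"
        return(list(gene_id = an$gene_id, effect = eff))
      }
      if (pos %in% an$splice_pos)
        return(list(gene_id = an$gene_id, effect = "splice_site"))
      return(list(gene_id = an$gene_id, effect = "noncoding"))
    }
    in_cds <- any(iv[1L] <= an$exon_segs$end & iv[2L] >= an$exon_segs$start)
    in_intron <- nrow(an$intron_segs) > 0L &&
      any(iv[1L] <= an$intron_segs$end & iv[2L] >= an$intron_segs$start)
    eff <- if (in_cds && in_intron) "splice_site"
      else if (in_cds) {
        if (abs(nchar(ref) - nchar(alt)) %% 3L != 0L) "frameshift"
        else "inframe_indel"
      } else if (any(an$splice_pos >= iv[1L] & an$splice_pos <= iv[2L]))
        "splice_site"
      else "noncoding"
    return(list(gene_id = an$gene_id, effect = eff))
  }
  list(gene_id = NA_character_, effect = "noncoding")
}

# plant one causal lesion of the requested class in a gene; returns
# chrom/pos/ref/alt/effect; `used` holds genomic anchor positions already
# taken in this gene
plant_causal <- function(an, effect, assembly, used) {
  seq <- assembly$chromosomes[[an$chrom]]
  base_at <- function(p) substr(seq, p, p)
  L <- nchar(an$cds)
  comp <- an$strand == "-"
  emit <- function(pos, ref, alt, eff)
    list(chrom = an$chrom, pos = pos, ref = ref, alt = alt, effect = eff)

  if (effect %in% c("missense", "nonsense")) {
    idx <- sample(setdiff(4:(L - 3L), NULL))
    for (i in idx) {
      pos <- an$cds_pos[i]
      if (pos %in% used) next
      codon_i <- ((i - 1L) %/% 3L) + 1L
      cstart <- (codon_i - 1L) * 3L + 1L
      ref_codon <- substr(an$cds, cstart, cstart + 2L)
      ref_aa <- unname(CODON_TABLE[ref_codon])
      sense_ref <- substr(an$cds, i, i)
      alts <- setdiff(c("A", "C", "G", "T"), sense_ref)
      # EMS-flavoured ordering: try the transition first when available
      trans <- c(G = "A", C = "T", A = "G", T = "C")[[sense_ref]]
      alts <- c(trans, setdiff(alts, trans))
      for (b in alts) {
        alt_codon <- ref_codon
        substr(alt_codon, i - cstart + 1L, i - cstart + 1L) <- b
        alt_aa <- unname(CODON_TABLE[alt_codon])
        ok <- if (effect == "nonsense") (alt_aa == "*" && ref_aa != "*")
              else (alt_aa != ref_aa && alt_aa != "*" && ref_aa != "*")
        if (ok) {
          return(emit(pos, base_at(pos),
                      if (comp) complement_base(b) else b, effect))
        }
      }
    }
    stop_ctx("could not plant a %s lesion in gene %s", effect, an$gene_id)
  }
  if (effect == "start_loss") {
    for (i in sample(1:3)) {
      pos <- an$cds_pos[i]
      if (pos %in% used) next
      sense_ref <- substr(an$cds, i, i)
      for (b in sample(setdiff(c("A", "C", "G", "T"), sense_ref))) {
        alt_codon <- substr(an$cds, 1L, 3L)
        substr(alt_codon, i, i) <- b
        aa <- unname(CODON_TABLE[alt_codon])
        if (aa != "M" && aa != "*")
          return(emit(pos, base_at(pos),
                      if (comp) complement_base(b) else b, "start_loss"))
      }
    }
    stop_ctx("could not plant a start-loss lesion in gene %s", an$gene_id)
  }
  if (effect == "splice_site") {
    for (pos in sample(an$splice_pos)) {
      if (pos %in% used) next
      ref <- base_at(pos)
      alt <- switch(ref, G = "A", C = "T",
                    sample(setdiff(c("A", "C", "G", "T"), ref), 1L))
      return(emit(pos, ref, alt, "splice_site"))
    }
    stop_ctx("no free splice position in gene %s", an$gene_id)
  }
  if (effect == "frameshift") {
    segs <- an$exon_segs[an$exon_segs$end - an$exon_segs$start + 1L >= 6L, ,
                         drop = FALSE]
    for (k in sample(nrow(segs))) {
      lo <- segs$start[k] + 1L
      hi <- segs$end[k] - 2L
      for (pos in sample(lo:hi, min(20L, hi - lo + 1L))) {
        if (pos %in% used) next
        ref <- substr(assembly$chromosomes[[an$chrom]], pos, pos + 1L)
        return(emit(pos, ref, substr(ref, 1L, 1L), "frameshift"))
      }
    }
    stop_ctx("could not plant a frameshift lesion in gene %s", an$gene_id)
  }
  if (effect == "intron_interior") {
    for (pos in sample(an$intron_interior_pos)) {
      if (pos %in% used) next
      ref <- base_at(pos)
      alt <- switch(ref, G = "A", C = "T",
                    sample(setdiff(c("A", "C", "G", "T"), ref), 1L))
      return(emit(pos, ref, alt, "intron_interior"))
    }
  }
  stop_ctx("unknown causal effect class '%s'", effect)
}

#' Simulate an EMS screen over a simulated genome
#'
#' For each complementation group a causal gene is sampled without
#' replacement and each member strain receives one distinct heterozygous
#' protein-affecting lesion in it (effect class drawn from
#' `causal_effect_mix`). Strains additionally carry EMS-biased background
#' mutations (some homozygous), and each collection carries planted
#' recurrent decoys shared by `recurrent_decoy_strains` strains. The
#' strain's mapped chromosome is the causal gene's chromosome, and its
#' collection is `"A"` for the first chromosome and `"B"` otherwise.
#'
#' The returned truth table records, for every planted variant, its class,
#' realized zygosity, generator-side effect, and the filter-cascade stage
#' expected to remove it (or `"none"` for surviving causal candidates),
#' computed from the generator's own bookkeeping.
#'
#' @param cfg a [simulation_config()].
#' @param genome a [simulate_genome()] result (must come from the same
#'   config geometry).
#' @param deep_intronic_groups group ids whose causal lesions are planted in
#'   intron interiors instead (reproducing the escape mode in which an
#'   intronic causal allele fails the effect filter).
#' @return a `sim_screen`: list with `strains` (named list of
#'   [strain_variant_set()]s), `groups` (named list of
#'   [complementation_group()]s), and `truth` (list of data.frames
#'   `strains`, `groups`, `causal`, `background`).
#' @export
simulate_screen <- function(cfg, genome, deep_intronic_groups = character(0)) {
  stopifnot(inherits(cfg, "simulation_config"),
            inherits(genome, "sim_genome"))
  with_seed((cfg$seed + 1000003L) %% 2147483647L, {
    assembly <- genome$assembly
    anatomy <- genome$anatomy
    chrom_names <- names(assembly$chromosomes)
    chrom_len <- assembly$lengths
    anatomy_by_chrom <- split(anatomy,
                              vapply(anatomy, function(a) a$chrom,
                                     character(1)))

    group_ids <- sprintf("grp%02d", seq_len(cfg$n_groups))
    if (!all(deep_intronic_groups %in% group_ids))
      stop_ctx("deep_intronic_groups contains unknown group id")
    causal_gene_ids <- sample(names(anatomy), cfg$n_groups)
    groups <- list()
    strain_rows <- list()
    causal_rows <- list()
    calls_by_strain <- list()
    bg_rows <- list()
    sid <- 0L

    mk_snv_alt <- function(ref) switch(ref, G = "A", C = "T",
                                       A = sample(c("C", "T"), 1L),
                                       T = sample(c("A", "G"), 1L))

    for (g in seq_len(cfg$n_groups)) {
      gene_id <- causal_gene_ids[g]
      an <- anatomy[[gene_id]]
      collection <- if (an$chrom == chrom_names[1L]) "A" else "B"
      members <- character(cfg$strains_per_group)
      used <- integer(0)
      for (s in seq_len(cfg$strains_per_group)) {
        sid <- sid + 1L
        strain <- sprintf("SIM%04d", sid)
        members[s] <- strain
        eff <- if (group_ids[g] %in% deep_intronic_groups) "intron_interior"
          else sample(names(cfg$causal_effect_mix), 1L,
                      prob = cfg$causal_effect_mix)
        v <- plant_causal(an, eff, assembly, used)
        used <- c(used, v$pos)
        d <- draw_depths(cfg, 1L)
        a <- draw_het_alt(d, cfg$het_alt_probability)
        calls_by_strain[[strain]] <- data.frame(
          chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
          total_depth = d, alt_depth = a, stringsAsFactors = FALSE)
        strain_rows[[strain]] <- data.frame(
          strain_id = strain, group_id = group_ids[g],
          collection = collection, mapped_chromosome = an$chrom,
          causal_gene = gene_id, stringsAsFactors = FALSE)
        causal_rows[[strain]] <- data.frame(
          group_id = group_ids[g], strain_id = strain, gene_id = gene_id,
          chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
          effect = v$effect, total_depth = d, alt_depth = a,
          stringsAsFactors = FALSE)
      }
      groups[[group_ids[g]]] <- complementation_group(group_ids[g], members,
                                                      an$chrom)
    }
    strain_meta <- do.call(rbind, strain_rows)

    # background mutations, strain-private, EMS-biased
    for (strain in strain_meta$strain_id) {
      n_bg <- cfg$background_mutations_per_strain
      if (n_bg > 0L) {
        taken <- new.env(hash = TRUE)
        for (p in calls_by_strain[[strain]]$pos)
          assign(as.character(p), TRUE, envir = taken)
        rows <- vector("list", n_bg)
        for (j in seq_len(n_bg)) {
          repeat {
            ch <- sample(chrom_names, 1L,
                         prob = chrom_len / sum(chrom_len))
            seq <- assembly$chromosomes[[ch]]
            is_trans <- stats::runif(1) < cfg$ems_transition_fraction
            is_indel <- !is_trans && stats::runif(1) < cfg$indel_fraction
            pos <- sample(chrom_len[[ch]] - 3L, 1L)
            key <- paste(ch, pos)
            if (!is.null(taken[[key]])) next
            ref_base <- substr(seq, pos, pos)
            if (is_trans && !(ref_base %in% c("G", "C"))) next
            if (is_indel) {
              dlen <- sample(1:2, 1L)
              ref <- substr(seq, pos, pos + dlen)
              alt <- ref_base
            } else {
              ref <- ref_base
              alt <- if (is_trans) c(G = "A", C = "T")[[ref_base]]
                     else mk_snv_alt(ref_base)
            }
            assign(key, TRUE, envir = taken)
            break
          }
          hom <- stats::runif(1) < cfg$homozygous_decoy_fraction
          d <- draw_depths(cfg, 1L)
          a <- if (hom) d else stats::rbinom(1L, d, cfg$het_alt_probability)
          rows[[j]] <- data.frame(
            strain_id = strain, chrom = ch, pos = pos, ref = ref, alt = alt,
            total_depth = d, alt_depth = a, class = "background",
            stringsAsFactors = FALSE)
        }
        bg <- do.call(rbind, rows)
        bg_rows[[strain]] <- bg
        calls_by_strain[[strain]] <- rbind(
          calls_by_strain[[strain]],
          bg[, c("chrom", "pos", "ref", "alt", "total_depth", "alt_depth")])
      }
    }

    # recurrent decoys per collection
    for (coll in unique(strain_meta$collection)) {
      members <- strain_meta$strain_id[strain_meta$collection == coll]
      k <- min(cfg$recurrent_decoy_strains, length(members))
      if (k < 2L || cfg$n_recurrent_decoys < 1L) next
      for (r in seq_len(cfg$n_recurrent_decoys)) {
        repeat {
          ch <- sample(chrom_names, 1L, prob = chrom_len / sum(chrom_len))
          pos <- sample(chrom_len[[ch]] - 3L, 1L)
          ref <- substr(assembly$chromosomes[[ch]], pos, pos)
          if (ref %in% c("G", "C")) break
        }
        alt <- c(G = "A", C = "T")[[ref]]
        carriers <- sample(members, k)
        for (strain in carriers) {
          d <- draw_depths(cfg, 1L)
          a <- draw_het_alt(d, cfg$het_alt_probability)
          calls_by_strain[[strain]] <- rbind(
            calls_by_strain[[strain]],
            data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
                       total_depth = d, alt_depth = a,
                       stringsAsFactors = FALSE))
          bg_rows[[paste0(strain, ".rec", r)]] <- data.frame(
            strain_id = strain, chrom = ch, pos = pos, ref = ref, alt = alt,
            total_depth = d, alt_depth = a, class = "recurrent",
            stringsAsFactors = FALSE)
        }
      }
    }

    strains <- lapply(seq_len(nrow(strain_meta)), function(i)
      strain_variant_set(strain_meta$strain_id[i],
                         strain_meta$collection[i],
                         strain_meta$mapped_chromosome[i],
                         calls_by_strain[[strain_meta$strain_id[i]]]))
    names(strains) <- strain_meta$strain_id

    # expected removal stage per non-causal variant, in cascade order,
    # against the default filter configuration
    background <- if (length(bg_rows)) do.call(rbind, bg_rows) else
      data.frame(strain_id = character(0), chrom = character(0),
                 pos = integer(0), ref = character(0), alt = character(0),
                 total_depth = integer(0), alt_depth = integer(0),
                 class = character(0), stringsAsFactors = FALSE)
    if (nrow(background)) {
      key_counts <- list()
      for (coll in unique(strain_meta$collection)) {
        members <- strain_meta$strain_id[strain_meta$collection == coll]
        keys <- unlist(lapply(members, function(s) {
          cl <- calls_by_strain[[s]]
          unique(variant_key(cl$chrom, cl$pos, cl$ref, cl$alt))
        }))
        key_counts[[coll]] <- table(keys)
      }
      cfg_default <- filter_config()
      mapped <- stats::setNames(strain_meta$mapped_chromosome,
                                strain_meta$strain_id)
      colls <- stats::setNames(strain_meta$collection,
                               strain_meta$strain_id)
      n <- nrow(background)
      zyg <- character(n); effects <- character(n); expected <- character(n)
      frac <- background$alt_depth / background$total_depth
      for (i in seq_len(n)) {
        k <- variant_key(background$chrom[i], background$pos[i],
                         background$ref[i], background$alt[i])
        cnt <- key_counts[[colls[[background$strain_id[i]]]]][k]
        cls <- sim_effect_of(anatomy_by_chrom, background$chrom[i],
                             background$pos[i], background$ref[i],
                             background$alt[i])
        effects[i] <- cls$effect
        zyg[i] <- if (frac[i] > HET_BAND[2L]) "homozygous"
                  else if (frac[i] < HET_BAND[1L]) "low_fraction"
                  else "heterozygous"
        expected[i] <-
          if (!is.na(cnt) && cnt > cfg_default$max_shared_strains)
            "recurrence"
          else if (zyg[i] != "heterozygous") "zygosity"
          else if (!effect_is_candidate(effects[i])) "effect"
          else if (background$chrom[i] != mapped[[background$strain_id[i]]])
            "chromosome"
          else "none"
      }
      background$zygosity <- zyg
      background$effect <- effects
      background$expected_filter <- expected
    } else {
      background$zygosity <- character(0)
      background$effect <- character(0)
      background$expected_filter <- character(0)
    }
    rownames(background) <- NULL

    truth <- list(
      strains = strain_meta,
      groups = unique(strain_meta[, c("group_id", "causal_gene",
                                      "collection", "mapped_chromosome")]),
      causal = do.call(rbind, causal_rows),
      background = background)
    rownames(truth$groups) <- rownames(truth$causal) <- NULL
    structure(list(strains = strains, groups = groups, truth = truth),
              class = "sim_screen")
  })
}

#' Score group resolutions against the simulator truth table
#'
#' @param resolutions list of `group_resolution`s covering exactly the
#'   truth table's groups (merged ids are matched by membership).
#' @param truth the `truth` element of a [simulate_screen()] result.
#' @return list with `per_group` (data.frame of group outcomes:
#'   `recovered_unique`, `recovered_among_multiple`, `missed`, `spurious`),
#'   `recovery` (fraction recovered) and `recovered_unique_fraction`.
#' @export
evaluate_against_truth <- function(resolutions, truth) {
  res_ids <- unlist(lapply(resolutions, function(r)
    strsplit(r$group_id, "+", fixed = TRUE)[[1L]]))
  if (!setequal(res_ids, truth$groups$group_id))
    stop_ctx("resolutions and truth table cover different groups")
  by_group <- list()
  for (r in resolutions)
    for (g in strsplit(r$group_id, "+", fixed = TRUE)[[1L]])
      by_group[[g]] <- r
  out <- data.frame(group_id = truth$groups$group_id,
                    causal_gene = truth$groups$causal_gene,
                    outcome = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    r <- by_group[[out$group_id[i]]]
    g <- out$causal_gene[i]
    out$outcome[i] <-
      if (is.null(r) || !length(r$candidate_genes)) "missed"
      else if (r$status %in% c("unique", "merged") &&
               length(r$candidate_genes) == 1L && r$candidate_genes == g)
        "recovered_unique"
      else if (g %in% r$candidate_genes) "recovered_among_multiple"
      else if (r$status == "unique") "spurious"
      else "missed"
  }
  list(per_group = out,
       recovery = mean(out$outcome %in%
                         c("recovered_unique", "recovered_among_multiple")),
       recovered_unique_fraction = mean(out$outcome == "recovered_unique"))
}

#' Run the filter cascade and group intersection over a simulated screen
#'
#' Convenience wrapper: cascade, per-group intersection, truth scoring.
#'
#' @param cfg a [simulation_config()].
#' @param deep_intronic_groups passed to [simulate_screen()].
#' @param bl optional blacklist.
#' @return list with `genome`, `screen`, `candidates`, `resolutions`,
#'   `evaluation`.
#' @export
run_simulated_screen <- function(cfg, deep_intronic_groups = character(0),
                                 bl = NULL) {
  genome <- simulate_genome(cfg)
  screen <- simulate_screen(cfg, genome, deep_intronic_groups)
  candidates <- run_cascade(screen$strains, genome$genes, genome$assembly,
                            bl = bl)
  resolutions <- lapply(screen$groups, intersect_candidates,
                        lists = candidates)
  evaluation <- evaluate_against_truth(resolutions, screen$truth)
  list(genome = genome, screen = screen, candidates = candidates,
       resolutions = unname(resolutions), evaluation = evaluation)
}

gff3_escape <- function(x) gsub("([;=&,\t])", "", x)

#' Write a simulated genome's gene models as GFF3
#'
#' @param genome a `sim_genome` (or list of gene models via `genes`).
#' @param path output GFF3.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genome, path) {
  genes <- if (inherits(genome, "sim_genome")) genome$genes else genome
  lines <- "##gff-version 3"
  for (g in genes) {
    sp <- gene_span(g)
    lines <- c(lines, sprintf("%s\tscreenmap\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                              g$chrom, sp$start, sp$end, g$strand,
                              gff3_escape(g$gene_id),
                              gff3_escape(g$public_name)))
    for (t in g$transcripts) {
      lines <- c(lines, sprintf("%s\tscreenmap\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                                t$chrom, min(t$exons$start), max(t$exons$end),
                                t$strand, gff3_escape(t$id),
                                gff3_escape(t$gene_id)))
      for (k in seq_len(nrow(t$exons)))
        lines <- c(lines, sprintf("%s\tscreenmap\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                                  t$chrom, t$exons$start[k], t$exons$end[k],
                                  t$strand, gff3_escape(t$id)))
      cds <- t$cds
      ord <- if (t$strand == "+") order(cds$start) else order(-cds$start)
      cum <- 0L
      phase <- integer(nrow(cds))
      for (k in ord) {
        phase[k] <- (3L - cum %% 3L) %% 3L
        cum <- cum + cds$end[k] - cds$start[k] + 1L
      }
      for (k in seq_len(nrow(cds)))
        lines <- c(lines, sprintf("%s\tscreenmap\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
                                  t$chrom, cds$start[k], cds$end[k],
                                  t$strand, phase[k], gff3_escape(t$id)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated run to a directory
#'
#' Emits the toy genome (FASTA), gene models (GFF3), one VCF per strain,
#' the strain metadata TSV and the truth tables (TSV). Byte-identical
#' across runs with the same config.
#'
#' @param genome a `sim_genome`.
#' @param screen a `sim_screen`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_run <- function(genome, screen, dir) {
  dir.create(file.path(dir, "strains"), recursive = TRUE,
             showWarnings = FALSE)
  write_assembly(genome$assembly, file.path(dir, "genome.fa"))
  write_gene_models_gff3(genome, file.path(dir, "genes.gff3"))
  for (s in screen$strains)
    write_strain_vcf(s, file.path(dir, "strains",
                                  paste0(s$strain_id, ".vcf")))
  meta <- screen$truth$strains
  meta$allele_name <- paste0("t", seq_len(nrow(meta)) + 1000L)
  meta$complementation_group <- meta$group_id
  write_tsv(meta[, c("strain_id", "allele_name", "collection",
                     "mapped_chromosome", "complementation_group")],
            file.path(dir, "strain_metadata.tsv"))
  write_tsv(screen$truth$groups, file.path(dir, "truth_groups.tsv"))
  write_tsv(screen$truth$causal, file.path(dir, "truth_causal.tsv"))
  write_tsv(screen$truth$background, file.path(dir, "truth_background.tsv"))
  invisible(dir)
}
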