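OTHER_BASE <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))

population_labels <- function(n_sister) {
  locales <- c("FRA", "GER", "IRA", "AFG", "CZE", "KAZ")
  n_dom <- ceiling(n_sister / 2)
  dom <- paste0("domesticus_",
                if (n_dom <= 3) locales[seq_len(n_dom)]
                else sprintf("P%02d", seq_len(n_dom)))
  n_mus <- n_sister - n_dom
  mus <- paste0("musculus_",
                if (n_mus <= 3) locales[3 + seq_len(n_mus)]
                else sprintf("P%02d", seq_len(n_mus)))
  list(focal = "castaneus_IND", sisters = c(dom, mus))
}

write_vcf <- function(path, chrom, chrom_len, pos, ref, alt, gt, samples) {
  stopifnot(length(pos) == length(ref), length(ref) == length(alt),
            is.matrix(gt) || length(pos) == 0)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=ciscreen-simulate",
    sprintf("##contig=<ID=%s,length=%d>", chrom, chrom_len),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  if (length(pos)) {
    body <- paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

# Genotype matrix (sites x individuals, 0/1/2 alt-allele dosages) for
# polymorphic sites: Hardy-Weinberg draws at a random allele frequency per
# site, conditioned on each site carrying at least one alternate allele and
# at least one homozygous reference individual, so every site segregates
# (and never masquerades as a fixed difference) under both
# heterozygote-assignment modes.
draw_poly_genotypes <- function(n_sites, n_ind) {
  if (n_sites == 0) return(matrix(integer(0), 0, n_ind))
  q <- runif(n_sites, 0.15, 0.85)
  g <- matrix(rbinom(n_sites * n_ind, 2, rep(q, n_ind)), nrow = n_sites)
  repeat {
    bad <- rowSums(g) == 0 | rowSums(g == 0) == 0
    if (!any(bad)) break
    g[bad, ] <- matrix(rbinom(sum(bad) * n_ind, 2, rep(q[bad], n_ind)),
                       nrow = sum(bad))
  }
  g
}

#' Simulate population VCFs with planted upstream divergence
#'
#' Plants two kinds of bi-allelic SNVs on top of the simulated reference.
#' Fixed differences between the focal population and a sister population
#' are drawn independently for every sister population, at
#' `background_div_rate` per bp genome-wide and at
#' `background_div_rate * site_div_enrichment` inside focal-regulator
#' binding sites upstream of pathway genes; at such a position every
#' individual of that sister population is homozygous for the alternate
#' allele while the focal population keeps the reference. Fixed differences
#' are direction-symmetric for the divergence/polymorphism contrast, and
#' planting them on the sister lineage keeps each focal-vs-sister comparison
#' an independent replicate of the stated rates. Within-population
#' polymorphisms are drawn independently per population (including the focal
#' one) at `background_poly_rate` per bp with Hardy-Weinberg genotypes and
#' explicit heterozygotes, so both heterozygote-assignment modes of
#' pseudogenome construction are exercised. A position is never both fixed
#' and segregating within the same population. One VCF v4.2 file is written
#' per population.
#'
#' @param cfg a [sim_config()].
#' @param anno output of [simulate_genome_annotation()].
#' @param pathway_genes character vector of pathway gene ids (defaults to
#'   the membership drawn from `cfg`).
#' @param dir output directory for the VCF files.
#' @return list with `vcf_paths` (named by population), `populations`
#'   (focal label and sister labels), `truth` (data.frame of planted
#'   divergent positions with `pos`, `gene_id`, `in_focal_site`), and
#'   `poly_truth` (per-population planted polymorphic position counts).
#' @export
simulate_population_vcfs <- function(cfg, anno, pathway_genes = NULL, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(pathway_genes)) {
    truth <- plant_truth(cfg)
    pathway_genes <- truth$gene_id[truth$in_pathway]
  }
  pathway_genes <- intersect(pathway_genes, anno$genes$gene_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pops <- population_labels(cfg$n_populations_sister)
  chrom_len <- anno$chrom_len
  ref_chars <- strsplit(as.character(anno$genome[["chr1"]]), "")[[1]]
  focal_reg <- anno$regulators[cfg$focal_regulator]

  # focal-site positions at pathway genes (1-based)
  fs <- anno$sites[anno$sites$regulator == focal_reg &
                     anno$sites$gene_id %in% pathway_genes, , drop = FALSE]
  focal_pos <- if (nrow(fs)) sort(unique(unlist(
    mapply(seq.int, fs$start + 1L, fs$end, SIMPLIFY = FALSE)))) else integer(0)

  seeds <- derive_seeds(cfg$seed, 8L)
  with_seed(seeds[5L], {
    p_div <- rep(cfg$background_div_rate, chrom_len)
    p_div[focal_pos] <- cfg$background_div_rate * cfg$site_div_enrichment
    n_ind <- cfg$n_haplotypes_per_pop
    all_pops <- c(pops$focal, pops$sisters)

    # sister-lineage fixed differences, independent per sister population
    div_pos <- lapply(all_pops, function(p) {
      if (p == pops$focal) integer(0)
      else which(runif(chrom_len) < p_div)
    })
    names(div_pos) <- all_pops
    # within-population segregating sites; never at that population's own
    # fixed positions
    poly_pos <- lapply(all_pops, function(p) {
      cand <- which(runif(chrom_len) < cfg$background_poly_rate)
      setdiff(cand, div_pos[[p]])
    })
    names(poly_pos) <- all_pops
    for (p in all_pops)
      if (length(intersect(poly_pos[[p]], div_pos[[p]])))
        stop_input("contradictory planted alleles in %s", p)

    # one ALT base per variant position, shared across populations
    var_pos <- sort(unique(c(unlist(div_pos, use.names = FALSE),
                             unlist(poly_pos, use.names = FALSE))))
    alt_base <- vapply(ref_chars[var_pos],
                       function(b) sample(OTHER_BASE[[b]], 1), character(1))
    names(alt_base) <- as.character(var_pos)

    gt_string <- function(dosage) c("0/0", "0/1", "1/1")[dosage + 1L]
    vcf_paths <- character(0)
    poly_counts <- integer(0)
    for (p in all_pops) {
      ppos <- sort(poly_pos[[p]])
      dpos <- div_pos[[p]]
      pos <- sort(c(dpos, ppos))
      is_div <- pos %in% dpos
      gt <- matrix("0/0", nrow = length(pos), ncol = n_ind)
      gt[is_div, ] <- "1/1"
      gt[!is_div, ] <- gt_string(draw_poly_genotypes(sum(!is_div), n_ind))
      path <- file.path(dir, paste0(p, ".vcf"))
      write_vcf(path, "chr1", chrom_len, pos,
                ref_chars[pos], alt_base[as.character(pos)], gt,
                sprintf("%s_ind%02d", p, seq_len(n_ind)))
      vcf_paths[p] <- path
      poly_counts[p] <- length(ppos)
    }

    # map planted divergent positions onto gene windows
    wins <- upstream_windows(
      data.frame(gene_id = anno$genes$gene_id, chrom = "chr1",
                 strand = anno$genes$strand, tss = anno$genes$tss,
                 orf_valid = TRUE, stringsAsFactors = FALSE),
      chrom_len, cfg$upstream_len)
    gene_of <- rep(NA_character_, chrom_len)
    for (i in seq_len(nrow(wins)))
      gene_of[(wins$start[i] + 1L):wins$end[i]] <- wins$gene_id[i]
    truth_div <- do.call(rbind, lapply(pops$sisters, function(p) {
      dp <- div_pos[[p]]
      if (!length(dp)) return(NULL)
      data.frame(pos = dp, population = p, gene_id = gene_of[dp],
                 in_focal_site = dp %in% focal_pos,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(truth_div))
      truth_div <- data.frame(pos = integer(0), population = character(0),
                              gene_id = character(0),
                              in_focal_site = logical(0))
    list(vcf_paths = vcf_paths, populations = pops, truth = truth_div,
         poly_truth = poly_counts, focal_regulator = focal_reg,
         windows = wins)
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Emits every input the pipeline consumes: genome FASTA, transcript models
#' GFF3, binding-site BED (4th column = regulator), one VCF per population,
#' the allele-count TSV, the gene-set TSV and a ground-truth JSON. With a
#' fixed seed the whole bundle is byte-identical between runs.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisible list of paths plus the in-memory `anno`, `ase` and
#'   `popgen` objects.
#' @export
simulate_fixture <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  anno <- simulate_genome_annotation(cfg)
  ase <- simulate_ase_counts(cfg)
  sets <- simulate_gene_sets(cfg, ase$truth)
  pop <- simulate_population_vcfs(
    cfg, anno, ase$truth$gene_id[ase$truth$in_pathway],
    dir = file.path(dir, "vcf"))
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "transcripts.gff3"),
    sites = file.path(dir, "sites.bed"),
    counts = file.path(dir, "ase_counts.tsv"),
    gene_sets = file.path(dir, "gene_sets.tsv"),
    truth = file.path(dir, "truth.json"),
    vcf = pop$vcf_paths
  )
  Biostrings::writeXStringSet(anno$genome, paths$genome, width = 70L)
  write_gff3(anno$gff, paths$gff3)
  write_sites_bed(anno$sites, paths$sites)
  write_tsv(ase$counts, paths$counts)
  write_tsv(sets$table, paths$gene_sets)
  truth <- list(
    seed = cfg$seed,
    pathway_genes = ase$truth$gene_id[ase$truth$in_pathway],
    planted_l2fc = setNames(ase$truth$planted_l2fc, ase$truth$gene_id),
    focal_term = sets$focal_term,
    focal_regulator = pop$focal_regulator,
    populations = pop$populations,
    divergent_positions = pop$truth
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, anno = anno, ase = ase, sets = sets,
                 popgen = pop, cfg = cfg))
}
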