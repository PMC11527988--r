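#' Configuration for the synthetic-data generators
#'
#' Collects every knob of the simulation in one validated list. The defaults
#' describe the study conditions the package is calibrated against: a
#' 2,000-gene expression universe with a 60-gene focal pathway in which two
#' thirds of the genes carry a cis-effect favouring allele 1 (log2 fold-change
#' 1) and one third favour allele 2, negative-binomial counts at a mean depth
#' of 500 reads per allele over 5 replicates, and a population-genomic layer
#' with one focal population plus six sister populations (three per sister
#' taxon), eight diploid individuals each, and divergent alleles planted into
#' focal-regulator binding sites at three times the background rate.
#'
#' @param seed integer RNG seed; a fixed seed makes every emitted file
#'   byte-identical between runs.
#' @param n_genes number of genes in the expression universe.
#' @param n_pathway_genes number of genes in the focal pathway.
#' @param frac_directional fraction of pathway genes whose planted cis-effect
#'   favours allele 1; the remainder favour allele 2.
#' @param planted_l2fc magnitude (log2 fold-change) of planted allelic effects.
#' @param nb_dispersion negative-binomial dispersion alpha
#'   (variance = mu + alpha * mu^2).
#' @param mean_depth mean reads per gene per allele per replicate.
#' @param n_replicates number of RNA-seq replicates.
#' @param n_populations_sister number of sister populations (split evenly
#'   between the two sister taxa).
#' @param n_haplotypes_per_pop diploid individuals sequenced per population;
#'   each yields one haploid pseudogenome per heterozygote-assignment mode.
#' @param site_div_enrichment multiplier on the fixed-difference rate inside
#'   focal-regulator binding sites upstream of pathway genes.
#' @param background_div_rate per-bp probability of a fixed difference between
#'   the focal population and all sister populations.
#' @param background_poly_rate per-bp, per-population probability of a
#'   within-population polymorphism.
#' @param upstream_len length in bp of the upstream window scanned for
#'   binding sites (the screen's default is 50 kb).
#' @param chrom_len chromosome length in bp, or `NULL` to derive the smallest
#'   length that tiles all genes with non-overlapping upstream windows.
#' @param n_regulators number of simulated transcriptional regulators.
#' @param focal_regulator index (1-based) of the regulator whose sites at
#'   pathway genes receive the planted divergence enrichment.
#' @param sites_per_gene binding sites placed per regulator in each gene's
#'   upstream window.
#' @param site_len_bp length of each binding site in bp.
#' @param n_background_terms random gene-set terms emitted besides the focal
#'   pathway term.
#' @param cds_len_bp length of each gene's primary coding sequence (multiple
#'   of 3).
#' @return an object of class `sim_config` (a named list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_pathway_genes = 60L,
                       frac_directional = 2 / 3,
                       planted_l2fc = 1,
                       nb_dispersion = 0.05,
                       mean_depth = 500,
                       n_replicates = 5L,
                       n_populations_sister = 6L,
                       n_haplotypes_per_pop = 8L,
                       site_div_enrichment = 3,
                       background_div_rate = 0.004,
                       background_poly_rate = 0.025,
                       upstream_len = 50000L,
                       chrom_len = NULL,
                       n_regulators = 10L,
                       focal_regulator = 1L,
                       sites_per_gene = 6L,
                       site_len_bp = 100L,
                       n_background_terms = 40L,
                       cds_len_bp = 300L) {
  cfg <- list(
    seed = seed, n_genes = n_genes, n_pathway_genes = n_pathway_genes,
    frac_directional = frac_directional, planted_l2fc = planted_l2fc,
    nb_dispersion = nb_dispersion, mean_depth = mean_depth,
    n_replicates = n_replicates,
    n_populations_sister = n_populations_sister,
    n_haplotypes_per_pop = n_haplotypes_per_pop,
    site_div_enrichment = site_div_enrichment,
    background_div_rate = background_div_rate,
    background_poly_rate = background_poly_rate,
    upstream_len = upstream_len, chrom_len = chrom_len,
    n_regulators = n_regulators, focal_regulator = focal_regulator,
    sites_per_gene = sites_per_gene, site_len_bp = site_len_bp,
    n_background_terms = n_background_terms, cds_len_bp = cds_len_bp
  )
  for (f in c("seed", "n_genes", "n_pathway_genes", "n_replicates",
              "n_populations_sister", "n_haplotypes_per_pop",
              "n_regulators", "focal_regulator", "sites_per_gene",
              "site_len_bp", "cds_len_bp"))
    if (!is_count(cfg[[f]])) stop_config(f, "must be a positive integer")
  if (!is_count(cfg$n_background_terms) && cfg$n_background_terms != 0)
    stop_config("n_background_terms", "must be a non-negative integer")
  for (f in c("frac_directional", "background_div_rate",
              "background_poly_rate"))
    if (!is_rate(cfg[[f]])) stop_config(f, "must be a rate in [0, 1]")
  if (!is.numeric(cfg$planted_l2fc) || !is.finite(cfg$planted_l2fc))
    stop_config("planted_l2fc", "must be finite")
  if (!is.numeric(cfg$nb_dispersion) || cfg$nb_dispersion < 0)
    stop_config("nb_dispersion", "must be >= 0")
  if (!is.numeric(cfg$mean_depth) || cfg$mean_depth <= 0)
    stop_config("mean_depth", "must be > 0")
  if (!is.numeric(cfg$site_div_enrichment) || cfg$site_div_enrichment < 0)
    stop_config("site_div_enrichment", "must be >= 0")
  if (!is_count(cfg$upstream_len))
    stop_config("upstream_len", "must be a positive integer")
  if (cfg$n_pathway_genes > cfg$n_genes)
    stop_config("n_pathway_genes", "cannot exceed n_genes")
  if (cfg$focal_regulator > cfg$n_regulators)
    stop_config("focal_regulator", "cannot exceed n_regulators")
  if (cfg$cds_len_bp %% 3 != 0)
    stop_config("cds_len_bp", "must be a multiple of 3")
  if (cfg$background_div_rate * cfg$site_div_enrichment > 1)
    stop_config("site_div_enrichment",
                "times background_div_rate must not exceed 1")
  # Geometry: gene bodies are cds_len_bp long; successive TSSs are spaced so
  # that upstream windows (strand-aware, either side) can never overlap.
  cfg$gene_spacing <- 2L * as.integer(cfg$upstream_len) +
    as.integer(cfg$cds_len_bp) + 1000L
  min_len <- as.integer(cfg$upstream_len) +
    cfg$gene_spacing * as.integer(cfg$n_genes) + 1000L
  if (is.null(cfg$chrom_len)) {
    cfg$chrom_len <- min_len
  } else if (!is_count(cfg$chrom_len)) {
    stop_config("chrom_len", "must be a positive integer or NULL")
  } else if (cfg$chrom_len < min_len) {
    stop_config("chrom_len", sprintf(
      "too short to tile %d genes with %d bp windows (need >= %d)",
      cfg$n_genes, cfg$upstream_len, min_len))
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  flds <- setdiff(names(x), "gene_spacing")
  for (f in flds) cat(sprintf("  %-22s %s\n", f, format(x[[f]])))
  invisible(x)
}
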