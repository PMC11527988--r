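test_that("sim_config validates fields and names the offender", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(frac_directional = 1.2), "frac_directional")
  expect_error(sim_config(planted_l2fc = Inf), "planted_l2fc")
  expect_error(sim_config(background_div_rate = -0.1), "background_div_rate")
  expect_error(sim_config(n_pathway_genes = 10, n_genes = 5),
               "n_pathway_genes")
  expect_error(sim_config(chrom_len = 100), "chrom_len")
})

test_that("planted truth arithmetic matches the configuration", {
  cfg <- sim_config(seed = 2, n_genes = 500, n_pathway_genes = 90,
                    frac_directional = 2 / 3, planted_l2fc = 1)
  truth <- simulate_ase_counts(cfg)$truth
  expect_equal(sum(truth$in_pathway), 90)
  expect_equal(sum(truth$planted_l2fc > 0), 60)
  expect_equal(sum(truth$planted_l2fc < 0), 30)
  expect_true(all(truth$planted_l2fc[!truth$in_pathway] == 0))
})

test_that("allele count ratios match the planted effects", {
  # no planted effect anywhere: pooled allele-1 fraction ~ 0.5
  cfg0 <- sim_config(seed = 3, n_genes = 400, n_pathway_genes = 10,
                     planted_l2fc = 0, mean_depth = 100, n_replicates = 3)
  counts <- simulate_ase_counts(cfg0)$counts
  tot1 <- sum(counts$allele1_count); tot2 <- sum(counts$allele2_count)
  n <- tot1 + tot2
  # overdispersed counts: binomial SE times a conservative inflation factor
  se <- sqrt(0.25 / n) * sqrt(1 + cfg0$nb_dispersion * cfg0$mean_depth)
  expect_lt(abs(tot1 / n - 0.5), 3 * se * sqrt(2))
  # planted l2fc = 1 at high depth: observed ratio ~ 2 within 3 SE
  cfg1 <- sim_config(seed = 4, n_genes = 200, n_pathway_genes = 200,
                     frac_directional = 1, planted_l2fc = 1,
                     mean_depth = 10000, n_replicates = 2)
  sim <- simulate_ase_counts(cfg1)
  dt <- sim$counts
  r <- sum(dt$allele1_count) / sum(dt$allele2_count)
  # NB variance: var = mu + alpha mu^2 per draw; delta-method SE of ratio
  mu1 <- 2 * 10000 * 2 / 3; mu2 <- 2 * 10000 / 3
  ndraw <- nrow(dt)
  v1 <- (mu1 + 0.05 * mu1^2) * ndraw; v2 <- (mu2 + 0.05 * mu2^2) * ndraw
  s1 <- sum(dt$allele1_count); s2 <- sum(dt$allele2_count)
  se_r <- r * sqrt(v1 / s1^2 + v2 / s2^2)
  expect_lt(abs(r - 2), 3 * se_r)
})

test_that("fixture generation is byte-identical under a fixed seed", {
  cfg <- tiny_popgen_cfg(seed = 8)
  d1 <- file.path(tempdir(), "fxa"); d2 <- file.path(tempdir(), "fxb")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_fixture(cfg, d1)
  simulate_fixture(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) >= 10)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_true(all(unname(h1) == unname(h2)))
  # and a different seed changes the data
  d3 <- file.path(tempdir(), "fxc")
  unlink(d3, recursive = TRUE)
  simulate_fixture(tiny_popgen_cfg(seed = 9), d3)
  h3 <- tools::md5sum(file.path(d3, "ase_counts.tsv"))
  expect_false(unname(h3) == unname(h1[file.path(d1, "ase_counts.tsv")]))
})

test_that("emitted formats parse cleanly with strict readers", {
  cfg <- tiny_popgen_cfg(seed = 12)
  dir <- file.path(tempdir(), "fx_formats")
  unlink(dir, recursive = TRUE)
  fx <- simulate_fixture(cfg, dir)
  genome <- read_genome(fx$paths$genome)
  expect_equal(unname(Biostrings::width(genome)), cfg$chrom_len)
  gff <- rtracklayer::import(fx$paths$gff3, format = "gff3")
  expect_true(all(c("gene", "mRNA", "exon", "CDS") %in%
                    as.character(gff$type)))
  bed <- rtracklayer::import(fx$paths$sites, format = "bed")
  expect_equal(length(bed), cfg$n_genes * cfg$n_regulators * cfg$sites_per_gene)
  v <- vcfR::read.vcfR(fx$paths$vcf[[1]], verbose = FALSE)
  expect_gt(nrow(v@fix), 0)
  expect_true(all(vcfR::extract.gt(v, "GT") %in% c("0/0", "0/1", "1/1")))
})

test_that("planted divergent positions lie in focal sites at the planted rate", {
  cfg <- tiny_popgen_cfg(seed = 13, n_genes = 20, n_pathway_genes = 8,
                         site_div_enrichment = 3)
  anno <- simulate_genome_annotation(cfg)
  truth <- simulate_ase_counts(cfg)$truth
  dir <- file.path(tempdir(), "fx_div")
  unlink(dir, recursive = TRUE)
  pop <- simulate_population_vcfs(cfg, anno,
                                  truth$gene_id[truth$in_pathway], dir)
  div <- pop$truth
  # every in-focal-site planted position is inside a recorded site interval
  fs <- anno$sites[anno$sites$regulator == pop$focal_regulator &
                     anno$sites$gene_id %in% truth$gene_id[truth$in_pathway], ]
  in_site <- vapply(div$pos[div$in_focal_site], function(p)
    any(p > fs$start & p <= fs$end), logical(1))
  expect_true(all(in_site))
  # enrichment: per-comparison in-site rate ~ 3x the background rate
  n_site_bp <- nrow(fs) * cfg$site_len_bp * cfg$n_populations_sister
  rate_in <- sum(div$in_focal_site) / n_site_bp
  expect_gt(rate_in, cfg$background_div_rate * 1.5)
  expect_lt(rate_in, cfg$background_div_rate * 4.5)
})

test_that("zero divergence rates produce no fixed differences anywhere", {
  cfg <- tiny_popgen_cfg(seed = 14, n_genes = 6, n_pathway_genes = 2,
                         background_div_rate = 0, site_div_enrichment = 0,
                         n_haplotypes_per_pop = 3L)
  anno <- simulate_genome_annotation(cfg)
  dir <- file.path(tempdir(), "fx_zero")
  unlink(dir, recursive = TRUE)
  pop <- simulate_population_vcfs(cfg, anno, NULL, dir)
  expect_equal(nrow(pop$truth), 0)
  genome <- anno$genome
  focal <- modes_for(pop$vcf_paths[[pop$populations$focal]], genome)
  for (sp in pop$populations$sisters) {
    sis <- modes_for(pop$vcf_paths[[sp]], genome)
    cand <- sort(unique(c(focal$het_alt$positions, sis$het_alt$positions,
                          focal$het_ref$positions, sis$het_ref$positions)))
    for (mode in c("het_alt", "het_ref")) {
      cls <- classify_positions(focal[[mode]], sis[[mode]], cand)
      expect_equal(sum(cls == "fixed_divergent", na.rm = TRUE), 0)
    }
  }
})

test_that("unenriched simulations have comparable in- and out-of-site divergence", {
  cfg <- tiny_popgen_cfg(seed = 15, n_genes = 30, n_pathway_genes = 10,
                         site_div_enrichment = 1)
  anno <- simulate_genome_annotation(cfg)
  truth <- simulate_ase_counts(cfg)$truth
  dir <- file.path(tempdir(), "fx_flat")
  unlink(dir, recursive = TRUE)
  pop <- simulate_population_vcfs(cfg, anno,
                                  truth$gene_id[truth$in_pathway], dir)
  fs <- anno$sites[anno$sites$regulator == pop$focal_regulator &
                     anno$sites$gene_id %in% truth$gene_id[truth$in_pathway], ]
  n_site_bp <- nrow(fs) * cfg$site_len_bp * cfg$n_populations_sister
  # windowed background bp: all windows minus focal-site bp
  win_bp <- nrow(pop$windows) * cfg$upstream_len * cfg$n_populations_sister
  in_win <- !is.na(pop$truth$gene_id)
  d_in <- sum(pop$truth$in_focal_site)
  d_out <- sum(in_win & !pop$truth$in_focal_site)
  rate_in <- d_in / n_site_bp
  rate_out <- d_out / (win_bp - n_site_bp)
  # both are binomial draws at the same rate; allow 3 SE on the difference
  se <- sqrt(rate_out * (1 - rate_out) * (1 / n_site_bp +
                                            1 / (win_bp - n_site_bp)))
  expect_lt(abs(rate_in - rate_out), 3 * se + 1e-9)
})

test_that("planted divergent positions are recovered by classification", {
  cfg <- tiny_popgen_cfg(seed = 16, n_genes = 8, n_pathway_genes = 3)
  anno <- simulate_genome_annotation(cfg)
  truth <- simulate_ase_counts(cfg)$truth
  dir <- file.path(tempdir(), "fx_round")
  unlink(dir, recursive = TRUE)
  pop <- simulate_population_vcfs(cfg, anno,
                                  truth$gene_id[truth$in_pathway], dir)
  genome <- anno$genome
  focal <- modes_for(pop$vcf_paths[[pop$populations$focal]], genome)
  sp <- pop$populations$sisters[1]
  sis <- modes_for(pop$vcf_paths[[sp]], genome)
  planted <- pop$truth$pos[pop$truth$population == sp]
  # positions also segregating within the focal population classify as
  # polymorphic, by definition; keep the clean planted positions
  planted <- setdiff(planted, focal$het_alt$positions)
  expect_gt(length(planted), 10)
  for (mode in c("het_alt", "het_ref")) {
    cls <- classify_positions(focal[[mode]], sis[[mode]], planted)
    expect_true(all(cls == "fixed_divergent"))
  }
})
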