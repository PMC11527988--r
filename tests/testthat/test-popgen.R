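test_that("hom-ref-only VCF reproduces the reference byte for byte", {
  genome <- random_genome(500, seed = 41)
  refc <- strsplit(as.character(genome[[1]]), "")[[1]]
  pos <- c(50L, 120L, 300L)
  vcf <- tiny_vcf(tempfile(fileext = ".vcf"), "chr1", 500, pos,
                  refc[pos], vapply(refc[pos], function(b)
                    setdiff(c("A", "C", "G", "T"), b)[1], character(1)),
                  matrix("0/0", 3, 2))
  for (mode in c("het_alt", "het_ref")) {
    ps <- build_pseudogenomes(vcf, genome, mode)
    seqs <- pseudogenome_sequences(ps)
    for (i in seq_along(seqs))
      expect_identical(as.character(seqs[[i]]), as.character(genome[[1]]))
    # written FASTA is byte-identical to the written reference
    fa <- tempfile(fileext = ".fa"); fb <- tempfile(fileext = ".fa")
    one <- seqs[1]; names(one) <- "chr1"
    Biostrings::writeXStringSet(one, fa, width = 70)
    Biostrings::writeXStringSet(genome, fb, width = 70)
    expect_identical(readLines(fa), readLines(fb))
  }
})

test_that("het modes differ exactly at heterozygous records", {
  genome <- random_genome(400, seed = 42)
  refc <- strsplit(as.character(genome[[1]]), "")[[1]]
  pos <- c(10L, 90L, 200L, 333L)
  alt <- vapply(refc[pos], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  # ind1: het, hom-alt, hom-ref, het ; ind2: hom-ref everywhere but one het
  gt <- matrix(c("0/1", "0/0",
                 "1/1", "0/0",
                 "0/0", "0/0",
                 "0/1", "0/1"), ncol = 2, byrow = TRUE)
  vcf <- tiny_vcf(tempfile(fileext = ".vcf"), "chr1", 400, pos,
                  refc[pos], alt, gt)
  pa <- pseudogenome_sequences(build_pseudogenomes(vcf, genome, "het_alt"))
  pr <- pseudogenome_sequences(build_pseudogenomes(vcf, genome, "het_ref"))
  for (i in 1:2) {
    ca <- strsplit(as.character(pa[[i]]), "")[[1]]
    cr <- strsplit(as.character(pr[[i]]), "")[[1]]
    het_pos <- pos[gt[, i] == "0/1"]
    expect_identical(which(ca != cr), as.integer(het_pos))
    # at het positions: ALT under het_alt, REF under het_ref
    expect_identical(ca[het_pos], unname(alt[match(het_pos, pos)]))
    expect_identical(cr[het_pos], unname(refc[het_pos]))
    # hom records substituted identically in both modes
    hom_alt <- pos[gt[, i] == "1/1"]
    expect_identical(ca[hom_alt], unname(alt[match(hom_alt, pos)]))
    expect_identical(cr[hom_alt], unname(alt[match(hom_alt, pos)]))
  }
})

test_that("REF mismatches and missing genotypes are handled", {
  genome <- random_genome(100, seed = 43)
  refc <- strsplit(as.character(genome[[1]]), "")[[1]]
  wrong <- setdiff(c("A", "C", "G", "T"), refc[20])[1]
  vcf <- tiny_vcf(tempfile(fileext = ".vcf"), "chr1", 100, 20L, wrong,
                  refc[20], matrix("0/0", 1, 2))
  expect_error(build_pseudogenomes(vcf, genome), "REF")
  vcf2 <- tiny_vcf(tempfile(fileext = ".vcf"), "chr1", 100, 20L, refc[20],
                   setdiff(c("A", "C", "G", "T"), refc[20])[1],
                   matrix(c("./.", "1/1"), 1, 2))
  ps <- build_pseudogenomes(vcf2, genome, "het_alt")
  expect_true(is.na(ps$bases[1, 1]))
  sq <- pseudogenome_sequences(ps)
  expect_identical(substr(as.character(sq[[1]]), 20, 20), "N")
})

test_that("position classes follow the truth table and are exchangeable", {
  genome <- random_genome(60, seed = 44)
  refc <- strsplit(as.character(genome[[1]]), "")[[1]]
  alt_of <- function(p) setdiff(c("A", "C", "G", "T"), refc[p])[1]
  pos <- as.integer(1:9 * 6)
  alt <- vapply(pos, alt_of, character(1))
  #            p1     p2     p3     p4     p5     p6     p7     p8     p9
  cast_gt <- c("0/0", "1/1", "0/1", "0/0", "1/1", "0/0", "0/1", "1/1", "0/0")
  sis_gt  <- c("0/0", "0/0", "0/0", "0/1", "1/1", "0/0", "0/1", "0/1", "./.")
  mk <- function(gt_codes, n_ind = 3) {
    gt <- matrix(rep(gt_codes, n_ind), ncol = n_ind)
    tiny_vcf(tempfile(fileext = ".vcf"), "chr1", 60, pos, refc[pos], alt, gt)
  }
  cast <- build_pseudogenomes(mk(cast_gt), genome, "het_alt")
  sis <- build_pseudogenomes(mk(sis_gt), genome, "het_alt")
  cls <- classify_positions(cast, sis, pos)
  # oracle: full scan over materialised sequences
  oc <- oracle_classify_scan(pseudogenome_sequences(cast),
                             pseudogenome_sequences(sis), pos)
  expect_identical(as.character(cls), oc)
  # spot checks of the truth table (all individuals share the genotype here)
  expect_equal(as.character(cls[1]), "invariant")        # both all REF
  expect_equal(as.character(cls[2]), "fixed_divergent")  # cast ALT, sis REF
  expect_equal(as.character(cls[5]), "invariant")        # both all ALT
  # p9: sister fully missing -> unclassifiable
  expect_true(is.na(cls[9]))
  # swapping focal and sister populations preserves fixed_divergent
  cls_sw <- classify_positions(sis, cast, pos)
  expect_identical(cls == "fixed_divergent", cls_sw == "fixed_divergent")
  # a position polymorphic within one population is never divergent
  mixed <- matrix(c("0/0", "1/1", "0/0"), ncol = 3)
  vcfm <- tiny_vcf(tempfile(fileext = ".vcf"), "chr1", 60, pos[1],
                   refc[pos[1]], alt[1], mixed)
  castm <- build_pseudogenomes(vcfm, genome, "het_alt")
  clsm <- classify_positions(castm, sis, pos[1])
  expect_equal(as.character(clsm), "polymorphic")
})

test_that("classes partition every classifiable position on random fixtures", {
  cfg <- tiny_popgen_cfg(seed = 45, n_genes = 6)
  anno <- simulate_genome_annotation(cfg)
  dir <- file.path(tempdir(), "fx_part")
  unlink(dir, recursive = TRUE)
  pop <- simulate_population_vcfs(cfg, anno, NULL, dir)
  focal <- modes_for(pop$vcf_paths[[pop$populations$focal]], anno$genome)
  sis <- modes_for(pop$vcf_paths[[pop$populations$sisters[2]]], anno$genome)
  set.seed(45)
  positions <- sort(sample.int(cfg$chrom_len, 4000))
  for (mode in c("het_alt", "het_ref")) {
    cls <- classify_positions(focal[[mode]], sis[[mode]], positions)
    oc <- oracle_classify_scan(pseudogenome_sequences(focal[[mode]]),
                               pseudogenome_sequences(sis[[mode]]),
                               positions)
    expect_identical(as.character(cls), oc)
    expect_true(all(!is.na(cls)))  # no missing genotypes planted here
  }
})

test_that("P_u/D_u counting averages the two heterozygote modes", {
  genome <- random_genome(100, seed = 46)
  refc <- strsplit(as.character(genome[[1]]), "")[[1]]
  alt_of <- function(p) setdiff(c("A", "C", "G", "T"), refc[p])[1]
  window <- 1:100
  sites <- c(10:19, 50:59)
  # divergent in-site at 12, 15, 57; divergent out-of-site at 30, 80
  dpos <- c(12L, 15L, 57L, 30L, 80L)
  dvcf <- tiny_vcf(tempfile(fileext = ".vcf"), "chr1", 100, dpos,
                   refc[dpos], vapply(dpos, alt_of, character(1)),
                   matrix("1/1", 5, 3))
  svcf <- tiny_vcf(tempfile(fileext = ".vcf"), "chr1", 100, dpos[1],
                   refc[dpos[1]], alt_of(dpos[1]), matrix("0/0", 1, 3))
  focal <- list(het_alt = build_pseudogenomes(dvcf, genome, "het_alt"),
                het_ref = build_pseudogenomes(dvcf, genome, "het_ref"))
  sis <- list(het_alt = build_pseudogenomes(svcf, genome, "het_alt"),
              het_ref = build_pseudogenomes(svcf, genome, "het_ref"))
  r <- count_pu_du(focal, sis, window, sites)
  expect_equal(r$D_u[r$category == "in_site"], 3)
  expect_equal(r$D_u[r$category == "out_site"], 2)
  expect_equal(r$P_u, c(0, 0))
  expect_equal(r$len, c(20, 80))

  # a site divergent under het_alt but polymorphic under het_ref
  # contributes 0.5 to D and 0.5 to P
  gt <- matrix(c("1/1", "0/1", "0/1"), ncol = 3)
  hvcf <- tiny_vcf(tempfile(fileext = ".vcf"), "chr1", 100, 12L,
                   refc[12], alt_of(12L), gt)
  focal2 <- list(het_alt = build_pseudogenomes(hvcf, genome, "het_alt"),
                 het_ref = build_pseudogenomes(hvcf, genome, "het_ref"))
  sis2 <- list(het_alt = build_pseudogenomes(svcf, genome, "het_alt"),
               het_ref = build_pseudogenomes(svcf, genome, "het_ref"))
  r2 <- count_pu_du(focal2, sis2, window, sites)
  expect_equal(r2$D_u[r2$category == "in_site"], 0.5)
  expect_equal(r2$P_u[r2$category == "in_site"], 0.5)
})

test_that("no variants in a window yields zero counts", {
  genome <- random_genome(100, seed = 47)
  refc <- strsplit(as.character(genome[[1]]), "")[[1]]
  v <- tiny_vcf(tempfile(fileext = ".vcf"), "chr1", 100, 5L, refc[5],
                setdiff(c("A", "C", "G", "T"), refc[5])[1],
                matrix("0/0", 1, 2))
  m <- list(het_alt = build_pseudogenomes(v, genome, "het_alt"),
            het_ref = build_pseudogenomes(v, genome, "het_ref"))
  r <- count_pu_du(m, m, 20:60, 30:35)
  expect_true(all(r$P_u == 0) && all(r$D_u == 0))
})

test_that("site_counts_table equals the brute-force window scan", {
  cfg <- tiny_popgen_cfg(seed = 48, n_genes = 8, n_pathway_genes = 3,
                         upstream_len = 1500L, n_regulators = 2L)
  anno <- simulate_genome_annotation(cfg)
  truth <- simulate_ase_counts(cfg)$truth
  dir <- file.path(tempdir(), "fx_scan")
  unlink(dir, recursive = TRUE)
  pop <- simulate_population_vcfs(cfg, anno,
                                  truth$gene_id[truth$in_pathway], dir)
  genome <- anno$genome
  focal <- modes_for(pop$vcf_paths[[pop$populations$focal]], genome)
  sisters <- lapply(pop$vcf_paths[pop$populations$sisters],
                    modes_for, genome = genome)
  names(sisters) <- pop$populations$sisters
  wins <- pop$windows
  sc <- site_counts_table(focal, sisters[1:2], wins, anno$sites)
  for (pn in names(sisters)[1:2]) {
    seqs_f <- lapply(focal, pseudogenome_sequences)
    seqs_s <- lapply(sisters[[pn]], pseudogenome_sequences)
    for (gi in c(1, 4, 8)) {
      wpos <- (wins$start[gi] + 1L):wins$end[gi]
      for (r in unique(anno$sites$regulator)) {
        spos <- sites_in_window(
          anno$sites[anno$sites$regulator == r, ], wins[gi, ])$positions
        oc <- oracle_pu_du(seqs_f, seqs_s, wpos, spos)
        row_in <- sc[sc$gene_id == wins$gene_id[gi] & sc$regulator == r &
                       sc$comparison == pn & sc$category == "in_site", ]
        row_out <- sc[sc$gene_id == wins$gene_id[gi] & sc$regulator == r &
                        sc$comparison == pn & sc$category == "out_site", ]
        expect_equal(c(row_in$P_u, row_in$D_u),
                     unname(oc["in_site", c("P_u", "D_u")]))
        expect_equal(c(row_out$P_u, row_out$D_u),
                     unname(oc["out_site", c("P_u", "D_u")]))
      }
    }
  }
})

test_that("normalized divergence handles zero polymorphism by exclusion", {
  expect_equal(normalized_divergence(4, 2), 2)
  expect_equal(normalized_divergence(0, 5), 0)
  expect_true(is.na(normalized_divergence(3, 0)))
})
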