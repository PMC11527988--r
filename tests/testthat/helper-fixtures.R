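# Small shared fixture builders.

tiny_popgen_cfg <- function(seed = 1L, ...) {
  defaults <- list(
    seed = seed, n_genes = 12L, n_pathway_genes = 4L, upstream_len = 2000L,
    n_haplotypes_per_pop = 4L, n_regulators = 3L, sites_per_gene = 4L,
    site_len_bp = 50L, n_background_terms = 5L,
    background_div_rate = 0.01, background_poly_rate = 0.02
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

modes_for <- function(vcf, genome, population = NULL) {
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  list(het_alt = build_pseudogenomes(vcf, genome, "het_alt", population),
       het_ref = build_pseudogenomes(vcf, genome, "het_ref", population))
}

read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# Write a minimal single-chromosome VCF for hand-built genotype scenarios.
tiny_vcf <- function(path, chrom, chrom_len, pos, ref, alt, gt) {
  samples <- sprintf("ind%02d", seq_len(ncol(gt)))
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, chrom_len),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    if (length(pos))
      paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT",
            apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  path
}

read_tsv_like <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

random_genome <- function(len, seed = 99, name = "chr1") {
  set.seed(seed)
  Biostrings::DNAStringSet(setNames(
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    name))
}

make_qc_fixture <- function() {
  set.seed(123)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  mutate_at <- function(s, at) {
    v <- strsplit(s, "")[[1]]
    for (p in at) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    paste(v, collapse = "")
  }
  g1a1 <- rand(100)
  g1a2 <- mutate_at(g1a1, c(10, 30, 50, 70, 90))  # every 20-mer is distinct
  g2 <- rand(100)                                  # identical alleles
  x <- rand(60)                                    # shared duplicated block
  g3a1 <- x
  g3a2 <- mutate_at(x, c(5, 15, 25, 35, 45, 55))
  g4a1 <- paste0(rand(40), x, rand(40))            # duplicate locus within allele 1
  g4a2 <- rand(120)
  list(
    a1 = Biostrings::DNAStringSet(c(G1 = g1a1, G2 = g2, G3 = g3a1, G4 = g4a1)),
    a2 = Biostrings::DNAStringSet(c(G1 = g1a2, G2 = g2, G3 = g3a2, G4 = g4a2))
  )
}

# mapped/ambiguous status of the read starting at `s` of transcript `i` in
# set `allele`, by naive substring scanning over every transcript
oracle_expected_fidelity <- function(tx1, tx2, gene, allele, k) {
  src <- if (allele == 1) tx1 else tx2
  s <- as.character(src[[gene]])
  all_seqs <- c(as.character(tx1), as.character(tx2))
  names(all_seqs) <- c(paste0("a1_", names(tx1)), paste0("a2_", names(tx2)))
  starts <- seq_len(nchar(s) - k + 1)
  ok <- vapply(starts, function(st) {
    read <- substr(s, st, st + k - 1)
    per <- vapply(all_seqs, function(z) {
      h <- gregexpr(read, z, fixed = TRUE)[[1]]
      if (h[1] == -1) 0L else length(h)
    }, integer(1))
    tot <- sum(per)
    if (tot == 1) return(TRUE)
    if (tot == 2) {
      where <- names(per)[per > 0]
      return(length(where) == 2 && all(per[where] == 1) &&
               identical(sort(sub("^a[12]_", "", where)), c(gene, gene)) &&
               length(unique(sub("_.*$", "", where))) == 2)
    }
    FALSE
  }, logical(1))
  100 * mean(ok)
}

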