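STOP_CODONS <- c("TAA", "TAG", "TGA")

rand_codons <- function(k, avoid_stops = TRUE) {
  if (k == 0) return(character(0))
  bases <- c("A", "C", "G", "T")
  out <- character(k)
  for (i in seq_len(k)) {
    repeat {
      cd <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      if (!avoid_stops || !cd %in% STOP_CODONS) break
    }
    out[i] <- cd
  }
  out
}

# Gene-body layout (transcript-local coordinates, 5'->3'):
#   A  = ATG + codons (no stops)          [shared first exon]
#   B1 = codons + TAA                     [tx1 second half, contiguous with A]
#   S  = spacer (never exonic)
#   C  = codons + TAA                     [tx2 second exon, spliced onto A]
# Gene classes cycle: 0 = tx1 only; 1 = tx2 valid and longer (selected);
# 2 = tx2 longer but with an internal in-frame stop (tx1 selected).
build_gene_body <- function(class, cds_len) {
  ka <- cds_len / 3L - 10L       # codons in A after ATG
  kb <- 8L                       # codons in B1 before TAA
  a <- c("ATG", rand_codons(ka))
  b1 <- c(rand_codons(kb), "TAA")
  spacer <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                  collapse = "")
  kc <- kb + 20L
  cc <- switch(as.character(class),
    "0" = character(0),
    "1" = c(rand_codons(kc), "TAA"),
    "2" = {
      z <- rand_codons(kc)
      z[ceiling(kc / 2)] <- "TGA"   # internal in-frame stop
      c(z, "TAA")
    })
  la <- 3L * length(a); lb <- 3L * length(b1); lc <- 3L * length(cc)
  seq <- paste0(paste(a, collapse = ""), paste(b1, collapse = ""),
                spacer, paste(cc, collapse = ""))
  list(
    seq = seq, la = la, lb = lb, ls = 30L, lc = lc,
    has_tx2 = class != 0,
    tx2_valid = class == 1,
    # local exon intervals [start, end] 1-based
    tx1_exons = list(c(1L, la + lb)),
    tx2_exons = if (class != 0)
      list(c(1L, la), c(la + lb + 30L + 1L, la + lb + 30L + lc))
  )
}

#' Simulate a genome with annotated genes and binding sites
#'
#' Builds one chromosome of random sequence with `n_genes` genes tiled at a
#' fixed spacing large enough that strand-aware upstream windows can never
#' overlap. Strands alternate. Each gene carries one single-exon transcript
#' with a valid ORF; cyclically, a second spliced transcript is added that is
#' either longer and valid (so it should be selected) or longer but broken
#' by an internal in-frame stop (so the first should be selected), which
#' exercises representative-transcript selection. Per regulator, a fixed
#' number of equal-length binding sites is placed at random non-overlapping
#' offsets inside every gene's upstream window.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (`DNAStringSet`, one chromosome `chr1`),
#'   `gff` (`GRanges` of gene/mRNA/exon/CDS features), `genes` (data.frame
#'   with `gene_id`, `tss`, `strand`, expected representative transcript and
#'   its CDS length), `sites` (data.frame `chrom`, `start`, `end`
#'   0-based half-open, `regulator`), `regulators` (character vector) and
#'   `chrom_len`.
#' @export
simulate_genome_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- derive_seeds(cfg$seed, 8L)
  with_seed(seeds[4L], {
    n <- cfg$n_genes
    chrom_len <- cfg$chrom_len
    chrom <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
    ids <- gene_ids(n)
    strand <- rep(c("+", "-"), length.out = n)
    tss <- as.integer(cfg$upstream_len + (seq_len(n) - 1L) * cfg$gene_spacing + 1L)

    feats <- vector("list", n)
    genes <- vector("list", n)
    for (i in seq_len(n)) {
      body <- build_gene_body((i - 1L) %% 3L, cfg$cds_len_bp)
      L <- nchar(body$seq)
      if (strand[i] == "+") {
        g0 <- tss[i]                              # genomic pos of local 1
        loc2gen <- function(iv) c(g0 + iv[1] - 1L, g0 + iv[2] - 1L)
        chrom[g0:(g0 + L - 1L)] <- strsplit(body$seq, "")[[1]]
      } else {
        g0 <- tss[i]
        loc2gen <- function(iv) c(g0 - iv[2] + 1L, g0 - iv[1] + 1L)
        rc <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(body$seq)))
        chrom[(g0 - L + 1L):g0] <- strsplit(rc, "")[[1]]
      }
      tx1 <- lapply(body$tx1_exons, loc2gen)
      tx2 <- if (body$has_tx2) lapply(body$tx2_exons, loc2gen)
      gid <- ids[i]
      t1 <- paste0(gid, ".t1")
      t2 <- paste0(gid, ".t2")
      span <- function(ex) c(min(vapply(ex, `[`, integer(1), 1L)),
                             max(vapply(ex, `[`, integer(1), 2L)))
      rows <- list(
        data.frame(type = "gene", id = gid, parent = NA,
                   start = span(c(tx1, tx2))[1], end = span(c(tx1, tx2))[2]),
        data.frame(type = "mRNA", id = t1, parent = gid,
                   start = span(tx1)[1], end = span(tx1)[2])
      )
      for (ex in tx1) {
        rows <- c(rows, list(
          data.frame(type = "exon", id = NA, parent = t1,
                     start = ex[1], end = ex[2]),
          data.frame(type = "CDS", id = NA, parent = t1,
                     start = ex[1], end = ex[2])))
      }
      if (body$has_tx2) {
        rows <- c(rows, list(
          data.frame(type = "mRNA", id = t2, parent = gid,
                     start = span(tx2)[1], end = span(tx2)[2])))
        for (ex in tx2) {
          rows <- c(rows, list(
            data.frame(type = "exon", id = NA, parent = t2,
                       start = ex[1], end = ex[2]),
            data.frame(type = "CDS", id = NA, parent = t2,
                       start = ex[1], end = ex[2])))
        }
      }
      f <- do.call(rbind, rows)
      f$strand <- strand[i]
      feats[[i]] <- f
      expect_tx <- if (body$has_tx2 && body$tx2_valid) t2 else t1
      expect_len <- if (body$has_tx2 && body$tx2_valid)
        body$la + body$lc else body$la + body$lb
      genes[[i]] <- data.frame(
        gene_id = gid, chrom = "chr1", strand = strand[i], tss = tss[i],
        expected_transcript = expect_tx, expected_cds_len = expect_len,
        stringsAsFactors = FALSE
      )
    }
    feats <- do.call(rbind, feats)
    gff <- GenomicRanges::GRanges(
      seqnames = "chr1",
      ranges = IRanges::IRanges(start = feats$start, end = feats$end),
      strand = feats$strand
    )
    S4Vectors::mcols(gff)$type <- feats$type
    S4Vectors::mcols(gff)$ID <- ifelse(is.na(feats$id), NA, feats$id)
    S4Vectors::mcols(gff)$Parent <- ifelse(is.na(feats$parent), "",
                                           feats$parent)
    genes <- do.call(rbind, genes)

    # Binding sites: the window is divided into sites_per_gene macro-slots
    # and each macro-slot into one sub-slot per regulator, with the site
    # jittered inside its sub-slot. Different regulators' site sets are
    # therefore disjoint, so a divergence enrichment planted at one
    # regulator leaves the others' in-site positions exactly at background.
    regs <- sprintf("TF%02d", seq_len(cfg$n_regulators))
    wins <- mapply(function(t, s) {
      w <- upstream_window(t, s, chrom_len, cfg$upstream_len)
      c(w$start, w$end)
    }, genes$tss, genes$strand)
    slot <- cfg$upstream_len %/% cfg$sites_per_gene
    sub_w <- slot %/% cfg$n_regulators
    if (sub_w < cfg$site_len_bp)
      stop_config("sites_per_gene",
                  "x site_len_bp x n_regulators exceeds the window width")
    sites <- list()
    for (j in seq_along(regs)) {
      jit <- matrix(
        sample.int(sub_w - cfg$site_len_bp + 1L,
                   n * cfg$sites_per_gene, replace = TRUE) - 1L,
        nrow = cfg$sites_per_gene)
      for (i in seq_len(n)) {
        st <- wins[1, i] + (seq_len(cfg$sites_per_gene) - 1L) * slot +
          (j - 1L) * sub_w + jit[, i]
        sites[[length(sites) + 1L]] <- data.frame(
          chrom = "chr1", start = st, end = st + cfg$site_len_bp,
          regulator = regs[j], gene_id = genes$gene_id[i],
          stringsAsFactors = FALSE)
      }
    }
    sites <- do.call(rbind, sites)
    genome <- Biostrings::DNAStringSet(
      setNames(paste(chrom, collapse = ""), "chr1"))
    list(genome = genome, gff = gff, genes = genes, sites = sites,
         regulators = regs, chrom_len = chrom_len)
  })
}

write_gff3 <- function(gff, path) {
  md <- S4Vectors::mcols(gff)
  attrs <- character(length(gff))
  has_id <- !is.na(md$ID)
  attrs[has_id] <- paste0("ID=", md$ID[has_id])
  has_par <- nzchar(md$Parent)
  attrs[has_par] <- paste0(attrs[has_par],
                           ifelse(has_id[has_par], ";", ""), "Parent=",
                           md$Parent[has_par])
  attrs[!nzchar(attrs)] <- "."
  lines <- paste(
    as.character(GenomicRanges::seqnames(gff)), "ciscreen",
    md$type, GenomicRanges::start(gff), GenomicRanges::end(gff), ".",
    as.character(GenomicRanges::strand(gff)), ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

write_sites_bed <- function(sites, path) {
  bed <- sites[order(sites$chrom, sites$start),
               c("chrom", "start", "end", "regulator")]
  con <- file(path, "wt")
  on.exit(close(con))
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a regulator binding-site BED file
#'
#' BED is 0-based half-open; the 4th column names the regulator.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end`, `regulator`.
#' @export
read_sites_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    regulator = S4Vectors::mcols(gr)$name,
    stringsAsFactors = FALSE
  )
}
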