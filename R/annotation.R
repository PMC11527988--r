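#' Validate an open reading frame
#'
#' A coding sequence is a valid ORF when it is at least two codons long, a
#' multiple of three, starts with ATG, ends with a stop codon (TAA, TAG or
#' TGA) and contains no internal in-frame stop. Sequences containing `N` are
#' never valid (an ambiguous base cannot certify the frame) but are not an
#' error.
#'
#' @param cds_sequence nucleotide string over A, C, G, T, N (case
#'   insensitive).
#' @return `TRUE` or `FALSE`.
#' @export
validate_orf <- function(cds_sequence) {
  s <- toupper(as.character(cds_sequence))
  if (grepl("[^ACGTN]", s)) stop_input("non-nucleotide characters in CDS")
  n <- nchar(s)
  if (n < 6 || n %% 3 != 0) return(FALSE)
  if (grepl("N", s, fixed = TRUE)) return(FALSE)
  codons <- substring(s, seq(1, n - 2, by = 3), seq(3, n, by = 3))
  stops <- c("TAA", "TAG", "TGA")
  codons[1] == "ATG" &&
    codons[length(codons)] %in% stops &&
    !any(codons[-length(codons)] %in% stops)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene, mRNA/transcript, exon and CDS features (1-based closed
#' coordinates, per the GFF3 standard) into a light container used by the
#' transcript-selection and window functions.
#'
#' @param gff3 path to a GFF3 file, or a `GRanges` already imported from one.
#' @return an object of class `gene_models`: a list with data.frames
#'   `genes` (gene_id, chrom, strand) and `transcripts` (transcript_id,
#'   gene_id, chrom, strand, start, end), plus `cds` and `exons`
#'   (data.frames of 1-based segments keyed by transcript_id).
#' @export
read_gene_models <- function(gff3) {
  gr <- if (inherits(gff3, "GRanges")) gff3
        else rtracklayer::import(gff3, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  parent <- if ("Parent" %in% names(md))
    vapply(md$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  else rep(NA_character_, length(gr))
  id <- if ("ID" %in% names(md)) as.character(md$ID)
        else rep(NA_character_, length(gr))
  df <- data.frame(
    type = type, id = id, parent = parent,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  genes <- df[df$type == "gene", c("id", "chrom", "strand")]
  names(genes)[1] <- "gene_id"
  tx <- df[df$type %in% c("mRNA", "transcript"),
           c("id", "parent", "chrom", "strand", "start", "end")]
  names(tx)[1:2] <- c("transcript_id", "gene_id")
  seg <- function(what) {
    z <- df[df$type == what, c("parent", "chrom", "start", "end", "strand")]
    names(z)[1] <- "transcript_id"
    z[order(z$transcript_id, z$start), , drop = FALSE]
  }
  structure(list(genes = genes, transcripts = tx,
                 cds = seg("CDS"), exons = seg("exon")),
            class = "gene_models")
}

# Spliced CDS sequence of one transcript, 5'->3'.
spliced_cds <- function(models, transcript_id, genome) {
  seg <- models$cds[models$cds$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(seg) == 0) return(NULL)
  chrom <- seg$chrom[1]
  if (!chrom %in% names(genome))
    stop_input("chromosome '%s' absent from genome", chrom)
  chrom_seq <- genome[[chrom]]
  if (any(seg$start < 1 | seg$end > length(chrom_seq)))
    stop_input("CDS of %s outside chromosome bounds", transcript_id)
  parts <- mapply(function(s, e)
    as.character(Biostrings::subseq(chrom_seq, s, e)),
    seg$start, seg$end)
  s <- Biostrings::DNAString(paste(parts, collapse = ""))
  if (seg$strand[1] == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Select one representative transcript per gene
#'
#' Among a gene's transcripts whose spliced CDS is a valid ORF
#' ([validate_orf()]), returns the one with the longest CDS; ties break to
#' the lexicographically smallest transcript id, and genes with no valid
#' transcript return `NA` (such genes are excluded from downstream upstream
#' window analysis).
#'
#' @param models a `gene_models` object.
#' @param gene_id gene to resolve.
#' @param genome `DNAStringSet` holding the chromosome sequences.
#' @return transcript id or `NA_character_`.
#' @export
select_representative_transcript <- function(models, gene_id, genome) {
  tx <- models$transcripts[models$transcripts$gene_id == gene_id, ,
                           drop = FALSE]
  if (nrow(tx) == 0) return(NA_character_)
  cds_seq <- vapply(tx$transcript_id,
                    function(t) spliced_cds(models, t, genome) %||% "",
                    character(1))
  ok <- nzchar(cds_seq) & vapply(cds_seq, validate_orf, logical(1))
  if (!any(ok)) return(NA_character_)
  lens <- nchar(cds_seq)
  cand <- tx$transcript_id[ok]
  cand_len <- lens[ok]
  cand[order(-cand_len, cand)][1]
}

#' Representative-transcript table with TSS coordinates
#'
#' Applies [select_representative_transcript()] to every gene and reports,
#' per gene, the chosen transcript, its CDS length, whether any transcript
#' passed ORF validation, and the transcription start site (the 5' end of
#' the chosen transcript: its start on + genes, its end on - genes).
#'
#' @inheritParams select_representative_transcript
#' @return data.frame with columns `gene_id`, `transcript_id`, `cds_len`,
#'   `orf_valid`, `chrom`, `strand`, `tss` (1-based; `NA` for genes with no
#'   valid ORF).
#' @export
representative_transcripts <- function(models, genome) {
  res <- lapply(models$genes$gene_id, function(g) {
    t <- select_representative_transcript(models, g, genome)
    if (is.na(t)) {
      return(data.frame(gene_id = g, transcript_id = NA_character_,
                        cds_len = NA_integer_, orf_valid = FALSE,
                        chrom = models$genes$chrom[models$genes$gene_id == g],
                        strand = models$genes$strand[models$genes$gene_id == g],
                        tss = NA_integer_, stringsAsFactors = FALSE))
    }
    tx <- models$transcripts[models$transcripts$transcript_id == t, ]
    data.frame(
      gene_id = g, transcript_id = t,
      cds_len = nchar(spliced_cds(models, t, genome)),
      orf_valid = TRUE, chrom = tx$chrom, strand = tx$strand,
      tss = if (tx$strand == "+") tx$start else tx$end,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Strand-aware upstream window of a TSS
#'
#' The window of `width` bp immediately upstream of (and excluding) the TSS,
#' in 0-based half-open coordinates, clipped at the chromosome edges. On the
#' plus strand this is `[max(0, tss - 1 - width), tss - 1)`; on the minus
#' strand `[tss, min(chrom_len, tss + width))`.
#'
#' @param tss 1-based transcription start site.
#' @param strand `"+"` or `"-"`.
#' @param chrom_len chromosome length in bp.
#' @param width window width in bp (default 50,000).
#' @return list with `start`, `end` (0-based half-open) and `length`.
#' @export
upstream_window <- function(tss, strand, chrom_len, width = 50000L) {
  if (!strand %in% c("+", "-")) stop_input("unknown strand '%s'", strand)
  stopifnot(tss >= 1, tss <= chrom_len)
  if (strand == "+") {
    start <- max(0, tss - 1 - width)
    end <- tss - 1
  } else {
    start <- tss
    end <- min(chrom_len, tss + width)
  }
  list(start = as.integer(start), end = as.integer(end),
       length = as.integer(end - start))
}

#' Upstream windows for all genes with a valid representative transcript
#'
#' @param rep_tx table from [representative_transcripts()].
#' @param chrom_len chromosome length (named vector when multiple
#'   chromosomes).
#' @param width window width in bp.
#' @return data.frame in BED-like 0-based half-open coordinates: `chrom`,
#'   `start`, `end`, `gene_id`, `strand`.
#' @export
upstream_windows <- function(rep_tx, chrom_len, width = 50000L) {
  rep_tx <- rep_tx[rep_tx$orf_valid & !is.na(rep_tx$tss), , drop = FALSE]
  cl <- function(chrom) {
    if (length(chrom_len) == 1L && is.null(names(chrom_len))) chrom_len
    else chrom_len[[chrom]]
  }
  rows <- lapply(seq_len(nrow(rep_tx)), function(i) {
    w <- upstream_window(rep_tx$tss[i], rep_tx$strand[i],
                         cl(rep_tx$chrom[i]), width)
    data.frame(chrom = rep_tx$chrom[i], start = w$start, end = w$end,
               gene_id = rep_tx$gene_id[i], strand = rep_tx$strand[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Binding-site positions inside an upstream window
#'
#' Intersects one regulator's binding sites with one window and returns the
#' union of covered genomic positions (overlapping sites count once), plus
#' the total in-window site length used by the length-normalised screen
#' variants.
#'
#' @param sites data.frame of 0-based half-open site intervals (`chrom`,
#'   `start`, `end`) for one regulator, or a `GRanges` (1-based closed, as
#'   imported from BED by rtracklayer).
#' @param window one-row window as returned in [upstream_windows()] (0-based
#'   half-open).
#' @return list with `positions` (sorted unique 1-based genomic positions),
#'   `site_len` (its length) and `window_len`.
#' @export
sites_in_window <- function(sites, window) {
  if (inherits(sites, "GRanges")) {
    sites <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(sites)),
      start = GenomicRanges::start(sites) - 1L,
      end = GenomicRanges::end(sites),
      stringsAsFactors = FALSE
    )
  }
  sites <- sites[sites$chrom == window$chrom, , drop = FALSE]
  ir <- IRanges::reduce(IRanges::IRanges(start = sites$start + 1L,
                                         end = sites$end))
  win <- IRanges::IRanges(start = window$start + 1L, end = window$end)
  hit <- IRanges::intersect(ir, win)
  positions <- sort(unique(unlist(
    mapply(seq.int, IRanges::start(hit), IRanges::end(hit),
           SIMPLIFY = FALSE), use.names = FALSE)))
  if (length(positions) == 0) positions <- integer(0)
  list(positions = positions,
       site_len = length(positions),
       window_len = as.integer(window$end - window$start))
}
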