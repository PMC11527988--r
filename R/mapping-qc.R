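#' Simulated-read mapping-fidelity table for two allele transcript sets
#'
#' Quality control for allele-specific quantification: error-free reads of
#' length `read_len` are sampled uniformly from each allele's transcripts
#' (about `reads_per_tx` per transcript per replicate) and looked up against
#' the concatenated two-allele transcript set by exact substring match. A
#' read counts as mapped when its sequence occurs at exactly one location,
#' or at exactly two locations that are the two orthologous copies of its
#' own gene (one per allele) — shared sequence between true homologs still
#' maps uniquely per locus, as in best-match diploid alignment. Any other
#' multi-locus match makes the read ambiguous and it is discarded. Mapping
#' fidelity is `100 * mapped / simulated` per gene per allele, averaged over
#' replicates; the table also carries the absolute fidelity difference
#' between alleles used by [mapping_bias_filter()].
#'
#' @param allele1_transcripts,allele2_transcripts named `DNAStringSet`s (or
#'   FASTA paths); names are gene ids, shared between the two sets as
#'   ortholog pairs.
#' @param reads_per_tx reads simulated per transcript per replicate
#'   (default 200).
#' @param read_len read length in bp; must not exceed the shortest
#'   transcript.
#' @param replicates number of simulation replicates (default 2).
#' @param seed optional RNG seed.
#' @return data.frame with columns `gene_id`, `fidelity_allele1`,
#'   `fidelity_allele2` (percent) and `abs_diff`.
#' @export
simulate_and_map <- function(allele1_transcripts, allele2_transcripts,
                             reads_per_tx = 200L, read_len = 50L,
                             replicates = 2L, seed = NULL) {
  a1 <- load_tx(allele1_transcripts, "allele1")
  a2 <- load_tx(allele2_transcripts, "allele2")
  if (anyDuplicated(names(a1)))
    stop_input("duplicate gene_ids within allele 1 transcript set")
  if (anyDuplicated(names(a2)))
    stop_input("duplicate gene_ids within allele 2 transcript set")
  shared <- intersect(names(a1), names(a2))
  if (length(shared) == 0) stop_input("no shared gene_ids between alleles")
  minw <- min(Biostrings::width(a1), Biostrings::width(a2))
  if (read_len > minw)
    stop_input("read_len (%d) exceeds shortest transcript (%d)",
               read_len, minw)

  idx <- kmer_index(a1, a2, read_len)
  sim_one <- function(txset, allele) {
    seqs <- as.character(txset)
    genes <- names(txset)
    res <- lapply(seq_along(seqs), function(i) {
      L <- nchar(seqs[i])
      starts <- sample.int(L - read_len + 1L, reads_per_tx, replace = TRUE)
      reads <- substring(seqs[i], starts, starts + read_len - 1L)
      st <- idx[data.table::data.table(seq = reads), on = "seq"]
      mapped <- st$n_total == 1L |
        (st$n_total == 2L & st$homolog_gene == genes[i])
      data.frame(gene_id = genes[i], allele = allele,
                 mapped = sum(mapped, na.rm = TRUE),
                 simulated = reads_per_tx, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }
  tab <- with_seed(seed, {
    reps <- lapply(seq_len(replicates), function(r) {
      rbind(sim_one(a1, "allele1"), sim_one(a2, "allele2"))
    })
    do.call(rbind, reps)
  })
  agg <- data.table::as.data.table(tab)[
    , .(fid = 100 * sum(mapped) / sum(simulated)),
    by = .(gene_id, allele)]
  wide <- data.table::dcast(agg, gene_id ~ allele, value.var = "fid")
  out <- data.frame(
    gene_id = wide$gene_id,
    fidelity_allele1 = wide$allele1 %||% NA_real_,
    fidelity_allele2 = wide$allele2 %||% NA_real_,
    stringsAsFactors = FALSE
  )
  out$abs_diff <- abs(out$fidelity_allele1 - out$fidelity_allele2)
  out[order(out$gene_id), , drop = FALSE]
}

load_tx <- function(x, what) {
  s <- if (is.character(x) && length(x) == 1 && file.exists(x))
    Biostrings::readDNAStringSet(x)
  else Biostrings::DNAStringSet(x)
  names(s) <- sub("\\s.*$", "", names(s))
  if (is.null(names(s)) || any(!nzchar(names(s))))
    stop_input("%s transcripts must be named by gene_id", what)
  s
}

# Index of every read_len-mer across both allele sets: total occurrence
# count, and when the k-mer occurs exactly twice as an ortholog pair (one
# copy per allele of one gene), that gene's id.
kmer_index <- function(a1, a2, k) {
  collect <- function(txset, allele) {
    seqs <- as.character(txset)
    n <- nchar(seqs) - k + 1L
    data.table::data.table(
      seq = unlist(lapply(seq_along(seqs), function(i)
        substring(seqs[i], seq_len(n[i]), seq_len(n[i]) + k - 1L))),
      allele = allele,
      gene = rep(names(txset), n)
    )
  }
  occ <- rbind(collect(a1, "allele1"), collect(a2, "allele2"))
  idx <- occ[, .(
    n_total = .N,
    homolog_gene = if (.N == 2L && data.table::uniqueN(gene) == 1L &&
                       data.table::uniqueN(allele) == 2L) gene[1]
                   else NA_character_
  ), by = seq]
  data.table::setkey(idx, seq)
  idx
}

#' Filter genes by allelic mapping-fidelity difference
#'
#' Removes genes whose absolute difference in mapping fidelity between the
#' two alleles exceeds `threshold` percent (strictly greater; a gene at
#' exactly the threshold is retained).
#'
#' @param fidelities table from [simulate_and_map()].
#' @param threshold maximum tolerated `abs_diff` in percent (default 5).
#' @return list with `retained` and `removed` gene-id vectors and
#'   `n_removed`.
#' @export
mapping_bias_filter <- function(fidelities, threshold = 5) {
  stopifnot(all(c("gene_id", "abs_diff") %in% names(fidelities)))
  bad <- fidelities$abs_diff > threshold
  message(sum(bad), " of ", nrow(fidelities),
          " genes removed by the mapping-bias filter (abs_diff > ",
          threshold, "%)")
  list(retained = fidelities$gene_id[!bad],
       removed = fidelities$gene_id[bad],
       n_removed = sum(bad))
}
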