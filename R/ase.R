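#' TPM-normalise a count matrix
#'
#' Transcripts-per-million: read counts are first divided by transcript
#' length in kb, then by the per-sample sum of those rates, and scaled to
#' 10^6, so every column of the result sums to one million (except all-zero
#' samples, which stay zero and raise a warning).
#'
#' @param counts numeric gene-by-sample matrix of read counts (rownames are
#'   gene ids).
#' @param transcript_lengths named numeric vector of transcript lengths in
#'   bp, covering at least every gene with a nonzero count.
#' @return matrix of TPM values with the same dimnames as `counts`.
#' @export
tpm_normalize <- function(counts, transcript_lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop_input("counts must have gene ids as rownames")
  if (any(counts < 0)) stop_input("counts must be non-negative")
  len <- transcript_lengths[rownames(counts)]
  expressed <- rowSums(counts) > 0
  bad <- expressed & (is.na(len) | len <= 0)
  if (any(bad))
    stop_input("missing or non-positive transcript length for expressed gene(s): %s",
               paste(head(rownames(counts)[bad], 5), collapse = ", "))
  len[is.na(len) | len <= 0] <- 1  # unexpressed genes only; rate stays 0
  rate <- counts / (len / 1000)
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("all-zero sample(s): ", paste(colnames(counts)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  sweep(rate, 2, tot, "/") * 1e6
}

# --- beta-binomial machinery -------------------------------------------------

# Method-of-moments estimate of a genome-wide intra-class correlation rho for
# allele-1 counts x out of totals n, grouped by gene. Uses the per-gene pooled
# fraction and corrects for the degrees of freedom absorbed by it; pooled over
# genes so single-replicate designs borrow strength from the full table.
estimate_overdispersion <- function(x, n, gene) {
  keep <- n > 0
  x <- x[keep]; n <- n[keep]; gene <- gene[keep]
  X <- tapply(x, gene, sum)
  N <- tapply(n, gene, sum)
  p <- (X / N)[as.character(gene)]
  Ntot <- N[as.character(gene)]
  pq <- p * (1 - p)
  ok <- pq > 0
  if (!any(ok)) return(0)
  x <- x[ok]; n <- n[ok]; p <- p[ok]; pq <- pq[ok]; Ntot <- Ntot[ok]
  gene <- gene[ok]
  resid2 <- (x - n * p)^2
  a <- n * pq                 # binomial variance component
  b <- n * (n - 1) * pq      # overdispersion variance component
  # E[sum (x_i - n_i p_hat)^2] = sum v_i (1 - 2 n_i / N) + (sum n_i^2 / N^2) sum v_j
  # with v_i = a_i + rho * b_i; accumulate the linear coefficients per gene.
  f1 <- 1 - 2 * n / Ntot
  sn2 <- tapply(n^2, gene, sum)[as.character(gene)] / Ntot^2
  A <- sum(a * f1) + sum(sn2 * a)
  B <- sum(b * f1) + sum(sn2 * b)
  if (B <= 0) return(0)
  rho <- (sum(resid2) - A) / B
  max(0, min(rho, 0.99))
}

bb_loglik <- function(p, x, n, theta) {
  a <- p * theta
  b <- (1 - p) * theta
  sum(lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b))
}

# Beta-binomial likelihood-ratio test of H0: allelic fraction = 0.5 with a
# fixed overdispersion rho shared across genes.
bb_lrt_one <- function(x, n, rho) {
  theta <- 1 / rho - 1
  opt <- optimize(function(p) bb_loglik(p, x, n, theta),
                  interval = c(1e-6, 1 - 1e-6), maximum = TRUE, tol = 1e-9)
  lrt <- max(0, 2 * (opt$objective - bb_loglik(0.5, x, n, theta)))
  pchisq(lrt, df = 1, lower.tail = FALSE)
}

#' Per-gene test for allelic imbalance
#'
#' Tests, for each gene, the null hypothesis that the allele-1 fraction of
#' reads is 0.5 across replicates. Genes with fewer than `min_total_reads`
#' reads summed over both alleles and all replicates are excluded before
#' testing. Overdispersion relative to the binomial is estimated genome-wide
#' by the method of moments and shared across genes; each gene is then tested
#' by a beta-binomial likelihood-ratio test (chi-square, 1 df). When the
#' estimated overdispersion is zero the test reduces to the exact two-sided
#' binomial test on pooled counts. The reported effect is
#' `l2r = log2((sum allele1 + 0.5) / (sum allele2 + 0.5))` (Haldane
#' correction), oriented so positive values mean allele 1 higher.
#'
#' @param counts data.frame with columns `gene_id`, `replicate`,
#'   `allele1_count`, `allele2_count`.
#' @param min_total_reads genes below this total are dropped (default 10).
#' @return data.frame with columns `gene_id`, `n_total`, `l2r`, `pvalue`,
#'   one row per tested gene; the number of excluded genes is in
#'   `attr(, "n_low_count")` and the overdispersion in `attr(, "rho")`.
#' @export
allelic_imbalance_test <- function(counts, min_total_reads = 10) {
  need <- c("gene_id", "replicate", "allele1_count", "allele2_count")
  if (!all(need %in% names(counts)))
    stop_input("counts must have columns %s", paste(need, collapse = ", "))
  if (any(counts$allele1_count < 0 | counts$allele2_count < 0))
    stop_input("negative counts")
  dt <- data.table::as.data.table(counts)
  tot <- dt[, .(a1 = sum(allele1_count), a2 = sum(allele2_count)),
            by = gene_id]
  tot[, n_total := a1 + a2]
  low <- tot$n_total < min_total_reads
  kept_ids <- tot$gene_id[!low]
  sub <- dt[dt$gene_id %in% kept_ids, ]
  x <- sub$allele1_count
  n <- sub$allele1_count + sub$allele2_count
  rho <- estimate_overdispersion(x, n, sub$gene_id)
  kept <- tot[!low, ]
  if (rho <= 0) {
    pv <- mapply(function(a1, nt) {
      if (nt == 0) return(1)
      binom.test(a1, nt, p = 0.5)$p.value
    }, kept$a1, kept$n_total)
  } else {
    keys <- split(seq_len(nrow(sub)), sub$gene_id)
    pv <- vapply(as.character(kept$gene_id), function(g) {
      i <- keys[[g]]
      ni <- n[i]
      use <- ni > 0
      if (!any(use)) return(1)
      bb_lrt_one(x[i][use], ni[use], rho)
    }, numeric(1))
  }
  out <- data.frame(
    gene_id = kept$gene_id,
    n_total = kept$n_total,
    l2r = log2((kept$a1 + 0.5) / (kept$a2 + 0.5)),
    pvalue = unname(pv),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_low_count") <- sum(low)
  attr(out, "rho") <- rho
  out
}

#' Signed significance statistic for directional tests
#'
#' `s` equals the log2 allelic ratio for genes whose BH-adjusted p-value is
#' below `alpha`, and 0 otherwise, so that summing `s` over a pathway
#' measures coordinated directionality while non-significant genes contribute
#' nothing. Positive `s` means the first-named allele is higher.
#'
#' @param l2r numeric vector of log2 allelic ratios.
#' @param padj BH-adjusted p-values, same length.
#' @param alpha significance threshold on `padj` (default 0.05).
#' @return numeric vector `s`.
#' @export
sign_statistic <- function(l2r, padj, alpha = 0.05) {
  stopifnot(length(l2r) == length(padj))
  ifelse(!is.na(padj) & padj < alpha, l2r, 0)
}

#' Full per-gene ASE analysis
#'
#' Runs [allelic_imbalance_test()], adds Benjamini-Hochberg adjusted
#' p-values across all tested genes and the sign statistic
#' [sign_statistic()].
#'
#' @inheritParams allelic_imbalance_test
#' @param alpha threshold on adjusted p for calling a gene significant.
#' @param retained_genes optional character vector (e.g. from
#'   [mapping_bias_filter()]); genes outside it are dropped before testing.
#' @return data.frame with columns `gene_id`, `n_total`, `l2r`, `pvalue`,
#'   `padj`, `s`.
#' @export
ase_results <- function(counts, min_total_reads = 10, alpha = 0.05,
                        retained_genes = NULL) {
  if (!is.null(retained_genes))
    counts <- counts[counts$gene_id %in% retained_genes, , drop = FALSE]
  res <- allelic_imbalance_test(counts, min_total_reads = min_total_reads)
  res$padj <- p.adjust(res$pvalue, method = "BH")
  res$s <- sign_statistic(res$l2r, res$padj, alpha = alpha)
  attr(res, "alpha") <- alpha
  res
}
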