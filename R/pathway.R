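#' Sum of the sign statistic over a gene set
#'
#' @param s_by_gene named numeric vector of per-gene sign statistics over the
#'   tested universe.
#' @param term_genes character vector of gene ids for one term.
#' @return list with `n` (genes in the term with expression data), `n_sig`
#'   (those with nonzero `s`) and `S_true` (sum of `s`), or `NULL` when the
#'   intersection is empty.
#' @export
score_term <- function(s_by_gene, term_genes) {
  genes <- intersect(term_genes, names(s_by_gene))
  if (length(genes) == 0) return(NULL)
  s <- s_by_gene[genes]
  list(n = length(genes), n_sig = sum(s != 0), S_true = sum(s))
}

#' Empirical p-value for a pathway sum by resampling
#'
#' Draws `B` random gene sets of size `n` without replacement from the full
#' tested universe (zeros included), sums their sign statistics, and reports
#' the two-sided empirical p-value: the proportion of resamples whose
#' absolute sum is at least `|S_true|` (ties count as extreme). With
#' `smooth = TRUE` the add-one estimate `(1 + k) / (1 + B)` is reported
#' instead, which can never be zero.
#'
#' @param s_all numeric vector of sign statistics over the whole universe.
#' @param n term size (genes drawn per resample).
#' @param S_true observed term sum.
#' @param B number of resamples (default 10,000).
#' @param seed optional seed for reproducibility.
#' @param smooth use the add-one smoothed estimator (default `FALSE`).
#' @return empirical p-value in (0, 1] (or [1/(B+1), 1] when smoothed).
#' @export
resample_null <- function(s_all, n, S_true, B = 10000L, seed = NULL,
                          smooth = FALSE) {
  if (n > length(s_all)) stop_input("term size n exceeds the gene universe")
  if (B < 1) stop_input("B must be >= 1")
  sums <- with_seed(seed, {
    vapply(seq_len(B),
           function(i) sum(s_all[sample.int(length(s_all), n)]),
           numeric(1))
  })
  k <- sum(abs(sums) >= abs(S_true) - 1e-12)
  if (smooth) (1 + k) / (1 + B) else k / B
}

#' Screen a gene-set collection for coordinated allelic direction
#'
#' For every term: intersect with the tested universe, drop terms with fewer
#' than `min_sig` genes carrying a nonzero sign statistic, compute the
#' observed sum `S_true` and its resampling p-value, then Benjamini-Hochberg
#' adjust across the tested terms.
#'
#' @param ase data.frame from [ase_results()] (needs `gene_id`, `l2r`,
#'   `padj`, `s`).
#' @param collection named list of character vectors (term id -> gene ids)
#'   or a data.frame with columns `term_id`, `gene_id`.
#' @param min_sig minimum significant (nonzero `s`) genes per term
#'   (default 10).
#' @param B resamples per term (default 10,000).
#' @param alpha significance threshold used for the directional ratio column.
#' @param seed master seed; per-term seeds are derived from it so results do
#'   not depend on term order.
#' @param smooth passed to [resample_null()].
#' @return data.frame with columns `term_id`, `n`, `n_sig`, `S_true`,
#'   `p_emp`, `padj`, `direction_ratio`, sorted by `padj`.
#' @export
screen_terms <- function(ase, collection, min_sig = 10, B = 10000L,
                         alpha = 0.05, seed = NULL, smooth = FALSE) {
  collection <- as_collection(collection)
  if (length(collection) == 0) {
    warning("empty gene-set collection")
    return(data.frame(term_id = character(), n = integer(),
                      n_sig = integer(), S_true = numeric(),
                      p_emp = numeric(), padj = numeric(),
                      direction_ratio = numeric()))
  }
  s_all <- setNames(ase$s, ase$gene_id)
  scored <- lapply(collection, score_term, s_by_gene = s_all)
  keep <- !vapply(scored, is.null, logical(1))
  if (any(!keep))
    message(sum(!keep), " term(s) had no overlap with the tested universe")
  scored <- scored[keep]
  collection <- collection[keep]
  n_sig <- vapply(scored, `[[`, integer(1), "n_sig")
  tested <- n_sig >= min_sig
  message(sum(!tested), " term(s) dropped with fewer than ", min_sig,
          " significant genes; ", sum(tested), " tested")
  scored <- scored[tested]
  collection <- collection[tested]
  if (length(scored) == 0)
    return(data.frame(term_id = character(), n = integer(),
                      n_sig = integer(), S_true = numeric(),
                      p_emp = numeric(), padj = numeric(),
                      direction_ratio = numeric()))
  seeds <- if (is.null(seed)) rep(list(NULL), length(scored))
           else as.list(derive_seeds(seed, length(scored)))
  p_emp <- mapply(function(sc, sd) {
    resample_null(s_all, sc$n, sc$S_true, B = B, seed = sd, smooth = smooth)
  }, scored, seeds)
  ratio <- vapply(collection, function(genes) {
    directional_report(ase$l2r, ase$padj, ase$gene_id, genes,
                       alpha = alpha)$ratio
  }, numeric(1))
  out <- data.frame(
    term_id = names(scored),
    n = vapply(scored, `[[`, integer(1), "n"),
    n_sig = n_sig[tested],
    S_true = vapply(scored, `[[`, numeric(1), "S_true"),
    p_emp = p_emp,
    padj = p.adjust(p_emp, method = "BH"),
    direction_ratio = ratio,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$padj, out$p_emp, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_collection <- function(collection) {
  if (is.data.frame(collection)) {
    stopifnot(all(c("term_id", "gene_id") %in% names(collection)))
    collection <- split(collection$gene_id, collection$term_id)
  }
  lapply(collection, unique)
}

#' Directional summary of a gene set
#'
#' Among the genes of a set, reports the percentage whose effect is oriented
#' each way, both restricted to significant genes (`padj < alpha`) and
#' unfiltered (sign of the effect only), plus the up:down ratio among
#' significant genes. Applies unchanged to any per-gene table of signed
#' effects with adjusted p-values, e.g. knockdown-vs-control differential
#' expression.
#'
#' @param l2fc per-gene signed log2 effect over the tested universe.
#' @param padj matching BH-adjusted p-values.
#' @param gene_ids matching gene ids.
#' @param gene_set character vector of set members.
#' @param alpha significance threshold (default 0.05).
#' @return list with `n`, `n_sig`, `pct_up_sig`, `pct_down_sig`,
#'   `pct_up_all`, `pct_down_all` and `ratio` (`NA` when no significant gene
#'   points down, or no significant genes at all).
#' @export
directional_report <- function(l2fc, padj, gene_ids, gene_set,
                               alpha = 0.05) {
  idx <- which(gene_ids %in% gene_set)
  if (length(idx) == 0)
    return(list(n = 0L, n_sig = 0L, pct_up_sig = NA_real_,
                pct_down_sig = NA_real_, pct_up_all = NA_real_,
                pct_down_all = NA_real_, ratio = NA_real_))
  fc <- l2fc[idx]
  sig <- !is.na(padj[idx]) & padj[idx] < alpha & fc != 0
  n_sig <- sum(sig)
  pct <- function(x, denom) if (denom > 0) 100 * sum(x) / denom else NA_real_
  up_all <- fc > 0
  pct_up_sig <- pct(fc[sig] > 0, n_sig)
  pct_down_sig <- pct(fc[sig] < 0, n_sig)
  ratio <- if (n_sig > 0 && pct_down_sig > 0) pct_up_sig / pct_down_sig
           else NA_real_
  list(
    n = length(idx), n_sig = n_sig,
    pct_up_sig = pct_up_sig, pct_down_sig = pct_down_sig,
    pct_up_all = pct(up_all, sum(fc != 0)),
    pct_down_all = pct(fc < 0, sum(fc != 0)),
    ratio = ratio
  )
}

#' Fisher's exact association for a 2x2 table
#'
#' Two-sided p-value from the conditional hypergeometric distribution (the
#' sum over tables whose probability does not exceed the observed one) and
#' the sample odds ratio, with a Haldane +0.5 correction applied to every
#' cell when any cell is zero.
#'
#' @param table_2x2 2x2 matrix of non-negative integer counts.
#' @return list with `odds_ratio` and `p` (both `NA` when a margin is zero).
#' @export
fisher_association <- function(table_2x2) {
  m <- as.matrix(table_2x2)
  if (!all(dim(m) == c(2, 2)) || any(m < 0) || any(m != round(m)))
    stop_input("table_2x2 must be a 2x2 matrix of non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(odds_ratio = NA_real_, p = NA_real_))
  p <- fisher.test(m)$p.value
  if (any(m == 0)) m <- m + 0.5
  list(odds_ratio = (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1]), p = p)
}
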