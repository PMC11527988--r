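gene_ids <- function(n) sprintf("g%05d", seq_len(n))

# Sample pathway membership and planted per-gene allelic effects.
# Direction split: round(frac_directional * n_pathway) genes favour allele 1
# (+planted_l2fc), the rest favour allele 2 (-planted_l2fc).
plant_truth <- function(cfg) {
  ids <- gene_ids(cfg$n_genes)
  n_up <- as.integer(round(cfg$frac_directional * cfg$n_pathway_genes))
  with_seed(derive_seeds(cfg$seed, 8L)[1L], {
    pathway <- sort(sample.int(cfg$n_genes, cfg$n_pathway_genes))
    up <- pathway[seq_len(n_up)]
    down <- setdiff(pathway, up)
    l2fc <- numeric(cfg$n_genes)
    l2fc[up] <- cfg$planted_l2fc
    l2fc[down] <- -cfg$planted_l2fc
    data.frame(
      gene_id = ids,
      in_pathway = seq_len(cfg$n_genes) %in% pathway,
      planted_l2fc = l2fc,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate an allele-specific read-count table with known ground truth
#'
#' Draws per-replicate negative-binomial counts for the two parental alleles
#' of every gene. A gene with planted log2 effect `d` has its total mean
#' `2 * mean_depth` split between alleles as `2^d / (1 + 2^d)` vs
#' `1 / (1 + 2^d)`, so the expected allele-1:allele-2 ratio is exactly `2^d`;
#' unplanted genes split evenly. Dispersion is the usual RNA-seq
#' parameterisation `var = mu + alpha * mu^2`.
#'
#' @param cfg a [sim_config()].
#' @return a list with `counts` (data.frame: gene_id, replicate,
#'   allele1_count, allele2_count) and `truth` (data.frame: gene_id,
#'   in_pathway, planted_l2fc).
#' @export
simulate_ase_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  truth <- plant_truth(cfg)
  n <- cfg$n_genes
  reps <- cfg$n_replicates
  w <- 2^truth$planted_l2fc
  mu1 <- 2 * cfg$mean_depth * w / (1 + w)
  mu2 <- 2 * cfg$mean_depth / (1 + w)
  size <- if (cfg$nb_dispersion > 0) 1 / cfg$nb_dispersion else Inf
  counts <- with_seed(derive_seeds(cfg$seed, 8L)[2L], {
    draw <- function(mu) {
      if (is.finite(size)) rnbinom(n * reps, mu = rep(mu, reps), size = size)
      else stats::rpois(n * reps, rep(mu, reps))
    }
    data.frame(
      gene_id = rep(truth$gene_id, reps),
      replicate = rep(seq_len(reps), each = n),
      allele1_count = draw(mu1),
      allele2_count = draw(mu2),
      stringsAsFactors = FALSE
    )
  })
  list(counts = counts, truth = truth)
}

#' Simulate a gene-set collection containing the planted pathway
#'
#' The first term is the focal pathway (all planted genes); the remaining
#' terms are random draws from the gene universe with sizes uniform between
#' 15 and 120 genes, mimicking GO biological-process term sizes.
#'
#' @param cfg a [sim_config()].
#' @param truth the truth table from [simulate_ase_counts()]; regenerated
#'   from `cfg` when omitted.
#' @return a list with `collection` (named list term_id -> gene_id vector),
#'   `table` (long data.frame: term_id, gene_id) and `focal_term`.
#' @export
simulate_gene_sets <- function(cfg, truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(truth)) truth <- plant_truth(cfg)
  focal <- truth$gene_id[truth$in_pathway]
  terms <- list(TERM00001 = focal)
  if (cfg$n_background_terms > 0) {
    bg <- with_seed(derive_seeds(cfg$seed, 8L)[3L], {
      sizes <- pmin(sample(15:120, cfg$n_background_terms, replace = TRUE),
                    nrow(truth))
      lapply(sizes, function(k) sort(sample(truth$gene_id, k)))
    })
    names(bg) <- sprintf("TERM%05d", seq_along(bg) + 1L)
    terms <- c(terms, bg)
  }
  tab <- data.frame(
    term_id = rep(names(terms), lengths(terms)),
    gene_id = unlist(terms, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  list(collection = terms, table = tab, focal_term = "TERM00001")
}
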