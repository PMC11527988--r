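#' Tabulate P_u and D_u for all genes, regulators and comparisons
#'
#' Drives [classify_positions()] over every comparison between the focal
#' population and one sister population, under both heterozygote-assignment
#' modes, and accumulates in-site / out-of-site counts per gene and
#' regulator (mode-averaged, as in [count_pu_du()]). Only positions carrying
#' a VCF record in either population can be non-invariant, so classification
#' is restricted to those candidates; the result is identical to an
#' exhaustive scan of every window position.
#'
#' @param focal_modes list (`het_alt`, `het_ref`) of `pseudogenome_set`s for
#'   the focal population.
#' @param sister_modes_by_pop named list (one element per sister
#'   population), each a list (`het_alt`, `het_ref`) of `pseudogenome_set`s.
#' @param windows window table from [upstream_windows()].
#' @param sites binding-site data.frame (`chrom`, `start`, `end` 0-based
#'   half-open, `regulator`), e.g. from [read_sites_bed()].
#' @return data.frame with columns `gene_id`, `regulator`, `comparison`,
#'   `category` (`in_site` / `out_site`), `P_u`, `D_u`, `len`.
#' @export
site_counts_table <- function(focal_modes, sister_modes_by_pop, windows,
                              sites) {
  stopifnot(all(c("het_alt", "het_ref") %in% names(focal_modes)))
  regulators <- sort(unique(sites$regulator))
  # per-gene window positions and per (regulator, gene) site positions
  win_pos <- lapply(seq_len(nrow(windows)), function(i)
    (windows$start[i] + 1L):windows$end[i])
  names(win_pos) <- windows$gene_id
  site_pos <- lapply(regulators, function(r) {
    rs <- sites[sites$regulator == r, , drop = FALSE]
    lapply(seq_len(nrow(windows)), function(i)
      sites_in_window(rs, windows[i, ])$positions)
  })
  names(site_pos) <- regulators
  all_win <- sort(unlist(win_pos, use.names = FALSE))
  gene_index <- rep(seq_len(nrow(windows)), lengths(win_pos))
  gene_index <- gene_index[order(unlist(win_pos, use.names = FALSE))]

  out <- list()
  for (pop in names(sister_modes_by_pop)) {
    sis <- sister_modes_by_pop[[pop]]
    # accumulators: gene x regulator matrices for in/out P and D
    nG <- nrow(windows); nR <- length(regulators)
    accP_in <- accD_in <- accP_tot <- accD_tot <-
      matrix(0, nG, nR, dimnames = list(windows$gene_id, regulators))
    for (mode in c("het_alt", "het_ref")) {
      cand <- sort(unique(c(focal_modes[[mode]]$positions,
                            sis[[mode]]$positions)))
      cand <- cand[cand %in% all_win]
      if (length(cand)) {
        cls <- classify_positions(focal_modes[[mode]], sis[[mode]], cand)
        gidx <- gene_index[match(cand, all_win)]
        isP <- cls == "polymorphic" & !is.na(cls)
        isD <- cls == "fixed_divergent" & !is.na(cls)
        for (g in unique(gidx)) {
          gp <- cand[gidx == g & isP]
          gd <- cand[gidx == g & isD]
          accP_tot[g, ] <- accP_tot[g, ] + length(gp) / 2
          accD_tot[g, ] <- accD_tot[g, ] + length(gd) / 2
          for (j in seq_len(nR)) {
            sp <- site_pos[[j]][[g]]
            accP_in[g, j] <- accP_in[g, j] + sum(gp %in% sp) / 2
            accD_in[g, j] <- accD_in[g, j] + sum(gd %in% sp) / 2
          }
        }
      }
    }
    for (j in seq_len(nR)) {
      site_len <- vapply(site_pos[[j]], length, integer(1))
      win_len <- lengths(win_pos)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = rep(windows$gene_id, 2),
        regulator = regulators[j],
        comparison = pop,
        category = rep(c("in_site", "out_site"), each = nG),
        P_u = c(accP_in[, j], accP_tot[, j] - accP_in[, j]),
        D_u = c(accD_in[, j], accD_tot[, j] - accD_in[, j]),
        len = c(site_len, win_len - site_len),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-regulator interaction screen on normalised divergence
#'
#' For each regulator, treats every (gene, category, population comparison)
#' as one observation of a divergence metric and fits a two-factor ANOVA
#' with interaction: factor A is binding-site identity (in-site vs
#' out-of-site), factor B is gene membership in the translation (focal) set,
#' and the reported p-value is that of the interaction term. The odds ratio
#' is the classic interaction contrast of cell means,
#' `(mean[in,set] / mean[out,set]) / (mean[in,other] / mean[out,other])`;
#' values above 1 indicate enrichment of the metric at the regulator's sites
#' upstream of set genes. P-values are Benjamini-Hochberg corrected across
#' regulators.
#'
#' Metrics: `"dp"` is `D_u / P_u` with zero-polymorphism observations
#' dropped; `"d_len"` and `"p_len"` are `D_u` and `P_u` alone, normalised by
#' the category's length in bp.
#'
#' @param site_counts table from [site_counts_table()].
#' @param translation_set character vector of focal (e.g. translation) gene
#'   ids.
#' @param metric `"dp"`, `"d_len"` or `"p_len"`.
#' @param pseudocount added to both `D_u` and `P_u` of the `"dp"` metric;
#'   the default 0 drops zero-polymorphism observations instead.
#' @param log_response analyse the metric on the natural-log scale
#'   (non-positive values are dropped); default is the raw ratio scale.
#' @return data.frame with columns `regulator`, `OR`, `anova_p`, `padj`,
#'   `metric`, sorted by `padj`; skipped regulators (a cell with fewer than
#'   2 non-missing observations) are absent, with a message.
#' @export
regulator_screen <- function(site_counts, translation_set,
                             metric = c("dp", "d_len", "p_len"),
                             pseudocount = 0, log_response = FALSE) {
  metric <- match.arg(metric)
  if (length(translation_set) == 0) stop_input("empty translation set")
  sc <- site_counts
  sc$value <- switch(metric,
    dp = if (pseudocount > 0)
      (sc$D_u + pseudocount) / (sc$P_u + pseudocount)
    else normalized_divergence(sc$D_u, sc$P_u),
    d_len = ifelse(sc$len > 0, sc$D_u / sc$len, NA_real_),
    p_len = ifelse(sc$len > 0, sc$P_u / sc$len, NA_real_))
  sc$value_raw <- sc$value   # OR is always reported on the ratio scale
  if (log_response)
    sc$value <- ifelse(!is.na(sc$value) & sc$value > 0, log(sc$value),
                       NA_real_)
  sc$in_set <- sc$gene_id %in% translation_set
  rows <- list()
  for (r in unique(sc$regulator)) {
    d <- sc[sc$regulator == r & !is.na(sc$value), , drop = FALSE]
    cells <- table(d$category, d$in_set)
    if (!all(dim(cells) == c(2, 2)) || any(cells < 2)) {
      message("regulator ", r, " skipped: a cell has < 2 observations")
      next
    }
    cm <- tapply(d$value_raw, list(d$category, d$in_set), mean)
    or <- (cm["in_site", "TRUE"] / cm["out_site", "TRUE"]) /
      (cm["in_site", "FALSE"] / cm["out_site", "FALSE"])
    if (!is.finite(or)) or <- NA_real_
    fit <- lm(value ~ category * in_set, data = d)
    an <- suppressWarnings(anova(fit))
    ss_int <- an["category:in_set", "Sum Sq"]
    p_int <- an["category:in_set", "Pr(>F)"]
    ss_tot <- sum(an[, "Sum Sq"])
    # an interaction that is numerically zero relative to the data carries
    # no evidence, whatever the (degenerate) F ratio says
    if (!is.finite(ss_int) || !is.finite(p_int) || ss_tot <= 1e-24 ||
        ss_int < 1e-9 * ss_tot) p_int <- 1
    rows[[length(rows) + 1L]] <- data.frame(
      regulator = r, OR = unname(or), anova_p = p_int,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(regulator = character(), OR = numeric(),
                      anova_p = numeric(), padj = numeric(),
                      metric = character()))
  res <- do.call(rbind, rows)
  res$padj <- p.adjust(res$anova_p, method = "BH")
  res$metric <- metric
  res <- res[order(res$padj, res$anova_p, res$regulator), , drop = FALSE]
  rownames(res) <- NULL
  res
}
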