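# Independent oracles used across tests. These deliberately use the dumbest
# possible algorithm (enumeration, full scans) and share no code with the
# package implementations they check.

# Benjamini-Hochberg step-up, straight from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-sided exact binomial p by summing probabilities <= observed.
oracle_binom_two_sided <- function(x, n, p = 0.5) {
  probs <- dbinom(0:n, n, p)
  sum(probs[probs <= dbinom(x, n, p) * (1 + 1e-7)])
}

# Exact resampling p for |sum(s over subset)| >= |S_true| by enumerating
# every size-n subset of the universe.
oracle_resample_exact <- function(s_all, n, S_true) {
  subs <- utils::combn(length(s_all), n)
  sums <- apply(subs, 2, function(i) sum(s_all[i]))
  mean(abs(sums) >= abs(S_true) - 1e-12)
}

# Two-sided Fisher p from the hypergeometric distribution by enumerating all
# tables with the observed margins.
oracle_fisher_two_sided <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); N <- sum(m)
  ks <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- dhyper(ks, c1, N - c1, r1)
  obs <- dhyper(m[1, 1], c1, N - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Full per-position classification scan from materialised pseudogenome
# sequences: the exhaustive counterpart of the candidate-restricted
# implementation.
oracle_classify_scan <- function(focal_seqs, sister_seqs, positions) {
  fmat <- sapply(as.character(focal_seqs),
                 function(s) substring(s, positions, positions))
  smat <- sapply(as.character(sister_seqs),
                 function(s) substring(s, positions, positions))
  if (length(positions) == 1) {
    fmat <- matrix(fmat, nrow = 1)
    smat <- matrix(smat, nrow = 1)
  }
  apply(cbind(seq_along(positions)), 1, function(k) {
    fb <- fmat[k, ]; sb <- smat[k, ]
    fb <- fb[fb != "N"]; sb <- sb[sb != "N"]
    if (length(fb) < 2 || length(sb) < 2) return(NA_character_)
    uf <- unique(fb); us <- unique(sb)
    if (length(uf) >= 2 || length(us) >= 2) return("polymorphic")
    if (uf != us) return("fixed_divergent")
    "invariant"
  })
}

# Brute-force P_u / D_u for one window and site set, from sequences.
oracle_pu_du <- function(focal_modes_seqs, sister_modes_seqs,
                         window_positions, site_positions) {
  acc <- matrix(0, 2, 2, dimnames = list(c("in_site", "out_site"),
                                         c("P_u", "D_u")))
  for (mode in c("het_alt", "het_ref")) {
    cls <- oracle_classify_scan(focal_modes_seqs[[mode]],
                                sister_modes_seqs[[mode]],
                                window_positions)
    ins <- window_positions %in% site_positions
    for (cat in c(TRUE, FALSE)) {
      row <- if (cat) "in_site" else "out_site"
      acc[row, "P_u"] <- acc[row, "P_u"] +
        sum(cls[ins == cat] == "polymorphic", na.rm = TRUE) / 2
      acc[row, "D_u"] <- acc[row, "D_u"] +
        sum(cls[ins == cat] == "fixed_divergent", na.rm = TRUE) / 2
    }
  }
  acc
}

# Count, by naive substring scanning, at how many locations a read occurs
# across a list of sequences (allele, gene, sequence).
oracle_occurrence_count <- function(read, seqs) {
  sum(vapply(seqs, function(s) {
    hits <- gregexpr(read, s, fixed = TRUE)[[1]]
    if (hits[1] == -1) 0L else length(hits)
  }, integer(1)))
}
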