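#' Build haploid pseudogenomes from a population VCF
#'
#' For each individual, the genotype-implied base is substituted into the
#' reference at every bi-allelic SNV record: homozygous reference keeps the
#' reference base, homozygous alternate takes the ALT base, and heterozygous
#' sites are resolved to ALT (`mode = "het_alt"`) or to REF
#' (`mode = "het_ref"`). Missing genotypes (`./.`) leave the position
#' uncalled for that individual (excluded from downstream classification;
#' rendered `N` in exported sequences). Indel and multi-allelic records are
#' skipped with a warning, since the position-wise divergence/polymorphism
#' classification requires a fixed coordinate frame.
#'
#' @param vcf path to a VCF v4.2 file, or a `vcfR` object.
#' @param reference `DNAStringSet` (or FASTA path) with the reference
#'   chromosome(s).
#' @param mode heterozygote assignment: `"het_alt"` or `"het_ref"`.
#' @param population optional population label stored on the result.
#' @return an object of class `pseudogenome_set`: list with `chrom`,
#'   `individuals`, `mode`, `positions` (1-based record positions),
#'   `ref_base`, `alt_base`, and `bases` (records x individuals character
#'   matrix, `NA` = missing call).
#' @export
build_pseudogenomes <- function(vcf, reference,
                                mode = c("het_alt", "het_ref"),
                                population = NULL) {
  mode <- match.arg(mode)
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  v <- if (inherits(vcf, "vcfR")) vcf else vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    ind <- tryCatch(setdiff(colnames(v@gt), "FORMAT"),
                    error = function(e) character(0))
    return(structure(list(chrom = names(reference)[1], reference = reference,
                          individuals = ind, mode = mode,
                          population = population,
                          positions = integer(0),
                          ref_base = character(0), alt_base = character(0),
                          bases = matrix(character(0), nrow = 0,
                                         ncol = length(ind),
                                         dimnames = list(NULL, ind))),
                     class = "pseudogenome_set"))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  chrom <- unique(fix$CHROM)
  if (length(chrom) != 1)
    stop_input("expected a single-chromosome VCF, found: %s",
               paste(chrom, collapse = ", "))
  if (!chrom %in% names(reference))
    stop_input("chromosome '%s' absent from reference", chrom)
  pos <- as.integer(fix$POS)
  snv <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE)
  if (any(!snv)) {
    warning(sum(!snv), " non-SNV record(s) skipped")
    fix <- fix[snv, , drop = FALSE]
    gt <- gt[snv, , drop = FALSE]
    pos <- pos[snv]
  }
  ref_seq <- reference[[chrom]]
  ref_at <- strsplit(as.character(Biostrings::extractAt(
    ref_seq, IRanges::IRanges(pos, pos))), "")
  ref_at <- vapply(ref_at, `[`, character(1), 1L)
  bad <- ref_at != fix$REF
  if (any(bad))
    stop_input("VCF REF does not match reference at %s:%d (VCF %s, FASTA %s)",
               chrom, pos[which(bad)[1]], fix$REF[which(bad)[1]],
               ref_at[which(bad)[1]])
  # alt-allele dosage per record x individual; NA for missing calls
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  g <- gsub("|", "/", gt, fixed = TRUE)
  dose[g %in% c("0/0", "0")] <- 0L
  dose[g %in% c("0/1", "1/0")] <- 1L
  dose[g %in% c("1/1", "1")] <- 2L
  cut <- if (mode == "het_alt") 1L else 2L
  bases <- matrix(rep(fix$REF, ncol(dose)), nrow = nrow(dose))
  take_alt <- !is.na(dose) & dose >= cut
  bases[take_alt] <- matrix(rep(fix$ALT, ncol(dose)),
                            nrow = nrow(dose))[take_alt]
  bases[is.na(dose)] <- NA_character_
  dimnames(bases) <- dimnames(gt)
  structure(list(chrom = chrom, reference = reference,
                 individuals = colnames(gt), mode = mode,
                 population = population, positions = pos,
                 ref_base = fix$REF, alt_base = fix$ALT, bases = bases),
            class = "pseudogenome_set")
}

#' Materialise pseudogenome sequences
#'
#' Substitutes each individual's called bases into the reference chromosome
#' and returns one haploid sequence per individual. Positions with missing
#' genotypes become `N`. With a homozygous-reference-only VCF the output is
#' identical to the reference.
#'
#' @param ps a `pseudogenome_set` from [build_pseudogenomes()].
#' @return named `DNAStringSet`, one sequence per individual.
#' @export
pseudogenome_sequences <- function(ps) {
  stopifnot(inherits(ps, "pseudogenome_set"))
  ref <- ps$reference[[ps$chrom]]
  seqs <- lapply(seq_along(ps$individuals), function(i) {
    b <- ps$bases[, i]
    b[is.na(b)] <- "N"
    change <- b != ps$ref_base
    s <- ref
    if (any(change))
      s <- Biostrings::replaceLetterAt(
        s, ps$positions[change], paste(b[change], collapse = ""))
    s
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ps$individuals
  out
}

# records x individuals base matrix restricted to `positions`; positions
# without a VCF record carry the reference base for every individual.
bases_at <- function(ps, positions) {
  ref <- ps$reference[[ps$chrom]]
  refb <- strsplit(as.character(Biostrings::extractAt(
    ref, IRanges::IRanges(positions, positions))), "")
  refb <- vapply(refb, `[`, character(1), 1L)
  m <- matrix(rep(refb, length(ps$individuals)), nrow = length(positions))
  hit <- match(ps$positions, positions)
  keep <- !is.na(hit)
  if (any(keep)) m[hit[keep], ] <- ps$bases[keep, , drop = FALSE]
  colnames(m) <- ps$individuals
  m
}

count_base_profile <- function(m) {
  tab <- sapply(c("A", "C", "G", "T"), function(b)
    rowSums(m == b, na.rm = TRUE))
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1,
                                       dimnames = list(NULL, c("A", "C", "G", "T")))
  tab
}

#' Classify positions as invariant, polymorphic or fixed-divergent
#'
#' A position is `fixed_divergent` when all called focal haplotypes share
#' one base, all called sister haplotypes share one base, and the two
#' differ; `polymorphic` when two or more bases segregate within the focal
#' and/or the sister population; `invariant` otherwise. Positions with
#' fewer than two called haplotypes in either population are unclassifiable
#' and returned as `NA`. The classes are mutually exclusive and (over
#' classifiable positions) exhaustive, and swapping which population is
#' called focal leaves `fixed_divergent` unchanged.
#'
#' @param focal_haps `pseudogenome_set` for the focal population.
#' @param sister_haps `pseudogenome_set` for one sister population (same
#'   mode).
#' @param positions 1-based genomic positions to classify.
#' @return factor with levels `invariant`, `polymorphic`, `fixed_divergent`
#'   (`NA` = unclassifiable).
#' @export
classify_positions <- function(focal_haps, sister_haps, positions) {
  stopifnot(inherits(focal_haps, "pseudogenome_set"),
            inherits(sister_haps, "pseudogenome_set"))
  if (length(positions) == 0)
    return(factor(character(0),
                  levels = c("invariant", "polymorphic", "fixed_divergent")))
  mf <- bases_at(focal_haps, positions)
  ms <- bases_at(sister_haps, positions)
  pf <- count_base_profile(mf)
  psx <- count_base_profile(ms)
  nf <- rowSums(pf)
  ns <- rowSums(psx)
  df <- rowSums(pf > 0)
  ds <- rowSums(psx > 0)
  mono_base <- function(prof, nd) {
    b <- colnames(prof)[max.col(prof, ties.method = "first")]
    ifelse(nd == 1, b, NA_character_)
  }
  bf <- mono_base(pf, df)
  bs <- mono_base(psx, ds)
  cls <- rep(NA_character_, length(positions))
  callable <- nf >= 2 & ns >= 2
  poly <- callable & (df >= 2 | ds >= 2)
  fixd <- callable & !poly & !is.na(bf) & !is.na(bs) & bf != bs
  inv <- callable & !poly & !fixd
  cls[poly] <- "polymorphic"
  cls[fixd] <- "fixed_divergent"
  cls[inv] <- "invariant"
  factor(cls, levels = c("invariant", "polymorphic", "fixed_divergent"))
}

#' Polymorphic and fixed-divergent counts inside and outside binding sites
#'
#' For one gene window and one regulator's in-window site positions,
#' classifies every window position under both heterozygote-assignment
#' modes, counts polymorphic (`P_u`) and fixed-divergent (`D_u`) positions
#' in the in-site set and its within-window complement, and averages the
#' two modes (values may therefore be half-integers).
#'
#' @param focal_modes list with elements `het_alt` and `het_ref`, each a
#'   `pseudogenome_set` for the focal population.
#' @param sister_modes same structure for one sister population.
#' @param window_positions 1-based positions of the full upstream window.
#' @param site_positions subset of `window_positions` covered by the
#'   regulator's binding sites.
#' @return data.frame with rows `in_site` and `out_site` and columns
#'   `category`, `P_u`, `D_u`, `len`.
#' @export
count_pu_du <- function(focal_modes, sister_modes, window_positions,
                        site_positions) {
  stopifnot(all(c("het_alt", "het_ref") %in% names(focal_modes)),
            all(c("het_alt", "het_ref") %in% names(sister_modes)))
  window_positions <- sort(unique(window_positions))
  in_site <- window_positions %in% site_positions
  acc <- matrix(0, nrow = 2, ncol = 2,
                dimnames = list(c("in_site", "out_site"), c("P_u", "D_u")))
  for (mode in c("het_alt", "het_ref")) {
    cls <- classify_positions(focal_modes[[mode]], sister_modes[[mode]],
                              window_positions)
    for (cat in c(TRUE, FALSE)) {
      row <- if (cat) "in_site" else "out_site"
      sel <- in_site == cat
      acc[row, "P_u"] <- acc[row, "P_u"] +
        sum(cls[sel] == "polymorphic", na.rm = TRUE) / 2
      acc[row, "D_u"] <- acc[row, "D_u"] +
        sum(cls[sel] == "fixed_divergent", na.rm = TRUE) / 2
    }
  }
  data.frame(
    category = rownames(acc),
    P_u = acc[, "P_u"], D_u = acc[, "D_u"],
    len = c(sum(in_site), sum(!in_site)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Divergence normalised by polymorphism
#'
#' @param D_u fixed-divergent position count.
#' @param P_u polymorphic position count.
#' @return `D_u / P_u`, or `NA` when `P_u` is 0 (the observation is dropped
#'   from the interaction ANOVA rather than pseudocounted).
#' @export
normalized_divergence <- function(D_u, P_u) {
  ifelse(P_u > 0, D_u / P_u, NA_real_)
}
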