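#' Build (or read) a pipeline run configuration
#'
#' All thresholds default to the screen's canonical settings: significance
#' alpha 0.05 on BH-adjusted p, at least 10 significant genes per term,
#' 10,000 resamples, a 5% mapping-fidelity threshold and 50 kb upstream
#' windows.
#'
#' @param path optional YAML file; entries override the defaults below.
#' @param input_dir directory holding the inputs (`genome.fa`,
#'   `transcripts.gff3`, `sites.bed`, `ase_counts.tsv`, `gene_sets.tsv`,
#'   `vcf/<population>.vcf`).
#' @param output_dir directory for stage outputs.
#' @param simulate when `TRUE`, [run_all()] first writes a synthetic fixture
#'   into `input_dir` using `sim` (a list of [sim_config()] overrides).
#' @param sim named list of [sim_config()] overrides used by the simulate
#'   stage.
#' @param focal_population population label treated as focal in the
#'   population-genomic screen (default `"castaneus_IND"`).
#' @param translation_term term id whose genes define the focal set for the
#'   regulator screen (default: first term in the gene-set table).
#' @param alpha significance threshold on BH-adjusted p-values.
#' @param min_sig minimum significant genes per tested term.
#' @param resamples resampling-null draws per term.
#' @param seed master seed; every stage derives its randomness from it.
#' @param mapping_threshold mapping-fidelity difference (percent) above
#'   which a gene is removed.
#' @param upstream_width upstream window width in bp.
#' @param screen_metric `"dp"`, `"d_len"` or `"p_len"`.
#' @param smooth use the add-one smoothed empirical p (see
#'   [resample_null()]).
#' @param pseudocount,log_response passed to [regulator_screen()].
#' @param run_mapping_qc run [simulate_and_map()] when allele transcript
#'   FASTAs (`allele1_tx.fa`, `allele2_tx.fa`) are present.
#' @return list of class `run_config`.
#' @export
run_config <- function(path = NULL, input_dir = ".", output_dir = "results",
                       simulate = FALSE, sim = list(),
                       focal_population = "castaneus_IND",
                       translation_term = NULL,
                       alpha = 0.05, min_sig = 10, resamples = 10000L,
                       seed = 1L, mapping_threshold = 5,
                       upstream_width = 50000L,
                       screen_metric = "dp", smooth = FALSE,
                       pseudocount = 0, log_response = FALSE,
                       run_mapping_qc = FALSE) {
  cfg <- list(input_dir = input_dir, output_dir = output_dir,
              simulate = simulate, sim = sim,
              focal_population = focal_population,
              translation_term = translation_term,
              alpha = alpha, min_sig = min_sig, resamples = resamples,
              seed = seed, mapping_threshold = mapping_threshold,
              upstream_width = upstream_width,
              screen_metric = screen_metric, smooth = smooth,
              pseudocount = pseudocount, log_response = log_response,
              run_mapping_qc = run_mapping_qc)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop_input("unknown config entries: %s", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  # fingerprint the analysis settings only, not where files happen to live
  cfg <- cfg[setdiff(names(cfg), c("input_dir", "output_dir"))]
  s <- paste(vapply(cfg[order(names(cfg))],
                    function(x) paste(format(x), collapse = ","),
                    character(1)),
             collapse = ";")
  # small stable polynomial hash; enough to fingerprint a config in headers
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

cfg_header <- function(cfg) output_header(cfg$seed, config_hash(cfg))

stage_path <- function(cfg, name) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  file.path(cfg$output_dir, name)
}

inp_path <- function(cfg, f, stage) {
  p <- file.path(cfg$input_dir, f)
  if (!file.exists(p)) stop_input("[%s] missing input: %s", stage, p)
  p
}

load_genome <- function(cfg, stage) {
  genome <- Biostrings::readDNAStringSet(inp_path(cfg, "genome.fa", stage))
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Pipeline stage: write a synthetic fixture
#'
#' @param cfg a [run_config()] with `simulate = TRUE` semantics; `cfg$sim`
#'   overrides [sim_config()] defaults and `cfg$seed` seeds the generators.
#' @return invisible fixture bundle from [simulate_fixture()].
#' @export
stage_simulate <- function(cfg) {
  message("[simulate] writing synthetic fixture to ", cfg$input_dir)
  sim_cfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  simulate_fixture(sim_cfg, cfg$input_dir)
}

#' Pipeline stage: transcript selection and upstream windows
#'
#' Reads `genome.fa` and `transcripts.gff3`, selects one representative
#' transcript per gene and derives strand-aware upstream windows; writes
#' `representative_transcripts.tsv` and `upstream_windows.bedlike.tsv`.
#'
#' @param cfg a [run_config()].
#' @return invisible list with `rep_tx` and `windows`.
#' @export
stage_annotate <- function(cfg) {
  message("[annotate] selecting representative transcripts")
  genome <- load_genome(cfg, "annotate")
  models <- read_gene_models(inp_path(cfg, "transcripts.gff3", "annotate"))
  rep_tx <- representative_transcripts(models, genome)
  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  windows <- upstream_windows(rep_tx, chrom_len, cfg$upstream_width)
  hdr <- cfg_header(cfg)
  write_tsv(rep_tx, stage_path(cfg, "representative_transcripts.tsv"), hdr)
  write_tsv(windows, stage_path(cfg, "upstream_windows.bedlike.tsv"), hdr)
  invisible(list(rep_tx = rep_tx, windows = windows))
}

#' Pipeline stage: allelic-imbalance testing (with optional mapping QC)
#'
#' Reads `ase_counts.tsv`, optionally removes mapping-biased genes using
#' simulated reads over `allele1_tx.fa` / `allele2_tx.fa`, and writes
#' `ase_results.tsv` (plus `mapping_fidelity.tsv` when QC ran).
#'
#' @param cfg a [run_config()].
#' @return invisible list with `ase` and (optionally) `mapping_fidelity`.
#' @export
stage_ase <- function(cfg) {
  message("[ase] testing allelic imbalance")
  counts <- read_tsv(inp_path(cfg, "ase_counts.tsv", "ase"))
  hdr <- cfg_header(cfg)
  out <- list()
  retained <- NULL
  if (isTRUE(cfg$run_mapping_qc)) {
    fid <- simulate_and_map(inp_path(cfg, "allele1_tx.fa", "ase"),
                            inp_path(cfg, "allele2_tx.fa", "ase"),
                            seed = cfg$seed)
    filt <- mapping_bias_filter(fid, cfg$mapping_threshold)
    retained <- filt$retained
    out$mapping_fidelity <- fid
    write_tsv(fid, stage_path(cfg, "mapping_fidelity.tsv"), hdr)
  }
  out$ase <- ase_results(counts, alpha = cfg$alpha,
                         retained_genes = retained)
  write_tsv(out$ase, stage_path(cfg, "ase_results.tsv"), hdr)
  invisible(out)
}

#' Pipeline stage: resampling gene-set screen
#'
#' Reads `gene_sets.tsv` and the `ase_results.tsv` written by [stage_ase()],
#' and writes `pathway_results.tsv` and `directional_reports.tsv`.
#'
#' @param cfg a [run_config()].
#' @return invisible list with `pathway` and `directional`.
#' @export
stage_pathway <- function(cfg) {
  message("[pathway-test] resampling gene-set screen")
  sets <- read_tsv(inp_path(cfg, "gene_sets.tsv", "pathway-test"))
  ase_path <- file.path(cfg$output_dir, "ase_results.tsv")
  if (!file.exists(ase_path))
    stop_input("[pathway-test] missing input: %s (run the ase stage first)",
               ase_path)
  ase <- read_tsv(ase_path)
  pathway <- screen_terms(ase, sets, min_sig = cfg$min_sig,
                          B = cfg$resamples, alpha = cfg$alpha,
                          seed = cfg$seed, smooth = cfg$smooth)
  collection <- as_collection(sets)
  directional <- do.call(rbind, lapply(pathway$term_id, function(tid) {
    r <- directional_report(ase$l2r, ase$padj, ase$gene_id,
                            collection[[tid]], alpha = cfg$alpha)
    data.frame(term_id = tid, n = r$n, n_sig = r$n_sig,
               pct_up_sig = r$pct_up_sig, pct_down_sig = r$pct_down_sig,
               pct_up_all = r$pct_up_all, pct_down_all = r$pct_down_all,
               ratio = r$ratio, stringsAsFactors = FALSE)
  }))
  if (is.null(directional))
    directional <- data.frame(term_id = character(0))
  hdr <- cfg_header(cfg)
  write_tsv(pathway, stage_path(cfg, "pathway_results.tsv"), hdr)
  write_tsv(directional, stage_path(cfg, "directional_reports.tsv"), hdr)
  invisible(list(pathway = pathway, directional = directional))
}

#' Pipeline stage: population-genomic regulator screen
#'
#' Builds pseudogenomes from every population VCF under both heterozygote
#' modes, counts polymorphic and fixed-divergent positions inside and
#' outside each regulator's binding sites across all upstream windows, and
#' runs the per-regulator interaction screen. Writes `site_counts.tsv` and
#' `screen_results.tsv`.
#'
#' @param cfg a [run_config()].
#' @return invisible list with `site_counts` and `screen`.
#' @export
stage_popgen <- function(cfg) {
  message("[popgen-screen] building pseudogenomes and counting variants")
  genome <- load_genome(cfg, "popgen-screen")
  win_path <- file.path(cfg$output_dir, "upstream_windows.bedlike.tsv")
  if (!file.exists(win_path))
    stop_input("[popgen-screen] missing input: %s (run the annotate stage first)",
               win_path)
  windows <- read_tsv(win_path)
  vcf_dir <- file.path(cfg$input_dir, "vcf")
  vcfs <- if (dir.exists(vcf_dir))
    list.files(vcf_dir, pattern = "\\.vcf$", full.names = TRUE)
  else character(0)
  if (length(vcfs) == 0)
    stop_input("[popgen-screen] missing input: no VCFs under %s", vcf_dir)
  pops <- sub("\\.vcf$", "", basename(vcfs))
  if (!cfg$focal_population %in% pops)
    stop_input("[popgen-screen] focal population '%s' has no VCF",
               cfg$focal_population)
  modes_for <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)  # parse once, build both modes
    list(het_alt = build_pseudogenomes(v, genome, "het_alt"),
         het_ref = build_pseudogenomes(v, genome, "het_ref"))
  }
  focal_modes <- modes_for(vcfs[match(cfg$focal_population, pops)])
  sisters <- setdiff(pops, cfg$focal_population)
  sister_modes <- lapply(vcfs[match(sisters, pops)], modes_for)
  names(sister_modes) <- sisters
  sites <- read_sites_bed(inp_path(cfg, "sites.bed", "popgen-screen"))
  sc <- site_counts_table(focal_modes, sister_modes, windows, sites)
  sets <- read_tsv(inp_path(cfg, "gene_sets.tsv", "popgen-screen"))
  term <- cfg$translation_term %||% sets$term_id[1]
  focal_set <- unique(sets$gene_id[sets$term_id == term])
  screen <- regulator_screen(sc, focal_set, metric = cfg$screen_metric,
                             pseudocount = cfg$pseudocount,
                             log_response = cfg$log_response)
  hdr <- cfg_header(cfg)
  write_tsv(sc, stage_path(cfg, "site_counts.tsv"), hdr)
  write_tsv(screen, stage_path(cfg, "screen_results.tsv"), hdr)
  invisible(list(site_counts = sc, screen = screen))
}

#' Run the full pipeline
#'
#' Executes, in order: simulate (optional) -> annotate -> ase ->
#' pathway-test -> popgen-screen. Each stage reads its inputs from disk and
#' writes one or more TSVs into the output directory, so running the stages
#' individually produces byte-identical outputs. Every output carries a
#' comment header with the package version, seed and a hash of the
#' configuration. A failing stage aborts with the stage named; later
#' outputs are not written.
#'
#' @param cfg a [run_config()].
#' @return invisible list with the per-stage result tables.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  res <- list()
  if (isTRUE(cfg$simulate)) res$fixture <- stage_simulate(cfg)
  res <- c(res, stage_annotate(cfg))
  res <- c(res, stage_ase(cfg))
  res <- c(res, stage_pathway(cfg))
  res <- c(res, stage_popgen(cfg))
  message("done: ", cfg$output_dir)
  invisible(res)
}
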