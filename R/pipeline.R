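#' Write a result table with provenance header
#'
#' Tab-separated with column header, preceded by `#`-prefixed comment lines
#' recording the package version, the seed and any extra notes, so every
#' table is self-describing and byte-identical across re-runs with the
#' same seed.
#'
#' @param x data.frame.
#' @param path output path.
#' @param seed seed recorded in the header (may be NA).
#' @param notes optional named character vector of extra header fields.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path, seed = NA, notes = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tropigwas %s",
                     as.character(utils::packageVersion("tropigwas"))), con)
  writeLines(sprintf("# seed: %s", seed), con)
  if (!is.null(notes))
    writeLines(sprintf("# %s: %s", names(notes), notes), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#' @param path table path.
#' @return data.frame (header comments skipped).
#' @export
read_result_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Configuration of an end-to-end run
#'
#' Thresholds default to the analysis constants used throughout the
#' package: table-level significance 0.001, heat-map level 0.0001,
#' genome-wide 5e-8, pleiotropy alpha 0.001, ancestry split 0.30,
#' divergent-SNP bounds 0.95/0.05, candidate window 3000 bp.
#'
#' @param n_individuals,n_snps,n_traits simulated cohort dimensions.
#' @param n_sires number of half-sib families.
#' @param divergence ancestral divergence of the two panels.
#' @param n_divergent constructed highly divergent SNPs.
#' @param qtl_spec passed to [simulation_config()].
#' @param thresholds named list overriding any of `p_table`, `p_heatmap`,
#'   `p_gw`, `pleiotropy_alpha`, `ancestry_split`, `divergent_hi`,
#'   `divergent_lo`, `candidate_window`.
#' @param seed seed governing every stage.
#' @param out_dir run directory for stage outputs.
#' @return List of class `run_config`.
#' @export
run_config <- function(n_individuals = 1000, n_snps = 5000, n_traits = 3,
                       n_sires = 25, divergence = 0.2, n_divergent = 100,
                       qtl_spec = NULL, thresholds = list(), seed = 1,
                       out_dir = tempfile("tropigwas_run_")) {
  defaults <- list(p_table = 1e-3, p_heatmap = 1e-4, p_gw = 5e-8,
                   pleiotropy_alpha = 1e-3, ancestry_split = 0.30,
                   divergent_hi = 0.95, divergent_lo = 0.05,
                   candidate_window = 3000)
  thresholds <- utils::modifyList(defaults, thresholds)
  stopifnot(thresholds$p_table > 0, thresholds$p_table < 1,
            thresholds$ancestry_split > 0, thresholds$ancestry_split < 1,
            thresholds$divergent_hi > thresholds$divergent_lo)
  structure(list(n_individuals = n_individuals, n_snps = n_snps,
                 n_traits = n_traits, n_sires = n_sires,
                 divergence = divergence, n_divergent = n_divergent,
                 qtl_spec = qtl_spec, thresholds = thresholds,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Run the full simulation-to-pleiotropy pipeline
#'
#' Simulates panels and an admixed half-sib cohort, LD-prunes, estimates
#' supervised ancestry, fits the animal model per trait, runs the
#' mixed-model GWAS, summarizes significance counts and FDR per trait,
#' and runs the pleiotropy scan; every stage writes a tab-separated table
#' under `config$out_dir`. A stage whose output file already exists is
#' skipped unless `force`, so deleting one output regenerates only the
#' downstream stages on a re-run.
#'
#' @param config a [run_config()].
#' @param force rerun stages whose outputs already exist (default FALSE).
#' @return List with the in-memory stage results: `cohort`, `pruned_idx`,
#'   `ancestry`, `reml` (per trait), `gwas` (per trait), `summary`
#'   (per-trait S and FDR), `heatmap` (chromosome x trait counts),
#'   `pleiotropy`, `out_dir`.
#' @export
run_pipeline <- function(config, force = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  thr <- config$thresholds
  path <- function(f) file.path(config$out_dir, f)
  seed <- config$seed

  traits <- paste0("T", seq_len(config$n_traits))
  h2 <- stats::setNames(
    seq(0.2, 0.5, length.out = config$n_traits), traits)
  sim_cfg <- simulation_config(
    n_individuals = config$n_individuals, n_sires = config$n_sires,
    h2_targets = h2, qtl_spec = config$qtl_spec, seed = seed)

  panels <- simulate_ancestral_panels(config$n_snps, config$divergence,
                                      n_divergent = config$n_divergent,
                                      seed = seed)
  cohort <- simulate_admixed_cohort(panels, sim_cfg)
  traits_sim <- simulate_traits(cohort, sim_cfg)
  ph <- traits_sim$phenotypes

  stage <- function(file, fn) {
    if (!force && file.exists(path(file))) return(invisible(NULL))
    fn()
  }
  stage("phenotypes.tsv", function()
    write_result_table(ph, path("phenotypes.tsv"), seed))
  stage("pedigree.tsv", function()
    write_result_table(cohort$pedigree, path("pedigree.tsv"), seed))

  pruned_idx <- ld_prune(cohort$genotypes)
  est <- estimate_ancestry_supervised(cohort$genotypes[, pruned_idx],
                                      panels$freq_A[pruned_idx],
                                      panels$freq_B[pruned_idx])
  stage("ancestry.tsv", function()
    write_result_table(est, path("ancestry.tsv"), seed,
                       c(n_pruned_snps = length(pruned_idx))))

  ph$lambda_hat <- est$lambda_hat
  K <- genomic_relationship(cohort$genotypes)

  models <- lapply(traits, function(tr) model_spec(tr,
                                                   ancestry = "lambda_hat"))
  mt <- gwas_scan_multitrait(cohort$genotypes, ph, K, models)
  scans <- mt$scans
  reml <- mt$null_fits
  stage("reml.tsv", function()
    write_result_table(
      data.frame(trait = traits,
                 sigma2_g = vapply(reml, `[[`, 0, "sigma2_g"),
                 sigma2_e = vapply(reml, `[[`, 0, "sigma2_e"),
                 h2 = vapply(reml, `[[`, 0, "h2"),
                 converged = vapply(reml, `[[`, TRUE, "converged")),
      path("reml.tsv"), seed))
  stage("gwas.tsv", function()
    write_result_table(do.call(rbind, lapply(scans, as.data.frame)),
                       path("gwas.tsv"), seed))

  counts <- count_significant(scans, thr$p_table)
  fdr <- fdr_at_threshold(thr$p_table,
                          counts$per_trait[traits], config$n_snps)
  summary_tbl <- data.frame(trait = traits, S = counts$per_trait[traits],
                            fdr = fdr$fdr, row.names = NULL)
  stage("summary.tsv", function()
    write_result_table(summary_tbl, path("summary.tsv"), seed,
                       c(p_threshold = thr$p_table)))
  heat <- count_significant(scans, thr$p_heatmap)$per_chrom
  stage("heatmap_counts.tsv", function()
    write_result_table(as.data.frame.matrix(heat),
                       path("heatmap_counts.tsv"), seed,
                       c(p_threshold = thr$p_heatmap)))

  pl <- pleiotropy_scan(mt$t_matrix, alpha = thr$pleiotropy_alpha)
  stage("pleiotropy.tsv", function()
    write_result_table(cbind(snp = cohort$genotypes$snps$id, pl$table),
                       path("pleiotropy.tsv"), seed,
                       c(critical = sprintf("%.3f", pl$critical))))

  list(cohort = cohort, pruned_idx = pruned_idx, ancestry = est,
       reml = reml, gwas = scans, summary = summary_tbl, heatmap = heat,
       pleiotropy = pl, out_dir = config$out_dir)
}
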