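#' Simulation configuration for the synthetic study
#'
#' Builds the single configuration object consumed by all `simulate_*` and
#' `generate_genome()` functions. Defaults describe the study conditions the
#' workflow is validated under: a small two-chromosome genome, CCGG sites
#' enriched inside CpG islands, a bimodal methylome (hypomethylated islands,
#' hypermethylated open sea, intermediate shores), sequencing depth around 60
#' reads per site, and a conditioned-place-preference design with 6 morphine
#' and 3 saline animals over 900-second (15 min) test sessions.
#'
#' @param seed integer seed; a fixed seed makes every simulated artifact
#'   byte-identical across runs.
#' @param n_chroms,chrom_length number and length (bp) of synthetic chromosomes.
#' @param n_genes number of gene models to place.
#' @param gene_length length-2 range (bp) genes are drawn from.
#' @param n_cgis number of CpG islands.
#' @param cgi_length length-2 range (bp) of island widths.
#' @param promoter_cgi_frac fraction of genes whose promoter overlaps a CGI.
#' @param ccgg_per_kb background density of planted CCGG sites (sites/kb).
#' @param cgi_ccgg_per_kb additional CCGG density inside islands (sites/kb).
#' @param beta_island,beta_shore,beta_sea length-2 Beta shape parameters for
#'   true site methylation by CGI context.
#' @param depth_mean,depth_size negative-binomial mean and size for per-site
#'   sequencing depth.
#' @param efficiency named numeric `c(hpa=, inv=)`: global library efficiency
#'   factors applied to the HpaII and inverse libraries (what spike-in
#'   normalization must correct).
#' @param n_spikeins,spikein_mean number of spike-in standards and mean count
#'   per standard per library (before efficiency scaling).
#' @param planted_dmrs `NULL` or data.frame (`chrom`, `start`, `end`, `dm`):
#'   unit-level regions whose group-B methylation is shifted by `dm`.
#' @param expr_slope,expr_noise_sd coupling of log2 expression change to mean
#'   promoter methylation change, and the Gaussian noise around it.
#' @param fpkm_meanlog,fpkm_sdlog log-normal parameters for baseline FPKM.
#' @param upstream_bp promoter width (bp upstream of the TSS) used for the
#'   expression coupling and the default integration window.
#' @param psi_truth `NULL` or data.frame (`event_id`, `group`, `psi`) of true
#'   percent-spliced-in values.
#' @param junction_reads junction reads per event per group.
#' @param n_morphine,n_saline animals per group in the CPP design.
#' @param session_s session length in seconds (both test phases).
#' @param drug_pref_pre mean pre-conditioning drug-side time share.
#' @param passage_frac mean share of session time spent in the passage.
#' @param cpp_effect additive increase of the morphine group's mean post-phase
#'   drug-side share (0.57 reproduces a 0.28 -> 0.85 shift).
#' @param cpp_concentration Dirichlet concentration controlling between-animal
#'   variability of the time allocation (smaller = noisier).
#'
#' @return a list of class `mscc_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 200000L,
                       n_genes = 40L,
                       gene_length = c(2000L, 6000L),
                       n_cgis = 30L,
                       cgi_length = c(500L, 1500L),
                       promoter_cgi_frac = 0.6,
                       ccgg_per_kb = 2,
                       cgi_ccgg_per_kb = 10,
                       beta_island = c(0.5, 10),
                       beta_shore = c(2, 2),
                       beta_sea = c(10, 0.5),
                       depth_mean = 60,
                       depth_size = 20,
                       efficiency = c(hpa = 1, inv = 1),
                       n_spikeins = 20L,
                       spikein_mean = 500,
                       planted_dmrs = NULL,
                       expr_slope = -2,
                       expr_noise_sd = 0.5,
                       fpkm_meanlog = 3,
                       fpkm_sdlog = 1,
                       upstream_bp = 2000L,
                       psi_truth = NULL,
                       junction_reads = 500L,
                       n_morphine = 6L,
                       n_saline = 3L,
                       session_s = 900,
                       drug_pref_pre = 0.28,
                       passage_frac = 0.2,
                       cpp_effect = 0.57,
                       cpp_concentration = 7) {
  cfg <- list(
    seed = as.integer(seed),
    n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length),
    n_cgis = as.integer(n_cgis),
    cgi_length = as.integer(cgi_length),
    promoter_cgi_frac = promoter_cgi_frac,
    ccgg_per_kb = ccgg_per_kb,
    cgi_ccgg_per_kb = cgi_ccgg_per_kb,
    beta_island = beta_island,
    beta_shore = beta_shore,
    beta_sea = beta_sea,
    depth_mean = depth_mean,
    depth_size = depth_size,
    efficiency = efficiency,
    n_spikeins = as.integer(n_spikeins),
    spikein_mean = spikein_mean,
    planted_dmrs = planted_dmrs,
    expr_slope = expr_slope,
    expr_noise_sd = expr_noise_sd,
    fpkm_meanlog = fpkm_meanlog,
    fpkm_sdlog = fpkm_sdlog,
    upstream_bp = as.integer(upstream_bp),
    psi_truth = psi_truth,
    junction_reads = as.integer(junction_reads),
    n_morphine = as.integer(n_morphine),
    n_saline = as.integer(n_saline),
    session_s = session_s,
    drug_pref_pre = drug_pref_pre,
    passage_frac = passage_frac,
    cpp_effect = cpp_effect,
    cpp_concentration = cpp_concentration
  )
  class(cfg) <- "mscc_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a list as produced by [sim_config()].
#' @return the config, invisibly; stops on the first invalid field.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  chk_prob <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      stop(sprintf("config field '%s' must lie in [0,1]", nm), call. = FALSE)
  }
  if (cfg$n_chroms < 1L || cfg$chrom_length < 1L)
    stop("need at least one chromosome of positive length", call. = FALSE)
  if (cfg$ccgg_per_kb < 0 || cfg$cgi_ccgg_per_kb < 0)
    stop("CCGG densities must be non-negative", call. = FALSE)
  for (nm in c("beta_island", "beta_shore", "beta_sea")) {
    b <- cfg[[nm]]
    if (length(b) != 2L || any(b <= 0))
      stop(sprintf("'%s' must be two positive Beta shapes", nm), call. = FALSE)
  }
  if (cfg$depth_mean < 0 || cfg$depth_size <= 0)
    stop("depth_mean must be >= 0 and depth_size > 0", call. = FALSE)
  if (length(cfg$efficiency) != 2L || any(cfg$efficiency <= 0))
    stop("efficiency must be two positive factors (hpa, inv)", call. = FALSE)
  chk_prob(cfg$promoter_cgi_frac, "promoter_cgi_frac")
  chk_prob(cfg$drug_pref_pre, "drug_pref_pre")
  chk_prob(cfg$passage_frac, "passage_frac")
  if (cfg$drug_pref_pre + cfg$passage_frac >= 1)
    stop("drug_pref_pre + passage_frac must be < 1", call. = FALSE)
  if (cfg$cpp_concentration <= 0)
    stop("cpp_concentration must be positive", call. = FALSE)
  if (!is.null(cfg$psi_truth)) {
    chk_prob(cfg$psi_truth$psi, "psi_truth$psi")
  }
  if (!is.null(cfg$planted_dmrs)) {
    pd <- cfg$planted_dmrs
    if (!all(c("chrom", "start", "end", "dm") %in% names(pd)))
      stop("planted_dmrs needs columns chrom, start, end, dm", call. = FALSE)
    if (any(abs(pd$dm) > 1)) stop("planted dm must lie in [-1,1]", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Unknown keys are rejected so that typos do not silently fall back to
#' defaults.
#'
#' @param path path to a YAML file whose keys are [sim_config()] arguments.
#' @return a validated `mscc_config` list.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(raw$planted_dmrs)) raw$planted_dmrs <- as.data.frame(raw$planted_dmrs)
  if (!is.null(raw$psi_truth)) raw$psi_truth <- as.data.frame(raw$psi_truth)
  if (!is.null(raw$efficiency)) raw$efficiency <- unlist(raw$efficiency)
  do.call(sim_config, raw)
}
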