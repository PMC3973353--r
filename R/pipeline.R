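# Pipeline orchestration: YAML config with validation, subcommand
# functions composing the module operations, and a run manifest for
# reproducibility. Every subcommand derives all randomness from the
# configured seed and never mutates its inputs.

pipeline_defaults <- function() {
  list(
    files = list(metabolites = NULL, covariates = NULL, genotypes = NULL,
                 genotype_format = "vcf", annotation = NULL,
                 delimiter = "\t", out_dir = "."),
    groups = list(obese_min = 30, nonobese_low = 18.5, nonobese_high = 25),
    qc = list(call_rate_min = 0.95, maf_min = 0.01, hwe_p_min = 1e-4),
    diffnet = list(threshold = 0.01, B = 100000L, seed = 1L),
    compare = list(edge_list_1 = NULL, edge_list_2 = NULL),
    gwca = list(base_threshold = 5e-8, pairs = "from-diffnet-overlap",
                comparison_report = NULL, max_gene_distance = 1e6),
    baselines = list(alpha = 0.01, direction = "bmi_on_metabolite"),
    # key is n_samples, not n: a bare "n" is a YAML 1.1 boolean
    simulation = list(n_samples = 3000L, n_true = 50L, n_null = 950L,
                      B = 1000L, seed = 1L, diffnet_arm = TRUE))
}

check_range <- function(x, name, lo, hi, lo_open = FALSE, hi_open = FALSE) {
  if (is.null(x)) return(invisible())
  bad <- !is.numeric(x) || is.na(x) ||
    (if (lo_open) x <= lo else x < lo) ||
    (if (hi_open) x >= hi else x > hi)
  if (bad) {
    stop(sprintf("config field '%s' = %s out of range %s%s, %s%s",
                 name, format(x), if (lo_open) "(" else "[", format(lo),
                 format(hi), if (hi_open) ")" else "]"), call. = FALSE)
  }
  invisible()
}

#' Read and validate a pipeline configuration file
#'
#' YAML file with sections \code{files}, \code{groups}, \code{qc},
#' \code{diffnet}, \code{compare}, \code{gwca}, \code{baselines},
#' \code{simulation}; unspecified fields fall back to the defaults
#' carrying the reference thresholds (QC 0.95/0.01/1e-4, network p < 0.01
#' with B = 100000, GWCA base 5e-8, Bonferroni alpha 0.01). Unknown keys
#' are rejected with a field-level message.
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @return Validated config list (class \code{pipeline_config}); the file
#'   path and its md5 are attached as attributes.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- pipeline_defaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(user)) {
    bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(bad)) {
      stop("unknown config key(s) in '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  check_range(cfg$qc$call_rate_min, "qc.call_rate_min", 0, 1)
  check_range(cfg$qc$maf_min, "qc.maf_min", 0, 0.5)
  check_range(cfg$qc$hwe_p_min, "qc.hwe_p_min", 0, 1)
  check_range(cfg$diffnet$threshold, "diffnet.threshold", 0, 1, TRUE)
  check_range(cfg$diffnet$B, "diffnet.B", 1, Inf)
  check_range(cfg$gwca$base_threshold, "gwca.base_threshold", 0, 1, TRUE)
  check_range(cfg$gwca$max_gene_distance, "gwca.max_gene_distance", 0, Inf)
  check_range(cfg$baselines$alpha, "baselines.alpha", 0, 1, TRUE)
  check_range(cfg$simulation$n_samples, "simulation.n_samples", 16, Inf)
  if (!cfg$baselines$direction %in% c("bmi_on_metabolite",
                                      "metabolite_on_bmi")) {
    stop("config field 'baselines.direction' must be 'bmi_on_metabolite' ",
         "or 'metabolite_on_bmi'", call. = FALSE)
  }
  if (!is.null(cfg$groups$nonobese_high) &&
      any(cfg$groups$nonobese_high > cfg$groups$obese_min)) {
    stop("config: overlapping BMI cutoff ranges", call. = FALSE)
  }
  attr(cfg, "path") <- path
  attr(cfg, "md5") <- if (!is.null(path)) unname(tools::md5sum(path))
  else NA_character_
  class(cfg) <- "pipeline_config"
  cfg
}

write_run_manifest <- function(out_dir, config, command, seed) {
  manifest <- list(
    command = command,
    config_file = attr(config, "path"),
    config_md5 = attr(config, "md5"),
    seed = seed,
    package_version = as.character(utils::packageVersion("gwcanet")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(manifest, file.path(out_dir,
                                       paste0(command, "_manifest.yaml")))
}

require_file <- function(path, what) {
  if (is.null(path)) stop("config: no ", what, " file configured",
                          call. = FALSE)
  if (!file.exists(path)) stop(what, " file not found: ", path,
                               call. = FALSE)
  path
}

load_inputs <- function(config, genotypes = FALSE) {
  delim <- config$files$delimiter
  out <- list()
  out$metabolites <- read_metabolite_table(
    require_file(config$files$metabolites, "metabolite"), delim)
  out$covariates <- read_covariate_table(
    require_file(config$files$covariates, "covariate"), delim)
  if (genotypes) {
    out$genotypes <- read_genotypes(
      require_file(config$files$genotypes, "genotype"),
      config$files$genotype_format, delim)
  }
  out
}

#' Pipeline subcommands
#'
#' Each subcommand is a pure composition of the module operations, writing
#' tab-separated outputs plus a run manifest (config hash, seed, versions,
#' timestamp) into \code{out_dir}.
#'
#' \describe{
#'   \item{cmd_qc}{marker QC: writes \code{qc_report.tsv}.}
#'   \item{cmd_residualize}{covariate residualization: writes
#'     \code{metabolites_residualized.tsv}.}
#'   \item{cmd_metab}{univariate metabolite-BMI regression table.}
#'   \item{cmd_gwas}{additive single-SNP GWAS table.}
#'   \item{cmd_diffnet}{BMI grouping, residualization, permutation test,
#'     differential network: writes \code{diffnet_edges.tsv}.}
#'   \item{cmd_compare}{cross-cohort overlap of two edge lists: writes
#'     \code{network_comparison.tsv}.}
#'   \item{cmd_gwca}{genome-wide correlation analysis over the configured
#'     pairs (or the replicated overlap): writes
#'     \code{gwca_associations.tsv}.}
#'   \item{cmd_simulate}{scenario suite: writes \code{simulation_aucs.tsv}.}
#' }
#'
#' @param config a [read_pipeline_config()] result.
#' @param out_dir output directory (created if absent).
#' @return The main result object of the subcommand, invisibly.
#' @name pipeline_commands
NULL

prep_out <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' @rdname pipeline_commands
#' @export
cmd_qc <- function(config, out_dir = config$files$out_dir) {
  prep_out(out_dir)
  gt <- read_genotypes(require_file(config$files$genotypes, "genotype"),
                       config$files$genotype_format, config$files$delimiter)
  qc <- snp_qc(gt, config$qc$call_rate_min, config$qc$maf_min,
               config$qc$hwe_p_min)
  utils::write.table(qc$report, file.path(out_dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_manifest(out_dir, config, "qc", NA)
  invisible(qc)
}

#' @rdname pipeline_commands
#' @export
cmd_residualize <- function(config, out_dir = config$files$out_dir) {
  prep_out(out_dir)
  inp <- load_inputs(config)
  res <- residualize_on_covariates(inp$metabolites, inp$covariates, "sex")
  tab <- data.frame(sample_id = res$sample_ids,
                    res$values, check.names = FALSE)
  utils::write.table(tab,
                     file.path(out_dir, "metabolites_residualized.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_manifest(out_dir, config, "residualize", NA)
  invisible(res)
}

#' @rdname pipeline_commands
#' @export
cmd_metab <- function(config, out_dir = config$files$out_dir) {
  prep_out(out_dir)
  inp <- load_inputs(config)
  tab <- metabolite_bmi_regression(inp$metabolites, inp$covariates,
                                   alpha = config$baselines$alpha,
                                   direction = config$baselines$direction)
  utils::write.table(tab, file.path(out_dir, "metabolite_bmi.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_manifest(out_dir, config, "metab", NA)
  invisible(tab)
}

#' @rdname pipeline_commands
#' @export
cmd_gwas <- function(config, out_dir = config$files$out_dir) {
  prep_out(out_dir)
  inp <- load_inputs(config, genotypes = TRUE)
  qc <- snp_qc(inp$genotypes, config$qc$call_rate_min, config$qc$maf_min,
               config$qc$hwe_p_min)
  tab <- single_snp_gwas(qc$genotypes, inp$covariates)
  utils::write.table(tab, file.path(out_dir, "gwas_bmi.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_manifest(out_dir, config, "gwas", NA)
  invisible(tab)
}

#' @rdname pipeline_commands
#' @export
cmd_diffnet <- function(config, out_dir = config$files$out_dir) {
  prep_out(out_dir)
  inp <- load_inputs(config)
  res <- residualize_on_covariates(inp$metabolites, inp$covariates, "sex")
  grp <- assign_bmi_groups(inp$covariates, config$groups)
  take <- function(lbl) {
    ids <- grp$sample_id[grp$label == lbl]
    keep <- res$sample_ids %in% ids
    drop_incomplete_samples(
      metab_matrix(res$values[keep, , drop = FALSE],
                   sample_ids = res$sample_ids[keep],
                   metabolite_ids = res$metabolite_ids,
                   residualized = TRUE))
  }
  X1 <- take("group1"); X2 <- take("group2")
  perm <- permutation_test_diffnet(X1, X2, B = config$diffnet$B,
                                   seed = config$diffnet$seed)
  net <- build_differential_network(perm,
                                    threshold = config$diffnet$threshold)
  write_edge_list(net, file.path(out_dir, "diffnet_edges.tsv"))
  write_run_manifest(out_dir, config, "diffnet", config$diffnet$seed)
  invisible(net)
}

#' @rdname pipeline_commands
#' @export
cmd_compare <- function(config, out_dir = config$files$out_dir) {
  prep_out(out_dir)
  inp <- load_inputs(config)
  nodes <- inp$metabolites$metabolite_ids
  net1 <- read_edge_list(require_file(config$compare$edge_list_1,
                                      "edge list 1"), nodes = nodes)
  net2 <- read_edge_list(require_file(config$compare$edge_list_2,
                                      "edge list 2"), nodes = nodes)
  cmpr <- compare_networks(net1, net2)
  ov <- cmpr$overlap
  header <- data.frame(N = cmpr$N, M_edges = cmpr$M_edges,
                       K_edges = cmpr$K_edges, x = cmpr$x,
                       concordance = cmpr$concordance,
                       p_hyper = fmt_p(cmpr$p_hyper))
  path <- file.path(out_dir, "network_comparison.tsv")
  utils::write.table(header, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  suppressWarnings(
    utils::write.table(ov, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE))
  write_run_manifest(out_dir, config, "compare", NA)
  invisible(cmpr)
}

# pairs for GWCA: explicit list in config, or the replicated overlap of a
# comparison output (D = overlap size)
resolve_gwca_pairs <- function(config) {
  pr <- config$gwca$pairs
  if (identical(pr, "from-diffnet-overlap")) {
    path <- require_file(config$gwca$comparison_report, "comparison report")
    tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 2,
                             stringsAsFactors = FALSE)
    if (nrow(tab) == 0L) stop("comparison report contains no overlap pairs")
    data.frame(metabolite_1 = tab$metabolite_1,
               metabolite_2 = tab$metabolite_2, stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(pr, function(x) {
      data.frame(metabolite_1 = x[[1L]], metabolite_2 = x[[2L]],
                 stringsAsFactors = FALSE)
    }))
  }
}

#' @rdname pipeline_commands
#' @export
cmd_gwca <- function(config, out_dir = config$files$out_dir) {
  prep_out(out_dir)
  inp <- load_inputs(config, genotypes = TRUE)
  qc <- snp_qc(inp$genotypes, config$qc$call_rate_min, config$qc$maf_min,
               config$qc$hwe_p_min)
  res <- residualize_on_covariates(inp$metabolites, inp$covariates, "sex")
  pairs <- resolve_gwca_pairs(config)
  thr <- gwca_threshold(nrow(pairs), config$gwca$base_threshold)
  rec <- run_gwca(qc$genotypes, res, pairs, threshold = thr)
  if (!is.null(config$files$annotation)) {
    ann <- read_annotation_table(config$files$annotation,
                                 config$files$delimiter)
    rec <- annotate_nearest_gene(rec, ann, config$gwca$max_gene_distance)
  }
  write_association_table(rec, file.path(out_dir, "gwca_associations.tsv"))
  write_run_manifest(out_dir, config, "gwca", NA)
  invisible(rec)
}

#' @rdname pipeline_commands
#' @export
cmd_simulate <- function(config, out_dir = config$files$out_dir) {
  prep_out(out_dir)
  sim <- config$simulation
  scen <- default_scenarios(n = sim$n_samples, n_true = sim$n_true,
                            n_null = sim$n_null, seed = sim$seed)
  tab <- run_scenario_suite(scen, B_perm = sim$B,
                            diffnet = isTRUE(sim$diffnet_arm))
  utils::write.table(tab, file.path(out_dir, "simulation_aucs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_manifest(out_dir, config, "simulate", sim$seed)
  invisible(tab)
}

#' Command-line entry point
#'
#' Dispatches \code{qc}, \code{residualize}, \code{diffnet},
#' \code{compare}, \code{gwca}, \code{gwas}, \code{metab} or
#' \code{simulate} with flags \code{--config}, \code{--seed},
#' \code{--out-dir}. Used by the thin wrapper script in
#' \code{inst/cli/gwcanet.R}.
#'
#' @param args character vector, by default the trailing command-line
#'   arguments.
#' @return Exit status, 0 on success (invisibly).
#' @export
gwcanet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  cmds <- c(qc = cmd_qc, residualize = cmd_residualize,
            diffnet = cmd_diffnet, compare = cmd_compare,
            gwca = cmd_gwca, gwas = cmd_gwas, metab = cmd_metab,
            simulate = cmd_simulate)
  if (length(args) < 1L || !args[1L] %in% names(cmds)) {
    message("usage: gwcanet <", paste(names(cmds), collapse = "|"),
            "> [--config FILE] [--seed N] [--out-dir DIR]")
    return(invisible(1L))
  }
  get_flag <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else NULL
  }
  config <- read_pipeline_config(get_flag("--config"))
  seed <- get_flag("--seed")
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    config$diffnet$seed <- seed
    config$simulation$seed <- seed
  }
  out_dir <- get_flag("--out-dir")
  if (is.null(out_dir)) out_dir <- config$files$out_dir
  cmds[[args[1L]]](config, out_dir = out_dir)
  invisible(0L)
}
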