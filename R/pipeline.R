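#' Pipeline run configuration
#'
#' @param manifest_path Lineage manifest TSV (see [read_manifest()]).
#' @param tree_path Newick tree over the manifest taxa.
#' @param mu_per_site_year Mutation rate per site per year.
#' @param generation_years Generation time in years.
#' @param bin_size PSMC bin size in sites.
#' @param cutoff_years Recent-history truncation cutoff.
#' @param peak_mode,epsilon,sd_mode Passed to [summarize_growth()].
#' @param n_permutations Permutations for the signal screen.
#' @param signal_alpha Screen threshold: variables with signal p below
#'   this are not contrast-tested unless `force`.
#' @param force Run contrasts even for variables showing signal.
#' @param seed Integer seed for the signal permutations.
#' @param output_dir Directory for result TSVs and the run log.
#' @return A `run_config` list.
#' @export
run_config <- function(manifest_path, tree_path = NULL,
                       mu_per_site_year = 2.3e-9, generation_years = 2.5,
                       bin_size = 100, cutoff_years = 50000,
                       peak_mode = "first_turning", epsilon = 0.05,
                       sd_mode = "population", n_permutations = 999,
                       signal_alpha = 0.05, force = FALSE, seed = 1L,
                       output_dir = tempfile("psmcgrowth_run")) {
  stopifnot(mu_per_site_year > 0, generation_years > 0, bin_size > 0,
            cutoff_years >= 0, n_permutations >= 1)
  structure(list(manifest_path = manifest_path, tree_path = tree_path,
                 mu_per_site_year = mu_per_site_year,
                 generation_years = generation_years, bin_size = bin_size,
                 cutoff_years = cutoff_years, peak_mode = peak_mode,
                 epsilon = epsilon, sd_mode = sd_mode,
                 n_permutations = n_permutations,
                 signal_alpha = signal_alpha, force = force,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

.contrast_variables <- c(mean_ne = "mean_ne_e4", cv = "cv", degree = "degree",
                         rate = "rate_per_yr", deltat = "deltat_yr")

#' Per-lineage growth statistics from PSMC files
#'
#' Stages 1-4 of the pipeline: parse each manifest entry's PSMC file, take
#' the converged round, scale to natural units, truncate recent history,
#' and summarize growth. Ne columns are reported in units of 10^4
#' individuals (the conventional plotting scale) alongside raw-unit
#' columns.
#'
#' @param manifest Data.frame from [read_manifest()].
#' @param config A [run_config()].
#' @return A data.frame in the Table-1 layout of [read_growth_table()],
#'   plus `mean_ne`, `sd_ne`, `t_peak_yr`, `t_trough_yr`, `n_steps`.
#' @export
summarize_manifest <- function(manifest, config) {
  sp <- scaling_params(config$mu_per_site_year, config$generation_years,
                       config$bin_size)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    taxon <- manifest$taxon_id[i]
    raw <- read_psmc(manifest$psmc_path[i], source_label = taxon)
    traj <- scale_round(last_round(raw), sp, taxon_id = taxon)
    traj <- truncate_recent(traj, config$cutoff_years)
    g <- summarize_growth(traj, peak_mode = config$peak_mode,
                          epsilon = config$epsilon,
                          sd_mode = config$sd_mode)
    data.frame(taxon_id = taxon, group = manifest$group[i],
               mean_ne_e4 = g$mean_ne / 1e4, sd_ne_e4 = g$sd_ne / 1e4,
               cv = g$cv, degree = g$degree,
               rate_per_yr = ifelse(g$rate_defined, g$rate, NA_real_),
               deltat_yr = g$delta_t,
               mean_ne = g$mean_ne, sd_ne = g$sd_ne,
               t_peak_yr = g$t_peak, t_trough_yr = g$t_trough,
               n_steps = g$n_steps_retained)
  })
  do.call(rbind, rows)
}

.screen_signal <- function(stats, tree, config) {
  if (is.null(tree)) return(NULL)
  miss <- setdiff(stats$taxon_id, tree$tip.label)
  if (length(miss)) {
    stop(sprintf("manifest taxa missing from tree: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  rows <- lapply(names(.contrast_variables), function(vn) {
    col <- .contrast_variables[[vn]]
    v <- stats[[col]]
    names(v) <- stats$taxon_id
    v <- v[is.finite(v)]
    if (length(v) < 3L || stats::var(v) == 0) {
      return(data.frame(variable = vn, cmean = NA_real_, p = NA_real_,
                        nperm = config$n_permutations, seed = config$seed))
    }
    keep <- ape::keep.tip(tree, names(v))
    s <- abouheif_cmean(keep, v, n_permutations = config$n_permutations,
                        seed = config$seed, variable = vn)
    data.frame(variable = vn, cmean = s$cmean_observed, p = s$p_value,
               nperm = s$n_permutations, seed = s$seed)
  })
  do.call(rbind, rows)
}

.run_contrasts <- function(stats, signal, config) {
  rows <- lapply(names(.contrast_variables), function(vn) {
    col <- .contrast_variables[[vn]]
    skip <- FALSE
    if (!is.null(signal) && !config$force) {
      p_sig <- signal$p[signal$variable == vn]
      skip <- length(p_sig) == 1L && is.finite(p_sig) &&
        p_sig <= config$signal_alpha
    }
    if (skip) {
      return(data.frame(variable = vn, U = NA_real_, n1 = NA_integer_,
                        n2 = NA_integer_, p_exact = NA_real_,
                        method = "not_run_phylogenetic_signal",
                        direction = "migrants > residents"))
    }
    mig <- stats[[col]][stats$group == "migrant"]
    res <- stats[[col]][stats$group == "resident"]
    ct <- suppressMessages(mann_whitney_one_tailed(mig, res))
    data.frame(variable = vn, U = ct$U, n1 = ct$n_migrant,
               n2 = ct$n_resident, p_exact = ct$p_value,
               method = ct$method, direction = ct$alternative)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' parse -> scale -> truncate -> summarize -> phylogenetic-signal screen
#' -> migrant-vs-resident contrasts. Writes `growth_stats.tsv` (Table-1
#' layout plus raw-unit columns), `signal.tsv`, `contrasts.tsv` and
#' `run_log.txt` into `config$output_dir`. Variables whose signal screen
#' rejects phylogenetic independence (p <= `signal_alpha`) are reported
#' but not contrast-tested unless `config$force`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `stats`, `signal`, `contrasts`, and the
#'   output paths.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  manifest <- read_manifest(config$manifest_path)
  tree <- if (!is.null(config$tree_path)) parse_newick(path = config$tree_path)
  stats <- summarize_manifest(manifest, config)
  signal <- .screen_signal(stats, tree, config)
  contrasts <- .run_contrasts(stats, signal, config)
  .write_run(stats, signal, contrasts, config)
}

#' Run the contrast stages from a pre-computed statistics table
#'
#' Entry point for a Table-1-layout statistics TSV (e.g. the packaged
#' [thrush_growth_table()] fixture written to disk): runs only the signal
#' screen and group contrasts, skipping PSMC parsing.
#'
#' @param stats_tsv Path to the statistics TSV ([read_growth_table()]
#'   layout).
#' @param config A [run_config()] (its `manifest_path` is ignored).
#' @return Invisibly, the same structure as [run_full()].
#' @export
run_table_mode <- function(stats_tsv, config = run_config(manifest_path = NA)) {
  stats <- read_growth_table(stats_tsv)
  if (nrow(stats) == 0L) stop("empty statistics table", call. = FALSE)
  tree <- if (!is.null(config$tree_path)) parse_newick(path = config$tree_path)
  signal <- .screen_signal(stats, tree, config)
  contrasts <- .run_contrasts(stats, signal, config)
  .write_run(stats, signal, contrasts, config)
}

.write_run <- function(stats, signal, contrasts, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stats_path <- file.path(config$output_dir, "growth_stats.tsv")
  write_table(stats, stats_path)
  signal_path <- NULL
  if (!is.null(signal)) {
    signal_path <- file.path(config$output_dir, "signal.tsv")
    write_table(signal, signal_path)
  }
  contrasts_path <- file.path(config$output_dir, "contrasts.tsv")
  write_table(contrasts, contrasts_path)

  log_path <- file.path(config$output_dir, "run_log.txt")
  cfg <- config
  cfg$output_dir <- NULL
  log_lines <- c(
    sprintf("psmcgrowth %s | R %s",
            as.character(utils::packageVersion("psmcgrowth")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("config: %s", paste(sprintf("%s=%s", names(cfg),
                                        vapply(cfg, function(x)
                                          paste(format(x), collapse = ","),
                                          character(1))),
                                collapse = " ")),
    sprintf("lineages: %d (%d migrant, %d resident)", nrow(stats),
            sum(stats$group == "migrant"), sum(stats$group == "resident")),
    sprintf("undefined rates flagged: %d", sum(!is.finite(stats$rate_per_yr))),
    sprintf("contrasts not run after signal screen: %d",
            sum(contrasts$method == "not_run_phylogenetic_signal"))
  )
  writeLines(log_lines, log_path)

  invisible(list(stats = stats, signal = signal, contrasts = contrasts,
                 stats_path = stats_path, signal_path = signal_path,
                 contrasts_path = contrasts_path, log_path = log_path))
}
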