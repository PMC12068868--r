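#' Parameters for a synthetic demographic archetype
#'
#' Describes a piecewise Ne history of the shape the comparative analysis
#' assumes: monotone (exponential) growth from `origin_ne` at the lineage's
#' inception (`origin_time` years before present) up to `peak_ne` over
#' `growth_duration` years, then a plateau modulated by a glacial-cycle
#' style oscillation (default period 100 kyr), then a recent decline —
#' most recent populations sitting below the historic peak. The migrant
#' archetype has a long growth phase, high peak and high variability; the
#' resident archetype a short growth phase, low peak and low variability.
#'
#' @param origin_time Lineage inception, years before present.
#' @param origin_ne Ne at inception (the trough of initial growth).
#' @param growth_duration Duration of initial growth in years (the true
#'   deltaT).
#' @param peak_ne Ne at the end of initial growth.
#' @param oscillation_period Plateau oscillation period, years.
#' @param oscillation_amplitude Relative amplitude in `[0, 1)`; the plateau
#'   oscillates within `[peak_ne * (1 - amplitude), peak_ne]`.
#' @param recent_decline Relative drop of the most recent step below the
#'   plateau, in `[0, 1)`.
#' @param decline_onset Years before present at which the recent decline
#'   starts.
#' @param noise_sigma SD of multiplicative lognormal noise applied to
#'   lambda at emission time (see [emit_psmc()]); the trajectory itself is
#'   deterministic.
#' @param seed Integer seed used at emission.
#' @return An `archetype_params` list.
#' @export
archetype_params <- function(origin_time = 4e6, origin_ne = 1e4,
                             growth_duration = 3e6, peak_ne = 8e5,
                             oscillation_period = 1e5,
                             oscillation_amplitude = 0.1,
                             recent_decline = 0.5,
                             decline_onset = 1.5e5,
                             noise_sigma = 0, seed = 1L) {
  stopifnot(origin_time > 0, origin_ne > 0, peak_ne > 0,
            growth_duration > 0, growth_duration < origin_time,
            oscillation_amplitude >= 0, oscillation_amplitude < 1,
            recent_decline >= 0, recent_decline < 1,
            decline_onset > 0, decline_onset < origin_time,
            noise_sigma >= 0)
  structure(list(origin_time = origin_time, origin_ne = origin_ne,
                 growth_duration = growth_duration, peak_ne = peak_ne,
                 oscillation_period = oscillation_period,
                 oscillation_amplitude = oscillation_amplitude,
                 recent_decline = recent_decline,
                 decline_onset = decline_onset,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "archetype_params")
}

#' Migrant-like archetype defaults
#'
#' Long growth phase (3.1 Myr), high peak and marked variability,
#' matching the scale of the published migrant rows (origin ~4.5 Myr,
#' peak Ne ~8e5).
#' @param ... Overrides passed to [archetype_params()].
#' @export
migrant_archetype <- function(...) {
  defaults <- list(origin_time = 4.5e6, origin_ne = 1.2e5,
                   growth_duration = 3.1e6, peak_ne = 8e5,
                   oscillation_amplitude = 0.35, recent_decline = 0.5,
                   noise_sigma = 0.1)
  do.call(archetype_params, utils::modifyList(defaults, list(...)))
}

#' Resident-like archetype defaults
#'
#' Short growth phase (1.7 Myr), low peak and low variability, matching
#' the scale of the published resident rows.
#' @param ... Overrides passed to [archetype_params()].
#' @export
resident_archetype <- function(...) {
  defaults <- list(origin_time = 2.8e6, origin_ne = 1.5e5,
                   growth_duration = 1.7e6, peak_ne = 3.2e5,
                   oscillation_amplitude = 0.15, recent_decline = 0.3,
                   noise_sigma = 0.1)
  do.call(archetype_params, utils::modifyList(defaults, list(...)))
}

#' Build a deterministic piecewise-constant Ne trajectory
#'
#' Steps sit on a log-spaced time grid from `t_min` to the origin, with
#' the archetype's own breakpoints (origin, end of growth, decline onset)
#' inserted as grid knots so the generator represents its phases exactly.
#' Growth is exponential (log-linear in time); the plateau is modulated as
#' `peak_ne * (1 - a/2 + a/2 * cos(2*pi*(t - t_growth_end)/period))`, so
#' the plateau attains `peak_ne` exactly at the end of growth; the recent
#' decline is log-linear from `decline_onset` to `t_min`. Deterministic
#' given the parameters — noise enters only at [emit_psmc()].
#'
#' @param p An [archetype_params()] object.
#' @param n_steps Number of log-spaced grid steps (default 64).
#' @param t_min Most recent grid time in years (default 1000).
#' @param taxon_id Label for the trajectory.
#' @return A `demographic_trajectory`.
#' @export
make_trajectory <- function(p, n_steps = 64, t_min = 1e3,
                            taxon_id = "synthetic") {
  stopifnot(inherits(p, "archetype_params"), n_steps >= 8, t_min > 0,
            t_min < p$origin_time)
  t_growth_end <- p$origin_time - p$growth_duration
  # first step at 0 (PSMC output always starts at coalescent time 0), then
  # log-spaced to the origin, with phase breakpoints inserted as knots
  grid <- exp(seq(log(t_min), log(p$origin_time), length.out = n_steps - 1L))
  grid[1] <- t_min                      # pin endpoints: exp(log(x)) can
  grid[length(grid)] <- p$origin_time   # drift by a few ulp
  knots <- c(t_growth_end, p$decline_onset)
  knots <- knots[knots > t_min & knots < p$origin_time]
  grid <- sort(unique(c(0, grid, knots)))
  if (sum(grid >= t_growth_end & grid <= p$origin_time) < 2L) {
    stop("grid too coarse to represent the growth phase", call. = FALSE)
  }
  ne <- vapply(grid, function(t) .archetype_ne(t, p, t_growth_end),
               numeric(1))
  new_trajectory(grid, ne, taxon_id)
}

.archetype_ne <- function(t, p, t_growth_end) {
  if (t >= t_growth_end) {
    # growth phase (and inception): log-linear from origin_ne at origin_time
    # down-time to peak_ne at t_growth_end
    frac <- (p$origin_time - t) / p$growth_duration  # 0 at origin, 1 at end
    frac <- min(max(frac, 0), 1)
    return(exp(log(p$origin_ne) + frac * (log(p$peak_ne) - log(p$origin_ne))))
  }
  a <- p$oscillation_amplitude
  plateau <- p$peak_ne *
    (1 - a / 2 + (a / 2) * cos(2 * pi * (t - t_growth_end) / p$oscillation_period))
  if (t >= p$decline_onset) return(plateau)
  # recent decline: log-linear factor from 1 at decline_onset to
  # (1 - recent_decline) at t = 0
  f <- 1 - p$recent_decline * (p$decline_onset - t) / p$decline_onset
  plateau * f
}

#' Emit a trajectory as PSMC-format text
#'
#' Inverse of [scale_round()]: the baseline `N0` is the Ne of the most
#' recent step, `theta0 = 4 * N0 * mu_gen * bin_size`,
#' `t_k = t_years / (2 * N0 * g)` and `lambda_k = Ne_k / N0`, the latter
#' multiplied by seeded lognormal noise `exp(rnorm(0, noise_sigma))` to
#' emulate PSMC estimation wobble. Output is a single-round block with
#' RD/TR/MT/PA/RS lines and a `//` terminator that [parse_psmc()] reads
#' back; with `noise_sigma = 0` the round trip is exact.
#'
#' @param traj A `demographic_trajectory`.
#' @param sp A [scaling_params()] object.
#' @param noise_sigma Lognormal noise SD on lambda.
#' @param seed Integer seed for the noise.
#' @param pattern Atomic time-interval pattern string echoed on the PA
#'   line (the finely split recent window recommended against artifactual
#'   recent peaks).
#' @return A single character scalar of PSMC-format text.
#' @export
emit_psmc <- function(traj, sp = scaling_params(), noise_sigma = 0,
                      seed = 1L, pattern = "1+1+1+1+25*2+4+6") {
  stopifnot(inherits(traj, "demographic_trajectory"), noise_sigma >= 0)
  mu_gen <- sp$mu_per_site_year * sp$generation_years
  n0 <- traj$ne[1]
  theta0 <- 4 * n0 * mu_gen * sp$bin_size
  rho0 <- theta0 / 4
  if (traj$t_years[1] != 0) {
    stop("PSMC emission requires the most recent step to start at time 0",
         call. = FALSE)
  }
  t_k <- traj$t_years / (2 * n0 * sp$generation_years)
  lambda <- traj$ne / n0
  if (noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
    lambda <- lambda * exp(stats::rnorm(length(lambda), 0, noise_sigma))
  }
  k <- seq_along(t_k) - 1L
  lines <- c(
    "RD 25",
    sprintf("LL %.6f", -1e5),
    sprintf("TR %.15g %.15g", theta0, rho0),
    sprintf("MT %.15g", max(t_k) * 1.2),
    sprintf("RS\t%d\t%.15g\t%.15g\t0\t0", k, t_k, lambda),
    sprintf("PA %s %.15g", pattern, theta0),
    "//"
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Specification of a synthetic migrant/resident cohort
#'
#' @param n_migrant,n_resident Group sizes (default 8 and 6, the published
#'   design).
#' @param migrant_params,resident_params Archetype means (see
#'   [migrant_archetype()], [resident_archetype()]).
#' @param jitter_sd SD of the lognormal jitter applied per taxon to
#'   origin_ne, peak_ne, growth_duration and origin_time around the
#'   archetype means.
#' @param tree_model Yule speciation rate for the cohort phylogeny.
#' @param clustered_groups If TRUE, group labels are assigned cladewise
#'   (one clade mostly migrant); if FALSE, randomly.
#' @param seed Master seed; all cohort randomness derives from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_migrant = 8L, n_resident = 6L,
                        migrant_params = migrant_archetype(),
                        resident_params = resident_archetype(),
                        jitter_sd = 0.25, tree_model = 1,
                        clustered_groups = TRUE, seed = 1L) {
  stopifnot(n_migrant + n_resident >= 4L, jitter_sd >= 0, tree_model > 0)
  structure(list(n_migrant = as.integer(n_migrant),
                 n_resident = as.integer(n_resident),
                 migrant_params = migrant_params,
                 resident_params = resident_params,
                 jitter_sd = jitter_sd, tree_model = tree_model,
                 clustered_groups = clustered_groups,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

.jitter_params <- function(base, jitter_sd, seed) {
  set.seed(seed)
  j <- function(x) x * exp(stats::rnorm(1, 0, jitter_sd))
  origin_time <- j(base$origin_time)
  # keep growth_duration strictly inside origin_time
  growth <- min(j(base$growth_duration), 0.95 * origin_time)
  archetype_params(origin_time = origin_time,
                   origin_ne = j(base$origin_ne),
                   growth_duration = growth,
                   peak_ne = j(base$peak_ne),
                   oscillation_period = base$oscillation_period,
                   oscillation_amplitude = base$oscillation_amplitude,
                   recent_decline = base$recent_decline,
                   decline_onset = base$decline_onset,
                   noise_sigma = base$noise_sigma,
                   seed = seed)
}

#' Generate a full synthetic cohort on disk
#'
#' Simulates a Yule phylogeny over the cohort, draws per-taxon archetype
#' parameters jittered around the group means, writes one PSMC-format file
#' per taxon (with emission noise), a TSV manifest, a Newick tree, and a
#' true-parameters table for recovery tests.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @param sp [scaling_params()] used for emission.
#' @param n_steps Grid steps per trajectory.
#' @return A list: `manifest_path`, `tree_path`, `truth_path`, `dir`,
#'   `truth` (data.frame of the per-taxon true parameters), and
#'   `trajectories` (the noise-free source trajectories, named by taxon).
#' @export
make_cohort <- function(spec = cohort_spec(), dir = tempfile("cohort"),
                        sp = scaling_params(), n_steps = 64) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- spec$n_migrant + spec$n_resident

  set.seed(spec$seed)
  tree <- ape::rphylo(n, birth = spec$tree_model, death = 0)
  tree$tip.label <- sprintf("taxon_%02d", seq_len(n))

  groups <- .assign_groups(tree, spec$n_migrant, spec$clustered_groups)

  taxa <- tree$tip.label
  truth <- vector("list", n)
  trajs <- vector("list", n)
  psmc_paths <- character(n)
  for (i in seq_len(n)) {
    base <- if (groups[i] == "migrant") spec$migrant_params else spec$resident_params
    # derive in double precision: integer arithmetic would overflow
    taxon_seed <- as.integer((as.numeric(spec$seed) * 1000 + i) %%
                               .Machine$integer.max)
    p_i <- .jitter_params(base, spec$jitter_sd, taxon_seed)
    tr <- make_trajectory(p_i, n_steps = n_steps, taxon_id = taxa[i])
    txt <- emit_psmc(tr, sp, noise_sigma = base$noise_sigma,
                     seed = taxon_seed)
    psmc_paths[i] <- file.path(dir, paste0(taxa[i], ".psmc"))
    writeLines(txt, psmc_paths[i], sep = "")
    trajs[[i]] <- tr
    truth[[i]] <- data.frame(taxon_id = taxa[i], group = groups[i],
                             origin_time = p_i$origin_time,
                             origin_ne = p_i$origin_ne,
                             growth_duration = p_i$growth_duration,
                             peak_ne = p_i$peak_ne,
                             noise_sigma = base$noise_sigma,
                             seed = taxon_seed)
  }
  names(trajs) <- taxa
  truth <- do.call(rbind, truth)

  manifest <- data.frame(taxon_id = taxa, group = groups,
                         psmc_path = basename(psmc_paths))
  manifest_path <- file.path(dir, "manifest.tsv")
  write_table(manifest, manifest_path)
  tree_path <- file.path(dir, "tree.nwk")
  ape::write.tree(tree, tree_path)
  truth_path <- file.path(dir, "true_params.tsv")
  write_table(truth, truth_path)

  list(manifest_path = manifest_path, tree_path = tree_path,
       truth_path = truth_path, dir = dir, truth = truth,
       trajectories = trajs)
}

.assign_groups <- function(tree, n_migrant, clustered) {
  n <- length(tree$tip.label)
  groups <- rep("resident", n)
  if (clustered) {
    # pick the clade whose tip count is closest to n_migrant, fill the
    # remainder (or trim) deterministically in tip order
    internal <- (n + 1L):(n + tree$Nnode)
    clade_tips <- lapply(internal, function(v) {
      which(tree$tip.label %in%
              ape::extract.clade(tree, v)$tip.label)
    })
    sizes <- lengths(clade_tips)
    best <- internal[which.min(abs(sizes - n_migrant))]
    mig <- clade_tips[[match(best, internal)]]
    if (length(mig) > n_migrant) mig <- mig[seq_len(n_migrant)]
    if (length(mig) < n_migrant) {
      mig <- c(mig, setdiff(seq_len(n), mig)[seq_len(n_migrant - length(mig))])
    }
  } else {
    mig <- sample.int(n, n_migrant)
  }
  groups[mig] <- "migrant"
  groups
}
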