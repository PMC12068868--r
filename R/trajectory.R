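#' Scaling constants for PSMC output
#'
#' PSMC reports times and sizes in coalescent units; converting to years
#' and individuals needs a mutation rate, a generation time and the bin
#' size used when the genome was consensus-encoded. The mutation rate here
#' is PER SITE PER YEAR (as commonly reported for birds); internally it is
#' multiplied by the generation time to get the per-generation rate psmc's
#' theta is scaled by.
#'
#' @param mu_per_site_year Mutation rate, mutations per site per year.
#' @param generation_years Generation time in years.
#' @param bin_size Sites per PSMC bin (psmcfa window, usually 100).
#' @return A `scaling_params` list.
#' @export
scaling_params <- function(mu_per_site_year = 2.3e-9,
                           generation_years = 2.5,
                           bin_size = 100) {
  stopifnot(mu_per_site_year > 0, generation_years > 0, bin_size > 0)
  structure(list(mu_per_site_year = mu_per_site_year,
                 generation_years = generation_years,
                 bin_size = bin_size),
            class = "scaling_params")
}

new_trajectory <- function(t_years, ne, taxon_id) {
  if (length(t_years) < 2L) {
    stop(sprintf("trajectory for '%s' needs at least 2 steps", taxon_id),
         call. = FALSE)
  }
  if (any(diff(t_years) <= 0)) {
    stop(sprintf("trajectory for '%s': times must be strictly increasing",
                 taxon_id), call. = FALSE)
  }
  if (any(!is.finite(ne)) || any(ne <= 0)) {
    stop(sprintf("trajectory for '%s': Ne must be finite and positive",
                 taxon_id), call. = FALSE)
  }
  structure(list(t_years = as.numeric(t_years), ne = as.numeric(ne),
                 taxon_id = taxon_id),
            class = "demographic_trajectory")
}

#' @export
print.demographic_trajectory <- function(x, ...) {
  cat(sprintf("Ne trajectory '%s': %d steps, %.3g-%.3g yr BP, Ne %.3g-%.3g\n",
              x$taxon_id, length(x$t_years), min(x$t_years), max(x$t_years),
              min(x$ne), max(x$ne)))
  invisible(x)
}

#' Scale a PSMC round to natural units
#'
#' Applies the standard psmc plotting conversion. With per-generation
#' mutation rate `mu_gen = mu_per_site_year * generation_years` and bin
#' size `s`, the baseline size is `N0 = theta0 / (4 * mu_gen * s)`; each
#' segment `(t_k, lambda_k)` maps to time `2 * N0 * t_k * generation_years`
#' years before present and size `lambda_k * N0` individuals. Steps are
#' returned ordered recent to ancient (file order).
#'
#' @param r A `psmc_round` (see [last_round()]).
#' @param sp A [scaling_params()] object.
#' @param taxon_id Label attached to the trajectory.
#' @return A `demographic_trajectory`: list with `t_years`, `ne`,
#'   `taxon_id`; `ne[k]` applies on `[t_years[k], t_years[k+1])`.
#' @export
scale_round <- function(r, sp = scaling_params(), taxon_id = "sample") {
  stopifnot(inherits(r, "psmc_round"))
  if (is.na(r$theta0) || r$theta0 <= 0) {
    stop("theta0 must be positive to scale a PSMC round", call. = FALSE)
  }
  mu_gen <- sp$mu_per_site_year * sp$generation_years
  n0 <- r$theta0 / (4 * mu_gen * sp$bin_size)
  t_years <- 2 * n0 * r$segments[, "t_k"] * sp$generation_years
  ne <- r$segments[, "lambda_k"] * n0
  new_trajectory(t_years, ne, taxon_id)
}

#' Drop the unreliable recent portion of a trajectory
#'
#' PSMC estimates for very recent times are unreliable; the analysis
#' ignores everything more recent than a cutoff (50 kyr by default). A
#' segment is kept iff its recent boundary `t_k` is at or above the cutoff
#' (no interpolation of the straddling segment).
#'
#' @param traj A `demographic_trajectory`.
#' @param cutoff_years Cutoff in years before present.
#' @return A new truncated `demographic_trajectory`.
#' @export
truncate_recent <- function(traj, cutoff_years = 50000) {
  stopifnot(inherits(traj, "demographic_trajectory"), cutoff_years >= 0)
  keep <- traj$t_years >= cutoff_years
  if (sum(keep) < 2L) {
    stop(sprintf("trajectory for '%s' is degenerate after truncation at %g yr (%d step(s) left)",
                 traj$taxon_id, cutoff_years, sum(keep)), call. = FALSE)
  }
  new_trajectory(traj$t_years[keep], traj$ne[keep], traj$taxon_id)
}

# Oldest-to-recent index order (steps are stored recent->ancient).
.old_to_recent <- function(traj) rev(seq_along(traj$t_years))

#' Summarize early growth of a demographic trajectory
#'
#' Computes the five per-lineage variables of the comparative analysis.
#' The trough is anchored at the OLDEST retained step (the lineage's PSMC
#' inception); the peak ends the initial growth phase. Derived variables:
#' degree of initial growth `1 - N_trough/N_peak` (negative when the
#' trajectory initially declines), `deltaT = t_trough - t_peak` in years,
#' and rate `degree/deltaT` per year. Mean, SD and CV (SD/mean) are taken
#' over the retained step values.
#'
#' Peak location on non-monotone curves is a convention, so two modes are
#' offered. `"first_turning"` scans from oldest to most recent and places
#' the peak at the first extremum where the running direction of change
#' reverses, provided the cumulative relative change since the origin
#' exceeds `epsilon` (step-noise filter); a monotone trajectory peaks at
#' the most recent step. `"global"` places the peak at the maximum Ne
#' (oldest such step under ties), except when that maximum is the origin
#' step itself, in which case the trajectory initially declines and the
#' "peak" is the minimum-Ne step, making the degree negative.
#'
#' @param traj A (typically truncated) `demographic_trajectory`.
#' @param peak_mode `"first_turning"` (default) or `"global"`.
#' @param epsilon Relative-change filter for `"first_turning"`.
#' @param sd_mode `"population"` (divisor n, default) or `"sample"`
#'   (divisor n-1) for the SD over retained steps.
#' @param weighted If TRUE, mean/SD are weighted by each step's time span
#'   (the span of the oldest step being zero-width is taken as the gap to
#'   its neighbour); default FALSE, i.e. unweighted over plotted segments.
#' @return A `growth_summary` list: `mean_ne`, `sd_ne`, `cv`, `n_peak`,
#'   `n_trough`, `t_peak`, `t_trough`, `degree`, `delta_t`, `rate`
#'   (NA with `rate_defined = FALSE` when `delta_t` is 0),
#'   `n_steps_retained`, `taxon_id`.
#' @export
summarize_growth <- function(traj, peak_mode = c("first_turning", "global"),
                             epsilon = 0.05,
                             sd_mode = c("population", "sample"),
                             weighted = FALSE) {
  stopifnot(inherits(traj, "demographic_trajectory"))
  peak_mode <- match.arg(peak_mode)
  sd_mode <- match.arg(sd_mode)
  ne <- traj$ne
  tt <- traj$t_years
  n <- length(ne)

  if (weighted) {
    w <- c(diff(tt), tt[n] - tt[n - 1L])  # span of each step; oldest reuses gap
    w <- w / sum(w)
    mean_ne <- sum(w * ne)
    var_ne <- sum(w * (ne - mean_ne)^2)
    if (sd_mode == "sample") var_ne <- var_ne * n / (n - 1L)
  } else {
    mean_ne <- mean(ne)
    var_ne <- sum((ne - mean_ne)^2) / if (sd_mode == "sample") n - 1L else n
  }
  sd_ne <- sqrt(var_ne)

  ord <- .old_to_recent(traj)           # indices oldest -> recent
  ne_o <- ne[ord]
  t_o <- tt[ord]
  i_trough <- 1L                        # oldest retained step
  i_peak <- .locate_peak(ne_o, peak_mode, epsilon)

  n_trough <- ne_o[i_trough]
  n_peak <- ne_o[i_peak]
  degree <- 1 - n_trough / n_peak
  delta_t <- t_o[i_trough] - t_o[i_peak]
  rate_defined <- delta_t > 0
  rate <- if (rate_defined) degree / delta_t else NA_real_

  structure(list(mean_ne = mean_ne, sd_ne = sd_ne, cv = sd_ne / mean_ne,
                 n_peak = n_peak, n_trough = n_trough,
                 t_peak = t_o[i_peak], t_trough = t_o[i_trough],
                 degree = degree, delta_t = delta_t, rate = rate,
                 rate_defined = rate_defined, n_steps_retained = n,
                 peak_mode = peak_mode, taxon_id = traj$taxon_id),
            class = "growth_summary")
}

# ne_o: Ne values ordered oldest -> most recent. Returns peak index in that
# ordering.
.locate_peak <- function(ne_o, peak_mode, epsilon) {
  n <- length(ne_o)
  if (peak_mode == "global") {
    i_max <- which(ne_o == max(ne_o))[1L]  # oldest step attaining the max
    if (i_max == 1L) {
      # initial decline: growth "peak" is the first extremum downward
      return(which(ne_o == min(ne_o))[1L])
    }
    return(i_max)
  }
  # first_turning: follow the running direction from the origin; the peak is
  # the extremum step where the direction first reverses, ignoring
  # reversals before the cumulative relative change since origin exceeds
  # epsilon. Monotone curves peak at the most recent step.
  dir <- 0
  for (i in 2:n) {
    d <- sign(ne_o[i] - ne_o[i - 1L])
    if (d == 0) next
    if (dir == 0) { dir <- d; next }
    if (d != dir && abs(ne_o[i - 1L] / ne_o[1L] - 1) > epsilon) {
      return(i - 1L)
    }
  }
  n
}

#' @export
print.growth_summary <- function(x, ...) {
  cat(sprintf("Growth summary '%s' (%d steps, peak_mode=%s):\n",
              x$taxon_id, x$n_steps_retained, x$peak_mode))
  cat(sprintf("  mean Ne %.4g (SD %.4g, CV %.3f)\n", x$mean_ne, x$sd_ne, x$cv))
  cat(sprintf("  trough %.4g @ %.4g yr; peak %.4g @ %.4g yr\n",
              x$n_trough, x$t_trough, x$n_peak, x$t_peak))
  cat(sprintf("  degree %.4f; deltaT %.4g yr; rate %s\n", x$degree,
              x$delta_t,
              if (x$rate_defined) sprintf("%.4g /yr", x$rate) else "undefined"))
  invisible(x)
}

#' Evaluate a step trajectory at arbitrary times
#'
#' `ne[k]` applies on `[t_years[k], t_years[k+1])`; times older than the
#' last step take the last Ne, times more recent than the first step take
#' the first.
#'
#' @param traj A `demographic_trajectory`.
#' @param times Numeric vector of years before present.
#' @return Numeric vector of Ne values.
#' @export
eval_trajectory <- function(traj, times) {
  idx <- findInterval(times, traj$t_years)
  idx[idx < 1L] <- 1L
  traj$ne[idx]
}

#' Envelope of bootstrap-replicate trajectories
#'
#' Evaluates each replicate trajectory at the grid times and returns
#' per-time order statistics across replicates, the numeric summary behind
#' the familiar pink bootstrap envelopes on PSMC plots.
#'
#' @param trajs Non-empty list of `demographic_trajectory` objects.
#' @param grid Numeric vector of evaluation times (years before present).
#' @return A data.frame with columns `t_years`, `min`, `median`, `max`.
#' @export
replicate_envelope <- function(trajs, grid) {
  if (length(trajs) == 0L) stop("empty replicate list", call. = FALSE)
  vals <- vapply(trajs, eval_trajectory, numeric(length(grid)), times = grid)
  vals <- matrix(vals, nrow = length(grid))
  data.frame(t_years = grid,
             min = apply(vals, 1, min),
             median = apply(vals, 1, stats::median),
             max = apply(vals, 1, max))
}
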