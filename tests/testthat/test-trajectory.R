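test_that("scale_round applies the standard PSMC conversion", {
  p <- parse_psmc(two_round_psmc(), "demo")
  r <- last_round(p)
  r$theta0 <- 0.0023
  r$segments <- cbind(t_k = c(0, 0.05), lambda_k = c(1, 3))
  tr <- scale_round(r, scaling_params(2.3e-9, 2.5, 100), taxon_id = "x")
  # N0 = 0.0023 / (4 * 5.75e-9 * 100) = 1000
  expect_equal(tr$ne[1], 1000)
  expect_equal(tr$t_years[2], 2 * 1000 * 0.05 * 2.5)  # 250 yr
  expect_equal(tr$ne[2], 3000)
})

test_that("constant lambda gives a constant trajectory at N0", {
  r <- structure(list(round_index = 25L, theta0 = 0.0023, rho0 = 5e-4,
                      max_t_coal = 15, pattern = "4+25*2+4+6",
                      segments = cbind(t_k = c(0, 0.1, 0.2, 0.5),
                                       lambda_k = rep(1, 4))),
                 class = "psmc_round")
  tr <- scale_round(r)
  expect_equal(tr$ne, rep(1000, 4))
  g <- summarize_growth(truncate_recent(tr, 0))
  expect_equal(g$degree, 0)
  expect_equal(g$cv, 0)
})

test_that("truncation keeps steps with t_k at or above the cutoff", {
  tr <- make_traj(c(10e3, 60e3, 200e3), c(1e4, 2e4, 3e4))
  out <- truncate_recent(tr, 50000)
  expect_equal(out$t_years, c(60e3, 200e3))
  expect_equal(out$ne, c(2e4, 3e4))
  # original untouched
  expect_length(tr$t_years, 3L)
  # cutoff 0 is the identity
  expect_equal(truncate_recent(tr, 0)$t_years, tr$t_years)
  expect_error(truncate_recent(tr, 1e6), "degenerate")
})

test_that("growth summary applies the degree/deltaT/rate formulas", {
  # two-step growth: trough at 3 Myr (1e4), peak at 1 Myr (5e4)
  tr <- make_traj(c(1e6, 3e6), c(5e4, 1e4))
  g <- summarize_growth(tr)
  expect_equal(g$degree, 0.8)
  expect_equal(g$delta_t, 2e6)
  expect_equal(g$rate, 4e-7)
  expect_equal(g$n_trough, 1e4)
  expect_equal(g$t_trough, 3e6)

  # initial decline: origin 7e4 at 0.9 Myr falling to 4e4 at 0.15 Myr
  dec <- make_traj(c(0.15e6, 0.9e6), c(4e4, 7e4))
  gd <- summarize_growth(dec)
  expect_equal(gd$degree, 1 - 7 / 4)  # -0.75
  expect_true(gd$rate < 0)
  expect_equal(sign(gd$rate), sign(gd$degree))
})

test_that("deltaT of zero yields a flagged undefined rate, not infinity", {
  # non-monotone curve whose global maximum sits at the origin step
  tr <- make_traj(c(1e5, 5e5, 1e6), c(2e4, 1e4, 9e4))
  g <- summarize_growth(tr, peak_mode = "global")
  # origin is the max -> initial-decline convention: peak = minimum step
  expect_equal(g$n_peak, 1e4)
  expect_true(g$degree < 0)
  # constant trajectory under global mode: peak collapses onto the origin
  # step, deltaT = 0, rate flagged missing rather than +-Inf
  flat <- make_traj(c(1e5, 5e5, 1e6), c(1e4, 1e4, 1e4))
  gf <- summarize_growth(flat, peak_mode = "global")
  expect_equal(gf$delta_t, 0)
  expect_false(gf$rate_defined)
  expect_true(is.na(gf$rate))
  expect_equal(gf$degree, 0)
})

test_that("global peak mode agrees with an exhaustive argmax/argmin scan", {
  set.seed(11)
  for (rep in 1:25) {
    n <- 50
    tt <- sort(runif(n, 5e4, 5e6))
    ne <- exp(rnorm(n, log(1e5), 0.8))
    tr <- make_traj(tt, ne)
    g <- summarize_growth(tr, peak_mode = "global")
    ne_o <- rev(ne)
    t_o <- rev(tt)
    i_max <- which(ne_o == max(ne_o))[1]
    i_peak <- if (i_max == 1L) which(ne_o == min(ne_o))[1] else i_max
    expect_equal(g$n_peak, ne_o[i_peak])
    expect_equal(g$t_peak, t_o[i_peak])
    expect_equal(g$delta_t, t_o[1] - t_o[i_peak])
    expect_equal(g$n_trough, ne_o[1])
    expect_true(g$degree < 1)
    expect_true(g$delta_t >= 0)
    if (g$rate_defined) expect_equal(sign(g$rate), sign(g$degree))
  }
})

test_that("cv and deltaT are invariant under rescaling Ne; mean scales", {
  set.seed(5)
  tt <- sort(runif(30, 6e4, 4e6))
  ne <- exp(rnorm(30, log(2e5), 0.5))
  a <- summarize_growth(make_traj(tt, ne))
  b <- summarize_growth(make_traj(tt, ne * 3.7))
  expect_equal(b$cv, a$cv)
  expect_equal(b$delta_t, a$delta_t)
  expect_equal(b$degree, a$degree)
  expect_equal(b$mean_ne, a$mean_ne * 3.7)
})

test_that("population and sample SD modes and time weighting behave as documented", {
  tt <- c(1e5, 2e5, 4e5, 1e6)
  ne <- c(1e4, 3e4, 2e4, 5e4)
  tr <- make_traj(tt, ne)
  gp <- summarize_growth(tr, sd_mode = "population")
  gs <- summarize_growth(tr, sd_mode = "sample")
  expect_equal(gp$sd_ne, sqrt(mean((ne - mean(ne))^2)))
  expect_equal(gs$sd_ne, sd(ne))
  gw <- summarize_growth(tr, weighted = TRUE)
  w <- c(diff(tt), 6e5); w <- w / sum(w)
  expect_equal(gw$mean_ne, sum(w * ne))
})

test_that("time-reversing a monotone growth trajectory flips the degree sign", {
  tt <- c(1e5, 3e5, 9e5, 2e6)
  grow <- make_traj(tt, c(8e4, 4e4, 2e4, 1e4))   # growth toward present
  decl <- make_traj(tt, c(1e4, 2e4, 4e4, 8e4))   # same values reversed
  gg <- summarize_growth(grow)
  gd <- summarize_growth(decl)
  expect_true(gg$degree > 0)
  expect_true(gd$degree < 0)
})

test_that("first_turning ignores sub-epsilon wiggles but catches real reversals", {
  # oldest -> recent: 1e4 rises to 5e4, tiny wiggle (2%), continues to 8e4
  tt <- c(1e5, 2e5, 4e5, 8e5, 1.6e6, 3e6)
  ne_o <- c(1e4, 3e4, 5e4, 4.9e4, 6e4, 8e4)    # oldest..recent
  tr <- make_traj(tt, rev(ne_o))
  g <- summarize_growth(tr, epsilon = 0.05)
  # the 2% dip at step 4 is a reversal but far above epsilon cumulative
  # change, so the peak locks at the preceding extremum (5e4)
  expect_equal(g$n_peak, 5e4)
  # with a large epsilon... the wiggle still reverses direction; check that
  # a monotone curve peaks at the most recent step instead
  mono <- make_traj(tt, rev(c(1e4, 2e4, 3e4, 4e4, 6e4, 8e4)))
  gm <- summarize_growth(mono)
  expect_equal(gm$n_peak, 8e4)
  expect_equal(gm$t_peak, min(tt))
})

test_that("replicate envelopes bracket their inputs", {
  one <- make_traj(c(1e5, 1e6), c(1e4, 3e4))
  env1 <- replicate_envelope(list(one), c(2e5, 5e5, 2e6))
  expect_equal(env1$min, env1$max)
  expect_equal(env1$median, eval_trajectory(one, c(2e5, 5e5, 2e6)))

  a <- make_traj(c(1e5, 1e6), c(1e4, 1e4))
  b <- make_traj(c(1e5, 1e6), c(3e4, 3e4))
  env2 <- replicate_envelope(list(a, b), c(2e5, 2e6))
  expect_equal(env2$median, c(2e4, 2e4))  # mean-of-middle under even count
  expect_error(replicate_envelope(list(), 1e5), "empty")

  # seeded noisy emissions of one archetype bracket the noise-free curve
  p <- resident_archetype(noise_sigma = 0)
  src <- make_trajectory(p, taxon_id = "src")
  sp <- scaling_params()
  reps <- lapply(1:100, function(i) {
    txt <- emit_psmc(src, sp, noise_sigma = 0.1, seed = i)
    scale_round(last_round(parse_psmc(txt, "r")), sp, taxon_id = "r")
  })
  grid <- src$t_years[src$t_years >= 5e4]
  env <- replicate_envelope(reps, grid)
  truth <- eval_trajectory(src, grid)
  inside <- mean(truth >= env$min & truth <= env$max)
  expect_gte(inside, 0.95)
})
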