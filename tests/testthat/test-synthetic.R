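test_that("trajectories are deterministic and shaped by their parameters", {
  p <- migrant_archetype(noise_sigma = 0)
  a <- make_trajectory(p)
  b <- make_trajectory(p)
  expect_identical(a, b)
  expect_equal(max(a$t_years), p$origin_time)
  expect_equal(a$t_years[1], 0)
  # origin value is origin_ne; global maximum is peak_ne
  expect_equal(a$ne[length(a$ne)], p$origin_ne)
  expect_equal(max(a$ne), p$peak_ne)
  # recent step sits below the historic peak (post-peak decline)
  expect_lt(a$ne[1], p$peak_ne)
})

test_that("summarize recovers archetype degree and deltaT from the trajectory", {
  for (p in list(migrant_archetype(noise_sigma = 0),
                 resident_archetype(noise_sigma = 0),
                 archetype_params())) {
    tr <- truncate_recent(make_trajectory(p, taxon_id = "syn"), 50000)
    for (mode in c("global", "first_turning")) {
      g <- summarize_growth(tr, peak_mode = mode)
      grid_step <- max(diff(tr$t_years))
      expect_lt(abs(g$delta_t - p$growth_duration), grid_step)
      expect_equal(g$degree, 1 - p$origin_ne / p$peak_ne, tolerance = 1e-6)
    }
  }
})

test_that("flat archetype (no oscillation, no decline) has closed-form cv", {
  p <- archetype_params(oscillation_amplitude = 0, recent_decline = 0)
  tr <- make_trajectory(p)
  # plateau exactly at peak_ne everywhere past the growth phase
  plateau <- tr$ne[tr$t_years < p$origin_time - p$growth_duration]
  expect_equal(plateau, rep(p$peak_ne, length(plateau)))
  g <- summarize_growth(tr)
  expect_equal(g$cv, sd(tr$ne) * sqrt((length(tr$ne) - 1) / length(tr$ne)) /
                 mean(tr$ne))
})

test_that("PSMC emission round-trips exactly without noise at any resolution", {
  sp <- scaling_params()
  for (n_steps in c(16, 64, 128)) {
    src <- make_trajectory(resident_archetype(noise_sigma = 0),
                           n_steps = n_steps, taxon_id = "rt")
    txt <- emit_psmc(src, sp, noise_sigma = 0)
    back <- scale_round(last_round(parse_psmc(txt, "rt")), sp,
                        taxon_id = "rt")
    expect_equal(back$ne, src$ne, tolerance = 1e-9)
    expect_equal(back$t_years, src$t_years, tolerance = 1e-9)
  }
})

test_that("emission noise is multiplicative lognormal with the right scale", {
  sp <- scaling_params()
  src <- make_trajectory(migrant_archetype(noise_sigma = 0), taxon_id = "n")
  mats <- sapply(1:100, function(i) {
    txt <- emit_psmc(src, sp, noise_sigma = 0.1, seed = i)
    scale_round(last_round(parse_psmc(txt, "n")), sp, taxon_id = "n")$ne
  })
  geo_mean <- exp(rowMeans(log(mats)))
  expect_true(all(abs(geo_mean / src$ne - 1) < 0.02))
})

test_that("emission is byte-identical for a fixed seed", {
  src <- make_trajectory(resident_archetype(), taxon_id = "d")
  t1 <- emit_psmc(src, noise_sigma = 0.2, seed = 123)
  t2 <- emit_psmc(src, noise_sigma = 0.2, seed = 123)
  t3 <- emit_psmc(src, noise_sigma = 0.2, seed = 124)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
})

test_that("cohorts are reproducible and carry coherent truth tables", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  spec <- cohort_spec(seed = 99)
  c1 <- make_cohort(spec, dir = dir1)
  c2 <- make_cohort(spec, dir = dir2)
  expect_equal(c1$truth, c2$truth)
  expect_identical(readLines(c1$tree_path), readLines(c2$tree_path))
  expect_identical(readLines(file.path(dir1, "taxon_01.psmc")),
                   readLines(file.path(dir2, "taxon_01.psmc")))

  m <- read_manifest(c1$manifest_path)
  expect_equal(nrow(m), 14L)
  expect_equal(sum(m$group == "migrant"), 8L)
  tree <- parse_newick(path = c1$tree_path)
  expect_setequal(tree$tip.label, m$taxon_id)
  expect_true(all(file.exists(m$psmc_path)))
})

test_that("true deltaT is recovered within one grid step across a parameter sweep", {
  set.seed(55)
  errs <- replicate(20, {
    gd <- runif(1, 0.7e6, 4.2e6)
    ot <- gd / runif(1, 0.55, 0.85)
    p <- archetype_params(origin_time = ot, growth_duration = gd,
                          origin_ne = exp(runif(1, log(5e3), log(2e5))),
                          peak_ne = exp(runif(1, log(2.5e5), log(1e6))),
                          oscillation_amplitude = runif(1, 0, 0.4))
    tr <- truncate_recent(make_trajectory(p, taxon_id = "s"), 50000)
    g <- summarize_growth(tr, peak_mode = "global")
    abs(g$delta_t - gd) / max(diff(tr$t_years))
  })
  expect_lte(median(errs), 1)
})

test_that("an empty migrant group fails manifest validation downstream", {
  spec <- cohort_spec(n_migrant = 0L, n_resident = 6L, seed = 1)
  dir <- withr::local_tempdir()
  co <- make_cohort(spec, dir = dir)
  m <- read_manifest(co$manifest_path)
  st <- summarize_manifest(m, run_config(co$manifest_path))
  expect_error(mann_whitney_one_tailed(st$mean_ne[st$group == "migrant"],
                                       st$mean_ne[st$group == "resident"]),
               "at least one")
})
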