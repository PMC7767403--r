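test_that("mean energies and block errors behave on degenerate series", {
  const <- energy_series("AT", "DNA", e_vdw = rep(-10, 100),
                         e_el = rep(-20, 100))
  m <- mean_interaction_energies(const, block_count = 10)
  expect_equal(m$mean_vdw, -10)
  expect_equal(m$mean_el, -20)
  expect_equal(m$se_vdw, 0)
  expect_equal(m$se_el, 0)
  expect_equal(m$n_samples, 100L)

  alt <- energy_series("AT", "DNA", e_vdw = rep(c(-1, 1), 50),
                       e_el = rep(c(1, -1), 50))
  expect_equal(mean_interaction_energies(alt, 2)$mean_vdw, 0)

  expect_error(mean_interaction_energies(
    energy_series("AT", "DNA", e_vdw = 1:5, e_el = 1:5), 10), "fewer")
})

test_that("block-averaged SE of an AR(1) mean agrees with a moving-block bootstrap", {
  es <- simulate_energy_series(mean_vdw = -50, mean_el = -50,
                               sigma_vdw = 2, sigma_el = 2, phi = 0.9,
                               n = 10000L, seed = 314)
  m <- mean_interaction_energies(es, block_count = 10)
  # mean within 3 effective standard errors of the generating value
  n_eff <- 10000 * (1 - 0.9) / (1 + 0.9)
  expect_lt(abs(m$mean_vdw - (-50)), 3 * 2 / sqrt(n_eff))
  # block SE within a factor of 2 of the bootstrap oracle
  boot <- mbb_se(es$e_vdw, block_len = 100, n_boot = 1000, seed = 9)
  expect_gt(m$se_vdw, boot / 2)
  expect_lt(m$se_vdw, boot * 2)
})

test_that("the LIE equation combines mean energies with alpha and beta", {
  bound <- mean_energies("AT", "Complex", mean_vdw = -100, mean_el = -200)
  unbound <- mean_energies("AT", "DNA", mean_vdw = -90, mean_el = -180)
  dg <- lie_delta_g(bound, unbound)
  expect_equal(dg$dg, 0.18 * (-10) + 0.43 * (-20))  # -10.40 kcal/mol
  expect_equal(dg$dg, -10.40)
  expect_equal(dg$vdw_component, -1.8)
  expect_equal(dg$el_component, -8.6)

  same <- lie_delta_g(bound, mean_energies("AT", "DNA", -100, -200))
  expect_equal(same$dg, 0)

  # linearity: doubling alpha doubles the vdW component only
  dg2 <- lie_delta_g(bound, unbound, lie_params(alpha = 0.36, beta = 0.43))
  expect_equal(dg2$vdw_component, 2 * dg$vdw_component)
  expect_equal(dg2$el_component, dg$el_component)

  expect_error(lie_delta_g(bound, mean_energies("GC", "DNA", 0, 0)),
               "different variants")
  expect_error(lie_delta_g(unbound, bound), "Complex")
})

test_that("the four-system cycle gives the hand-computed ddG split", {
  cells <- preset_means("paper_default")
  r <- ddg_bind(cells)
  expect_equal(r$ddg, -0.800, tolerance = 1e-12)
  expect_equal(r$ddg_el_component, -0.700, tolerance = 1e-12)
  expect_equal(r$ddg_vdw_component, -0.100, tolerance = 1e-12)
  expect_equal(r$ddg, r$dg_bind_gc - r$dg_bind_at, tolerance = 1e-12)
  expect_equal(r$ddg, r$ddg_el_component + r$ddg_vdw_component,
               tolerance = 1e-12)

  null <- ddg_bind(preset_means("null"))
  expect_equal(null$ddg, 0)
  expect_error(ddg_bind(cells[1:3]), "incomplete thermodynamic cycle")
})

test_that("the cycle closes identically and ddG is antisymmetric and linear", {
  set.seed(99)
  for (i in 1:25) {
    cells <- random_cells()
    expect_lt(abs(cycle_closure(cells)), 1e-10)
    r <- ddg_bind(cells)
    swapped <- ddg_bind(swap_variants(cells))
    expect_identical(swapped$ddg, -r$ddg)
    # decomposition sums to the total up to round-off
    expect_lt(abs(r$ddg_el_component + r$ddg_vdw_component - r$ddg), 1e-10)
    # zero parameters give zero; components scale linearly
    expect_equal(ddg_bind(cells, lie_params(0, 0))$ddg, 0)
    r2 <- ddg_bind(cells, lie_params(0.36, 0.86))
    expect_equal(r2$ddg_vdw_component, 2 * r$ddg_vdw_component,
                 tolerance = 1e-12)
    expect_equal(r2$ddg_el_component, 2 * r$ddg_el_component,
                 tolerance = 1e-12)
  }
})

test_that("pooling averages runs and reports the replicate standard error", {
  one <- ddg_bind(preset_means("paper_default"))
  pooled <- pool_runs(rep(list(one), 16))
  expect_equal(pooled$ddg, one$ddg)
  expect_equal(pooled$se_ddg, 0)
  expect_equal(pooled$n_runs, 16L)

  mk <- function(ddg) {
    cells <- preset_means("null")
    cells[[3]]$mean_el <- cells[[3]]$mean_el + ddg / 0.43
    ddg_bind(cells)
  }
  two <- pool_runs(list(mk(-1.0), mk(-0.6)))
  expect_equal(two$ddg, -0.8)
  expect_equal(two$se_ddg, stats::sd(c(-1, -0.6)) / sqrt(2))
  expect_equal(two$se_ddg, 0.2)

  perm <- pool_runs(list(mk(-0.6), mk(-1.0)))
  expect_equal(perm$ddg, two$ddg)
  expect_equal(perm$se_ddg, two$se_ddg)

  expect_error(pool_runs(list(one)), "at least 2")
})

test_that("lie_ddg fits replicate series end to end with a model interface", {
  ds <- synthetic_preset("paper_default", seed = 11,
                         components = "energies")
  fit <- lie_ddg(ds$energies)
  expect_s3_class(fit, "lie_result")
  expect_equal(fit$n_runs, 16L)
  expect_equal(nrow(fit$per_run), 16L)
  co <- coef(fit)
  expect_named(co, c("ddg", "ddg_el", "ddg_vdw"))
  expect_equal(unname(co[["ddg"]]),
               unname(co[["ddg_el"]] + co[["ddg_vdw"]]))
  ci <- confint(fit)
  expect_lt(ci[1, 1], fit$ddg)
  expect_gt(ci[1, 2], fit$ddg)
  expect_output(print(fit), "ddG_bind")
  expect_output(print(summary(fit)), "Per-run")

  # single-run input degrades gracefully to an unpooled result
  single <- lie_ddg(ds$energies[[1]])
  expect_equal(single$n_runs, 1L)
  expect_null(single$per_run)
})

test_that("parameter recovery: the pooled estimate converges on the generating ddG", {
  ds <- synthetic_preset("paper_default", seed = 202,
                         components = "energies")
  fit <- lie_ddg(ds$energies)
  expect_lt(abs(fit$ddg - (-0.800)), 3 * fit$se_ddg)
  # the null preset is exactly symmetric by construction
  null_fit <- lie_ddg(synthetic_preset("null", seed = 202,
                                       components = "energies")$energies)
  expect_equal(null_fit$ddg, 0)
})
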