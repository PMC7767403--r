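test_that("duplex atom counts follow the residue templates", {
  # A: 11 heavy + H61/H62; T: 10 heavy + H3 -> 24 atoms for one A:T pair
  s <- build_duplex("A")
  expect_equal(nrow(s$atoms), 24L)
  # G: 12 heavy + H1/H21/H22; C: 9 heavy + H41/H42 -> 26 for one G:C pair
  expect_equal(nrow(build_duplex("G")$atoms), 26L)
  expect_error(build_duplex("AXT"), "invalid base")
  expect_error(build_duplex(""), "non-empty")
})

test_that("stacked pairs sit one helical rise apart along the axis", {
  s <- build_duplex("GA")
  rise <- pair_centroid(s, 2)[3] - pair_centroid(s, 1)[3]
  expect_equal(unname(rise), 3.38, tolerance = 1e-9)
  # stacking introduces no spurious inter-pair hydrogen bonds
  expect_equal(nrow(detect_hbonds(s)), 3L + 2L)
})

test_that("duplexes survive the round trip and donor assignment cleanly", {
  s <- build_duplex("ACGT")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  back <- read_pdb(f)
  expect_equal(back$atoms$name, s$atoms$name)
  expect_equal(coords(back), coords(s), tolerance = 1e-3)
  expect_no_warning(assign_donors_acceptors(s))
})

test_that("substituting the pair swaps the hydrogen-bond count 2 -> 3 and is local", {
  wt <- build_duplex("GCATG")
  expect_equal(nrow(detect_hbonds(wt)), 3L + 3L + 2L + 2L + 3L)
  mut <- mutate_pair(wt, 3, "GC")
  expect_equal(nrow(detect_hbonds(mut)), 3L + 3L + 3L + 2L + 3L)

  # atoms outside the substituted pair keep their exact coordinates
  for (s_pair in list(c("A", 1L), c("B", 5L), c("A", 4L))) {
    pick <- function(s) {
      a <- s$atoms
      m <- a[a$chain_id == s_pair[1] & a$res_seq == as.integer(s_pair[2]), ]
      as.matrix(m[order(m$name), c("x", "y", "z")])
    }
    expect_identical(unname(pick(mut)), unname(pick(wt)))
  }

  # substituting by the identical pair reproduces the structure
  same <- mutate_pair(wt, 3, "AT")
  expect_equal(coords(same), coords(wt), tolerance = 1e-6)
  expect_error(mutate_pair(wt, 9, "GC"), "out of range")
})

test_that("the toy complex always offers a protein-DNA contact, the water one bridge", {
  for (seq_site in list(list("GCATG", 3L), list("TTGTT", 3L),
                        list("ACA", 2L))) {
    d <- build_duplex(seq_site[[1]])
    cx <- build_toy_complex(d, seq_site[[2]])
    expect_equal(coords(cx)[seq_len(nrow(d$atoms)), ], coords(d),
                 ignore_attr = TRUE)
    ev <- detect_hbonds(cx)
    cls <- bindshift:::residue_class(cx$atoms$res_name)
    pd <- xor(cls[ev$donor] == "protein", cls[ev$acceptor] == "protein") &
      (cls[ev$donor] == "dna" | cls[ev$acceptor] == "dna")
    expect_gte(sum(pd), 1L)
    w <- place_bridging_water(cx, seq_site[[2]])
    br <- detect_water_bridges(w, pair_centroid(w, seq_site[[2]]))
    expect_equal(nrow(br), 1L)
  }
})

test_that("trajectory noise has the advertised amplitude and determinism", {
  base <- build_duplex("GC")
  frozen <- simulate_trajectory(base, sigma = 0, n_frames = 5, seed = 1)
  for (fr in frozen$frames)
    expect_equal(fr, coords(base), ignore_attr = TRUE)
  expect_equal(rmsd_series(frozen, reference = base, fit = FALSE)$values,
               rep(0, 5))

  t1 <- simulate_trajectory(base, sigma = 0.5, n_frames = 50, seed = 7)
  t2 <- simulate_trajectory(base, sigma = 0.5, n_frames = 50, seed = 7)
  expect_identical(t1$frames, t2$frames)
  t3 <- simulate_trajectory(base, sigma = 0.5, n_frames = 50, seed = 8)
  expect_false(identical(t1$frames, t3$frames))

  # E[RMSD^2] = 3 sigma^2 for isotropic per-coordinate noise (heavy atoms)
  tl <- simulate_trajectory(base, sigma = 0.5, n_frames = 1000, seed = 12)
  msd <- mean(rmsd_series(tl, reference = base, fit = FALSE,
                          selection = "heavy")$values^2)
  expect_lt(abs(msd - 0.75) / 0.75, 0.05)
})

test_that("hydrogens ride their heavy atom so bond geometry stays intact", {
  base <- build_duplex("G")
  tr <- simulate_trajectory(base, sigma = 0.6, n_frames = 10, seed = 4)
  a <- base$atoms
  h <- which(a$name == "H1")        # imino hydrogen of guanine N1
  n1 <- which(a$chain_id == "A" & a$name == "N1")
  for (fr in tr$frames)
    expect_equal(bindshift:::vec_norm(fr[h, ] - fr[n1, ]),
                 bindshift:::vec_norm(coords(base)[h, ] - coords(base)[n1, ]),
                 tolerance = 1e-12)
})

test_that("AR(1) series match their generating parameters", {
  # phi = 0, sigma = 0: constant at the mean
  c0 <- simulate_energy_series(-50, -60, sigma_vdw = 0, sigma_el = 0,
                               phi = 0, n = 100, seed = 1)
  expect_equal(c0$e_vdw, rep(-50, 100))
  expect_equal(c0$e_el, rep(-60, 100))

  # long series: mean within 3 sigma/sqrt(n_eff)
  es <- simulate_energy_series(-50, -60, sigma_vdw = 2, sigma_el = 2,
                               phi = 0.9, n = 100000L, seed = 5)
  n_eff <- 100000 * (1 - 0.9) / (1 + 0.9)
  expect_lt(abs(mean(es$e_vdw) - (-50)), 3 * 2 / sqrt(n_eff))
  expect_lt(abs(mean(es$e_el) - (-60)), 3 * 2 / sqrt(n_eff))

  # lag-1 autocorrelation close to phi, marginal sd close to sigma
  es2 <- simulate_energy_series(0, 0, sigma_vdw = 1, sigma_el = 1,
                                phi = 0.7, n = 10000L, seed = 6)
  r1 <- stats::acf(es2$e_vdw, plot = FALSE, lag.max = 1)$acf[2]
  expect_lt(abs(r1 - 0.7), 0.05)
  expect_lt(abs(stats::sd(es2$e_vdw) - 1), 0.1)
  expect_error(simulate_energy_series(0, 0, phi = 1), "phi")
})

test_that("presets are reproducible and distinct across runs and seeds", {
  d1 <- synthetic_preset("paper_default", seed = 3, components = "energies")
  d2 <- synthetic_preset("paper_default", seed = 3, components = "energies")
  expect_identical(d1$energies, d2$energies)
  expect_false(identical(
    d1$energies[[1]]$AT.Complex$e_el, d1$energies[[2]]$AT.Complex$e_el))
  d3 <- synthetic_preset("paper_default", seed = 4, components = "energies")
  expect_false(identical(d1$energies[[1]]$AT.Complex$e_el,
                         d3$energies[[1]]$AT.Complex$e_el))
  expect_error(synthetic_preset("bogus"), "arg")
})
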