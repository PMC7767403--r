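test_that("water chemistry: one donor with two hydrogens, one acceptor", {
  s <- place_bridging_water(
    build_toy_complex(build_duplex("GAG"), 2), 2)
  wat <- s$atoms$res_name == "HOH"
  da <- assign_donors_acceptors(s)
  wd <- da$donors[wat[da$donors$donor], ]
  expect_equal(nrow(wd), 1L)
  expect_equal(s$atoms$name[wd$donor], "OW")
  expect_equal(length(wd$hydrogens[[1]]), 2L)
  expect_equal(sum(wat[da$acceptors]), 1L)
})

test_that("cytosine exposes the N4 donor and the N3/O2 acceptor face", {
  s <- build_duplex("G")          # chain B holds the cytosine
  da <- assign_donors_acceptors(s)
  a <- s$atoms
  cyt <- a$res_name == "DC"
  expect_setequal(a$name[da$donors$donor[cyt[da$donors$donor]]], "N4")
  expect_setequal(a$name[da$acceptors[cyt[da$acceptors]]], c("N3", "O2"))
})

test_that("a hydrogen-free structure yields no donors but keeps acceptors, with a warning", {
  s <- build_duplex("AC")
  heavy <- s$atoms[toupper(s$atoms$element) != "H", ]
  heavy$serial <- seq_len(nrow(heavy))
  bare <- pdb_structure(heavy)
  expect_warning(da <- assign_donors_acceptors(bare), "no hydrogens")
  expect_equal(nrow(da$donors), 0L)
  expect_gt(length(da$acceptors), 0L)
})

test_that("a stray hydrogen with no parent heavy atom is a topology error", {
  s <- build_duplex("A")
  a <- s$atoms
  a <- rbind(a, data.frame(serial = max(a$serial) + 1L, name = "HX",
                           element = "H", res_name = "DA", res_seq = 1L,
                           chain_id = "A", x = 50, y = 50, z = 50,
                           record = "ATOM"))
  expect_error(assign_donors_acceptors(pdb_structure(a)), "1.2 A")
})

test_that("Watson-Crick pairs carry exactly 3 (G:C) and 2 (A:T) bonds", {
  expect_equal(nrow(detect_hbonds(build_duplex("G"))), 3L)
  expect_equal(nrow(detect_hbonds(build_duplex("A"))), 2L)
})

test_that("both geometric criteria are strict and individually binding", {
  # distance criterion fails: 3.5 A at perfect angle
  expect_equal(nrow(detect_hbonds(tiny_donor_acceptor(3.5, 0))), 0L)
  # angle criterion fails: 2.8 A at 25 degrees
  expect_equal(nrow(detect_hbonds(tiny_donor_acceptor(2.8, 25))), 0L)
  # both pass
  ev <- detect_hbonds(tiny_donor_acceptor(2.8, 10))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$distance, 2.8, tolerance = 1e-12)
  expect_equal(ev$angle, 10, tolerance = 1e-9)
  # boundary values are excluded (strict inequalities)
  expect_equal(nrow(detect_hbonds(tiny_donor_acceptor(3.0, 0))), 0L)
  expect_equal(nrow(detect_hbonds(tiny_donor_acceptor(2.8, 20))), 0L)
})

test_that("detection is invariant under a global rigid transform", {
  s <- place_bridging_water(build_toy_complex(build_duplex("GCATG"), 3), 3)
  ev <- detect_hbonds(s)
  R <- bindshift:::rot_axis_angle(c(1.2, 0.4, -0.8))
  moved <- set_coords(s, sweep(coords(s) %*% R, 2, -c(10, -4, 2)))
  ev2 <- detect_hbonds(moved)
  expect_equal(ev2[, c("donor", "hydrogen", "acceptor")],
               ev[, c("donor", "hydrogen", "acceptor")])
  expect_equal(ev2$distance, ev$distance, tolerance = 1e-9)
  expect_equal(ev2$angle, ev$angle, tolerance = 1e-6)
})

test_that("water bridges require the radius and both interface sides", {
  cx <- build_toy_complex(build_duplex("GCATG"), 3)
  s <- place_bridging_water(cx, 3)
  cen <- pair_centroid(s, 3)
  br <- detect_water_bridges(s, cen)
  expect_equal(nrow(br), 1L)
  ow <- which(s$atoms$name == "OW")
  expect_lt(bindshift:::vec_norm(coords(s)[ow, ] - cen), 10)

  # water moved 12 A away from the site: excluded by the radius
  xyz <- coords(s)
  wsel <- s$atoms$res_name == "HOH"
  xyz[wsel, ] <- sweep(xyz[wsel, ], 2, -c(12, 0, 0))
  expect_equal(nrow(detect_water_bridges(set_coords(s, xyz), cen)), 0L)

  # perturbing the water +3 A breaks the bond geometry itself
  xyz2 <- coords(s)
  xyz2[wsel, ] <- sweep(xyz2[wsel, ], 2, -c(0, 0, 3))
  moved <- detect_water_bridges(set_coords(s, xyz2), cen)
  expect_equal(nrow(moved), 0L)

  # no water at all: empty result with a warning
  expect_warning(none <- detect_water_bridges(cx, cen), "no water")
  expect_equal(nrow(none), 0L)
})

test_that("a water bonded to only one side is not a bridge", {
  s <- place_bridging_water(build_toy_complex(build_duplex("GCATG"), 3), 3)
  # strip the protein-facing hydrogen so only the DNA-side bond survives
  keep <- !(s$atoms$name == "HW2")
  a <- s$atoms[keep, ]; a$serial <- seq_len(nrow(a))
  s1 <- pdb_structure(a)
  ev <- detect_hbonds(s1)
  wat_side <- s1$atoms$res_name[ev$donor] == "HOH" |
    s1$atoms$res_name[ev$acceptor] == "HOH"
  expect_gt(sum(wat_side), 0L)
  expect_equal(nrow(detect_water_bridges(s1, pair_centroid(s1, 3))), 0L)
})

test_that("occupancy and duration statistics follow the run-length rule", {
  mk_frame <- function(present) {
    if (!present) return(bindshift:::empty_hbond_events())
    data.frame(donor = 1L, hydrogen = 2L, acceptor = 3L, distance = 2.8,
               angle = 5, frame = 0L, donor_label = "A:DA1:N6",
               acceptor_label = "B:DT1:O4", stringsAsFactors = FALSE)
  }
  # present in frames {0,1,2,5,6} of 10, dt = 1 ps
  pattern <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
               FALSE)
  st <- hbond_statistics(lapply(pattern, mk_frame), n_frames = 10, dt_ps = 1)
  expect_equal(st$summary$occupancy, 0.5)
  expect_equal(st$summary$n_events, 2L)
  expect_equal(st$summary$mean_duration_ps, 2.5)
  expect_equal(st$counts, as.integer(pattern))

  # continuous presence: one event spanning the whole trajectory
  st2 <- hbond_statistics(lapply(rep(TRUE, 10), mk_frame), 10, dt_ps = 1)
  expect_equal(st2$summary$occupancy, 1.0)
  expect_equal(st2$summary$n_events, 1L)
  expect_equal(st2$summary$mean_duration_ps, 10)

  # no events at all
  st3 <- hbond_statistics(lapply(rep(FALSE, 4), mk_frame), 4, dt_ps = 1)
  expect_equal(nrow(st3$summary), 0L)
  expect_equal(st3$counts, rep(0L, 4))
})

test_that("occupancies stay in [0,1] and durations bounded for random event streams", {
  set.seed(31)
  keys <- sprintf("bond%02d", 1:6)
  for (rep_i in 1:5) {
    nf <- sample(5:40, 1)
    dt <- runif(1, 0.5, 5)
    frames <- lapply(seq_len(nf), function(m) {
      on <- keys[runif(6) < 0.4]
      if (!length(on)) return(bindshift:::empty_hbond_events())
      data.frame(donor = 1L, hydrogen = 2L, acceptor = 3L, distance = 2.5,
                 angle = 1, frame = m - 1L, donor_label = on,
                 acceptor_label = "acc", stringsAsFactors = FALSE)
    })
    st <- hbond_statistics(frames, nf, dt)
    expect_true(all(st$summary$occupancy >= 0 & st$summary$occupancy <= 1))
    expect_true(all(st$summary$mean_duration_ps >= dt - 1e-12))
    tot <- st$summary$mean_duration_ps * st$summary$n_events
    expect_true(all(tot <= nf * dt + 1e-9))
    expect_equal(sum(st$counts), sum(vapply(frames, nrow, 1L)))
  }
})
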