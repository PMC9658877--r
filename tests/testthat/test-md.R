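make_test_traj <- function(seed = 70, n_frames = 6, sigma = 0.4,
                           rotation = 0) {
  fx <- fixture_pentamer(seed = seed)
  traj <- make_trajectory(fx$model, n_frames,
                          noise_schedule = rep(sigma, n_frames),
                          interdomain_rotation = rotation,
                          dmap = fx$chain$domain_map, seed = seed + 1)
  list(fx = fx, traj = traj)
}

test_that("read_trajectory round-trips multi-model PDB and checks inventories", {
  tt <- make_test_traj(n_frames = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tt$traj, path)
  back <- read_trajectory(path)
  expect_length(back$frames, 4L)
  expect_equal(coords(back$frames[[3]]),
               round(coords(tt$traj$frames[[3]]), 3), tolerance = 1e-12)
  # single-model file: one frame
  p1 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tt$fx$model, p1)
  expect_length(read_trajectory(p1)$frames, 1L)
  # drop one atom from model 3: format error naming the index
  lines <- readLines(path)
  atom_idx <- grep("^ATOM", lines)
  model_starts <- grep("^MODEL", lines)
  in_model3 <- atom_idx[atom_idx > model_starts[3]][1]
  writeLines(lines[-in_model3], path)
  expect_error(read_trajectory(path), "model 3")
})

test_that("rmsd_series behaves on identity, rigid motion, and noise", {
  tt <- make_test_traj(n_frames = 3, sigma = 0)
  rs <- rmsd_series(tt$traj)
  expect_equal(as.numeric(rs), rep(0, 3), tolerance = 1e-10)
  expect_equal(attr(rs, "label"), "low")
  # rigidly rotated frames fit back to ~0
  frames <- lapply(1:3, function(k) {
    R <- random_rotation()
    fr <- as.data.frame(tt$fx$model)
    fr[, c("x", "y", "z")] <- as.matrix(fr[, c("x", "y", "z")]) %*% t(R)
    assembly_model(fr)
  })
  rot_traj <- trajectory(frames)
  expect_lt(max(rmsd_series(rot_traj, reference = tt$fx$model)), 1e-8)
  # without fitting, the same frames are far away
  expect_gt(min(rmsd_series(rot_traj, reference = tt$fx$model, fit = FALSE)),
            1)
})

test_that("fitted rmsd never exceeds unfitted rmsd", {
  tt <- make_test_traj(n_frames = 5, sigma = 0.6, rotation = 8)
  fit <- rmsd_series(tt$traj, fit = TRUE)
  raw <- rmsd_series(tt$traj, fit = FALSE)
  expect_true(all(as.numeric(fit) <= as.numeric(raw) + 1e-9))
})

test_that("stability bands are exhaustive with boundaries in the larger band", {
  expect_equal(oligoqc:::stability_label(2.999), "low")
  expect_equal(oligoqc:::stability_label(3.0), "limited")
  expect_equal(oligoqc:::stability_label(5.999), "limited")
  expect_equal(oligoqc:::stability_label(6.0), "high")
})

test_that("per-domain series isolate the interdomain rotation mode", {
  tt <- make_test_traj(n_frames = 8, sigma = 0, rotation = 12)
  dm <- tt$fx$chain$domain_map
  fit_btb <- list(domain = "BTB", domain_map = dm, atom_names = "CA")
  btb <- rmsd_series(tt$traj, selection = fit_btb, fit_selection = fit_btb)
  ctd <- rmsd_series(tt$traj, selection = list(domain = "CTD",
                                               domain_map = dm,
                                               atom_names = "CA"),
                     fit_selection = fit_btb)
  expect_lt(max(btb), 1e-8)          # BTB does not move
  expect_gt(max(ctd), 0.5)           # CTD carries the rotation mode
  # global unfitted series sees the mode at the rotation extremes
  glob <- rmsd_series(tt$traj, fit = FALSE)
  expect_gt(max(glob), max(btb))
})

test_that("ss_series sums to 100 and degrades with noise", {
  tt <- make_test_traj(n_frames = 4, sigma = 0)
  ss <- ss_series(tt$traj)
  expect_equal(ss$H + ss$E + ss$C, rep(100, 4), tolerance = 1e-9)
  expect_gt(ss$H[1], 30)
  # progressive noise: H fraction trend non-increasing (Spearman <= 0)
  fx <- fixture_pentamer(seed = 71)
  sched <- seq(0, 3, length.out = 6)
  traj <- make_trajectory(fx$model, 6, noise_schedule = sched, seed = 72)
  h <- ss_series(traj)$H
  expect_lte(suppressWarnings(cor(h, seq_along(h), method = "spearman")), 0)
})

test_that("closest_to_average picks the constructed midpoint and breaks ties low", {
  fx <- fixture_pentamer(seed = 73)
  base <- fx$model
  # non-rigid displacement (chain A only) so superposition cannot absorb it
  shift <- function(m, dx) {
    fr <- as.data.frame(m)
    fr$x[fr$chain_id == "A"] <- fr$x[fr$chain_id == "A"] + dx
    assembly_model(fr)
  }
  traj3 <- trajectory(list(shift(base, -2), base, shift(base, 2)))
  expect_equal(as.integer(closest_to_average(traj3)), 2L)
  # identical frames: tie broken to index 1
  same <- trajectory(list(base, base, base))
  expect_equal(as.integer(closest_to_average(same)), 1L)
  # invariant under a global rigid motion of all frames
  R <- random_rotation()
  moved <- trajectory(lapply(traj3$frames, function(m) {
    fr <- as.data.frame(m)
    fr[, c("x", "y", "z")] <-
      sweep(as.matrix(fr[, c("x", "y", "z")]) %*% t(R), 2, c(3, 1, -2), `+`)
    assembly_model(fr)
  }))
  expect_equal(as.integer(closest_to_average(moved)), 2L)
})

test_that("analyze_trajectory assembles labels, series and closest frame", {
  tt <- make_test_traj(n_frames = 5, sigma = 0.3, rotation = 5)
  ta <- analyze_trajectory(tt$traj, domain_map = tt$fx$chain$domain_map)
  expect_named(ta$rmsd_series, c("global", "BTB", "CTD"))
  expect_length(ta$rmsd_series$global, 5L)
  expect_true(all(ta$stability_labels %in% c("low", "limited", "high")))
  expect_true(ta$closest_frame >= 1 && ta$closest_frame <= 5)
  expect_equal(nrow(ta$ss_fraction_series), 5L)
})
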