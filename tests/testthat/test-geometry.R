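test_that("estimate_symmetry returns 360/n on generator-perfect rings", {
  ch <- make_chain(synthetic_spec(btb = 12, hinge = 3, ctd = 16, seed = 50))
  for (n in 3:8) {
    m <- make_cn_assembly(ch$model, n, ring_radius = 16, seed = 51)
    sym <- estimate_symmetry(m, compute_interfaces = FALSE)
    expect_equal(sym$order, n)
    expect_lt(abs(sym$angle_per_step - 360 / n), 1e-6)
    expect_lt(sym$symmetry_rmsd, 1e-6)
    expect_equal(sqrt(sum(sym$axis^2)), 1, tolerance = 1e-8)
    expect_gt(abs(sym$axis[3]), 0.999)  # generator axis is z
  }
})

test_that("estimate_symmetry tolerates 0.2 A thermal noise within 1 degree", {
  ch <- make_chain(synthetic_spec(seed = 52))
  for (seed in 1:5) {
    m <- make_cn_assembly(ch$model, 5, 18, noise_sigma = 0.2, seed = seed)
    sym <- estimate_symmetry(m, compute_interfaces = FALSE)
    expect_lt(abs(sym$angle_per_step - 72), 1)
    expect_lt(sym$symmetry_rmsd, 1)
  }
})

test_that("estimate_symmetry rejects dissimilar chains", {
  ch <- make_chain(synthetic_spec(btb = 12, hinge = 3, ctd = 16, seed = 53))
  m <- make_cn_assembly(ch$model, 3, 16, seed = 54)
  scrambled <- as.data.frame(m)
  third <- scrambled$chain_id == "C"
  set.seed(99)
  scrambled[third, c("x", "y", "z")] <-
    matrix(rnorm(sum(third) * 3, 0, 25), ncol = 3)
  expect_error(estimate_symmetry(assembly_model(scrambled),
                                 compute_interfaces = FALSE),
               "not symmetric")
})

test_that("shrake_rupley matches closed forms and the high-density oracle", {
  # isolated atom: exactly 4*pi*(r+probe)^2 at any sampling density
  a1 <- shrake_rupley(matrix(0, 1, 3), "C")
  expect_equal(a1, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01 * a1)
  # two overlapping atoms vs 100k-point oracle
  xyz <- rbind(c(0, 0, 0), c(2.0, 0, 0))
  got <- sum(shrake_rupley(xyz, c("C", "O")))
  want <- oracle_sasa(xyz, c(1.70, 1.52))
  expect_equal(got, want, tolerance = 0.02 * want)
  # far-apart atoms: sum of isolated areas
  far <- rbind(c(0, 0, 0), c(100, 0, 0))
  expect_equal(sum(shrake_rupley(far, c("C", "C"))),
               2 * 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-9)
  expect_warning(shrake_rupley(matrix(0, 1, 3), "ZZ"), "unknown element")
})

test_that("interface_area is symmetric, zero at distance, and relabel-invariant", {
  fx <- fixture_pentamer(seed = 60)
  m <- fx$model
  ab <- as.numeric(interface_area(m, "A", "B", points = 240))
  ba <- as.numeric(interface_area(m, "B", "A", points = 240))
  expect_equal(ab, ba, tolerance = 1e-9)
  expect_gt(ab, 50)
  # chains 100 A apart bury nothing
  sep <- as.data.frame(select_atoms(m, chains = c("A", "B")))
  sep[sep$chain_id == "B", "x"] <- sep[sep$chain_id == "B", "x"] + 300
  expect_equal(as.numeric(interface_area(assembly_model(sep), "A", "B",
                                         points = 240)), 0)
  # total adjacent buried area invariant under chain relabeling
  sym <- estimate_symmetry(m, interface_points = 240)
  relab <- as.data.frame(m)
  relab$chain_id <- chartr("ABCDE", "CDEAB", relab$chain_id)
  sym2 <- estimate_symmetry(assembly_model(relab), interface_points = 240)
  expect_equal(sum(sym$interfaces$buried_area),
               sum(sym2$interfaces$buried_area), tolerance = 1e-6)
})

test_that("detect_open_assembly applies the relative+absolute rule", {
  fake_sym <- function(areas) {
    n <- length(areas)
    structure(list(order = n, ring_chains = LETTERS[1:n],
                   interfaces = data.frame(
                     chain_a = LETTERS[1:n],
                     chain_b = LETTERS[c(2:n, 1)],
                     buried_area = areas)),
              class = "symmetry_estimate")
  }
  r <- detect_open_assembly(NULL, fake_sym(c(800, 820, 790, 810, 150)))
  expect_true(r$open)
  expect_equal(sort(r$weakest_pair), c("A", "E"))
  expect_false(detect_open_assembly(NULL, fake_sym(rep(805, 5)))$open)
  # uniformly small but intact interfaces stay closed (conjunctive rule)
  expect_false(detect_open_assembly(NULL, fake_sym(rep(90, 5)))$open)
})

test_that("open and closed generated rings are classified correctly", {
  closed <- fixture_pentamer(seed = 61, noise = 0.2)
  sym_c <- estimate_symmetry(closed$model, interface_points = 240)
  expect_true(sym_c$closed)
  open_ <- fixture_pentamer(seed = 62, noise = 0.2, open = 15)
  sym_o <- estimate_symmetry(open_$model, interface_points = 240)
  expect_false(sym_o$closed)
  oc <- detect_open_assembly(open_$model, sym_o)
  expect_true("E" %in% oc$weakest_pair)  # the displaced chain
})

test_that("pore_profile matches closed forms and is rigid-motion invariant", {
  # ring of carbons at cylinder radius 10: slab radius 10 - 1.7 = 8.3
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- data.frame(serial = 1:36, atom_name = "CA", residue_name = "ALA",
                     chain_id = rep(c("A", "B", "C"), each = 12),
                     residue_number = rep(1:12, 3),
                     x = rep(10 * cos(th), 3), y = rep(10 * sin(th), 3),
                     z = rep(c(-3, 0, 3), each = 12),
                     occupancy = 1, bfactor = 50, element = "C")
  rm <- assembly_model(ring)
  sym <- list(axis = c(0, 0, 1), center = c(0, 0, 0))
  pp <- pore_profile(rm, sym)
  expect_equal(pp$min_radius, 8.3, tolerance = 1e-9)
  mid <- pp$samples$radius[pp$samples$z == 0]
  expect_equal(mid, 8.3, tolerance = 1e-9)
  # empty slabs (between the rings) report max_radius
  expect_true(any(pp$samples$radius == 30))
  # rigid motion leaves the sorted radius profile unchanged
  fx <- fixture_pentamer(seed = 63)
  s1 <- estimate_symmetry(fx$model, compute_interfaces = FALSE)
  p1 <- pore_profile(fx$model, s1)
  R <- random_rotation()
  moved <- as.data.frame(fx$model)
  xyz <- sweep(as.matrix(moved[, c("x", "y", "z")]) %*% t(R), 2,
               c(11, -4, 7), `+`)
  moved[, c("x", "y", "z")] <- xyz
  m2 <- assembly_model(moved)
  s2 <- estimate_symmetry(m2, compute_interfaces = FALSE)
  p2 <- pore_profile(m2, s2)
  expect_equal(p1$samples$radius, p2$samples$radius, tolerance = 1e-6)
  expect_equal(p1$min_radius, p2$min_radius, tolerance = 1e-6)
})

test_that("assign_ss recognizes ideal helices, strands, and short chains", {
  helix <- oligoqc:::ideal_helix(12)
  expect_true(all(assign_ss(helix) == "H"))
  strand <- oligoqc:::ideal_strand(10, c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_true(all(assign_ss(strand) == "E"))
  short <- matrix(rnorm(12), 4, 3)
  expect_true(all(assign_ss(short) == "C"))
  # chain gaps break runs and are flagged
  gap_chain <- rbind(helix, sweep(helix, 2, c(50, 0, 0), `+`))
  ss <- assign_ss(gap_chain)
  expect_true(12 %in% attr(ss, "gaps"))
})

test_that("assign_ss recovers >= 90% of generator ground truth", {
  for (seed in c(1, 7, 13)) {
    ch <- make_chain(synthetic_spec(seed = seed))
    ss <- assign_ss(ch$model)
    expect_gte(mean(ss == ch$ss), 0.9)
  }
  # determinism
  ch <- make_chain(synthetic_spec(seed = 3))
  expect_identical(assign_ss(ch$model), assign_ss(ch$model))
})
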