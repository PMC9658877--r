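two_chain_map <- domain_map(data.frame(domain = c("BTB", "hinge", "CTD"),
                                       start = c(1, 13, 16),
                                       end = c(12, 15, 30)))
two_chain_seg <- data.frame(chain_id = c("A", "B"),
                            residue_count = c(30L, 30L))

test_that("read_pae accepts both JSON dialects and they agree", {
  set.seed(42)
  vals <- matrix(runif(9, 0, 20), 3, 3)
  diag(vals) <- 0.4
  p_nested <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(predicted_aligned_error = vals), p_nested,
                       digits = 8, matrix = "rowmajor")
  p_triplet <- withr::local_tempfile(fileext = ".json")
  idx <- expand.grid(r1 = 1:3, r2 = 1:3)
  jsonlite::write_json(list(residue1 = idx$r1, residue2 = idx$r2,
                            distance = vals[cbind(idx$r1, idx$r2)]),
                       p_triplet, digits = 8)
  seg <- data.frame(chain_id = "A", residue_count = 3L)
  m1 <- read_pae(p_nested, seg)
  m2 <- read_pae(p_triplet, seg)
  expect_equal(m1$values, m2$values, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(m1$values[1, 3], vals[1, 3], tolerance = 1e-7)

  p_bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(pae = list(1:4, 1:4, 1:4)), p_bad)
  expect_error(read_pae(p_bad, seg), "square|lengths")
  p_keys <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(foo = 1, bar = 2), p_keys)
  expect_error(read_pae(p_keys, seg), "dialect error.*foo.*bar")
})

test_that("pae_matrix validates shape, segmentation and diagonal", {
  expect_error(pae_matrix(matrix(1, 3, 4), two_chain_seg), "square")
  expect_error(pae_matrix(matrix(1, 60, 60),
                          data.frame(chain_id = "A", residue_count = 10L)),
               "segmentation")
  big_diag <- matrix(1, 4, 4); diag(big_diag) <- 20
  expect_warning(pae_matrix(big_diag,
                            data.frame(chain_id = "A", residue_count = 4L)),
                 "dialect")
})

test_that("block_fractions handles uniform matrices and strict thresholds", {
  mk <- function(fill) {
    v <- matrix(fill, 60, 60); diag(v) <- 0.5
    pae_matrix(v, two_chain_seg)
  }
  b0 <- block_fractions(mk(0), two_chain_map)
  expect_true(all(b0$fraction_below == 100))
  b20 <- block_fractions(mk(20), two_chain_map)
  expect_true(all(b20$fraction_below == 0))
  # entries exactly at the threshold are NOT below it
  b10 <- block_fractions(mk(10), two_chain_map)
  expect_true(all(b10$fraction_below == 0))
  b_under <- block_fractions(mk(10 - 1e-9), two_chain_map)
  expect_true(all(b_under$fraction_below == 100))
})

test_that("block_fractions equals the brute-force oracle on random matrices", {
  for (seed in 1:8) {
    set.seed(seed)
    v <- matrix(runif(60 * 60, 0, 20), 60, 60)
    diag(v) <- 0.5
    pm <- pae_matrix(v, two_chain_seg)
    got <- as.data.frame(block_fractions(pm, two_chain_map))
    got <- got[order(got$block), ]
    chain_of <- rep(1:2, each = 30)
    dom_of <- rep(c(rep("BTB", 12), rep("hinge", 3), rep("CTD", 15)), 2)
    want <- oracle_block_fractions(v, chain_of, dom_of)
    expect_equal(got$block, want$block)
    expect_equal(got$pair_count, want$pair_count)
    expect_equal(got$fraction_below, want$fraction_below, tolerance = 1e-12)
  }
})

test_that("block_fractions is invariant under chain-respecting permutations", {
  set.seed(9)
  v <- matrix(runif(60 * 60, 0, 20), 60, 60); diag(v) <- 0.5
  pm <- pae_matrix(v, two_chain_seg)
  base <- as.data.frame(block_fractions(pm, two_chain_map))
  # swap the two chains wholesale (same intra-chain order)
  perm <- c(31:60, 1:30)
  pm2 <- pae_matrix(v[perm, perm], two_chain_seg)
  swapped <- as.data.frame(block_fractions(pm2, two_chain_map))
  expect_equal(base[order(base$block), ], swapped[order(swapped$block), ],
               ignore_attr = TRUE)
})

test_that("raising the threshold never decreases any fraction", {
  set.seed(10)
  v <- matrix(runif(60 * 60, 0, 25), 60, 60); diag(v) <- 0.5
  pm <- pae_matrix(v, two_chain_seg)
  prev <- rep(0, 5)
  for (thr in c(2, 5, 10, 15, 22)) {
    cfg <- analysis_config(pae_threshold = thr)
    cur <- block_fractions(pm, two_chain_map, cfg)$fraction_below
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("classify_reliability applies strict boundaries and monotonicity", {
  mk_blocks <- function(intra, inter) {
    structure(data.frame(
      block = c("intra-BTB", "intra-CTD", "inter-BTB", "inter-CTD"),
      pair_count = rep(100L, 4),
      fraction_below = c(intra, intra, inter, inter)),
      class = c("block_statistics", "data.frame"))
  }
  expect_equal(classify_reliability(mk_blocks(100, 100))$grade, "R")
  expect_equal(classify_reliability(mk_blocks(100, 100))$stability, "S")
  # exactly 65.0% is NOT "higher than 65%"
  at_boundary <- classify_reliability(mk_blocks(90, 65))
  expect_equal(at_boundary$grade, "PR")
  just_above <- classify_reliability(mk_blocks(90, 65 + 1e-9))
  expect_equal(just_above$grade, "R")
  # low inter with good intra under the PR band: unstable
  low <- classify_reliability(mk_blocks(90, 20))
  expect_equal(low$grade, "U")
  expect_equal(low$stability, "U")
  # exactly 40.0% inter is not "higher than 40%"
  expect_equal(classify_reliability(mk_blocks(90, 40))$grade, "U")
  # monotone: elementwise-increasing fractions never demote
  rank_of <- c(U = 1, PR = 2, R = 3)
  set.seed(11)
  for (i in 1:20) {
    f <- runif(2, 0, 100)
    g1 <- classify_reliability(mk_blocks(f[1], f[2]))$grade
    bump <- runif(2, 0, 100 - f)
    g2 <- classify_reliability(mk_blocks(f[1] + bump[1], f[2] + bump[2]))$grade
    expect_gte(rank_of[[g2]], rank_of[[g1]])
  }
})

test_that("grading recovers the intended regime from generated matrices", {
  fx <- fixture_pentamer(seed = 20)
  seg <- segmentation(fx$model)
  dm <- fx$chain$domain_map
  good <- make_pae(seg, dm, list(inter_btb = 6, inter_ctd = 6), 1, seed = 21)
  expect_equal(classify_reliability(block_fractions(good, dm))$grade, "R")
  bad <- make_pae(seg, dm, list(inter_btb = 25, inter_ctd = 25, cross = 25),
                  1, seed = 22)
  expect_equal(classify_reliability(block_fractions(bad, dm))$grade, "U")
})

test_that("infer_substoichiometry finds planted components and matches the oracle", {
  fx <- fixture_pentamer(seed = 30)
  seg <- segmentation(fx$model)
  dm <- fx$chain$domain_map
  # all quadrants confident: single pentamer
  all_low <- make_pae(seg, dm, list(cross = 4, hinge = 4), 0.5, seed = 31)
  r_all <- infer_substoichiometry(all_low)
  expect_length(r_all$components, 1L)
  expect_false(r_all$dimer_propensity)
  # planted {A,B} and {C,D} dimers
  dimers <- make_pae(seg, dm,
                     list(inter_btb = 25, inter_ctd = 25, cross = 25,
                          chain_pairs = list("A:B" = 4, "C:D" = 4)),
                     1, seed = 32)
  r_dim <- infer_substoichiometry(dimers)
  expect_true(r_dim$dimer_propensity)
  expect_equal(r_dim$label, "dimer propensity")
  expect_equal(lapply(r_dim$components, sort),
               list(c("A", "B"), c("C", "D"), "E"))
  # random edge patterns agree with the reachability oracle
  for (seed in 1:10) {
    set.seed(seed)
    n <- 5L
    pairs <- t(combn(n, 2))
    on <- runif(nrow(pairs)) < 0.4
    cp <- lapply(seq_len(nrow(pairs))[on], function(k) 4)
    names(cp) <- sprintf("%s:%s", LETTERS[pairs[on, 1]], LETTERS[pairs[on, 2]])
    pm <- make_pae(seg, dm,
                   list(inter_btb = 25, inter_ctd = 25, cross = 25,
                        chain_pairs = cp),
                   0.5, seed = seed + 500)
    got <- infer_substoichiometry(pm)$components
    adj <- matrix(FALSE, n, n)
    adj[pairs[on, , drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    want <- oracle_components(adj, LETTERS[1:n])
    expect_equal(lapply(got, sort), lapply(want, sort))
  }
  one_seg <- data.frame(chain_id = "A", residue_count = 10L)
  one <- pae_matrix(matrix(1, 10, 10), one_seg)
  expect_error(infer_substoichiometry(one), ">= 2 chains")
})
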