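# Synthetic-data generators: Cn-symmetric multi-domain assemblies with known
# secondary structure, block-structured PAE matrices, and trajectories with a
# BTB-vs-CTD inter-domain rotation mode. Every generator is a pure function
# of (spec, seed) so fixtures are reproducible byte for byte.

#' Specification for the synthetic generators
#'
#' Defaults describe the "stated world" the analyses assume: a C5 ring of
#' two-domain chains (helical BTB-like body, strand-bearing CTD-like body),
#' confident intra-domain PAE blocks around 4 A versus configurable
#' inter-chain blocks, 0.2 A thermal coordinate noise on assemblies, and a
#' 1 A PAE noise scale.
#'
#' @param n_chains number of subunits (default 5).
#' @param btb,hinge,ctd residues per domain (defaults 40, 5, 40; BTB and CTD
#'   must be >= 8, hinge may be 0).
#' @param ring_radius ring placement radius in Angstrom (default 18).
#' @param noise_sigma per-coordinate Gaussian noise on assemblies (default
#'   0.2 A).
#' @param pae_block_means named list of block means in Angstrom; recognized
#'   names `intra_btb`, `intra_ctd`, `inter_btb`, `inter_ctd`, `cross`,
#'   `hinge`, plus optional `chain_pairs` (named list `"A:B" = mean`
#'   overriding whole inter-chain quadrants).
#' @param pae_noise Gaussian noise on PAE entries (default 1 A).
#' @param open_displacement radial displacement of the last chain in Angstrom
#'   (default 0 = closed ring).
#' @param interdomain_rotation amplitude (degrees) of the CTD-vs-BTB rotation
#'   mode in trajectories (default 0).
#' @param seed integer seed; fixed seed implies byte-identical outputs.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_chains = 5L, btb = 40L, hinge = 5L, ctd = 40L,
                           ring_radius = 18, noise_sigma = 0.2,
                           pae_block_means = list(), pae_noise = 1,
                           open_displacement = 0, interdomain_rotation = 0,
                           seed = 1L) {
  defaults <- list(intra_btb = 4, intra_ctd = 4, inter_btb = 6, inter_ctd = 6,
                   cross = 8, hinge = 12)
  pae_block_means <- utils::modifyList(defaults, pae_block_means)
  if (n_chains < 1L) stop("n_chains must be >= 1")
  if (noise_sigma < 0 || pae_noise < 0) stop("noise scales must be >= 0")
  structure(list(n_chains = as.integer(n_chains), btb = as.integer(btb),
                 hinge = as.integer(hinge), ctd = as.integer(ctd),
                 ring_radius = ring_radius, noise_sigma = noise_sigma,
                 pae_block_means = pae_block_means, pae_noise = pae_noise,
                 open_displacement = open_displacement,
                 interdomain_rotation = interdomain_rotation,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

ideal_helix <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  i <- seq_len(n) - 1L
  th <- deg2rad(twist) * i
  cbind(radius * cos(th), radius * sin(th), rise * i)
}

# extended strand along unit direction u, zig-zag along v
ideal_strand <- function(n, origin, u, v, spacing = 3.35, amp = 0.95) {
  i <- seq_len(n) - 1L
  sweep(outer(i * spacing, u) + outer(amp * (-1)^i, v), 2L, origin, `+`)
}

# straight connector of n points from a (exclusive) to b (exclusive)
connector <- function(n, a, b) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  f <- seq_len(n) / (n + 1L)
  sweep(outer(f, b - a), 2L, a, `+`)
}

ca_atom_rows <- function(xyz, chain, start_res, bfac) {
  n <- nrow(xyz)
  data.frame(serial = seq_len(n), atom_name = "CA", altloc = "",
             residue_name = "ALA", chain_id = chain,
             residue_number = start_res + seq_len(n) - 1L,
             insertion_code = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = 1, bfactor = bfac, element = "C",
             stringsAsFactors = FALSE)
}

#' Generate one synthetic two-domain chain
#'
#' A Calpha-only chain: an ideal alpha-helix for the BTB-like body, a
#' connector hinge, then a strand-hairpin CTD-like body (two extended strands
#' joined by a turn, trailing residues as coil). Synthetic pLDDT values
#' (Normal(85, 5) clipped to \[0, 100\]) are stored in the B-factor column.
#'
#' @param spec a [synthetic_spec()] (uses `btb`, `hinge`, `ctd`, `seed`).
#' @return list with `model` (single-chain [assembly_model()]), `ss`
#'   (ground-truth per-residue codes), `domain_map`.
#' @export
make_chain <- function(spec = synthetic_spec()) {
  if (spec$btb < 8L || spec$ctd < 8L)
    stop("btb and ctd must each have >= 8 residues")
  if (spec$hinge < 0L) stop("hinge must be >= 0 residues")
  set.seed(spec$seed)
  helix <- ideal_helix(spec$btb)
  # CTD frame: strands run perpendicular to the helix axis
  u <- c(1, 0, 0); v <- c(0, 1, 0)
  k <- max(6L, (spec$ctd - 4L) %/% 2L)
  k <- min(k, spec$ctd %/% 2L)
  n_turn <- 4L
  leftover <- spec$ctd - 2L * k - n_turn
  if (leftover < 0L) { n_turn <- n_turn + leftover; leftover <- 0L }
  # keep the BTB->CTD step short enough that a zero-length hinge has no gap
  ctd_origin <- helix[spec$btb, ] +
    if (spec$hinge > 0L) c(6, 0, 4) else c(2.2, 0, 2.2)
  s1 <- ideal_strand(k, ctd_origin, u, v)
  s2_origin <- s1[k, ] + c(0, 8, 0)
  s2 <- ideal_strand(k, s2_origin, -u, v)
  turn <- connector(n_turn, s1[k, ], s2_origin + 0)  # arc approximated by line
  tail_pts <- if (leftover > 0L) {
    dir_ <- unit(c(0.3, 0.6, 0.74))
    sweep(outer(seq_len(leftover) * 3.4, dir_), 2L, s2[k, ], `+`)
  } else matrix(numeric(0), 0, 3)
  hinge_pts <- connector(spec$hinge, helix[spec$btb, ], ctd_origin)
  xyz <- rbind(helix, hinge_pts, s1, turn, s2, tail_pts)
  ss <- c(rep("H", spec$btb), rep("C", spec$hinge), rep("E", k),
          rep("C", n_turn), rep("E", k), rep("C", leftover))
  n <- nrow(xyz)
  stopifnot(length(ss) == n)
  plddt <- pmin(100, pmax(0, stats::rnorm(n, 85, 5)))
  model <- assembly_model(ca_atom_rows(xyz, "A", 1L, round(plddt, 2)))
  dm_entries <- data.frame(domain = "BTB", start = 1L, end = spec$btb)
  if (spec$hinge > 0L)
    dm_entries <- rbind(dm_entries, data.frame(
      domain = "hinge", start = spec$btb + 1L, end = spec$btb + spec$hinge))
  dm_entries <- rbind(dm_entries, data.frame(
    domain = "CTD", start = spec$btb + spec$hinge + 1L, end = n))
  list(model = model, ss = ss, domain_map = domain_map(dm_entries))
}

#' Assemble n noisy copies of a chain into a Cn ring
#'
#' Copies are placed by exact 360/n-degree rotations about the z axis at
#' `ring_radius`, then perturbed by iid Gaussian coordinate noise. With
#' `open_displacement > 0` the last chain is additionally translated radially
#' outward, breaking its two ring contacts (an "open" assembly).
#'
#' @param chain single-chain [assembly_model()] (e.g. from [make_chain()]).
#' @param n number of subunits.
#' @param ring_radius placement radius (Angstrom).
#' @param noise_sigma iid per-coordinate Gaussian noise (Angstrom).
#' @param open_displacement radial displacement of the last chain (Angstrom).
#' @param seed integer seed.
#' @return an [assembly_model()] with chains `A`, `B`, ...
#' @export
make_cn_assembly <- function(chain, n = 5L, ring_radius = 18,
                             noise_sigma = 0, open_displacement = 0,
                             seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  set.seed(seed)
  base <- coords(chain)
  base <- sweep(base, 2L, colMeans(base))
  base <- sweep(base, 2L, c(ring_radius, 0, 0), `+`)
  rows <- list()
  for (kk in seq_len(n)) {
    R <- rotation_about(c(0, 0, 1), 360 * (kk - 1L) / n)
    xyz <- base %*% t(R)
    if (kk == n && open_displacement > 0) {
      cen <- colMeans(xyz)
      radial <- unit(c(cen[1], cen[2], 0))
      xyz <- sweep(xyz, 2L, radial * open_displacement, `+`)
    }
    if (noise_sigma > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise_sigma),
                          ncol = 3L)
    at <- as.data.frame(chain)
    at$chain_id <- LETTERS[kk]
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    rows[[kk]] <- at
  }
  assembly_model(do.call(rbind, rows))
}

pae_class_matrix <- function(segmentation, dmap, residues = NULL) {
  chain_idx <- seg_chain_index(segmentation)
  resno <- seg_residue_numbers(segmentation, residues)
  dom <- domain_of_residues(dmap, resno)
  L <- length(chain_idx)
  same_chain <- outer(chain_idx, chain_idx, `==`)
  cls <- matrix("cross", L, L)
  for (d in c("BTB", "CTD")) {
    in_d <- dom %in% d
    both <- outer(in_d, in_d, `&`)
    cls[both & same_chain] <- paste0("intra_", tolower(d))
    cls[both & !same_chain] <- paste0("inter_", tolower(d))
  }
  hinge_involved <- outer(dom %in% "hinge" | is.na(dom),
                          rep(TRUE, L), `&`)
  cls[hinge_involved | t(hinge_involved)] <- "hinge"
  cls
}

#' Generate a block-structured PAE matrix
#'
#' Entry (i, j) is drawn as max(0, Normal(block mean, `pae_noise`)) where the
#' block class is determined by the chains and domains of i and j; the
#' diagonal is set to 0.5 A and the matrix is left unsymmetrized, as real
#' PAE dialects are. Whole inter-chain quadrants can be overridden per chain
#' pair via `block_means$chain_pairs` (e.g. `list("A:B" = 4)`), emulating the
#' low-error off-diagonal quadrants that signal dimer propensity.
#'
#' @param segmentation data frame `chain_id`, `residue_count`.
#' @param dmap a [domain_map()].
#' @param block_means named list of means (see [synthetic_spec()]).
#' @param pae_noise Gaussian sd in Angstrom.
#' @param seed integer seed.
#' @return a [pae_matrix()].
#' @export
make_pae <- function(segmentation, dmap, block_means = list(), pae_noise = 1,
                     seed = 1L) {
  block_means <- utils::modifyList(
    list(intra_btb = 4, intra_ctd = 4, inter_btb = 6, inter_ctd = 6,
         cross = 8, hinge = 12), block_means)
  set.seed(seed)
  cls <- pae_class_matrix(segmentation, dmap)
  L <- nrow(cls)
  mean_mat <- matrix(unlist(block_means[cls], use.names = FALSE), L, L)
  pairs <- block_means$chain_pairs
  if (!is.null(pairs)) {
    chain_idx <- seg_chain_index(segmentation)
    ids <- segmentation$chain_id
    for (nm in names(pairs)) {
      ab <- strsplit(nm, ":", fixed = TRUE)[[1]]
      ia <- which(chain_idx == match(ab[1], ids))
      ib <- which(chain_idx == match(ab[2], ids))
      mean_mat[ia, ib] <- pairs[[nm]]
      mean_mat[ib, ia] <- pairs[[nm]]
    }
  }
  vals <- mean_mat + matrix(stats::rnorm(L * L, 0, pae_noise), L, L)
  vals[vals < 0] <- 0
  diag(vals) <- 0.5
  pae_matrix(vals, segmentation)
}

#' Generate a trajectory with an inter-domain rotation mode
#'
#' Frame t carries the CTD atoms of every chain rotated about the z symmetry
#' axis by `interdomain_rotation * sin(2*pi*(t-1)/n_frames)` degrees plus iid
#' Gaussian noise `noise_schedule[t]`; frame 1 is the unperturbed starting
#' model (emulating relative BTB/CTD rotation on top of thermal noise).
#'
#' @param model starting [assembly_model()] in the generator frame (ring axis
#'   = z through the origin).
#' @param n_frames number of frames.
#' @param noise_schedule numeric vector of per-frame noise sigmas (length
#'   `n_frames`; entry 1 is ignored, frame 1 stays exact).
#' @param interdomain_rotation amplitude in degrees.
#' @param dmap a [domain_map()] locating the CTD.
#' @param seed integer seed.
#' @return a [trajectory()].
#' @export
make_trajectory <- function(model, n_frames, noise_schedule = NULL,
                            interdomain_rotation = 0, dmap = NULL,
                            seed = 1L) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  noise_schedule <- noise_schedule %||% rep(0, n_frames)
  if (length(noise_schedule) != n_frames)
    stop("noise_schedule length must equal n_frames")
  set.seed(seed)
  ctd_mask <- rep(FALSE, nrow(model))
  if (interdomain_rotation != 0) {
    if (is.null(dmap)) stop("interdomain rotation requires a domain map")
    rng <- domain_range(dmap, "CTD")
    for (k in seq_len(nrow(rng)))
      ctd_mask <- ctd_mask | (model$residue_number >= rng$start[k] &
                              model$residue_number <= rng$end[k])
  }
  base <- coords(model)
  frames <- vector("list", n_frames)
  frames[[1]] <- model
  for (t in seq_len(n_frames)[-1L]) {
    xyz <- base
    phase <- sin(2 * pi * (t - 1L) / n_frames)
    if (interdomain_rotation != 0 && phase != 0) {
      R <- rotation_about(c(0, 0, 1), interdomain_rotation * phase)
      xyz[ctd_mask, ] <- xyz[ctd_mask, , drop = FALSE] %*% t(R)
    }
    if (noise_schedule[t] > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise_schedule[t]),
                          ncol = 3L)
    fr <- as.data.frame(model)
    fr$x <- xyz[, 1]; fr$y <- xyz[, 2]; fr$z <- xyz[, 3]
    frames[[t]] <- assembly_model(fr, model_id = t)
  }
  trajectory(frames)
}

#' Write a complete synthetic fixture set
#'
#' Emits, under `dir` with prefix `id`: `<id>_model.pdb`, `<id>_pae.json`
#' (nested-list dialect), `<id>_domains.tsv`, optionally `<id>_traj.pdb`
#' (when `n_frames > 1`), and `<id>_truth.json` holding the generator's
#' ground-truth labels (grade, stability, closed, order, angle).
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @param id fixture prefix (default "synthetic").
#' @param n_frames trajectory frames (default 1 = no trajectory file).
#' @return invisibly, the list of written paths plus the truth record.
#' @export
write_fixture_set <- function(spec, dir, id = "synthetic", n_frames = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ch <- make_chain(spec)
  model <- make_cn_assembly(ch$model, spec$n_chains, spec$ring_radius,
                            spec$noise_sigma, spec$open_displacement,
                            seed = spec$seed + 1L)
  seg <- segmentation(model)
  pae <- make_pae(seg, ch$domain_map, spec$pae_block_means, spec$pae_noise,
                  seed = spec$seed + 2L)
  paths <- list(
    model = file.path(dir, paste0(id, "_model.pdb")),
    pae = file.path(dir, paste0(id, "_pae.json")),
    domains = file.path(dir, paste0(id, "_domains.tsv")),
    truth = file.path(dir, paste0(id, "_truth.json")))
  write_structure(model, paths$model)
  jsonlite::write_json(list(pae = pae$values), paths$pae, digits = 4,
                       matrix = "rowmajor")
  write_domain_map(ch$domain_map, paths$domains, protein = id)
  if (n_frames > 1L) {
    paths$traj <- file.path(dir, paste0(id, "_traj.pdb"))
    traj <- make_trajectory(model, n_frames,
                            noise_schedule = rep(spec$noise_sigma, n_frames),
                            interdomain_rotation = spec$interdomain_rotation,
                            dmap = ch$domain_map, seed = spec$seed + 3L)
    write_trajectory(traj, paths$traj)
  }
  exp_grade <- expected_grade(spec)
  truth <- list(id = id, grade = exp_grade,
                stability = if (exp_grade %in% c("R", "PR")) "S" else "U",
                closed = spec$open_displacement <= 0,
                order = spec$n_chains,
                angle = 360 / spec$n_chains,
                seed = spec$seed)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE)
  invisible(list(paths = paths, truth = truth))
}

#' Expected reliability grade of a synthetic regime
#'
#' Closed-form ground truth for [write_fixture_set()]: the expected
#' confident-pair percentage of each block under Normal(mean, `pae_noise`)
#' entries is `100 * pnorm((threshold - mean) / pae_noise)`, and the grading
#' rule is applied to those expectations. Independent of the matrix actually
#' drawn, so recovery tests are not circular.
#'
#' @param spec a [synthetic_spec()].
#' @param config an [analysis_config()] supplying the thresholds.
#' @return `"R"`, `"PR"` or `"U"`.
#' @export
expected_grade <- function(spec, config = analysis_config()) {
  m <- spec$pae_block_means
  expect_pct <- function(mean_) {
    if (spec$pae_noise <= 0) return(100 * (mean_ < config$pae_threshold))
    100 * stats::pnorm((config$pae_threshold - mean_) / spec$pae_noise)
  }
  intra <- vapply(c("intra_btb", "intra_ctd"), function(k) expect_pct(m[[k]]),
                  numeric(1))
  inter <- vapply(c("inter_btb", "inter_ctd"), function(k) expect_pct(m[[k]]),
                  numeric(1))
  rp <- config$reliable_percent; pp <- config$partial_percent
  if (all(c(intra, inter) > rp)) "R"
  else if (all(intra > rp) && all(inter > pp)) "PR"
  else "U"
}

#' Write a trajectory as a multi-model PDB
#' @param traj a [trajectory()].
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(pdb_lines_for_model(traj$frames[[k]]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(NULL)
}
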