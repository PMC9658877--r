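# Rigid-body fitting: closed-form Kabsch superposition, iterative outlier
# rejection, and symmetry-aware whole-oligomer alignment with a chain-mapping
# search (cyclic shifts or exhaustive bijections).

superposition_result <- function(rotation, translation, rmsd, atoms_aligned,
                                 chain_mapping = NULL, cycles = 1L,
                                 retained = NULL, notes = character(0)) {
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 rmsd = rmsd, atoms_aligned = as.integer(atoms_aligned),
                 chain_mapping = chain_mapping, cycles = as.integer(cycles),
                 retained = retained, notes = notes),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition_result> rmsd=%.4f A over %d atoms (%d cycle%s)\n",
              x$rmsd, x$atoms_aligned, x$cycles, if (x$cycles == 1) "" else "s"))
  if (!is.null(x$chain_mapping))
    cat("  mapping:", paste(names(x$chain_mapping), x$chain_mapping,
                            sep = "->", collapse = " "), "\n")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

as_coord_matrix <- function(x) {
  if (inherits(x, "assembly_model")) x <- coords(x)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("coordinates must be an n x 3 matrix")
  x
}

apply_transform <- function(xyz, fit) {
  sweep(as_coord_matrix(xyz) %*% t(fit$rotation), 2L, -fit$translation)
}

rmsd_of <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares proper rotation and translation mapping `mobile` onto
#' `target`; correspondence is given by row order. The reflection case is
#' resolved to det(R) = +1, so mirror images fit with nonzero residual.
#'
#' @param mobile,target n x 3 coordinate matrices (or `assembly_model`s, whose
#'   coordinates are taken in atom order), n >= 3.
#' @return a `superposition_result` with `rotation` (3x3, det +1),
#'   `translation` (x' = R x + t), `rmsd`, `atoms_aligned`. Degenerate
#'   (collinear) inputs are flagged in `notes` but still solved.
#' @export
kabsch_fit <- function(mobile, target) {
  A <- as_coord_matrix(mobile); B <- as_coord_matrix(target)
  if (nrow(A) != nrow(B)) stop("point sets differ in length")
  n <- nrow(A)
  if (n < 3L) stop("at least 3 points are required")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca); B0 <- sweep(B, 2L, cb)
  H <- crossprod(A0, B0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cb - as.numeric(R %*% ca)
  fitted <- sweep(A %*% t(R), 2L, -tvec)
  notes <- character(0)
  # collinear/degenerate: second singular value of the centered set ~ 0
  if (svd(A0, nu = 0, nv = 0)$d[2] < 1e-8 * max(svd(A0, nu = 0, nv = 0)$d[1], 1))
    notes <- c(notes, "degenerate (collinear) point set")
  superposition_result(R, tvec, rmsd_of(fitted, B), n, cycles = 1L,
                       retained = rep(TRUE, n), notes = notes)
}

#' Superposition with iterative outlier rejection
#'
#' Repeats: fit on the retained pairs, compute per-pair deviations, drop pairs
#' deviating more than the mean plus `reject_sigma` times the standard
#' deviation of the current deviations, refit. Stops when the retained set is
#' unchanged or
#' after `max_cycles`. The final `rmsd` and `atoms_aligned` cover the retained
#' pairs only. A floor of 0.01 Angstrom on the rejection cutoff (when
#' `reject_sigma > 0`) keeps numerically exact fits from rejecting everything.
#'
#' @inheritParams kabsch_fit
#' @param max_cycles maximum refinement cycles (default 5).
#' @param reject_sigma rejection multiplier (default 2). `0` rejects all pairs
#'   immediately and falls back to the plain fit with a warning.
#' @return a `superposition_result`; `retained` is the logical inlier mask.
#' @export
refine_fit <- function(mobile, target, max_cycles = 5L, reject_sigma = 2.0) {
  A <- as_coord_matrix(mobile); B <- as_coord_matrix(target)
  if (nrow(A) != nrow(B)) stop("point sets differ in length")
  n <- nrow(A)
  keep <- rep(TRUE, n)
  fit <- kabsch_fit(A, B)
  cycles <- 1L
  repeat {
    dev <- sqrt(rowSums((apply_transform(A, fit) - B)^2))
    spread <- stats::sd(dev[keep])
    if (is.na(spread)) spread <- 0
    # centered rule: a pure sd cutoff rejects everything under homogeneous
    # noise (sd(dev) << mean(dev)); reject_sigma = 0 keeps the bare cutoff so
    # the immediate-fallback path still triggers
    cutoff <- if (reject_sigma > 0)
      max(mean(dev[keep]) + reject_sigma * spread, 0.01) else 0
    new_keep <- keep & dev <= cutoff
    if (sum(new_keep) < 3L) {
      warning("outlier rejection would leave < 3 pairs; returning previous cycle")
      fit$notes <- c(fit$notes, "rejection fell below 3 pairs; previous cycle kept")
      break
    }
    converged <- identical(new_keep, keep)
    if (converged || cycles >= max_cycles) {
      keep <- new_keep
      if (!converged)
        fit$notes <- c(fit$notes, "max_cycles reached before convergence")
      if (!converged) fit <- kabsch_fit(A[keep, , drop = FALSE],
                                        B[keep, , drop = FALSE])
      break
    }
    keep <- new_keep
    fit <- kabsch_fit(A[keep, , drop = FALSE], B[keep, , drop = FALSE])
    cycles <- cycles + 1L
  }
  fitted <- apply_transform(A, fit)
  superposition_result(fit$rotation, fit$translation,
                       rmsd_of(fitted[keep, , drop = FALSE],
                               B[keep, , drop = FALSE]),
                       sum(keep), cycles = cycles, retained = keep,
                       notes = fit$notes)
}

# Calpha coordinates of one chain keyed by residue number
chain_ca <- function(model, chain) {
  sub <- model[model$chain_id == chain & model$atom_name == "CA", , drop = FALSE]
  list(resno = sub$residue_number, xyz = cbind(sub$x, sub$y, sub$z))
}

# all cyclic chain mappings (shift x direction) as permutations of 1..n
cyclic_mappings <- function(n) {
  maps <- list()
  for (s in 0:(n - 1L)) {
    maps[[length(maps) + 1L]] <- ((seq_len(n) - 1L + s) %% n) + 1L
    maps[[length(maps) + 1L]] <- ((s - (seq_len(n) - 1L)) %% n) + 1L
  }
  unique(maps)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

#' Symmetry-aware whole-oligomer superposition
#'
#' Two-stage protocol for fitting one homo-oligomer onto another. Stage 1
#' fits a single mobile monomer onto a target monomer with outlier rejection
#' ([refine_fit()]) to define the aligned core (the retained residues). Stage
#' 2 enumerates chain mappings -- `"cyclic"`: the n rotations times 2
#' directions of the ring order; `"exhaustive"`: all n! bijections -- fits the
#' full assembly on the core Calpha atoms under each mapping, and returns the
#' minimum-RMSD result with its mapping.
#'
#' Residues are paired by residue-number intersection across all chains of
#' both assemblies (common-core trimming).
#'
#' @param mobile,target `assembly_model`s with the same number of chains
#'   (n >= 2).
#' @param search `"cyclic"` (default) or `"exhaustive"` (n <= 7).
#' @param core_chain 1-based index of the monomer used for stage 1.
#' @param max_cycles,reject_sigma stage-1 refinement parameters.
#' @return a `superposition_result` with `chain_mapping` a named character
#'   vector (mobile chain -> target chain).
#' @export
oligomer_fit <- function(mobile, target, search = c("cyclic", "exhaustive"),
                         core_chain = 1L, max_cycles = 5L, reject_sigma = 2.0) {
  search <- match.arg(search)
  m_ch <- chain_ids(mobile); t_ch <- chain_ids(target)
  n <- length(m_ch)
  if (n != length(t_ch))
    stop(sprintf("stoichiometry error: %d vs %d chains", n, length(t_ch)))
  if (n < 2L) stop("oligomer_fit requires >= 2 chains")
  m_ca <- lapply(m_ch, chain_ca, model = mobile)
  t_ca <- lapply(t_ch, chain_ca, model = target)
  common <- Reduce(intersect, c(lapply(m_ca, `[[`, "resno"),
                                lapply(t_ca, `[[`, "resno")))
  if (length(common) < 3L) stop("empty common residue core across chains")
  common <- sort(common)
  # stage 1: monomer fit to define the aligned core
  mc <- m_ca[[core_chain]]; tc <- t_ca[[core_chain]]
  s1 <- refine_fit(mc$xyz[match(common, mc$resno), , drop = FALSE],
                   tc$xyz[match(common, tc$resno), , drop = FALSE],
                   max_cycles = max_cycles, reject_sigma = reject_sigma)
  core_res <- common[s1$retained]
  if (length(core_res) < 3L) core_res <- common
  pick <- function(ca) ca$xyz[match(core_res, ca$resno), , drop = FALSE]
  m_mats <- lapply(m_ca, pick)
  t_mats <- lapply(t_ca, pick)
  mappings <- if (search == "cyclic") cyclic_mappings(n) else {
    if (n > 7L) stop("exhaustive search limited to 7 chains")
    all_permutations(n)
  }
  best <- NULL
  for (perm in mappings) {
    fit <- kabsch_fit(do.call(rbind, m_mats),
                      do.call(rbind, t_mats[perm]))
    if (is.null(best) || fit$rmsd < best$rmsd) {
      best <- fit
      best$chain_mapping <- stats::setNames(t_ch[perm], m_ch)
    }
  }
  best$cycles <- s1$cycles
  best$notes <- c(best$notes,
                  sprintf("core of %d residues per chain from stage-1 refinement",
                          length(core_res)))
  best
}
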