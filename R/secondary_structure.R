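# Calpha-geometry secondary-structure assignment (P-SEA-style distance
# windows), usable on reduced and synthetic models where hydrogen-bond-based
# assignment (DSSP) is not applicable.

# window constants (Angstrom): helix d(i,i+3), d(i,i+4); strand d(i,i+2)
SS_H_D3 <- c(4.4, 5.6)
SS_H_D4 <- c(5.5, 6.9)
SS_E_D2 <- c(6.1, 7.3)
SS_E_D3_MIN <- 8.5       # low-curvature requirement where d(i,i+3) exists
SS_GAP_DIST <- 4.5       # consecutive Calpha further apart break runs
SS_H_RUN <- 4L
SS_E_RUN <- 3L

in_range <- function(x, rng) !is.na(x) & x >= rng[1] & x <= rng[2]

run_starts_to_labels <- function(flags, span, run_min, n) {
  lab <- rep(FALSE, n)
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < run_min) next
    lab[starts[k]:min(n, ends[k] + span)] <- TRUE
  }
  lab
}

#' Assign secondary structure from Calpha geometry
#'
#' Distance-window assignment in the spirit of P-SEA: residue windows are
#' helix candidates when d(i,i+3) is 5.0 +/- 0.6 A and d(i,i+4) is
#' 6.2 +/- 0.7 A, strand candidates when d(i,i+2) is 6.7 +/- 0.6 A with low
#' curvature; candidate runs of >= 4 (helix) or >= 3 (strand) windows mark the
#' covered residues H or E, everything else is C. Chain gaps (consecutive
#' Calpha more than 4.5 A apart) break runs and are flagged.
#'
#' @param chain_xyz n x 3 Calpha coordinate matrix of a single chain (in
#'   residue order), or a single-chain [assembly_model()] (its CA atoms are
#'   used).
#' @return character vector of per-residue codes in `{H, E, C}` with
#'   attribute `gaps` (indices i where the i -> i+1 step exceeds 4.5 A).
#' @export
assign_ss <- function(chain_xyz) {
  if (inherits(chain_xyz, "assembly_model")) {
    ca <- chain_xyz[chain_xyz$atom_name == "CA", , drop = FALSE]
    if (length(unique(ca$chain_id)) > 1L)
      stop("assign_ss expects a single chain; use ss_series for assemblies")
    chain_xyz <- cbind(ca$x, ca$y, ca$z)
  }
  x <- as_coord_matrix(chain_xyz)
  n <- nrow(x)
  ss <- rep("C", n)
  if (n < 5L) return(structure(ss, gaps = integer(0)))
  dk <- function(k) {
    i <- seq_len(n - k)
    sqrt(rowSums((x[i + k, , drop = FALSE] - x[i, , drop = FALSE])^2))
  }
  d1 <- dk(1); d2 <- dk(2); d3 <- dk(3); d4 <- dk(4)
  gaps <- which(d1 > SS_GAP_DIST)
  intact <- function(i, k) {
    # all virtual bonds i..i+k-1 intact
    vapply(i, function(ii) all(d1[ii:(ii + k - 1L)] <= SS_GAP_DIST), logical(1))
  }
  h_flag <- rep(FALSE, n)
  iH <- seq_len(n - 4L)
  h_flag[iH] <- in_range(d3[iH], SS_H_D3) & in_range(d4[iH], SS_H_D4) &
    intact(iH, 4L)
  e_flag <- rep(FALSE, n)
  iE <- seq_len(n - 2L)
  d3_ok <- rep(TRUE, length(iE))
  has_d3 <- iE <= n - 3L
  d3_ok[has_d3] <- d3[iE[has_d3]] > SS_E_D3_MIN
  e_flag[iE] <- in_range(d2[iE], SS_E_D2) & d3_ok & intact(iE, 2L)
  is_h <- run_starts_to_labels(h_flag, 4L, SS_H_RUN, n)
  is_e <- run_starts_to_labels(e_flag, 2L, SS_E_RUN, n)
  ss[is_e] <- "E"
  ss[is_h] <- "H"    # helix takes precedence
  structure(ss, gaps = gaps)
}

# per-chain assignment over a whole model; returns named list of SS vectors
assign_ss_model <- function(model) {
  out <- lapply(chain_ids(model), function(ch) {
    ca <- model[model$chain_id == ch & model$atom_name == "CA", , drop = FALSE]
    assign_ss(cbind(ca$x, ca$y, ca$z))
  })
  stats::setNames(out, chain_ids(model))
}
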