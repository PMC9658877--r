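# Cyclic (Cn) symmetry estimation, open-ring detection, and the axial pore
# profile of a ring-shaped homo-oligomer.

rotation_angle_axis <- function(R) {
  tr <- sum(diag(R))
  angle <- acos(pmin(1, pmax(-1, (tr - 1) / 2)))
  if (abs(sin(angle)) < 1e-12) {
    axis <- c(0, 0, 1)
  } else {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(angle))
  }
  list(angle_deg = rad2deg(angle), axis = axis)
}

# chains ordered by centroid azimuth about the principal (smallest-variance)
# axis of the chain centroids; returns ordering, axis, ring center
ring_order <- function(cent) {
  center <- colMeans(cent)
  cc <- sweep(cent, 2L, center)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  axis <- ev$vectors[, 3L]           # smallest variance = ring normal
  # in-plane basis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(ref - sum(ref * axis) * axis)
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  az <- atan2(cc %*% v, cc %*% u)
  list(order = order(az), axis = axis, center = center)
}

#' Estimate cyclic (Cn) symmetry of a homo-oligomer
#'
#' Chains are put in ring order by centroid azimuth about the principal axis
#' of the chain centroids; each chain is Kabsch-fitted onto its cyclic
#' neighbor, and the per-step rotation angles/axes are pooled (circular mean).
#' The symmetry RMSD is the residual of superposing the whole assembly onto
#' itself advanced by one ring step. Adjacent buried interface areas are
#' computed per ring-ordered pair, and the closed/open call applies
#' [detect_open_assembly()] with its default cutoffs.
#'
#' @param model an [assembly_model()] with >= 3 chains of compatible residue
#'   numbering.
#' @param interface_points sphere points for the interface SASA (default 960).
#' @param compute_interfaces set `FALSE` to skip the (relatively costly)
#'   buried-area computation; `interfaces` is then `NULL` and `closed` is `NA`.
#' @return list of class `symmetry_estimate`: `order`, `axis` (unit vector),
#'   `angle_per_step` (degrees), `symmetry_rmsd`, `closed`, `interfaces`
#'   (data frame `chain_a`, `chain_b`, `buried_area`), `ring_chains`,
#'   `center`.
#' @export
estimate_symmetry <- function(model, interface_points = 960L,
                              compute_interfaces = TRUE) {
  chains <- chain_ids(model)
  n <- length(chains)
  if (n < 3L) stop("symmetry estimation requires >= 3 chains")
  cas <- lapply(chains, chain_ca, model = model)
  common <- sort(Reduce(intersect, lapply(cas, `[[`, "resno")))
  if (length(common) < 3L) stop("chains share too few residues")
  mats <- lapply(cas, function(ca) ca$xyz[match(common, ca$resno), , drop = FALSE])
  cent <- do.call(rbind, lapply(mats, colMeans))
  rng <- ring_order(cent)
  ord <- rng$order
  ring_chains <- chains[ord]
  mats <- mats[ord]
  angles <- numeric(n); axes <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    nxt <- if (k == n) 1L else k + 1L
    fit <- kabsch_fit(mats[[k]], mats[[nxt]])
    if (fit$rmsd > 10)
      stop(sprintf("not symmetric: monomer fit %s->%s has RMSD %.1f A",
                   ring_chains[k], ring_chains[nxt], fit$rmsd))
    aa <- rotation_angle_axis(fit$rotation)
    ax <- aa$axis
    if (sum(ax * rng$axis) < 0) ax <- -ax   # sign-align with ring normal
    angles[k] <- aa$angle_deg
    axes[k, ] <- ax
  }
  ang <- rad2deg(atan2(mean(sin(deg2rad(angles))), mean(cos(deg2rad(angles)))))
  if (ang < 0) ang <- ang + 360
  axis <- unit(colMeans(axes))
  # whole-assembly self-fit advanced by one ring step
  shifted <- c(2:n, 1L)
  self_fit <- kabsch_fit(do.call(rbind, mats), do.call(rbind, mats[shifted]))
  interfaces <- NULL
  closed <- NA
  if (compute_interfaces) {
    interfaces <- data.frame(
      chain_a = ring_chains,
      chain_b = ring_chains[shifted],
      buried_area = vapply(seq_len(n), function(k)
        as.numeric(interface_area(model, ring_chains[k],
                                  ring_chains[shifted][k],
                                  points = interface_points)), numeric(1)),
      stringsAsFactors = FALSE)
  }
  est <- structure(list(order = n, axis = axis, angle_per_step = ang,
                        symmetry_rmsd = self_fit$rmsd, closed = closed,
                        interfaces = interfaces, ring_chains = ring_chains,
                        center = rng$center),
                   class = "symmetry_estimate")
  if (compute_interfaces) {
    oc <- detect_open_assembly(model, est)
    est$closed <- !oc$open
  }
  est
}

#' @export
print.symmetry_estimate <- function(x, ...) {
  cat(sprintf("<symmetry_estimate> C%d, %.2f deg/step, symmetry RMSD %.3f A, %s\n",
              x$order, x$angle_per_step, x$symmetry_rmsd,
              if (isTRUE(x$closed)) "closed" else if (isFALSE(x$closed))
                "open" else "open/closed not evaluated"))
  invisible(x)
}

#' Detect an open (broken-contact) ring
#'
#' A ring is called open when its weakest adjacent interface is both much
#' smaller than the typical one (below `rel_cutoff` times the median adjacent
#' buried area) and absolutely small (below `abs_cutoff`). Both conditions
#' are required so that uniformly small but intact rings stay "closed".
#'
#' @param model an [assembly_model()] (used only if interfaces must be
#'   recomputed).
#' @param sym a `symmetry_estimate` from [estimate_symmetry()].
#' @param rel_cutoff fraction of the median adjacent buried area (default
#'   0.25).
#' @param abs_cutoff absolute buried-area cutoff in Angstrom^2 (default 200).
#' @return list with `open` (logical), `weakest_pair` (chain id pair),
#'   `weakest_area`, `median_area`, `cutoffs`.
#' @export
detect_open_assembly <- function(model, sym, rel_cutoff = 0.25,
                                 abs_cutoff = 200) {
  ifc <- sym$interfaces
  if (is.null(ifc)) {
    shifted <- c(2:sym$order, 1L)
    ifc <- data.frame(
      chain_a = sym$ring_chains, chain_b = sym$ring_chains[shifted],
      buried_area = vapply(seq_len(sym$order), function(k)
        as.numeric(interface_area(model, sym$ring_chains[k],
                                  sym$ring_chains[shifted][k])), numeric(1)))
  }
  i_min <- which.min(ifc$buried_area)
  a_min <- ifc$buried_area[i_min]
  med <- stats::median(ifc$buried_area)
  open <- (a_min < rel_cutoff * med) && (a_min < abs_cutoff)
  list(open = open,
       weakest_pair = c(ifc$chain_a[i_min], ifc$chain_b[i_min]),
       weakest_area = a_min, median_area = med,
       cutoffs = c(rel_cutoff = rel_cutoff, abs_cutoff = abs_cutoff))
}

#' Radial pore profile along the symmetry axis
#'
#' The assembly is sliced into slabs of width `step` along the symmetry axis;
#' in each slab the pore radius is the minimum over atoms of (distance from
#' the axis minus the atom's van der Waals radius), floored at 0 and capped at
#' `max_radius` (empty slabs report `max_radius`). The axis direction is
#' canonicalized by the sign of the third moment of the axial coordinate, so
#' the profile is invariant under global rigid motions.
#'
#' @param model an [assembly_model()].
#' @param sym a `symmetry_estimate` (supplies axis and center).
#' @param step slab width (Angstrom, default 1.0).
#' @param max_radius cap (Angstrom, default 30).
#' @return list of class `pore_profile`: `samples` (data frame `z`,
#'   `radius`), `min_radius`, `z_at_min`.
#' @export
pore_profile <- function(model, sym, step = 1.0, max_radius = 30) {
  xyz <- coords(model)
  radii <- vdw_radii_of(model$element, warn = FALSE)
  a <- unit(sym$axis)
  center <- colMeans(xyz)
  rel <- sweep(xyz, 2L, center)
  z <- as.numeric(rel %*% a)
  if (sum(z^3) < 0) { a <- -a; z <- -z }   # canonical orientation
  perp <- rel - outer(z, a)
  r_ax <- sqrt(rowSums(perp^2))
  zs <- seq(floor(min(z)), ceiling(max(z)), by = step)
  rad <- vapply(zs, function(zk) {
    in_slab <- abs(z - zk) <= step / 2
    if (!any(in_slab)) return(max_radius)
    min(max_radius, max(0, min(r_ax[in_slab] - radii[in_slab])))
  }, numeric(1))
  i_min <- which.min(rad)
  structure(list(samples = data.frame(z = zs, radius = rad),
                 min_radius = rad[i_min], z_at_min = zs[i_min]),
            class = "pore_profile")
}

#' @export
print.pore_profile <- function(x, ...) {
  cat(sprintf("<pore_profile> %d slabs, min radius %.2f A at z = %.1f A\n",
              nrow(x$samples), x$min_radius, x$z_at_min))
  invisible(x)
}
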