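# Trajectory post-processing: per-selection RMSD series against the starting
# model, secondary-structure content evolution, closest-to-average frame,
# and 3/6-Angstrom stability labels.

#' Construct a trajectory from a list of models
#' @param frames list of [assembly_model()]s with identical atom inventories.
#' @param frame_times optional numeric times (ns), one per frame.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(frames, frame_times = NULL) {
  if (!length(frames)) stop("a trajectory needs >= 1 frame")
  inv <- function(m) paste(m$chain_id, m$residue_number, m$insertion_code,
                           m$atom_name, collapse = "|")
  ref_inv <- inv(frames[[1]])
  for (k in seq_along(frames)[-1L]) {
    if (!identical(inv(frames[[k]]), ref_inv))
      stop(sprintf("format error: model %d atom inventory differs from model 1", k))
  }
  if (!is.null(frame_times) && length(frame_times) != length(frames))
    stop("frame_times length must equal frame count")
  structure(list(frames = frames, frame_times = frame_times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames of %d atoms\n", length(x$frames),
              nrow(x$frames[[1]])))
  invisible(x)
}

#' Read a multi-model PDB trajectory
#'
#' One frame per MODEL record; atom inventories must match across frames
#' (mismatches raise a format error naming the model index). Frame 1 is the
#' reference by default ("the starting model").
#'
#' @param path multi-model PDB file.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  blocks <- pdb_model_blocks(lines)
  frames <- lapply(seq_along(blocks), function(k) {
    atoms <- parse_pdb_atoms(blocks[[k]], path)
    if (is.null(atoms)) stop(sprintf("empty input: model %d has no atoms", k))
    assembly_model(resolve_altlocs(atoms), model_id = k)
  })
  trajectory(frames)
}

# resolve a selection spec (list of select_atoms args, or NULL = all CA)
select_or_ca <- function(model, selection) {
  if (is.null(selection)) {
    sel <- model[model$atom_name == "CA", , drop = FALSE]
    if (nrow(sel) == 0L) sel <- model
    assembly_model(sel, attr(model, "model_id"))
  } else if (is.list(selection)) {
    do.call(select_atoms, c(list(model = model), selection))
  } else stop("selection must be NULL or a list of select_atoms arguments")
}

stability_label <- function(mean_rmsd) {
  # boundary goes to the larger band: exactly 3.0 -> limited, 6.0 -> high
  if (mean_rmsd < 3) "low" else if (mean_rmsd < 6) "limited" else "high"
}

#' RMSD series of a trajectory against a reference
#'
#' Per frame, optionally least-squares-fits the selection onto the reference
#' selection (Kabsch) and reports the RMSD over it. The trajectory-mean RMSD
#' is labelled `low` (< 3 A), `limited` (3-6 A) or `high` (>= 6 A);
#' boundaries belong to the larger band.
#'
#' @param traj a [trajectory()].
#' @param reference reference [assembly_model()]; default frame 1.
#' @param selection `NULL` (all Calpha) or a list of [select_atoms()]
#'   arguments, e.g. `list(domain = "CTD", domain_map = dm)`.
#' @param fit superpose each frame before measuring (default TRUE).
#' @param fit_selection optional selection used for the superposition when it
#'   should differ from the measured one (e.g. fit on the BTB ring, measure
#'   the CTD ring to expose inter-domain motion).
#' @return numeric series (one value per frame) with attributes `label` and
#'   `mean_rmsd`.
#' @export
rmsd_series <- function(traj, reference = NULL, selection = NULL, fit = TRUE,
                        fit_selection = NULL) {
  reference <- reference %||% traj$frames[[1]]
  ref_sel <- coords(select_or_ca(reference, selection))
  ref_fit <- if (is.null(fit_selection)) ref_sel else
    coords(select_or_ca(reference, fit_selection))
  series <- vapply(traj$frames, function(fr) {
    mob <- coords(select_or_ca(fr, selection))
    if (nrow(mob) != nrow(ref_sel))
      stop("selection sizes differ between frame and reference")
    if (!fit) return(rmsd_of(mob, ref_sel))
    if (is.null(fit_selection)) return(kabsch_fit(mob, ref_sel)$rmsd)
    f <- kabsch_fit(coords(select_or_ca(fr, fit_selection)), ref_fit)
    rmsd_of(apply_transform(mob, f), ref_sel)
  }, numeric(1))
  m <- mean(series)
  structure(series, label = stability_label(m), mean_rmsd = m)
}

#' Secondary-structure content per frame
#'
#' Runs [assign_ss()] per chain per frame and pools the per-residue codes into
#' H/E/C percentages (summing to 100 per frame).
#'
#' @param traj a [trajectory()].
#' @return data frame with columns `frame`, `H`, `E`, `C` (percent).
#' @export
ss_series <- function(traj) {
  rows <- lapply(seq_along(traj$frames), function(k) {
    codes <- unlist(assign_ss_model(traj$frames[[k]]), use.names = FALSE)
    n <- length(codes)
    data.frame(frame = k,
               H = 100 * sum(codes == "H") / n,
               E = 100 * sum(codes == "E") / n,
               C = 100 * sum(codes == "C") / n)
  })
  do.call(rbind, rows)
}

#' Frame closest to the trajectory average
#'
#' Fits every frame onto frame 1 over the selection, averages the fitted
#' coordinates, and returns the (1-based) index of the frame with minimum
#' RMSD to that average; ties break to the lowest index.
#'
#' @inheritParams rmsd_series
#' @return integer frame index with attribute `rmsd_to_average`.
#' @export
closest_to_average <- function(traj, selection = NULL) {
  ref <- coords(select_or_ca(traj$frames[[1]], selection))
  fitted <- lapply(traj$frames, function(fr) {
    mob <- coords(select_or_ca(fr, selection))
    f <- kabsch_fit(mob, ref)
    apply_transform(mob, f)
  })
  avg <- Reduce(`+`, fitted) / length(fitted)
  dists <- vapply(fitted, rmsd_of, numeric(1), b = avg)
  idx <- which.min(dists)   # which.min takes the first minimum (lowest index)
  structure(as.integer(idx), rmsd_to_average = dists[idx])
}

#' Full trajectory stability analysis
#'
#' Convenience wrapper producing the global / BTB / CTD RMSD series (fitted,
#' Calpha), the secondary-structure series, the closest-to-average frame and
#' the per-selection stability labels.
#'
#' @param traj a [trajectory()].
#' @param domain_map optional [domain_map()] enabling the per-domain series.
#' @param reference reference model (default frame 1).
#' @return list of class `trajectory_analysis`.
#' @export
analyze_trajectory <- function(traj, domain_map = NULL, reference = NULL) {
  sels <- list(global = NULL)
  if (!is.null(domain_map)) {
    for (d in intersect(c("BTB", "CTD"), unique(domain_map$domain)))
      sels[[d]] <- list(domain = d, domain_map = domain_map,
                        atom_names = "CA")
  }
  series <- lapply(sels, function(s) rmsd_series(traj, reference, s))
  structure(list(
    rmsd_series = lapply(series, as.numeric),
    stability_labels = vapply(series, attr, character(1), "label"),
    mean_rmsd = vapply(series, attr, numeric(1), "mean_rmsd"),
    ss_fraction_series = ss_series(traj),
    closest_frame = as.integer(closest_to_average(traj))),
    class = "trajectory_analysis")
}

#' @export
print.trajectory_analysis <- function(x, ...) {
  cat(sprintf("<trajectory_analysis> %d frames; labels: %s; closest frame %d\n",
              length(x$rmsd_series$global),
              paste(names(x$stability_labels), x$stability_labels,
                    sep = "=", collapse = ", "), x$closest_frame))
  invisible(x)
}
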