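# Orchestration: per-assembly assessment (confidence -> geometry -> optional
# trajectory analysis), batch reporting in the style of a stability/
# reliability summary table, and a sequence-identity utility.

#' Assess one predicted oligomer assembly
#'
#' Runs the full per-assembly pipeline: PAE block statistics and
#' stable/unstable + reliable/partially-reliable grading, chain-pair quadrant
#' sub-stoichiometry, Cn symmetry with adjacent buried interfaces and the
#' open/closed call, the axial pore profile, and (optionally) trajectory
#' stability analysis. Every threshold that enters a decision is echoed into
#' the returned object (and the log when `verbose`).
#'
#' @param structure path to a PDB/mmCIF file, or an [assembly_model()].
#' @param pae path to a PAE JSON file, or a [pae_matrix()]. Its dimension
#'   must equal the structure's residue count.
#' @param domains path to a domain-map TSV (`protein`, `domain`, `start`,
#'   `end`), or a [domain_map()].
#' @param config an [analysis_config()].
#' @param trajectory optional multi-model PDB path or [trajectory()].
#' @param protein_id identifier used in reports.
#' @param interface_points sphere points for interface SASA.
#' @param verbose log one line per stage to the console.
#' @return list of class `assembly_assessment`.
#' @export
assess_assembly <- function(structure, pae, domains,
                            config = analysis_config(), trajectory = NULL,
                            protein_id = "assembly",
                            interface_points = 240L, verbose = FALSE) {
  log_line <- function(...) if (verbose) message(sprintf(...))
  model <- if (is.character(structure)) read_structure(structure) else structure
  dmap <- if (is.character(domains)) read_domain_map(domains, protein = NULL)
          else domains
  seg <- segmentation(model)
  pm <- if (is.character(pae)) read_pae(pae, segmentation = seg) else pae
  L <- sum(seg$residue_count)
  if (nrow(pm$values) != L)
    stop(sprintf("dimension mismatch: PAE is %d x %d but structure has %d residues",
                 nrow(pm$values), nrow(pm$values), L))
  if (!identical(pm$segmentation$residue_count, seg$residue_count))
    pm <- pae_matrix(pm$values, seg)
  log_line("[confidence] threshold=%g A reliable>%g%% partial>%g%% adjacency=%s",
           config$pae_threshold, config$reliable_percent,
           config$partial_percent, config$adjacency)
  blocks <- block_fractions(pm, dmap, config, residues = residue_table(model))
  reliability <- classify_reliability(blocks, config)
  substoich <- if (nrow(seg) >= 2L) infer_substoichiometry(pm, config) else NULL
  sym <- NULL; pore <- NULL; open_call <- NULL
  if (nrow(seg) >= 3L) {
    sym <- tryCatch(estimate_symmetry(model, interface_points = interface_points),
                    error = function(e) {
                      log_line("[geometry] skipped: %s", conditionMessage(e))
                      NULL
                    })
    if (!is.null(sym)) {
      open_call <- detect_open_assembly(model, sym)
      pore <- pore_profile(model, sym)
      log_line("[geometry] C%d angle=%.2f deg closed=%s (rel_cutoff=%g abs_cutoff=%g)",
               sym$order, sym$angle_per_step, sym$closed,
               open_call$cutoffs["rel_cutoff"], open_call$cutoffs["abs_cutoff"])
    }
  }
  md <- NULL
  if (!is.null(trajectory)) {
    traj <- if (is.character(trajectory)) read_trajectory(trajectory)
            else trajectory
    md <- analyze_trajectory(traj, domain_map = dmap, reference = model)
    log_line("[md] labels: %s (bands 3/6 A)",
             paste(names(md$stability_labels), md$stability_labels,
                   sep = "=", collapse = ", "))
  }
  structure(list(protein_id = protein_id, reliability = reliability,
                 substoichiometry = substoich, symmetry = sym,
                 open_call = open_call, pore = pore, md = md,
                 config = unclass(config)),
            class = "assembly_assessment")
}

#' @export
print.assembly_assessment <- function(x, ...) {
  cat(sprintf("<assembly_assessment> %s: stability=%s grade=%s\n",
              x$protein_id, x$reliability$stability, x$reliability$grade))
  if (!is.null(x$symmetry))
    cat(sprintf("  C%d, %.2f deg/step, %s; min pore radius %.2f A\n",
                x$symmetry$order, x$symmetry$angle_per_step,
                if (isTRUE(x$symmetry$closed)) "closed" else "open",
                x$pore$min_radius))
  if (!is.null(x$substoichiometry))
    cat(sprintf("  sub-stoichiometry: %s\n", x$substoichiometry$label))
  invisible(x)
}

block_pct <- function(blocks, name) {
  i <- match(name, blocks$block)
  if (is.na(i)) NA_real_ else blocks$fraction_below[i]
}

# restrict structure + PAE to one domain (BTB-only assessment)
restrict_to_domain <- function(model, pm, dmap, domain) {
  rng <- domain_range(dmap, domain)
  res <- residue_table(model)
  resno_all <- res$residue_number
  keep_res <- rep(FALSE, length(resno_all))
  for (k in seq_len(nrow(rng)))
    keep_res <- keep_res | (resno_all >= rng$start[k] & resno_all <= rng$end[k])
  sub_model <- select_atoms(model, domain = domain, domain_map = dmap)
  seg <- segmentation(sub_model)
  sub_pae <- pae_matrix(pm$values[keep_res, keep_res, drop = FALSE], seg)
  list(model = sub_model, pae = sub_pae,
       dmap = domain_map(data.frame(domain = domain,
                                    start = min(rng$start),
                                    end = max(rng$end))))
}

#' Batch assessment report over a fixture directory
#'
#' Scans `directory` for fixture triples named `<id>_model.pdb`,
#' `<id>_pae.json`, `<id>_domains.tsv` (as written by [write_fixture_set()]),
#' assesses each both BTB-only and full-length, and writes a deterministic
#' TSV (and JSON) report sorted by protein id. Unreadable entries yield a row
#' with `status = "FAILED: <reason>"` and the run continues.
#'
#' @param directory fixture directory.
#' @param config an [analysis_config()].
#' @param out optional output path prefix; writes `<out>.tsv` and
#'   `<out>.json`.
#' @param interface_points sphere points for interface SASA.
#' @return the report data frame (invisibly when `out` is given).
#' @export
batch_report <- function(directory, config = analysis_config(), out = NULL,
                         interface_points = 240L) {
  files <- list.files(directory, pattern = "_model\\.pdb$")
  ids <- sort(sub("_model\\.pdb$", "", files))
  if (!length(ids)) warning("no fixtures found in ", directory)
  schema <- c("protein_id", "btb_stability", "btb_grade", "fl_stability",
              "fl_grade", "pct_intra_btb", "pct_intra_ctd", "pct_inter_btb",
              "pct_inter_ctd", "order", "angle_deg", "state",
              "min_pore_radius", "status")
  rows <- lapply(ids, function(id) {
    row <- as.list(stats::setNames(rep(NA, length(schema)), schema))
    row$protein_id <- id
    row$status <- "OK"
    tryCatch({
      model <- read_structure(file.path(directory, paste0(id, "_model.pdb")))
      dmap <- read_domain_map(file.path(directory, paste0(id, "_domains.tsv")))
      pm <- read_pae(file.path(directory, paste0(id, "_pae.json")),
                     segmentation = segmentation(model))
      fl <- assess_assembly(model, pm, dmap, config,
                            protein_id = id,
                            interface_points = interface_points)
      btb_in <- restrict_to_domain(model, pm, dmap, "BTB")
      btb_blocks <- block_fractions(btb_in$pae, btb_in$dmap, config)
      btb_rel <- classify_reliability(btb_blocks, config)
      row$btb_stability <- btb_rel$stability
      row$btb_grade <- btb_rel$grade
      row$fl_stability <- fl$reliability$stability
      row$fl_grade <- fl$reliability$grade
      bl <- fl$reliability$blocks
      row$pct_intra_btb <- round(block_pct(bl, "intra-BTB"), 2)
      row$pct_intra_ctd <- round(block_pct(bl, "intra-CTD"), 2)
      row$pct_inter_btb <- round(block_pct(bl, "inter-BTB"), 2)
      row$pct_inter_ctd <- round(block_pct(bl, "inter-CTD"), 2)
      if (!is.null(fl$symmetry)) {
        row$order <- fl$symmetry$order
        row$angle_deg <- round(fl$symmetry$angle_per_step, 3)
        row$state <- if (isTRUE(fl$symmetry$closed)) "closed" else "open"
        row$min_pore_radius <- round(fl$pore$min_radius, 2)
      }
    }, error = function(e) {
      row$status <<- paste0("FAILED: ", conditionMessage(e))
    })
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  report <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(stats::setNames(rep(list(character(0)), length(schema)),
                                  schema))
  if (!is.null(out)) {
    utils::write.table(report, paste0(out, ".tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "-")
    jsonlite::write_json(list(config = unclass(config), rows = report),
                         paste0(out, ".json"), auto_unbox = TRUE, digits = NA,
                         na = "null")
    return(invisible(report))
  }
  report
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Percent sequence identity from a global alignment
#'
#' Needleman-Wunsch global alignment with identity scoring (match +1,
#' mismatch 0) and affine gaps (open 10, extend 0.5), via
#' `Biostrings::pairwiseAlignment`. Identity is 100 x identical columns over
#' alignment columns, by default excluding terminal-gap columns.
#'
#' @param seq_a,seq_b amino-acid sequences (single strings, 20-letter
#'   alphabet plus X).
#' @param denominator `"excl_terminal_gaps"` (default) or `"all_columns"`.
#' @return percent identity (0-100).
#' @export
pairwise_identity <- function(seq_a, seq_b,
                              denominator = c("excl_terminal_gaps",
                                              "all_columns")) {
  denominator <- match.arg(denominator)
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  ok <- c(AA_ALPHABET, "X")
  bad <- setdiff(unique(c(strsplit(seq_a, "")[[1]], strsplit(seq_b, "")[[1]])),
                 ok)
  if (length(bad))
    stop("invalid residue character(s): ", paste(bad, collapse = ", "))
  letters_ <- ok
  subst <- matrix(0, length(letters_), length(letters_),
                  dimnames = list(letters_, letters_))
  diag(subst) <- 1
  subst["X", "X"] <- 0   # X never counts as a match
  aln <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                       substitutionMatrix = subst,
                                       gapOpening = 10, gapExtension = 0.5)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  cols <- seq_along(a)
  if (denominator == "excl_terminal_gaps") {
    lead_a <- which(a != "-"); lead_b <- which(b != "-")
    first <- max(min(lead_a), min(lead_b))
    last <- min(max(lead_a), max(lead_b))
    cols <- cols[cols >= first & cols <= last]
  }
  if (!length(cols)) return(0)
  100 * sum(a[cols] == b[cols] & a[cols] != "-") / length(cols)
}
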