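# PAE parsing and domain-decomposed reliability statistics: the fraction of
# residue pairs with expected aligned error below a threshold, evaluated per
# intra/inter-domain block, graded into S/U stability and R/PR/U reliability,
# and chain-pair quadrant analysis for sub-stoichiometric (dimer) propensity.

#' Construct a PAE matrix object
#'
#' @param values square numeric matrix of expected aligned errors (Angstrom).
#' @param segmentation data frame with columns `chain_id`, `residue_count`
#'   whose counts sum to `nrow(values)`.
#' @return an object of class `pae_matrix`.
#' @export
pae_matrix <- function(values, segmentation) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop(sprintf("PAE matrix must be square (got %d x %d)", nrow(values),
                 ncol(values)))
  if (any(!is.finite(values)) || any(values < 0))
    stop("PAE entries must be finite and >= 0")
  segmentation <- as.data.frame(segmentation, stringsAsFactors = FALSE)
  if (!all(c("chain_id", "residue_count") %in% names(segmentation)))
    stop("segmentation requires columns chain_id, residue_count")
  if (sum(segmentation$residue_count) != nrow(values))
    stop(sprintf("segmentation totals %d residues but PAE is %d x %d",
                 sum(segmentation$residue_count), nrow(values), nrow(values)))
  if (anyDuplicated(segmentation$chain_id)) stop("duplicate chain ids")
  dialect_warning <- NULL
  if (nrow(values) > 0 && any(diag(values) > 5)) {
    dialect_warning <- "diagonal entries > 5 Angstrom: unusual PAE dialect?"
    warning(dialect_warning)
  }
  structure(list(values = values, segmentation = segmentation,
                 dialect_warning = dialect_warning),
            class = "pae_matrix")
}

#' @export
print.pae_matrix <- function(x, ...) {
  cat(sprintf("<pae_matrix> %d x %d, chains: %s\n", nrow(x$values),
              ncol(x$values),
              paste(sprintf("%s(%d)", x$segmentation$chain_id,
                            x$segmentation$residue_count), collapse = ", ")))
  invisible(x)
}

# 0-based-free residue bookkeeping: chain index and residue offsets per chain
seg_chain_index <- function(segmentation) {
  rep(seq_len(nrow(segmentation)), segmentation$residue_count)
}

# author residue numbers per concatenated index, assuming each chain numbers
# 1..count unless a residue table is supplied
seg_residue_numbers <- function(segmentation, residues = NULL) {
  if (!is.null(residues)) return(residues$residue_number)
  unlist(lapply(segmentation$residue_count, seq_len), use.names = FALSE)
}

#' Read a PAE matrix from JSON
#'
#' Understands the two common dialects: nested list-of-lists under key
#' `"pae"` or `"predicted_aligned_error"` (optionally wrapped in a top-level
#' one-element array, as ColabFold writes), and the flat triplet dialect with
#' parallel `residue1`/`residue2`/`distance` arrays. Identical data in either
#' dialect yields identical matrices.
#'
#' @param path JSON file path.
#' @param segmentation chain segmentation (data frame `chain_id`,
#'   `residue_count`). If `NULL`, a sidecar `<path>.seg.json` is tried, then a
#'   single chain `"A"` spanning the matrix is assumed.
#' @return a [pae_matrix()].
#' @export
read_pae <- function(path, segmentation = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  # unwrap [ { ... } ]
  if (is.data.frame(obj) && nrow(obj) == 1L) obj <- as.list(obj[1L, ])
  if (is.list(obj) && is.null(names(obj)) && length(obj) == 1L) obj <- obj[[1L]]
  vals <- NULL
  if (is.list(obj)) {
    for (key in c("pae", "predicted_aligned_error")) {
      if (!is.null(obj[[key]])) {
        v <- obj[[key]]
        if (is.list(v) && !is.data.frame(v)) {
          lens <- lengths(v)
          if (length(unique(lens)) != 1L || lens[1] != length(v))
            stop(sprintf("format error in '%s': nested PAE rows have lengths %s for %d rows",
                         path, paste(unique(lens), collapse = "/"), length(v)))
          v <- do.call(rbind, v)
        }
        v <- as.matrix(v)
        if (nrow(v) != ncol(v))
          stop(sprintf("format error in '%s': PAE is %d x %d, not square",
                       path, nrow(v), ncol(v)))
        vals <- v
        break
      }
    }
    if (is.null(vals) && all(c("residue1", "residue2", "distance") %in% names(obj))) {
      r1 <- as.integer(obj$residue1); r2 <- as.integer(obj$residue2)
      d <- as.numeric(obj$distance)
      if (length(r1) != length(r2) || length(r1) != length(d))
        stop(sprintf("format error in '%s': triplet arrays have unequal lengths", path))
      L <- max(r1, r2)
      if (length(d) != L * L)
        stop(sprintf("format error in '%s': %d triplets cannot fill a %d x %d matrix",
                     path, length(d), L, L))
      vals <- matrix(NA_real_, L, L)
      vals[cbind(r1, r2)] <- d
      if (anyNA(vals))
        stop(sprintf("format error in '%s': triplet dialect leaves missing entries", path))
    }
  }
  if (is.null(vals))
    stop(sprintf("dialect error in '%s': no PAE payload; keys found: %s", path,
                 paste(names(obj) %||% "(none)", collapse = ", ")))
  if (is.null(segmentation)) {
    sidecar <- paste0(path, ".seg.json")
    if (file.exists(sidecar)) {
      segmentation <- as.data.frame(jsonlite::fromJSON(sidecar))
    } else {
      segmentation <- data.frame(chain_id = "A", residue_count = nrow(vals))
    }
  }
  pae_matrix(vals, segmentation)
}

#' Analysis configuration for PAE reliability grading
#'
#' @param pae_threshold error threshold in Angstrom; pairs count as confident
#'   when their (symmetrized) PAE is strictly below it. Default 10.
#' @param reliable_percent a block is reliable when its confident-pair
#'   percentage is strictly above this. Default 65.
#' @param partial_percent lower band for "partially reliable" grading of
#'   inter-chain blocks. Default 40.
#' @param adjacency `"cyclic"` pools inter-chain pairs over adjacent chains in
#'   ring order only; `"all_pairs"` pools every distinct chain pair.
#' @param pair_symmetrization how the two ordered entries of a residue pair
#'   are combined: `"mean"`, `"min"`, or `"ordered"` (use the upper-triangle
#'   entry as-is).
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(pae_threshold = 10, reliable_percent = 65,
                            partial_percent = 40,
                            adjacency = c("cyclic", "all_pairs"),
                            pair_symmetrization = c("mean", "min", "ordered")) {
  adjacency <- match.arg(adjacency)
  pair_symmetrization <- match.arg(pair_symmetrization)
  if (pae_threshold <= 0) stop("pae_threshold must be > 0")
  if (!(partial_percent > 0 && partial_percent < reliable_percent &&
        reliable_percent < 100))
    stop("need 0 < partial_percent < reliable_percent < 100")
  structure(list(pae_threshold = pae_threshold,
                 reliable_percent = reliable_percent,
                 partial_percent = partial_percent,
                 adjacency = adjacency,
                 pair_symmetrization = pair_symmetrization),
            class = "analysis_config")
}

sym_pair_matrix <- function(values, mode) {
  switch(mode,
         mean = (values + t(values)) / 2,
         min = pmin(values, t(values)),
         ordered = values)
}

# adjacency chain pairs (i < j chain indices) under the config
adjacent_chain_pairs <- function(n_chains, adjacency) {
  if (n_chains < 2L) return(matrix(integer(0), ncol = 2))
  if (adjacency == "all_pairs" || n_chains == 2L) {
    t(utils::combn(n_chains, 2L))
  } else {
    a <- seq_len(n_chains)
    b <- c(seq_len(n_chains)[-1L], 1L)
    unique(t(apply(cbind(a, b), 1L, sort)))
  }
}

count_below <- function(vals, threshold) sum(vals < threshold)

#' Domain-block confident-pair percentages of a PAE matrix
#'
#' For each block class (intra-BTB, intra-CTD, inter-BTB, inter-CTD,
#' cross-domain) the percentage of unordered residue pairs whose symmetrized
#' expected error is strictly below `config$pae_threshold`. Intra classes pool
#' same-chain pairs over all chains (diagonal excluded); inter classes pool
#' pairs from distinct chains, restricted to adjacent chains in ring order
#' when `config$adjacency == "cyclic"`. Hinge and unmapped residues are
#' excluded. The cross-domain (BTB vs CTD, all chain combinations) class is
#' reported but not used for grading.
#'
#' @param pae a [pae_matrix()].
#' @param domains a [domain_map()].
#' @param config an [analysis_config()].
#' @param residues optional residue table (author numbering) aligned with the
#'   matrix; defaults to 1..count per chain.
#' @return data frame of class `block_statistics` with columns `block`,
#'   `pair_count`, `fraction_below`; omitted zero-pair classes are listed in
#'   the `notes` attribute.
#' @export
block_fractions <- function(pae, domains, config = analysis_config(),
                            residues = NULL) {
  stopifnot(inherits(pae, "pae_matrix"))
  seg <- pae$segmentation
  n_chains <- nrow(seg)
  chain_idx <- seg_chain_index(seg)
  resno <- seg_residue_numbers(seg, residues)
  dom <- domain_of_residues(domains, resno)
  S <- sym_pair_matrix(pae$values, config$pair_symmetrization)
  thr <- config$pae_threshold

  graded_domains <- intersect(c("BTB", "CTD"), unique(domains$domain))
  if (!length(graded_domains))
    stop("domain map contains neither BTB nor CTD")

  rows <- list()
  notes <- character(0)
  add_row <- function(block, pair_count, n_below) {
    if (pair_count == 0L) {
      notes <<- c(notes, sprintf("block '%s' has zero pairs; omitted", block))
      return(invisible(NULL))
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      block = block, pair_count = pair_count,
      fraction_below = 100 * n_below / pair_count, stringsAsFactors = FALSE)
  }

  # intra-domain: same chain, both residues in the domain, i < j
  for (d in graded_domains) {
    cnt <- 0L; below <- 0L
    for (c_ in seq_len(n_chains)) {
      idx <- which(chain_idx == c_ & dom %in% d)
      if (length(idx) < 2L) next
      vals <- S[idx, idx][upper.tri(diag(length(idx)))]
      cnt <- cnt + length(vals)
      below <- below + count_below(vals, thr)
    }
    add_row(paste0("intra-", d), cnt, below)
  }
  # inter-domain: same domain, distinct chains under the adjacency rule
  pairs <- adjacent_chain_pairs(n_chains, config$adjacency)
  for (d in graded_domains) {
    cnt <- 0L; below <- 0L
    if (nrow(pairs)) for (p in seq_len(nrow(pairs))) {
      ia <- which(chain_idx == pairs[p, 1L] & dom %in% d)
      ib <- which(chain_idx == pairs[p, 2L] & dom %in% d)
      if (!length(ia) || !length(ib)) next
      vals <- S[ia, ib, drop = FALSE]
      cnt <- cnt + length(vals)
      below <- below + count_below(vals, thr)
    }
    add_row(paste0("inter-", d), cnt, below)
  }
  # cross-domain (BTB vs CTD), all chain combinations; informational only
  if (all(c("BTB", "CTD") %in% graded_domains)) {
    ia <- which(dom %in% "BTB"); ib <- which(dom %in% "CTD")
    vals <- S[ia, ib, drop = FALSE]
    add_row("cross-domain", length(vals), count_below(vals, thr))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("block_statistics", "data.frame"), notes = notes)
}

#' Grade a model from its block statistics
#'
#' Reliability grade `R` requires every graded block percentage strictly above
#' `reliable_percent`; `PR` requires all intra blocks above `reliable_percent`
#' and every inter block above `partial_percent`; anything else is `U`.
#' Stability is `S` when the grade is `R` or `PR`, else `U`. The cross-domain
#' block never enters grading.
#'
#' @param blocks a `block_statistics` data frame from [block_fractions()].
#' @param config an [analysis_config()].
#' @return list of class `reliability_report` with `stability`, `grade`,
#'   `blocks`, `notes`, `thresholds`.
#' @export
classify_reliability <- function(blocks, config = analysis_config()) {
  graded <- blocks[blocks$block != "cross-domain", , drop = FALSE]
  if (nrow(graded) == 0L) stop("no graded blocks present")
  intra <- graded[startsWith(graded$block, "intra-"), ]
  inter <- graded[startsWith(graded$block, "inter-"), ]
  rp <- config$reliable_percent; pp <- config$partial_percent
  grade <- if (all(graded$fraction_below > rp)) {
    "R"
  } else if (nrow(intra) > 0L && all(intra$fraction_below > rp) &&
             nrow(inter) > 0L && all(inter$fraction_below > pp)) {
    "PR"
  } else "U"
  stability <- if (grade %in% c("R", "PR")) "S" else "U"
  structure(list(stability = stability, grade = grade, blocks = blocks,
                 notes = attr(blocks, "notes") %||% character(0),
                 thresholds = unclass(config)),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> stability=%s grade=%s\n", x$stability,
              x$grade))
  print(as.data.frame(x$blocks))
  invisible(x)
}

# fraction of confident pairs in the whole inter-chain quadrant of one pair
chain_pair_fraction <- function(S, chain_idx, a, b, thr) {
  ia <- which(chain_idx == a); ib <- which(chain_idx == b)
  vals <- S[ia, ib, drop = FALSE]
  100 * count_below(vals, thr) / length(vals)
}

#' Infer sub-stoichiometric assemblies from PAE chain-pair quadrants
#'
#' Builds a graph on chains with an edge wherever the whole inter-chain PAE
#' quadrant of a pair has a confident-pair percentage strictly above
#' `config$reliable_percent`, and returns its connected components sorted by
#' decreasing size. Low-error off-diagonal quadrants confined to particular
#' chain pairs indicate a propensity to form smaller oligomers (e.g. dimers)
#' rather than the full ring.
#'
#' @param pae a [pae_matrix()] with at least 2 chains.
#' @param config an [analysis_config()].
#' @return list of class `substoichiometry` with `components` (list of chain
#'   id vectors), `edges` (data frame chain_a, chain_b, fraction_below),
#'   `dimer_propensity` (logical), `label`.
#' @export
infer_substoichiometry <- function(pae, config = analysis_config()) {
  seg <- pae$segmentation
  n <- nrow(seg)
  if (n < 2L) stop("sub-stoichiometry inference requires >= 2 chains")
  chain_idx <- seg_chain_index(seg)
  S <- sym_pair_matrix(pae$values, config$pair_symmetrization)
  prs <- t(utils::combn(n, 2L))
  frac <- vapply(seq_len(nrow(prs)), function(k)
    chain_pair_fraction(S, chain_idx, prs[k, 1], prs[k, 2],
                        config$pae_threshold), numeric(1))
  edges <- data.frame(chain_a = seg$chain_id[prs[, 1]],
                      chain_b = seg$chain_id[prs[, 2]],
                      fraction_below = frac, stringsAsFactors = FALSE)
  linked <- frac > config$reliable_percent
  # connected components by BFS over the chain graph
  adj <- matrix(FALSE, n, n)
  if (any(linked)) {
    adj[prs[linked, , drop = FALSE]] <- TRUE
    adj[prs[linked, 2:1, drop = FALSE]] <- TRUE
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comps <- split(seg$chain_id, comp)
  comps <- comps[order(-lengths(comps),
                       vapply(comps, function(x) x[1], character(1)))]
  names(comps) <- NULL
  sizes <- lengths(comps)
  label <- if (length(comps) == 1L) {
    sprintf("single %d-mer", n)
  } else if (max(sizes) == 2L) {
    "dimer propensity"
  } else if (max(sizes) == 1L) {
    "no confident inter-chain contacts"
  } else "mixed sub-stoichiometry"
  structure(list(components = comps, edges = edges,
                 dimer_propensity = length(comps) > 1L && max(sizes) == 2L,
                 label = label),
            class = "substoichiometry")
}

#' @export
print.substoichiometry <- function(x, ...) {
  cat(sprintf("<substoichiometry> %s: %s\n", x$label,
              paste(vapply(x$components, paste, character(1), collapse = "+"),
                    collapse = " | ")))
  invisible(x)
}
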