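# Domain maps: BTB/hinge/CTD residue ranges applied identically to every
# chain of a homo-oligomer. Author numbering, 1-based inclusive.

DOMAIN_NAMES <- c("BTB", "hinge", "CTD", "other")

#' Construct a domain map
#'
#' @param entries data frame with columns `domain` (one of BTB, hinge, CTD,
#'   other), `start`, `end` (1-based inclusive author numbering). Ranges must
#'   not overlap.
#' @return an object of class `domain_map`.
#' @export
domain_map <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("domain", "start", "end")
  if (!all(need %in% names(entries)))
    stop("domain map requires columns: ", paste(need, collapse = ", "))
  bad <- setdiff(entries$domain, DOMAIN_NAMES)
  if (length(bad))
    stop("unknown domain name(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(DOMAIN_NAMES, collapse = "/"), ")")
  entries$start <- as.integer(entries$start)
  entries$end <- as.integer(entries$end)
  if (any(entries$start > entries$end)) stop("domain range with start > end")
  entries <- entries[order(entries$start), , drop = FALSE]
  if (nrow(entries) > 1L &&
      any(entries$start[-1L] <= entries$end[-nrow(entries)]))
    stop("overlapping domain ranges")
  rownames(entries) <- NULL
  structure(entries, class = c("domain_map", "data.frame"))
}

#' Read a domain map from a TSV file
#'
#' Expected columns: `protein` (optional filter), `domain`, `start`, `end`.
#'
#' @param path TSV file path.
#' @param protein optional protein id to filter on.
#' @return a [domain_map()].
#' @export
read_domain_map <- function(path, protein = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("domain", "start", "end")
  if (!all(need %in% names(tab)))
    stop("domain map TSV requires columns: protein (optional), ",
         paste(need, collapse = ", "))
  if (!is.null(protein) && "protein" %in% names(tab))
    tab <- tab[tab$protein == protein, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no domain map rows", if (!is.null(protein))
    paste0(" for protein '", protein, "'") else "")
  domain_map(tab[, need])
}

domain_range <- function(map, domain) {
  rng <- map[map$domain == domain, , drop = FALSE]
  if (nrow(rng) == 0L)
    stop(sprintf("domain '%s' absent from map (has: %s)", domain,
                 paste(unique(map$domain), collapse = ", ")))
  rng
}

# per-residue domain label for a vector of residue numbers; NA when unmapped
domain_of_residues <- function(map, residue_numbers) {
  lab <- rep(NA_character_, length(residue_numbers))
  for (k in seq_len(nrow(map))) {
    hit <- residue_numbers >= map$start[k] & residue_numbers <= map$end[k]
    lab[hit] <- map$domain[k]
  }
  lab
}

#' Write a domain map as TSV
#' @param map a [domain_map()].
#' @param path output path.
#' @param protein protein id written into the `protein` column.
#' @export
write_domain_map <- function(map, path, protein = "protein") {
  tab <- data.frame(protein = protein, domain = map$domain,
                    start = map$start, end = map$end)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
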