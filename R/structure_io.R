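# Multi-chain structure I/O: fixed-column PDB and mmCIF atom_site readers,
# PDB writer, atom selection, per-residue confidence extraction.

ATOM_COLS <- c("serial", "atom_name", "altloc", "residue_name", "chain_id",
               "residue_number", "insertion_code", "x", "y", "z",
               "occupancy", "bfactor", "element")

#' Construct an assembly model
#'
#' An `assembly_model` is a data frame of atom records (one row per atom) with
#' columns `serial`, `atom_name`, `altloc`, `residue_name`, `chain_id`,
#' `residue_number`, `insertion_code`, `x`, `y`, `z`, `occupancy`, `bfactor`,
#' `element`, ordered by chain then residue. For AlphaFold-style models the
#' B-factor column carries pLDDT (0-100).
#'
#' @param atoms data frame with the columns above (`altloc` optional).
#' @param model_id integer model number (multi-model files; default 1).
#' @return an object of class `assembly_model`.
#' @export
assembly_model <- function(atoms, model_id = 1L) {
  if (!is.data.frame(atoms) || nrow(atoms) == 0L)
    stop("empty model: an assembly must contain at least one atom")
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$insertion_code)) atoms$insertion_code <- ""
  missing_cols <- setdiff(ATOM_COLS, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[, ATOM_COLS]
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(is.na(atoms$chain_id) | atoms$chain_id == ""))
    stop("chain_id must be nonempty for every atom")
  # stable order: chain (order of first appearance), residue_number, insertion code
  ch_levels <- unique(atoms$chain_id)
  ord <- order(match(atoms$chain_id, ch_levels), atoms$residue_number,
               atoms$insertion_code)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(atoms, class = c("assembly_model", "data.frame"),
            model_id = as.integer(model_id))
}

#' @export
print.assembly_model <- function(x, ...) {
  seg <- segmentation(x)
  cat(sprintf("<assembly_model> %d atoms, %d chain(s): %s\n", nrow(x),
              nrow(seg), paste(sprintf("%s(%d res)", seg$chain_id,
                                       seg$residue_count), collapse = ", ")))
  invisible(x)
}

#' Chain identifiers of a model, in order of appearance
#' @param model an `assembly_model`.
#' @return character vector of chain ids.
#' @export
chain_ids <- function(model) unique(model$chain_id)

#' Residue-level segmentation of a model
#'
#' One row per chain with its residue count, in chain order. This is the
#' shared object that keeps structure indexing and PAE indexing aligned.
#'
#' @param model an `assembly_model`.
#' @return data frame with columns `chain_id`, `residue_count`.
#' @export
segmentation <- function(model) {
  key <- paste(model$chain_id, model$residue_number, model$insertion_code)
  first <- !duplicated(key)
  res <- model[first, c("chain_id", "residue_number", "insertion_code")]
  counts <- table(factor(res$chain_id, levels = unique(res$chain_id)))
  data.frame(chain_id = names(counts), residue_count = as.integer(counts),
             stringsAsFactors = FALSE)
}

# per-residue table (chain, resnum, icode) in concatenated order
residue_table <- function(model) {
  key <- paste(model$chain_id, model$residue_number, model$insertion_code)
  res <- model[!duplicated(key), c("chain_id", "residue_number", "insertion_code")]
  rownames(res) <- NULL
  res
}

#' Atom coordinates as an n x 3 matrix
#' @param model an `assembly_model`.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(model) {
  m <- cbind(model$x, model$y, model$z)
  colnames(m) <- c("x", "y", "z")
  m
}

trim_ws <- function(x) sub("^\\s+", "", sub("\\s+$", "", x))

parse_pdb_atoms <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  idx <- which(keep)
  if (!length(idx)) return(NULL)
  ln <- lines[idx]
  short <- nchar(ln) < 54  # z field ends at column 54
  if (any(short))
    stop(sprintf("parse error in '%s': ATOM record truncated at line %d",
                 path, idx[which(short)[1]]))
  num <- function(s, from, to) {
    v <- suppressWarnings(as.numeric(substr(s, from, to)))
    v
  }
  x <- num(ln, 31, 38); y <- num(ln, 39, 46); z <- num(ln, 47, 54)
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad))
    stop(sprintf("parse error in '%s': malformed coordinates at line %d",
                 path, idx[bad[1]]))
  occ <- num(ln, 55, 60); occ[is.na(occ)] <- 1
  bf <- num(ln, 61, 66); bf[is.na(bf)] <- 0
  serial <- suppressWarnings(as.integer(substr(ln, 7, 11)))
  serial[is.na(serial)] <- seq_along(ln)[is.na(serial)]
  resno <- suppressWarnings(as.integer(substr(ln, 23, 26)))
  if (anyNA(resno))
    stop(sprintf("parse error in '%s': malformed residue number at line %d",
                 path, idx[which(is.na(resno))[1]]))
  element <- trim_ws(substr(ln, 77, 78))
  guess <- trim_ws(substr(ln, 13, 14))
  element <- ifelse(element == "", substr(gsub("[^A-Za-z]", "", guess), 1, 1),
                    element)
  data.frame(
    serial = serial,
    atom_name = trim_ws(substr(ln, 13, 16)),
    altloc = trim_ws(substr(ln, 17, 17)),
    residue_name = trim_ws(substr(ln, 18, 20)),
    chain_id = trim_ws(substr(ln, 22, 22)),
    residue_number = resno,
    insertion_code = trim_ws(substr(ln, 27, 27)),
    x = x, y = y, z = z, occupancy = occ, bfactor = bf,
    element = toupper(element),
    stringsAsFactors = FALSE
  )
}

# split PDB lines into models; a file without MODEL records is one model
pdb_model_blocks <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (!length(starts)) return(list(`1` = lines))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  blocks <- lapply(seq_along(starts), function(i) {
    lines[(starts[i] + 1L):(ends[i] - 1L)]
  })
  ids <- suppressWarnings(as.integer(trim_ws(substr(lines[starts], 7, 20))))
  ids[is.na(ids)] <- seq_along(starts)[is.na(ids)]
  names(blocks) <- ids
  blocks
}

# resolve alternate locations: keep highest occupancy, ties -> first seen
resolve_altlocs <- function(atoms) {
  if (all(atoms$altloc %in% c("", "A"))) {
    return(atoms)
  }
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$insertion_code,
               atoms$atom_name)
  ord <- order(match(key, unique(key)), -atoms$occupancy,
               seq_len(nrow(atoms)))
  a <- atoms[ord, ]
  a <- a[!duplicated(paste(a$chain_id, a$residue_number, a$insertion_code,
                           a$atom_name)), ]
  a[order(a$serial), ]
}

read_pdb_model <- function(path, model = 1L) {
  lines <- readLines(path, warn = FALSE)
  blocks <- pdb_model_blocks(lines)
  i <- if (model <= length(blocks)) model else
    stop(sprintf("model %d not present in '%s' (%d models)", model, path,
                 length(blocks)))
  atoms <- parse_pdb_atoms(blocks[[i]], path)
  if (is.null(atoms) || nrow(atoms) == 0L)
    stop(sprintf("empty input: no atoms in '%s'", path))
  assembly_model(resolve_altlocs(atoms), model_id = as.integer(names(blocks)[i]))
}

# minimal mmCIF atom_site loop reader (whitespace-tokenized, quoted values)
read_mmcif_model <- function(path, model = 1L) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- grep("^\\s*loop_", lines)
  for (ls in loop_starts) {
    j <- ls + 1L
    fields <- character(0)
    while (j <= length(lines) && grepl("^\\s*_", lines[j])) {
      fields <- c(fields, trim_ws(lines[j]))
      j <- j + 1L
    }
    if (!any(grepl("^_atom_site\\.", fields))) next
    fields <- sub("^_atom_site\\.", "", fields)
    rows <- list()
    while (j <= length(lines)) {
      l <- trim_ws(lines[j])
      if (l == "" || grepl("^(loop_|_|#)", l)) break
      toks <- scan(text = l, what = character(), quiet = TRUE)
      if (length(toks) != length(fields))
        stop(sprintf("parse error in '%s': atom_site row %d has %d tokens, expected %d",
                     path, j, length(toks), length(fields)))
      rows[[length(rows) + 1L]] <- toks
      j <- j + 1L
    }
    tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(tab) <- fields
    pick <- function(...) {
      for (nm in c(...)) if (nm %in% names(tab)) return(tab[[nm]])
      NULL
    }
    if (!is.null(tab$pdbx_PDB_model_num)) {
      models <- unique(tab$pdbx_PDB_model_num)
      if (model > length(models))
        stop(sprintf("model %d not present in '%s'", model, path))
      tab <- tab[tab$pdbx_PDB_model_num == models[model], ]
    }
    dot_na <- function(v) ifelse(v %in% c(".", "?"), "", v)
    atoms <- data.frame(
      serial = as.integer(pick("id") %||% seq_len(nrow(tab))),
      atom_name = dot_na(pick("auth_atom_id", "label_atom_id")),
      altloc = dot_na(pick("label_alt_id") %||% rep("", nrow(tab))),
      residue_name = dot_na(pick("auth_comp_id", "label_comp_id")),
      chain_id = dot_na(pick("auth_asym_id", "label_asym_id")),
      residue_number = as.integer(dot_na(pick("auth_seq_id", "label_seq_id"))),
      insertion_code = dot_na(pick("pdbx_PDB_ins_code") %||% rep("", nrow(tab))),
      x = as.numeric(pick("Cartn_x")), y = as.numeric(pick("Cartn_y")),
      z = as.numeric(pick("Cartn_z")),
      occupancy = as.numeric(dot_na(pick("occupancy") %||% rep("1", nrow(tab)))),
      bfactor = as.numeric(dot_na(pick("B_iso_or_equiv") %||% rep("0", nrow(tab)))),
      element = toupper(dot_na(pick("type_symbol") %||% rep("", nrow(tab)))),
      stringsAsFactors = FALSE
    )
    atoms$occupancy[is.na(atoms$occupancy)] <- 1
    atoms$bfactor[is.na(atoms$bfactor)] <- 0
    if (nrow(atoms) == 0L) stop(sprintf("empty input: no atoms in '%s'", path))
    return(assembly_model(resolve_altlocs(atoms), model_id = model))
  }
  stop(sprintf("parse error in '%s': no atom_site loop found", path))
}

#' Read a multi-chain structure file
#'
#' Reads fixed-column PDB or mmCIF (`atom_site` loop) files. Multi-model files
#' default to the first model; trajectories should go through
#' [read_trajectory()] instead. B-factors (pLDDT for AlphaFold models) are
#' preserved verbatim. Alternate locations are resolved to the
#' highest-occupancy conformer (ties: first encountered).
#'
#' @param path file path.
#' @param format one of `"pdb"`, `"mmcif"`, `"auto"` (by extension).
#' @param model 1-based model index for multi-model files.
#' @return an [assembly_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           model = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "mmcif",
                     mmcif = "mmcif",
                     stop(sprintf("cannot detect format from extension '.%s'", ext)))
  }
  switch(format, pdb = read_pdb_model(path, model),
         mmcif = read_mmcif_model(path, model))
}

format_pdb_atom_line <- function(a) {
  name <- a$atom_name
  # short atom names start in column 14 by convention
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$serial %% 100000L, name_fmt, substr(a$altloc, 1, 1), a$residue_name,
          substr(a$chain_id, 1, 1), a$residue_number %% 10000L,
          substr(a$insertion_code, 1, 1), a$x, a$y, a$z, a$occupancy, a$bfactor,
          a$element)
}

pdb_lines_for_model <- function(model) {
  out <- character(0)
  for (ch in chain_ids(model)) {
    sub <- model[model$chain_id == ch, , drop = FALSE]
    out <- c(out, vapply(seq_len(nrow(sub)), function(i)
      format_pdb_atom_line(sub[i, ]), character(1)), "TER")
  }
  out
}

#' Write a model as a fixed-column PDB file
#'
#' Coordinates are serialized to 3 decimals (PDB fixed columns);
#' `read_structure(write_structure(m))` reproduces coordinates to 3 decimals
#' and chain/residue identities exactly.
#'
#' @param model an [assembly_model()].
#' @param path output file path.
#' @param format only `"pdb"` is supported for writing.
#' @export
write_structure <- function(model, path, format = "pdb") {
  if (!inherits(model, "assembly_model") || nrow(model) == 0L)
    stop("empty model: nothing to write")
  if (format != "pdb") stop("only PDB output is supported")
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e))))
  on.exit(close(con))
  writeLines(c(pdb_lines_for_model(model), "END"), con)
  invisible(NULL)
}

#' Select atoms by chain, domain and atom name
#'
#' Filters preserve the original order. Domain selection applies the same
#' [domain_map()] residue ranges to every chain (homo-oligomer convention).
#'
#' @param model an [assembly_model()].
#' @param chains optional character vector of chain ids to keep.
#' @param domain optional domain name (requires `domain_map`).
#' @param domain_map a [domain_map()] when `domain` is given.
#' @param atom_names optional character vector (e.g. `"CA"`).
#' @return the filtered [assembly_model()].
#' @export
select_atoms <- function(model, chains = NULL, domain = NULL,
                         domain_map = NULL, atom_names = NULL) {
  keep <- rep(TRUE, nrow(model))
  if (!is.null(chains)) {
    missing_ch <- setdiff(chains, chain_ids(model))
    if (length(missing_ch))
      stop("chain(s) not in model: ", paste(missing_ch, collapse = ", "))
    keep <- keep & model$chain_id %in% chains
  }
  if (!is.null(domain)) {
    if (is.null(domain_map)) stop("domain selection requires a domain_map")
    rng <- domain_range(domain_map, domain)
    in_dom <- rep(FALSE, nrow(model))
    for (k in seq_len(nrow(rng)))
      in_dom <- in_dom | (model$residue_number >= rng$start[k] &
                          model$residue_number <= rng$end[k])
    keep <- keep & in_dom
  }
  if (!is.null(atom_names)) keep <- keep & model$atom_name %in% atom_names
  if (!any(keep)) stop("empty selection")
  assembly_model(model[keep, , drop = FALSE], model_id = attr(model, "model_id"))
}

#' Extract per-residue confidence (pLDDT) from B-factors
#'
#' Per residue, the value is the B-factor of its Calpha atom, falling back to
#' the mean over the residue's atoms. Values outside \[0, 100\] (true
#' crystallographic B-factors) set the `out_of_range` attribute rather than
#' failing.
#'
#' @param model an [assembly_model()].
#' @return numeric vector in concatenated chain order, with attributes
#'   `residues` (data frame) and `out_of_range` (logical).
#' @export
extract_plddt <- function(model) {
  if (nrow(model) == 0L) stop("empty model")
  res <- residue_table(model)
  key_model <- paste(model$chain_id, model$residue_number, model$insertion_code)
  key_res <- paste(res$chain_id, res$residue_number, res$insertion_code)
  grp <- match(key_model, key_res)
  is_ca <- model$atom_name == "CA"
  vals <- tapply(model$bfactor, grp, mean)[as.character(seq_len(nrow(res)))]
  vals <- as.numeric(vals)
  if (any(is_ca)) {
    ca_val <- tapply(model$bfactor[is_ca], grp[is_ca], function(v) v[1])
    hit <- match(seq_len(nrow(res)), as.integer(names(ca_val)))
    vals[!is.na(hit)] <- as.numeric(ca_val)[hit[!is.na(hit)]]
  }
  oor <- any(vals < 0 | vals > 100)
  if (oor) warning("B-factors outside [0, 100]: not pLDDT?")
  structure(vals, residues = res, out_of_range = oor)
}
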