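#' Molecular structures as atom tables
#'
#' A structure is a tibble with one row per atom and columns `serial`,
#' `name` (PDB atom name), `element`, `resname`, `resseq`, `chain`,
#' `het` (logical HETATM flag) and `x`, `y`, `z` (Angstrom). The entry
#' identifier and source path travel as attributes so the table pipes
#' cleanly through dplyr verbs.
#'
#' @param atoms a data frame with the columns listed above.
#' @param entry_id character scalar identifying the entry.
#' @param source_path where the structure came from (may be `NA`).
#' @param modres optional table of MODRES-declared residues with columns
#'   `resname`, `chain`, `resseq`.
#' @return a `pdb_structure` tibble.
#' @export
new_structure <- function(atoms, entry_id, source_path = NA_character_, modres = NULL) {
  needed <- c("serial", "name", "element", "resname", "resseq", "chain", "het", "x", "y", "z")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    abort_contract(paste0("structure table lacks columns: ", paste(missing, collapse = ", ")))
  }
  extras <- setdiff(names(atoms), needed)
  atoms <- as_tibble(atoms[, c(needed, extras)])
  if (nrow(atoms) == 0) abort_empty(sprintf("structure '%s' has no atoms", entry_id))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort_contract("non-finite coordinates")
  }
  if (any(is.na(atoms$element) | atoms$element == "")) {
    abort_contract("every atom needs a non-empty element symbol")
  }
  structure(atoms,
    entry_id = entry_id, source_path = source_path, modres = modres,
    class = c("pdb_structure", class(atoms))
  )
}

#' @export
#' @rdname new_structure
#' @param x object to query.
entry_id <- function(x) attr(x, "entry_id")

# keep attributes when subsetting rows internally
restructure <- function(structure, atoms) {
  new_structure(atoms,
    entry_id = attr(structure, "entry_id"),
    source_path = attr(structure, "source_path"),
    modres = attr(structure, "modres")
  )
}

# element from a (trimmed) PDB atom name when columns 77-78 are blank
infer_element <- function(name) {
  two_letter <- c(
    "FE", "ZN", "MG", "MN", "CU", "NI", "CO", "NA", "CL", "BR",
    "SE", "MO", "CD", "HG", "AL", "SI", "AS", "RB", "SR", "CS", "BA", "LI"
  )
  vapply(name, function(nm) {
    stripped <- gsub("[0-9']", "", toupper(nm))
    if (stripped == "") return("X")
    if (substr(stripped, 1, 1) %in% c("H", "D") && nchar(nm) > 2) return("H")
    if (stripped %in% two_letter) return(stripped)
    substr(stripped, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

strip_pdb_ext <- function(path) {
  id <- basename(path)
  sub("\\.(pdb[0-9]*|ent)(\\.gz)?$", "", id, ignore.case = TRUE)
}

#' Read a PDB-format coordinate file
#'
#' Parses fixed-column ATOM/HETATM records via [bio3d::read.pdb()]. Only
#' the first MODEL of multi-model (e.g. NMR) files is kept, and only
#' atoms with blank or 'A' alternate-location codes, so no position is
#' counted twice. `.pdb`, `.pdb1` (biological-assembly) and
#' gzip-compressed files are accepted. Element symbols come from columns
#' 77-78, falling back to inference from the atom name when blank.
#' MODRES records are retained (as an attribute) so that preprocessing
#' can recognize covalently modified polymer residues.
#'
#' @param path path to a PDB-format file.
#' @param entry_id identifier for the entry; defaults to the file name
#'   without its extension.
#' @return a `pdb_structure` tibble (see [new_structure()]).
#' @export
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' write_structure(make_helix("AAGG"), f)
#' s <- read_structure(f)
#' nrow(s)
read_structure <- function(path, entry_id = NULL) {
  if (!file.exists(path)) abort_input(sprintf("no such file: %s", path))
  if (is.null(entry_id)) entry_id <- strip_pdb_ext(path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE, verbose = FALSE)),
    error = function(e) abort_input(sprintf("could not parse '%s': %s", path, conditionMessage(e)))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) abort_empty(sprintf("no atoms parsed from '%s'", path))
  element <- toupper(trimws(at$elesy))
  blank <- is.na(element) | element == ""
  if (any(blank)) element[blank] <- infer_element(trimws(at$elety[blank]))
  atoms <- tibble(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = element,
    resname = trimws(at$resid),
    resseq = as.integer(at$resno),
    chain = ifelse(is.na(at$chain), "", at$chain),
    het = at$type == "HETATM",
    x = at$x, y = at$y, z = at$z
  )
  new_structure(atoms, entry_id, source_path = path, modres = read_modres(path))
}

read_modres <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character(0))
  lines <- lines[startsWith(lines, "MODRES")]
  if (length(lines) == 0) return(NULL)
  tibble(
    resname = trimws(substr(lines, 13, 15)),
    chain = trimws(substr(lines, 17, 17)),
    resseq = suppressWarnings(as.integer(substr(lines, 19, 22)))
  )
}

water_residues <- c("HOH", "WAT", "DOD")

#' Preprocess a structure for fingerprinting
#'
#' Removes hydrogen and deuterium atoms and water residues, then drops
#' HETATM atoms unless their residue is judged part of the polymer (a
#' covalently modified residue such as a phosphoserine). A HETATM
#' residue counts as polymer-linked when its (chain, residue number)
#' falls within the residue-number span of the ATOM records of the same
#' chain, or when it is declared in a MODRES record. Atom order is
#' preserved; the operation is idempotent.
#'
#' @param structure a `pdb_structure`.
#' @return the filtered `pdb_structure`.
#' @export
preprocess_structure <- function(structure) {
  keep <- !(structure$element %in% c("H", "D")) & !(structure$resname %in% water_residues)
  s <- structure[keep, , drop = FALSE]
  if (nrow(s) == 0) abort_empty("no heavy atoms left after water/hydrogen removal")
  het <- s$het
  if (any(het)) {
    linked <- polymer_linked(s, attr(structure, "modres"))
    s <- s[!het | linked, , drop = FALSE]
  }
  if (nrow(s) == 0) abort_empty("no atoms left after HETATM filtering")
  restructure(structure, s)
}

# which HETATM rows belong to residues embedded in the polymer chain
polymer_linked <- function(s, modres) {
  spans <- dplyr::summarise(
    dplyr::group_by(as_tibble(s)[!s$het, c("chain", "resseq")], .data$chain),
    lo = min(.data$resseq), hi = max(.data$resseq), .groups = "drop"
  )
  linked <- rep(FALSE, nrow(s))
  idx <- which(s$het)
  if (length(idx) == 0) return(linked)
  m <- match(s$chain[idx], spans$chain)
  in_span <- !is.na(m) & s$resseq[idx] >= spans$lo[m] & s$resseq[idx] <= spans$hi[m]
  in_modres <- rep(FALSE, length(idx))
  if (!is.null(modres) && nrow(modres) > 0) {
    key <- paste(s$resname[idx], s$chain[idx], s$resseq[idx])
    in_modres <- key %in% paste(modres$resname, modres$chain, modres$resseq)
  }
  linked[idx] <- in_span | in_modres
  linked
}

#' HETATM-content admission filter
#'
#' Computes the fraction of heavy atoms flagged HETATM, after water and
#' hydrogen removal but before any HETATM discarding, and whether the
#' entry passes the admission rule: entries whose HETATM atoms occupy
#' more than 20 % of the heavy-atom count are excluded from a database
#' (strictly greater than; exactly 20 % passes).
#'
#' @param structure a parsed `pdb_structure` (raw, not yet preprocessed).
#' @param threshold exclusion threshold on the HETATM fraction.
#' @return a one-row tibble with columns `entry_id`, `fraction`, `ok`.
#' @export
hetatm_fraction <- function(structure, threshold = 0.20) {
  keep <- !(structure$element %in% c("H", "D")) & !(structure$resname %in% water_residues)
  s <- structure[keep, , drop = FALSE]
  if (nrow(s) == 0) abort_empty("no heavy atoms to assess")
  frac <- sum(s$het) / nrow(s)
  tibble(entry_id = attr(structure, "entry_id"), fraction = frac, ok = frac <= threshold)
}

# ---- atom categories --------------------------------------------------------

the <- new.env(parent = emptyenv())

residue_templates <- function() {
  if (is.null(the$templates)) {
    path <- system.file("extdata", "residue_templates.tsv", package = "pdbshape")
    the$templates <- readr::read_tsv(path, col_types = "cccdddi", progress = FALSE,
                                     col_names = TRUE, show_col_types = FALSE)
    the$templates$hydrophobic <- as.logical(the$templates$hydrophobic)
  }
  the$templates
}

#' Assign atoms to the four fingerprint categories
#'
#' Tags every heavy atom of a preprocessed structure with the categories
#' used by the fingerprint: *all* (every heavy atom), *positive* (the
#' lysine terminal zeta amino nitrogen NZ and the arginine zeta carbon
#' CZ), *negative* (the aspartate gamma carbon CG, the glutamate delta
#' carbon CD, and every phosphorus atom named P — nucleic-acid backbone
#' and phosphate-group phosphorus), and *hydrophobic* (carbon atoms
#' covalently bonded only to carbon or hydrogen).
#'
#' Hydrophobic carbons are resolved from a per-residue lookup table
#' derived from ideal residue topologies (20 standard amino acids plus
#' A/C/G/U and DA/DC/DG/DT nucleotides). Atoms of residues absent from
#' the table fall back to geometric bond inference: two heavy atoms
#' closer than `bond_cutoff` are taken as bonded.
#'
#' @param structure a preprocessed `pdb_structure`.
#' @param method `"template"` (lookup with geometric fallback) or
#'   `"bonds"` (geometric inference for every atom, used as an
#'   independent cross-check in tests).
#' @param bond_cutoff heavy-atom bond distance cutoff in Angstrom.
#' @return the structure with logical columns `is_positive`,
#'   `is_negative`, `is_hydrophobic` added.
#' @export
#' @examples
#' s <- assign_categories(make_helix("KLED"))
#' category_counts(s)
assign_categories <- function(structure, method = c("template", "bonds"), bond_cutoff = 1.9) {
  method <- match.arg(method)
  s <- structure
  s$is_positive <- (s$resname == "LYS" & s$name == "NZ") |
    (s$resname == "ARG" & s$name == "CZ")
  s$is_negative <- (s$resname == "ASP" & s$name == "CG") |
    (s$resname == "GLU" & s$name == "CD") |
    (s$element == "P" & s$name == "P")
  if (method == "template") {
    tpl <- residue_templates()
    key <- paste(s$resname, s$name)
    tpl_key <- paste(tpl$resname, tpl$atom)
    m <- match(key, tpl_key)
    hydro <- tpl$hydrophobic[m]
    known_res <- s$resname %in% unique(tpl$resname)
    # known residue, unknown atom name (e.g. nonstandard naming): not hydrophobic
    hydro[known_res & is.na(hydro)] <- FALSE
    fallback <- !known_res
    if (any(fallback)) hydro[fallback] <- infer_hydrophobic(s, which(fallback), bond_cutoff)
  } else {
    hydro <- infer_hydrophobic(s, seq_len(nrow(s)), bond_cutoff)
  }
  s$is_hydrophobic <- as.logical(hydro)
  restructure(structure, s)
}

# carbon atoms whose heavy neighbors (< cutoff) are all carbons
infer_hydrophobic <- function(s, idx, cutoff) {
  p <- coords_matrix(s)
  is_c <- s$element == "C"
  vapply(idx, function(i) {
    if (!is_c[i]) return(FALSE)
    d2 <- (p[, 1] - p[i, 1])^2 + (p[, 2] - p[i, 2])^2 + (p[, 3] - p[i, 3])^2
    nb <- which(d2 < cutoff^2 & d2 > 1e-12)
    all(is_c[nb])
  }, logical(1))
}

#' @export
#' @rdname assign_categories
category_counts <- function(structure) {
  if (is.null(structure$is_positive)) structure <- assign_categories(structure)
  tibble(
    category = c("all", "positive", "negative", "hydrophobic"),
    n = c(
      nrow(structure), sum(structure$is_positive),
      sum(structure$is_negative), sum(structure$is_hydrophobic)
    )
  )
}

category_indices <- function(structure) {
  list(
    all = seq_len(nrow(structure)),
    positive = which(structure$is_positive),
    negative = which(structure$is_negative),
    hydrophobic = which(structure$is_hydrophobic)
  )
}
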