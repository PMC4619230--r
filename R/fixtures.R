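# Synthetic structure generator: protein-like polymers (ideal helix or
# self-avoiding coil) with template side chains, tagged point clouds
# with analytically known descriptors, multimer assembly, and a
# fixed-column PDB writer. Everything is deterministic given a seed.

aa1to3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

# place point D given A-B-C, bond length |CD|, angle B-C-D (deg),
# dihedral A-B-C-D (deg): the standard internal-coordinate chain step
place_atom <- function(a, b, c, length, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(
    ab[2] * bc[3] - ab[3] * bc[2],
    ab[3] * bc[1] - ab[1] * bc[3],
    ab[1] * bc[2] - ab[2] * bc[1]
  )
  n <- n / sqrt(sum(n^2))
  m <- c(
    n[2] * bc[3] - n[3] * bc[2],
    n[3] * bc[1] - n[1] * bc[3],
    n[1] * bc[2] - n[2] * bc[1]
  )
  d2 <- c(
    -length * cos(ang),
    length * sin(ang) * cos(dih),
    length * sin(ang) * sin(dih)
  )
  c + bc * d2[1] + m * d2[2] + n * d2[3]
}

backbone_geometry <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8
)

# rigidly map a residue template onto built backbone N/CA/C positions
# using the orthonormal frame spanned by (CA->N, CA->C)
align_sidechain <- function(resname, n_pos, ca_pos, c_pos) {
  tpl <- residue_templates()
  rows <- tpl[tpl$resname == resname, ]
  if (nrow(rows) == 0) abort_contract(sprintf("no template for residue '%s'", resname))
  frame_from <- function(n, ca, c) {
    e1 <- n - ca
    e1 <- e1 / sqrt(sum(e1^2))
    v <- c - ca
    e2 <- v - sum(v * e1) * e1
    e2 <- e2 / sqrt(sum(e2^2))
    e3 <- c(
      e1[2] * e2[3] - e1[3] * e2[2],
      e1[3] * e2[1] - e1[1] * e2[3],
      e1[1] * e2[2] - e1[2] * e2[1]
    )
    cbind(e1, e2, e3)
  }
  t_n <- unlist(rows[rows$atom == "N", c("x", "y", "z")])
  t_ca <- unlist(rows[rows$atom == "CA", c("x", "y", "z")])
  t_c <- unlist(rows[rows$atom == "C", c("x", "y", "z")])
  ft <- frame_from(t_n, t_ca, t_c)
  fb <- frame_from(n_pos, ca_pos, c_pos)
  side <- rows[!(rows$atom %in% c("N", "CA", "C", "O")), ]
  if (nrow(side) == 0) return(NULL)
  local <- t(as.matrix(side[, c("x", "y", "z")])) - t_ca
  mapped <- fb %*% (t(ft) %*% local) + ca_pos
  tibble(
    name = side$atom, element = side$element,
    x = mapped[1, ], y = mapped[2, ], z = mapped[3, ]
  )
}

build_chain <- function(sequence, phi_psi, entry_id, chain = "A",
                        clash_cutoff = 2.0, max_tries = 50,
                        resample = NULL) {
  letters1 <- strsplit(sequence, "")[[1]]
  if (length(letters1) < 1) abort_contract("empty sequence")
  bad <- setdiff(letters1, names(aa1to3))
  if (length(bad) > 0) {
    abort_contract(paste0("unknown residue letter(s): ", paste(unique(bad), collapse = ", ")))
  }
  resnames <- unname(aa1to3[letters1])
  g <- backbone_geometry
  nres <- length(resnames)
  rows <- vector("list", nres)
  # backbone anchors of the previous residue
  prev <- list(
    n = c(0, 0, 0),
    ca = c(g$n_ca, 0, 0),
    c = place_atom(c(0, -1, 0), c(0, 0, 0), c(g$n_ca, 0, 0), g$ca_c, g$ang_n_ca_c, 120)
  )
  placed <- NULL # matrix of coordinates placed so far (for clash checks)
  placed_res <- integer(0)
  placed_bb_c <- integer(0) # row index of each residue's backbone C
  for (i in seq_len(nres)) {
    ok <- FALSE
    tries <- 0
    repeat {
      tries <- tries + 1
      ang <- phi_psi(i)
      if (i == 1) {
        n_i <- prev$n; ca_i <- prev$ca
      } else {
        n_i <- place_atom(rows[[i - 1]]$npos, rows[[i - 1]]$capos, rows[[i - 1]]$cpos,
                          g$c_n, g$ang_ca_c_n, rows[[i - 1]]$psi)
        ca_i <- place_atom(rows[[i - 1]]$capos, rows[[i - 1]]$cpos, n_i,
                           g$n_ca, g$ang_c_n_ca, 180) # omega trans
      }
      c_i <- if (i == 1) {
        prev$c
      } else {
        place_atom(rows[[i - 1]]$cpos, n_i, ca_i, g$ca_c, g$ang_n_ca_c, ang[1])
      }
      # carbonyl O anti to the next N, i.e. dihedral psi + 180
      o_i <- place_atom(n_i, ca_i, c_i, g$c_o, g$ang_ca_c_o, ang[2] + 180)
      side <- align_sidechain(resnames[i], n_i, ca_i, c_i)
      res_atoms <- rbind(
        matrix(c(n_i, ca_i, c_i, o_i), ncol = 3, byrow = TRUE),
        if (!is.null(side)) as.matrix(side[, c("x", "y", "z")])
      )
      clash <- FALSE
      if (!is.null(placed)) {
        for (r in seq_len(nrow(res_atoms))) {
          d2 <- (placed[, 1] - res_atoms[r, 1])^2 + (placed[, 2] - res_atoms[r, 2])^2 +
            (placed[, 3] - res_atoms[r, 3])^2
          # the peptide bond C(i-1)-N(i) is covalent, not a clash
          exempt <- if (r == 1) utils::tail(placed_bb_c, 1) else integer(0)
          near <- which(d2 < clash_cutoff^2)
          if (length(setdiff(near, exempt)) > 0) {
            clash <- TRUE
            break
          }
        }
      }
      if (!clash || is.null(resample)) {
        ok <- !clash
        break
      }
      if (tries >= max_tries) break
    }
    if (!ok && !is.null(resample) && i > 1) {
      abort_contract(sprintf("could not grow a self-avoiding chain at residue %d", i))
    }
    rows[[i]] <- list(
      resname = resnames[i], npos = n_i, capos = ca_i, cpos = c_i, opos = o_i,
      side = side, psi = ang[2]
    )
    start_row <- if (is.null(placed)) 0 else nrow(placed)
    placed <- rbind(placed, res_atoms)
    placed_bb_c <- c(placed_bb_c, start_row + 3L)
  }
  atoms <- purrr::imap_dfr(rows, function(r, i) {
    bb <- tibble(
      name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
      x = c(r$npos[1], r$capos[1], r$cpos[1], r$opos[1]),
      y = c(r$npos[2], r$capos[2], r$cpos[2], r$opos[2]),
      z = c(r$npos[3], r$capos[3], r$cpos[3], r$opos[3])
    )
    res <- dplyr::bind_rows(bb, r$side)
    res$resname <- r$resname
    res$resseq <- i
    res
  })
  atoms$serial <- seq_len(nrow(atoms))
  atoms$chain <- chain
  atoms$het <- FALSE
  new_structure(atoms, entry_id = entry_id, source_path = NA_character_)
}

#' Ideal alpha-helical synthetic peptide
#'
#' Builds a peptide with ideal backbone geometry and helical dihedrals
#' (phi = -57, psi = -47, omega = 180; 1.5 A rise and ~100 degrees turn
#' per residue emerge from these), attaching ideal-geometry heavy-atom
#' side chains rigidly at each residue. Fully deterministic.
#'
#' @param sequence one-letter residue codes (20 standard amino acids).
#' @param entry_id identifier (default `"helix"`).
#' @param chain chain identifier.
#' @return a `pdb_structure`.
#' @export
#' @examples
#' h <- make_helix("MKKRLAYAIIQFLHDQLRHGGLSS")
#' category_counts(assign_categories(h))
make_helix <- function(sequence, entry_id = "helix", chain = "A") {
  build_chain(sequence, function(i) c(-57, -47), entry_id, chain,
              resample = NULL)
}

#' Self-avoiding random-coil synthetic peptide
#'
#' Grows a peptide with ideal backbone geometry and random backbone
#' dihedrals drawn from broad coil-compatible ranges, re-drawing a
#' residue's dihedrals (up to `max_tries` times) whenever any new atom
#' comes within `clash_cutoff` of a previously placed, non-bonded atom.
#' Consecutive CA-CA distances are ~3.8 A (trans peptide). Seed
#' determines the conformation completely; composition depends only on
#' the sequence.
#'
#' @param sequence one-letter residue codes.
#' @param seed integer seed.
#' @param entry_id identifier (default `"coil"`).
#' @param chain chain identifier.
#' @param clash_cutoff minimum allowed non-bonded heavy-atom distance.
#' @param max_tries dihedral re-draws per residue before giving up.
#' @return a `pdb_structure`.
#' @export
make_coil <- function(sequence, seed = 1L, entry_id = "coil", chain = "A",
                      clash_cutoff = 2.0, max_tries = 50) {
  withr::with_seed(seed, {
    draw <- function(i) {
      c(stats::runif(1, -150, -60), stats::runif(1, -60, 160))
    }
    # a compact intermediate can wall in the growing end; restart the
    # whole chain (advancing the RNG stream) rather than backtracking
    for (attempt in 1:25) {
      s <- tryCatch(
        build_chain(sequence, draw, entry_id, chain,
                    clash_cutoff = clash_cutoff, max_tries = max_tries,
                    resample = TRUE),
        error = function(e) NULL
      )
      if (!is.null(s)) return(s)
    }
    abort_contract("could not grow a self-avoiding coil for this sequence/seed")
  })
}

point_tags <- tibble::tibble(
  tag = c("all", "positive", "negative", "hydrophobic"),
  resname = c("ALA", "LYS", "ASP", "ALA"),
  name = c("CA", "NZ", "CG", "CB"),
  element = c("C", "N", "C", "C")
)

#' Point-cloud structure with prescribed category tags
#'
#' Emits one pseudo-atom per point, choosing residue and atom names so
#' that [assign_categories()] reproduces the requested tags exactly:
#' `"all"` becomes an alanine CA (no charge, not hydrophobic),
#' `"positive"` a lysine NZ, `"negative"` an aspartate CG,
#' `"hydrophobic"` an alanine CB. Each point is its own residue.
#' Useful for fixtures whose fingerprints and shape descriptors are
#' known analytically.
#'
#' @param points an n x 3 matrix (or data frame) of coordinates.
#' @param tags category tag per point, recycled (default `"all"`).
#' @param entry_id identifier.
#' @return a `pdb_structure`.
#' @export
#' @examples
#' make_point_cloud(cbind(c(0, 2.02), 0, 0)) # the two-atom micro-example
make_point_cloud <- function(points, tags = "all", entry_id = "cloud") {
  p <- as.matrix(points)
  if (ncol(p) != 3 || nrow(p) < 1) abort_contract("points must be an n x 3 matrix")
  tags <- rep_len(tags, nrow(p))
  bad <- setdiff(tags, point_tags$tag)
  if (length(bad) > 0) {
    abort_contract(paste0("unknown category tag(s): ", paste(unique(bad), collapse = ", ")))
  }
  m <- match(tags, point_tags$tag)
  atoms <- tibble(
    serial = seq_len(nrow(p)),
    name = point_tags$name[m],
    element = point_tags$element[m],
    resname = point_tags$resname[m],
    resseq = seq_len(nrow(p)),
    chain = "A",
    het = FALSE,
    x = p[, 1], y = p[, 2], z = p[, 3]
  )
  new_structure(atoms, entry_id = entry_id)
}

#' Assemble rigid copies of a structure into a multimer
#'
#' Concatenates rigid-body copies of a structure (emulating a deposited
#' biological assembly such as a homodimer), giving each copy its own
#' chain identifier and renumbering atom serials.
#'
#' @param structure a `pdb_structure`.
#' @param transforms a list of rigid transforms, each a list with
#'   `rotation` (3 x 3) and `translation` (length 3); the first copy is
#'   usually the identity.
#' @param entry_id identifier of the assembly.
#' @return a `pdb_structure` with `length(transforms)` chains.
#' @export
#' @examples
#' dimer <- assemble_multimer(make_helix("AAAA"), list(
#'   list(rotation = diag(3), translation = c(0, 0, 0)),
#'   list(rotation = diag(3), translation = c(50, 0, 0))
#' ))
assemble_multimer <- function(structure, transforms, entry_id = NULL) {
  if (length(transforms) < 1) abort_contract("need at least one transform")
  chains <- make.unique(rep(LETTERS, length.out = length(transforms)), sep = "")
  copies <- purrr::imap(transforms, function(tr, i) {
    rot <- tr$rotation %||% diag(3)
    tra <- tr$translation %||% c(0, 0, 0)
    s <- transform_structure(structure, rot, tra)
    s$chain <- chains[i]
    as_tibble(s)
  })
  atoms <- dplyr::bind_rows(copies)
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms,
    entry_id = entry_id %||% paste0(attr(structure, "entry_id"), "_x", length(transforms))
  )
}

#' Add Gaussian coordinate noise to a structure
#'
#' Convenience perturbation for building families of near-identical
#' conformers (e.g. retrieval benchmarks): isotropic normal noise of
#' standard deviation `sd` Angstrom on every coordinate.
#'
#' @param structure a `pdb_structure`.
#' @param sd noise standard deviation (A).
#' @param seed integer seed.
#' @param entry_id identifier of the perturbed copy.
#' @return a `pdb_structure`.
#' @export
jitter_structure <- function(structure, sd = 0.5, seed = 1L, entry_id = NULL) {
  p <- coords_matrix(structure)
  noise <- withr::with_seed(seed, matrix(stats::rnorm(length(p), sd = sd), ncol = 3))
  s <- structure
  s$x <- p[, 1] + noise[, 1]
  s$y <- p[, 2] + noise[, 2]
  s$z <- p[, 3] + noise[, 3]
  if (!is.null(entry_id)) attr(s, "entry_id") <- entry_id
  s
}

#' Write a structure as a fixed-column PDB file
#'
#' Emits standard ATOM/HETATM records (plus TER and END) parseable by
#' [read_structure()]; coordinates round-trip at the format's 3-decimal
#' precision and the HETATM flag is preserved.
#'
#' @param structure a `pdb_structure`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_structure <- function(structure, path) {
  s <- structure
  rec <- ifelse(s$het, "HETATM", "ATOM  ")
  # atom-name column convention: names of <= 3 characters start in column 14
  nm <- ifelse(nchar(s$name) <= 3, paste0(" ", s$name), s$name)
  lines <- sprintf(
    "%s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, s$serial %% 100000, nm, s$resname, substr(s$chain, 1, 1), s$resseq %% 10000,
    s$x, s$y, s$z, 1.0, 0.0, s$element
  )
  ter <- cumsum(rle(paste(s$chain, s$het))$lengths)
  out <- character(0)
  last <- 0
  for (t in ter) {
    out <- c(out, lines[(last + 1):t])
    last <- t
  }
  writeLines(c(out, "TER", "END"), path)
  invisible(path)
}
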