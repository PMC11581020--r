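# A structure is a list with class "recep_structure":
#   $atoms  : data.frame, one row per atom, ordered as in the file:
#             serial, name, altloc, resname, chain, resno, ins,
#             x, y, z, occ, b, element, het
#   $source : named list of provenance metadata (tool, model_rank, ptm,
#             iptm, f_scor -- all optional)
# Residues are identified by (chain, resno, ins); residue order within a
# chain is file order (author numbering is never rewritten).

#' Construct a structure object from an atom table
#'
#' @param atoms data.frame with columns serial, name, altloc, resname,
#'   chain, resno, ins, x, y, z, occ, b, element, het.
#' @param source named list of provenance metadata (e.g. tool, ptm, iptm,
#'   f_scor). Stored verbatim; never used to gate analysis.
#' @return An object of class `recep_structure`.
#' @export
new_structure <- function(atoms, source = list()) {
  required <- c("serial", "name", "altloc", "resname", "chain", "resno",
                "ins", "x", "y", "z", "occ", "b", "element", "het")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    stop("atom table missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("structure must contain at least one atom")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source = source), class = "recep_structure")
}

#' @export
print.recep_structure <- function(x, ...) {
  ch <- chain_ids(x)
  cat("<recep_structure> ", nrow(x$atoms), " atoms, ",
      length(ch), " chain(s): ", paste(ch, collapse = ", "), "\n", sep = "")
  for (cid in ch) {
    a <- x$atoms[x$atoms$chain == cid, , drop = FALSE]
    cat("  chain ", cid, ": ", length(unique(residue_keys(a))),
        " residues, ", nrow(a), " atoms\n", sep = "")
  }
  invisible(x)
}

residue_keys <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")
}

#' Chain identifiers of a structure
#' @param structure A `recep_structure`.
#' @return Character vector of chain ids in file order.
#' @export
chain_ids <- function(structure) {
  unique(structure$atoms$chain)
}

#' Extract the atom table of one chain
#' @param structure A `recep_structure`.
#' @param chain Chain identifier.
#' @return data.frame of atoms belonging to that chain, file order.
#' @export
chain_atoms <- function(structure, chain) {
  a <- structure$atoms[structure$atoms$chain == chain, , drop = FALSE]
  if (nrow(a) == 0) stop("no such chain: '", chain, "'")
  rownames(a) <- NULL
  a
}

#' Per-chain residue table
#'
#' One row per residue in chain order, with the residue key used throughout
#' the package (`chain|resno|ins`).
#' @param structure A `recep_structure`.
#' @param chain Chain identifier.
#' @return data.frame with columns key, resname, resno, ins, pos (1-based
#'   position in chain order).
#' @export
chain_residues <- function(structure, chain) {
  a <- chain_atoms(structure, chain)
  key <- residue_keys(a)
  first <- !duplicated(key)
  data.frame(key = key[first], resname = a$resname[first],
             resno = a$resno[first], ins = a$ins[first],
             pos = seq_len(sum(first)), stringsAsFactors = FALSE)
}

# Coordinates of one named atom in one residue (by residue key), or NULL.
residue_atom_xyz <- function(structure, key, atom_name) {
  a <- structure$atoms
  hit <- which(residue_keys(a) == key & a$name == atom_name)
  if (length(hit) == 0) return(NULL)
  as.numeric(a[hit[1], c("x", "y", "z")])
}

# ---- element radius tables ------------------------------------------------

#' Van der Waals radius table
#'
#' Viewer-compatible radii used for contact detection. The values are
#' user-overridable: pass a named numeric vector to replace individual
#' elements.
#'
#' @param override Named numeric vector, element symbol -> radius in
#'   Angstrom, replacing defaults.
#' @param fallback Radius used for elements absent from the table.
#' @return List with `radii` (named numeric) and `fallback`.
#' @export
vdw_radius_table <- function(override = NULL, fallback = 1.70) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
  if (!is.null(override)) {
    if (is.null(names(override)) || any(names(override) == "")) {
      stop("vdw radius override must be a named numeric vector")
    }
    radii[names(override)] <- as.numeric(override)
  }
  if (any(radii <= 0) || fallback <= 0) stop("all radii must be > 0")
  list(radii = radii, fallback = fallback)
}

# Single-bond covalent radii (Angstrom) for bond inference.
covalent_radius <- function(element) {
  tab <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
           SE = 1.20)
  r <- tab[toupper(element)]
  r[is.na(r)] <- 0.77
  unname(r)
}

lookup_vdw <- function(element, table) {
  r <- table$radii[toupper(element)]
  r[is.na(r)] <- table$fallback
  unname(r)
}

# ---- PDB reading ----------------------------------------------------------

# Infer element symbol from a PDB atom name when columns 77-78 are blank.
element_from_name <- function(name) {
  two_letter <- c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR", "CA",
                  "SE", "NI", "CO", "CD", "HG")
  vapply(name, function(nm) {
    s <- gsub("[0-9']", "", trimws(nm))
    if (nchar(s) == 0) return("X")
    if (substr(trimws(nm), 1, 1) %in% as.character(0:9)) return("H")
    up <- toupper(s)
    if (nchar(up) >= 2 && substr(up, 1, 2) %in% two_letter) {
      return(substr(up, 1, 2))
    }
    substr(up, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records using wwPDB v3.3 fixed columns. Only the
#' first model of a multi-model file is read. Alternate locations are
#' resolved to the highest-occupancy conformer (ties: first in file order).
#' HETATM atoms are retained and flagged in the `het` column.
#'
#' @param path Path to a PDB file.
#' @param format Input format; only `"pdb"` is supported.
#' @param source Optional named list of provenance metadata to attach.
#' @return A `recep_structure`.
#' @export
read_structure <- function(path, format = "pdb", source = list()) {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  # keep MODEL 1 only: drop everything after the first ENDMDL
  endmdl <- which(trimws(rec) == "ENDMDL")
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1)]
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("no ATOM records found in ", path)
  al <- lines[is_atom]
  lineno <- which(is_atom)

  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & trimws(s) != "")
    if (length(bad) > 0) {
      stop("cannot parse ", what, " at line ", lineno[bad[1]], ": '",
           al[bad[1]], "'")
    }
    v
  }
  pad <- function(s, n) formatC(s, width = n, flag = "-")
  al_p <- vapply(al, pad, character(1), n = 80, USE.NAMES = FALSE)

  atoms <- data.frame(
    serial  = num(substr(al_p, 7, 11), "serial"),
    name    = trimws(substr(al_p, 13, 16)),
    altloc  = trimws(substr(al_p, 17, 17)),
    resname = trimws(substr(al_p, 18, 20)),
    chain   = trimws(substr(al_p, 22, 22)),
    resno   = num(substr(al_p, 23, 26), "residue number"),
    ins     = trimws(substr(al_p, 27, 27)),
    x       = num(substr(al_p, 31, 38), "x coordinate"),
    y       = num(substr(al_p, 39, 46), "y coordinate"),
    z       = num(substr(al_p, 47, 54), "z coordinate"),
    occ     = num(substr(al_p, 55, 60), "occupancy"),
    b       = num(substr(al_p, 61, 66), "b-factor"),
    element = trimws(substr(al_p, 77, 78)),
    het     = substr(al, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    bad <- which(!is.finite(atoms$x))[1]
    stop("missing coordinates at line ", lineno[bad])
  }
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  blank <- atoms$element == ""
  if (any(blank)) atoms$element[blank] <- element_from_name(atoms$name[blank])
  atoms$chain[atoms$chain == ""] <- "A"

  # altloc resolution: within (chain, resno, ins, name) keep highest
  # occupancy; ties broken by file order.
  if (any(atoms$altloc != "")) {
    grp <- paste(residue_keys(atoms), atoms$name, sep = "|")
    keep <- rep(TRUE, nrow(atoms))
    for (g in unique(grp[duplicated(grp) | duplicated(grp, fromLast = TRUE)])) {
      idx <- which(grp == g)
      best <- idx[which.max(atoms$occ[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
    atoms <- atoms[keep, , drop = FALSE]
  }
  new_structure(atoms, source = source)
}

#' Write a structure to a PDB file
#'
#' Emits wwPDB v3.3 fixed-column ATOM/HETATM records with TER records
#' between chains. Coordinates are written with three decimals, so a
#' read/write round trip preserves them to 1e-3 Angstrom.
#'
#' @param structure A `recep_structure`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  fmt_name <- function(nm, el) {
    # element-aligned atom name: 1-letter elements start in column 14
    if (nchar(nm) >= 4) return(substr(nm, 1, 4))
    if (nchar(el) == 1) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
  }
  out <- character(0)
  for (cid in unique(a$chain)) {
    ca <- a[a$chain == cid, , drop = FALSE]
    recs <- sprintf(
      "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(ca$het, "HETATM", "ATOM"),
      as.integer(ca$serial) %% 100000,
      vapply(seq_len(nrow(ca)),
             function(i) fmt_name(ca$name[i], ca$element[i]), character(1)),
      ca$altloc, ca$resname, ca$chain, as.integer(ca$resno) %% 10000,
      ca$ins, ca$x, ca$y, ca$z, ca$occ, ca$b, toupper(ca$element))
    out <- c(out, recs, "TER")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

# ---- geometry helpers -----------------------------------------------------

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

# Rotation matrix for angle theta (radians) about unit axis u (Rodrigues).
rotation_matrix <- function(axis, theta) {
  u <- unit(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

#' Apply a rigid-body transform to a structure
#'
#' @param structure A `recep_structure`.
#' @param rotation 3x3 rotation matrix (applied first).
#' @param translation length-3 numeric vector (applied second).
#' @param chains Optional chain ids to transform; default all.
#' @return Transformed `recep_structure`.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0), chains = NULL) {
  a <- structure$atoms
  sel <- if (is.null(chains)) rep(TRUE, nrow(a)) else a$chain %in% chains
  xyz <- as.matrix(a[sel, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  a$x[sel] <- xyz[, 1]; a$y[sel] <- xyz[, 2]; a$z[sel] <- xyz[, 3]
  new_structure(a, structure$source)
}

# All atom pairs (i from set A, j from set B) within `cutoff` Angstrom,
# found with a uniform grid so large chains stay tractable. Returns a
# two-column integer matrix of row indices into xyz_a / xyz_b.
neighbor_pairs <- function(xyz_a, xyz_b, cutoff) {
  na <- nrow(xyz_a); nb <- nrow(xyz_b)
  if (na == 0 || nb == 0) {
    return(matrix(integer(0), ncol = 2))
  }
  if (as.double(na) * nb <= 250000) {
    d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), "+") -
      2 * xyz_a %*% t(xyz_b)
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    colnames(hit) <- NULL
    return(hit)
  }
  cell <- cutoff
  key_of <- function(xyz) {
    ijk <- floor(sweep(xyz, 2, c(0, 0, 0), "-") / cell)
    paste(ijk[, 1], ijk[, 2], ijk[, 3])
  }
  ijk_b <- floor(xyz_b / cell)
  bmap <- split(seq_len(nb), paste(ijk_b[, 1], ijk_b[, 2], ijk_b[, 3]))
  ijk_a <- floor(xyz_a / cell)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(0); out_j <- integer(0)
  for (ai in seq_len(na)) {
    cand <- integer(0)
    for (o in seq_len(27)) {
      k <- paste(ijk_a[ai, 1] + offs[o, 1], ijk_a[ai, 2] + offs[o, 2],
                 ijk_a[ai, 3] + offs[o, 3])
      hits <- bmap[[k]]
      if (!is.null(hits)) cand <- c(cand, hits)
    }
    if (length(cand) == 0) next
    d2 <- (xyz_b[cand, 1] - xyz_a[ai, 1])^2 +
      (xyz_b[cand, 2] - xyz_a[ai, 2])^2 +
      (xyz_b[cand, 3] - xyz_a[ai, 3])^2
    ok <- cand[d2 <= cutoff^2]
    out_i <- c(out_i, rep.int(ai, length(ok)))
    out_j <- c(out_j, ok)
  }
  cbind(out_i, out_j, deparse.level = 0)
}
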