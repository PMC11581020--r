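# The six structural features: two measured on ectodomain (ECD) complexes,
# four on transmembrane-domain (TMD) dimers.
#
#   ecd_distance       Angstrom   Calpha-Calpha between the last residue of
#                                 each receptor chain inside a secondary-
#                                 structure element
#   ecd_contacts       count      inter-chain atom pairs with vdW overlap
#                                 >= cutoff (ligand chains excluded)
#   tmd_distance       Angstrom   Calpha-Calpha between final residues
#   tmd_contacts       count      as ecd_contacts, on the TMD dimer
#   tmd_crossing_angle degrees    signed inter-helix-axis angle, |.| <= 90
#   tmd_exit_angle     degrees    angle in [0, 180] between the XY-projected
#                                 Calpha->C vectors of the final residues

#' Contact detection parameters
#'
#' @param overlap_cutoff Signed van der Waals overlap cutoff in Angstrom. A
#'   pair of atoms is a contact when `r_i + r_j - d_ij >= overlap_cutoff`.
#'   The default -0.40 matches the common viewer default (atoms up to
#'   0.4 A apart beyond the sum of radii still count); set `+0.40` for the
#'   strict interpenetration-only reading.
#' @param bond_exclusion Pairs this many covalent bonds apart or fewer are
#'   ignored (default 4). Vacuous across chains, but enforced.
#' @param radius_table A table from [vdw_radius_table()].
#' @return List of class `recep_contact_params`.
#' @export
contact_params <- function(overlap_cutoff = -0.40, bond_exclusion = 4,
                           radius_table = vdw_radius_table()) {
  if (bond_exclusion < 0) stop("bond_exclusion must be >= 0")
  structure(list(overlap_cutoff = overlap_cutoff,
                 bond_exclusion = bond_exclusion,
                 radius_table = radius_table),
            class = "recep_contact_params")
}

#' Count inter-chain van der Waals contacts
#'
#' An unordered atom pair (one atom per chain) is a contact when its vdW
#' overlap `r_i + r_j - d_ij` meets `params$overlap_cutoff`, excluding
#' pairs at most `params$bond_exclusion` covalent bonds apart. Only atoms
#' of the two named chains participate; ligand chains are never included.
#'
#' @param structure A `recep_structure`.
#' @param chain_a,chain_b Chain identifiers (order-symmetric).
#' @param params A [contact_params()] object.
#' @param bonds Optional precomputed [infer_bonds()] graph; computed on
#'   demand when a pair could be within the bond-exclusion range.
#' @return List with `count` (integer) and `pairs` (data.frame of serial_a,
#'   serial_b, distance, overlap).
#' @export
interchain_contacts <- function(structure, chain_a, chain_b,
                                params = contact_params(), bonds = NULL) {
  aa <- chain_atoms(structure, chain_a)
  ab <- chain_atoms(structure, chain_b)
  rt <- params$radius_table
  ra <- lookup_vdw(aa$element, rt)
  rb <- lookup_vdw(ab$element, rt)
  # overlap >= cutoff  <=>  d <= r_i + r_j - cutoff
  maxcut <- max(outer(ra, rb, "+")) - params$overlap_cutoff
  if (maxcut <= 0) {
    return(list(count = 0L,
                pairs = data.frame(serial_a = numeric(0), serial_b = numeric(0),
                                   distance = numeric(0), overlap = numeric(0))))
  }
  xa <- as.matrix(aa[, c("x", "y", "z")])
  xb <- as.matrix(ab[, c("x", "y", "z")])
  pr <- neighbor_pairs(xa, xb, maxcut)
  if (nrow(pr) > 0) {
    d <- sqrt(rowSums((xa[pr[, 1], , drop = FALSE] -
                         xb[pr[, 2], , drop = FALSE])^2))
    ov <- ra[pr[, 1]] + rb[pr[, 2]] - d
    keep <- ov >= params$overlap_cutoff
    pr <- pr[keep, , drop = FALSE]; d <- d[keep]; ov <- ov[keep]
  } else {
    d <- numeric(0); ov <- numeric(0)
  }
  if (nrow(pr) > 0 && params$bond_exclusion > 0) {
    if (is.null(bonds)) bonds <- infer_bonds(structure)
    bd <- bond_distance_matrix(bonds, aa$serial[unique(pr[, 1])],
                               ab$serial[unique(pr[, 2])])
    ia <- match(as.character(aa$serial[pr[, 1]]), rownames(bd))
    ib <- match(as.character(ab$serial[pr[, 2]]), colnames(bd))
    keep <- bd[cbind(ia, ib)] > params$bond_exclusion
    pr <- pr[keep, , drop = FALSE]; d <- d[keep]; ov <- ov[keep]
  }
  list(count = nrow(pr),
       pairs = data.frame(serial_a = aa$serial[pr[, 1]],
                          serial_b = ab$serial[pr[, 2]],
                          distance = d, overlap = ov))
}

#' ECD terminal distance
#'
#' Euclidean distance between the Calpha atoms of the last residue of each
#' receptor chain that lies inside a secondary-structure element (H or E).
#'
#' @param structure A `recep_structure`.
#' @param chain_a,chain_b Receptor chain identifiers.
#' @param ss A `recep_ss` assignment; computed on demand when `NULL`.
#' @return Distance in Angstrom.
#' @export
ecd_terminal_distance <- function(structure, chain_a, chain_b, ss = NULL) {
  if (is.null(ss)) ss <- assign_secondary_structure(structure)
  pa <- last_structured_residue(structure, chain_a, ss)
  pb <- last_structured_residue(structure, chain_b, ss)
  ca_a <- residue_atom_xyz(structure, pa$key, "CA")
  ca_b <- residue_atom_xyz(structure, pb$key, "CA")
  if (is.null(ca_a)) stop("residue ", pa$key, " lacks a CA atom")
  if (is.null(ca_b)) stop("residue ", pb$key, " lacks a CA atom")
  vnorm(ca_a - ca_b)
}

#' TMD terminal distance
#'
#' Calpha-Calpha distance between the final residues of a two-chain TMD
#' dimer.
#'
#' @param dimer A `recep_structure` with exactly two chains.
#' @return Distance in Angstrom.
#' @export
tmd_terminal_distance <- function(dimer) {
  ch <- chain_ids(dimer)
  if (length(ch) != 2) stop("TMD dimer must have exactly 2 chains, found ",
                            length(ch))
  ca <- lapply(ch, function(cid) {
    rr <- chain_residues(dimer, cid)
    xyz <- residue_atom_xyz(dimer, rr$key[nrow(rr)], "CA")
    if (is.null(xyz)) stop("final residue of chain ", cid, " lacks CA")
    xyz
  })
  vnorm(ca[[1]] - ca[[2]])
}

#' Helix axis of a chain
#'
#' Principal direction of 4-residue sliding-window-averaged Calpha
#' positions, oriented N to C.
#'
#' @param structure A `recep_structure`.
#' @param chain Chain identifier (needs >= 8 Calpha atoms).
#' @return List with unit `direction` (length-3) and `centroid`.
#' @export
helix_axis <- function(structure, chain) {
  a <- chain_atoms(structure, chain)
  ca <- as.matrix(a[a$name == "CA", c("x", "y", "z")])
  if (nrow(ca) < 8) stop("chain ", chain, " has fewer than 8 CA atoms")
  w <- 4
  sm <- t(vapply(seq_len(nrow(ca) - w + 1),
                 function(i) colMeans(ca[i:(i + w - 1), , drop = FALSE]),
                 numeric(3)))
  ctr <- colMeans(sm)
  pc <- prcomp(sm, center = TRUE)
  dir <- pc$rotation[, 1]
  if (sum(dir * (sm[nrow(sm), ] - sm[1, ])) < 0) dir <- -dir
  list(direction = unname(dir / vnorm(dir)), centroid = unname(ctr))
}

#' Signed TMD crossing angle
#'
#' Magnitude is the inter-axis angle folded to `[0, 90]` degrees; the sign
#' is the handedness of the packing, taken from the torsion of the two axis
#' directions about their common normal (right-handed crossings positive).
#' Invariant under chain-order swap.
#'
#' @param dimer A `recep_structure` with exactly two helical chains.
#' @return Angle in degrees, in `[-90, 90]`.
#' @export
tmd_crossing_angle <- function(dimer) {
  ch <- chain_ids(dimer)
  if (length(ch) != 2) stop("TMD dimer must have exactly 2 chains")
  a1 <- helix_axis(dimer, ch[1])
  a2 <- helix_axis(dimer, ch[2])
  u1 <- a1$direction; u2 <- a2$direction
  w <- a2$centroid - a1$centroid     # from axis 1 towards axis 2
  # canonicalize so the inter-axis angle lands in [0, 90] (helix direction
  # is defined N->C, but packing angle is axis-line geometry)
  if (sum(u1 * u2) < 0) u2 <- -u2
  cx <- c(u1[2] * u2[3] - u1[3] * u2[2],
          u1[3] * u2[1] - u1[1] * u2[3],
          u1[1] * u2[2] - u1[2] * u2[1])
  ang <- acos(max(-1, min(1, sum(u1 * u2)))) * 180 / pi
  if (vnorm(cx) < 1e-9) return(0)    # parallel axes
  # handedness: torsion of u2 about the centroid-connecting direction
  s <- sign(sum(cx * w))
  if (s == 0) s <- 1
  s * ang
}

#' TMD exit angle
#'
#' Angle between the XY-plane projections of the final-residue Calpha -> C
#' (carbonyl carbon) vectors of the two chains, via the arccosine of their
#' normalized dot product. Requires the structure to be in the membrane
#' frame (membrane normal along Z); the value is frame-dependent by
#' construction. Set `project = FALSE` for a full-3D variant (a deliberate
#' non-standard option, labeled as such).
#'
#' @param dimer A `recep_structure` with exactly two chains whose final
#'   residues carry CA and C atoms.
#' @param project Project onto the XY plane (default TRUE, the defining
#'   convention).
#' @return Angle in degrees in `[0, 180]`.
#' @export
tmd_exit_angle <- function(dimer, project = TRUE) {
  ch <- chain_ids(dimer)
  if (length(ch) != 2) stop("TMD dimer must have exactly 2 chains")
  vecs <- lapply(ch, function(cid) {
    rr <- chain_residues(dimer, cid)
    key <- rr$key[nrow(rr)]
    ca <- residue_atom_xyz(dimer, key, "CA")
    cc <- residue_atom_xyz(dimer, key, "C")
    if (is.null(ca) || is.null(cc)) {
      stop("final residue of chain ", cid, " lacks CA or C")
    }
    v <- cc - ca
    if (project) v <- c(v[1], v[2])
    if (vnorm(v) <= 1e-6) {
      stop("degenerate geometry: projected Calpha->C vector of chain ",
           cid, " has near-zero norm")
    }
    v
  })
  cosv <- sum(vecs[[1]] * vecs[[2]]) / (vnorm(vecs[[1]]) * vnorm(vecs[[2]]))
  acos(max(-1, min(1, cosv))) * 180 / pi
}

#' Average TMD features over the two orderings of a heterodimer
#'
#' TMD dimer predictions depend on which sequence is entered first; for
#' heterodimeric pairs both orderings are modeled and the element-wise
#' arithmetic mean of the four TMD features is used downstream. Averaged
#' contact counts may be non-integral.
#'
#' @param features_ab,features_ba Named numeric vectors (or lists) carrying
#'   tmd_distance, tmd_contacts, tmd_crossing_angle, tmd_exit_angle.
#' @return Named numeric vector of the four averaged TMD features.
#' @export
average_ordered_tmd_features <- function(features_ab, features_ba) {
  keys <- c("tmd_distance", "tmd_contacts", "tmd_crossing_angle",
            "tmd_exit_angle")
  fa <- unlist(features_ab)[keys]
  fb <- unlist(features_ba)[keys]
  if (any(is.na(fa)) || any(is.na(fb))) {
    stop("both inputs must carry all four TMD features")
  }
  (fa + fb) / 2
}

#' TMD features of a dimer structure
#'
#' @param dimer A two-chain `recep_structure` in the membrane frame.
#' @param params A [contact_params()] object.
#' @return Named numeric vector: tmd_distance, tmd_contacts,
#'   tmd_crossing_angle, tmd_exit_angle.
#' @export
tmd_features <- function(dimer, params = contact_params()) {
  ch <- chain_ids(dimer)
  if (length(ch) != 2) stop("TMD dimer must have exactly 2 chains")
  c(tmd_distance = tmd_terminal_distance(dimer),
    tmd_contacts = as.numeric(
      interchain_contacts(dimer, ch[1], ch[2], params)$count),
    tmd_crossing_angle = tmd_crossing_angle(dimer),
    tmd_exit_angle = tmd_exit_angle(dimer))
}

#' ECD features of a two-receptor complex
#'
#' @param structure A `recep_structure`; may also carry ligand chains,
#'   which never enter the contact count.
#' @param chain_a,chain_b Receptor chain identifiers.
#' @param ss Optional `recep_ss`; computed on demand.
#' @param params A [contact_params()] object.
#' @return Named numeric vector: ecd_distance, ecd_contacts.
#' @export
ecd_features <- function(structure, chain_a, chain_b, ss = NULL,
                         params = contact_params()) {
  if (is.null(ss)) ss <- assign_secondary_structure(structure)
  c(ecd_distance = ecd_terminal_distance(structure, chain_a, chain_b, ss),
    ecd_contacts = as.numeric(
      interchain_contacts(structure, chain_a, chain_b, params)$count))
}

#' ECD features of a heterotetrameric complex
#'
#' For receptor-ligand complexes with two copies each of an alpha and a
#' beta receptor chain, the perfect matching of alpha to beta chains that
#' minimizes the summed ECD terminal distance is selected, and the two
#' matched pairs' (ecd_distance, ecd_contacts) are averaged.
#'
#' @param structure A `recep_structure` carrying the four receptor chains.
#' @param alpha_chains,beta_chains Length-2 character vectors of chain ids.
#' @param ss Optional `recep_ss`; computed on demand.
#' @param params A [contact_params()] object.
#' @return List with `features` (named numeric: ecd_distance, ecd_contacts)
#'   and `pairing` (2x2 character matrix of selected alpha-beta pairs).
#' @export
tetramer_ecd_features <- function(structure, alpha_chains, beta_chains,
                                  ss = NULL, params = contact_params()) {
  if (length(alpha_chains) != 2 || length(beta_chains) != 2) {
    stop("exactly two alpha and two beta chains are required")
  }
  if (is.null(ss)) ss <- assign_secondary_structure(structure)
  d <- function(a, b) ecd_terminal_distance(structure, a, b, ss)
  # two possible perfect matchings of {a1,a2} to {b1,b2}
  m1 <- d(alpha_chains[1], beta_chains[1]) + d(alpha_chains[2], beta_chains[2])
  m2 <- d(alpha_chains[1], beta_chains[2]) + d(alpha_chains[2], beta_chains[1])
  pairs <- if (m1 <= m2) {
    rbind(c(alpha_chains[1], beta_chains[1]),
          c(alpha_chains[2], beta_chains[2]))
  } else {
    rbind(c(alpha_chains[1], beta_chains[2]),
          c(alpha_chains[2], beta_chains[1]))
  }
  vals <- apply(pairs, 1, function(p) {
    ecd_features(structure, p[1], p[2], ss, params)
  })
  list(features = rowMeans(vals), pairing = pairs)
}

# ---- manifest-driven feature table ---------------------------------------

#' Read a complex manifest
#'
#' CSV with header columns design_id, structure_file, receptor_chain_a,
#' receptor_chain_b, ligand_chains (semicolon-separated), complex_kind
#' (`dimer` or `tetramer`), tmd_file_ab, tmd_file_ba (empty for homodimeric
#' TMD pairs). Paths are resolved relative to the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return data.frame, one row per design.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  required <- c("design_id", "structure_file", "receptor_chain_a",
                "receptor_chain_b", "ligand_chains", "complex_kind",
                "tmd_file_ab", "tmd_file_ba")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0) {
    stop("manifest missing columns: ", paste(missing, collapse = ", "))
  }
  bad <- which(m$receptor_chain_a == m$receptor_chain_b)
  if (length(bad) > 0) {
    stop("receptor chains must be distinct (design ",
         m$design_id[bad[1]], ")")
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(p == "" | grepl("^/", p), p, file.path(base, p))
  }
  m$structure_file <- resolve(m$structure_file)
  m$tmd_file_ab <- resolve(m$tmd_file_ab)
  m$tmd_file_ba <- resolve(m$tmd_file_ba)
  m
}

# Feature vector for one manifest row.
features_for_row <- function(row, params) {
  st <- read_structure(row$structure_file)
  ss <- assign_secondary_structure(st)
  ecd <- if (identical(row$complex_kind, "tetramer")) {
    # receptor_chain_a / _b hold semicolon-separated alpha / beta pairs
    ac <- strsplit(row$receptor_chain_a, ";")[[1]]
    bc <- strsplit(row$receptor_chain_b, ";")[[1]]
    tetramer_ecd_features(st, ac, bc, ss, params)$features
  } else {
    ecd_features(st, row$receptor_chain_a, row$receptor_chain_b, ss, params)
  }
  tab <- tmd_features(read_structure(row$tmd_file_ab), params)
  tmd <- if (!is.na(row$tmd_file_ba) && nzchar(row$tmd_file_ba)) {
    tba <- tmd_features(read_structure(row$tmd_file_ba), params)
    average_ordered_tmd_features(tab, tba)
  } else {
    tab
  }
  c(ecd, tmd)
}

#' Build the feature table for a manifest of designs
#'
#' One row per design: the two ECD features from the ectodomain-ligand
#' complex (dimer or tetramer routing by `complex_kind`) and the four TMD
#' features from the TMD dimer model(s), averaging the two orderings for
#' heterodimeric TMD pairs.
#'
#' @param manifest data.frame from [read_manifest()] (or built in code).
#' @param params A [contact_params()] object.
#' @param skip_errors Collect per-design failures and continue (default
#'   FALSE: abort, reporting every failing design).
#' @return data.frame with design_id and the six feature columns.
#' @export
build_feature_table <- function(manifest, params = contact_params(),
                                skip_errors = FALSE) {
  cols <- c("ecd_distance", "ecd_contacts", "tmd_distance", "tmd_contacts",
            "tmd_crossing_angle", "tmd_exit_angle")
  out <- data.frame(design_id = character(0))
  for (col in cols) out[[col]] <- numeric(0)
  if (nrow(manifest) == 0) return(out)
  rows <- vector("list", nrow(manifest))
  failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, , drop = FALSE]
    fv <- tryCatch(features_for_row(row, params), error = function(e) e)
    if (inherits(fv, "error")) {
      failures <- c(failures,
                    paste0(row$design_id, ": ", conditionMessage(fv)))
    } else {
      rows[[i]] <- data.frame(design_id = row$design_id, t(fv))
    }
  }
  if (length(failures) > 0 && !skip_errors) {
    stop("feature extraction failed for ", length(failures), " design(s):\n",
         paste(failures, collapse = "\n"))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Write a feature table CSV
#'
#' Emits a comment header line documenting units, then the table.
#' @param features data.frame from [build_feature_table()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# units: ecd_distance A, ecd_contacts count,",
                   "tmd_distance A, tmd_contacts count,",
                   "tmd_crossing_angle deg, tmd_exit_angle deg"), con)
  utils::write.csv(features, con, row.names = FALSE)
  invisible(path)
}

#' Read a feature table CSV written by [write_feature_table()]
#' @param path CSV path (comment lines starting with `#` are skipped).
#' @return data.frame.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
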