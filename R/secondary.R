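# Hydrogen-bond-pattern secondary structure assignment (Kabsch-Sander
# style), collapsed to three states: H (helix), E (strand), C (coil).
#
# The amide hydrogen is placed geometrically (PDB models rarely carry it):
# H sits 1.01 A from N along the bisector of the N->C(prev) and N->CA
# directions, pointing away from both. The electrostatic H-bond energy
#   E = 0.084 * 332 * (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN)  [kcal/mol]
# defines a bond when E < threshold (default -0.5 kcal/mol). Helices come
# from consecutive i -> i+3/4/5 turns, strands from parallel/antiparallel
# bridge ladders; H takes priority over E on overlap.

# Per-residue backbone coordinate table across all chains.
backbone_table <- function(structure) {
  a <- structure$atoms
  key <- residue_keys(a)
  first <- !duplicated(key)
  res <- data.frame(key = key[first], chain = a$chain[first],
                    resno = a$resno[first], ins = a$ins[first],
                    resname = a$resname[first], stringsAsFactors = FALSE)
  res$pos <- stats::ave(seq_len(nrow(res)), res$chain, FUN = seq_along)
  coord_of <- function(atname) {
    m <- matrix(NA_real_, nrow(res), 3)
    hit <- a$name == atname
    idx <- match(key[hit], res$key)
    m[idx, ] <- as.matrix(a[hit, c("x", "y", "z")])
    m
  }
  res$N <- coord_of("N"); res$CA <- coord_of("CA")
  res$C <- coord_of("C"); res$O <- coord_of("O")
  res$complete <- stats::complete.cases(res$N) & stats::complete.cases(res$CA) &
    stats::complete.cases(res$C) & stats::complete.cases(res$O)
  res
}

# Geometric amide hydrogen positions; NA for chain-first residues, prolines,
# and residues with incomplete backbone context.
place_amide_hydrogens <- function(res) {
  H <- matrix(NA_real_, nrow(res), 3)
  for (i in seq_len(nrow(res))) {
    if (res$pos[i] == 1 || res$resname[i] == "PRO" || !res$complete[i]) next
    p <- i - 1
    if (res$chain[p] != res$chain[i] || !res$complete[p]) next
    n <- res$N[i, ]; cprev <- res$C[p, ]; ca <- res$CA[i, ]
    d1 <- n - cprev; d2 <- n - ca
    if (vnorm(d1) < 1e-6 || vnorm(d2) < 1e-6) next
    dir <- d1 / vnorm(d1) + d2 / vnorm(d2)
    if (vnorm(dir) < 1e-6) next
    H[i, ] <- n + 1.01 * dir / vnorm(dir)
  }
  H
}

hbond_energy <- function(C, O, N, H) {
  q <- 0.084 * 332
  d <- function(a, b) sqrt(sum((a - b)^2))
  q * (1 / d(O, N) + 1 / d(C, H) - 1 / d(O, H) - 1 / d(C, N))
}

#' Assign secondary structure from backbone hydrogen-bond patterns
#'
#' @param structure A `recep_structure`. Chains need backbone atoms N, CA,
#'   C, O for most residues; residues with incomplete backbones are labeled
#'   C and excluded from the hydrogen-bond search.
#' @param energy_threshold Hydrogen-bond energy cutoff in kcal/mol
#'   (default -0.5; more negative is stricter).
#' @return An object of class `recep_ss`: data.frame with columns key,
#'   chain, resno, ins, pos and label in `c("H", "E", "C")`, one row per
#'   residue of every chain.
#' @export
assign_secondary_structure <- function(structure, energy_threshold = -0.5) {
  res <- backbone_table(structure)
  n <- nrow(res)
  label <- rep("C", n)

  for (cid in unique(res$chain)) {
    if (sum(res$complete & res$chain == cid) < 3) {
      warning("chain ", cid, " has fewer than 3 complete-backbone residues; ",
              "assigned all-coil")
    }
  }

  Hpos <- place_amide_hydrogens(res)
  donors <- which(!is.na(Hpos[, 1]))
  acceptors <- which(res$complete)

  hb <- matrix(FALSE, n, n)  # hb[i, j]: CO of i accepts H from NH of j
  if (length(donors) > 0 && length(acceptors) > 0) {
    cand <- neighbor_pairs(res$CA[acceptors, , drop = FALSE],
                           res$CA[donors, , drop = FALSE], 9.0)
    for (r in seq_len(nrow(cand))) {
      i <- acceptors[cand[r, 1]]; j <- donors[cand[r, 2]]
      if (i == j) next
      if (res$chain[i] == res$chain[j] && abs(res$pos[i] - res$pos[j]) < 2) next
      e <- hbond_energy(res$C[i, ], res$O[i, ], res$N[j, ], Hpos[j, ])
      if (e < energy_threshold) hb[i, j] <- TRUE
    }
  }

  # same-chain neighbor indices in the global table
  nxt <- rep(NA_integer_, n); prv <- rep(NA_integer_, n)
  ii <- seq_len(n - 1)
  same <- res$chain[ii] == res$chain[ii + 1]
  nxt[ii[same]] <- ii[same] + 1L
  prv[ii[same] + 1L] <- ii[same]
  ahead <- function(i, k) {       # i + k within the same chain, else NA
    j <- i
    for (s in seq_len(k)) { j <- nxt[j]; if (is.na(j)) return(NA_integer_) }
    j
  }

  # turns: CO of i accepts from NH of i+k
  turn <- function(k) {
    t <- rep(FALSE, n)
    for (i in seq_len(n)) {
      j <- ahead(i, k)
      if (!is.na(j) && hb[i, j]) t[i] <- TRUE
    }
    t
  }
  is_helix <- rep(FALSE, n)
  for (k in c(4, 3, 5)) {
    tk <- turn(k)
    for (i in 2:n) {
      if (!is.na(prv[i]) && tk[prv[i]] && tk[i]) {
        run <- i
        for (s in seq_len(k - 1)) {
          run <- c(run, ahead(i, s))
        }
        is_helix[run[!is.na(run)]] <- TRUE
      }
    }
  }

  # bridges
  is_strand <- rep(FALSE, n)
  for (i in seq_len(n)) {
    jj <- which(hb[i, ] | hb[, i])
    jj <- unique(c(jj, jj - 1L, jj + 1L))
    jj <- jj[jj >= 1 & jj <= n]
    for (j in jj) {
      if (res$chain[i] == res$chain[j] && abs(res$pos[i] - res$pos[j]) < 3) next
      im <- prv[i]; ip <- nxt[i]; jm <- prv[j]; jp <- nxt[j]
      par <- (!is.na(im) && !is.na(ip) && hb[im, j] && hb[j, ip]) ||
             (!is.na(jm) && !is.na(jp) && hb[jm, i] && hb[i, jp])
      anti <- (hb[i, j] && hb[j, i]) ||
              (!is.na(im) && !is.na(jp) && !is.na(jm) && !is.na(ip) &&
               hb[im, jp] && hb[jm, ip])
      if (par || anti) { is_strand[i] <- TRUE; is_strand[j] <- TRUE }
    }
  }

  label[is_strand] <- "E"
  label[is_helix] <- "H"
  label[!res$complete] <- "C"
  out <- data.frame(key = res$key, chain = res$chain, resno = res$resno,
                    ins = res$ins, pos = res$pos, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("recep_ss", class(out))
  out
}

#' Last residue of a chain inside a secondary-structure element
#'
#' Selects the residue with the greatest chain position whose label is H or
#' E. Chains with no structured residue raise an error -- callers must not
#' silently fall back to the chain terminus.
#'
#' @param structure A `recep_structure`.
#' @param chain Chain identifier.
#' @param ss A `recep_ss` assignment covering the chain.
#' @return One-row data.frame (key, chain, resno, ins, pos, label).
#' @export
last_structured_residue <- function(structure, chain, ss) {
  s <- ss[ss$chain == chain, , drop = FALSE]
  if (nrow(s) == 0) stop("chain '", chain, "' not present in assignment")
  hit <- which(s$label %in% c("H", "E"))
  if (length(hit) == 0) {
    stop("chain '", chain, "' has no residue in a secondary-structure element")
  }
  s[hit[length(hit)], , drop = FALSE]
}
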