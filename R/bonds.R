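# Covalent bond inference and bond-graph distances.
#
# Bonds are inferred within chains only: two atoms of the same chain are
# bonded iff their distance is at most the sum of their single-bond
# covalent radii plus a 0.4 A tolerance. Inter-chain covalent bonds are
# never inferred, so bond-graph distances across chains are infinite --
# which is what makes the "ignore pairs <= 4 bonds apart" contact
# exclusion vacuous (but still enforced) for inter-chain contacts.

#' Infer covalent bonds of a structure
#'
#' @param structure A `recep_structure`.
#' @param tolerance Distance tolerance in Angstrom added to the sum of
#'   covalent radii (default 0.4).
#' @return An object of class `recep_bondgraph`: an igraph whose vertex
#'   names are atom serial numbers.
#' @export
infer_bonds <- function(structure, tolerance = 0.4) {
  a <- structure$atoms
  edges <- matrix(character(0), ncol = 2)
  for (cid in unique(a$chain)) {
    ca <- a[a$chain == cid, , drop = FALSE]
    xyz <- as.matrix(ca[, c("x", "y", "z")])
    rad <- covalent_radius(ca$element)
    maxcut <- 2 * max(rad) + tolerance
    pr <- neighbor_pairs(xyz, xyz, maxcut)
    pr <- pr[pr[, 1] < pr[, 2], , drop = FALSE]
    if (nrow(pr) == 0) next
    d <- sqrt(rowSums((xyz[pr[, 1], , drop = FALSE] -
                         xyz[pr[, 2], , drop = FALSE])^2))
    ok <- d <= rad[pr[, 1]] + rad[pr[, 2]] + tolerance
    if (any(ok)) {
      edges <- rbind(edges,
                     cbind(as.character(ca$serial[pr[ok, 1]]),
                           as.character(ca$serial[pr[ok, 2]])))
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(a), name = as.character(a$serial))
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  class(g) <- c("recep_bondgraph", class(g))
  g
}

#' Number of covalent bonds separating two atoms
#'
#' Shortest path length in the bond graph; `Inf` when the atoms are in
#' disconnected components (always the case across chains).
#'
#' @param graph A `recep_bondgraph` from [infer_bonds()].
#' @param a,b Atom serial numbers.
#' @return Non-negative integer count of bonds, or `Inf`.
#' @export
bond_distance <- function(graph, a, b) {
  va <- as.character(a); vb <- as.character(b)
  nm <- igraph::V(graph)$name
  if (!(va %in% nm)) stop("unknown atom id: ", a)
  if (!(vb %in% nm)) stop("unknown atom id: ", b)
  as.numeric(igraph::distances(graph, v = va, to = vb))
}

# Bond-graph distances from each atom in `from` to each in `to`
# (serial-number vectors); returns a matrix. Used for contact exclusion.
bond_distance_matrix <- function(graph, from, to) {
  igraph::distances(graph, v = as.character(from), to = as.character(to))
}
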