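# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdirs.

# Minimal atom-table row(s) for hand-placed atoms.
toy_atoms <- function(x, y, z, element = "C", chain = "A",
                      resno = seq_along(x), name = "X", resname = "UNK",
                      serial_offset = 0) {
  n <- length(x)
  data.frame(serial = seq_len(n) + serial_offset,
             name = rep_len(name, n), altloc = "",
             resname = rep_len(resname, n), chain = rep_len(chain, n),
             resno = rep_len(resno, n), ins = "",
             x = x, y = y, z = z, occ = 1, b = 0,
             element = rep_len(element, n), het = FALSE,
             stringsAsFactors = FALSE)
}

toy_structure <- function(...) new_structure(toy_atoms(...))

# Two-chain random point cloud for contact-oracle comparisons.
random_two_chain <- function(n_a, n_b, box = 15,
                             elements = c("C", "N", "O", "S", "H")) {
  mk <- function(n, chain, off) {
    toy_atoms(runif(n, 0, box), runif(n, 0, box), runif(n, 0, box),
              element = sample(elements, n, replace = TRUE),
              chain = chain, serial_offset = off)
  }
  new_structure(rbind(mk(n_a, "A", 0), mk(n_b, "B", n_a)))
}

# Exhaustive all-pairs contact count; the independent oracle.
brute_force_contacts <- function(structure, chain_a, chain_b,
                                 overlap_cutoff = -0.4,
                                 table = vdw_radius_table()) {
  aa <- chain_atoms(structure, chain_a)
  ab <- chain_atoms(structure, chain_b)
  cnt <- 0L
  for (i in seq_len(nrow(aa))) {
    ri <- recepstruct:::lookup_vdw(aa$element[i], table)
    for (j in seq_len(nrow(ab))) {
      rj <- recepstruct:::lookup_vdw(ab$element[j], table)
      d <- sqrt((aa$x[i] - ab$x[j])^2 + (aa$y[i] - ab$y[j])^2 +
                  (aa$z[i] - ab$z[j])^2)
      if (ri + rj - d >= overlap_cutoff) cnt <- cnt + 1L
    }
  }
  cnt
}

# Swap chain labels of a two-chain structure (A<->B), reordering atoms so
# the new chain A comes first.
swap_chains <- function(structure) {
  a <- structure$atoms
  a$chain <- ifelse(a$chain == "A", "B", "A")
  a <- a[order(match(a$chain, c("A", "B"))), , drop = FALSE]
  a$serial <- seq_len(nrow(a))
  new_structure(a)
}

# The end-to-end synthetic dataset is expensive (~20 s); build it once per
# test run and share.
demo_cache <- new.env(parent = emptyenv())
cached_demo <- function(seed = 1) {
  key <- paste0("seed", seed)
  if (is.null(demo_cache[[key]])) demo_cache[[key]] <- demo_dataset(seed)
  demo_cache[[key]]
}
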