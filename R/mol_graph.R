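# Internal molecular-graph plumbing: canonical SMILES -> atoms/bonds/topological
# distances, via OpenBabel's SDF writer. Aromatic rings arrive kekulized
# (alternating bond orders 1/2), which is what the shingle encoding consumes.

# Average atomic masses for the single-heavy-atom fallback and generator
# bookkeeping. Implicit hydrogens use 1.008.
ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                 P = 30.974, F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904,
                 B = 10.81, Si = 28.085, Se = 78.971)

# Standard implicit valences used only by the single-atom fallback.
STD_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
                 I = 1, B = 3, H = 1)

# Parse a batch of valid SMILES into molecule graphs.
# Returns a list (one element per SMILES) of lists with fields:
#   element  character vector of heavy-atom element symbols
#   bonds    data.frame(from, to, order) (possibly 0 rows)
#   n_heavy  heavy atom count
# SMILES must already be canonical/parseable (see smi_canonical); an entry
# that fails to convert is returned as NULL.
parse_mol_graphs <- function(smiles) {
  n <- length(smiles)
  if (n == 0) return(list())
  tags <- paste0("m", seq_len(n))
  payload <- paste0(paste(smiles, tags), collapse = "\n")
  sdftxt <- suppressWarnings(ChemmineOB::convertFormat(
    "SMI", "SDF", paste0(payload, "\n"),
    options = data.frame(names = "e", args = "", stringsAsFactors = FALSE)
  ))
  blocks <- strsplit(sdftxt, "$$$$\n", fixed = TRUE)[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  out <- vector("list", n)
  for (b in blocks) {
    lines <- strsplit(b, "\n", fixed = TRUE)[[1]]
    title <- trimws(lines[[1]])
    slot <- match(title, tags)
    if (is.na(slot)) next
    counts <- lines[[4]]
    natom <- as.integer(substr(counts, 1, 3))
    nbond <- as.integer(substr(counts, 4, 6))
    if (is.na(natom) || natom < 1) next
    atom_lines <- lines[4 + seq_len(natom)]
    element <- trimws(substr(atom_lines, 32, 34))
    bonds <- if (nbond > 0) {
      bl <- lines[4 + natom + seq_len(nbond)]
      data.frame(
        from = as.integer(substr(bl, 1, 3)),
        to = as.integer(substr(bl, 4, 6)),
        order = as.integer(substr(bl, 7, 9))
      )
    } else {
      data.frame(from = integer(0), to = integer(0), order = integer(0))
    }
    out[[slot]] <- list(element = element, bonds = bonds, n_heavy = natom)
  }
  out
}

# Topological (bond-count) distance matrix of a molecule graph; Inf between
# disconnected fragments.
mol_distances <- function(mol) {
  n <- mol$n_heavy
  if (nrow(mol$bonds) == 0) {
    d <- matrix(Inf, n, n)
    diag(d) <- 0
    return(d)
  }
  g <- igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("from", "to")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::distances(g)
}

BOND_SYMBOL <- c("-", "=", "#", ":")

# Canonical rooted environment strings for every atom at radii 1..max_radius,
# by iterated neighborhood refinement: the radius-r label of an atom is its
# radius-(r-1) label followed by the sorted bond-tagged radius-(r-1) labels
# of its neighbors. Deterministic given the canonical SMILES; symmetric
# atoms receive identical labels.
atom_environments <- function(mol, max_radius = 2L) {
  n <- mol$n_heavy
  lab <- mol$element
  nb <- vector("list", n)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      f <- mol$bonds$from[k]; t <- mol$bonds$to[k]
      sym <- BOND_SYMBOL[min(mol$bonds$order[k], 4L)]
      nb[[f]] <- rbind(nb[[f]], c(t, sym))
      nb[[t]] <- rbind(nb[[t]], c(f, sym))
    }
  }
  envs <- vector("list", max_radius)
  for (r in seq_len(max_radius)) {
    new_lab <- character(n)
    for (i in seq_len(n)) {
      if (is.null(nb[[i]])) {
        new_lab[i] <- paste0(lab[i], "()")
      } else {
        parts <- paste0(nb[[i]][, 2], lab[as.integer(nb[[i]][, 1])])
        # radix sort: byte-wise ordering, independent of the session locale
        new_lab[i] <- paste0(lab[i], "(",
                             paste(sort(parts, method = "radix"), collapse = ","),
                             ")")
      }
    }
    envs[[r]] <- new_lab
    lab <- new_lab
  }
  envs
}
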