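# Download-free synthetic molecule generator. Molecules are assembled from
# a fragment grammar: chain units are SMILES snippets with an open valence
# at both ends, so any concatenation is a valid SMILES by construction;
# terminal caps close the chain. Class-specific motif pools give
# controllable substructure signal (oligopeptide backbones vs polyketide
# aromatics); both classes interleave a shared decoration pool so each
# class spans many structural families rather than one tight similarity
# cluster, emulating the family diversity of real natural-product tables.

# Chain units: open attachment point before and after the snippet.
FRAG_PEPTIDE_UNITS <- c(
  "NC(C)C(=O)", "NCC(=O)", "NC(CC(C)C)C(=O)", "NC(CO)C(=O)",
  "NC(Cc1ccccc1)C(=O)", "NC(C(C)C)C(=O)", "NC(CS)C(=O)", "NC(CCC(N)=O)C(=O)",
  "NC(CCCCN)C(=O)", "NC(CC(=O)O)C(=O)", "NC(Cc1ccc(O)cc1)C(=O)", "NC(CCSC)C(=O)",
  "NC(CC(N)=O)C(=O)", "NC(CCC(=O)O)C(=O)", "NC(C(C)O)C(=O)", "NC(C(C)CC)C(=O)"
)
FRAG_POLYKETIDE_UNITS <- c(
  "c1ccccc1", "C(C)C", "C=C", "CC(=O)", "C(O)", "CC(C)", "Cc1ccc(O)cc1",
  "CC(=O)C", "C(C)=C", "c1ccc2ccccc2c1", "C(=O)c1ccccc1", "C(O)C(C)",
  "c1cc(O)ccc1", "C(C)(C)C", "C=CC(C)", "CC(O)C"
)
FRAG_SHARED_UNITS <- c(
  "C", "CC", "C(C)", "CO", "CC(C)C", "C(O)C", "CCO", "C(C)CC",
  "CCC", "C(C)(C)", "COC", "CC(O)"
)
# Terminal caps (single open valence, placed at the chain end).
FRAG_CAPS <- c("C", "O", "CC", "CO", "C(C)C")
CAP_GLYCOSIDE <- "OC1OC(CO)C(O)C(O)C1O"

# Approximate mass added by a chain unit: the methyl-capped fragment's MW
# minus ethane. Computed once per session through the descriptor pipeline.
frag_mass_env <- new.env(parent = emptyenv())
fragment_masses <- function(frags) {
  key <- paste(frags, collapse = ";")
  if (!is.null(frag_mass_env[[key]])) return(frag_mass_env[[key]])
  capped <- paste0("C", frags, "C")
  mw <- compute_descriptors(capped)$mw
  ethane <- 2 * ATOMIC_MASS[["C"]] + 6 * ATOMIC_MASS[["H"]]
  m <- mw - ethane
  names(m) <- frags
  frag_mass_env[[key]] <- m
  m
}

# Assemble one molecule: chain units appended until target_mw is reached,
# then a terminal cap. A fraction of the units is drawn from the shared
# decoration pool; `prefix` units (if any) are placed first.
build_chain <- function(pool_motif, shared_frac, target_mw, cap,
                        prefix = character(0)) {
  mm <- fragment_masses(pool_motif)
  ms <- fragment_masses(FRAG_SHARED_UNITS)
  picked <- prefix
  total <- sum(mm[prefix], na.rm = TRUE)
  while (total < target_mw) {
    if (stats::runif(1) < shared_frac) {
      u <- sample(FRAG_SHARED_UNITS, 1)
      total <- total + ms[[u]]
    } else {
      u <- sample(pool_motif, 1)
      total <- total + mm[[u]]
    }
    picked <- c(picked, u)
  }
  paste0(paste(picked, collapse = ""), cap)
}

#' Generate a synthetic two-class molecule dataset
#'
#' Emulates the statistical shape of a microbial natural-product table: two
#' origin classes (`bacterium`, `fungus`) over a broad size range, many
#' structural families per class, and a configurable class signal.
#'
#' * `signal = "substructure"`: bacterial molecules are oligopeptide chains
#'   (always opening with a dipeptide block, occasionally closed by a
#'   glycoside cap), fungal molecules are aromatic polyketide chains; both
#'   interleave shared aliphatic decorations and share one size
#'   distribution, so the classes differ in substructure content only.
#' * `signal = "property"`: both classes draw from one pooled grammar but
#'   their molecular-weight targets differ by about one chain unit
#'   (`property_means`, `property_sd`) — a shift that is small in
#'   structure space yet crisp in descriptor space.
#' * `signal = "none"`: both classes are sampled identically.
#'
#' All SMILES are valid by construction and every molecule has at least two
#' heavy atoms.
#'
#' @param n_per_class Molecules per class.
#' @param seed Integer seed; the same seed reproduces the SMILES list
#'   byte-identically.
#' @param signal One of `"substructure"`, `"property"`, `"none"`.
#' @param size_range Molecular-weight bounds (Da) for the matched-size
#'   signals; targets are drawn log-uniformly inside the range.
#' @param property_means Class mean MW targets (bacterium, fungus) for
#'   `signal = "property"`.
#' @param property_sd MW target standard deviation for
#'   `signal = "property"`.
#' @return Molecule tibble: `compound_id`, `smiles_raw`, `origin`, `doi`.
#' @export
generate_dataset <- function(n_per_class = 200L, seed = 1L,
                             signal = c("substructure", "property", "none"),
                             size_range = c(150, 2500),
                             property_means = c(500, 620),
                             property_sd = 60) {
  signal <- match.arg(signal)
  if (size_range[1] >= size_range[2] || size_range[1] < 80) {
    stop("configuration error: unreachable size bounds")
  }
  smiles <- withr::with_seed(seed, {
    draw_target <- function(n) {
      exp(stats::runif(n, log(size_range[1]), log(size_range[2])))
    }
    bact <- fung <- character(n_per_class)
    if (signal == "substructure") {
      tb <- draw_target(n_per_class)
      tf <- draw_target(n_per_class)
      pep_mass <- fragment_masses(FRAG_PEPTIDE_UNITS)
      for (i in seq_len(n_per_class)) {
        # every bacterial chain ends in a dipeptide block closed by an O
        # (acid/ester) or a glycoside cap, so the class motif is always
        # present; the block's mass is discounted from the size target
        motif <- sample(FRAG_PEPTIDE_UNITS, 2, replace = TRUE)
        cap <- if (stats::runif(1) < 0.15) CAP_GLYCOSIDE else "O"
        body_target <- max(60, tb[i] - sum(pep_mass[motif]))
        body <- build_chain(FRAG_PEPTIDE_UNITS, 0.45, body_target, cap = "")
        bact[i] <- paste0(body, paste(motif, collapse = ""), cap)
        fung[i] <- build_chain(FRAG_POLYKETIDE_UNITS, 0.45, tf[i],
                               sample(FRAG_CAPS, 1))
      }
    } else {
      pool <- c(FRAG_PEPTIDE_UNITS, FRAG_POLYKETIDE_UNITS)
      if (signal == "property") {
        tb <- pmax(120, stats::rnorm(n_per_class, property_means[1], property_sd))
        tf <- pmax(120, stats::rnorm(n_per_class, property_means[2], property_sd))
      } else {
        tb <- draw_target(n_per_class)
        tf <- draw_target(n_per_class)
      }
      for (i in seq_len(n_per_class)) {
        bact[i] <- build_chain(pool, 0.3, tb[i], sample(FRAG_CAPS, 1))
        fung[i] <- build_chain(pool, 0.3, tf[i], sample(FRAG_CAPS, 1))
      }
    }
    c(bact, fung)
  })
  tibble::tibble(
    compound_id = sprintf("SYN%05d", seq_along(smiles)),
    smiles_raw = smiles,
    origin = rep(c("bacterium", "fungus"), each = n_per_class),
    doi = NA_character_
  )
}

#' Generate a calibration panel of molecule pairs
#'
#' Pairs spanning exact Jaccard shingle-set similarity roughly uniformly
#' over [0, 0.9], built by progressive fragment substitution: each pair
#' shares a base chain with a cycled fraction of its units replaced, plus
#' fully unrelated pairs near 0 and identical pairs at 1. Used to calibrate
#' the MinHash similarity estimator against [exact_jaccard()].
#'
#' @param n_pairs Number of pairs.
#' @param seed Integer seed.
#' @return Tibble: `pair_id`, `smiles_a`, `smiles_b`.
#' @export
generate_pair_panel <- function(n_pairs = 200L, seed = 1L) {
  pool_a <- c(FRAG_PEPTIDE_UNITS, FRAG_SHARED_UNITS)
  pool_b <- FRAG_POLYKETIDE_UNITS
  # substituted fraction per pair, cycled; chosen so the exact Jaccard of
  # atom-pair shingle sets decays roughly uniformly over (0, 0.9]
  fracs <- c(0, 0.05, 0.08, 0.12, 0.16, 0.22, 0.3, 0.45, 0.65, 1)
  withr::with_seed(seed, {
    res <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      slot <- i %% (length(fracs) + 1L)
      if (slot == length(fracs)) {
        # unrelated pair from disjoint pools
        a <- paste0(paste(sample(pool_a, 10, replace = TRUE), collapse = ""), "C")
        b <- paste0(paste(sample(pool_b, 10, replace = TRUE), collapse = ""), "C")
      } else {
        m <- sample(c(12L, 16L, 20L, 24L), 1)
        j <- if (fracs[slot + 1L] == 0) 0L else max(1L, round(m * fracs[slot + 1L]))
        units <- sample(pool_a, m, replace = TRUE)
        alt <- units
        if (j > 0) {
          at <- sample.int(m, j)
          alt[at] <- sample(pool_a, j, replace = TRUE)
        }
        a <- paste0(paste(units, collapse = ""), "C")
        b <- paste0(paste(alt, collapse = ""), "C")
      }
      res[[i]] <- tibble::tibble(pair_id = sprintf("P%04d", i),
                                 smiles_a = a, smiles_b = b)
    }
    dplyr::bind_rows(res)
  })
}
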