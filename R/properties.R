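# Physico-chemical annotation: descriptors, Joback boiling point, Lipinski
# flag, SMARTS substructure classes, display clamping, average ranking.

# Substructure patterns used for compound-class assignment (applied to
# stereochemistry-free canonical structures).
SMARTS_DIPEPTIDE <- "[NX3,NX4+][CH1,CH2][CX3](=[OX1])[NX3,NX4+][CH1,CH2][CX3](=[OX1])[O,N]"
SMARTS_GLYCOSIDE <- "[CR][OR][CHR]([OR0,NR0])[CR]"

# Resolve the SMILES column of a molecule tibble (canonical preferred).
pick_smiles <- function(data) {
  if (is.character(data)) return(unname(data))
  col <- intersect(c("smiles_canonical", "smiles_raw", "smiles"), names(data))[1]
  if (is.na(col)) stop("no SMILES column found")
  data[[col]]
}

# Build a ChemmineR SDFset for the multi-atom molecules of a SMILES vector.
# Returns list(sdf = SDFset, multi = logical index of molecules included,
# mols = parsed graphs for all molecules). Single-heavy-atom molecules
# cannot round-trip through the SDF plumbing and are handled by fallbacks.
mol_sdfset <- function(smiles) {
  mols <- parse_mol_graphs(smiles)
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad)) {
    stop("invalid structure: SMILES failed to parse: ",
         paste(utils::head(smiles[bad], 5), collapse = ", "))
  }
  nheavy <- vapply(mols, `[[`, numeric(1), "n_heavy")
  multi <- nheavy >= 2
  sdf <- NULL
  if (any(multi)) {
    tags <- paste0("m", which(multi))
    payload <- paste0(paste(smiles[multi], tags), collapse = "\n")
    txt <- suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(payload, "\n"),
      options = data.frame(names = "e", args = "", stringsAsFactors = FALSE)))
    sdf <- suppressWarnings(ChemmineR::read.SDFset(strsplit(txt, "\n", fixed = TRUE)[[1]]))
  }
  list(sdf = sdf, multi = multi, mols = mols)
}

# Fraction of carbon atoms whose bonds are all single (sp3), from the
# kekulized molecular graph; 0 when the molecule has no carbon.
fsp3_carbon <- function(mol) {
  is_c <- mol$element == "C"
  if (!any(is_c)) return(0)
  maxord <- rep(1L, mol$n_heavy)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[k]
      maxord[mol$bonds$from[k]] <- max(maxord[mol$bonds$from[k]], o)
      maxord[mol$bonds$to[k]] <- max(maxord[mol$bonds$to[k]], o)
    }
  }
  sum(is_c & maxord == 1L) / sum(is_c)
}

#' Compute molecular descriptors
#'
#' Adds molecular weight (`mw`, Da), fraction of sp3 carbons (`fsp3c`),
#' hydrogen-bond acceptor and donor counts (`hba` as N+O count, `hbd`),
#' Crippen-style `alogp` and topological polar surface area (`tpsa`, A^2)
#' to a molecule table, via OpenBabel's published descriptor
#' implementations. Single-heavy-atom molecules use a minimal elemental
#' fallback (`alogp` is `NA` there).
#'
#' @param data Molecule tibble with a SMILES column, or a character vector
#'   of parseable SMILES.
#' @return The input as a tibble with descriptor columns appended.
#' @examples
#' compute_descriptors(c("CCO", "c1ccccc1"))
#' @export
compute_descriptors <- function(data) {
  smi <- pick_smiles(data)
  ms <- mol_sdfset(smi)
  n <- length(smi)
  mw <- fsp3c <- alogp <- tpsa <- rep(NA_real_, n)
  hba <- hbd <- rep(NA_real_, n)
  if (any(ms$multi)) {
    pr <- ChemmineR::propOB(ms$sdf)
    mw[ms$multi] <- pr$MW
    hba[ms$multi] <- pr$HBA1
    hbd[ms$multi] <- pr$HBD
    alogp[ms$multi] <- pr$logP
    tpsa[ms$multi] <- pr$TPSA
  }
  fsp3c <- vapply(ms$mols, fsp3_carbon, numeric(1))
  if (any(!ms$multi)) {
    for (i in which(!ms$multi)) {
      el <- ms$mols[[i]]$element[1]
      nh <- if (el %in% names(STD_VALENCE)) STD_VALENCE[[el]] else 0
      mw[i] <- (if (el %in% names(ATOMIC_MASS)) ATOMIC_MASS[[el]] else NA_real_) +
        nh * ATOMIC_MASS[["H"]]
      hba[i] <- as.numeric(el %in% c("N", "O"))
      hbd[i] <- as.numeric(el %in% c("N", "O") && nh > 0)
      tpsa[i] <- if (el %in% c("N", "O")) NA_real_ else 0
      alogp[i] <- NA_real_
    }
    warning("single-heavy-atom molecule(s): elemental descriptor fallback used; alogp is NA")
  }
  out <- if (is.character(data)) {
    tibble::tibble(compound_id = if (is.null(names(data))) as.character(seq_len(n)) else names(data),
                   smiles_canonical = smi)
  } else {
    tibble::as_tibble(data)
  }
  out$mw <- mw; out$fsp3c <- fsp3c; out$hba <- hba; out$hbd <- hbd
  out$alogp <- alogp; out$tpsa <- tpsa
  out
}

#' The packaged Joback group-contribution table
#'
#' Group-contribution rows (SMARTS pattern, boiling-point contribution in
#' Kelvin, heavy atoms consumed per match) for the Joback additive boiling
#' point estimate. Patterns are written to be mutually exclusive so that
#' each heavy atom is consumed by at most one group.
#'
#' @return Tibble with columns `group`, `smarts`, `tb`, `natoms`, `note`.
#' @export
joback_group_table <- function() {
  path <- system.file("extdata", "joback_groups.csv", package = "map4np")
  readr::read_csv(path, show_col_types = FALSE)
}

#' Joback group-contribution boiling point
#'
#' `T_b = 198.2 + sum_i N_i t_bi` (Kelvin), where `N_i` is the occurrence
#' count of functional group `i` in the molecule and `t_bi` its tabulated
#' contribution. A molecule matching no group returns exactly the 198.2 K
#' intercept. Atoms not consumed by any group contribute 0 and trigger a
#' coverage warning; per-molecule coverage is reported in the
#' `joback_coverage` attribute.
#'
#' @param data Molecule tibble or character vector of SMILES.
#' @param table Group table, defaulting to [joback_group_table()].
#' @return Tibble with a `t_joback` column appended (or, for character
#'   input, a tibble of ids, SMILES and `t_joback`).
#' @examples
#' joback_boiling_point("CCO")   # 198.2 + CH3 + CH2 + OH contributions
#' @export
joback_boiling_point <- function(data, table = joback_group_table()) {
  smi <- pick_smiles(data)
  ms <- mol_sdfset(smi)
  n <- length(smi)
  counts <- matrix(0, n, nrow(table))
  if (any(ms$multi)) {
    for (j in seq_len(nrow(table))) {
      counts[ms$multi, j] <- suppressWarnings(
        ChemmineR::smartsSearchOB(ms$sdf, table$smarts[j], uniqueMatches = TRUE))
    }
  }
  tb <- 198.2 + as.numeric(counts %*% table$tb)
  covered <- as.numeric(counts %*% table$natoms)
  heavy <- vapply(ms$mols, `[[`, numeric(1), "n_heavy")
  coverage <- tibble::tibble(smiles = smi, heavy_atoms = heavy,
                             covered_atoms = covered)
  if (any(covered != heavy)) {
    warning(sum(covered != heavy),
            " molecule(s) with atoms not covered by any Joback group ",
            "(uncovered atoms contribute 0 K)")
  }
  out <- if (is.character(data)) {
    tibble::tibble(compound_id = if (is.null(names(data))) as.character(seq_len(n)) else names(data),
                   smiles_canonical = smi)
  } else {
    tibble::as_tibble(data)
  }
  out$t_joback <- tb
  attr(out, "joback_coverage") <- coverage
  out
}

#' Lipinski rule-of-five flag
#'
#' Rules: MW <= 500 Da, AlogP <= 5, HBD <= 5, HBA <= 10. Following the
#' source convention for natural products, a molecule is flagged
#' non-Lipinski only when it violates more than one rule; `TRUE` means at
#' most one violation. `NA` descriptor values are not counted as
#' violations.
#'
#' @param mw,alogp,hbd,hba Numeric descriptor vectors (recycled).
#' @return Logical vector.
#' @export
lipinski_flag <- function(mw, alogp, hbd, hba) {
  v <- (!is.na(mw) & mw > 500) + (!is.na(alogp) & alogp > 5) +
    (!is.na(hbd) & hbd > 5) + (!is.na(hba) & hba > 10)
  v <= 1
}

#' Classify peptidic / glycosidic substructure content
#'
#' Applies the dipeptide and glycoside SMARTS patterns (used verbatim) to
#' each molecule: `peptide` when only the dipeptide pattern matches,
#' `glycoside` when only the glycoside pattern matches, `glycopeptide` when
#' both match, `none` otherwise.
#'
#' @param data Molecule tibble or character vector of SMILES.
#' @return Character vector of classes (or the tibble with a
#'   `substructure_class` column appended).
#' @export
classify_substructure <- function(data) {
  smi <- pick_smiles(data)
  ms <- mol_sdfset(smi)
  n <- length(smi)
  pep <- gly <- rep(0, n)
  if (any(ms$multi)) {
    pep[ms$multi] <- suppressWarnings(
      ChemmineR::smartsSearchOB(ms$sdf, SMARTS_DIPEPTIDE, uniqueMatches = TRUE))
    gly[ms$multi] <- suppressWarnings(
      ChemmineR::smartsSearchOB(ms$sdf, SMARTS_GLYCOSIDE, uniqueMatches = TRUE))
  }
  cls <- dplyr::case_when(
    pep > 0 & gly > 0 ~ "glycopeptide",
    pep > 0 ~ "peptide",
    gly > 0 ~ "glycoside",
    TRUE ~ "none"
  )
  if (is.character(data)) return(cls)
  out <- tibble::as_tibble(data)
  out$substructure_class <- cls
  out
}

# Display clamping bounds for map color gradients.
CLAMP_RULES <- list(
  mw = c(-Inf, 1000),
  t_joback = c(-Inf, 2000),
  hbd = c(-Inf, 10),
  hba = c(-Inf, 20),
  alogp = c(-2, 8),
  tpsa = c(-Inf, 500)
)

#' Clamp property values for display
#'
#' Map color gradients saturate extreme values: MW at 1000 Da, Joback
#' boiling point at 2000 K, HBD at 10, HBA at 20, AlogP into [-2, 8], TPSA
#' at 500 A^2. Properties without a rule pass through unchanged. The
#' operation is idempotent and order-preserving within bounds.
#'
#' @param name Property name (one of `mw`, `t_joback`, `hbd`, `hba`,
#'   `alogp`, `tpsa`, or any other name for a pass-through).
#' @param value Numeric vector.
#' @return Clamped numeric vector.
#' @export
clamp_for_display <- function(name, value) {
  rule <- CLAMP_RULES[[name]]
  if (is.null(rule)) return(value)
  pmin(pmax(value, rule[1]), rule[2])
}

#' Average (fractional) ranking
#'
#' Standard average ranking of a numeric vector: tied values share the mean
#' of the ranks they span, so ranks always sum to `n (n + 1) / 2`.
#'
#' @param values Numeric vector.
#' @return Numeric vector of ranks.
#' @examples
#' average_rank(c(10, 10, 30))  # 1.5 1.5 3
#' @export
average_rank <- function(values) {
  rank(values, ties.method = "average")
}

#' Full property annotation of a molecule table
#'
#' Composes [compute_descriptors()], [joback_boiling_point()],
#' [lipinski_flag()] and [classify_substructure()], and (by default)
#' appends an average-rank column (`rank_*`) for every continuous property,
#' as used for map color codes.
#'
#' @param data Molecule tibble with a SMILES column.
#' @param ranks Add rank columns for the continuous properties?
#' @return Annotated tibble.
#' @export
annotate_properties <- function(data, ranks = TRUE) {
  out <- compute_descriptors(data)
  out <- joback_boiling_point(out)
  out$lipinski_ok <- lipinski_flag(out$mw, out$alogp, out$hbd, out$hba)
  out <- classify_substructure(out)
  if (ranks) {
    for (p in c("mw", "fsp3c", "hba", "hbd", "alogp", "tpsa", "t_joback")) {
      out[[paste0("rank_", p)]] <- average_rank(out[[p]])
    }
  }
  out
}
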