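#' Read a molecule table
#'
#' Reads a delimited table (CSV/TSV by extension, or a whitespace-delimited
#' `.smi` file of `SMILES [id]` lines) into a molecule tibble with columns
#' `compound_id`, `smiles_raw`, `origin` and `doi`. Column names in the file
#' are mapped through `column_map`; only a SMILES column is mandatory.
#' Missing ids are filled with row numbers, missing origins with `"unknown"`.
#'
#' @param path Path to the input file.
#' @param column_map Named character vector mapping the canonical names
#'   `id`, `smiles`, `origin`, `doi` to column names in the file.
#' @return A tibble with one row per input row. No parsing or
#'   canonicalization is performed here; see [prepare_dataset()].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("compound_id,smiles,origin",
#'              "m1,CCO,bacterium", "m2,c1ccccc1,fungus"), tf)
#' read_molecule_table(tf)
#' @export
read_molecule_table <- function(path,
                                column_map = c(id = "compound_id",
                                               smiles = "smiles",
                                               origin = "origin",
                                               doi = "doi")) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "smi") {
    tab <- readr::read_table(path, col_names = FALSE, col_types = readr::cols(.default = "c"))
    if (nrow(tab) == 0) stop("empty dataset: no molecules in ", path)
    out <- tibble::tibble(
      compound_id = if (ncol(tab) >= 2) tab[[2]] else as.character(seq_len(nrow(tab))),
      smiles_raw = tab[[1]],
      origin = "unknown",
      doi = NA_character_
    )
    return(out)
  }
  delim <- if (ext %in% c("tsv", "txt", "tab")) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  if (nrow(tab) == 0) stop("empty dataset: no molecules in ", path)
  cm <- column_map
  if (is.null(names(cm)) || !"smiles" %in% names(cm)) {
    stop("column_map must name a 'smiles' entry")
  }
  if (!cm[["smiles"]] %in% names(tab)) {
    stop("configuration error: SMILES column '", cm[["smiles"]],
         "' not found in ", path)
  }
  pick <- function(key, default) {
    nm <- if (key %in% names(cm)) cm[[key]] else NA_character_
    if (!is.na(nm) && nm %in% names(tab)) tab[[nm]] else default
  }
  tibble::tibble(
    compound_id = pick("id", as.character(seq_len(nrow(tab)))),
    smiles_raw = tab[[cm[["smiles"]]]],
    origin = pick("origin", rep("unknown", nrow(tab))),
    doi = pick("doi", rep(NA_character_, nrow(tab)))
  )
}

# Strip stereochemistry markers from SMILES text: tetrahedral '@' flags and
# cis/trans bond direction slashes. The remaining string describes the same
# constitution with plain single bonds.
strip_stereo_text <- function(smiles) {
  gsub("[@/\\\\]", "", smiles)
}

# Vectorized canonicalization through OpenBabel, mapping outputs back to
# inputs via title tags so unparseable entries surface as NA (with a
# "reason" attribute) instead of derailing the batch.
smi_canonical <- function(smiles) {
  n <- length(smiles)
  if (n == 0) return(character(0))
  stripped <- strip_stereo_text(smiles)
  tags <- paste0("m", seq_len(n))
  payload <- paste0(paste(stripped, tags), collapse = "\n")
  out <- suppressWarnings(ChemmineOB::convertFormat(
    "SMI", "CAN", paste0(payload, "\n"),
    options = data.frame(names = "e", args = "", stringsAsFactors = FALSE)
  ))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else NA_character_, character(1))
  can <- vapply(parts, `[[`, character(1), 1)
  res <- rep(NA_character_, n)
  idx <- match(got, tags)
  ok <- !is.na(idx)
  res[idx[ok]] <- can[ok]
  attr(res, "reason") <- ifelse(is.na(res), "SMILES failed to parse", NA_character_)
  res
}

#' Canonicalize a SMILES and remove stereochemistry
#'
#' Stereochemistry markers (tetrahedral `@` flags, cis/trans bond slashes)
#' are removed first, then the structure is written as an OpenBabel
#' canonical SMILES. The result is a fixed point: applying the function to
#' its own output returns the same string, and all stereoisomers of a
#' structure collapse to one canonical form.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical, stereochemistry-free SMILES.
#'   Unparseable input is an error.
#' @examples
#' canonicalize_strip_stereo("C[C@@H](N)C(=O)O")
#' canonicalize_strip_stereo(c("OCC", "CCO"))
#' @export
canonicalize_strip_stereo <- function(smiles) {
  res <- smi_canonical(smiles)
  if (anyNA(res)) {
    bad <- smiles[is.na(res)]
    stop("invalid structure: SMILES failed to parse: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  as.character(res)
}

#' Canonicalize a molecule table, routing failures to a rejects report
#'
#' Adds a `smiles_canonical` column to a molecule tibble (as produced by
#' [read_molecule_table()] or [generate_dataset()]). Rows whose SMILES fail
#' to parse are removed from the returned dataset and collected, with a
#' reason, in the `rejects` attribute (a tibble); they are never silently
#' dropped without record.
#'
#' @param data Tibble with at least `compound_id` and `smiles_raw` columns
#'   (a `smiles` column is accepted as an alias).
#' @param rejects_path Optional path; when given, the rejects tibble is also
#'   written there as TSV.
#' @return The input tibble with `smiles_canonical` added, parse failures
#'   removed, and attributes `rejects` (tibble) set.
#' @export
prepare_dataset <- function(data, rejects_path = NULL) {
  data <- tibble::as_tibble(data)
  if (!"smiles_raw" %in% names(data) && "smiles" %in% names(data)) {
    data$smiles_raw <- data$smiles
  }
  stopifnot("compound_id" %in% names(data), "smiles_raw" %in% names(data))
  can <- smi_canonical(data$smiles_raw)
  bad <- is.na(can)
  rejects <- tibble::tibble(
    compound_id = data$compound_id[bad],
    smiles_raw = data$smiles_raw[bad],
    reason = attr(can, "reason")[bad]
  )
  if (!is.null(rejects_path)) {
    readr::write_tsv(rejects, rejects_path)
  }
  out <- data[!bad, , drop = FALSE]
  out$smiles_canonical <- as.character(can[!bad])
  if (nrow(rejects) > 0) {
    message(nrow(rejects), " molecule(s) failed to parse; see the 'rejects' attribute")
  }
  attr(out, "rejects") <- rejects
  out
}

#' Deduplicate a canonicalized molecule table
#'
#' Collapses rows sharing a canonical SMILES to one record. When duplicate
#' rows disagree on origin, one of the observed origins is drawn uniformly
#' at random under `seed`, and each such assignment is recorded in the
#' `dual_origin_log` attribute (and messaged). Deduplication is idempotent.
#'
#' @param data Tibble with a `smiles_canonical` column.
#' @param seed Integer seed for dual-origin resolution.
#' @return Deduplicated tibble (first-seen record per canonical SMILES,
#'   possibly with reassigned origin), with attribute `dual_origin_log`.
#' @export
deduplicate <- function(data, seed = 1L) {
  data <- tibble::as_tibble(data)
  stopifnot("smiles_canonical" %in% names(data))
  grp <- split(seq_len(nrow(data)), data$smiles_canonical)
  keep <- vapply(grp, `[[`, integer(1), 1)
  keep <- sort(keep)
  out <- data[keep, , drop = FALSE]
  log <- tibble::tibble(compound_id = character(0),
                        smiles_canonical = character(0),
                        origins = character(0),
                        assigned = character(0))
  if ("origin" %in% names(data)) {
    conflicted <- Filter(function(ix) length(unique(data$origin[ix])) > 1, grp)
    if (length(conflicted) > 0) {
      conflicted <- conflicted[order(vapply(conflicted, `[[`, integer(1), 1))]
      assigned <- withr::with_seed(seed, vapply(conflicted, function(ix) {
        sample(sort(unique(data$origin[ix]), method = "radix"), 1)
      }, character(1)))
      for (i in seq_along(conflicted)) {
        ix <- conflicted[[i]]
        first <- ix[[1]]
        out$origin[match(data$smiles_canonical[first], out$smiles_canonical)] <- assigned[[i]]
        log <- dplyr::bind_rows(log, tibble::tibble(
          compound_id = data$compound_id[first],
          smiles_canonical = data$smiles_canonical[first],
          origins = paste(sort(unique(data$origin[ix])), collapse = "|"),
          assigned = assigned[[i]]
        ))
      }
      message(nrow(log), " duplicate SMILES with conflicting origin assigned at random (seed ",
              seed, ")")
    }
  }
  attr(out, "dual_origin_log") <- log
  out
}

#' Split a molecule table into training and test sets
#'
#' Plain random partition, reproducible under `seed`. At `train_fraction`
#' 0.5 the two part sizes differ by at most one.
#'
#' @param data Tibble of molecules (deduplicated for classifier use).
#' @param train_fraction Proportion assigned to training, in (0, 1).
#' @param seed Integer seed.
#' @return A list with elements `train` and `test` (disjoint tibbles that
#'   together cover the input).
#' @export
split_train_test <- function(data, train_fraction = 0.5, seed = 1L) {
  data <- tibble::as_tibble(data)
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("configuration error: train_fraction must be in (0, 1)")
  }
  n <- nrow(data)
  n_train <- floor(train_fraction * n + 1e-9)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(train = data[sort(idx), , drop = FALSE],
       test = data[setdiff(seq_len(n), sort(idx)), , drop = FALSE])
}

#' Write a molecule table as TSV
#'
#' Fixed column order (`compound_id`, `smiles_raw`, `smiles_canonical`,
#' `origin`, `doi`, then any extras), UTF-8, LF line endings, so that a
#' write/read round trip reproduces all fields.
#'
#' @param data Molecule tibble.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_molecule_table <- function(data, path) {
  lead <- intersect(c("compound_id", "smiles_raw", "smiles_canonical", "origin", "doi"),
                    names(data))
  data <- data[, c(lead, setdiff(names(data), lead)), drop = FALSE]
  readr::write_tsv(data, path)
  invisible(data)
}

#' Keep only the largest fragment of multi-fragment SMILES
#'
#' Optional normalization for salt-stripped analyses: for SMILES containing
#' `.`-separated fragments, keeps the fragment with the most heavy atoms
#' (ties: first). Default pipelines keep full SMILES intact.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector with at most one fragment per entry.
#' @export
largest_fragment <- function(smiles) {
  vapply(strsplit(smiles, ".", fixed = TRUE), function(fr) {
    if (length(fr) == 1) return(fr)
    sizes <- vapply(fr, function(f) {
      nchar(gsub("[^A-Za-z]", "", gsub("H", "", f)))
    }, numeric(1))
    fr[[which.max(sizes)]]
  }, character(1))
}
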