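#' Extract MinHashed-atom-pair shingles from a molecule
#'
#' Encodes every unordered pair of heavy atoms as a token combining the
#' canonical circular-substructure environment of each atom (radii 1 and 2)
#' with the shortest-path distance in bonds between them:
#' `envA|d|envB`, with `envA <= envB` lexicographically so the token is
#' symmetric in the two atoms. One token is produced per pair and radius;
#' the returned set is deduplicated. Environments are canonical rooted
#' refinement strings over the kekulized molecular graph (see the methods
#' vignette for the frozen encoding). Atom pairs spanning disconnected
#' fragments (infinite topological distance) are skipped.
#'
#' @param smiles A single canonical SMILES (see
#'   [canonicalize_strip_stereo()]); molecules with fewer than two heavy
#'   atoms are an error.
#' @return Character vector: the unique shingle tokens of the molecule.
#' @examples
#' extract_shingles(canonicalize_strip_stereo("CCO"))
#' @export
extract_shingles <- function(smiles) {
  stopifnot(length(smiles) == 1)
  mols <- parse_mol_graphs(smiles)
  if (is.null(mols[[1]])) stop("invalid structure: SMILES failed to parse: ", smiles)
  shingles_of(mols[[1]])
}

# Shingle set of a parsed molecule graph.
shingles_of <- function(mol) {
  if (mol$n_heavy < 2) {
    stop("too-small-molecule: need at least 2 heavy atoms")
  }
  d <- mol_distances(mol)
  envs <- atom_environments(mol, 2L)
  idx <- which(upper.tri(d) & is.finite(d), arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop("too-small-molecule: no bonded atom pairs (all fragments are single atoms)")
  }
  dd <- d[idx]
  toks <- character(0)
  for (r in 1:2) {
    e1 <- envs[[r]][idx[, 1]]
    e2 <- envs[[r]][idx[, 2]]
    # order the two environments byte-wise (locale-independent) so the
    # token is symmetric in the two atoms
    lev <- sort(unique(c(e1, e2)), method = "radix")
    i1 <- match(e1, lev); i2 <- match(e2, lev)
    lo <- ifelse(i1 <= i2, e1, e2)
    hi <- ifelse(i1 <= i2, e2, e1)
    toks <- c(toks, paste(lo, dd, hi, sep = "|"))
  }
  unique(toks)
}

#' Construct the MinHash hash family
#'
#' A family of `dims` universal hash functions
#' `h_i(x) = ((a_i * x + b_i) mod (2^61 - 1)) mod 2^32`, with coefficients
#' drawn once from a Mersenne-Twister stream at `seed`. Tokens enter the
#' family as 32-bit integers derived from the first four bytes
#' (little-endian) of their SHA-1 digest. The same `(seed, dims)` pair
#' yields an identical family on every platform; signatures are only
#' comparable within one family and encoding version.
#'
#' @param dims Number of hash functions (signature length), default 1024.
#' @param seed Integer seed of the family.
#' @return A `hash_family` list with fields `a`, `b`, `dims`, `seed`,
#'   `version`.
#' @export
hash_family <- function(dims = 1024L, seed = MAP4NP_HASH_SEED) {
  coef <- withr::with_seed(seed, list(
    a = sample.int(2147483645L, dims, replace = TRUE),
    b = sample.int(2147483646L, dims, replace = TRUE) - 1L
  ))
  structure(list(a = as.numeric(coef$a), b = as.numeric(coef$b),
                 dims = as.integer(dims), seed = as.integer(seed),
                 version = MAP4NP_ENCODING_VERSION),
            class = "hash_family")
}

# 32-bit base hash of shingle tokens: first 4 bytes of SHA-1, little-endian.
token_hash32 <- function(tokens) {
  if (length(tokens) == 0) return(numeric(0))
  h <- as.character(openssl::sha1(tokens))
  b1 <- strtoi(substring(h, 1, 2), 16L)
  b2 <- strtoi(substring(h, 3, 4), 16L)
  b3 <- strtoi(substring(h, 5, 6), 16L)
  b4 <- strtoi(substring(h, 7, 8), 16L)
  b1 + b2 * 256 + b3 * 65536 + b4 * 16777216
}

#' MinHash a shingle set
#'
#' `values[i] = min over tokens of h_i(token)`: the elementwise minimum of
#' the hash family over the token set. Equal sets give equal signatures;
#' adding tokens can only decrease or preserve each element.
#'
#' @param shingles Character vector of shingle tokens (non-empty).
#' @param family A [hash_family()].
#' @return Numeric vector of length `family$dims` of unsigned 32-bit hash
#'   values.
#' @export
minhash <- function(shingles, family = hash_family()) {
  if (length(shingles) == 0) stop("empty shingle set: no signature defined")
  hs <- token_hash32(unique(shingles))
  drop(minhash_cpp(list(hs), family$a, family$b))
}

#' MAP4-style fingerprints for a table of molecules
#'
#' Composition of [canonicalize_strip_stereo()], [extract_shingles()] and
#' [minhash()], vectorized over a molecule table. Two SMILES of the same
#' molecule, including stereoisomers, receive bit-identical signatures.
#'
#' @param data Molecule tibble with `compound_id` and a `smiles_canonical`
#'   (preferred) or `smiles_raw`/`smiles` column, or a character vector of
#'   SMILES.
#' @param family A [hash_family()].
#' @return Numeric matrix, one row per molecule (rownames = compound ids),
#'   `family$dims` columns.
#' @examples
#' map4_fingerprint(c(a = "CCO", b = "c1ccccc1O"))
#' @export
map4_fingerprint <- function(data, family = hash_family()) {
  if (is.character(data)) {
    ids <- names(data)
    if (is.null(ids)) ids <- as.character(seq_along(data))
    data <- tibble::tibble(compound_id = ids, smiles_raw = unname(data))
  }
  smi <- if ("smiles_canonical" %in% names(data)) {
    data$smiles_canonical
  } else {
    col <- intersect(c("smiles_raw", "smiles"), names(data))[1]
    if (is.na(col)) stop("no SMILES column found")
    canonicalize_strip_stereo(data[[col]])
  }
  mols <- parse_mol_graphs(smi)
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad)) {
    stop("invalid structure: SMILES failed to parse: ",
         paste(utils::head(smi[bad], 5), collapse = ", "))
  }
  sets <- lapply(mols, function(m) token_hash32(shingles_of(m)))
  sig <- minhash_cpp(sets, family$a, family$b)
  rownames(sig) <- data$compound_id
  sig
}

#' Estimate Jaccard similarity from two MinHash signatures
#'
#' The fraction of signature positions holding the same value, an unbiased
#' estimator of the Jaccard similarity of the underlying shingle sets.
#' Symmetric, bounded in `[0, 1]`, exactly 1 for identical signatures.
#'
#' @param a,b Numeric signature vectors of equal length.
#' @return Estimated Jaccard similarity in `[0, 1]`.
#' @export
estimate_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("signature length mismatch")
  mean(a == b)
}

#' Exact Jaccard similarity of two shingle sets
#'
#' `|intersection| / |union|` of the two sets; the quantity
#' [estimate_similarity()] estimates. Serves as the exact oracle for
#' estimator calibration.
#'
#' @param s1,s2 Character vectors (shingle sets), non-empty.
#' @return Jaccard similarity in `[0, 1]`.
#' @export
exact_jaccard <- function(s1, s2) {
  s1 <- unique(s1); s2 <- unique(s2)
  if (length(s1) == 0 || length(s2) == 0) stop("shingle sets must be non-empty")
  length(intersect(s1, s2)) / length(union(s1, s2))
}

#' Write / read a signature matrix
#'
#' TSV with one row per molecule (id, then the signature values), preceded
#' by a `#`-prefixed JSON header recording the hash-family seed, dimension
#' and encoding version. [read_signatures()] refuses files whose encoding
#' version differs from the package's.
#'
#' @param sig Signature matrix from [map4_fingerprint()].
#' @param path Output path.
#' @param family The [hash_family()] used to compute `sig`.
#' @return `sig`, invisibly (write) or the signature matrix (read).
#' @export
write_signatures <- function(sig, path, family = hash_family()) {
  hdr <- jsonlite::toJSON(list(seed = family$seed, dims = family$dims,
                               version = family$version), auto_unbox = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con, sep = "\n")
  body <- cbind(id = rownames(sig),
                matrix(format(sig, scientific = FALSE, trim = TRUE),
                       nrow = nrow(sig)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con, sep = "\n")
  invisible(sig)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#")) stop("not a signature file (missing JSON header)")
  hdr <- jsonlite::fromJSON(sub("^#", "", first))
  if (!identical(hdr$version, MAP4NP_ENCODING_VERSION)) {
    stop("signature file encoding version ", hdr$version,
         " does not match package version ", MAP4NP_ENCODING_VERSION)
  }
  tab <- utils::read.table(path, sep = "\t", skip = 1,
                           colClasses = c("character", rep("numeric", hdr$dims)))
  sig <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(sig) <- list(tab[[1]], NULL)
  attr(sig, "family_seed") <- hdr$seed
  sig
}
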