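# Shared fixtures and independent oracles for the suite.

# Five fixture molecules used for golden-signature and property checks.
FIXTURE_SMILES <- c(
  ethanol = "CCO",
  phenol = "c1ccccc1O",
  glygly = "NCC(=O)NCC(=O)O",
  meglu = "COC1OC(CO)C(O)C(O)C1O",
  leucine = "CC(C)CC(N)C(=O)O"
)

# Ten-molecule neighbor fixture: three alcohols, three benzenes, two
# dipeptides, two pyranoses - nearest neighbors are chemically forced.
TEN_SMILES <- c(
  m01 = "CCO", m02 = "CCCO", m03 = "CCCCO",
  m04 = "c1ccccc1", m05 = "Cc1ccccc1", m06 = "CCc1ccccc1",
  m07 = "NC(C)C(=O)NC(C)C(=O)O", m08 = "NC(C)C(=O)NC(CC)C(=O)O",
  m09 = "OCC1OC(O)C(O)C(O)C1O", m10 = "COC1OC(CO)C(O)C(O)C1O"
)

sig_digest <- function(sig_row) {
  as.character(openssl::sha1(paste(
    format(sig_row, scientific = FALSE, trim = TRUE), collapse = ",")))
}

# Independent MST oracle: igraph's minimum spanning tree (Prim under
# weights) total weight.
prim_total_weight <- function(edges) {
  g <- igraph::graph_from_data_frame(edges[, c("from", "to", "weight")],
                                     directed = FALSE)
  sum(igraph::E(igraph::mst(g, weights = igraph::E(g)$weight))$weight)
}

# Random weighted graph on n nodes: Erdos-Renyi edges plus a random
# spanning path so the graph is connected.
random_graph <- function(n, p = 0.12) {
  ids <- sprintf("n%03d", seq_len(n))
  all_pairs <- t(utils::combn(n, 2))
  pick <- stats::runif(nrow(all_pairs)) < p
  perm <- sample.int(n)
  path <- cbind(perm[-n], perm[-1])
  ij <- unique(rbind(all_pairs[pick, , drop = FALSE], t(apply(path, 1, sort))))
  e <- tibble::tibble(from = ids[ij[, 1]], to = ids[ij[, 2]],
                      weight = stats::runif(nrow(ij)))
  structure(e, nodes = ids, class = c("neighbor_graph", class(e)))
}

# From-scratch metric formulas, written directly from the definitions.
oracle_metrics <- function(tp, fp, tn, fn) {
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  tnr <- if (tn + fp == 0) 0 else tn / (tn + fp)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(f1 = f1, balanced_accuracy = (rec + tnr) / 2, mcc = mcc)
}

# Mean top-k recall of approximate neighbor lists against exact ones.
mean_recall <- function(approx_hits, exact_hits, k) {
  ids <- unique(exact_hits$query)
  mean(vapply(ids, function(q) {
    a <- approx_hits$id[approx_hits$query == q]
    e <- exact_hits$id[exact_hits$query == q]
    length(intersect(utils::head(a, k), utils::head(e, k))) / min(k, length(e))
  }, numeric(1)))
}

# Exact per-node top-k neighbor lists from a similarity matrix, with the
# documented (distance, id) tie-break.
exact_topk <- function(K, k) {
  ids <- rownames(K)
  dplyr::bind_rows(lapply(seq_len(nrow(K)), function(i) {
    sims <- K[i, -i]
    cand <- ids[-i]
    ord <- order(-sims, cand, method = "radix")
    tibble::tibble(query = ids[i], id = cand[utils::head(ord, k)])
  }))
}

# Independent SMARTS engine: RDKit via the system python. Returns a logical
# matrix (molecules x patterns).
rdkit_smarts_matches <- function(smiles, smarts) {
  script <- paste(
    "import sys, json",
    "from rdkit import Chem",
    "data = json.load(sys.stdin)",
    "pats = [Chem.MolFromSmarts(s) for s in data['smarts']]",
    "out = []",
    "for smi in data['smiles']:",
    "    m = Chem.MolFromSmiles(smi)",
    "    out.append([bool(m.HasSubstructMatch(p)) for p in pats])",
    "print(json.dumps(out))",
    sep = "\n")
  payload <- jsonlite::toJSON(list(smiles = smiles, smarts = smarts))
  res <- system2("python", c("-c", shQuote(script)), input = payload,
                 stdout = TRUE, stderr = FALSE)
  matrix(unlist(jsonlite::fromJSON(res[length(res)], simplifyMatrix = FALSE)),
         nrow = length(smiles), byrow = TRUE)
}

# Tiny deterministic signature set builder for graph tests: k well
# separated clusters with within-cluster corruption.
cluster_signatures <- function(n_clusters, per_cluster, corrupt = 0.1,
                               dims = 1024, seed = 1) {
  withr::with_seed(seed, {
    base <- matrix(sample(1e7, n_clusters * dims, TRUE), n_clusters)
    sig <- base[rep(seq_len(n_clusters), each = per_cluster), , drop = FALSE]
    noise <- matrix(sample(1e7, length(sig), TRUE), nrow(sig))
    mask <- matrix(stats::runif(length(sig)) < corrupt, nrow(sig))
    sig[mask] <- noise[mask]
    rownames(sig) <- sprintf("s%03d", seq_len(nrow(sig)))
    sig
  })
}
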