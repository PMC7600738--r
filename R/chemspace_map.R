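# TMAP-style chemical-space graph pipeline: LSH-forest approximate kNN over
# MinHash signatures -> symmetrized weighted kNN graph -> Kruskal minimum
# spanning tree/forest -> export and simple tree layout.

# Fixed-width key strings so lexicographic string order equals numeric
# order of the underlying signature slices.
lsh_key <- function(mat) {
  apply(matrix(formatC(mat, width = 10, flag = "0", format = "d"),
               nrow = nrow(mat)), 1, paste, collapse = "")
}

#' Build an LSH forest over MinHash signatures
#'
#' An ensemble of `n_trees` prefix trees: each tree draws a random
#' permutation of the signature positions (from `seed`) and indexes every
#' molecule by the first `depth` values of its permuted signature. Queries
#' descend to the deepest prefix level with enough candidates, union
#' candidates across trees, and re-rank them with the exact
#' [estimate_similarity()] estimator.
#'
#' @param signatures Signature matrix from [map4_fingerprint()] (rownames =
#'   molecule ids).
#' @param n_trees Number of prefix trees (default 32, the layout pipeline's
#'   standard setting).
#' @param depth Indexed prefix length per tree (documented constant,
#'   default 8).
#' @param seed Integer seed for the per-tree permutations.
#' @return An `lsh_forest` object.
#' @export
build_lsh_forest <- function(signatures, n_trees = 32L, depth = 8L, seed = 1L) {
  if (is.null(dim(signatures)) || nrow(signatures) < 1) {
    stop("need at least one signature")
  }
  dims <- ncol(signatures)
  ids <- rownames(signatures)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(signatures)))
  perms <- withr::with_seed(seed, lapply(seq_len(n_trees), function(t) {
    sample.int(dims, depth)
  }))
  trees <- lapply(perms, function(p) {
    keys <- lsh_key(signatures[, p, drop = FALSE])
    ord <- order(keys, method = "radix")
    list(keys = keys[ord], ord = ord)
  })
  structure(list(signatures = signatures, ids = ids, trees = trees,
                 perms = perms, n_trees = as.integer(n_trees),
                 depth = as.integer(depth), seed = as.integer(seed)),
            class = "lsh_forest")
}

# Smallest index i with keys[i] >= val in a sorted character vector
# (length(keys) + 1 when no such element).
bsearch_lower <- function(keys, val) {
  lo <- 1L
  hi <- length(keys) + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (keys[mid] < val) lo <- mid + 1L else hi <- mid
  }
  lo
}

# Candidate row indices for one query signature in one tree: the narrowest
# key-prefix window holding at least min_cand entries (or the deepest
# non-empty window). Keys are digit strings, so "~" is a safe upper sentinel.
lsh_tree_candidates <- function(tree, qkey, depth, min_cand) {
  keys <- tree$keys
  best <- integer(0)
  for (l in depth:0) {
    if (l == 0) { best <- tree$ord; break }
    pre <- substr(qkey, 1, 10 * l)
    lo <- bsearch_lower(keys, pre)
    hi <- bsearch_lower(keys, paste0(pre, "~")) - 1L
    if (hi >= lo) {
      best <- tree$ord[lo:hi]
      if (length(best) >= min_cand) break
    }
  }
  best
}

#' Query an LSH forest
#'
#' @param forest An [build_lsh_forest()] object.
#' @param query Signature vector or matrix of query signatures.
#' @param k Number of neighbors to return.
#' @param exclude_self Drop a candidate identical in id to the query row
#'   name (used for self-joins).
#' @return Tibble with columns `query`, `id`, `similarity`, `rank`.
#' @export
lsh_query <- function(forest, query, k = 20L, exclude_self = FALSE) {
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  qids <- rownames(query)
  if (is.null(qids)) qids <- paste0("q", seq_len(nrow(query)))
  res <- vector("list", nrow(query))
  for (i in seq_len(nrow(query))) {
    cands <- integer(0)
    for (t in seq_len(forest$n_trees)) {
      qkey <- lsh_key(query[i, forest$perms[[t]], drop = FALSE])
      cands <- c(cands, lsh_tree_candidates(forest$trees[[t]], qkey,
                                            forest$depth, k + 1L))
    }
    cands <- sort(unique(cands))
    if (exclude_self) cands <- cands[forest$ids[cands] != qids[i]]
    if (length(cands) == 0) next
    sims <- drop(simmat_cpp(query[i, , drop = FALSE],
                            forest$signatures[cands, , drop = FALSE]))
    ord <- order(-sims, forest$ids[cands], method = "radix")
    take <- utils::head(ord, k)
    res[[i]] <- tibble::tibble(query = qids[i], id = forest$ids[cands][take],
                               similarity = sims[take],
                               rank = seq_along(take))
  }
  dplyr::bind_rows(res)
}

# Assemble a symmetrized neighbor-graph tibble from per-node neighbor hits.
neighbor_edges <- function(hits) {
  e <- hits |>
    dplyr::transmute(
      from = pmin(.data$query, .data$id),
      to = pmax(.data$query, .data$id),
      weight = 1 - .data$similarity
    ) |>
    dplyr::distinct(.data$from, .data$to, .keep_all = TRUE) |>
    dplyr::arrange(.data$weight, .data$from, .data$to)
  e
}

#' Exact k-nearest-neighbor graph by brute force
#'
#' Computes all pairwise estimated Jaccard distances and links each node to
#' its `k` nearest neighbors (ties broken by distance then smaller id),
#' then symmetrizes by edge union. The exact oracle for [knn_graph()].
#'
#' @param signatures Signature matrix (>= 2 rows).
#' @param k Neighbors per node; values `>= n` are truncated to `n - 1` with
#'   a warning.
#' @return A `neighbor_graph` tibble with columns `from`, `to`, `weight`
#'   and a `nodes` attribute.
#' @export
brute_force_knn <- function(signatures, k = 20L) {
  n <- nrow(signatures)
  if (n < 2) stop("need at least two signatures")
  ids <- rownames(signatures)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (k >= n) {
    warning("k >= number of molecules; truncating k to n - 1")
    k <- n - 1L
  }
  S <- simmat_cpp(signatures, signatures)
  hits <- lapply(seq_len(n), function(i) {
    sims <- S[i, -i]
    cand <- ids[-i]
    ord <- order(-sims, cand, method = "radix")
    take <- utils::head(ord, k)
    tibble::tibble(query = ids[i], id = cand[take], similarity = sims[take],
                   rank = seq_along(take))
  })
  e <- neighbor_edges(dplyr::bind_rows(hits))
  structure(e, nodes = ids, class = c("neighbor_graph", class(e)))
}

#' Approximate k-nearest-neighbor graph from an LSH forest
#'
#' Per-node top-`k` candidates from the forest, symmetrized by edge union;
#' edge weights are recomputed with [estimate_similarity()] (not the
#' index's internal approximation).
#'
#' @param forest An [build_lsh_forest()] object.
#' @param k Neighbors per node; values `>= n` are truncated with a warning.
#' @return A `neighbor_graph` tibble (`from`, `to`, `weight`; `nodes`
#'   attribute).
#' @export
knn_graph <- function(forest, k = 20L) {
  n <- nrow(forest$signatures)
  if (n < 2) stop("need at least two signatures")
  if (k >= n) {
    warning("k >= number of molecules; truncating k to n - 1")
    k <- n - 1L
  }
  hits <- lsh_query(forest, forest$signatures, k = k, exclude_self = TRUE)
  e <- neighbor_edges(hits)
  structure(e, nodes = forest$ids, class = c("neighbor_graph", class(e)))
}

#' Minimum spanning tree (forest) by Kruskal's algorithm
#'
#' Edges are scanned in increasing `(weight, from, to)` order (ids compared
#' lexicographically), which makes the result deterministic across
#' platforms and input row orders. Disconnected inputs yield a spanning
#' forest; the component of every node is reported in the `components`
#' attribute. Optionally, components can be linked through their closest
#' inter-component pair to recover a single display tree.
#'
#' @param graph A `neighbor_graph` tibble (or any tibble with `from`, `to`,
#'   `weight`).
#' @param link_components If `TRUE`, greedily add the lightest
#'   inter-component edge (computed from `signatures`) until one tree
#'   remains; such edges are flagged in a `linked` column.
#' @param signatures Signature matrix, required when `link_components` is
#'   `TRUE`.
#' @return A `spanning_tree` tibble of the retained edges with attributes
#'   `nodes`, `components` (named membership vector) and `total_weight`.
#' @export
mst_kruskal <- function(graph, link_components = FALSE, signatures = NULL) {
  if (nrow(graph) == 0) stop("non-empty graph required")
  nodes <- attr(graph, "nodes")
  if (is.null(nodes)) nodes <- sort(unique(c(graph$from, graph$to)))
  n <- length(nodes)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  lo <- pmin(graph$from, graph$to)
  hi <- pmax(graph$from, graph$to)
  ord <- order(graph$weight, lo, hi, method = "radix")
  keep <- logical(nrow(graph))
  fi <- match(lo, nodes)
  ti <- match(hi, nodes)
  for (e in ord) {
    rf <- find(fi[e]); rt <- find(ti[e])
    if (rf != rt) {
      parent[rf] <- rt
      keep[e] <- TRUE
    }
  }
  tree <- graph[keep, , drop = FALSE]
  tree <- dplyr::arrange(tree, .data$weight, pmin(.data$from, .data$to),
                         pmax(.data$from, .data$to))
  comp_root <- vapply(seq_len(n), find, integer(1))
  comp <- stats::setNames(match(comp_root, unique(comp_root)), nodes)
  tree$linked <- FALSE
  if (link_components && max(comp) > 1) {
    if (is.null(signatures)) {
      stop("link_components = TRUE requires the signature matrix")
    }
    sig <- signatures[nodes, , drop = FALSE]
    while (max(comp) > 1) {
      S <- simmat_cpp(sig, sig)
      D <- 1 - S
      inter <- outer(comp, comp, "!=") & upper.tri(D)
      D[!inter] <- Inf
      at <- arrayInd(which.min(D), dim(D))
      u <- nodes[at[1]]; v <- nodes[at[2]]
      tree <- dplyr::bind_rows(tree, tibble::tibble(
        from = min(u, v), to = max(u, v), weight = D[at], linked = TRUE))
      comp[comp == comp[at[2]]] <- comp[at[1]]
      comp <- stats::setNames(match(comp, sort(unique(comp))), nodes)
    }
  }
  structure(tree, nodes = nodes, components = comp,
            total_weight = sum(tree$weight),
            class = c("spanning_tree", class(tree)))
}

#' Export a spanning tree with node annotations
#'
#' Writes an edge-list TSV (`from`, `to`, `weight`) and a GraphML file with
#' one node attribute per annotation column, ready for external graph
#' viewers.
#'
#' @param tree A [mst_kruskal()] result.
#' @param annotations Tibble with a `compound_id` column and one column per
#'   node property; every tree node must be present.
#' @param path_prefix Output prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>.graphml`.
#' @return Named character vector of the written paths, invisibly.
#' @export
export_graph <- function(tree, annotations = NULL, path_prefix) {
  nodes <- attr(tree, "nodes")
  edge_path <- paste0(path_prefix, "_edges.tsv")
  readr::write_tsv(tibble::as_tibble(tree)[, c("from", "to", "weight")], edge_path)
  g <- igraph::graph_from_data_frame(tree[, c("from", "to", "weight")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  if (!is.null(annotations)) {
    stopifnot("compound_id" %in% names(annotations))
    miss <- setdiff(nodes, annotations$compound_id)
    if (length(miss) > 0) {
      stop("annotations missing for node id(s): ",
           paste(utils::head(miss, 10), collapse = ", "))
    }
    ann <- annotations[match(nodes, annotations$compound_id), , drop = FALSE]
    for (col in setdiff(names(ann), "compound_id")) {
      g <- igraph::set_vertex_attr(g, col, value = ann[[col]])
    }
  }
  gml_path <- paste0(path_prefix, ".graphml")
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(c(edges = edge_path, graphml = gml_path))
}

#' Deterministic 2-D layout of a spanning tree
#'
#' Reingold–Tilford tree drawing per component (root = highest-degree node,
#' ties to the smallest id), components offset side by side. Edges of the
#' drawn tree connect only tree neighbors.
#'
#' @param tree A [mst_kruskal()] result.
#' @param seed Retained for interface stability; the default layout is
#'   fully deterministic and does not consume randomness.
#' @return Tibble with columns `id`, `x`, `y`.
#' @export
tree_layout <- function(tree, seed = 1L) {
  nodes <- attr(tree, "nodes")
  comp <- attr(tree, "components")
  g <- igraph::graph_from_data_frame(tree[, c("from", "to", "weight")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  out <- vector("list", max(comp))
  offset <- 0
  for (ci in sort(unique(comp))) {
    members <- names(comp)[comp == ci]
    sub <- igraph::induced_subgraph(g, members)
    deg <- igraph::degree(sub)
    root <- names(sort(deg, decreasing = TRUE))
    root <- root[order(-deg[root], root)][1]
    xy <- igraph::layout_as_tree(sub, root = which(igraph::V(sub)$name == root))
    xy[, 1] <- xy[, 1] - min(xy[, 1]) + offset
    offset <- max(xy[, 1]) + 2
    out[[ci]] <- tibble::tibble(id = igraph::V(sub)$name,
                                x = xy[, 1], y = xy[, 2])
  }
  res <- dplyr::bind_rows(out)
  res[match(nodes, res$id), , drop = FALSE]
}
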