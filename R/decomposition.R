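#' Weighted Newman modularity of a partition
#'
#' Fraction of edge weight falling within groups minus the expectation if
#' edges were distributed at random, preserving strengths:
#' Q = sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j) / 2m. Computed directly
#' from the fragment-graph weight matrix, independently of any clustering
#' backend.
#'
#' @param membership integer group id per node
#' @param fgraph a `fragment_graph` (or a bare symmetric weight matrix)
#' @return modularity score in [-0.5, 1]
#' @export
modularity_score <- function(membership, fgraph) {
  A <- if (inherits(fgraph, "fragment_graph")) fgraph$weight else fgraph
  stopifnot(nrow(A) == length(membership))
  if (nrow(A) == 0) stop("empty graph")
  m2 <- sum(A)
  if (m2 == 0) return(0)
  k <- rowSums(A)
  same <- outer(membership, membership, "==")
  sum((A - outer(k, k) / m2) * same) / m2
}

.algorithms <- list(
  fastgreedy = function(g, seed) igraph::cluster_fast_greedy(g),
  infomap = function(g, seed) { set.seed(seed); igraph::cluster_infomap(g) },
  eigenvectors = function(g, seed) igraph::cluster_leading_eigen(g),
  label_propagation = function(g, seed) { set.seed(seed); igraph::cluster_label_prop(g) },
  multilevel = function(g, seed) { set.seed(seed); igraph::cluster_louvain(g) },
  edge_betweenness = function(g, seed) igraph::cluster_edge_betweenness(g),
  spinglass = function(g, seed) { set.seed(seed); igraph::cluster_spinglass(g) },
  walktrap = function(g, seed) igraph::cluster_walktrap(g)
)

fragment_igraph <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}

#' Decompose a fragment graph into compact rigid groups
#'
#' Community clustering maximizes the modularity of the fragment graph
#' whose edge weights encode spatial proximity (inverse mean CV distance,
#' boosted for same-type pairs), so the groups that emerge are compact
#' local folds suitable for rigid-group (gyre/gimble-style) refinement.
#' With `sheets_together` every sheet is collapsed into a single pre-merged
#' node, so strands of one sheet can never be split across groups. With
#' `homogeneous_size`, intra-group edges of the largest group are
#' iteratively downweighted and the graph re-clustered until group sizes
#' differ by at most one fragment (or 20 rounds), biasing the optimum
#' toward size-homogeneous clusters; the reported modularity is always
#' recomputed on the original weights.
#'
#' @param annotation a `cv_annotation` (or a `fragment_graph`)
#' @param algorithm one of fastgreedy, infomap, eigenvectors,
#'   label_propagation, multilevel, edge_betweenness, spinglass, walktrap
#' @param sheets_together force all strands of a sheet into one group
#' @param homogeneous_size bias toward equal-size groups
#' @param seed seed for stochastic algorithms
#' @return a `cv_decomposition`: `membership` (group per fragment),
#'   `modularity`, `algorithm`, `constraints`
#' @export
decompose_fold <- function(annotation, algorithm = "fastgreedy",
                      sheets_together = FALSE, homogeneous_size = FALSE,
                      seed = 42L) {
  fg <- if (inherits(annotation, "cv_annotation")) annotation$fragment_graph
        else annotation
  if (is.null(fg) || length(fg$fragments_label) == 0) {
    stop("no secondary-structure fragments to decompose")
  }
  if (!algorithm %in% names(.algorithms)) {
    stop("unknown clustering algorithm: ", algorithm, " (supported: ",
         paste(names(.algorithms), collapse = ", "), ")")
  }
  nf <- length(fg$fragments_label)
  sheets <- if (inherits(annotation, "cv_annotation")) annotation$sheets
            else rep(NA_integer_, nf)

  # collapse sheets into supernodes
  node_of <- seq_len(nf)
  if (sheets_together && any(!is.na(sheets))) {
    grp <- ifelse(is.na(sheets), paste0("f", seq_len(nf)), paste0("s", sheets))
    node_of <- match(grp, unique(grp))
  }
  nn <- max(node_of)
  W0 <- matrix(0, nn, nn)
  for (a in seq_len(nf)) for (b in seq_len(nf)) {
    if (node_of[a] != node_of[b]) {
      W0[node_of[a], node_of[b]] <- W0[node_of[a], node_of[b]] + fg$weight[a, b]
    }
  }

  cluster_once <- function(W) {
    if (nrow(W) == 1) return(1L)
    cm <- .algorithms[[algorithm]](fragment_igraph(W), seed)
    as.integer(igraph::membership(cm))
  }
  W <- W0
  memb_n <- cluster_once(W)
  if (homogeneous_size) {
    for (round in seq_len(20L)) {
      sizes <- table(memb_n)
      if (max(sizes) - min(sizes) <= 1) break
      big <- as.integer(names(sizes)[which.max(sizes)])
      inside <- which(memb_n == big)
      W[inside, inside] <- W[inside, inside] * 0.8
      memb_n <- cluster_once(W)
    }
  }
  membership <- memb_n[node_of]
  membership <- match(membership, unique(membership))
  structure(list(membership = membership,
                 modularity = modularity_score(membership, fg),
                 algorithm = algorithm,
                 constraints = list(sheets_together = sheets_together,
                                    homogeneous_size = homogeneous_size),
                 fragment_graph = fg, sheets = sheets),
            class = "cv_decomposition")
}

#' @export
print.cv_decomposition <- function(x, ...) {
  cat(sprintf("<cv_decomposition> %d groups over %d fragments (%s), Q = %.3f\n",
              length(unique(x$membership)), length(x$membership),
              x$algorithm, x$modularity))
  invisible(x)
}

#' Hierarchical decomposition
#'
#' Iterates the clustering over every granularity, producing one level per
#' group count from a single all-encompassing cluster down to one fragment
#' per group, each level with its recomputed modularity. The underlying
#' dendrogram comes from an agglomerative community algorithm
#' (fastgreedy/walktrap/edge betweenness).
#'
#' @param annotation a `cv_annotation` (or `fragment_graph`)
#' @param algorithm an agglomerative algorithm with a full merge tree
#' @return a `cv_decomposition_tree`: list of levels, each with
#'   `membership` and `modularity`; plus the merge tree for dendrograms
#' @export
decompose_hierarchical <- function(annotation,
                                   algorithm = c("fastgreedy", "walktrap",
                                                 "edge_betweenness")) {
  algorithm <- match.arg(algorithm)
  fg <- if (inherits(annotation, "cv_annotation")) annotation$fragment_graph
        else annotation
  if (is.null(fg) || length(fg$fragments_label) == 0) {
    stop("no secondary-structure fragments to decompose")
  }
  nf <- length(fg$fragments_label)
  g <- fragment_igraph(fg$weight)
  cm <- .algorithms[[algorithm]](g, 42L)
  levels <- lapply(seq_len(nf), function(k) {
    memb <- if (k == 1) rep(1L, nf)
            else if (k == nf) seq_len(nf)
            else as.integer(igraph::cut_at(cm, no = k))
    list(membership = memb, modularity = modularity_score(memb, fg))
  })
  structure(list(levels = levels, algorithm = algorithm, communities = cm,
                 fragment_graph = fg),
            class = "cv_decomposition_tree")
}

#' @export
print.cv_decomposition_tree <- function(x, ...) {
  cat(sprintf("<cv_decomposition_tree> %d levels (%s)\n",
              length(x$levels), x$algorithm))
  invisible(x)
}

#' Render the decomposition dendrogram
#'
#' @param tree a `cv_decomposition_tree`
#' @param path PNG output file
#' @return `path`, invisibly
#' @export
plot_dendrogram <- function(tree, path) {
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  hc <- tryCatch(igraph::as.hclust(tree$communities), error = function(e) NULL)
  if (!is.null(hc)) {
    plot(hc, main = "Fragment decomposition dendrogram",
         xlab = "fragment", sub = "")
  } else {
    q <- vapply(tree$levels, function(l) l$modularity, numeric(1))
    plot(seq_along(q), q, type = "b", xlab = "number of groups",
         ylab = "modularity", main = "Decomposition levels")
  }
  invisible(path)
}

#' Write a decomposition as a PDB file with one chain per group
#'
#' Residues belonging to a fragment take their group's chain identifier;
#' coil residues between fragments are assigned to the nearest group by
#' minimum CA distance, so the output model is exhaustive and directly
#' usable for rigid-group refinement.
#'
#' @param annotation the `cv_annotation` that was decomposed
#' @param decomposition a `cv_decomposition`
#' @param path output PDB path
#' @return the per-residue group assignment (list per stretch), invisibly
#' @export
write_decomposition <- function(annotation, decomposition, path) {
  strc <- annotation$structure
  frags <- annotation$fragments
  memb <- decomposition$membership
  chains <- c(LETTERS, letters, as.character(0:9))
  groups <- sort(unique(memb))
  # CA coordinates per group, for nearest-group assignment of coil
  group_ca <- lapply(groups, function(g) {
    do.call(rbind, lapply(which(memb == g), function(fi) {
      f <- frags[[fi]]
      strc$stretches[[f$stretch]]$xyz$CA[f$start:f$end, , drop = FALSE]
    }))
  })
  assign <- vector("list", length(strc$stretches))
  for (s in seq_along(strc$stretches)) {
    n <- length(strc$stretches[[s]]$resno)
    a <- rep(NA_integer_, n)
    for (fi in seq_along(frags)) {
      f <- frags[[fi]]
      if (f$stretch == s) a[f$start:f$end] <- memb[fi]
    }
    ca <- strc$stretches[[s]]$xyz$CA
    for (r in which(is.na(a))) {
      d <- vapply(group_ca, function(m) {
        min(sqrt(colSums((t(m) - ca[r, ])^2)))
      }, numeric(1))
      a[r] <- groups[which.min(d)]
    }
    assign[[s]] <- a
  }
  write_structure(strc, path,
                  chain_override = lapply(assign, function(a) {
                    chains[match(a, groups)]
                  }))
  invisible(assign)
}

#' Exhaustive best-modularity partition (oracle for small graphs)
#'
#' Enumerates every partition of up to `max_n` nodes (Bell number growth)
#' and returns the maximum-modularity one. Intended as an independent check
#' of the clustering heuristics on small graphs.
#'
#' @param fgraph a `fragment_graph` or weight matrix
#' @param max_n guard on the number of nodes
#' @return list with `membership` and `modularity`
#' @export
best_partition_exhaustive <- function(fgraph, max_n = 8L) {
  A <- if (inherits(fgraph, "fragment_graph")) fgraph$weight else fgraph
  n <- nrow(A)
  stopifnot(n <= max_n)
  best <- list(membership = rep(1L, n), modularity = -Inf)
  memb <- integer(n)
  recurse <- function(i, k) {
    if (i > n) {
      q <- modularity_score(memb[seq_len(n)], A)
      if (q > best$modularity) best <<- list(membership = memb[seq_len(n)],
                                             modularity = q)
      return(invisible())
    }
    for (g in seq_len(k + 1L)) {
      memb[i] <<- g
      recurse(i + 1L, max(k, g))
    }
  }
  recurse(1L, 0L)
  best
}
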