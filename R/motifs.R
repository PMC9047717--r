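# Directed triad census, degree-preserving null model, and significance
# profiles for comparing a learned network topology to reference graphs
# (e.g. connectomes supplied as edge lists).

# The 13 connected classes of the standard 16-class directed triad census,
# in conventional census order (the 3 classes with an isolated node --
# empty, single-edge, mutual-pair -- are excluded):
#   1 021D  2 021U  3 021C  4 111D  5 111U  6 030T  7 030C
#   8 201   9 120D 10 120U 11 120C 12 210  13 300
.motif_cache <- new.env(parent = emptyenv())

# 6-bit code of a labelled 3-node digraph: bits (e12, e21, e13, e31, e23, e32)
triad_code <- function(adj3) {
  sum(c(adj3[1, 2], adj3[2, 1], adj3[1, 3],
        adj3[3, 1], adj3[2, 3], adj3[3, 2]) * c(1, 2, 4, 8, 16, 32))
}

code_to_adj <- function(code) {
  bits <- as.integer(intToBits(code))[1:6]
  m <- matrix(0L, 3, 3)
  m[1, 2] <- bits[1]; m[2, 1] <- bits[2]; m[1, 3] <- bits[3]
  m[3, 1] <- bits[4]; m[2, 3] <- bits[5]; m[3, 2] <- bits[6]
  m
}

canonical_code <- function(code) {
  adj <- code_to_adj(code)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  min(vapply(perms, function(p) triad_code(adj[p, p]), 0))
}

# 64-entry lookup: labelled code -> connected class 1..13, or 0 (a node
# not weakly connected to the other two). Built once from one exemplar
# per class.
triad_lookup <- function() {
  tab <- get0("table64", envir = .motif_cache)
  if (!is.null(tab)) return(tab)
  ex <- list(
    rbind(c(0,0,0), c(1,0,1), c(0,0,0)),              # 021D  A<-B->C
    rbind(c(0,1,0), c(0,0,0), c(0,1,0)),              # 021U  A->B<-C
    rbind(c(0,1,0), c(0,0,1), c(0,0,0)),              # 021C  A->B->C
    rbind(c(0,1,0), c(1,0,0), c(0,1,0)),              # 111D  A<->B<-C
    rbind(c(0,1,0), c(1,0,1), c(0,0,0)),              # 111U  A<->B->C
    rbind(c(0,1,1), c(0,0,0), c(0,1,0)),              # 030T
    rbind(c(0,0,1), c(1,0,0), c(0,1,0)),              # 030C  cycle
    rbind(c(0,1,0), c(1,0,1), c(0,1,0)),              # 201   A<->B<->C
    rbind(c(0,0,1), c(1,0,1), c(1,0,0)),              # 120D  A<-B->C, A<->C
    rbind(c(0,1,1), c(0,0,0), c(1,1,0)),              # 120U  A->B<-C, A<->C
    rbind(c(0,1,1), c(0,0,1), c(1,0,0)),              # 120C  A->B->C, A<->C
    rbind(c(0,1,1), c(0,0,1), c(1,1,0)),              # 210
    rbind(c(0,1,1), c(1,0,1), c(1,1,0)))              # 300
  canon_class <- vapply(ex, function(m) canonical_code(triad_code(m)), 0)
  tab <- integer(64)
  for (code in 0:63) {
    cl <- match(canonical_code(code), canon_class)
    tab[code + 1L] <- if (is.na(cl)) 0L else cl
  }
  assign("table64", tab, envir = .motif_cache)
  tab
}

#' Census of connected 3-node directed motifs
#'
#' Counts the induced subgraph isomorphism class of every node triple of a
#' directed graph and returns the occurrences of the 13 connected triad
#' classes, in conventional census order (021D, 021U, 021C, 111D, 111U,
#' 030T, 030C, 201, 120D, 120U, 120C, 210, 300). Triples containing an
#' isolated node are not motifs and are not counted.
#'
#' @param adjacency square 0/1 (or logical) adjacency matrix of a directed
#'   graph without self-loops; `adjacency[i, j] = 1` is an edge i -> j.
#' @return integer vector of 13 motif counts.
#' @export
triad_census <- function(adjacency) {
  A <- (as.matrix(adjacency) != 0) * 1L
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (any(diag(A) != 0)) stop("self-loops are not allowed")
  n <- nrow(A)
  counts <- integer(13)
  if (n < 3L) return(counts)
  tab <- triad_lookup()
  tri <- utils::combn(n, 3L)
  a <- tri[1L, ]; b <- tri[2L, ]; c_ <- tri[3L, ]
  code <- A[cbind(a, b)] + 2L * A[cbind(b, a)] + 4L * A[cbind(a, c_)] +
    8L * A[cbind(c_, a)] + 16L * A[cbind(b, c_)] + 32L * A[cbind(c_, b)]
  cls <- tab[code + 1L]
  tabulate(cls[cls > 0L], nbins = 13L)
}

#' Degree-preserving random reference ensemble
#'
#' Generates random directed graphs with exactly the in- and out-degree
#' sequence of the input via repeated edge swaps (no self-loops or
#' multi-edges introduced; 10 x edge-count swap attempts per sample). Graphs
#' too small or rigid to randomize (< 2 edges) yield identity copies with a
#' warning.
#'
#' @param adjacency 0/1 adjacency matrix.
#' @param n_random ensemble size (>= 20 recommended for profiles).
#' @param seed optional integer seed for reproducible ensembles.
#' @return list of adjacency matrices.
#' @export
degree_preserving_ensemble <- function(adjacency, n_random = 100,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- (as.matrix(adjacency) != 0) * 1L
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  n_edges <- igraph::ecount(g)
  if (n_edges < 2L) {
    warning("graph too small to randomize; returning identity samples")
    return(replicate(n_random, A, simplify = FALSE))
  }
  lapply(seq_len(n_random), function(i) {
    r <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                  niter = 10 * n_edges))
    unname(igraph::as_adjacency_matrix(r, sparse = FALSE))
  })
}

#' Motif significance profile of a directed graph
#'
#' For each of the 13 connected triad motifs, computes the z-score of the
#' observed count against a degree-preserving random ensemble,
#' `z = (N_obs - mean(N_rand)) / sd(N_rand)`, and scales the z-vector to
#' unit Euclidean norm. Motifs whose count has zero variance in the
#' ensemble get z = 0, keeping the profile finite; if every component is 0
#' the profile is undefined and an error is signalled.
#'
#' @inheritParams degree_preserving_ensemble
#' @return object of class `"bpsr_motif_profile"`: list with `counts`
#'   (observed), `z`, the unit-norm profile `sp`, and `n_random`.
#' @export
significance_profile <- function(adjacency, n_random = 100, seed = NULL) {
  counts <- triad_census(adjacency)
  ens <- degree_preserving_ensemble(adjacency, n_random, seed = seed)
  rand <- vapply(ens, triad_census, integer(13))
  mu <- rowMeans(rand)
  sd_ <- apply(rand, 1, stats::sd)
  z <- ifelse(sd_ > 0, (counts - mu) / sd_, 0)
  nrm <- sqrt(sum(z^2))
  if (nrm == 0)
    stop("significance profile undefined: all motif z-scores are zero")
  structure(list(counts = counts, z = z, sp = z / nrm, n_random = n_random),
            class = "bpsr_motif_profile")
}

#' @export
print.bpsr_motif_profile <- function(x, ...) {
  nm <- c("021D", "021U", "021C", "111D", "111U", "030T", "030C",
          "201", "120D", "120U", "120C", "210", "300")
  cat("<bpsr_motif_profile> (", x$n_random, "random references )\n")
  print(round(stats::setNames(x$sp, nm), 3))
  invisible(x)
}

#' Adjacency graph of a trained network's synapses
#'
#' Builds the directed graph whose edges are the existing (unmasked,
#' nonzero) synapses of the selected layers, for motif analysis of the
#' learned structure. With `layers = 1` (the default scope) the graph spans
#' the input channels and the first layer's neurons -- inter-layer synapses
#' give bipartite edges and, for a recurrent layer, intra-layer synapses
#' add edges among its neurons. Selected layers must be contiguous; each
#' additional layer appends its neurons and in-edges.
#'
#' @param network list of layers or fitted `bpsr` object.
#' @param layers contiguous indices of layers to include (default 1).
#' @return 0/1 adjacency matrix over input + selected-layer neurons.
#' @export
network_to_graph <- function(network, layers = 1L) {
  if (inherits(network, "bpsr")) network <- network$layers
  layers <- sort(as.integer(layers))
  if (length(layers) > 1L && any(diff(layers) != 1L))
    stop("selected layers must be contiguous")
  sizes <- c(ncol(network[[layers[1]]]$w_in),
             vapply(network[layers], function(l) nrow(l$w_in), 0L))
  total <- sum(sizes)
  offs <- cumsum(c(0L, sizes))
  A <- matrix(0L, total, total)
  for (i in seq_along(layers)) {
    l <- network[[layers[i]]]
    src <- offs[i] + seq_len(sizes[i])
    dst <- offs[i + 1L] + seq_len(sizes[i + 1L])
    A[src, dst] <- t((l$mask_in & l$w_in != 0) * 1L)
    A[dst, dst] <- t((l$mask_rec & l$w_rec != 0) * 1L)
  }
  A
}

#' Read a directed edge list as an adjacency matrix
#'
#' Two-column whitespace/comma-separated text, one `from to` pair per line
#' (integer ids or names), e.g. a connectome graph for comparison against a
#' learned topology.
#'
#' @param path path to the edge-list file.
#' @return 0/1 adjacency matrix.
#' @export
read_edgelist <- function(path) {
  el <- utils::read.table(path, header = FALSE,
                          sep = "", stringsAsFactors = FALSE)[, 1:2]
  nodes <- sort(unique(c(el[[1]], el[[2]])))
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  A[cbind(match(el[[1]], nodes), match(el[[2]], nodes))] <- 1L
  A
}
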