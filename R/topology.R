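#' Bipartite miRNA-mRNA topology
#'
#' A bipartite graph with miRNA nodes on one side, mRNA (gene) nodes on the
#' other, and undirected edges only between the two sides. Duplicate edges
#' are collapsed; edges referring to unknown nodes are an error.
#'
#' @param mirnas character vector of miRNA node ids (unique).
#' @param mrnas character vector of mRNA node ids (unique, disjoint from
#'   `mirnas`).
#' @param edges a data.frame with character columns `mirna` and `mrna`.
#' @return An object of class `bipartite_topology` with components
#'   `mirnas`, `mrnas` and `edges` (deduplicated, ordered).
#' @examples
#' bipartite_topology(c("r1"), c("t1", "t2"),
#'                    data.frame(mirna = "r1", mrna = c("t1", "t2")))
#' @export
bipartite_topology <- function(mirnas, mrnas, edges) {
  mirnas <- as.character(mirnas)
  mrnas <- as.character(mrnas)
  if (anyDuplicated(mirnas)) stop("duplicate miRNA ids", call. = FALSE)
  if (anyDuplicated(mrnas)) stop("duplicate mRNA ids", call. = FALSE)
  if (length(intersect(mirnas, mrnas)))
    stop("node ids shared between the miRNA and mRNA sides: ",
         paste(utils::head(intersect(mirnas, mrnas), 3), collapse = ", "),
         call. = FALSE)
  stopifnot(is.data.frame(edges), all(c("mirna", "mrna") %in% names(edges)))
  edges <- data.frame(mirna = as.character(edges$mirna),
                      mrna = as.character(edges$mrna),
                      stringsAsFactors = FALSE)
  if (!all(edges$mirna %in% mirnas))
    stop("edge refers to unknown miRNA: ",
         paste(utils::head(setdiff(edges$mirna, mirnas), 3), collapse = ", "),
         call. = FALSE)
  if (!all(edges$mrna %in% mrnas))
    stop("edge refers to unknown mRNA: ",
         paste(utils::head(setdiff(edges$mrna, mrnas), 3), collapse = ", "),
         call. = FALSE)
  edges <- unique(edges)
  edges <- edges[order(edges$mirna, edges$mrna), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(mirnas = mirnas, mrnas = mrnas, edges = edges),
            class = "bipartite_topology")
}

#' @export
print.bipartite_topology <- function(x, ...) {
  cat(sprintf("<bipartite_topology> %d miRNAs, %d mRNAs, %d edges\n",
              length(x$mirnas), length(x$mrnas), nrow(x$edges)))
  invisible(x)
}

#' Convert a bipartite topology to an igraph graph
#'
#' Vertices carry a logical `type` attribute (`TRUE` for mRNAs), the igraph
#' bipartite convention used by [project()].
#'
#' @param topology a [bipartite_topology()] object.
#' @return An undirected igraph object.
#' @export
as_igraph <- function(topology) {
  stopifnot(inherits(topology, "bipartite_topology"))
  verts <- data.frame(
    name = c(topology$mirnas, topology$mrnas),
    type = c(rep(FALSE, length(topology$mirnas)),
             rep(TRUE, length(topology$mrnas))),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(topology$edges, directed = FALSE,
                                vertices = verts)
}

chain_node_names <- function(N) {
  ells <- 0:(2 * N - 1)
  ifelse(ells %% 2 == 0, paste0("T", ells), paste0("R", ells))
}

#' Build a chain of alternating miRNAs and targets
#'
#' Constructs the reaction system for a chain of `2N` RNA species: `N`
#' targets at even positions `0, 2, ..., 2N-2` and `N` miRNAs at odd
#' positions `1, 3, ..., 2N-1`. Each miRNA at position `l` represses the
#' targets at `l - 1` and `l + 1`; with `boundary = "open"` out-of-range
#' neighbours are dropped, with `boundary = "circular"` positions wrap
#' modulo `2N`, so every node has exactly two partners.
#'
#' @param N number of miRNA-target pairs (`N >= 1`).
#' @param params a single [kinetic_params()] object applied homogeneously,
#'   or a list of `2N` such objects giving position-specific parameters
#'   (entry `l + 1` belongs to position `l`; edge-level binding parameters
#'   are taken from the miRNA's entry).
#' @param boundary `"open"` or `"circular"`.
#' @return A `reaction_system` object with chain metadata (`$chain$ell`).
#' @examples
#' sys <- build_chain(3, kinetic_params(), boundary = "open")
#' nrow(sys$edges)  # 5 edges
#' @export
build_chain <- function(N, params = kinetic_params(),
                        boundary = c("open", "circular")) {
  boundary <- match.arg(boundary)
  stopifnot(N >= 1)
  nodes <- chain_node_names(N)
  ells <- 0:(2 * N - 1)
  if (inherits(params, "kinetic_params")) {
    plist <- rep(list(params), 2 * N)
  } else {
    stopifnot(is.list(params), length(params) == 2 * N)
    lapply(params, validate_kinetic_params)
    plist <- params
  }
  mirna_ells <- ells[ells %% 2 == 1]
  mrna_ells <- ells[ells %% 2 == 0]
  mirnas <- nodes[mirna_ells + 1]
  mrnas <- nodes[mrna_ells + 1]

  edge_rows <- list()
  for (l in mirna_ells) {
    for (nb in c(l - 1, l + 1)) {
      nb2 <- if (boundary == "circular") nb %% (2 * N) else nb
      if (nb2 < 0 || nb2 > 2 * N - 1) next
      pe <- plist[[l + 1]]
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        mirna = nodes[l + 1], mrna = nodes[nb2 + 1],
        b = pe$b, u_C = pe$u_C, d_C = pe$d_C, alpha = pe$alpha,
        stringsAsFactors = FALSE)
    }
  }
  edges <- unique(do.call(rbind, edge_rows))
  g <- numeric(2 * N); d <- numeric(2 * N)
  for (l in ells) {
    pe <- plist[[l + 1]]
    if (l %% 2 == 1) { g[l + 1] <- pe$g_R; d[l + 1] <- pe$d_R }
    else { g[l + 1] <- pe$g_T; d[l + 1] <- pe$d_T }
  }
  names(g) <- nodes; names(d) <- nodes
  new_reaction_system(
    topology = bipartite_topology(mirnas, mrnas, edges[c("mirna", "mrna")]),
    edge_params = edges,
    g = g, d = d,
    chain = list(ell = stats::setNames(ells, nodes), N = N,
                 boundary = boundary))
}

new_reaction_system <- function(topology, edge_params, g, d, chain = NULL) {
  edges <- merge(topology$edges, edge_params, by = c("mirna", "mrna"),
                 sort = FALSE)
  edges <- edges[order(match(edges$mirna, topology$mirnas),
                       match(edges$mrna, topology$mrnas)), , drop = FALSE]
  rownames(edges) <- NULL
  edges$i <- match(edges$mirna, topology$mirnas)
  edges$j <- match(edges$mrna, topology$mrnas)
  nodes <- c(topology$mirnas, topology$mrnas)
  stopifnot(setequal(names(g), nodes), setequal(names(d), nodes))
  structure(list(
    topology = topology,
    mirnas = topology$mirnas, mrnas = topology$mrnas,
    edges = edges,
    g_R = g[topology$mirnas], d_R = d[topology$mirnas],
    g_T = g[topology$mrnas], d_T = d[topology$mrnas],
    chain = chain), class = "reaction_system")
}

#' @export
print.reaction_system <- function(x, ...) {
  kind <- if (!is.null(x$chain)) sprintf("chain (N=%d, %s)", x$chain$N,
                                         x$chain$boundary) else "network"
  cat(sprintf("<reaction_system> %s: %d miRNAs, %d mRNAs, %d complexes\n",
              kind, length(x$mirnas), length(x$mrnas), nrow(x$edges)))
  invisible(x)
}

#' Build a reaction system on an arbitrary bipartite topology
#'
#' Attaches kinetic parameters to a bipartite interactome. Generation rates
#' are either uniform (`base_rate` for every node) or degree-proportional
#' (`base_rate * degree`), the latter mirroring the convention in which the
#' synthesis rate of each RNA is proportional to its number of interaction
#' partners. Degradation rates and per-edge binding parameters come from
#' `params`.
#'
#' @param topology a [bipartite_topology()] object.
#' @param params a [kinetic_params()] object supplying `d_R`, `d_T` and the
#'   per-edge `b`, `u_C`, `d_C`, `alpha` (applied to every edge).
#' @param generation_mode `"uniform"` or `"degree_proportional"`.
#' @param base_rate base generation rate (level/s); for
#'   `degree_proportional`, each node receives `base_rate * degree`.
#'   Isolated nodes then get zero generation (with a warning).
#' @return A `reaction_system` object.
#' @export
build_network <- function(topology, params = kinetic_params(),
                          generation_mode = c("uniform", "degree_proportional"),
                          base_rate = 1) {
  generation_mode <- match.arg(generation_mode)
  stopifnot(inherits(topology, "bipartite_topology"))
  if (length(topology$mirnas) == 0 || length(topology$mrnas) == 0)
    stop("topology must have nodes on both sides", call. = FALSE)
  nodes <- c(topology$mirnas, topology$mrnas)
  deg <- stats::setNames(numeric(length(nodes)), nodes)
  tab <- table(c(topology$edges$mirna, topology$edges$mrna))
  deg[names(tab)] <- as.numeric(tab)
  if (generation_mode == "uniform") {
    g <- stats::setNames(rep(base_rate, length(nodes)), nodes)
  } else {
    if (any(deg == 0))
      warning("isolated node(s) receive zero generation rate under ",
              "degree-proportional mode: ",
              paste(utils::head(names(deg)[deg == 0], 3), collapse = ", "))
    g <- base_rate * deg
  }
  d <- stats::setNames(
    c(rep(params$d_R, length(topology$mirnas)),
      rep(params$d_T, length(topology$mrnas))), nodes)
  ep <- cbind(topology$edges,
              b = params$b, u_C = params$u_C, d_C = params$d_C,
              alpha = params$alpha)
  new_reaction_system(topology, ep, g, d)
}

#' Multiply one node's generation rate
#'
#' Returns a copy of the system in which the generation rate of `node` is
#' multiplied by `factor` (e.g. `factor = 9/10` for a mild depletion of a
#' miRNA source, `factor = 0` for a knockout). All other parameters are
#' shared with the input system.
#'
#' @param system a `reaction_system`.
#' @param node node id (miRNA or mRNA).
#' @param factor nonnegative multiplier.
#' @return A `reaction_system`.
#' @export
perturb_generation_rate <- function(system, node, factor) {
  stopifnot(inherits(system, "reaction_system"), factor >= 0)
  if (node %in% system$mirnas) {
    system$g_R[node] <- system$g_R[node] * factor
  } else if (node %in% system$mrnas) {
    system$g_T[node] <- system$g_T[node] * factor
  } else {
    stop("unknown node: ", node, call. = FALSE)
  }
  system
}
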