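#' Column dialect for CLASH-style interaction tables
#'
#' Maps the logical fields of an interaction record to column names of a
#' tab-separated file. `gene` may be `NULL` when the table only carries
#' transcript ids, in which case transcripts are treated as genes.
#'
#' @param mirna,transcript,gene,reads,energy,region column names
#'   (`region` and `gene` optional, `NULL` to omit).
#' @return A named list of class `interaction_dialect`.
#' @export
interaction_dialect <- function(mirna = "mirna", transcript = "transcript",
                                gene = "gene", reads = "reads",
                                energy = "energy", region = NULL) {
  structure(list(mirna = mirna, transcript = transcript, gene = gene,
                 reads = reads, energy = energy, region = region),
            class = "interaction_dialect")
}

#' Read a CLASH-style interaction table
#'
#' Reads a tab-separated table of miRNA-target interactions (miRNA id,
#' transcript id, read count, binding free energy in kcal/mol) and
#' aggregates transcript-level records to the gene level: read counts of
#' all transcripts of a gene are summed per miRNA-gene pair, and the
#' minimum (most stable) binding energy is kept.
#'
#' @param path path to a TSV file with a header row.
#' @param dialect an [interaction_dialect()] mapping column names.
#' @return A data.frame of class `interaction_table` with columns `mirna`,
#'   `gene`, `reads`, `energy`, one row per miRNA-gene pair.
#' @export
read_interaction_table <- function(path, dialect = interaction_dialect()) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  needed <- c(dialect$mirna, dialect$transcript, dialect$reads,
              dialect$energy)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("interaction table is missing mapped column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  energy <- suppressWarnings(as.numeric(raw[[dialect$energy]]))
  bad <- which(is.na(energy) & !is.na(raw[[dialect$energy]]) &
                 nzchar(raw[[dialect$energy]]))
  if (length(bad))
    stop("non-numeric binding energy at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  reads <- suppressWarnings(as.numeric(raw[[dialect$reads]]))
  if (any(is.na(reads)) || any(reads < 0))
    stop("read counts must be nonnegative numbers", call. = FALSE)
  gene <- if (!is.null(dialect$gene) && dialect$gene %in% names(raw))
    as.character(raw[[dialect$gene]])
  else as.character(raw[[dialect$transcript]])
  df <- data.frame(mirna = as.character(raw[[dialect$mirna]]),
                   gene = gene, reads = reads, energy = energy,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    return(structure(df, class = c("interaction_table", "data.frame")))
  if (any(!nzchar(df$mirna)) || any(!nzchar(df$gene)))
    stop("empty miRNA or gene id in interaction table", call. = FALSE)
  aggregate_interactions(df)
}

#' Aggregate transcript-level interaction records to gene level
#'
#' Collapses records to one row per miRNA-gene pair: read counts are
#' summed and the minimum (most stable) binding energy is kept. Applied
#' automatically by [read_interaction_table()]; exported for tables built
#' in memory (e.g. from [generate_interactome()]).
#'
#' @param df a data.frame with columns `mirna`, `gene`, `reads`, `energy`.
#' @return An `interaction_table` data.frame.
#' @export
aggregate_interactions <- function(df) {
  key <- interaction(df$mirna, df$gene, drop = TRUE)
  agg <- data.frame(
    mirna = tapply(df$mirna, key, `[`, 1),
    gene = tapply(df$gene, key, `[`, 1),
    reads = as.numeric(tapply(df$reads, key, sum)),
    energy = as.numeric(tapply(df$energy, key, min)),
    stringsAsFactors = FALSE)
  agg <- agg[order(agg$mirna, agg$gene), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, class = c("interaction_table", "data.frame"))
}

#' Write an interaction table as TSV
#'
#' Inverse of [read_interaction_table()] for gene-level tables (one
#' transcript per gene, named after the gene), so generated tables
#' round-trip through write/read identically.
#'
#' @param records an `interaction_table` (or compatible data.frame).
#' @param path output path.
#' @param dialect an [interaction_dialect()].
#' @export
write_interaction_table <- function(records, path,
                                    dialect = interaction_dialect()) {
  out <- data.frame(records$mirna,
                    if ("transcript" %in% names(records)) records$transcript
                    else records$gene,
                    records$gene, records$reads, records$energy,
                    stringsAsFactors = FALSE)
  names(out) <- c(dialect$mirna, dialect$transcript,
                  if (is.null(dialect$gene)) "gene" else dialect$gene,
                  dialect$reads, dialect$energy)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Filter interactions to the high-confidence set
#'
#' Keeps records whose binding free energy is strictly below
#' `energy_threshold` (default -13.4 kcal/mol; a record at exactly the
#' threshold is removed) and, optionally, whose read count exceeds
#' `min_reads`.
#'
#' @param records an `interaction_table`.
#' @param energy_threshold energy cutoff in kcal/mol (strict `<`).
#' @param min_reads optional read-count cutoff (strict `>`); `NULL` keeps
#'   all read counts.
#' @return The filtered `interaction_table`.
#' @export
filter_high_confidence <- function(records, energy_threshold = -13.4,
                                   min_reads = NULL) {
  keep <- records$energy < energy_threshold
  if (!is.null(min_reads)) keep <- keep & records$reads > min_reads
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("interaction_table", "data.frame"))
}

#' Build the bipartite interactome from interaction records
#'
#' One undirected edge per distinct miRNA-gene pair (duplicates
#' collapsed).
#'
#' @param records an `interaction_table`.
#' @return A [bipartite_topology()].
#' @export
build_bipartite <- function(records) {
  edges <- unique(data.frame(mirna = records$mirna, mrna = records$gene,
                             stringsAsFactors = FALSE))
  bipartite_topology(sort(unique(records$mirna)), sort(unique(records$gene)),
                     edges)
}

#' Project a bipartite network onto one side
#'
#' Unipartite projection: two nodes of the chosen side are connected when
#' they share at least one neighbour on the other side, with edge weight
#' equal to the number of shared neighbours. No self-edges.
#'
#' @param topology a [bipartite_topology()].
#' @param side `"mirna"` or `"mrna"`.
#' @return A weighted undirected igraph graph.
#' @export
project <- function(topology, side = c("mirna", "mrna")) {
  side <- match.arg(side)
  g <- as_igraph(topology)
  pr <- igraph::bipartite_projection(g, multiplicity = TRUE)
  # proj1 = type FALSE (miRNAs), proj2 = type TRUE (mRNAs)
  if (side == "mirna") pr$proj1 else pr$proj2
}

as_graph_input <- function(graph) {
  if (inherits(graph, "bipartite_topology")) as_igraph(graph) else graph
}

#' Shortest-path statistics
#'
#' Unweighted BFS shortest paths on the largest connected component:
#' average shortest path length (ASPL, mean over connected ordered node
#' pairs excluding self-pairs) and the path-length histogram.
#'
#' @param graph an igraph graph or a [bipartite_topology()].
#' @return A list with `aspl`, `histogram` (data.frame `length`, `count`
#'   over unordered pairs), `n_nodes_lcc`, `n_nodes`.
#' @export
path_statistics <- function(graph) {
  g <- as_graph_input(graph)
  if (igraph::vcount(g) < 2) stop("graph needs at least 2 nodes", call. = FALSE)
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  lcc <- igraph::induced_subgraph(g, keep)
  d <- igraph::distances(lcc, weights = NA)
  vals <- d[upper.tri(d)]
  tab <- table(vals)
  data_hist <- data.frame(length = as.numeric(names(tab)),
                          count = as.numeric(tab))
  list(aspl = mean(vals), histogram = data_hist,
       n_nodes_lcc = igraph::vcount(lcc), n_nodes = igraph::vcount(g))
}

#' Average clustering coefficient
#'
#' Mean of the local (unweighted) clustering coefficients over all nodes;
#' nodes of degree below 2 contribute 0.
#'
#' @param graph an igraph graph or a [bipartite_topology()].
#' @return A number in `[0, 1]`.
#' @export
clustering_coefficient <- function(graph) {
  g <- as_graph_input(graph)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Small-world coefficient against an Erdős–Rényi ensemble
#'
#' `sigma = (C / C_rand) / (ASPL / ASPL_rand)`, where `C_rand` and
#' `ASPL_rand` are averaged over `n_random` Erdős–Rényi graphs with the
#' same node count and matched edge probability
#' `p = |E| / choose(|V|, 2)` (statistics taken on each random graph's
#' largest component). `sigma > 1` flags a small-world topology. Ensemble
#' draws whose largest component has fewer than 2 nodes are resampled and
#' counted.
#'
#' @param graph an igraph graph or a [bipartite_topology()].
#' @param n_random ensemble size (default 100).
#' @param seed RNG seed for the ensemble.
#' @return A list with `sigma`, `small_world`, `C`, `aspl`, `C_rand`,
#'   `aspl_rand`, `n_random`, `n_resampled`.
#' @export
small_world_sigma <- function(graph, n_random = 100, seed = 1) {
  g <- as_graph_input(graph)
  n <- igraph::vcount(g)
  p <- igraph::ecount(g) / choose(n, 2)
  C_obs <- clustering_coefficient(g)
  aspl_obs <- path_statistics(g)$aspl
  set.seed(seed)
  cc <- numeric(n_random); pl <- numeric(n_random)
  resampled <- 0L
  for (k in seq_len(n_random)) {
    repeat {
      rg <- igraph::sample_gnp(n, p)
      comp <- igraph::components(rg)
      if (max(comp$csize) >= 2) break
      resampled <- resampled + 1L
      if (resampled > 100 * n_random)
        stop("random ensemble keeps producing trivial components",
             call. = FALSE)
    }
    cc[k] <- clustering_coefficient(rg)
    pl[k] <- path_statistics(rg)$aspl
  }
  C_rand <- mean(cc); aspl_rand <- mean(pl)
  sigma <- (C_obs / C_rand) / (aspl_obs / aspl_rand)
  list(sigma = sigma, small_world = sigma > 1, C = C_obs, aspl = aspl_obs,
       C_rand = C_rand, aspl_rand = aspl_rand, n_random = n_random,
       n_resampled = resampled)
}

#' Fit a power law to a degree distribution
#'
#' Default method: least-squares fit of log frequency against log degree
#' over the positive-frequency support, returning the slope magnitude as
#' the exponent and the Pearson correlation of the log-log relation. Bins
#' are weighted by their counts, which stabilizes the fit against the
#' scatter of sparsely populated high-degree bins without affecting exact
#' power-law inputs. `method = "mle"` instead uses the discrete
#' maximum-likelihood fit (`igraph::fit_power_law`) as an alternative
#' estimate (its `r` is `NA`).
#'
#' @param graph an igraph graph, a [bipartite_topology()] (degrees of
#'   both sides pooled), or a numeric vector of node degrees.
#' @param method `"lsq"` (default) or `"mle"`.
#' @param min_distinct minimum number of distinct positive degrees
#'   required (default 10).
#' @return A list with `exponent`, `r` and `n_degrees`.
#' @export
degree_powerlaw_fit <- function(graph, method = c("lsq", "mle"),
                                min_distinct = 10) {
  method <- match.arg(method)
  deg <- if (is.numeric(graph)) graph
  else igraph::degree(as_graph_input(graph))
  deg <- deg[deg > 0]
  distinct <- length(unique(deg))
  if (distinct < min_distinct)
    stop("degree distribution too degenerate for a power-law fit (",
         distinct, " distinct degrees)", call. = FALSE)
  if (method == "mle") {
    fit <- igraph::fit_power_law(deg, xmin = 1)
    return(list(exponent = fit$alpha, r = NA_real_, n_degrees = distinct))
  }
  tab <- table(deg)
  k <- as.numeric(names(tab)); f <- as.numeric(tab)
  lk <- log(k); lf <- log(f)
  fit <- stats::lm(lf ~ lk, weights = f)
  list(exponent = -unname(stats::coef(fit)[2]),
       r = stats::cor(lk, lf), n_degrees = distinct)
}

#' Summary statistics of a bipartite interactome
#'
#' Convenience wrapper computing node/edge counts, ASPL and path histogram
#' of the bipartite graph, and the degree power-law fit.
#'
#' @param topology a [bipartite_topology()].
#' @return A list of class `network_stats`.
#' @export
network_stats <- function(topology) {
  stopifnot(inherits(topology, "bipartite_topology"))
  ps <- path_statistics(topology)
  pf <- tryCatch(degree_powerlaw_fit(topology), error = function(e) NULL)
  structure(list(
    n_mirna = length(topology$mirnas), n_mrna = length(topology$mrnas),
    n_edges = nrow(topology$edges),
    aspl = ps$aspl, path_histogram = ps$histogram,
    powerlaw_exponent = if (is.null(pf)) NA_real_ else pf$exponent,
    powerlaw_r = if (is.null(pf)) NA_real_ else pf$r), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(paste0("<network_stats> %d miRNAs, %d mRNAs, %d edges; ",
                     "ASPL = %.3f; power law exponent = %.2f (r = %.2f)\n"),
              x$n_mirna, x$n_mrna, x$n_edges, x$aspl,
              x$powerlaw_exponent, x$powerlaw_r))
  invisible(x)
}
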