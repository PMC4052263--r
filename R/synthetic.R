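#' Sample kinetic parameter sets around a base set
#'
#' Draws `n` parameter sets whose entries are independent Gaussians with
#' mean equal to the base value and standard deviation `cv` times the base
#' value (so each parameter's spread is a fixed fraction of its value).
#' Negative draws are rejected and resampled; `alpha` is clipped to
#' `[0, 1]`.
#'
#' @param base a [kinetic_params()] object.
#' @param cv coefficient of variation (default 0.1).
#' @param n number of parameter sets.
#' @param seed RNG seed.
#' @return A list of `n` `kinetic_params` objects.
#' @export
sample_parameters <- function(base, cv = 0.1, n, seed = 1) {
  stopifnot(inherits(base, "kinetic_params"), cv >= 0, n >= 1)
  set.seed(seed)
  draw <- function(mu) {
    if (mu == 0 || cv == 0) return(rep(mu, n))
    out <- stats::rnorm(n, mu, cv * mu)
    tries <- 0
    while (any(out < 0)) {
      bad <- out < 0
      out[bad] <- stats::rnorm(sum(bad), mu, cv * mu)
      tries <- tries + 1
      if (tries > 1000)
        stop("rejection sampling failed: cv too large relative to ", mu,
             call. = FALSE)
    }
    out
  }
  vals <- lapply(unclass(base), draw)
  vals$alpha <- pmin(pmax(vals$alpha, 0), 1)
  lapply(seq_len(n), function(k)
    kinetic_params(g_R = vals$g_R[k], g_T = vals$g_T[k], b = vals$b[k],
                   u_C = vals$u_C[k], d_C = vals$d_C[k], d_R = vals$d_R[k],
                   d_T = vals$d_T[k], alpha = vals$alpha[k]))
}

#' Generate a synthetic CLASH-style interactome
#'
#' Produces a bipartite miRNA-gene interaction table with heavy-tailed
#' degrees: per-node attachment weights are drawn from a truncated power
#' law with the given exponent and edges are wired by weighted stub
#' matching with duplicate collapsing. Binding free energies are drawn
#' from Normal(-17, 3) kcal/mol and read counts from a geometric
#' distribution, so confidence filtering is exercisable on synthetic
#' data. A fraction of miRNA-gene pairs is emitted as two transcript
#' records with split reads, exercising transcript-to-gene aggregation.
#' No within-side edges can occur by construction.
#'
#' @param n_mirna,n_mrna side sizes. The default 40/300 keeps the
#'   gene-per-miRNA ratio high, as in measured interactomes, so that
#'   single-regulator targets (the retained 2-sep group of the k-sep
#'   analysis) are well populated.
#' @param mean_degree target mean gene degree; the target edge count is
#'   `round(mean_degree * n_mrna)`. `NULL` keeps the natural density of
#'   the drawn power-law sequence (cleanest degree histogram).
#' @param exponent power-law exponent of the attachment weights
#'   (default 2.6).
#' @param seed RNG seed; fixed seed gives identical output.
#' @param two_transcript_fraction fraction of pairs split into two
#'   transcript records (default 0.1).
#' @return A transcript-level data.frame with columns `mirna`,
#'   `transcript`, `gene`, `reads`, `energy`. Aggregate with
#'   [aggregate_interactions()] or round-trip through
#'   [write_interaction_table()] / [read_interaction_table()].
#' @export
generate_interactome <- function(n_mirna = 40, n_mrna = 300,
                                 mean_degree = 2, exponent = 2.6,
                                 seed = 1, two_transcript_fraction = 0.1) {
  stopifnot(n_mirna >= 1, n_mrna >= 1, mean_degree > 0, exponent > 1)
  set.seed(seed)
  mirnas <- sprintf("miR-%03d", seq_len(n_mirna))
  genes <- sprintf("G%04d", seq_len(n_mrna))
  draw <- function(n, kmax)
    sample(1:kmax, n, replace = TRUE, prob = (1:kmax)^(-exponent))
  k_ge_raw <- draw(n_mrna, max(2, min(50, n_mirna)))
  # NULL mean_degree: keep the natural density of the drawn power law
  # (no rescaling, so the drawn exponent is cleanly recoverable);
  # an explicit mean_degree stretches the sequence multiplicatively,
  # which preserves the tail exponent but broadens the small-degree head
  E <- if (is.null(mean_degree)) sum(k_ge_raw) else round(mean_degree * n_mrna)
  rescale <- function(k_raw) {
    n <- length(k_raw)
    k_sc <- k_raw * E / sum(k_raw)
    deg <- pmax(floor(k_sc) + (stats::runif(n) < (k_sc - floor(k_sc))), 1)
    while (sum(deg) > E) {  # trim/pad single stubs to hit E stubs exactly
      i <- sample(which(deg > 1), 1)
      deg[i] <- deg[i] - 1
    }
    while (sum(deg) < E) {
      i <- sample.int(n, 1)
      deg[i] <- deg[i] + 1
    }
    deg
  }
  deg_ge <- rescale(k_ge_raw)
  deg_mi <- rescale(draw(n_mirna, max(2, min(50, n_mrna))))
  # configuration wiring: shuffle stub lists against each other, dedup,
  # then top duplicates back up with weighted redraws
  df <- unique(data.frame(
    mirna = sample(rep(mirnas, deg_mi)),
    gene = sample(rep(genes, deg_ge)),
    stringsAsFactors = FALSE))
  tries <- 0
  while (nrow(df) < E && tries < 50) {
    need <- E - nrow(df)
    df <- unique(rbind(df, data.frame(
      mirna = sample(mirnas, need, replace = TRUE, prob = deg_mi),
      gene = sample(genes, need, replace = TRUE, prob = deg_ge),
      stringsAsFactors = FALSE)))
    tries <- tries + 1
  }
  if (nrow(df) < 0.9 * E)
    warning("duplicate collapsing removed >10% of drawn edges (",
            nrow(df), " of ", E, " kept)")
  df <- df[order(df$mirna, df$gene), , drop = FALSE]
  n <- nrow(df)
  df$reads <- stats::rgeom(n, prob = 0.2) + 1
  df$energy <- stats::rnorm(n, mean = -17, sd = 3)

  split_it <- stats::runif(n) < two_transcript_fraction & df$reads >= 2
  keep <- df[!split_it, , drop = FALSE]
  keep$transcript <- paste0(keep$gene, ".1")
  two <- df[split_it, , drop = FALSE]
  out <- keep
  if (nrow(two)) {
    r1 <- pmax(1, floor(two$reads / 2))
    t1 <- two; t1$reads <- r1; t1$transcript <- paste0(two$gene, ".1")
    t2 <- two; t2$reads <- two$reads - r1
    t2$transcript <- paste0(two$gene, ".2")
    # the second transcript binds slightly less stably
    t2$energy <- two$energy + abs(stats::rnorm(nrow(two), 0, 0.5))
    out <- rbind(keep, t1, t2)
  }
  out <- out[order(out$mirna, out$transcript),
             c("mirna", "transcript", "gene", "reads", "energy")]
  rownames(out) <- NULL
  out
}

# append a decoy target (e.g. an anti-miR oligonucleotide) bound to one miRNA
add_decoy_target <- function(system, source, g_decoy, params,
                             decoy_id = "DECOY") {
  stopifnot(inherits(system, "reaction_system"),
            source %in% system$mirnas)
  topo <- system$topology
  topo2 <- bipartite_topology(
    topo$mirnas, c(topo$mrnas, decoy_id),
    rbind(topo$edges, data.frame(mirna = source, mrna = decoy_id)))
  ep <- rbind(system$edges[c("mirna", "mrna", "b", "u_C", "d_C", "alpha")],
              data.frame(mirna = source, mrna = decoy_id, b = params$b,
                         u_C = params$u_C, d_C = params$d_C, alpha = 1))
  g <- c(system$g_R, system$g_T,
         stats::setNames(g_decoy, decoy_id))
  d <- c(system$d_R, system$d_T,
         stats::setNames(params$d_T, decoy_id))
  new_reaction_system(topo2, ep, g, d, chain = NULL)
}

#' Simulate a miRNA depletion experiment on an interactome
#'
#' End-to-end synthetic analogue of an anti-miR transfection experiment:
#' a reaction system is built on the connected component of the
#' interactome containing the source miRNA, its steady state computed,
#' the source depleted, and per-gene log2 fold changes of free target
#' levels emitted with additive Gaussian measurement noise (log2 units).
#' Control genes outside the interactome carry pure noise. The ground
#' truth distance classification is returned alongside, enabling
#' signal-recovery tests of the k-sep analysis.
#'
#' Depletion is modelled either as a reduction of the source miRNA's
#' generation rate (`mode = "generation"`, rate multiplied by `factor`)
#' or as a high-affinity decoy target that titrates the source
#' (`mode = "decoy"`, decoy generation rate `(1 - factor) / factor`
#' times the source's, mimicking the oligonucleotide mechanism).
#'
#' @param records a gene-level `interaction_table` (e.g. an aggregated
#'   [generate_interactome()] output).
#' @param params a [kinetic_params()] object for the kinetic system.
#' @param source source miRNA id; default: the highest-degree miRNA.
#' @param factor depletion factor in `(0, 1]` (default 0.5).
#' @param noise_sd measurement noise sd in log2 units (default 0.1).
#' @param n_control number of pure-noise control genes (default 300).
#' @param generation_mode passed to [build_network()]
#'   (default `"degree_proportional"`).
#' @param mode `"generation"` or `"decoy"`.
#' @param seed RNG seed for the measurement noise.
#' @return A list with `expression` (data.frame `gene`, `log2fc`),
#'   `classification` ([classify_sep_groups()] on the full interactome
#'   with the control universe), `source`, `factor`, `levels`
#'   (data.frame `gene`, `T_before`, `T_after` for simulated genes) and
#'   `system`.
#' @export
simulate_perturbation_experiment <- function(records,
                                             params = kinetic_params(),
                                             source = NULL, factor = 0.5,
                                             noise_sd = 0.1,
                                             n_control = 300,
                                             generation_mode = "degree_proportional",
                                             mode = c("generation", "decoy"),
                                             seed = 1) {
  mode <- match.arg(mode)
  stopifnot(factor > 0, factor <= 1, noise_sd >= 0)
  topo <- build_bipartite(records)
  if (is.null(source)) {
    degs <- table(topo$edges$mirna)
    source <- names(degs)[which.max(degs)]
  }
  if (!source %in% topo$mirnas)
    stop("source miRNA not in interactome: ", source, call. = FALSE)
  g <- as_igraph(topo)
  comp <- igraph::components(g)
  inside <- names(comp$membership)[comp$membership ==
                                     comp$membership[source]]
  sub <- bipartite_topology(
    intersect(topo$mirnas, inside), intersect(topo$mrnas, inside),
    topo$edges[topo$edges$mirna %in% inside &
                 topo$edges$mrna %in% inside, ])
  system <- build_network(sub, params, generation_mode = generation_mode)
  before <- steady_state(system)
  perturbed <- if (mode == "generation") {
    perturb_generation_rate(system, source, factor)
  } else {
    add_decoy_target(system, source,
                     g_decoy = (1 - factor) / factor *
                       system$g_R[[source]], params)
  }
  after <- steady_state(perturbed, state0 = NULL)

  sim_genes <- sub$mrnas
  T_before <- before$T[sim_genes]
  T_after <- after$T[sim_genes]
  lfc_sim <- log2(T_after / T_before)

  other_genes <- setdiff(topo$mrnas, sim_genes)  # other components: unperturbed
  ctrl_genes <- if (n_control > 0) sprintf("CTRL%04d", seq_len(n_control))
  else character(0)

  set.seed(seed)
  all_genes <- c(sim_genes, other_genes, ctrl_genes)
  signal <- c(lfc_sim, rep(0, length(other_genes) + length(ctrl_genes)))
  expression <- data.frame(
    gene = all_genes,
    log2fc = signal + if (noise_sd > 0)
      stats::rnorm(length(all_genes), 0, noise_sd) else 0,
    stringsAsFactors = FALSE)

  classification <- classify_sep_groups(topo, source,
                                        universe = all_genes)
  list(expression = expression, classification = classification,
       source = source, factor = factor,
       levels = data.frame(gene = sim_genes, T_before = unname(T_before),
                           T_after = unname(T_after),
                           stringsAsFactors = FALSE),
       system = system)
}

#' Bundled synthetic 15-miRNA/6-mRNA subnetwork
#'
#' Loads the packaged synthetic stand-in for a small, densely intertwined
#' miRNA-mRNA subnetwork (15 miRNAs, 6 mRNAs) used for network
#' perturbation experiments. The mRNAs form a chain of neighbourhoods
#' bridged by target-sharing miRNAs, so every miRNA has both 2-sep and
#' 4-sep partners. The edge list is synthetic (constructed, not measured).
#'
#' @return A [bipartite_topology()].
#' @export
example_subnetwork <- function() {
  path <- system.file("extdata", "subnetwork_15x6_synthetic.tsv",
                      package = "ceRNAflow")
  tab <- read_interaction_table(path)
  build_bipartite(tab)
}
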