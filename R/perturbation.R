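#' Classify nodes by bipartite distance from a perturbation source
#'
#' Emulates the distance-stratified ("k-sep") grouping used to trace a
#' perturbation through the miRNA-mRNA interactome. An artificial source
#' (e.g. an anti-miR oligonucleotide) is attached to the perturbed miRNA,
#' so the miRNA itself is 1-sep, its direct targets 2-sep, miRNAs sharing
#' those targets 3-sep, and so on: miRNAs carry odd labels, targets even
#' labels, each at its minimum BFS distance.
#'
#' Group membership additionally applies a uniqueness rule to target
#' groups: a target at distance `2k` is retained in the `2k`-sep group
#' only when every miRNA regulating it is itself `(2k-1)`-sep, so that the
#' propagation path to the target is unambiguous; targets with
#' mixed-label regulator sets are labelled by distance but flagged
#' excluded. The number of defining `(2k-1)`-sep regulators is recorded
#' for the single- versus multi-regulator sub-analysis
#' ([split_by_regulator_count()]).
#'
#' Control genes are the members of `universe` absent from the interactome
#' altogether.
#'
#' @param topology a [bipartite_topology()] (typically built from ALL
#'   interactions, including low-confidence ones, so that potential direct
#'   targets are not misassigned as distant ceRNAs; pass a filtered
#'   topology to rerun with high-confidence interactions only).
#' @param source_mirna the perturbed miRNA id.
#' @param universe character vector of gene ids measured in the expression
#'   experiment; genes not in the interactome become controls. `NULL` for
#'   no control group (with a warning).
#' @param max_sep largest sep label assigned (default 6); nodes farther
#'   away, or unreachable, are excluded.
#' @return An object of class `sep_classification`: a data.frame with
#'   columns `id`, `kind` (`"mirna"`/`"gene"`), `distance` (sep number,
#'   `NA` for controls/unreachable), `label` (`"1-sep"`, ..., `"control"`,
#'   `"excluded"`), `retained`, `n_defining_regulators`, `reason`; the
#'   source and topology are kept as attributes.
#' @export
classify_sep_groups <- function(topology, source_mirna, universe = NULL,
                                max_sep = 6) {
  stopifnot(inherits(topology, "bipartite_topology"))
  if (!source_mirna %in% topology$mirnas)
    stop("source miRNA not in topology: ", source_mirna, call. = FALSE)
  g <- as_igraph(topology)
  d <- igraph::distances(g, v = source_mirna, weights = NA)[1, ]
  sep <- d + 1  # artificial source node sits one edge above the miRNA
  ids <- igraph::V(g)$name
  kind <- ifelse(ids %in% topology$mirnas, "mirna", "gene")

  label <- rep("excluded", length(ids))
  reason <- rep(NA_character_, length(ids))
  retained <- rep(FALSE, length(ids))
  n_def <- rep(NA_integer_, length(ids))

  finite <- is.finite(sep)
  inrange <- finite & sep <= max_sep
  label[inrange] <- paste0(sep[inrange], "-sep")
  reason[!finite] <- "unreachable"
  reason[finite & sep > max_sep] <- "beyond-max-sep"
  retained[inrange & kind == "mirna"] <- TRUE

  # regulator sets per gene
  reg_of <- split(topology$edges$mirna, topology$edges$mrna)
  for (ix in which(inrange & kind == "gene")) {
    gene <- ids[ix]
    regs <- reg_of[[gene]]
    reg_sep <- sep[match(regs, ids)]
    defining <- sum(reg_sep == sep[ix] - 1)
    n_def[ix] <- as.integer(defining)
    if (all(reg_sep == sep[ix] - 1)) {
      retained[ix] <- TRUE
    } else {
      reason[ix] <- "mixed-regulator-labels"
    }
  }

  df <- data.frame(id = ids, kind = kind,
                   distance = ifelse(finite, sep, NA_real_),
                   label = label, retained = retained,
                   n_defining_regulators = n_def, reason = reason,
                   stringsAsFactors = FALSE, row.names = NULL)

  if (is.null(universe)) {
    warning("no expression universe supplied: control group is empty")
  } else {
    ctrl <- setdiff(universe, c(topology$mirnas, topology$mrnas))
    if (length(ctrl))
      df <- rbind(df, data.frame(
        id = ctrl, kind = "gene", distance = NA_real_, label = "control",
        retained = TRUE, n_defining_regulators = NA_integer_,
        reason = NA_character_, stringsAsFactors = FALSE))
  }
  structure(df, class = c("sep_classification", "data.frame"),
            source = source_mirna, topology = topology)
}

#' @export
print.sep_classification <- function(x, ...) {
  cat(sprintf("<sep_classification> source %s\n", attr(x, "source")))
  print(sep_group_sizes(x))
  invisible(x)
}

#' Group sizes of a sep classification
#'
#' Counts members per label, both as raw distance labels and as retained
#' group members (after the uniqueness rule). Both counts are reported
#' because membership before and after intersecting with a measured-gene
#' universe can differ.
#'
#' @param classification a [classify_sep_groups()] result.
#' @return A data.frame with columns `label`, `n_labelled`, `n_retained`.
#' @export
sep_group_sizes <- function(classification) {
  labs <- unique(classification$label)
  labs <- labs[order(match(labs, c(paste0(1:9, "-sep"), "control", "excluded")))]
  data.frame(
    label = labs,
    n_labelled = vapply(labs, function(l)
      sum(classification$label == l), integer(1)),
    n_retained = vapply(labs, function(l)
      sum(classification$label == l & classification$retained), integer(1)),
    row.names = NULL)
}

#' Median-centre log2 fold changes
#'
#' Subtracts the global median so the table's median log2 fold change
#' becomes exactly 0 (microarray-style median normalization).
#'
#' @param records a data.frame with columns `gene` and `log2fc`.
#' @return The same data.frame with centred `log2fc`.
#' @export
normalize_log2fc <- function(records) {
  stopifnot(is.data.frame(records), all(c("gene", "log2fc") %in% names(records)),
            nrow(records) >= 1)
  records$log2fc <- records$log2fc - stats::median(records$log2fc)
  records
}

group_values <- function(records, classification, label) {
  ids <- classification$id[classification$label == label &
                             classification$retained &
                             classification$kind == "gene"]
  records$log2fc[records$gene %in% ids]
}

#' Compare expression shifts between sep groups
#'
#' Two-sided two-sample Kolmogorov-Smirnov tests of log2 fold-change
#' distributions between group pairs (by default every even sep group
#' against the control group). The direction is the sign of the median
#' difference (first group minus second). Exact p-values are used when
#' both groups have at most 25 values, the asymptotic distribution
#' otherwise. Group pairs with fewer than 2 values on either side are
#' skipped with a reason. P-values are reported raw (no multiple-testing
#' correction); all tests performed are listed.
#'
#' @param records expression data.frame (`gene`, `log2fc`), typically
#'   [normalize_log2fc()]-ed. Genes classified but absent from `records`
#'   simply contribute no value.
#' @param classification a [classify_sep_groups()] result.
#' @param pairs list of 2-character vectors of labels, e.g.
#'   `list(c("2-sep", "control"))`. Default: each even sep label present
#'   versus control.
#' @return A data.frame with columns `group1`, `group2`, `n1`, `n2`, `D`,
#'   `p_value`, `direction`, `skipped`, `reason`.
#' @export
compare_groups <- function(records, classification, pairs = NULL) {
  stopifnot(all(c("gene", "log2fc") %in% names(records)))
  if (is.null(pairs)) {
    even <- intersect(paste0(seq(2, 8, 2), "-sep"),
                      unique(classification$label))
    pairs <- lapply(even, function(l) c(l, "control"))
  }
  rows <- lapply(pairs, function(pr) {
    v1 <- group_values(records, classification, pr[1])
    v2 <- group_values(records, classification, pr[2])
    out <- data.frame(group1 = pr[1], group2 = pr[2],
                      n1 = length(v1), n2 = length(v2),
                      D = NA_real_, p_value = NA_real_,
                      direction = NA_real_, skipped = FALSE,
                      reason = NA_character_, stringsAsFactors = FALSE)
    if (length(v1) < 2 || length(v2) < 2) {
      out$skipped <- TRUE
      out$reason <- "fewer than 2 values in a group"
      return(out)
    }
    exact <- length(v1) <= 25 && length(v2) <= 25
    kt <- suppressWarnings(
      stats::ks.test(v1, v2, alternative = "two.sided", exact = exact))
    out$D <- unname(kt$statistic)
    out$p_value <- kt$p.value
    out$direction <- sign(stats::median(v1) - stats::median(v2))
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' ECDF table for plotting group comparisons
#'
#' @param records expression data.frame (`gene`, `log2fc`).
#' @param classification a [classify_sep_groups()] result.
#' @param labels group labels to tabulate.
#' @return A data.frame with columns `label`, `log2fc`, `ecdf`.
#' @export
ecdf_table <- function(records, classification,
                       labels = c("2-sep", "4-sep", "6-sep", "control")) {
  rows <- lapply(labels, function(l) {
    v <- sort(group_values(records, classification, l))
    if (!length(v)) return(NULL)
    data.frame(label = l, log2fc = v, ecdf = seq_along(v) / length(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Split a target group by defining-regulator count
#'
#' Partitions the retained members of a target group (default 4-sep) into
#' those regulated by exactly one miRNA of the defining group and those
#' regulated by more than one, for testing whether multi-miRNA relay
#' strengthens the propagated effect.
#'
#' @param classification a [classify_sep_groups()] result.
#' @param group target group label (default `"4-sep"`).
#' @return A list with character vectors `single` and `multi`.
#' @export
split_by_regulator_count <- function(classification, group = "4-sep") {
  sel <- classification$label == group & classification$retained &
    classification$kind == "gene"
  n <- classification$n_defining_regulators[sel]
  ids <- classification$id[sel]
  out <- list(single = ids[n == 1], multi = ids[n > 1])
  if (!length(out$single) || !length(out$multi))
    message("one side of the regulator-count split is empty (single: ",
            length(out$single), ", multi: ", length(out$multi), ")")
  out
}

#' Remove transcription-factor confounds from the 4-sep group
#'
#' An apparent distant-ceRNA effect on a 4-sep target could instead arise
#' transcriptionally: if a 2-sep target encodes a TF activator, depleting
#' the source miRNA raises the TF and hence its transcriptional targets.
#' This filter drops from the 4-sep group (1) every listed target of a TF
#' activator whose gene is a retained 2-sep target, and (2) every gene
#' sharing at least one miRNA regulator with such a dropped gene (its
#' immediate ceRNAs; `depth` co-regulation steps, default 1).
#'
#' @param classification a [classify_sep_groups()] result.
#' @param tf_table data.frame with columns `tf_gene`, `target_gene`,
#'   `mode` (`"activator"` rows are used).
#' @param depth number of co-regulation expansion steps (default 1).
#' @return The classification with affected 4-sep members flagged
#'   `retained = FALSE` (reason `"tf-confound"`); removals are reported
#'   via message.
#' @export
tf_confound_filter <- function(classification, tf_table, depth = 1) {
  if (is.null(tf_table) || nrow(tf_table) == 0) {
    warning("empty TF table: classification returned unchanged")
    return(classification)
  }
  stopifnot(all(c("tf_gene", "target_gene", "mode") %in% names(tf_table)))
  topology <- attr(classification, "topology")
  two_sep <- classification$id[classification$label == "2-sep" &
                                 classification$retained]
  act <- tf_table[tf_table$mode == "activator" &
                    tf_table$tf_gene %in% two_sep, , drop = FALSE]
  direct <- unique(act$target_gene)
  remove <- direct
  reg_of <- split(topology$edges$mirna, topology$edges$mrna)
  frontier <- direct
  for (k in seq_len(depth)) {
    mirnas <- unique(unlist(reg_of[intersect(frontier, names(reg_of))]))
    cereg <- unique(topology$edges$mrna[topology$edges$mirna %in% mirnas])
    frontier <- setdiff(cereg, remove)
    remove <- union(remove, cereg)
    if (!length(frontier)) break
  }
  hit <- classification$label == "4-sep" & classification$retained &
    classification$id %in% remove
  if (any(hit)) {
    classification$retained[hit] <- FALSE
    classification$reason[hit] <- "tf-confound"
    message("tf_confound_filter removed ", sum(hit),
            " gene(s) from the 4-sep group")
  }
  classification
}
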