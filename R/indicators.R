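# accept a taxa-x-samples matrix, a community data.frame (first column
# taxon names) or a biomon_agg + rank
community_matrix <- function(community, tax_lev = "Taxa") {
  if (inherits(community, "biomon_agg")) {
    return(rank_matrix(community, tax_lev))
  }
  if (is.data.frame(community)) {
    m <- as.matrix(community[, -1, drop = FALSE])
    rownames(m) <- as.character(community[[1]])
    storage.mode(m) <- "double"
    return(m)
  }
  as.matrix(community)
}

indval_stats <- function(m, groups, corrected = TRUE) {
  glev <- sort(unique(groups))
  A <- B <- matrix(0, nrow(m), length(glev),
                   dimnames = list(rownames(m), glev))
  for (gi in seq_along(glev)) {
    in_g <- groups == glev[gi]
    A[, gi] <- if (corrected) rowMeans(m[, in_g, drop = FALSE])
               else rowSums(m[, in_g, drop = FALSE])
    B[, gi] <- rowMeans(m[, in_g, drop = FALSE] > 0)
  }
  tot <- rowSums(A)
  A <- A / ifelse(tot > 0, tot, 1)
  list(A = A, B = B, indval = A * B * 100)
}

#' Indicator-value analysis with permutation test
#'
#' Dufrene-Legendre indicator values: for every taxon and group,
#' specificity \eqn{A} (group mean abundance over the sum of group mean
#' abundances; group-size corrected by default), fidelity \eqn{B}
#' (occurrence fraction within the group) and \eqn{IndVal = A B \cdot 100}.
#' Significance comes from permuting the sample-to-group labels:
#' \eqn{p = (1 + \#\{IndVal^{perm} \ge IndVal\}) / (1 + n_{perm})},
#' computed per (taxon, group).
#'
#' @param community Taxa-by-samples matrix, community data frame (first
#'   column taxon names) or \code{biomon_agg}.
#' @param groups Group label per sample (named or in sample order).
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @param corrected Use the group-size-corrected specificity (mean
#'   abundances); \code{FALSE} uses raw group sums.
#' @param tax_lev Rank, when \code{community} is a \code{biomon_agg}.
#' @return Data frame (class \code{biomon_indval}): taxon, group, A, B,
#'   indval, p.
#' @export
indval <- function(community, groups, n_perm = 999, seed = 1,
                   corrected = TRUE, tax_lev = "Taxa") {
  m <- community_matrix(community, tax_lev)
  if (!is.null(names(groups)) && all(colnames(m) %in% names(groups))) {
    groups <- groups[colnames(m)]
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(m)) {
    stop("one group label per sample required", call. = FALSE)
  }
  if (length(unique(groups)) < 2L) {
    stop("indval needs at least two groups", call. = FALSE)
  }
  obs <- indval_stats(m, groups, corrected)
  ge <- matrix(0L, nrow(obs$indval), ncol(obs$indval))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- indval_stats(m, sample(groups), corrected)
      ge <- ge + (perm$indval >= obs$indval - 1e-12)
    }
  })
  p <- (1 + ge) / (1 + n_perm)
  out <- data.frame(
    taxon = rep(rownames(obs$indval), ncol(obs$indval)),
    group = rep(colnames(obs$indval), each = nrow(obs$indval)),
    A = as.vector(obs$A), B = as.vector(obs$B),
    indval = as.vector(obs$indval), p = as.vector(p),
    row.names = NULL)
  class(out) <- c("biomon_indval", "data.frame")
  out
}

# hierarchical clustering of samples: Bray-Curtis + average linkage
cluster_samples <- function(m) {
  stats::hclust(vegan::vegdist(t(m), method = "bray"), method = "average")
}

resolve_groups <- function(agg, groups = NULL, k = NULL,
                           tax_lev = "Taxa") {
  if (!is.null(groups)) {
    if (!is.null(names(groups))) groups <- groups[agg$samples]
    return(stats::setNames(as.character(groups), agg$samples))
  }
  if (is.null(k)) stop("supply either 'groups' or a cluster count 'k'",
                       call. = FALSE)
  m <- rank_matrix(agg, tax_lev)
  cl <- stats::cutree(cluster_samples(m), k = k)
  stats::setNames(paste0("cluster", cl), agg$samples)
}

#' Sankey data of significant indicator taxa
#'
#' Runs [indval()] at the finer of the two ranks and keeps the taxa whose
#' best-group indicator value is significant at \code{alpha}. The
#' structure links each upper-rank taxon to its significant finer-rank
#' taxa (weight: the finer taxon's share of the upper taxon's total
#' abundance) and each finer taxon to its indicator group (weight: the
#' share of the taxon's abundance falling in that group). Groups are
#' either given per sample or derived from hierarchical clustering
#' (Bray-Curtis dissimilarity, average linkage, \code{k} clusters).
#'
#' @param agg A \code{biomon_agg}.
#' @param groups Group label per sample, or \code{NULL} to cluster.
#' @param k Number of clusters when \code{groups} is \code{NULL}.
#' @param ranks Length-2 character: upper and finer rank.
#' @param alpha Significance level filtering taxa.
#' @param n_perm,seed Permutation settings passed to [indval()].
#' @return List (class \code{biomon_sankey}) with \code{nodes} (data frame
#'   name, role) and \code{links} (source, target, weight), plus the
#'   \code{indval} table.
#' @export
plot_indicator_taxa_data <- function(agg, groups = NULL, k = NULL,
                                     ranks = c("Order", "Family"),
                                     alpha = 0.05, n_perm = 199,
                                     seed = 1) {
  stopifnot(length(ranks) == 2)
  groups <- resolve_groups(agg, groups, k, tax_lev = ranks[2])
  m <- rank_matrix(agg, ranks[2])
  iv <- indval(m, groups, n_perm = n_perm, seed = seed)
  # best group per taxon, then significance filter
  best <- do.call(rbind, lapply(split(iv, iv$taxon), function(d) {
    d[which.max(d$indval), , drop = FALSE]
  }))
  sig <- best[best$p <= alpha & best$indval > 0, , drop = FALSE]
  ref <- agg$reference
  upper_of <- vapply(sig$taxon, function(nm) {
    i <- which(norm_name(ref[[ranks[2]]]) == norm_name(nm))[1]
    if (is.na(i)) "" else ref[[ranks[1]]][i]
  }, "")
  keep <- upper_of != ""
  sig <- sig[keep, , drop = FALSE]
  upper_of <- upper_of[keep]
  links <- list()
  for (i in seq_len(nrow(sig))) {
    tx <- sig$taxon[i]; up <- upper_of[i]; g <- sig$group[i]
    tx_tot <- sum(m[tx, ])
    up_tot <- sum(m[norm_name(upper_of) == norm_name(up), , drop = FALSE])
    links[[length(links) + 1L]] <- data.frame(
      source = up, target = tx,
      weight = if (up_tot > 0) tx_tot / up_tot else 0)
    links[[length(links) + 1L]] <- data.frame(
      source = tx, target = g,
      weight = if (tx_tot > 0) sum(m[tx, groups == g]) / tx_tot else 0)
  }
  links <- if (length(links)) do.call(rbind, links) else
    data.frame(source = character(0), target = character(0),
               weight = numeric(0))
  nodes <- rbind(
    data.frame(name = unique(upper_of), role = rep(ranks[1],
                                                   length(unique(upper_of)))),
    data.frame(name = unique(sig$taxon), role = rep(ranks[2],
                                                    nrow(sig))),
    data.frame(name = unique(groups), role = rep("group",
                                                 length(unique(groups)))))
  nodes <- nodes[!duplicated(nodes$name), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, links = links, indval = iv,
                 groups = groups, ranks = ranks, alpha = alpha),
            class = "biomon_sankey")
}

#' Prevalence of a rank within an upper rank
#'
#' Counts, over the whole dataset, how many \code{rank}-level taxa fall
#' under each \code{upper_rank} taxon, with shares summing to one.
#'
#' @param agg A \code{biomon_agg}.
#' @param rank Counted rank (e.g. Family).
#' @param upper_rank Grouping rank (e.g. Order).
#' @return Data frame: upper, count, share.
#' @export
prevalence_data <- function(agg, rank = "Family", upper_rank = "Order") {
  ranks <- attr(agg$reference, "ranks")
  if (rank_index(upper_rank, ranks) >= rank_index(rank, ranks)) {
    stop("upper_rank must be coarser than rank", call. = FALSE)
  }
  m <- rank_matrix(agg, rank)
  taxa <- rownames(m)[rowSums(m) > 0]
  if (!length(taxa)) {
    return(data.frame(upper = character(0), count = integer(0),
                      share = numeric(0)))
  }
  ref <- agg$reference
  upper <- vapply(taxa, function(nm) {
    i <- which(norm_name(ref[[rank]]) == norm_name(nm))[1]
    if (is.na(i)) "" else ref[[upper_rank]][i]
  }, "")
  tab <- table(upper[upper != ""])
  data.frame(upper = names(tab), count = as.integer(tab),
             share = as.numeric(tab) / sum(tab), row.names = NULL)
}

#' Cluster-ordered community composition
#'
#' Per-sample taxon proportions at a rank, with the samples ordered by the
#' leaf order of a hierarchical clustering (Bray-Curtis, average linkage),
#' ready for a stacked composition barplot.
#'
#' @param agg A \code{biomon_agg}.
#' @param tax_lev Rank of the composition.
#' @return List: \code{proportions} (taxa x samples, columns in leaf
#'   order), \code{sample_order}.
#' @export
composition_barplot_data <- function(agg, tax_lev = "Taxa") {
  m <- rank_matrix(agg, tax_lev)
  tot <- colSums(m)
  props <- sweep(m, 2, ifelse(tot > 0, tot, 1), "/")
  ord <- if (ncol(m) > 1) {
    hc <- cluster_samples(m)
    colnames(m)[hc$order]
  } else colnames(m)
  list(proportions = props[, ord, drop = FALSE], sample_order = ord)
}
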