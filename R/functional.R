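#' Gower dissimilarity between fuzzy-coded trait profiles
#'
#' Each trait block contributes one component: affinities are first
#' normalised within the block (row block-sum 1), then the component is the
#' range-scaled mean absolute difference of the normalised affinities over
#' the block's modalities. The overall dissimilarity is the mean over the
#' blocks for which both rows carry information (block sum > 0); a row with
#' no information in any block is an error. The result need not be
#' Euclidean - that is what the PCoA corrections are for.
#'
#' @param traits A \code{biomon_traits}.
#' @return Symmetric dissimilarity matrix with taxon labels and a
#'   \code{metric} attribute.
#' @export
gower_distance <- function(traits) {
  stopifnot(inherits(traits, "biomon_traits"))
  blocks <- attr(traits, "blocks")
  prof <- trait_profile_matrix(traits)
  n <- nrow(prof)
  if (anyDuplicated(rownames(prof))) stop("duplicate taxon in trait table",
                                          call. = FALSE)
  has_block <- sapply(blocks, function(b) {
    rowSums(prof[, b, drop = FALSE]) > 0
  })
  if (is.null(dim(has_block))) has_block <- matrix(has_block, nrow = n)
  empty <- rowSums(has_block) == 0
  if (any(empty)) {
    stop("taxon with no trait information: ",
         paste(rownames(prof)[empty], collapse = ", "), call. = FALSE)
  }
  comp <- array(NA_real_, c(n, n, length(blocks)))
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    a <- prof[, b, drop = FALSE]
    s <- rowSums(a)
    a[s > 0, ] <- a[s > 0, , drop = FALSE] / s[s > 0]
    rng <- apply(a, 2, function(col) diff(range(col)))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (!has_block[i, bi] || !has_block[j, bi]) next
        dif <- abs(a[i, ] - a[j, ])
        sc <- ifelse(rng > 0, dif / rng, 0)
        comp[i, j, bi] <- mean(sc)
      }
    }
  }
  d <- apply(comp, c(1, 2), function(v) mean(v, na.rm = TRUE))
  dimnames(d) <- list(rownames(prof), rownames(prof))
  diag(d) <- 0
  structure(d, metric = "gower")
}

check_dist <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12 ||
      any(abs(diag(d)) > 1e-12) || any(d < 0)) {
    stop("distance matrix must be symmetric, non-negative, zero-diagonal",
         call. = FALSE)
  }
  d
}

gower_center <- function(d2) {
  n <- nrow(d2)
  C <- diag(n) - matrix(1 / n, n, n)
  -0.5 * C %*% d2 %*% C
}

#' Principal coordinates analysis with Euclideanarity corrections
#'
#' Embeds a distance matrix into Euclidean axes by eigendecomposition of
#' the double-centred squared-distance matrix. Non-Euclidean input (e.g.
#' Gower dissimilarities on fuzzy traits) yields negative eigenvalues;
#' four corrections are available: \code{sqrt} (element-wise square root),
#' \code{lingoes} (\eqn{d' = \sqrt{d^2 + 2 c_2}} off-diagonal with the
#' minimal constant \eqn{c_2}), \code{cailliez} (\eqn{d' = d + c_1}
#' off-diagonal with the minimal \eqn{c_1}) and \code{quasi} (drop
#' negative-eigenvalue axes).
#'
#' @param d Symmetric distance matrix (labelled).
#' @param correction \code{"none"}, \code{"cailliez"}, \code{"lingoes"},
#'   \code{"sqrt"} or \code{"quasi"}.
#' @return A \code{biomon_space}: list with \code{coordinates} (taxa x
#'   axes, descending eigenvalue order, positive axes only),
#'   \code{eigenvalues} (all, of the corrected matrix), \code{correction},
#'   \code{constant} (Cailliez/Lingoes constant, 0 otherwise),
#'   \code{dist} (the corrected distances) and \code{labels}.
#' @export
pcoa <- function(d, correction = c("none", "cailliez", "lingoes",
                                   "sqrt", "quasi")) {
  correction <- match.arg(correction)
  d <- check_dist(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  constant <- 0
  dc <- d
  if (correction == "sqrt") {
    dc <- sqrt(d)
  } else if (correction == "lingoes") {
    ev <- eigen(gower_center(d^2), symmetric = TRUE, only.values = TRUE)
    constant <- max(0, -min(ev$values))
    if (constant > 0) {
      dc <- sqrt(d^2 + 2 * constant)
      diag(dc) <- 0
    }
  } else if (correction == "cailliez") {
    d1 <- gower_center(d^2)
    d2 <- gower_center(d)
    big <- rbind(cbind(matrix(0, n, n), 2 * d1),
                 cbind(-diag(n), -4 * d2))
    constant <- max(0, max(Re(eigen(big, only.values = TRUE)$values)))
    if (constant > 0) {
      dc <- d + constant
      diag(dc) <- 0
    }
  }
  B <- gower_center(dc^2)
  e <- eigen(B, symmetric = TRUE)
  vals <- e$values
  tol <- max(abs(vals)) * 1e-9
  pos <- which(vals > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(vals[pos]), length(pos))
  rownames(coords) <- labels
  colnames(coords) <- paste0("A", seq_along(pos))
  structure(list(coordinates = coords, eigenvalues = vals,
                 correction = correction, constant = constant,
                 dist = dc, labels = labels),
            class = "biomon_space")
}

#' @export
print.biomon_space <- function(x, ...) {
  cat(sprintf(
    "trait space: %d taxa, %d positive axes, correction %s (constant %.4g)\n",
    length(x$labels), ncol(x$coordinates), x$correction, x$constant))
  invisible(x)
}

#' Trait-space quality over the number of retained axes
#'
#' For every dimensionality m up to the number of positive axes, computes
#' three quality criteria of the reduced space: the Pearson correlation
#' between the m-axis Euclidean distances and the (corrected) input
#' distances; the cumulative relative eigenvalue r-squared; and the mean
#' squared deviation (mSD) between max-scaled reduced and input distances.
#' The recommended m is the argmin of mSD, or the smallest m reaching
#' \code{threshold} for the correlation / r-squared criteria.
#'
#' @param d Distance matrix.
#' @param correction Passed to [pcoa()].
#' @param criterion Criterion used to recommend m.
#' @param threshold Quality threshold for \code{corr}/\code{r2}.
#' @param m_max Largest dimensionality examined (default all positive
#'   axes).
#' @return Data frame (m, corr, r2, msd) with attributes
#'   \code{recommended}, \code{criterion}, \code{correction},
#'   \code{constant}.
#' @export
select_pcoa_axes <- function(d, correction = "none",
                             criterion = c("msd", "corr", "r2"),
                             threshold = 0.95, m_max = NULL) {
  criterion <- match.arg(criterion)
  space <- pcoa(d, correction)
  co <- space$coordinates
  if (is.null(m_max)) m_max <- ncol(co)
  m_max <- min(m_max, ncol(co))
  dc <- space$dist
  lower <- lower.tri(dc)
  dv <- dc[lower]
  pos <- space$eigenvalues[space$eigenvalues > 0]
  out <- data.frame(m = seq_len(m_max), corr = NA_real_, r2 = NA_real_,
                    msd = NA_real_)
  for (m in seq_len(m_max)) {
    dm <- as.matrix(stats::dist(co[, seq_len(m), drop = FALSE]))
    dmv <- dm[lower]
    out$corr[m] <- if (stats::sd(dmv) > 0 && stats::sd(dv) > 0) {
      stats::cor(dmv, dv)
    } else NA_real_
    out$r2[m] <- sum(pos[seq_len(m)]) / sum(pos)
    s1 <- if (max(dmv) > 0) dmv / max(dmv) else dmv
    s2 <- if (max(dv) > 0) dv / max(dv) else dv
    out$msd[m] <- mean((s1 - s2)^2)
  }
  rec <- switch(criterion,
                msd = out$m[which.min(out$msd)],
                corr = {
                  hit <- which(out$corr >= threshold)
                  if (length(hit)) min(hit) else m_max
                },
                r2 = {
                  hit <- which(out$r2 >= threshold)
                  if (length(hit)) min(hit) else m_max
                })
  structure(out, recommended = rec, criterion = criterion,
            correction = space$correction, constant = space$constant)
}

# ---- convex hull volume -------------------------------------------------

# exact 2-D convex hull area: grDevices::chull + shoelace
hull_area_2d <- function(p) {
  p <- unique(p)
  if (nrow(p) < 3) return(0)
  h <- grDevices::chull(p[, 1], p[, 2])
  x <- p[h, 1]; y <- p[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# m >= 3: qhull via the system python (scipy.spatial.ConvexHull)
hull_volume_qhull <- function(p) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") stop("convex hulls in >2 dimensions need a python with ",
                     "scipy on the PATH", call. = FALSE)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.table(p, f, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  code <- paste0(
    "import sys,numpy\n",
    "from scipy.spatial import ConvexHull\n",
    "p=numpy.loadtxt(sys.argv[1],delimiter=',',ndmin=2)\n",
    "try:\n    print(repr(ConvexHull(p).volume))\n",
    "except Exception:\n    print('degenerate')\n")
  res <- suppressWarnings(system2(py, c("-c", shQuote(code), shQuote(f)),
                                  stdout = TRUE, stderr = FALSE))
  if (!length(res) || identical(res[1], "degenerate")) return(0)
  as.numeric(res[1])
}

hull_volume <- function(p) {
  m <- ncol(p)
  if (nrow(unique(p)) <= m) return(0)
  if (m == 1) return(diff(range(p)))
  if (m == 2) return(hull_area_2d(p))
  hull_volume_qhull(p)
}

# present taxa + relative abundances of a sample within a trait space
space_sample <- function(space, m_abund, j) {
  present <- rownames(m_abund)[m_abund[, j] > 0]
  present <- intersect(present, space$labels)
  p <- m_abund[present, j]
  list(taxa = present, p = p / sum(p))
}

check_space_community <- function(space, agg, tax_lev) {
  m <- rank_matrix(agg, tax_lev)
  missing <- setdiff(rownames(m)[rowSums(m) > 0], space$labels)
  if (length(missing)) {
    warning("taxa absent from the trait space are ignored: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  m
}

#' @name functional-indices
#' @title Functional diversity indices in a trait space
#'
#' @description Per-sample functional indices. \code{f_rich} is the convex
#' hull volume of the present taxa in the first \code{m} axes (needs more
#' than m taxa; degenerate configurations are flagged \code{NaN});
#' \code{f_disp} the abundance-weighted mean distance to the
#' abundance-weighted centroid; \code{f_eve} the minimum-spanning-tree
#' evenness of Villeger (needs \eqn{S \ge 3}); \code{f_divs} Rao's
#' quadratic entropy \eqn{Q = \sum_i \sum_j p_i p_j d_{ij}} on a distance
#' matrix; \code{f_red} the functional redundancy, Gini-Simpson diversity
#' minus Q with distances scaled to [0, 1].
#'
#' @param space A \code{biomon_space} from [pcoa()].
#' @param d Distance matrix (for \code{f_divs}/\code{f_red}).
#' @param agg A \code{biomon_agg}.
#' @param tax_lev Rank whose taxa match the space/distance labels.
#' @param m Number of trait-space axes used.
#' @param max_m Guard: refuse hulls above this dimensionality.
#' @return A \code{biomon_result} per sample.
NULL

#' @rdname functional-indices
#' @export
f_rich <- function(space, agg, tax_lev = "Taxa", m = 2, max_m = 6) {
  if (m > max_m) stop("f_rich: m > ", max_m,
                      " refused (raise max_m to override)", call. = FALSE)
  if (m > ncol(space$coordinates)) {
    stop("trait space has only ", ncol(space$coordinates), " axes",
         call. = FALSE)
  }
  ma <- check_space_community(space, agg, tax_lev)
  vals <- numeric(length(agg$samples)); flags <- character(length(vals))
  for (j in seq_along(agg$samples)) {
    ss <- space_sample(space, ma, j)
    if (length(ss$taxa) <= m) {
      vals[j] <- NaN; flags[j] <- "S <= m"
      next
    }
    co <- space$coordinates[ss$taxa, seq_len(m), drop = FALSE]
    v <- hull_volume(co)
    # PCoA coordinates carry ~1e-9 reconstruction noise, so a degenerate
    # (e.g. collinear) configuration can yield a tiny spurious volume
    tol <- max(apply(co, 2, function(x) diff(range(x))))^m * 1e-8
    if (v <= tol) {
      vals[j] <- NaN; flags[j] <- "degenerate hull"
    } else vals[j] <- v
  }
  biomon_result(stats::setNames(vals, agg$samples), "f_rich", tax_lev,
                flags)
}

#' @rdname functional-indices
#' @export
f_disp <- function(space, agg, tax_lev = "Taxa",
                   m = ncol(space$coordinates)) {
  ma <- check_space_community(space, agg, tax_lev)
  vals <- numeric(length(agg$samples)); flags <- character(length(vals))
  for (j in seq_along(agg$samples)) {
    ss <- space_sample(space, ma, j)
    if (!length(ss$taxa)) {
      vals[j] <- NaN; flags[j] <- "empty sample"
      next
    }
    co <- space$coordinates[ss$taxa, seq_len(m), drop = FALSE]
    centroid <- colSums(co * ss$p)
    vals[j] <- sum(ss$p * sqrt(rowSums(sweep(co, 2, centroid)^2)))
  }
  biomon_result(stats::setNames(vals, agg$samples), "f_disp", tax_lev,
                flags)
}

# Prim's minimum spanning tree on a distance matrix; returns edge list
mst_edges <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  edges <- matrix(0L, n - 1, 2)
  for (k in seq_len(n - 1)) {
    dd <- d[in_tree, !in_tree, drop = FALSE]
    ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    i <- which(in_tree)[ij[1]]
    j <- which(!in_tree)[ij[2]]
    edges[k, ] <- c(i, j)
    in_tree[j] <- TRUE
  }
  edges
}

#' @rdname functional-indices
#' @export
f_eve <- function(space, agg, tax_lev = "Taxa",
                  m = ncol(space$coordinates)) {
  ma <- check_space_community(space, agg, tax_lev)
  vals <- numeric(length(agg$samples)); flags <- character(length(vals))
  for (j in seq_along(agg$samples)) {
    ss <- space_sample(space, ma, j)
    S <- length(ss$taxa)
    if (S < 3) {
      vals[j] <- NaN; flags[j] <- "S < 3"
      next
    }
    co <- space$coordinates[ss$taxa, seq_len(m), drop = FALSE]
    d <- as.matrix(stats::dist(co))
    ed <- mst_edges(d)
    ew <- d[ed] / (ss$p[ed[, 1]] + ss$p[ed[, 2]])
    pew <- ew / sum(ew)
    thr <- 1 / (S - 1)
    vals[j] <- (sum(pmin(pew, thr)) - thr) / (1 - thr)
  }
  biomon_result(stats::setNames(vals, agg$samples), "f_eve", tax_lev,
                flags)
}

#' @rdname functional-indices
#' @export
f_divs <- function(d, agg, tax_lev = "Taxa") {
  d <- check_dist(d)
  ma <- rank_matrix(agg, tax_lev)
  vals <- numeric(length(agg$samples)); flags <- character(length(vals))
  for (j in seq_along(agg$samples)) {
    present <- intersect(rownames(ma)[ma[, j] > 0], rownames(d))
    if (!length(present)) {
      vals[j] <- NaN; flags[j] <- "empty sample"
      next
    }
    p <- ma[present, j]; p <- p / sum(p)
    vals[j] <- drop(p %*% d[present, present, drop = FALSE] %*% p)
  }
  biomon_result(stats::setNames(vals, agg$samples), "f_divs", tax_lev,
                flags)
}

#' @rdname functional-indices
#' @export
f_red <- function(d, agg, tax_lev = "Taxa") {
  d <- check_dist(d)
  if (max(d) > 0) d <- d / max(d)
  q <- f_divs(d, agg, tax_lev)
  gs <- simpson(agg, tax_lev)
  biomon_result(stats::setNames(as.numeric(gs) - as.numeric(q),
                                agg$samples),
                "f_red", tax_lev, attr(q, "flags"))
}

#' Community-weighted mean trait profile
#'
#' Per sample and trait modality, the abundance-weighted mean
#' \eqn{\sum_i p_i t_i} over the taxa covered by the trait table (relative
#' abundances renormalised over covered taxa).
#'
#' @param traits A \code{biomon_traits} with one row per community taxon.
#' @param agg A \code{biomon_agg}.
#' @param tax_lev Rank whose taxa match the trait rows.
#' @return Data frame: sample x modality.
#' @export
cwm <- function(traits, agg, tax_lev = "Taxa") {
  stopifnot(inherits(traits, "biomon_traits"))
  prof <- trait_profile_matrix(traits)
  ma <- rank_matrix(agg, tax_lev)
  common <- intersect(rownames(ma), rownames(prof))
  out <- matrix(NA_real_, length(agg$samples), ncol(prof),
                dimnames = list(agg$samples, colnames(prof)))
  for (j in seq_along(agg$samples)) {
    present <- common[ma[common, j] > 0]
    if (!length(present)) next
    p <- ma[present, j]; p <- p / sum(p)
    out[j, ] <- colSums(prof[present, , drop = FALSE] * p)
  }
  as.data.frame(out)
}

#' Taxon and community trait-specialization indices
#'
#' The taxon specialization index (TSI) of a fuzzy profile is computed per
#' block from the inverse Simpson concentration of the block-normalised
#' affinities: a block with all affinity in one modality scores 1, uniform
#' affinity over its K modalities scores 0 (rescaled as
#' \eqn{(K - 1/\sum a^2)/(K - 1)}); TSI is the mean over informative
#' blocks. The community specialization index (CSI) is the
#' abundance-weighted mean TSI over the taxa present.
#'
#' @inheritParams cwm
#' @return \code{tsi}: named vector per taxon; \code{csi}: a
#'   \code{biomon_result} per sample.
#' @export
tsi <- function(traits) {
  stopifnot(inherits(traits, "biomon_traits"))
  blocks <- attr(traits, "blocks")
  prof <- trait_profile_matrix(traits)
  vapply(seq_len(nrow(prof)), function(i) {
    per_block <- vapply(blocks, function(b) {
      a <- prof[i, b]
      s <- sum(a)
      if (s <= 0) return(NA_real_)
      a <- a / s
      K <- length(b)
      if (K == 1) return(1)
      (K - 1 / sum(a^2)) / (K - 1)
    }, 0)
    mean(per_block, na.rm = TRUE)
  }, 0) -> v
  stats::setNames(v, rownames(prof))
}

#' @rdname tsi
#' @export
csi <- function(traits, agg, tax_lev = "Taxa") {
  t <- tsi(traits)
  ma <- rank_matrix(agg, tax_lev)
  common <- intersect(rownames(ma), names(t))
  vals <- numeric(length(agg$samples)); flags <- character(length(vals))
  for (j in seq_along(agg$samples)) {
    present <- common[ma[common, j] > 0]
    if (!length(present)) {
      vals[j] <- NaN; flags[j] <- "no taxa with traits"
      next
    }
    p <- ma[present, j]; p <- p / sum(p)
    vals[j] <- sum(p * t[present])
  }
  biomon_result(stats::setNames(vals, agg$samples), "csi", tax_lev, flags)
}

#' Ratio of community-weighted fuzzy affinities
#'
#' Per sample, the ratio \eqn{\sum_i p_i a_i(num) / \sum_i p_i a_i(den)}
#' of block-normalised affinities summed over numerator and denominator
#' modality sets. With the numerator a stressor-specific modality subset
#' and the denominator its full block this yields trait-based pressure
#' indices; \code{flow_t} is the flow-intermittency instance.
#'
#' @inheritParams cwm
#' @param numerator,denominator Modality column names.
#' @param block For \code{flow_t}: name of the flow-affinity block;
#'   \code{numerator} defaults to its first modality.
#' @return A \code{biomon_result} per sample.
#' @export
fuzzy_trait_ratio <- function(traits, agg, numerator, denominator,
                              tax_lev = "Taxa") {
  stopifnot(inherits(traits, "biomon_traits"))
  blocks <- attr(traits, "blocks")
  mods <- trait_modalities(traits)
  bad <- setdiff(c(numerator, denominator), mods)
  if (length(bad)) stop("unknown modalities: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  prof <- trait_profile_matrix(traits)
  aprof <- normalise_blocks(prof, blocks)
  ma <- rank_matrix(agg, tax_lev)
  common <- intersect(rownames(ma), rownames(aprof))
  vals <- numeric(length(agg$samples)); flags <- character(length(vals))
  for (j in seq_along(agg$samples)) {
    present <- common[ma[common, j] > 0]
    if (!length(present)) {
      vals[j] <- NaN; flags[j] <- "no taxa with traits"
      next
    }
    p <- ma[present, j]; p <- p / sum(p)
    num <- sum(p * rowSums(aprof[present, numerator, drop = FALSE]))
    den <- sum(p * rowSums(aprof[present, denominator, drop = FALSE]))
    if (den <= 0) {
      vals[j] <- NaN; flags[j] <- "zero denominator"
    } else vals[j] <- num / den
  }
  biomon_result(stats::setNames(vals, agg$samples), "fuzzy_trait_ratio",
                tax_lev, flags)
}

#' @rdname fuzzy_trait_ratio
#' @export
flow_t <- function(traits, agg, block, numerator = NULL,
                   tax_lev = "Taxa") {
  blocks <- attr(traits, "blocks")
  if (!block %in% names(blocks)) stop("unknown trait block '", block, "'",
                                      call. = FALSE)
  if (is.null(numerator)) numerator <- blocks[[block]][1]
  res <- fuzzy_trait_ratio(traits, agg, numerator, blocks[[block]],
                           tax_lev)
  attr(res, "index") <- "flow_t"
  res
}
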