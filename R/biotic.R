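#' @name biotic-indices
#' @title Sensitivity-score biotic indices
#'
#' @description Biomonitoring indices based on taxon-specific sensitivity
#' scores, with pluggable score tables ([score_table()]), abundance-class
#' weighting ([class_rule()]), composite-family aggregation and full
#' traceability. All return a \code{biomon_result} (one value per sample);
#' with \code{trace_b = TRUE} the result carries a \code{trace} attribute
#' recording, per sample, the taxa used with their assigned scores/classes,
#' the taxa excluded with the reason, and composite substitutions. The
#' reported value is always exactly recomputable from the trace
#' ([recompute_from_trace()]).
#'
#' Taxa present at the index's rank but missing from the score table are
#' excluded (and traced), never interpolated. Input taxa resolved finer
#' than the score rank are scored via their ancestor at that rank (this is
#' what rank aggregation does); taxa resolved coarser never reach the rank
#' table.
#'
#' @param agg A \code{biomon_agg} from [aggregate_taxa()].
#' @param scores A \code{score_table} of the type the index needs.
#' @param tax_lev Rank at which to compute; must equal the score table's
#'   rank.
#' @param trace_b Attach the per-sample trace.
#' @param composite Apply composite-family rules (scalar-score indices).
#' @return A \code{biomon_result}.
NULL

check_scores <- function(scores, index, types) {
  if (!inherits(scores, "score_table")) {
    stop(index, " needs a score_table; see ?score_table and ?show_scores",
         call. = FALSE)
  }
  if (!scores$type %in% types) {
    stop(index, " needs a score table of type ",
         paste(types, collapse = "/"), ", got '", scores$type, "'",
         call. = FALSE)
  }
  scores
}

# shared scoring skeleton: per sample, split present taxa into used /
# excluded, apply composite substitution, delegate per-taxon scoring to
# `score_fun(taxon, abundance)` (returns one-row df or NULL for unscored)
# and `combine(used_df)` for the sample value.
biotic_engine <- function(agg, scores, tax_lev, trace_b, composite,
                          index, score_fun, combine) {
  if (is.null(tax_lev)) tax_lev <- scores$rank
  if (!identical(tax_lev, scores$rank)) {
    stop(index, ": score table is at rank '", scores$rank,
         "', incompatible with tax_lev '", tax_lev, "'", call. = FALSE)
  }
  m <- rank_matrix(agg, tax_lev)
  ent <- scores$entries
  key <- norm_name(ent$taxon)
  vals <- numeric(length(agg$samples))
  flags <- character(length(agg$samples))
  traces <- list()
  comp <- if (isTRUE(composite)) scores$composite else NULL

  for (j in seq_along(agg$samples)) {
    present <- rownames(m)[m[, j] > 0]
    used <- list(); excl <- list(); subs <- list()
    claimed <- character(0)
    if (!is.null(comp)) {
      for (cn in names(comp)) {
        members <- comp[[cn]][norm_name(comp[[cn]]) %in% norm_name(present)]
        if (!length(members)) next
        row <- score_fun(cn, sum(m[members, j]))
        if (is.null(row)) next
        used[[length(used) + 1L]] <- row
        subs[[cn]] <- members
        claimed <- c(claimed, norm_name(members))
        for (mb in members) {
          excl[[length(excl) + 1L]] <- data.frame(
            taxon = mb, reason = paste0("member of composite ", cn))
        }
      }
    }
    for (tx in present) {
      if (norm_name(tx) %in% claimed) next
      row <- score_fun(tx, m[tx, j])
      if (is.null(row)) {
        excl[[length(excl) + 1L]] <- data.frame(taxon = tx,
                                                reason = "no score entry")
      } else {
        used[[length(used) + 1L]] <- row
      }
    }
    used_df <- if (length(used)) do.call(rbind, used) else NULL
    r <- combine(used_df)
    vals[j] <- r$value
    flags[j] <- r$flag
    traces[[agg$samples[j]]] <- list(
      used = if (is.null(used_df)) data.frame(taxon = character(0))
             else used_df,
      excluded = if (length(excl)) do.call(rbind, excl)
                 else data.frame(taxon = character(0),
                                 reason = character(0)),
      composites = subs)
  }
  res <- biomon_result(stats::setNames(vals, agg$samples), index, tax_lev,
                       flags)
  if (trace_b) attr(res, "trace") <- traces
  res
}

scalar_score_fun <- function(scores) {
  ent <- scores$entries
  key <- norm_name(ent$taxon)
  function(taxon, n) {
    i <- match(norm_name(taxon), key)
    if (is.na(i)) return(NULL)
    data.frame(taxon = ent$taxon[i], score = ent$score[i])
  }
}

#' @rdname biotic-indices
#' @details \code{bmwp}: sum of the scalar scores of the present scoring
#'   taxa. With \code{composite = TRUE}, families belonging to one
#'   composite rule are scored once through the composite entry.
#' @export
bmwp <- function(agg, scores, tax_lev = NULL, trace_b = FALSE,
                 composite = FALSE) {
  check_scores(scores, "bmwp", "scalar")
  biotic_engine(agg, scores, tax_lev, trace_b, composite, "bmwp",
                scalar_score_fun(scores),
                function(u) if (is.null(u)) ok(0) else ok(sum(u$score)))
}

#' @rdname biotic-indices
#' @details \code{aspt}: BMWP divided by the number of scoring taxa
#'   (composites count once). \code{dehli} follows the same averaging
#'   contract with drought-sensitivity scores.
#' @export
aspt <- function(agg, scores, tax_lev = NULL, trace_b = FALSE,
                 composite = FALSE) {
  check_scores(scores, "aspt", "scalar")
  biotic_engine(agg, scores, tax_lev, trace_b, composite, "aspt",
                scalar_score_fun(scores),
                function(u) if (is.null(u)) undef("no scoring taxa")
                            else ok(mean(u$score)))
}

#' @rdname biotic-indices
#' @export
dehli <- function(agg, scores, tax_lev = NULL, trace_b = FALSE) {
  check_scores(scores, "dehli", "scalar")
  biotic_engine(agg, scores, tax_lev, trace_b, FALSE, "dehli",
                scalar_score_fun(scores),
                function(u) if (is.null(u)) undef("no scoring taxa")
                            else ok(mean(u$score)))
}

#' @rdname biotic-indices
#' @param metric For \code{whpt}, \code{"aspt"} (mean) or \code{"bmwp"}
#'   (sum); for \code{ept}, \code{"richness"} or \code{"abundance"}.
#' @param occurrence For \code{whpt}, use the presence-only score column
#'   (\code{score_occ}) instead of abundance-class scores.
#' @details \code{whpt}: each present taxon contributes the score of its
#'   abundance class (log-10 classes by default); taxa with a defined class
#'   score count in the denominator even when that score is 0.
#' @export
whpt <- function(agg, scores, metric = c("aspt", "bmwp"), tax_lev = NULL,
                 trace_b = FALSE, occurrence = FALSE) {
  metric <- match.arg(metric)
  check_scores(scores, "whpt", "class")
  ent <- scores$entries
  key <- norm_name(ent$taxon)
  if (occurrence && !"score_occ" %in% names(ent)) {
    stop("whpt occurrence mode needs a 'score_occ' column", call. = FALSE)
  }
  sf <- function(taxon, n) {
    i <- match(norm_name(taxon), key)
    if (is.na(i)) return(NULL)
    cl <- abundance_class(n, scores$rule)
    sc <- if (occurrence) ent$score_occ[i]
          else ent[[paste0("score_class", cl)]][i]
    data.frame(taxon = ent$taxon[i], class = cl, score = sc)
  }
  biotic_engine(agg, scores, tax_lev, trace_b, FALSE,
                paste0("whpt_", metric), sf,
                function(u) {
                  if (is.null(u)) return(
                    if (metric == "bmwp") ok(0) else undef("no scoring taxa"))
                  ok(if (metric == "bmwp") sum(u$score) else mean(u$score))
                })
}

#' @rdname biotic-indices
#' @details \code{life}: mean over present scored taxa of the flow score
#'   looked up by (flow group, abundance class) in the table's
#'   group-by-class score matrix.
#' @export
life <- function(agg, scores, tax_lev = NULL, trace_b = FALSE) {
  check_scores(scores, "life", "flow")
  ent <- scores$entries
  key <- norm_name(ent$taxon)
  sf <- function(taxon, n) {
    i <- match(norm_name(taxon), key)
    if (is.na(i)) return(NULL)
    cl <- abundance_class(n, scores$rule)
    g <- as.character(ent$group[i])
    data.frame(taxon = ent$taxon[i], group = g, class = cl,
               score = scores$score_matrix[g, cl])
  }
  biotic_engine(agg, scores, tax_lev, trace_b, FALSE, "life", sf,
                function(u) if (is.null(u)) undef("no scoring taxa")
                            else ok(mean(u$score)))
}

#' @rdname biotic-indices
#' @details \code{psi}: 100 times the abundance-class weight carried by
#'   sediment-sensitive groups (default groups A and B of A-D) over the
#'   weight of all scored groups. \code{epsi} is the empirically weighted
#'   variant: per-taxon scalar weights with a logical \code{sensitive}
#'   column.
#' @export
psi <- function(agg, scores, tax_lev = NULL, trace_b = FALSE) {
  check_scores(scores, "psi", "psi")
  ent <- scores$entries
  key <- norm_name(ent$taxon)
  sf <- function(taxon, n) {
    i <- match(norm_name(taxon), key)
    if (is.na(i)) return(NULL)
    cl <- abundance_class(n, scores$rule)
    g <- as.character(ent$group[i])
    data.frame(taxon = ent$taxon[i], group = g, class = cl,
               weight = scores$score_matrix[g, cl],
               sensitive = g %in% scores$sensitive)
  }
  biotic_engine(agg, scores, tax_lev, trace_b, FALSE, "psi", sf,
                function(u) {
                  if (is.null(u) || sum(u$weight) <= 0) {
                    return(undef("no scored weight"))
                  }
                  ok(100 * sum(u$weight[u$sensitive]) / sum(u$weight))
                })
}

#' @rdname biotic-indices
#' @export
epsi <- function(agg, scores, tax_lev = NULL, trace_b = FALSE) {
  check_scores(scores, "epsi", "epsi")
  ent <- scores$entries
  key <- norm_name(ent$taxon)
  sf <- function(taxon, n) {
    i <- match(norm_name(taxon), key)
    if (is.na(i)) return(NULL)
    data.frame(taxon = ent$taxon[i], weight = ent$weight[i],
               sensitive = as.logical(ent$sensitive[i]))
  }
  biotic_engine(agg, scores, tax_lev, trace_b, FALSE, "epsi", sf,
                function(u) {
                  if (is.null(u) || sum(u$weight) <= 0) {
                    return(undef("no scored weight"))
                  }
                  ok(100 * sum(u$weight[u$sensitive]) / sum(u$weight))
                })
}

#' @rdname biotic-indices
#' @param orders Parent order names for \code{ept} (default the three EPT
#'   orders).
#' @param count_rank Rank at which EPT taxa are counted/summed.
#' @details \code{ept}: richness (or total abundance) of
#'   Ephemeroptera + Plecoptera + Trichoptera at \code{count_rank}.
#' @export
ept <- function(agg, metric = c("richness", "abundance"),
                orders = c("Ephemeroptera", "Plecoptera", "Trichoptera"),
                count_rank = "Family", trace_b = FALSE) {
  metric <- match.arg(metric)
  m <- rank_matrix(agg, count_rank)
  ref <- agg$reference
  parent_of <- vapply(rownames(m), function(nm) {
    i <- which(norm_name(ref[[count_rank]]) == norm_name(nm))[1]
    if (is.na(i)) "" else ref$Order[i]
  }, "")
  keep <- norm_name(parent_of) %in% norm_name(orders)
  vals <- if (metric == "richness") colSums(m[keep, , drop = FALSE] > 0)
          else colSums(m[keep, , drop = FALSE])
  res <- biomon_result(stats::setNames(as.numeric(vals), agg$samples),
                       paste0("ept_", metric), count_rank)
  if (trace_b) {
    attr(res, "trace") <- lapply(stats::setNames(seq_along(agg$samples),
                                                 agg$samples), function(j) {
      present <- rownames(m)[m[, j] > 0]
      out_tx <- setdiff(present, rownames(m)[keep])
      in_tx <- intersect(present, rownames(m)[keep])
      list(used = data.frame(taxon = in_tx, abundance = m[in_tx, j],
                             row.names = NULL),
           excluded = data.frame(taxon = out_tx,
                                 reason = rep("not an EPT order",
                                              length(out_tx))),
           composites = list())
    })
  }
  res
}

#' @rdname biotic-indices
#' @details \code{eptd}: \eqn{\log_{10}(1 + } summed abundance of a
#'   selected list of EPTD families\eqn{)}. The family list travels in a
#'   \code{score_table} of type \code{"list"}.
#' @export
eptd <- function(agg, scores, tax_lev = NULL, trace_b = FALSE) {
  check_scores(scores, "eptd", "list")
  ent <- scores$entries
  key <- norm_name(ent$taxon)
  sf <- function(taxon, n) {
    i <- match(norm_name(taxon), key)
    if (is.na(i)) return(NULL)
    data.frame(taxon = ent$taxon[i], abundance = n)
  }
  biotic_engine(agg, scores, tax_lev, trace_b, FALSE, "eptd", sf,
                function(u) ok(log10(1 + if (is.null(u)) 0
                                         else sum(u$abundance))))
}

#' @rdname biotic-indices
#' @param gold Named list of rank -> taxon names defining the tolerant
#'   GOLD groups (default Gastropoda and Oligochaeta at Class, Diptera at
#'   Order).
#' @details \code{igold}: one minus the relative abundance of the GOLD
#'   groups (Gastropoda, Oligochaeta, Diptera), computed on the
#'   finest-resolution (\code{Taxa}) table via reference lineages.
#' @export
igold <- function(agg, gold = list(Class = c("Gastropoda", "Oligochaeta"),
                                   Order = "Diptera"),
                  trace_b = FALSE) {
  m <- rank_matrix(agg, "Taxa")
  ref <- agg$reference
  is_gold <- vapply(rownames(m), function(nm) {
    lin <- ref_lineage(ref, nm)
    if (is.null(lin)) return(FALSE)
    any(vapply(names(gold), function(r) {
      norm_name(lin[[r]]) %in% norm_name(gold[[r]])
    }, TRUE))
  }, TRUE)
  vals <- numeric(length(agg$samples))
  flags <- character(length(agg$samples))
  traces <- list()
  for (j in seq_along(agg$samples)) {
    tot <- sum(m[, j])
    if (tot <= 0) {
      vals[j] <- NaN; flags[j] <- "empty sample"
    } else {
      vals[j] <- 1 - sum(m[is_gold, j]) / tot
    }
    present <- m[, j] > 0
    traces[[agg$samples[j]]] <- list(
      used = data.frame(taxon = rownames(m)[present],
                        abundance = m[present, j],
                        gold = is_gold[present], row.names = NULL),
      excluded = data.frame(taxon = character(0), reason = character(0)),
      composites = list())
  }
  res <- biomon_result(stats::setNames(vals, agg$samples), "igold", "Taxa",
                       flags)
  if (trace_b) attr(res, "trace") <- traces
  res
}

#' @rdname biotic-indices
#' @details \code{ibmr}: macrophyte index
#'   \eqn{\sum CS_i E_i K_i / \sum E_i K_i} over present scored taxa, with
#'   sensitivity score \eqn{CS}, stenoecy coefficient \eqn{E} and cover
#'   abundance class \eqn{K}.
#' @export
ibmr <- function(agg, scores, tax_lev = NULL, trace_b = FALSE) {
  check_scores(scores, "ibmr", "ibmr")
  ent <- scores$entries
  key <- norm_name(ent$taxon)
  sf <- function(taxon, n) {
    i <- match(norm_name(taxon), key)
    if (is.na(i)) return(NULL)
    data.frame(taxon = ent$taxon[i], cs = ent$cs[i], e = ent$e[i],
               k = abundance_class(n, scores$rule))
  }
  biotic_engine(agg, scores, tax_lev, trace_b, FALSE, "ibmr", sf,
                function(u) {
                  if (is.null(u) || sum(u$e * u$k) <= 0) {
                    return(undef("no scored cover"))
                  }
                  ok(sum(u$cs * u$e * u$k) / sum(u$e * u$k))
                })
}

#' Biocontamination by alien taxa
#'
#' Per sample: abundance contamination \eqn{ACI} = alien abundance / total
#' abundance; richness contamination \eqn{RCI} = alien richness / total
#' richness; and the ordinal site biocontamination class \eqn{SBCI} derived
#' from the worse of the two. The default class table assigns, to each of
#' ACI and RCI, class \eqn{k} when the value falls in
#' \eqn{[t_k, t_{k+1})} for lower bounds \eqn{t = (0, 0.01, 0.1, 0.2,
#' 0.5)} (class 4 for values \eqn{\ge 0.5}); SBCI is the maximum of the two
#' classes.
#'
#' @param agg A \code{biomon_agg}.
#' @param alien Character vector of alien taxon names (resolvable in the
#'   reference), or a \code{score_table} of type \code{"list"}.
#' @param tax_lev Rank at which to compute.
#' @param class_bounds Ascending lower bounds of classes 1..k.
#' @param trace_b Attach trace.
#' @return Data frame (class \code{biomon_bioco}): sample, aci, rci, sbci.
#' @export
bioco <- function(agg, alien, tax_lev = "Taxa",
                  class_bounds = c(0.01, 0.1, 0.2, 0.5), trace_b = FALSE) {
  if (inherits(alien, "score_table")) alien <- alien$entries$taxon
  m <- rank_matrix(agg, tax_lev)
  is_alien <- norm_name(rownames(m)) %in% norm_name(alien)
  cls <- function(v) findInterval(v, class_bounds)
  out <- data.frame(sample = agg$samples, aci = NA_real_, rci = NA_real_,
                    sbci = NA_integer_)
  traces <- list()
  for (j in seq_along(agg$samples)) {
    present <- m[, j] > 0
    tot_n <- sum(m[, j]); tot_s <- sum(present)
    if (tot_s == 0) {
      traces[[agg$samples[j]]] <- list(
        used = data.frame(taxon = character(0)),
        excluded = data.frame(taxon = character(0), reason = character(0)),
        composites = list())
      next
    }
    aci <- sum(m[is_alien, j]) / tot_n
    rci <- sum(present & is_alien) / tot_s
    out$aci[j] <- aci
    out$rci[j] <- rci
    out$sbci[j] <- max(cls(aci), cls(rci))
    traces[[agg$samples[j]]] <- list(
      used = data.frame(taxon = rownames(m)[present],
                        abundance = m[present, j],
                        alien = is_alien[present], row.names = NULL),
      excluded = data.frame(taxon = character(0), reason = character(0)),
      composites = list())
  }
  attr(out, "class_bounds") <- class_bounds
  if (trace_b) attr(out, "trace") <- traces
  class(out) <- c("biomon_bioco", "data.frame")
  out
}

#' Recompute an index value from its trace
#'
#' Every biotic index with \code{trace_b = TRUE} records, per sample, the
#' taxa used with their scores/classes/weights. This function re-derives
#' the per-sample values from the trace alone; it must reproduce the
#' reported values exactly, which is the package's trace-completeness
#' contract.
#'
#' @param result A \code{biomon_result} carrying a \code{trace} attribute.
#' @return Named numeric vector of recomputed per-sample values.
#' @export
recompute_from_trace <- function(result) {
  tr <- attr(result, "trace")
  if (is.null(tr)) stop("result carries no trace; rerun with trace_b = TRUE",
                        call. = FALSE)
  index <- attr(result, "index")
  vapply(tr, function(t) {
    u <- t$used
    n <- nrow(u)
    switch(sub("_(aspt|bmwp|richness|abundance)$", "", index),
      bmwp = if (index == "bmwp") { if (n) sum(u$score) else 0 }
             else NA_real_,
      whpt = if (n == 0) { if (index == "whpt_bmwp") 0 else NaN }
             else if (index == "whpt_bmwp") sum(u$score) else mean(u$score),
      aspt = if (n) mean(u$score) else NaN,
      dehli = if (n) mean(u$score) else NaN,
      life = if (n) mean(u$score) else NaN,
      psi = if (n && sum(u$weight) > 0)
              100 * sum(u$weight[u$sensitive]) / sum(u$weight) else NaN,
      epsi = if (n && sum(u$weight) > 0)
               100 * sum(u$weight[u$sensitive]) / sum(u$weight) else NaN,
      eptd = log10(1 + if (n) sum(u$abundance) else 0),
      igold = if (n) 1 - sum(u$abundance[u$gold]) / sum(u$abundance)
              else NaN,
      ibmr = if (n && sum(u$e * u$k) > 0)
               sum(u$cs * u$e * u$k) / sum(u$e * u$k) else NaN,
      ept = if (index == "ept_richness") n
            else if (n) sum(u$abundance) else 0,
      stop("no trace recomputation rule for index '", index, "'",
           call. = FALSE))
  }, 0)
}
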