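#' Match a community table against a taxonomic reference dataset
#'
#' The entry point of the workflow. Taxon names in the community table are
#' matched (case-insensitively, after whitespace trimming) against the
#' \code{Taxa} column of the reference dataset. Matched taxa are joined to
#' their full lineage; unmatched taxa are excluded from the joined table but
#' reported, together with ranked misspelling suggestions within
#' \code{suggestion_cutoff} optimal-string-alignment (Damerau-Levenshtein)
#' distance. Fuzzy matches are never applied silently: with
#' \code{correct_names = TRUE} the best suggestion is applied only after
#' interactive confirmation, or unconditionally with \code{force = TRUE}.
#'
#' @param community Data frame: first column taxon names, remaining columns
#'   numeric per-sample abundances (or 0/1 occurrences).
#' @param ref Reference dataset ([as_reference()]).
#' @param correct_names Apply accepted suggestions before joining.
#' @param suggestion_cutoff Maximum edit distance for suggestions.
#' @param force With \code{correct_names}, apply best suggestions without
#'   interactive confirmation.
#' @return A \code{biomon_tagged} object: list with \code{data} (lineage
#'   columns + sample columns), \code{match_report}, \code{reference},
#'   \code{samples}.
#' @export
#' @examples
#' ref <- generate_reference(seed = 1)
#' com <- generate_community(ref, n_samples = 3, seed = 1)
#' tagged <- as_biomonitor(com, ref)
#' tagged$match_report$unmatched
as_biomonitor <- function(community, ref, correct_names = FALSE,
                          suggestion_cutoff = 2, force = FALSE) {
  if (!inherits(ref, "biomon_ref")) ref <- as_reference(ref)
  community <- as.data.frame(community, stringsAsFactors = FALSE)
  if (ncol(community) < 2L) {
    stop("community table needs a taxon column plus at least one sample",
         call. = FALSE)
  }
  taxa_in <- trimws(as.character(community[[1]]))
  if (anyDuplicated(norm_name(taxa_in))) {
    stop("duplicate taxon names in community table: ",
         paste(unique(taxa_in[duplicated(norm_name(taxa_in))]),
               collapse = ", "), call. = FALSE)
  }
  samples <- names(community)[-1]
  abund <- community[, -1, drop = FALSE]
  for (s in samples) {
    abund[[s]] <- as.numeric(abund[[s]])
    if (anyNA(abund[[s]]) || any(abund[[s]] < 0)) {
      stop("abundances must be non-negative numbers (sample '", s, "')",
           call. = FALSE)
    }
  }

  ref_keys <- norm_name(ref$Taxa)
  idx <- match(norm_name(taxa_in), ref_keys)
  unmatched <- taxa_in[is.na(idx)]
  suggestions <- lapply(unmatched, function(nm) {
    d <- vapply(ref$Taxa, function(cand) dl_distance(norm_name(nm),
                                                     norm_name(cand)), 0L)
    keep <- which(d <= suggestion_cutoff)
    if (!length(keep)) {
      return(data.frame(candidate = character(0), distance = integer(0)))
    }
    cand <- ref$Taxa[keep]; dist <- d[keep]
    o <- order(dist, cand)
    data.frame(candidate = cand[o], distance = as.integer(dist[o]),
               row.names = NULL)
  })
  names(suggestions) <- unmatched

  corrected <- character(0)
  if (correct_names && length(unmatched)) {
    for (nm in unmatched) {
      sug <- suggestions[[nm]]
      if (!nrow(sug)) next
      best <- sug$candidate[1]
      ok <- force
      if (!ok && interactive()) {
        ans <- readline(sprintf("replace '%s' with '%s'? [y/N] ", nm, best))
        ok <- tolower(substr(ans, 1, 1)) == "y"
      }
      if (ok) {
        taxa_in[norm_name(taxa_in) == norm_name(nm)] <- best
        corrected[nm] <- best
      }
    }
    idx <- match(norm_name(taxa_in), ref_keys)
    unmatched <- setdiff(taxa_in, taxa_in[!is.na(idx)])
  }

  matched_i <- which(!is.na(idx))
  matched <- stats::setNames(ref$Taxa[idx[matched_i]], taxa_in[matched_i])
  if (!length(matched_i)) {
    warning("no community taxon matched the reference dataset",
            call. = FALSE)
  }

  lranks <- lineage_ranks(attr(ref, "ranks"))
  lineage <- ref[idx[matched_i], c(lranks, "Taxa"), drop = FALSE]
  data <- cbind(lineage, abund[matched_i, , drop = FALSE])
  rownames(data) <- NULL

  structure(list(
    data = data,
    match_report = list(matched = as.list(matched),
                        unmatched = unmatched,
                        suggestions = suggestions[unmatched],
                        corrected = as.list(corrected)),
    reference = ref,
    samples = samples
  ), class = "biomon_tagged")
}

#' @export
print.biomon_tagged <- function(x, ...) {
  cat("biomon tagged community:", nrow(x$data), "matched taxa,",
      length(x$match_report$unmatched), "unmatched,",
      length(x$samples), "samples\n")
  invisible(x)
}

#' Aggregate a tagged community at every taxonomic rank
#'
#' For every rank with at least one non-empty lineage value, abundances are
#' summed over all input taxa sharing that rank value. Taxa whose lineage is
#' empty at a rank are omitted from that rank's table (never pooled into an
#' "unidentified" pseudo-taxon). The mixed original-resolution table is kept
#' under \code{"Taxa"}.
#'
#' @param tagged A \code{biomon_tagged} object from [as_biomonitor()].
#' @return A \code{biomon_agg} object: list with \code{per_rank} (rank ->
#'   data frame of Taxon + sample columns), \code{reference},
#'   \code{match_report}, \code{samples}.
#' @export
aggregate_taxa <- function(tagged) {
  stopifnot(inherits(tagged, "biomon_tagged"))
  ranks <- attr(tagged$reference, "ranks")
  samples <- tagged$samples
  data <- tagged$data

  agg_at <- function(col) {
    vals <- data[[col]]
    keep <- vals != ""
    if (!any(keep)) return(NULL)
    d <- data[keep, samples, drop = FALSE]
    out <- stats::aggregate(d, by = list(Taxon = vals[keep]), FUN = sum)
    out[order(out$Taxon), , drop = FALSE]
  }
  per_rank <- list()
  for (r in ranks) {
    t <- agg_at(r)
    if (!is.null(t)) {
      rownames(t) <- NULL
      per_rank[[r]] <- t
    }
  }
  structure(list(per_rank = per_rank, reference = tagged$reference,
                 match_report = tagged$match_report, samples = samples),
            class = "biomon_agg")
}

#' @export
print.biomon_agg <- function(x, ...) {
  cat("biomon aggregated community;", length(x$samples), "samples\n")
  for (r in names(x$per_rank)) {
    cat(sprintf("  %-10s %d taxa\n", r, nrow(x$per_rank[[r]])))
  }
  invisible(x)
}

# fetch the rank table, with a clear error when the rank is absent
rank_table <- function(agg, tax_lev) {
  stopifnot(inherits(agg, "biomon_agg"))
  check_rank(tax_lev, attr(agg$reference, "ranks"))
  t <- agg$per_rank[[tax_lev]]
  if (is.null(t)) {
    t <- data.frame(Taxon = character(0))
    for (s in agg$samples) t[[s]] <- numeric(0)
  }
  t
}

# abundance matrix (taxa x samples) from a rank table
rank_matrix <- function(agg, tax_lev) {
  t <- rank_table(agg, tax_lev)
  m <- as.matrix(t[, agg$samples, drop = FALSE])
  rownames(m) <- t$Taxon
  m
}

#' Per-sample abundance of named taxa
#'
#' Sums the abundances of the listed taxa at the stated rank, per sample.
#' Names absent at that rank contribute zero with a warning.
#'
#' @param agg A \code{biomon_agg}.
#' @param taxa Character vector of taxon names.
#' @param tax_lev Rank at which the names live.
#' @return Named numeric vector, one value per sample.
#' @export
get_taxa_abundance <- function(agg, taxa, tax_lev = "Taxa") {
  if (!length(taxa)) stop("'taxa' must name at least one taxon",
                          call. = FALSE)
  m <- rank_matrix(agg, tax_lev)
  hit <- match(norm_name(taxa), norm_name(rownames(m)))
  if (anyNA(hit)) {
    warning("not found at rank ", tax_lev, ": ",
            paste(taxa[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  hit <- hit[!is.na(hit)]
  if (!length(hit)) return(stats::setNames(rep(0, length(agg$samples)),
                                           agg$samples))
  colSums(m[hit, , drop = FALSE])
}

#' Per-sample richness of taxa descending from named parents
#'
#' Counts, per sample, the \code{count_rank} taxa with positive abundance
#' whose lineage at \code{parent_rank} is one of the given parent names.
#' E.g. parents \code{c("Ephemeroptera","Plecoptera","Trichoptera")} at
#' \code{Order} counted at \code{Family} gives EPT family richness.
#'
#' @param agg A \code{biomon_agg}.
#' @param taxa Parent taxon names at \code{parent_rank}.
#' @param parent_rank,count_rank Ranks; \code{parent_rank} must be coarser.
#' @return Named integer vector per sample.
#' @export
get_taxa_richness <- function(agg, taxa, parent_rank, count_rank) {
  ranks <- attr(agg$reference, "ranks")
  if (rank_index(parent_rank, ranks) >= rank_index(count_rank, ranks)) {
    stop("parent_rank must be coarser than count_rank", call. = FALSE)
  }
  if (!length(taxa)) stop("'taxa' must name at least one taxon",
                          call. = FALSE)
  m <- rank_matrix(agg, count_rank)
  ref <- agg$reference
  # parent of each count_rank name, read off the reference lineages
  parent_of <- vapply(rownames(m), function(nm) {
    i <- which(norm_name(ref[[count_rank]]) == norm_name(nm))[1]
    if (is.na(i)) "" else ref[[parent_rank]][i]
  }, "")
  keep <- norm_name(parent_of) %in% norm_name(taxa)
  if (!any(keep)) return(stats::setNames(rep(0L, length(agg$samples)),
                                         agg$samples))
  counts <- colSums(m[keep, , drop = FALSE] > 0)
  stats::setNames(as.integer(counts), agg$samples)
}
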