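#' Construct a taxonomic reference dataset
#'
#' A reference dataset maps every terminal taxon to its full ranked lineage.
#' It is a data frame with one column per rank (see [biomon_ranks()]); empty
#' strings mark missing ranks. The \code{Taxa} column holds the finest
#' non-empty name of each row and is the key against which community tables
#' are matched.
#'
#' @param x Data frame with rank-named columns; missing ranks may be absent
#'   or empty (\code{""} / \code{NA}).
#' @param ranks Ordered rank list.
#' @param validate If \code{TRUE} (default), fail on invariant violations.
#' @return A \code{biomon_ref} data frame with all rank columns present.
#' @seealso [validate_reference()], [ref_from_tree()]
#' @export
as_reference <- function(x, ranks = biomon_ranks(), validate = TRUE) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (r in ranks) {
    if (!r %in% names(x)) x[[r]] <- ""
    x[[r]] <- trimws(as.character(x[[r]]))
    x[[r]][is.na(x[[r]])] <- ""
  }
  x <- x[, ranks, drop = FALSE]
  ref <- structure(x, class = c("biomon_ref", "data.frame"), ranks = ranks)
  if (validate) {
    v <- validate_reference(ref)
    if (length(v)) {
      stop("invalid reference dataset:\n  ", paste(v, collapse = "\n  "),
           call. = FALSE)
    }
  }
  ref
}

#' Validate a reference dataset
#'
#' Checks the three structural invariants of a reference dataset:
#' unique non-empty \code{Taxa} values, \code{Taxa} equal to the finest
#' non-empty rank of each row, and lineage consistency (two rows sharing a
#' name at some rank must agree at all coarser ranks).
#'
#' @param ref Reference data frame (coerced with [as_reference()] if needed).
#' @return Character vector of violation messages; empty if valid.
#' @export
validate_reference <- function(ref) {
  if (!inherits(ref, "biomon_ref")) ref <- as_reference(ref, validate = FALSE)
  ranks <- attr(ref, "ranks")
  lranks <- lineage_ranks(ranks)
  out <- character(0)
  if (nrow(ref) == 0L) return(out)

  taxa <- ref$Taxa
  if (any(taxa == "")) {
    out <- c(out, sprintf("row %s: empty Taxa value",
                          paste(which(taxa == ""), collapse = ",")))
  }
  dup <- unique(taxa[duplicated(taxa) & taxa != ""])
  if (length(dup)) {
    out <- c(out, sprintf("duplicate Taxa value '%s'", dup))
  }
  # Taxa must equal the finest non-empty lineage rank
  for (i in seq_len(nrow(ref))) {
    vals <- unlist(ref[i, lranks], use.names = FALSE)
    nz <- which(vals != "")
    if (!length(nz)) {
      out <- c(out, sprintf("row %d: no lineage values", i))
    } else if (taxa[i] != "" && vals[max(nz)] != taxa[i]) {
      out <- c(out, sprintf(
        "row %d: Taxa '%s' is not the finest non-empty rank value ('%s')",
        i, taxa[i], vals[max(nz)]))
    }
  }
  # lineage consistency: a name at rank r determines all coarser ranks
  for (ri in seq_along(lranks)) {
    r <- lranks[ri]
    vals <- ref[[r]]
    for (v in unique(vals[vals != ""])) {
      rows <- ref[vals == v, lranks[seq_len(ri)], drop = FALSE]
      if (nrow(unique(rows)) > 1L) {
        out <- c(out, sprintf(
          "inconsistent lineage above %s '%s'", r, v))
      }
    }
  }
  out
}

#' Build a reference dataset from a nested taxonomic tree
#'
#' The tree is a nested named list in which every node is named
#' \code{"Name@Rank"} (e.g. \code{"Baetidae@Family"}). Leaves and internal
#' nodes alike become terminal \code{Taxa} entries: a family with no listed
#' genera is itself a terminal taxon.
#'
#' @param tree Nested named list; leaf nodes are empty lists (or \code{NULL}).
#' @param ranks Ordered rank list.
#' @return A validated \code{biomon_ref}.
#' @export
#' @examples
#' ref_from_tree(list("Ephemeroptera@Order" =
#'   list("Baetidae@Family" = list("Baetis@Genus" = list()))))
ref_from_tree <- function(tree, ranks = biomon_ranks()) {
  lranks <- lineage_ranks(ranks)
  rows <- list()
  walk <- function(node, lineage, parent_rank_i) {
    nms <- names(node)
    if (length(node) && is.null(nms)) {
      stop("tree nodes must be named 'Name@Rank'", call. = FALSE)
    }
    for (nm in nms) {
      parts <- strsplit(nm, "@", fixed = TRUE)[[1]]
      if (length(parts) != 2L) {
        stop("malformed node label '", nm, "'; expected 'Name@Rank'",
             call. = FALSE)
      }
      name <- trimws(parts[1]); rank <- trimws(parts[2])
      if (!rank %in% lranks) {
        stop("unknown rank '", rank, "' in node '", nm, "'", call. = FALSE)
      }
      ri <- match(rank, lranks)
      if (ri <= parent_rank_i) {
        stop("rank-order error at node '", nm,
             "': child rank must be strictly finer than parent", call. = FALSE)
      }
      lin <- lineage
      lin[rank] <- name
      row <- stats::setNames(rep("", length(lranks)), lranks)
      row[names(lin)] <- lin
      rows[[length(rows) + 1L]] <<- c(row, Taxa = name)
      walk(node[[nm]], lin, ri)
    }
  }
  walk(tree, stats::setNames(character(0), character(0)), 0L)
  df <- if (length(rows)) {
    as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  } else {
    as.data.frame(stats::setNames(
      rep(list(character(0)), length(ranks)), ranks))
  }
  as_reference(df, ranks = ranks)
}

#' @export
print.biomon_ref <- function(x, ...) {
  cat("Taxonomic reference dataset:", nrow(x), "terminal taxa\n")
  NextMethod()
}

# lineage (named character, lineage ranks only) of a Taxa entry
ref_lineage <- function(ref, taxon) {
  i <- match(norm_name(taxon), norm_name(ref$Taxa))
  if (is.na(i)) return(NULL)
  unlist(ref[i, lineage_ranks(attr(ref, "ranks"))])
}

# rank at which a reference taxon terminates (finest non-empty)
ref_rank_of <- function(ref, taxon) {
  lin <- ref_lineage(ref, taxon)
  if (is.null(lin)) return(NA_character_)
  nz <- which(lin != "")
  names(lin)[max(nz)]
}
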