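#' Abundance-class rule
#'
#' Maps abundances to ordinal abundance classes, as used by
#' abundance-weighted biotic indices (WHPT, LIFE, PSI, IBMR). The default is
#' log-10 classes: 1-9 -> 1, 10-99 -> 2, 100-999 -> 3, >= 1000 -> 4.
#' Zero abundance is "absent" (class 0).
#'
#' @param breakpoints Strictly ascending positive numbers; class k covers
#'   abundances in \code{[breakpoints[k-1], breakpoints[k])}.
#' @return An \code{abundance_class_rule} object (callable on abundances).
#' @export
#' @examples
#' r <- class_rule()
#' abundance_class(c(0, 5, 150, 2000), r)  # 0 1 3 4
class_rule <- function(breakpoints = c(10, 100, 1000)) {
  breakpoints <- as.numeric(breakpoints)
  if (any(diff(breakpoints) <= 0) || any(breakpoints <= 0)) {
    stop("breakpoints must be strictly ascending and positive",
         call. = FALSE)
  }
  structure(list(breakpoints = breakpoints,
                 n_classes = length(breakpoints) + 1L),
            class = "abundance_class_rule")
}

#' @rdname class_rule
#' @param n Numeric abundances.
#' @param rule An \code{abundance_class_rule}.
#' @export
abundance_class <- function(n, rule = class_rule()) {
  cl <- findInterval(n, rule$breakpoints) + 1L
  cl[n <= 0] <- 0L
  cl
}

#' Construct a sensitivity-score table
#'
#' A score table maps taxon names (at a stated rank) to the information a
#' biotic index needs: a scalar score (BMWP/ASPT/DEHLI), per-abundance-class
#' scores (WHPT), a flow group plus a group-by-class score matrix (LIFE), a
#' sensitivity group plus group-by-class weights (PSI), empirical weights
#' (EPSI), sensitivity and stenoecy coefficients (IBMR), or plain taxon
#' lists (EPTD family list, alien taxa). Optional composite rules declare
#' sets of families scored once when any member is present.
#'
#' @param entries Data frame with a \code{taxon} column plus type-specific
#'   columns: \code{score} (scalar); \code{score_class1..K} and optionally
#'   \code{score_occ} (class); \code{group} (flow/psi); \code{weight} and
#'   logical \code{sensitive} (epsi); \code{cs} and \code{e} (ibmr); none
#'   (list).
#' @param index Index family the table serves (metadata).
#' @param rank Rank at which the taxon names live.
#' @param type One of \code{"scalar"}, \code{"class"}, \code{"flow"},
#'   \code{"psi"}, \code{"epsi"}, \code{"ibmr"}, \code{"list"}.
#' @param rule Abundance-class rule, for class-dependent types.
#' @param score_matrix Group-by-class score/weight matrix (flow/psi types);
#'   rownames are group labels.
#' @param composite Named list: composite name -> member taxa. The
#'   composite's own score must appear in \code{entries}.
#' @param sensitive Group labels (psi) counted as sediment-sensitive.
#' @param origin Free-text provenance label.
#' @return A \code{score_table} object.
#' @export
score_table <- function(entries, index, rank = "Family",
                        type = c("scalar", "class", "flow", "psi",
                                 "epsi", "ibmr", "list"),
                        rule = NULL, score_matrix = NULL,
                        composite = NULL, sensitive = c("A", "B"),
                        origin = "user") {
  type <- match.arg(type)
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (!"taxon" %in% names(entries)) stop("entries need a 'taxon' column",
                                         call. = FALSE)
  entries$taxon <- trimws(as.character(entries$taxon))
  if (anyDuplicated(norm_name(entries$taxon))) {
    stop("duplicate taxon in score table", call. = FALSE)
  }
  need <- switch(type,
                 scalar = "score", class = "score_class1",
                 flow = "group", psi = "group",
                 epsi = c("weight", "sensitive"), ibmr = c("cs", "e"),
                 list = character(0))
  miss <- setdiff(need, names(entries))
  if (length(miss)) stop("score table of type '", type, "' needs column(s) ",
                         paste(miss, collapse = ", "), call. = FALSE)
  num_cols <- setdiff(names(entries), c("taxon", "group", "sensitive"))
  for (cc in num_cols) {
    entries[[cc]] <- as.numeric(entries[[cc]])
    if (any(!is.finite(entries[[cc]]))) {
      stop("non-finite score in column '", cc, "'", call. = FALSE)
    }
  }
  if (type %in% c("class", "flow", "psi", "ibmr") && is.null(rule)) {
    rule <- class_rule()
  }
  if (type == "class") {
    k <- sum(grepl("^score_class[0-9]+$", names(entries)))
    if (k != rule$n_classes) {
      stop("class-score columns (", k, ") must match number of classes (",
           rule$n_classes, ")", call. = FALSE)
    }
  }
  if (type %in% c("flow", "psi")) {
    if (is.null(score_matrix)) stop("type '", type,
                                    "' needs a score_matrix", call. = FALSE)
    score_matrix <- as.matrix(score_matrix)
    if (ncol(score_matrix) != rule$n_classes) {
      stop("score_matrix must have one column per abundance class",
           call. = FALSE)
    }
    bad <- setdiff(unique(entries$group), rownames(score_matrix))
    if (length(bad)) stop("groups missing from score_matrix: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(composite)) {
    if (is.null(names(composite)) || any(names(composite) == "")) {
      stop("composite rules must be a named list", call. = FALSE)
    }
    bad <- setdiff(names(composite), entries$taxon)
    if (length(bad)) stop("composite name(s) without a score entry: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(entries = entries, index = index, rank = rank,
                 type = type, rule = rule, score_matrix = score_matrix,
                 composite = composite, sensitive = sensitive,
                 origin = origin),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score table for %s (%s, rank %s, origin %s): %d taxa\n",
              x$index, x$type, x$rank, x$origin, nrow(x$entries)))
  invisible(x)
}

#' Show a packaged default score table
#'
#' Returns one of the package's default score tables. The defaults are
#' synthetic: they are generated deterministically against the demo
#' reference dataset (seed 42) and stand in for published national score
#' sets, which are not redistributed. Users load real score sets with
#' [read_scores()].
#'
#' @param index Index name (\code{bmwp}, \code{aspt}, \code{whpt},
#'   \code{life}, \code{psi}, \code{epsi}, \code{dehli}, \code{ibmr},
#'   \code{eptd}, \code{alien}).
#' @param origin Score-set label; only \code{"synthetic"} is packaged.
#' @return A \code{score_table}.
#' @export
show_scores <- function(index, origin = "synthetic") {
  avail <- c("bmwp", "aspt", "whpt", "life", "psi", "epsi", "dehli",
             "ibmr", "eptd", "alien")
  if (!identical(origin, "synthetic") || !index %in% avail) {
    stop("unknown index/origin; available: ",
         paste(avail, collapse = ", "), " (origin 'synthetic')",
         call. = FALSE)
  }
  ref <- generate_reference(seed = 42)
  kind <- if (index == "aspt") "bmwp" else index
  generate_scores(ref, kind = kind, seed = 42)
}
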