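#' Ordered taxonomic rank list
#'
#' The fixed rank hierarchy used throughout the package, from coarsest to
#' finest, plus the terminal pseudo-rank \code{"Taxa"} which always holds the
#' finest non-empty name of a lineage. Users working with other hierarchies
#' (e.g. species groups) can supply a custom ordered list via the
#' \code{ranks} argument of the functions that take one.
#'
#' @return Character vector of rank names, coarsest first.
#' @export
#' @examples
#' biomon_ranks()
biomon_ranks <- function() {
  c("Phylum", "Class", "Subclass", "Order", "Family", "Subfamily",
    "Tribus", "Genus", "Species", "Subspecies", "Taxa")
}

# ranks that carry real lineage information (everything except "Taxa")
lineage_ranks <- function(ranks = biomon_ranks()) setdiff(ranks, "Taxa")

check_rank <- function(rank, ranks = biomon_ranks()) {
  if (length(rank) != 1L || !rank %in% ranks) {
    stop("unknown rank '", rank, "'; must be one of: ",
         paste(ranks, collapse = ", "), call. = FALSE)
  }
  rank
}

rank_index <- function(rank, ranks = biomon_ranks()) {
  match(check_rank(rank, ranks), ranks)
}

# normalise a taxon name for matching: trim whitespace, case-fold
norm_name <- function(x) tolower(trimws(x))

#' Optimal string alignment (restricted Damerau-Levenshtein) distance
#'
#' Edit distance counting insertions, deletions, substitutions and
#' transpositions of adjacent characters. Used to rank name suggestions for
#' taxa that fail to match the reference dataset.
#'
#' @param a,b Character scalars.
#' @return Integer distance.
#' @export
#' @examples
#' dl_distance("Beatis", "Baetis") # one transposition
dl_distance <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  s <- strsplit(a, "")[[1]]; t <- strsplit(b, "")[[1]]
  n <- length(s); m <- length(t)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0L:n
  d[1L, ] <- 0L:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (s[i] == t[j]) 0L else 1L
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L,
                               d[i + 1L, j] + 1L,
                               d[i, j] + cost)
      if (i > 1L && j > 1L && s[i] == t[j - 1L] && s[i - 1L] == t[j]) {
        d[i + 1L, j + 1L] <- min(d[i + 1L, j + 1L], d[i - 1L, j - 1L] + cost)
      }
    }
  }
  d[n + 1L, m + 1L]
}
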