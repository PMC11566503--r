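# run expr with a temporary RNG state; leaves the global stream untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Construct a fuzzy-coded trait dataset
#'
#' A trait dataset holds one row per taxon and one column per trait
#' modality; modalities are partitioned into trait blocks (e.g. the block
#' "feeding" with modalities shredder/grazer/predator). Affinities are
#' non-negative reals; within a block they are interpreted as fuzzy-coded
#' affinity scores.
#'
#' @param x Data frame with a \code{Taxon} column (optionally \code{Rank})
#'   and numeric modality columns.
#' @param blocks Named list: trait name -> character vector of its modality
#'   column names. Every modality column must belong to exactly one block.
#' @return A \code{biomon_traits} data frame with a \code{blocks} attribute.
#' @export
trait_dataset <- function(x, blocks) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"Taxon" %in% names(x)) stop("trait table needs a 'Taxon' column",
                                   call. = FALSE)
  x$Taxon <- trimws(as.character(x$Taxon))
  mods <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(mods)) stop("a modality belongs to more than one block",
                                call. = FALSE)
  miss <- setdiff(mods, names(x))
  if (length(miss)) stop("modality column(s) missing: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  for (mcol in mods) {
    x[[mcol]] <- as.numeric(x[[mcol]])
    if (anyNA(x[[mcol]]) || any(x[[mcol]] < 0)) {
      stop("modality '", mcol, "' must be non-negative and complete",
           call. = FALSE)
    }
  }
  structure(x, blocks = blocks, class = c("biomon_traits", "data.frame"))
}

#' @export
print.biomon_traits <- function(x, ...) {
  b <- attr(x, "blocks")
  cat("trait dataset:", nrow(x), "taxa,", length(b), "blocks (",
      paste(names(b), collapse = ", "), ")\n")
  invisible(x)
}

trait_modalities <- function(traits) {
  unlist(attr(traits, "blocks"), use.names = FALSE)
}

trait_profile_matrix <- function(traits) {
  m <- as.matrix(traits[, trait_modalities(traits), drop = FALSE])
  rownames(m) <- traits$Taxon
  m
}

# resolve the terminal rank of a name inside the reference (Taxa entry or
# plain rank value); NA when unknown
resolve_rank <- function(ref, name) {
  r <- ref_rank_of(ref, name)
  if (!is.na(r)) return(r)
  for (rk in lineage_ranks(attr(ref, "ranks"))) {
    if (norm_name(name) %in% norm_name(ref[[rk]])) return(rk)
  }
  NA_character_
}

# signed taxonomic distance in non-empty rank steps between a community
# taxon at `tax_lev` and a trait taxon; NA when lineages are incompatible
signed_tax_distance <- function(ref, community_taxon, tax_lev, trait_taxon) {
  ranks <- lineage_ranks(attr(ref, "ranks"))
  t_rank <- resolve_rank(ref, trait_taxon)
  if (is.na(t_rank)) return(NA_integer_)
  if (norm_name(community_taxon) == norm_name(trait_taxon) &&
      identical(t_rank, tax_lev)) {
    return(0L)
  }
  ci <- match(tax_lev, ranks); ti <- match(t_rank, ranks)
  if (ti > ci) {
    # candidate finer: its lineage must pass through the community taxon
    row <- which(norm_name(ref[[t_rank]]) == norm_name(trait_taxon) &
                 norm_name(ref[[tax_lev]]) == norm_name(community_taxon))[1]
    if (is.na(row)) return(NA_integer_)
    between <- ref[row, ranks[(ci + 1):ti]]
    return(sum(unlist(between) != ""))
  }
  if (ti < ci) {
    # candidate coarser: community taxon's lineage must contain it
    row <- which(norm_name(ref[[tax_lev]]) ==
                   norm_name(community_taxon) &
                 norm_name(ref[[t_rank]]) == norm_name(trait_taxon))[1]
    if (is.na(row)) return(NA_integer_)
    between <- ref[row, ranks[(ti + 1):ci]]
    return(-sum(unlist(between) != ""))
  }
  # same rank but different name
  NA_integer_
}

#' Match trait rows to community taxa across taxonomic levels
#'
#' For every community taxon at \code{tax_lev}, finds the trait rows whose
#' taxon equals it (distance 0), descends from it (positive distance) or is
#' one of its ancestors (negative distance). Distances count the non-empty
#' rank steps separating the two names along the reference lineage, so a
#' genus-level trait row under a family-level taxon is at distance +1 when
#' no subfamily/tribus names intervene.
#'
#' @param agg A \code{biomon_agg}.
#' @param traits A \code{biomon_traits} dataset.
#' @param tax_lev Rank of the community taxa to annotate.
#' @return A \code{biomon_assign} object: list with \code{candidates}
#'   (taxon -> data frame of trait-row index, trait taxon, distance),
#'   \code{no_candidates}, \code{traits}, \code{tax_lev}, \code{agg}.
#' @export
assign_traits <- function(agg, traits, tax_lev = "Taxa") {
  stopifnot(inherits(traits, "biomon_traits"))
  m <- rank_matrix(agg, tax_lev)
  ref <- agg$reference
  cands <- list()
  none <- character(0)
  for (tx in rownames(m)) {
    d <- vapply(seq_len(nrow(traits)), function(i) {
      signed_tax_distance(ref, tx, tax_lev, traits$Taxon[i])
    }, 0L)
    keep <- which(!is.na(d))
    if (!length(keep)) {
      none <- c(none, tx)
      next
    }
    o <- keep[order(abs(d[keep]), d[keep], traits$Taxon[keep])]
    cands[[tx]] <- data.frame(row = o, taxon = traits$Taxon[o],
                              distance = d[o], row.names = NULL)
  }
  structure(list(candidates = cands, no_candidates = none,
                 traits = traits, tax_lev = tax_lev),
            class = "biomon_assign")
}

#' @export
print.biomon_assign <- function(x, ...) {
  cat("trait assignment at rank", x$tax_lev, ":",
      length(x$candidates), "taxa with candidates,",
      length(x$no_candidates), "without\n")
  invisible(x)
}

#' Filter trait candidates by taxonomic proximity
#'
#' Keeps, per community taxon, only the candidates at minimal absolute
#' taxonomic distance, optionally restricted to finer
#' (\code{nearest_finer}) or coarser (\code{nearest_coarser}) candidates.
#' Ties at equal absolute distance (one finer, one coarser) are all kept by
#' \code{nearest}.
#'
#' @param assign A \code{biomon_assign}.
#' @param method \code{"nearest"}, \code{"nearest_finer"} or
#'   \code{"nearest_coarser"}.
#' @return A filtered \code{biomon_assign}.
#' @export
manage_traits <- function(assign, method = c("nearest", "nearest_finer",
                                             "nearest_coarser")) {
  method <- match.arg(method)
  stopifnot(inherits(assign, "biomon_assign"))
  out <- assign
  dropped <- character(0)
  for (tx in names(assign$candidates)) {
    cd <- assign$candidates[[tx]]
    cd <- switch(method,
                 nearest = cd,
                 nearest_finer = cd[cd$distance >= 0, , drop = FALSE],
                 nearest_coarser = cd[cd$distance <= 0, , drop = FALSE])
    if (!nrow(cd)) {
      out$candidates[[tx]] <- NULL
      dropped <- c(dropped, tx)
      next
    }
    out$candidates[[tx]] <- cd[abs(cd$distance) == min(abs(cd$distance)), ,
                               drop = FALSE]
  }
  out$no_candidates <- union(assign$no_candidates, dropped)
  out
}

# renormalise each fuzzy block of a profile matrix to sum 1 (0 stays 0)
normalise_blocks <- function(m, blocks) {
  for (b in blocks) {
    s <- rowSums(m[, b, drop = FALSE])
    nz <- s > 0
    m[nz, b] <- m[nz, b, drop = FALSE] / s[nz]
  }
  m
}

#' Average candidate trait rows per community taxon
#'
#' Modality values are averaged arithmetically over a taxon's candidates,
#' then renormalised within each fuzzy block to sum 1 (blocks summing 0
#' are left at 0), keeping the profiles valid fuzzy codes.
#'
#' @param assign A \code{biomon_assign} (optionally filtered by
#'   [manage_traits()]).
#' @return A \code{biomon_traits} dataset with one row per covered taxon.
#' @export
average_traits <- function(assign) {
  stopifnot(inherits(assign, "biomon_assign"))
  traits <- assign$traits
  mods <- trait_modalities(traits)
  blocks <- attr(traits, "blocks")
  prof <- as.matrix(traits[, mods, drop = FALSE])
  rows <- lapply(names(assign$candidates), function(tx) {
    idx <- assign$candidates[[tx]]$row
    colMeans(prof[idx, , drop = FALSE])
  })
  m <- do.call(rbind, rows)
  m <- normalise_blocks(m, blocks)
  out <- data.frame(Taxon = names(assign$candidates),
                    Rank = assign$tax_lev, m, row.names = NULL,
                    check.names = FALSE)
  trait_dataset(out, blocks)
}

#' Sample one candidate trait row per community taxon
#'
#' Draws, for every covered taxon, one of its candidate trait rows
#' uniformly at random; reproducible under a fixed seed.
#'
#' @param assign A \code{biomon_assign}.
#' @param seed Integer seed.
#' @return A \code{biomon_traits} dataset with one row per covered taxon.
#' @export
sample_traits <- function(assign, seed = 1) {
  stopifnot(inherits(assign, "biomon_assign"))
  traits <- assign$traits
  mods <- trait_modalities(traits)
  prof <- as.matrix(traits[, mods, drop = FALSE])
  picks <- with_seed(seed, vapply(names(assign$candidates), function(tx) {
    idx <- assign$candidates[[tx]]$row
    idx[sample.int(length(idx), 1L)]
  }, 0L))
  out <- data.frame(Taxon = names(assign$candidates),
                    Rank = assign$tax_lev,
                    prof[picks, , drop = FALSE], row.names = NULL,
                    check.names = FALSE)
  trait_dataset(out, attr(traits, "blocks"))
}

#' Merge community taxa with identical trait profiles
#'
#' Taxa (at \code{tax_lev}) whose trait profiles are exactly identical are
#' merged into one: abundances are summed per sample and the merged taxon
#' takes the alphabetically first name. This removes the zero distances
#' that prevent a Gower/PCoA trait space from being built.
#'
#' @param agg A \code{biomon_agg}.
#' @param traits A \code{biomon_traits} with one row per community taxon.
#' @param tax_lev Rank whose table is merged.
#' @return The \code{biomon_agg} with the \code{tax_lev} table merged; the
#'   merge map (new name -> old names) is in attribute \code{merge_map},
#'   and the correspondingly merged trait table in attribute
#'   \code{merged_traits}.
#' @export
zerodist_rm <- function(agg, traits, tax_lev = "Taxa") {
  stopifnot(inherits(traits, "biomon_traits"))
  t <- rank_table(agg, tax_lev)
  prof <- trait_profile_matrix(traits)
  idx <- match(norm_name(t$Taxon), norm_name(rownames(prof)))
  # group key: full profile for taxa with traits, own name otherwise
  key <- ifelse(is.na(idx), paste0("self:", t$Taxon),
                apply(prof[ifelse(is.na(idx), 1L, idx), , drop = FALSE],
                      1, paste, collapse = "|"))
  groups <- split(seq_len(nrow(t)), key)
  merge_map <- list()
  keep_rows <- list()
  for (g in groups) {
    nms <- sort(t$Taxon[g])
    new <- nms[1]
    row <- t[g[1], , drop = FALSE]
    row$Taxon <- new
    row[agg$samples] <- as.list(colSums(
      as.matrix(t[g, agg$samples, drop = FALSE])))
    keep_rows[[length(keep_rows) + 1L]] <- row
    if (length(g) > 1L) merge_map[[new]] <- nms
  }
  out <- do.call(rbind, keep_rows)
  out <- out[order(out$Taxon), , drop = FALSE]
  rownames(out) <- NULL
  agg$per_rank[[tax_lev]] <- out
  merged_names <- out$Taxon
  tr_idx <- match(norm_name(merged_names), norm_name(traits$Taxon))
  mt <- traits[tr_idx[!is.na(tr_idx)], , drop = FALSE]
  attr(agg, "merge_map") <- merge_map
  attr(agg, "merged_traits") <- trait_dataset(mt, attr(traits, "blocks"))
  agg
}

#' Break identical trait profiles with a small random bias
#'
#' Adds independent uniform(0, magnitude) noise to every modality value so
#' that no two rows remain identical (an alternative to [zerodist_rm()]).
#' If identical rows survive, the magnitude is doubled and the noise redrawn
#' up to three times before failing.
#'
#' @param traits A \code{biomon_traits}.
#' @param magnitude Upper bound of the uniform noise.
#' @param seed Integer seed.
#' @return A \code{biomon_traits} with perturbed, pairwise-distinct rows.
#' @export
add_bias_to_traits <- function(traits, magnitude = 1e-6, seed = 1) {
  stopifnot(inherits(traits, "biomon_traits"))
  mods <- trait_modalities(traits)
  base <- as.matrix(traits[, mods, drop = FALSE])
  out <- with_seed(seed, {
    mag <- magnitude
    for (attempt in 1:4) {
      m <- base + matrix(stats::runif(length(base), 0, mag),
                         nrow(base), ncol(base))
      key <- apply(m, 1, paste, collapse = "|")
      if (!anyDuplicated(key)) break
      if (attempt == 4) stop("could not break identical trait profiles",
                             call. = FALSE)
      mag <- mag * 2
    }
    m
  })
  traits[, mods] <- out
  traits
}
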