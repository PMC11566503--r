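#' @name biomon-io
#' @title Readers and writers for the package's table formats
#'
#' @description CSV/TSV readers with validation and coordinate-bearing
#' error messages, plus JSON (de)serialisation of score tables, trait
#' tables, aggregated communities and match reports. The \code{dialect}
#' argument is a list with \code{sep} (field separator; \code{","} or
#' \code{"\t"}) and \code{dec} (decimal mark, \code{","} accepted for
#' continental files).
#'
#' @param path File to read or write.
#' @param dialect List: \code{sep}, \code{dec}.
NULL

default_dialect <- list(sep = ",", dec = ".")

read_delim_checked <- function(path, dialect) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = dialect$sep,
                    dec = dialect$dec, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"",
                    colClasses = "character")
}

parse_numeric_cols <- function(df, cols, path) {
  for (cc in cols) {
    v <- df[[cc]]
    if (!is.null(default_dialect)) v <- gsub(" ", "", v)
    n <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(n) & !is.na(v) & v != "")
    if (length(bad)) {
      stop(sprintf("malformed numeric cell in %s: row %d, column '%s' ('%s')",
                   path, bad[1], cc, v[bad[1]]), call. = FALSE)
    }
    df[[cc]] <- n
  }
  df
}

#' @rdname biomon-io
#' @return \code{read_community}: data frame, first column \code{Taxon}.
#' @export
read_community <- function(path, dialect = default_dialect) {
  df <- read_delim_checked(path, dialect)
  if (ncol(df) < 2L) stop("community file needs a taxon column plus ",
                          "at least one sample column", call. = FALSE)
  if (dialect$dec == ",") {
    for (cc in names(df)[-1]) df[[cc]] <- gsub(",", ".", df[[cc]],
                                               fixed = TRUE)
  }
  df <- parse_numeric_cols(df, names(df)[-1], path)
  names(df)[1] <- "Taxon"
  df
}

#' @rdname biomon-io
#' @param ranks Ordered rank list the header must use.
#' @return \code{read_reference}: a validated \code{biomon_ref}.
#' @export
read_reference <- function(path, dialect = default_dialect,
                           ranks = biomon_ranks()) {
  df <- read_delim_checked(path, dialect)
  if (!"Taxa" %in% names(df)) {
    stop("reference file ", path, ": missing required column 'Taxa'",
         call. = FALSE)
  }
  unknown <- setdiff(names(df), ranks)
  if (length(unknown)) {
    stop("reference file ", path, ": unknown rank column(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  as_reference(df, ranks = ranks)
}

#' @rdname biomon-io
#' @param blocks_path JSON file \code{{"trait": ["modality", ...]}}.
#' @return \code{read_traits}: a \code{biomon_traits}.
#' @export
read_traits <- function(path, blocks_path, dialect = default_dialect) {
  df <- read_delim_checked(path, dialect)
  if (!"Taxon" %in% names(df)) names(df)[1] <- "Taxon"
  blocks <- jsonlite::read_json(blocks_path, simplifyVector = TRUE)
  blocks <- lapply(blocks, as.character)
  mods <- unlist(blocks, use.names = FALSE)
  if (dialect$dec == ",") {
    for (cc in intersect(mods, names(df))) {
      df[[cc]] <- gsub(",", ".", df[[cc]], fixed = TRUE)
    }
  }
  df <- parse_numeric_cols(df, intersect(mods, names(df)), path)
  trait_dataset(df, blocks)
}

#' @rdname biomon-io
#' @param traits A \code{biomon_traits} to write.
#' @export
write_traits <- function(traits, path, blocks_path) {
  utils::write.csv(as.data.frame(traits), path, row.names = FALSE)
  jsonlite::write_json(attr(traits, "blocks"), blocks_path)
  invisible(c(path, blocks_path))
}

#' @rdname biomon-io
#' @param meta_path JSON sidecar holding type, index, rank, class rule,
#'   score matrix, composite rules, sensitive groups and origin. Defaults
#'   to \code{path} with extension \code{.json}.
#' @return \code{read_scores}: a \code{score_table}.
#' @export
read_scores <- function(path, meta_path = NULL,
                        dialect = default_dialect) {
  if (is.null(meta_path)) meta_path <- sub("\\.[ct]sv$", ".json", path)
  if (!file.exists(meta_path)) {
    stop("score sidecar not found: ", meta_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- read_delim_checked(path, dialect)
  num <- setdiff(names(df), c("taxon", "group", "sensitive"))
  df <- parse_numeric_cols(df, num, path)
  if ("sensitive" %in% names(df)) {
    df$sensitive <- as.logical(df$sensitive)
  }
  rule <- if (!is.null(meta$breakpoints)) {
    class_rule(as.numeric(meta$breakpoints))
  } else NULL
  sm <- NULL
  if (!is.null(meta$score_matrix)) {
    sm <- as.matrix(as.data.frame(meta$score_matrix))
    rownames(sm) <- meta$score_matrix_groups
  }
  comp <- if (!is.null(meta$composite) && length(meta$composite)) {
    lapply(meta$composite, as.character)
  } else NULL
  score_table(df, index = meta$index, rank = meta$rank, type = meta$type,
              rule = rule, score_matrix = sm, composite = comp,
              sensitive = if (is.null(meta$sensitive)) c("A", "B")
                          else as.character(meta$sensitive),
              origin = if (is.null(meta$origin)) "user" else meta$origin)
}

#' @rdname biomon-io
#' @param scores A \code{score_table} to write.
#' @export
write_scores <- function(scores, path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.[ct]sv$", ".json", path)
  utils::write.csv(scores$entries, path, row.names = FALSE)
  meta <- list(index = scores$index, rank = scores$rank,
               type = scores$type, origin = scores$origin,
               sensitive = scores$sensitive)
  if (!is.null(scores$rule)) meta$breakpoints <- scores$rule$breakpoints
  if (!is.null(scores$score_matrix)) {
    meta$score_matrix <- as.data.frame(scores$score_matrix)
    meta$score_matrix_groups <- rownames(scores$score_matrix)
  }
  if (!is.null(scores$composite)) meta$composite <- scores$composite
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, meta_path))
}

#' @rdname biomon-io
#' @param agg A \code{biomon_agg} to serialise.
#' @export
write_agg_json <- function(agg, path) {
  obj <- list(
    samples = agg$samples,
    per_rank = lapply(agg$per_rank, function(t) t),
    reference = as.data.frame(agg$reference),
    match_report = agg$match_report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname biomon-io
#' @return \code{read_agg_json}: a \code{biomon_agg}.
#' @export
read_agg_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- as_reference(as.data.frame(obj$reference))
  per_rank <- lapply(obj$per_rank, function(t) {
    as.data.frame(t, stringsAsFactors = FALSE)
  })
  mr <- obj$match_report
  mr$suggestions <- lapply(mr$suggestions, as.data.frame)
  structure(list(per_rank = per_rank, reference = ref,
                 match_report = mr,
                 samples = as.character(obj$samples)),
            class = "biomon_agg")
}

#' @rdname biomon-io
#' @param report A match report (from \code{as_biomonitor}) to export.
#' @export
write_match_report <- function(report, path) {
  jsonlite::write_json(
    list(matched = report$matched,
         unmatched = report$unmatched,
         suggestions = report$suggestions),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname biomon-io
#' @param result A \code{biomon_result} to write as CSV (columns sample,
#'   value, index, rank, flags).
#' @export
write_result_csv <- function(result, path) {
  df <- data.frame(sample = names(result), value = as.numeric(result),
                   index = attr(result, "index"),
                   rank = attr(result, "tax_lev"),
                   flags = attr(result, "flags"), row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
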