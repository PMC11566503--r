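#' @name diversity-indices
#' @title Richness, diversity, dominance and evenness indices
#'
#' @description Each function takes an aggregated community and a taxonomic
#' rank (\code{tax_lev}) and returns one value per sample as a
#' \code{biomon_result}: a named numeric vector with \code{index},
#' \code{tax_lev} and \code{flags} attributes. Zero-abundance taxa are
#' treated as absent. Samples where an index is undefined get \code{NaN}
#' plus a machine-readable flag, never a silent zero.
#'
#' With per-sample abundances \eqn{n_i}, \eqn{N = \sum n_i},
#' \eqn{S} = number of taxa with \eqn{n_i > 0} and \eqn{p_i = n_i / N}:
#' \itemize{
#' \item \code{richness}: \eqn{S}
#' \item \code{shannon}: \eqn{H = -\sum p_i \log_b p_i} (default base e)
#' \item \code{simpson}: Gini-Simpson \eqn{1 - D} with \eqn{D = \sum p_i^2};
#'   \code{variant = "concentration"} returns \eqn{D}
#' \item \code{invsimpson}: \eqn{1/D}; \code{esimpson}: \eqn{(1/D)/S}
#' \item \code{pielou}: \eqn{J = H / \log_b S}, undefined for \eqn{S \le 1}
#' \item \code{berpar}: \eqn{d = \max n_i / N}; \code{invberpar}: \eqn{1/d}
#' \item \code{margalef}: \eqn{(S-1)/\ln N}; \code{menhinick}:
#'   \eqn{S/\sqrt N} (undefined for \eqn{N \le 1} / \eqn{N = 0})
#' \item \code{brillouin}: \eqn{HB = (\ln N! - \sum \ln n_i!)/N}
#'   (integer abundances only)
#' \item \code{mcintosh}: \eqn{(N-U)/(N-\sqrt N)}, \eqn{U=\sqrt{\sum n_i^2}}
#' \item \code{fisher_alpha}: \eqn{\alpha} solving
#'   \eqn{S = \alpha \ln(1 + N/\alpha)}
#' }
#'
#' @param agg A \code{biomon_agg} from [aggregate_taxa()].
#' @param tax_lev Taxonomic rank at which to compute.
#' @param base Logarithm base for \code{shannon}/\code{pielou}.
#' @param variant Simpson variant, see Details.
#' @return A \code{biomon_result} named numeric vector (one value per
#'   sample).
NULL

biomon_result <- function(values, index, tax_lev, flags = NULL) {
  structure(values, index = index, tax_lev = tax_lev,
            flags = if (is.null(flags)) rep("", length(values)) else flags,
            class = "biomon_result")
}

#' @export
print.biomon_result <- function(x, ...) {
  cat(attr(x, "index"), "at rank", attr(x, "tax_lev"), "\n")
  print(stats::setNames(as.numeric(x), names(x)))
  fl <- attr(x, "flags")
  if (any(fl != "")) cat("flags:", paste(unique(fl[fl != ""]),
                                         collapse = "; "), "\n")
  invisible(x)
}

# run a per-sample function over the abundance matrix at a rank
per_sample <- function(agg, tax_lev, index, fun, integer_only = FALSE,
                       abundance_only = FALSE) {
  m <- rank_matrix(agg, tax_lev)
  if (integer_only && nrow(m) &&
      any(abs(m - round(m)) > 1e-9)) {
    stop(index, " requires integer abundances", call. = FALSE)
  }
  # occurrence heuristic: a 0/1 matrix that records absences is
  # presence/absence data; all-singleton counts (no zeros) are left alone
  if (abundance_only && nrow(m) && all(m %in% c(0, 1)) && any(m == 0)) {
    stop(index, " requires abundance data, not presence/absence",
         call. = FALSE)
  }
  vals <- numeric(length(agg$samples))
  flags <- character(length(agg$samples))
  for (j in seq_along(agg$samples)) {
    n <- m[, j]
    n <- n[n > 0]
    r <- fun(n)
    vals[j] <- r$value
    flags[j] <- r$flag
  }
  biomon_result(stats::setNames(vals, agg$samples), index, tax_lev, flags)
}

ok <- function(v) list(value = v, flag = "")
undef <- function(flag) list(value = NaN, flag = flag)

#' @rdname diversity-indices
#' @export
richness <- function(agg, tax_lev = "Taxa") {
  per_sample(agg, tax_lev, "richness", function(n) ok(length(n)))
}

#' @rdname diversity-indices
#' @export
shannon <- function(agg, tax_lev = "Taxa", base = exp(1)) {
  per_sample(agg, tax_lev, "shannon", function(n) {
    if (!length(n)) return(undef("empty sample"))
    p <- n / sum(n)
    ok(-sum(p * log(p, base = base)))
  })
}

#' @rdname diversity-indices
#' @export
simpson <- function(agg, tax_lev = "Taxa",
                    variant = c("gini", "concentration")) {
  variant <- match.arg(variant)
  per_sample(agg, tax_lev, paste0("simpson_", variant), function(n) {
    if (!length(n)) return(undef("empty sample"))
    D <- sum((n / sum(n))^2)
    ok(if (variant == "gini") 1 - D else D)
  })
}

#' @rdname diversity-indices
#' @export
invsimpson <- function(agg, tax_lev = "Taxa") {
  per_sample(agg, tax_lev, "invsimpson", function(n) {
    if (!length(n)) return(undef("empty sample"))
    ok(1 / sum((n / sum(n))^2))
  })
}

#' @rdname diversity-indices
#' @export
esimpson <- function(agg, tax_lev = "Taxa") {
  per_sample(agg, tax_lev, "esimpson", function(n) {
    if (!length(n)) return(undef("empty sample"))
    ok(1 / sum((n / sum(n))^2) / length(n))
  })
}

#' @rdname diversity-indices
#' @export
pielou <- function(agg, tax_lev = "Taxa", base = exp(1)) {
  per_sample(agg, tax_lev, "pielou", function(n) {
    if (length(n) <= 1L) return(undef("S <= 1"))
    p <- n / sum(n)
    ok(-sum(p * log(p, base = base)) / log(length(n), base = base))
  })
}

#' @rdname diversity-indices
#' @export
berpar <- function(agg, tax_lev = "Taxa") {
  per_sample(agg, tax_lev, "berpar", function(n) {
    if (!length(n)) return(undef("empty sample"))
    ok(max(n) / sum(n))
  }, abundance_only = FALSE)
}

#' @rdname diversity-indices
#' @export
invberpar <- function(agg, tax_lev = "Taxa") {
  per_sample(agg, tax_lev, "invberpar", function(n) {
    if (!length(n)) return(undef("empty sample"))
    ok(sum(n) / max(n))
  })
}

#' @rdname diversity-indices
#' @export
margalef <- function(agg, tax_lev = "Taxa") {
  per_sample(agg, tax_lev, "margalef", function(n) {
    N <- sum(n)
    if (N <= 1) return(undef("N <= 1"))
    ok((length(n) - 1) / log(N))
  })
}

#' @rdname diversity-indices
#' @export
menhinick <- function(agg, tax_lev = "Taxa") {
  per_sample(agg, tax_lev, "menhinick", function(n) {
    N <- sum(n)
    if (N <= 0) return(undef("N = 0"))
    ok(length(n) / sqrt(N))
  })
}

#' @rdname diversity-indices
#' @export
brillouin <- function(agg, tax_lev = "Taxa") {
  per_sample(agg, tax_lev, "brillouin", function(n) {
    N <- sum(n)
    if (N <= 0) return(undef("N = 0"))
    ok((lfactorial(N) - sum(lfactorial(n))) / N)
  }, integer_only = TRUE, abundance_only = TRUE)
}

#' @rdname diversity-indices
#' @export
mcintosh <- function(agg, tax_lev = "Taxa") {
  per_sample(agg, tax_lev, "mcintosh", function(n) {
    N <- sum(n)
    if (N <= 1) return(undef("N <= 1"))
    U <- sqrt(sum(n^2))
    ok((N - U) / (N - sqrt(N)))
  }, abundance_only = TRUE)
}

# alpha solving S = alpha * log(1 + N/alpha); bracketed root finding
fisher_alpha_solve <- function(S, N, tol = 1e-9) {
  # f(a) -> 0^- as a -> 0+ and increases to N as a -> Inf; S < N required
  f <- function(a) a * log1p(N / a) - S
  lo <- 1e-12
  hi <- max(S, 1)
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' @rdname diversity-indices
#' @export
fisher_alpha <- function(agg, tax_lev = "Taxa") {
  per_sample(agg, tax_lev, "fisher_alpha", function(n) {
    S <- length(n); N <- sum(n)
    if (S <= 0) return(undef("empty sample"))
    if (S >= N) return(undef("S >= N (all singletons)"))
    ok(fisher_alpha_solve(S, N))
  }, integer_only = TRUE, abundance_only = TRUE)
}

#' All diversity indices at all available ranks
#'
#' Runs every diversity index of the registry at every rank present in the
#' aggregated community. Each cell equals the corresponding single-index
#' call; \code{NaN} cells carry their flag in the \code{flag} column.
#'
#' @param agg A \code{biomon_agg}.
#' @param indices Index names (default: all diversity indices).
#' @return Long-format data frame: sample, rank, index, value, flag.
#' @export
allindices <- function(agg, indices = NULL) {
  reg <- index_registry()
  div <- reg$name[reg$category == "diversity"]
  if (is.null(indices)) indices <- div
  indices <- match.arg(indices, div, several.ok = TRUE)
  out <- list()
  for (r in names(agg$per_rank)) {
    for (ix in indices) {
      res <- tryCatch(do.call(ix, list(agg = agg, tax_lev = r)),
                      error = function(e) NULL)
      if (is.null(res)) next
      out[[length(out) + 1L]] <- data.frame(
        sample = names(res), rank = r, index = ix,
        value = as.numeric(res), flag = attr(res, "flags"),
        row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' @rdname allindices
#' @export
allrich <- function(agg) {
  allindices(agg, indices = "richness")
}
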