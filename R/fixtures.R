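#' @name fixtures
#' @title Synthetic data generators
#'
#' @description Deterministic (seeded) generators for every input the
#' package consumes: a macroinvertebrate-like taxonomic reference, mixed
#' taxonomic resolution communities with log-series abundances, fuzzy-coded
#' trait tables and sensitivity-score tables. They stand in for the
#' published reference datasets and national score sets, which are not
#' redistributed; schemas are identical, values are synthetic.
NULL

# fixed upper-taxonomy scaffold with real order names so that EPT and GOLD
# semantics (Ephemeroptera/Plecoptera/Trichoptera; Gastropoda, Oligochaeta,
# Diptera) are meaningful on synthetic data
order_scaffold <- function() {
  data.frame(
    Phylum = c("Arthropoda", "Arthropoda", "Arthropoda", "Arthropoda",
               "Arthropoda", "Arthropoda", "Arthropoda", "Mollusca",
               "Annelida"),
    Class = c("Insecta", "Insecta", "Insecta", "Insecta", "Insecta",
              "Insecta", "Insecta", "Gastropoda", "Oligochaeta"),
    Order = c("Ephemeroptera", "Plecoptera", "Trichoptera", "Diptera",
              "Coleoptera", "Odonata", "Hemiptera", "Basommatophora",
              "Haplotaxida"),
    stringsAsFactors = FALSE)
}

# pronounceable synthetic names: alternating consonant/vowel syllables
syllable_name <- function(n_syl = 3) {
  cons <- c("b", "c", "d", "g", "l", "m", "n", "p", "r", "s", "t", "v")
  vow <- c("a", "e", "i", "o", "u")
  paste0(vapply(seq_len(n_syl), function(i) {
    paste0(sample(cons, 1), sample(vow, 1))
  }, ""), collapse = "")
}

cap <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

unique_names <- function(n, maker, taken = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    nm <- maker()
    if (!nm %in% c(out, taken)) out <- c(out, nm)
  }
  out
}

#' @rdname fixtures
#' @param n_orders Number of orders drawn from the fixed scaffold (max 9).
#' @param n_families_per_order,n_genera,n_species Children per parent.
#' @param seed Integer seed.
#' @return \code{generate_reference}: a validated \code{biomon_ref}
#'   containing one terminal \code{Taxa} row for every order, family,
#'   genus and species.
#' @export
generate_reference <- function(n_orders = 6, n_families_per_order = 3,
                               n_genera = 2, n_species = 2, seed = 1) {
  scaf <- order_scaffold()
  n_orders <- min(n_orders, nrow(scaf))
  with_seed(seed, {
    rows <- list()
    taken <- character(0)
    add <- function(phy, cls, ord, fam = "", gen = "", sp = "") {
      taxa <- c(sp, gen, fam, ord)
      taxa <- taxa[taxa != ""][1]
      rows[[length(rows) + 1L]] <<- data.frame(
        Phylum = phy, Class = cls, Order = ord, Family = fam,
        Genus = gen, Species = sp, Taxa = taxa,
        stringsAsFactors = FALSE)
    }
    for (oi in seq_len(n_orders)) {
      phy <- scaf$Phylum[oi]; cls <- scaf$Class[oi]; ord <- scaf$Order[oi]
      add(phy, cls, ord)
      fams <- unique_names(n_families_per_order,
                           function() paste0(cap(syllable_name(2)), "idae"),
                           taken)
      taken <- c(taken, fams)
      for (fam in fams) {
        add(phy, cls, ord, fam)
        gens <- unique_names(n_genera,
                             function() cap(syllable_name(3)), taken)
        taken <- c(taken, gens)
        for (gen in gens) {
          add(phy, cls, ord, fam, gen)
          eps <- unique_names(n_species, function() syllable_name(3),
                              taken)
          for (ep in eps) {
            sp <- paste(gen, ep)
            taken <- c(taken, sp)
            add(phy, cls, ord, fam, gen, sp)
          }
        }
      }
    }
    as_reference(do.call(rbind, rows))
  })
}

# log-series abundance sampler: P(n) = -x^n / (n log(1-x)), n >= 1
rlogseries <- function(n, x) {
  vapply(seq_len(n), function(i) {
    u <- stats::runif(1)
    k <- 1L
    cum <- -x / log1p(-x)
    pk <- cum
    while (u > cum && k < 1e6) {
      pk <- pk * x * k / (k + 1)
      k <- k + 1L
      cum <- cum + pk
    }
    k
  }, 0L)
}

#' @rdname fixtures
#' @param ref A \code{biomon_ref}.
#' @param n_samples Number of samples.
#' @param resolution_mix Named fractions of taxa reported at Species,
#'   Genus and Family resolution.
#' @param alpha Fisher's alpha of the log-series abundance model; with
#'   \code{n_target} it fixes the log-series parameter
#'   \eqn{x = N/(N+\alpha)} and the expected richness
#'   \eqn{S = \alpha \ln(1 + N/\alpha)}.
#' @param n_target Target number of individuals per sample.
#' @param occurrence Return presence/absence instead of abundances.
#' @return \code{generate_community}: data frame, first column
#'   \code{Taxon}, one numeric column per sample.
#' @export
generate_community <- function(ref, n_samples = 5,
                               resolution_mix = c(Species = 0.6,
                                                  Genus = 0.2,
                                                  Family = 0.2),
                               alpha = 5, n_target = 500,
                               occurrence = FALSE, seed = 1) {
  stopifnot(inherits(ref, "biomon_ref"))
  x <- n_target / (n_target + alpha)
  s_exp <- alpha * log1p(n_target / alpha)
  with_seed(seed, {
    pick_at <- function(rank, n) {
      pool <- ref$Taxa[vapply(ref$Taxa, function(tx) {
        identical(ref_rank_of(ref, tx), rank)
      }, TRUE)]
      sample(pool, min(n, length(pool)))
    }
    mix <- resolution_mix / sum(resolution_mix)
    pool_size <- max(4, ceiling(1.3 * s_exp))
    want <- round(pool_size * mix)
    taxa <- unique(c(pick_at("Species", want[["Species"]]),
                     pick_at("Genus", want[["Genus"]]),
                     pick_at("Family", want[["Family"]])))
    out <- data.frame(Taxon = taxa, stringsAsFactors = FALSE)
    p_present <- min(1, s_exp / length(taxa))
    for (j in seq_len(n_samples)) {
      present <- stats::runif(length(taxa)) < p_present
      if (!any(present)) present[sample.int(length(taxa), 1)] <- TRUE
      n <- integer(length(taxa))
      n[present] <- rlogseries(sum(present), x)
      out[[paste0("S", j)]] <- if (occurrence) as.integer(n > 0) else n
    }
    out
  })
}

#' @rdname fixtures
#' @param blocks Named list: block name -> number of modalities.
#' @param ranks_covered Terminal ranks for which trait rows are generated.
#' @param specialization Dirichlet concentration is
#'   \code{1/specialization}: larger values give more specialised (peaked)
#'   fuzzy profiles.
#' @return \code{generate_traits}: a \code{biomon_traits} with one
#'   block-normalised row per covered reference taxon.
#' @export
generate_traits <- function(ref, blocks = list(feeding = 3, locomotion = 4,
                                               flow = 3),
                            ranks_covered = c("Species", "Genus", "Family"),
                            specialization = 1, seed = 1) {
  stopifnot(inherits(ref, "biomon_ref"))
  block_cols <- lapply(names(blocks), function(b) {
    paste0(b, "_", seq_len(blocks[[b]]))
  })
  names(block_cols) <- names(blocks)
  taxa <- ref$Taxa[vapply(ref$Taxa, function(tx) {
    ref_rank_of(ref, tx) %in% ranks_covered
  }, TRUE)]
  conc <- 1 / specialization
  with_seed(seed, {
    prof <- lapply(block_cols, function(cols) {
      g <- matrix(stats::rgamma(length(taxa) * length(cols), shape = conc),
                  length(taxa), length(cols))
      g / rowSums(g)
    })
    m <- do.call(cbind, prof)
    colnames(m) <- unlist(block_cols)
    trait_dataset(data.frame(Taxon = taxa, m, check.names = FALSE),
                  block_cols)
  })
}

#' @rdname fixtures
#' @param kind Which score table to generate: \code{bmwp} (scalar, with a
#'   composite rule), \code{whpt} (class scores), \code{life} (flow
#'   groups), \code{psi} (sensitivity groups A-D), \code{epsi} (empirical
#'   weights), \code{dehli} (scalar drought scores), \code{ibmr}
#'   (sensitivity + stenoecy), \code{eptd} (EPTD family list),
#'   \code{alien} (alien taxon list).
#' @param coverage Fraction of candidate taxa receiving an entry.
#' @return \code{generate_scores}: a \code{score_table}.
#' @export
generate_scores <- function(ref, kind = c("bmwp", "whpt", "life", "psi",
                                          "epsi", "dehli", "ibmr", "eptd",
                                          "alien"),
                            coverage = 0.8, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(ref, "biomon_ref"))
  fams <- sort(unique(ref$Family[ref$Family != ""]))
  with_seed(seed, {
    pick <- sort(sample(fams, max(2, round(coverage * length(fams)))))
    rule <- class_rule()
    k <- rule$n_classes
    switch(kind,
      bmwp = {
        ent <- data.frame(taxon = pick,
                          score = sample(1:10, length(pick), TRUE))
        comp <- NULL
        if (length(pick) >= 4) {
          members <- pick[1:2]
          ent <- rbind(ent, data.frame(taxon = "CompositeA",
                                       score = max(ent$score[1:2])))
          comp <- list(CompositeA = members)
        }
        score_table(ent, index = "bmwp", rank = "Family", type = "scalar",
                    composite = comp, origin = "synthetic")
      },
      dehli = {
        ent <- data.frame(taxon = pick,
                          score = sample(1:12, length(pick), TRUE))
        score_table(ent, index = "dehli", rank = "Family",
                    type = "scalar", origin = "synthetic")
      },
      whpt = {
        base <- stats::runif(length(pick), 1, 10)
        ent <- data.frame(taxon = pick)
        for (cl in seq_len(k)) {
          ent[[paste0("score_class", cl)]] <-
            round(base + stats::rnorm(length(pick), 0, 0.5), 1)
        }
        ent$score_occ <- round(base, 1)
        score_table(ent, index = "whpt", rank = "Family", type = "class",
                    rule = rule, origin = "synthetic")
      },
      life = {
        ent <- data.frame(taxon = pick,
                          group = sample(paste0("G", 1:6), length(pick),
                                         TRUE))
        fs <- outer(9:4, 0:(k - 1), function(g, cl) pmax(1, g - cl))
        rownames(fs) <- paste0("G", 1:6)
        score_table(ent, index = "life", rank = "Family", type = "flow",
                    rule = rule, score_matrix = fs, origin = "synthetic")
      },
      psi = {
        ent <- data.frame(taxon = pick,
                          group = sample(LETTERS[1:4], length(pick), TRUE))
        w <- outer(c(2, 2, 1, 1), seq_len(k), function(g, cl) g * cl)
        rownames(w) <- LETTERS[1:4]
        score_table(ent, index = "psi", rank = "Family", type = "psi",
                    rule = rule, score_matrix = w,
                    sensitive = c("A", "B"), origin = "synthetic")
      },
      epsi = {
        ent <- data.frame(taxon = pick,
                          weight = round(stats::runif(length(pick)), 3),
                          sensitive = sample(c(TRUE, FALSE), length(pick),
                                             TRUE))
        score_table(ent, index = "epsi", rank = "Family", type = "epsi",
                    origin = "synthetic")
      },
      ibmr = {
        ent <- data.frame(taxon = pick,
                          cs = sample(0:20, length(pick), TRUE),
                          e = sample(1:3, length(pick), TRUE))
        score_table(ent, index = "ibmr", rank = "Family", type = "ibmr",
                    rule = rule, origin = "synthetic")
      },
      eptd = {
        eptd_orders <- c("Ephemeroptera", "Plecoptera", "Trichoptera",
                         "Diptera")
        cand <- sort(unique(ref$Family[ref$Order %in% eptd_orders &
                                         ref$Family != ""]))
        cand <- cand[seq_len(max(1, floor(length(cand) / 2)))]
        score_table(data.frame(taxon = cand), index = "eptd",
                    rank = "Family", type = "list", origin = "synthetic")
      },
      alien = {
        terminals <- ref$Taxa[ref$Species != ""]
        aliens <- sort(sample(terminals,
                              max(1, round(0.1 * length(terminals)))))
        score_table(data.frame(taxon = aliens), index = "alien",
                    rank = "Taxa", type = "list", origin = "synthetic")
      })
  })
}

#' @rdname fixtures
#' @param dir Output directory.
#' @return \code{generate_demo_workspace}: (invisibly) the paths written:
#'   reference, community, traits + blocks, one score CSV/JSON pair per
#'   score kind.
#' @export
generate_demo_workspace <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- generate_reference(seed = seed)
  com <- generate_community(ref, seed = seed)
  tr <- generate_traits(ref, seed = seed)
  paths <- list(
    reference = file.path(dir, "reference.csv"),
    community = file.path(dir, "community.csv"),
    traits = file.path(dir, "traits.csv"),
    blocks = file.path(dir, "trait_blocks.json"))
  utils::write.csv(as.data.frame(ref), paths$reference, row.names = FALSE)
  utils::write.csv(com, paths$community, row.names = FALSE)
  write_traits(tr, paths$traits, paths$blocks)
  for (kind in c("bmwp", "whpt", "life", "psi", "epsi", "dehli", "ibmr",
                 "eptd", "alien")) {
    st <- generate_scores(ref, kind = kind, seed = seed)
    p <- file.path(dir, paste0("scores_", kind, ".csv"))
    write_scores(st, p, sub("csv$", "json", p))
    paths[[paste0("scores_", kind)]] <- p
  }
  invisible(paths)
}
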