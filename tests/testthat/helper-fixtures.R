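# shared fixture builders; everything is generated in code, no files

# minimal EPT-flavoured reference: two insect orders + one snail order
tiny_ref <- function() {
  ref_from_tree(list(
    "Ephemeroptera@Order" = list(
      "Baetidae@Family" = list(
        "Baetis@Genus" = list("Baetis rhodani@Species" = list()),
        "Cloeon@Genus" = list()),
      "Heptageniidae@Family" = list()),
    "Plecoptera@Order" = list(
      "Perlidae@Family" = list("Perla@Genus" = list())),
    "Trichoptera@Order" = list(
      "Hydropsychidae@Family" = list()),
    "Basommatophora@Order" = list(
      "Lymnaeidae@Family" = list("Lymnaea@Genus" = list()))))
}

# fill the coarser ranks of tiny_ref so GOLD/Class lookups work
tiny_ref_full <- function() {
  r <- as.data.frame(tiny_ref())
  ins <- r$Order %in% c("Ephemeroptera", "Plecoptera", "Trichoptera")
  r$Phylum <- ifelse(ins, "Arthropoda", "Mollusca")
  r$Class <- ifelse(ins, "Insecta", "Gastropoda")
  as_reference(r)
}

# community data.frame from a named abundance matrix (taxa x samples)
com_df <- function(m) {
  data.frame(Taxon = rownames(m), as.data.frame(m), check.names = FALSE)
}

make_agg <- function(com, ref) {
  suppressWarnings(aggregate_taxa(as_biomonitor(com, ref)))
}

# one-sample aggregated community from a bare abundance vector; taxa are
# standalone genus-level entries
vec_agg <- function(n, taxa = paste0("Tax", seq_along(n))) {
  ref <- as_reference(data.frame(Genus = taxa, Taxa = taxa))
  com <- data.frame(Taxon = taxa, S1 = n)
  make_agg(com, ref)
}

# random mixed-resolution fixture on a shared reference
rand_fixture <- function(seed, ref = NULL, n_samples = 3) {
  if (is.null(ref)) ref <- generate_reference(seed = 1)
  com <- generate_community(ref, n_samples = n_samples, seed = seed)
  list(ref = ref, com = com, agg = make_agg(com, ref))
}

# independent double-loop Gower oracle (block-normalised, range-scaled)
gower_oracle <- function(traits) {
  blocks <- attr(traits, "blocks")
  prof <- as.matrix(traits[, unlist(blocks), drop = FALSE])
  rownames(prof) <- traits$Taxon
  n <- nrow(prof)
  norm <- prof
  for (b in blocks) {
    for (i in seq_len(n)) {
      s <- sum(prof[i, b])
      if (s > 0) norm[i, b] <- prof[i, b] / s
    }
  }
  rng <- apply(norm, 2, function(x) diff(range(x)))
  d <- matrix(0, n, n, dimnames = list(rownames(prof), rownames(prof)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      comps <- c()
      for (b in blocks) {
        if (sum(prof[i, b]) <= 0 || sum(prof[j, b]) <= 0) next
        terms <- vapply(b, function(k) {
          if (rng[k] > 0) abs(norm[i, k] - norm[j, k]) / rng[k] else 0
        }, 0)
        comps <- c(comps, mean(terms))
      }
      d[i, j] <- mean(comps)
    }
  }
  d
}

# brute-force IndVal oracle (group-size-corrected A)
indval_oracle <- function(m, groups) {
  glev <- sort(unique(groups))
  out <- NULL
  for (tx in rownames(m)) {
    means <- vapply(glev, function(g) mean(m[tx, groups == g]), 0)
    for (g in glev) {
      A <- if (sum(means) > 0) means[g] / sum(means) else 0
      B <- mean(m[tx, groups == g] > 0)
      out <- rbind(out, data.frame(taxon = tx, group = g,
                                   indval = A * B * 100))
    }
  }
  out
}

# shoelace polygon area for an explicitly ordered triangle (FRic oracle)
shoelace <- function(x, y) {
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
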