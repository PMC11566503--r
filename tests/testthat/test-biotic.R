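# score table over the families of tiny_ref()
fam_scores <- function(scores = c(Baetidae = 10, Heptageniidae = 6,
                                  Perlidae = 2),
                       composite = NULL) {
  score_table(data.frame(taxon = names(scores), score = unname(scores)),
              index = "bmwp", rank = "Family", type = "scalar",
              composite = composite, origin = "test")
}

fam_agg <- function(n, taxa = names(n)) {
  make_agg(data.frame(Taxon = taxa, S1 = unname(n)), tiny_ref())
}

test_that("bmwp sums scores; composite families count once", {
  agg <- fam_agg(c(Baetidae = 5, Heptageniidae = 1, Perlidae = 30))
  expect_equal(as.numeric(bmwp(agg, fam_scores())), 18)
  # composite: two member families present, one score counted
  st <- score_table(
    data.frame(taxon = c("Baetidae", "Heptageniidae", "Perlidae", "Ephem"),
               score = c(10, 6, 2, 10)),
    index = "bmwp", rank = "Family", type = "scalar",
    composite = list(Ephem = c("Baetidae", "Heptageniidae")))
  v <- bmwp(agg, st, composite = TRUE, trace_b = TRUE)
  expect_equal(as.numeric(v), 10 + 2)
  tr <- attr(v, "trace")$S1
  expect_true("Ephem" %in% tr$used$taxon)
  expect_setequal(tr$excluded$taxon[grepl("composite",
                                          tr$excluded$reason)],
                  c("Baetidae", "Heptageniidae"))
  # without the flag, members score individually
  expect_equal(as.numeric(bmwp(agg, st, composite = FALSE)), 18)
  # no scoring families present -> 0 with all-excluded trace
  agg2 <- fam_agg(c(Lymnaeidae = 4))
  v2 <- bmwp(agg2, fam_scores(), trace_b = TRUE)
  expect_equal(as.numeric(v2), 0)
  expect_equal(attr(v2, "trace")$S1$excluded$taxon, "Lymnaeidae")
})

test_that("aspt and dehli average scores; aspt == bmwp / n", {
  agg <- fam_agg(c(Baetidae = 5, Heptageniidae = 1, Perlidae = 30))
  expect_equal(as.numeric(aspt(agg, fam_scores())), 6)
  expect_equal(as.numeric(aspt(fam_agg(c(Perlidae = 9)), fam_scores())), 2)
  d <- score_table(data.frame(taxon = c("Baetidae", "Perlidae"),
                              score = c(4, 2)), index = "dehli",
                   rank = "Family", type = "scalar")
  expect_equal(as.numeric(dehli(fam_agg(c(Baetidae = 1)), d)), 4)
  expect_equal(
    as.numeric(dehli(fam_agg(c(Baetidae = 1, Perlidae = 2)), d)), 3)
  # identity oracle on random fixtures
  ref <- generate_reference(seed = 1)
  st <- generate_scores(ref, "bmwp", seed = 2)
  for (s in 1:10) {
    agg <- rand_fixture(seed = s, ref = ref)$agg
    b <- bmwp(agg, st, trace_b = TRUE)
    a <- aspt(agg, st)
    n_used <- vapply(attr(b, "trace"), function(t) nrow(t$used), 0)
    idx <- n_used > 0
    expect_equal(as.numeric(a)[idx], unname(as.numeric(b) / n_used)[idx])
    expect_true(all(is.nan(as.numeric(a)[!idx])))
  }
})

test_that("whpt uses abundance-class scores; aspt = bmwp / n", {
  ent <- data.frame(taxon = c("Baetidae", "Perlidae"),
                    score_class1 = c(4, 6), score_class2 = c(5, 7),
                    score_class3 = c(6, 8), score_class4 = c(7, 9),
                    score_occ = c(4.5, 6.5))
  st <- score_table(ent, index = "whpt", rank = "Family", type = "class")
  agg <- fam_agg(c(Baetidae = 150, Perlidae = 3))
  v <- whpt(agg, st, metric = "bmwp", trace_b = TRUE)
  expect_equal(as.numeric(v), 6 + 6)  # class 3 and class 1
  expect_equal(attr(v, "trace")$S1$used$class, c(3, 1))
  expect_equal(as.numeric(whpt(agg, st, metric = "aspt")), 6)
  # single taxon: aspt equals its class score
  expect_equal(as.numeric(whpt(fam_agg(c(Baetidae = 7)), st, "aspt")), 4)
  # occurrence mode reads the presence-only column
  expect_equal(as.numeric(whpt(agg, st, "aspt", occurrence = TRUE)), 5.5)
  # mean equals sum / n
  expect_equal(as.numeric(whpt(agg, st, "aspt")),
               as.numeric(whpt(agg, st, "bmwp")) / 2)
})

test_that("life looks up (flow group, abundance class) scores", {
  fs <- matrix(c(9, 10, 11, 12,
                 7, 7, 7, 7), nrow = 2, byrow = TRUE,
               dimnames = list(c("G1", "G2"), NULL))
  st <- score_table(data.frame(taxon = c("Baetidae", "Perlidae"),
                               group = c("G1", "G2")),
                    index = "life", rank = "Family", type = "flow",
                    score_matrix = fs)
  # single taxon, class 2 of group G1 -> 10
  v1 <- life(fam_agg(c(Baetidae = 50)), st, trace_b = TRUE)
  expect_equal(as.numeric(v1), 10)
  expect_equal(attr(v1, "trace")$S1$used$score, 10)
  # two taxa: mean of 10 and 7
  expect_equal(
    as.numeric(life(fam_agg(c(Baetidae = 50, Perlidae = 2)), st)), 8.5)
})

test_that("psi and epsi give the sensitive-weight percentage", {
  w <- matrix(rep(c(2, 2, 1, 1), 4), nrow = 4,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  st <- score_table(data.frame(taxon = c("Baetidae", "Heptageniidae",
                                         "Perlidae"),
                               group = c("A", "B", "D")),
                    index = "psi", rank = "Family", type = "psi",
                    score_matrix = w, sensitive = c("A", "B"))
  # only sensitive groups present -> 100
  expect_equal(
    as.numeric(psi(fam_agg(c(Baetidae = 5, Heptageniidae = 2)), st)), 100)
  # A+B weight 4, total 5 -> 80
  expect_equal(
    as.numeric(psi(fam_agg(c(Baetidae = 5, Heptageniidae = 2,
                             Perlidae = 1)), st)), 100 * 4 / 5)
  # no scored taxa -> NaN with flag
  vp <- psi(fam_agg(c(Lymnaeidae = 3)), st)
  expect_true(is.nan(as.numeric(vp)))
  expect_match(attr(vp, "flags"), "no scored weight")
  expect_true(all(as.numeric(psi(fam_agg(c(Baetidae = 1, Perlidae = 9)),
                                 st)) >= 0))
  # epsi with empirical taxon weights
  se <- score_table(data.frame(taxon = c("Baetidae", "Perlidae"),
                               weight = c(4, 4),
                               sensitive = c(TRUE, FALSE)),
                    index = "epsi", rank = "Family", type = "epsi")
  expect_equal(
    as.numeric(epsi(fam_agg(c(Baetidae = 1, Perlidae = 1)), se)), 50)
})

test_that("ept equals get_taxa_richness over the EPT orders", {
  agg <- fam_agg(c(Baetidae = 5, Heptageniidae = 1, Perlidae = 2,
                   Hydropsychidae = 4, Lymnaeidae = 9))
  expect_equal(as.numeric(ept(agg)), 4)
  expect_equal(as.numeric(ept(agg, "abundance")), 12)
  expect_equal(as.numeric(ept(agg)),
               as.numeric(get_taxa_richness(
                 agg, c("Ephemeroptera", "Plecoptera", "Trichoptera"),
                 "Order", "Family")))
  expect_equal(as.numeric(ept(fam_agg(c(Lymnaeidae = 3)))), 0)
})

test_that("eptd is log10(1 + selected-family abundance), monotone", {
  st <- score_table(data.frame(taxon = c("Baetidae", "Perlidae")),
                    index = "eptd", rank = "Family", type = "list")
  expect_equal(as.numeric(eptd(fam_agg(c(Lymnaeidae = 5)), st)), 0)
  expect_equal(
    as.numeric(eptd(fam_agg(c(Baetidae = 90, Perlidae = 9)), st)), 2)
  v <- vapply(c(1, 10, 100, 1000), function(n) {
    as.numeric(eptd(fam_agg(c(Baetidae = n)), st))
  }, 0)
  expect_true(all(diff(v) > 0))
})

test_that("igold is one minus the GOLD relative abundance", {
  ref <- tiny_ref_full()
  agg1 <- make_agg(data.frame(Taxon = c("Baetis", "Perla"), S1 = c(3, 2)),
                   ref)
  expect_equal(as.numeric(igold(agg1)), 1)
  agg2 <- make_agg(data.frame(Taxon = "Lymnaea", S1 = 5), ref)
  expect_equal(as.numeric(igold(agg2)), 0)
  agg3 <- make_agg(data.frame(Taxon = c("Baetis", "Lymnaea"),
                              S1 = c(7, 3)), ref)
  expect_equal(as.numeric(igold(agg3)), 0.7)
})

test_that("ibmr weights sensitivity by stenoecy and cover class", {
  st <- score_table(data.frame(taxon = c("Baetidae", "Perlidae"),
                               cs = c(10, 5), e = c(1, 1)),
                    index = "ibmr", rank = "Family", type = "ibmr")
  # single taxon -> its CS
  expect_equal(as.numeric(ibmr(fam_agg(c(Baetidae = 3)), st)), 10)
  # CS=(10,5), E=(1,1), K=(2,1) -> 25/3
  expect_equal(
    as.numeric(ibmr(fam_agg(c(Baetidae = 50, Perlidae = 5)), st)),
    25 / 3)
  # bounded by score range on random abundances
  set.seed(5)
  for (i in 1:5) {
    n <- stats::setNames(rpois(2, 40) + 1, c("Baetidae", "Perlidae"))
    v <- as.numeric(ibmr(fam_agg(n), st))
    expect_gte(v, 5); expect_lte(v, 10)
  }
})

test_that("bioco computes ACI, RCI and the ordinal SBCI class", {
  ref <- tiny_ref()
  agg <- make_agg(data.frame(
    Taxon = c("Baetis", "Perla", "Lymnaea", "Cloeon"),
    S1 = c(5, 3, 0, 2), S2 = c(2, 0, 2, 0), S3 = c(0, 0, 4, 0)), ref)
  b <- bioco(agg, alien = "Lymnaea")
  expect_equal(b$aci, c(0, 0.5, 1))
  expect_equal(b$rci, c(0, 0.5, 1))
  expect_equal(b$sbci, c(0L, 4L, 4L))
  b2 <- bioco(make_agg(data.frame(Taxon = c("Baetis", "Lymnaea"),
                                  S1 = c(85, 15)), ref), "Lymnaea")
  expect_equal(b2$aci, 0.15)
  expect_equal(b2$sbci, 4L)  # rci = 0.5 dominates: class 4
})

test_that("averaged biotic indices stay within their score range", {
  ref <- generate_reference(seed = 1)
  st <- generate_scores(ref, "bmwp", seed = 3)
  sl <- generate_scores(ref, "life", seed = 3)
  sw <- generate_scores(ref, "whpt", seed = 3)
  for (s in 1:5) {
    agg <- rand_fixture(seed = 100 + s, ref = ref)$agg
    a <- as.numeric(aspt(agg, st))
    a <- a[!is.nan(a)]
    expect_true(all(a >= min(st$entries$score) &
                    a <= max(st$entries$score)))
    l <- as.numeric(life(agg, sl))
    l <- l[!is.nan(l)]
    expect_true(all(l >= min(sl$score_matrix) & l <= max(sl$score_matrix)))
    w <- as.numeric(whpt(agg, sw, "aspt"))
    w <- w[!is.nan(w)]
    sc <- as.matrix(sw$entries[, grepl("score_class",
                                       names(sw$entries))])
    expect_true(all(w >= min(sc) & w <= max(sc)))
  }
})

test_that("occurrence data gives the same BMWP/ASPT as any abundances", {
  ref <- generate_reference(seed = 1)
  st <- generate_scores(ref, "bmwp", seed = 2)
  fx <- rand_fixture(seed = 21, ref = ref)
  com_occ <- fx$com
  com_occ[-1] <- lapply(com_occ[-1], function(x) as.integer(x > 0))
  agg_occ <- make_agg(com_occ, ref)
  expect_equal(as.numeric(bmwp(fx$agg, st)),
               as.numeric(bmwp(agg_occ, st)))
  expect_equal(as.numeric(aspt(fx$agg, st)),
               as.numeric(aspt(agg_occ, st)))
})

test_that("rank coherence: species-resolved vs pre-aggregated families", {
  ref <- generate_reference(seed = 1)
  st <- generate_scores(ref, "bmwp", seed = 4)
  fx <- rand_fixture(seed = 31, ref = ref)
  tg <- suppressWarnings(as_biomonitor(fx$com, ref))
  fam <- fx$agg$per_rank$Family
  com_fam <- data.frame(Taxon = fam$Taxon,
                        fam[, fx$agg$samples, drop = FALSE])
  agg_fam <- make_agg(com_fam, ref)
  expect_equal(as.numeric(bmwp(fx$agg, st)),
               as.numeric(bmwp(agg_fam, st)))
  expect_equal(as.numeric(shannon(fx$agg, "Family")),
               as.numeric(shannon(agg_fam, "Family")))
})

test_that("score-table validation and show_scores behave", {
  expect_error(score_table(data.frame(x = 1), "bmwp"), "taxon")
  expect_error(fam_scores(c(Baetidae = Inf)), "non-finite")
  expect_error(
    score_table(data.frame(taxon = "A", score = 1), "bmwp",
                composite = list(Comp = "B")),
    "without a score entry")
  expect_error(bmwp(fam_agg(c(Baetidae = 1)), fam_scores(),
                    tax_lev = "Genus"), "incompatible")
  expect_error(bmwp(fam_agg(c(Baetidae = 1)), "not scores"),
               "score_table")
  expect_error(show_scores("nope"), "available")
  st <- show_scores("bmwp")
  expect_s3_class(st, "score_table")
  expect_identical(st$origin, "synthetic")
  # round trip through the CSV + sidecar format
  p <- tempfile(fileext = ".csv")
  write_scores(st, p)
  st2 <- read_scores(p)
  expect_equal(st2$entries, st$entries)
  expect_equal(st2$composite, st$composite)
  expect_equal(st2$rule$breakpoints, st$rule$breakpoints)
})
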