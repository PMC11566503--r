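# agg with given taxa present in one sample, plus matching trait/space labels
flat_agg <- function(n, taxa = paste0("Tax", seq_along(n))) {
  vec_agg(n, taxa)
}

# distance matrix from a coordinate matrix (Euclidean fixture)
coord_dist <- function(x, labels = paste0("Tax", seq_len(nrow(x)))) {
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(labels, labels)
  d
}

test_that("gower_distance matches the double-loop oracle", {
  blocks <- list(A = c("a1", "a2"), B = c("b1", "b2", "b3"))
  # identical profiles -> 0; opposite single-block binaries -> 1
  t0 <- trait_dataset(data.frame(Taxon = c("x", "y"),
                                 a1 = c(1, 1), a2 = c(0, 0),
                                 b1 = c(0.5, 0.5), b2 = c(0.5, 0.5),
                                 b3 = 0), blocks)
  expect_equal(max(gower_distance(t0)), 0)
  t1 <- trait_dataset(data.frame(Taxon = c("x", "y"),
                                 a1 = c(1, 0), a2 = c(0, 1)),
                      list(A = c("a1", "a2")))
  expect_equal(gower_distance(t1)["x", "y"], 1)
  # oracle equivalence on random fuzzy tables (<= 10 taxa)
  for (s in 1:3) {
    ref <- generate_reference(seed = 2)
    tr <- generate_traits(ref, specialization = 3, seed = s)
    tr <- trait_dataset(as.data.frame(tr)[1:9, ], attr(tr, "blocks"))
    expect_equal(unclass(gower_distance(tr)), gower_oracle(tr),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # a row with no information errors with the taxon name
  tbad <- trait_dataset(data.frame(Taxon = c("x", "y"), a1 = c(1, 0),
                                   a2 = c(0, 0)),
                        list(A = c("a1", "a2")))
  expect_error(gower_distance(tbad), "y")
})

test_that("pcoa reproduces Euclidean distances with zero constants", {
  x <- matrix(c(0, 1, 3, 7), ncol = 1)
  d <- coord_dist(x, letters[1:4])
  for (corr in c("none", "cailliez", "lingoes", "sqrt", "quasi")) {
    sp <- pcoa(d, corr)
    if (corr %in% c("cailliez", "lingoes")) {
      expect_lt(sp$constant, 1e-8)
    }
    if (corr != "sqrt") {
      expect_equal(as.matrix(stats::dist(sp$coordinates)), d,
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("pcoa on an equilateral triple gives 2 axes with unit spacing", {
  d <- matrix(1, 3, 3) - diag(3)
  dimnames(d) <- list(letters[1:3], letters[1:3])
  sp <- pcoa(d)
  expect_equal(ncol(sp$coordinates), 2)
  expect_equal(as.numeric(stats::dist(sp$coordinates)), rep(1, 3),
               tolerance = 1e-8)
})

test_that("cailliez and lingoes remove negative eigenvalues", {
  ref <- generate_reference(seed = 1)
  tr <- generate_traits(ref, specialization = 4, seed = 1)
  tr <- trait_dataset(as.data.frame(tr)[1:10, ], attr(tr, "blocks"))
  g <- gower_distance(tr)
  raw <- pcoa(g)
  expect_lt(min(raw$eigenvalues), -1e-6)  # genuinely non-Euclidean
  for (corr in c("cailliez", "lingoes")) {
    sp <- pcoa(g, corr)
    expect_gt(sp$constant, 0)
    expect_gt(min(sp$eigenvalues), -1e-8 * max(sp$eigenvalues))
  }
  # minimality of the Cailliez constant: 90% of it is not enough
  c1 <- pcoa(g, "cailliez")$constant
  dshort <- g + 0.9 * c1
  diag(dshort) <- 0
  ev <- eigen(-0.5 * (diag(10) - 1 / 10) %*% dshort^2 %*%
                (diag(10) - 1 / 10), symmetric = TRUE,
              only.values = TRUE)$values
  expect_lt(min(ev), -1e-10)
})

test_that("select_pcoa_axes quality criteria behave on Euclidean input", {
  set.seed(8)
  x <- matrix(rnorm(7 * 3), 7, 3)
  d <- coord_dist(x)
  q <- select_pcoa_axes(d)
  m_all <- nrow(q)
  expect_equal(q$corr[m_all], 1, tolerance = 1e-10)
  expect_equal(q$r2[m_all], 1, tolerance = 1e-12)
  expect_equal(q$msd[m_all], 0, tolerance = 1e-12)
  expect_true(all(diff(q$msd) < 1e-12))   # monotone non-increasing
  # eigenvalues (3, 1): r2 at m = 1 is 0.75
  pts <- rbind(c(sqrt(1.5), 0), c(-sqrt(1.5), 0),
               c(0, sqrt(0.5)), c(0, -sqrt(0.5)))
  q2 <- select_pcoa_axes(coord_dist(pts))
  expect_equal(q2$r2[1], 0.75, tolerance = 1e-12)
  expect_true(attr(q2, "recommended") >= 1)
  # criterion dispatch
  for (cr in c("corr", "r2", "msd")) {
    expect_true(is.numeric(attr(select_pcoa_axes(d, criterion = cr),
                                "recommended")))
  }
})

test_that("f_rich equals the shoelace oracle and is hull-monotone", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1))
  sp <- pcoa(coord_dist(pts, c("Tax1", "Tax2", "Tax3")))
  # pcoa coordinates are a rigid motion of the input: hull area preserved
  agg <- flat_agg(c(1, 1, 1))
  expect_equal(as.numeric(f_rich(sp, agg, m = 2)),
               shoelace(pts[, 1], pts[, 2]), tolerance = 1e-10)
  expect_equal(as.numeric(f_rich(sp, agg, m = 2)), 0.5, tolerance = 1e-10)
  # collinear present taxa inside a genuinely 2-D space: degenerate hull
  spc <- pcoa(coord_dist(rbind(c(0, 0), c(1, 1), c(2, 2), c(5, 0)),
                         paste0("Tax", 1:4)))
  v <- f_rich(spc, vec_agg(c(1, 1, 1, 0), paste0("Tax", 1:4)), m = 2)
  expect_true(is.nan(as.numeric(v)))
  expect_match(attr(v, "flags"), "degenerate|S <= m")
  # interior point leaves the hull unchanged; supersets never shrink it
  pts4 <- rbind(pts, c(0.2, 0.2))
  sp4 <- pcoa(coord_dist(pts4, paste0("Tax", 1:4)))
  expect_equal(as.numeric(f_rich(sp4, flat_agg(c(1, 1, 1, 1)), m = 2)),
               0.5, tolerance = 1e-10)
  pts5 <- rbind(pts, c(2, 2))
  sp5 <- pcoa(coord_dist(pts5, paste0("Tax", 1:4)))
  sub <- as.numeric(f_rich(sp5, vec_agg(c(1, 1, 1, 0), paste0("Tax", 1:4)),
                           m = 2))
  full <- as.numeric(f_rich(sp5, flat_agg(rep(1, 4), paste0("Tax", 1:4)),
                            m = 2))
  expect_gte(full, sub - 1e-10)
  expect_error(f_rich(sp, agg, m = 7), "refused")
})

test_that("f_rich computes 3-D hull volumes (qhull backend)", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(.1, .1, .1))
  sp <- pcoa(coord_dist(tet, paste0("Tax", 1:5)))
  v <- as.numeric(f_rich(sp, flat_agg(rep(1, 5)), m = 3))
  expect_equal(v, 1 / 6, tolerance = 1e-6)
})

test_that("f_disp is the weighted mean distance to the weighted centroid", {
  sp <- pcoa(coord_dist(matrix(c(0, 1), ncol = 1), c("Tax1", "Tax2")))
  expect_equal(as.numeric(f_disp(sp, flat_agg(c(1, 1)), m = 1)), 0.5)
  expect_equal(as.numeric(f_disp(sp, vec_agg(c(5, 0), c("Tax1", "Tax2")),
                                 m = 1)), 0)
  # rotation invariance
  set.seed(2)
  x <- matrix(rnorm(12), 6, 2)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  n <- rpois(6, 5) + 1
  d1 <- f_disp(pcoa(coord_dist(x)), flat_agg(n), m = 2)
  d2 <- f_disp(pcoa(coord_dist(x %*% R)), flat_agg(n), m = 2)
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-9)
  # abundance rescaling invariance
  d3 <- f_disp(pcoa(coord_dist(x)), flat_agg(n * 13), m = 2)
  expect_equal(as.numeric(d1), as.numeric(d3), tolerance = 1e-12)
})

test_that("f_eve is 1 for evenly spread communities and lives in [0,1]", {
  x <- matrix(c(0, 1, 2, 3), ncol = 1)
  sp <- pcoa(coord_dist(x, paste0("Tax", 1:4)))
  expect_equal(as.numeric(f_eve(sp, flat_agg(rep(2, 4)), m = 1)), 1)
  v <- f_eve(sp, vec_agg(c(1, 1, 0, 0), paste0("Tax", 1:4)), m = 1)
  expect_true(is.nan(as.numeric(v)))
  expect_match(attr(v, "flags"), "S < 3")
  set.seed(4)
  for (i in 1:5) {
    y <- matrix(rnorm(14), 7, 2)
    n <- rpois(7, 6) + 1
    e <- as.numeric(f_eve(pcoa(coord_dist(y)), flat_agg(n), m = 2))
    expect_gte(e, 0); expect_lte(e, 1)
  }
})

test_that("f_divs (Rao Q) and f_red match brute force", {
  d <- matrix(1, 2, 2) - diag(2)
  dimnames(d) <- list(c("Tax1", "Tax2"), c("Tax1", "Tax2"))
  expect_equal(as.numeric(f_divs(d, flat_agg(c(1, 1)))), 0.5)
  expect_equal(as.numeric(f_divs(d, vec_agg(c(3, 0),
                                            c("Tax1", "Tax2")))), 0)
  # oracle: double loop on random data
  set.seed(6)
  y <- matrix(rnorm(16), 8, 2)
  dd <- coord_dist(y)
  n <- rpois(8, 10) + 1
  p <- n / sum(n)
  q <- 0
  for (i in 1:8) for (j in 1:8) q <- q + p[i] * p[j] * dd[i, j]
  expect_equal(as.numeric(f_divs(dd, flat_agg(n))), q, tolerance = 1e-10)
  expect_lte(as.numeric(f_divs(dd, flat_agg(n))), max(dd))
  # redundancy: all pairwise d = 1 -> 0; d = 0 -> Gini-Simpson
  agg <- flat_agg(c(2, 3))
  d1 <- matrix(1, 2, 2) - diag(2)
  dimnames(d1) <- list(c("Tax1", "Tax2"), c("Tax1", "Tax2"))
  expect_equal(as.numeric(f_red(d1, agg)), 0, tolerance = 1e-12)
  d0 <- matrix(0, 2, 2)
  dimnames(d0) <- dimnames(d1)
  expect_equal(as.numeric(f_red(d0, agg)),
               as.numeric(simpson(agg)), tolerance = 1e-12)
  expect_gte(as.numeric(f_red(dd / max(dd), flat_agg(n))), 0)
})

test_that("cwm is the abundance-weighted mean profile", {
  blocks <- list(A = c("a1", "a2"))
  tr <- trait_dataset(data.frame(Taxon = c("Tax1", "Tax2"),
                                 a1 = c(2, 4), a2 = c(0.5, 0.25)),
                      blocks)
  agg <- flat_agg(c(1, 3))
  out <- cwm(tr, agg)
  expect_equal(out$a1, 3.5)
  # single taxon -> its own profile
  expect_equal(cwm(tr, vec_agg(c(2, 0), c("Tax1", "Tax2")))$a1, 2)
  # fuzzy block sums preserved at 1
  ref <- generate_reference(seed = 2)
  fx <- rand_fixture(seed = 6, ref = ref)
  trf <- average_traits(assign_traits(fx$agg, generate_traits(ref,
                                                              seed = 6),
                                      "Family"))
  cw <- cwm(trf, fx$agg, "Family")
  for (b in attr(trf, "blocks")) {
    expect_equal(rowSums(cw[, b, drop = FALSE]),
                 rep(1, nrow(cw)), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("tsi/csi score specialists 1 and generalists 0", {
  blocks <- list(A = c("a1", "a2"), B = c("b1", "b2", "b3"))
  tr <- trait_dataset(data.frame(
    Taxon = c("Tax1", "Tax2"),
    a1 = c(1, 0.5), a2 = c(0, 0.5),
    b1 = c(1, 1 / 3), b2 = c(0, 1 / 3), b3 = c(0, 1 / 3)), blocks)
  t <- tsi(tr)
  expect_equal(unname(t["Tax1"]), 1)
  expect_equal(unname(t["Tax2"]), 0)
  v <- as.numeric(csi(tr, flat_agg(c(1, 1))))
  expect_equal(v, 0.5)
  expect_gte(v, min(t)); expect_lte(v, max(t))
})

test_that("fuzzy_trait_ratio and flow_t use block-normalised affinities", {
  blocks <- list(FL = c("f1", "f2", "f3", "f4"))
  tr <- trait_dataset(data.frame(Taxon = "Tax1", f1 = 1, f2 = 1, f3 = 1,
                                 f4 = 1), blocks)
  agg <- flat_agg(4, "Tax1")
  expect_equal(as.numeric(fuzzy_trait_ratio(tr, agg, "f1",
                                            blocks$FL)), 0.25)
  expect_equal(as.numeric(fuzzy_trait_ratio(tr, agg, blocks$FL,
                                            blocks$FL)), 1)
  ft <- flow_t(tr, agg, "FL")
  expect_equal(as.numeric(ft), 0.25)
  expect_equal(attr(ft, "index"), "flow_t")
  # zero denominator flags NaN
  tr2 <- trait_dataset(data.frame(Taxon = "Tax1", f1 = 0, f2 = 0, f3 = 1,
                                  f4 = 0), blocks)
  z <- fuzzy_trait_ratio(tr2, agg, "f1", "f2")
  expect_true(is.nan(as.numeric(z)))
  expect_match(attr(z, "flags"), "zero denominator")
  expect_error(fuzzy_trait_ratio(tr, agg, "nope", "f1"), "unknown")
})
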