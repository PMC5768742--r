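genome1 <- genome_layout("c1", 1e6)
centers1 <- structure(data.frame(chrom = rep("c1", 5),
                                 pos = c(1e5, 3e5, 5e5, 7e5, 9e5)),
                      class = c("boundary_set", "data.frame"),
                      genome = genome1)

test_that("occupancy profiles have the documented geometry and closed forms", {
  const <- signal_track("c1", 0, 1e6, 2.5)
  prof <- occupancy_profile(const, centers1, flank = 4000, window = 80)
  expect_equal(nrow(prof), 100)                      # 2*4000/80 windows
  expect_equal(prof$occupancy, rep(2.5, 100))
  expect_equal(range(prof$offset), c(-3960, 3960))
  # delta signal exactly at each center: only the central window non-zero
  delta <- signal_track(rep("c1", 5), centers1$pos, centers1$pos + 1, 80)
  pd <- occupancy_profile(delta, centers1)
  expect_true(all(pd$occupancy[pd$offset != 40] == 0))
  expect_gt(pd$occupancy[pd$offset == 40], 0)
  # centers too close to the chromosome end are clipped and flagged
  edge <- structure(data.frame(chrom = "c1", pos = 1000),
                    class = c("boundary_set", "data.frame"),
                    genome = genome1)
  pe <- occupancy_profile(const, edge)
  expect_equal(attr(pe, "clipped"), 1L)
})

test_that("occupancy profiles are linear in the track", {
  set.seed(19)
  s1 <- seq(0, 9.9e5, 1e4)
  t1 <- signal_track("c1", s1, s1 + 1e4, runif(length(s1)))
  s2 <- seq(0, 9.8e5, 2e4)
  t2 <- signal_track("c1", s2, s2 + 5e3, runif(length(s2)))
  sum_track <- NULL # profiles add even when computed separately
  p1 <- occupancy_profile(t1, centers1)
  p2 <- occupancy_profile(t2, centers1)
  # build the sum track on the union of breakpoints
  brk <- sort(unique(c(0, t1$start, t1$end, t2$start, t2$end, 1e6)))
  f1 <- tadscape:::track_integrator(t1)
  f2 <- tadscape:::track_integrator(t2)
  v <- (f1("c1", brk[-1]) - f1("c1", brk[-length(brk)]) +
          f2("c1", brk[-1]) - f2("c1", brk[-length(brk)])) / diff(brk)
  ts <- signal_track("c1", brk[-length(brk)], brk[-1], v)
  ps <- occupancy_profile(ts, centers1)
  expect_equal(ps$occupancy, p1$occupancy + p2$occupancy, tolerance = 1e-9)
})

test_that("shuffled background is seeded, constant-correct and unbiased", {
  const <- signal_track("c1", 0, 1e6, 1.7)
  bg1 <- shuffled_background(const, c(c1 = 5), genome1, n_shuffles = 3,
                             seed = 99)
  expect_equal(bg1$occupancy, rep(1.7, 100))
  bg2 <- shuffled_background(const, c(c1 = 5), genome1, n_shuffles = 3,
                             seed = 99)
  expect_identical(bg1, bg2)                        # determinism
  # law of large numbers: window means approach the track mean
  set.seed(23)
  vals <- runif(100)
  tr <- signal_track("c1", seq(0, 9.9e5, 1e4), seq(1e4, 1e6, 1e4), vals)
  m <- mean(vals)
  bg <- shuffled_background(tr, c(c1 = 40), genome1, n_shuffles = 50,
                            seed = 7)
  se <- sd(vals) / sqrt(40 * 50)
  expect_true(all(abs(bg$occupancy - m) < max(6 * se, 0.05)))
})

test_that("enrichment ratios handle equality and degenerate backgrounds", {
  obs <- data.frame(offset = c(-40, 40), occupancy = c(2, 4))
  bg <- data.frame(offset = c(-40, 40), occupancy = c(2, 0))
  er <- enrichment_ratio(obs, bg)
  expect_equal(er$ratio[1], 1)
  expect_true(is.na(er$ratio[2]) && er$flagged[2])  # no infinities
  expect_error(enrichment_ratio(obs, data.frame(offset = 0, occupancy = 1)),
               "grids")
})

test_that("pair sites respect the gap rule and are symmetric in loci", {
  a <- peak_set("c1", c(100, 100, 100), c(200, 200, 200),
                protein = "A")[1, , drop = FALSE]
  class(a) <- c("peak_set", "data.frame"); attr(a, "protein") <- "A"
  mk <- function(s, e, prot) peak_set("c1", s, e, protein = prot)
  expect_equal(nrow(pair_sites(mk(100, 200, "A"), mk(150, 250, "B"), 0)), 1)
  expect_equal(nrow(pair_sites(mk(100, 200, "A"), mk(500, 600, "B"), 100)), 0)
  expect_equal(nrow(pair_sites(mk(100, 200, "A"), mk(300, 400, "B"), 200)), 1)
  # symmetry: both orders mark the same loci
  set.seed(29)
  s <- sort(sample(1e5, 30)) * 10
  t <- sort(sample(1e5, 40)) * 10
  pa <- peak_set("c1", s, s + 300, protein = "A")
  pb <- peak_set("c1", t, t + 300, protein = "B")
  ab <- pair_sites(pa, pb, 200)
  ba <- pair_sites(pb, pa, 200)
  # each AB site has a BA site within peak-scale distance and vice versa
  expect_true(all(vapply(ab$pos, function(p) any(abs(ba$pos - p) < 1e4),
                         logical(1))))
  expect_equal(nrow(ab) > 0, nrow(ba) > 0)
})

test_that("colocalization applies the 2 kb rule per border and per site", {
  sites <- data.frame(chrom = "c1", pos = c(1e5 + 1500, 3e5 + 3000, 5e5))
  co <- colocalize(sites, centers1, tol = 2000)
  expect_equal(co$borders_hit, 2)         # center 1 (1.5 kb) and center 3
  expect_equal(co$sites_at_borders, 2)    # 3 kb site misses
  expect_equal(co$borders_hit_prop, 2 / 5)
  # every center given one site at distance zero
  all0 <- data.frame(chrom = "c1", pos = centers1$pos)
  expect_equal(colocalize(all0, centers1)$borders_hit_prop, 1.0)
  # multiple qualifying sites still count a border once
  dup <- data.frame(chrom = "c1", pos = c(1e5 - 10, 1e5 + 10))
  expect_equal(colocalize(dup, centers1)$borders_hit, 1)
})

test_that("planted at-border fractions are recovered by colocalize", {
  set.seed(31)
  n <- 400
  centers <- structure(
    data.frame(chrom = "c1", pos = sort(sample(seq(5e3, 9.95e6, 1e4), n))),
    class = c("boundary_set", "data.frame"),
    genome = genome_layout("c1", 1e7))
  f <- 0.6
  has <- runif(n) < f
  sites <- data.frame(chrom = "c1",
                      pos = centers$pos[has] + round(rnorm(sum(has), 0, 100)))
  co <- colocalize(sites, centers, tol = 2000)
  expect_lt(abs(co$borders_hit_prop - f), 3 * sqrt(f * (1 - f) / n))
})

test_that("border enrichment test equals exact hypergeometric enumeration", {
  # no association
  expect_equal(border_enrichment_test(5, 10, 0.5)$p.value, 1.0)
  # [[10,0],[0,10]]: enumerate the hypergeometric support directly
  ft <- stats::fisher.test(matrix(c(10, 0, 0, 10), 2))
  probs <- dhyper(0:10, 10, 10, 10)
  p_exact <- sum(probs[probs <= probs[11] * (1 + 1e-7)])
  expect_equal(ft$p.value, p_exact, tolerance = 1e-12)
  expect_equal(border_enrichment_test(10, 10, 0)$p.value, p_exact,
               tolerance = 1e-12)
  # zero margin: p = 1
  expect_equal(border_enrichment_test(0, 10, 0)$p.value, 1.0)
})

test_that("border venn partitions sum to the border count", {
  set.seed(37)
  sets <- list(
    A = peak_set("c1", centers1$pos[1:3] - 150, centers1$pos[1:3] + 150,
                 protein = "A"),
    B = peak_set("c1", centers1$pos[2:4] - 150, centers1$pos[2:4] + 150,
                 protein = "B"))
  v <- border_venn(sets, centers1, tol = 2000)
  expect_equal(sum(v), nrow(centers1))
  expect_equal(as.vector(v["A&B"]), 2)
  expect_equal(as.vector(v["none"]), 1)
})
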