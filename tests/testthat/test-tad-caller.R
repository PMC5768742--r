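test_that("quality table matches the O(n^4) brute-force oracle", {
  set.seed(3)
  for (gamma in c(0, 0.7, 1)) {
    M <- random_sym(8)
    cm <- dense_cm(M)
    qt <- domain_quality(cm, gamma)
    expect_equal(qt$q, brute_quality(M, gamma), tolerance = 1e-12)
    expect_equal(qt$mu, colMeans(qt$q, na.rm = TRUE))
    expect_equal(qt$qprime, sweep(qt$q, 2, qt$mu, `-`))
  }
})

test_that("quality has the closed-form small cases", {
  cval <- 3.5
  cm <- dense_cm(matrix(c(0, cval, cval, 0), 2))
  qt <- domain_quality(cm, gamma = 1)
  expect_equal(qt$q[1, 1], cval)      # q(0,1) = c / 1^gamma
  expect_equal(qt$mu[1], cval)
  expect_equal(qt$qprime[1, 1], 0)
  # gamma = 0: q equals the raw interval sum over off-diagonal pairs
  M <- random_sym(6)
  qt0 <- domain_quality(dense_cm(M), gamma = 0)
  expect_equal(qt0$q[2, 3], sum(M[2:5, 2:5][upper.tri(M[2:5, 2:5])]))
})

test_that("the segmentation DP attains the exhaustive-enumeration optimum", {
  set.seed(5)
  for (rep in 1:8) {
    n <- sample(6:12, 1)
    M <- random_sym(n)
    cm <- dense_cm(M)
    for (centering in c("none", "mean")) {
      cfg <- caller_config(gamma = runif(1, 0.3, 1.5), centering = centering)
      dom <- call_domains_dp(cm, cfg)
      sc <- dp_score_matrix(cm, cfg)
      expect_equal(sum(dom$score), brute_best_segmentation(sc, 2),
                   tolerance = 1e-9)
    }
  }
})

test_that("canonical segmentations are recovered", {
  # two dense blocks with weak off-block contacts: exactly the two blocks
  M <- matrix(0.5, 8, 8); M[1:4, 1:4] <- 5; M[5:8, 5:8] <- 5; diag(M) <- 6
  for (centering in c("none", "mean")) {
    dom <- call_domains_dp(dense_cm(M),
                           caller_config(gamma = 0.9, centering = centering))
    expect_equal(dom$start_bin, c(1, 5))
    expect_equal(dom$end_bin, c(4, 8))
  }
  # all-zero matrix: no domains
  fr <- uniform_fragments(6, 100)
  zero <- contact_matrix(integer(0), integer(0), numeric(0),
                         fragment_axis(fr))
  expect_equal(nrow(call_domains_dp(zero, caller_config())), 0)
  # one dense block spanning the whole axis: a single covering domain
  M1 <- matrix(4, 6, 6)
  dom1 <- call_domains_dp(dense_cm(M1), caller_config(gamma = 0.5))
  expect_equal(nrow(dom1), 1)
  expect_equal(c(dom1$start_bin, dom1$end_bin), c(1, 6))
  # chromosome shorter than min_domain_bins: empty set
  tiny <- dense_cm(matrix(2, 1, 1))
  expect_equal(nrow(call_domains_dp(tiny, caller_config())), 0)
})

test_that("called domains are invariant to global scaling and never overlap", {
  set.seed(7)
  M <- random_sym(15, 6)
  cm <- dense_cm(M)
  cm10 <- cm
  cm10$counts <- cm$counts * 10
  for (centering in c("none", "mean")) {
    cfg <- caller_config(gamma = 0.8, centering = centering)
    d1 <- call_domains_dp(cm, cfg)
    d2 <- call_domains_dp(cm10, cfg)
    expect_equal(d1[c("start_bin", "end_bin")], d2[c("start_bin", "end_bin")])
    if (nrow(d1) > 1)
      expect_true(all(d1$start_bin[-1] > d1$end_bin[-nrow(d1)]))
  }
})

test_that("read-desert fallback re-annotates only affected chromosomes", {
  set.seed(9)
  # two chromosomes; chromosome c2 has a 5-bin desert abutting a boundary
  M <- matrix(0.2, 20, 20)
  M[1:8, 1:8] <- 5; M[9:14, 9:14] <- 5; M[15:20, 15:20] <- 5
  M[9:13, ] <- 0; M[, 9:13] <- 0       # desert right after first domain
  fr <- uniform_fragments(40, 100, c("c1", "c2"))
  ax <- fragment_axis(fr)
  big <- matrix(0, 40, 40)
  big[1:20, 1:20] <- random_sym(20, 5) + 1   # c1: fully covered
  big[21:40, 21:40] <- M                     # c2: desert at bins 29..33
  idx <- which(upper.tri(big, diag = TRUE) & big != 0, arr.ind = TRUE)
  cm <- contact_matrix(idx[, 1], idx[, 2], big[idx], ax)
  cfg <- caller_config(gamma = 0.9, desert_min = 3)
  dom <- call_domains_dp(cm, cfg)
  out <- readdesert_fallback(cm, dom, cfg)
  expect_equal(attr(out, "fallback_chroms"), "c2")
  expect_true(all(out$gamma_used[out$chrom == "c2"] == cfg$gamma_fallback))
  expect_true(all(out$gamma_used[out$chrom == "c1"] == cfg$gamma))
  expect_equal(nrow(attr(out, "deserts")), 1)
  # no masked bins: identical output
  cm1 <- dense_cm(random_sym(10, 5) + 1)
  d1 <- call_domains_dp(cm1, cfg)
  out1 <- readdesert_fallback(cm1, d1, cfg)
  expect_equal(out1$start_bin, d1$start_bin)
  expect_equal(out1$end_bin, d1$end_bin)
  expect_equal(out1$gamma_used, d1$gamma_used)
  expect_equal(attr(out1, "fallback_chroms"), character(0))
  # masked run far from all boundaries: no re-annotation
  M3 <- matrix(3, 16, 16) + diag(3, 16)
  M3[7:10, ] <- 0; M3[, 7:10] <- 0
  M3[1:4, 1:4] <- 9; M3[13:16, 13:16] <- 9
  cm3 <- dense_cm(M3)
  cfg3 <- caller_config(gamma = 0.2, desert_min = 3, centering = "mean")
  d3 <- call_domains_dp(cm3, cfg3)
  keep <- d3$end_bin < 5 | d3$start_bin > 12   # only far-from-desert domains
  out3 <- readdesert_fallback(cm3, d3[keep, ], cfg3)
  expect_equal(attr(out3, "fallback_chroms"), character(0))
})

test_that("boundary centers are junction midpoints", {
  df <- data.frame(chrom = c("c1", "c1", "c1"),
                   start_bin = c(1, 7, 12), end_bin = c(5, 11, 20),
                   start_bp = c(0, 7000, 12000),
                   end_bp = c(5000, 11000, 20000),
                   score = 1, gamma_used = 0.9)
  dom <- tadscape:::new_domain_set(df, "TAD",
                                   list(genome = genome_layout("c1", 2e4),
                                        kind = "fragment"))
  ctr <- boundary_centers(dom)
  expect_equal(nrow(ctr), 2)                 # 3 domains -> 2 centers
  expect_equal(ctr$pos, c(6000, 11500))      # floor((5000+7000)/2) etc.
  # contiguous domains: center at the shared coordinate
  df2 <- df[1:2, ]; df2$start_bp[2] <- 5000
  dom2 <- tadscape:::new_domain_set(df2, "TAD",
                                    list(genome = genome_layout("c1", 2e4),
                                         kind = "fragment"))
  expect_equal(boundary_centers(dom2)$pos, 5000)
})

test_that("contiguity counts same-fragment junctions", {
  df <- data.frame(chrom = "c1", start_bin = c(1, 6, 15),
                   end_bin = c(5, 9, 20),
                   start_bp = c(0, 600, 1500), end_bp = c(500, 900, 2000),
                   score = 1, gamma_used = 0.9)
  dom <- tadscape:::new_domain_set(df, "TAD",
                                   list(genome = genome_layout("c1", 2e3),
                                        kind = "fragment"))
  ct <- contiguity_fraction(dom)
  expect_equal(ct$table$gap_fragments, c(0L, 5L))
  expect_equal(ct$fraction, 0.5)             # one gap-0, one gap-5 junction
  expect_equal(ct$table$same_fragment, c(TRUE, FALSE))
})

test_that("TADs nest into super-TADs at the 75% inclusion rule", {
  genome <- genome_layout("c1", 1e5)
  mk <- function(s, e, level = "TAD")
    tadscape:::new_domain_set(
      data.frame(chrom = "c1", start_bin = NA, end_bin = NA,
                 start_bp = s, end_bp = e, score = 1, gamma_used = 0.9),
      level, list(genome = genome, kind = "fragment"))
  sup <- mk(c(10000, 60000), c(40000, 90000), "super-TAD")
  # 80% inside the first super-TAD -> assigned
  tads <- mk(c(8000, 35000, 45000), c(18000, 45000, 55000))
  nst <- nest_domains(tads, sup)
  expect_equal(nst$assignment$localization,
               c("super-TAD", "unassigned", "inter-super-TAD"))
  # 50% inside at threshold 0.75 -> unassigned; at 0.5 -> assigned
  nst2 <- nest_domains(mk(35000, 45000), sup, inclusion = 0.5)
  expect_equal(nst2$assignment$localization, "super-TAD")
  # counts histogram sums to assigned TADs
  expect_equal(sum(nst$counts$n_tads), 2)
})

test_that("domain size statistics match closed forms", {
  genome <- genome_layout("c1", 1e6)
  df <- data.frame(chrom = "c1", start_bin = NA, end_bin = NA,
                   start_bp = c(0, 10000, 100000),
                   end_bp = c(3000, 23000, 560000),
                   score = 1, gamma_used = 0.9)
  dom <- tadscape:::new_domain_set(df, "TAD",
                                   list(genome = genome, kind = "fragment"))
  st <- domain_size_stats(dom)
  expect_equal(st$median_bp, 13000)          # sizes 3, 13, 460 kb
  expect_equal(st$n_domains, 3)
  one <- dom[3, ]
  attr(one, "genome") <- genome
  st1 <- domain_size_stats(tadscape:::new_domain_set(
    data.frame(chrom = "c1", start_bin = NA, end_bin = NA, start_bp = 0,
               end_bp = 5e5, score = 1, gamma_used = 0.9), "TAD",
    list(genome = genome, kind = "fragment")))
  expect_equal(st1$coverage, 0.5)
})

test_that("domain sets round-trip through BED", {
  set.seed(13)
  M <- random_sym(12, 6)
  dom <- call_domains_dp(dense_cm(M), caller_config(gamma = 0.7))
  path <- withr::local_tempfile(fileext = ".bed")
  write_domains(dom, path)
  back <- read_domains(path)
  expect_equal(back$start_bp, dom$start_bp)
  expect_equal(back$end_bp, dom$end_bp)
  expect_equal(back$gamma_used, dom$gamma_used)
})

test_that("super-TAD calling recovers planted super blocks", {
  des <- small_design(genome_mb = 3, depth = 8e6, seed = 17)
  fr <- make_fragment_map(des)
  tr <- plant_domains(des, fr)
  mat <- simulate_contact_matrix(des, fr, tr)
  sup <- call_supertads(mat, caller_config())
  expect_gt(nrow(sup), 0)
  expect_equal(attr(sup, "level"), "super-TAD")
  nst <- nest_domains(tr$tads, sup)
  tab <- table(tr$tad_in_super,
               nst$assignment$localization == "super-TAD")
  agreement <- (tab["TRUE", "TRUE"] + tab["FALSE", "FALSE"]) / sum(tab)
  expect_gt(agreement, 0.6)
})
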