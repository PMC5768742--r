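# Dense matrix whose entries depend only on the distance bin: the
# distance-normalised machinery must treat it as exactly expected.
decay_cm <- function(n, width = 100, binwidth = 200,
                     f = function(b) 50 / (b + 1), boost_block = NULL,
                     boost = 1) {
  M <- matrix(0, n, n)
  for (d in seq_len(n - 1)) {
    b <- floor(d * width / binwidth)
    M[cbind(seq_len(n - d), seq_len(n - d) + d)] <- f(b)
  }
  M <- M + t(M)
  if (!is.null(boost_block))
    M[boost_block[[1]], boost_block[[2]]] <-
      M[boost_block[[1]], boost_block[[2]]] * boost
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  dense_cm(M, width)
}

mk_dom <- function(cm, s, e) {
  tab <- cm$axis$table
  data.frame(chrom = tab$chrom[s], start_bin = s, end_bin = e,
             start_bp = tab$start[s], end_bp = tab$end[e])
}

test_that("expected-by-distance reproduces a planted decay", {
  cm <- decay_cm(80)
  ex <- expected_by_distance(cm, binwidth = 200, max_distance = 8000)
  e <- ex$c1
  filled <- which(e$n_pairs > 0)
  expect_equal(e$mean[filled], 50 / (filled - 1 + 1),
               tolerance = 1e-12)
  # constant matrix: constant expectation
  cmc <- decay_cm(40, f = function(b) 7)
  exc <- expected_by_distance(cmc, binwidth = 200, max_distance = 4000)
  expect_true(all(abs(exc$c1$mean[exc$c1$n_pairs > 0] - 7) < 1e-12))
  # empty distance bins are flagged with NA, not a value
  expect_true(all(is.na(e$mean[e$n_pairs == 0])))
})

test_that("condensation is the mean over intra-TAD pairs", {
  M <- matrix(4, 3, 3); diag(M) <- 0
  cm <- dense_cm(M, width = 2000)     # one 6 kb TAD, within the 5-20 kb set
  dom <- tadscape:::new_domain_set(
    cbind(mk_dom(cm, 1, 3), score = 1, gamma_used = 0.9), "TAD", cm$axis)
  ct <- condensation(cm, dom)
  expect_equal(ct$condensation, 4)
  expect_equal(ct$n_pairs, 3L)
  expect_true(ct$included)
  # a zero-ligation fragment is excluded: mean over the remaining pair
  M2 <- M; M2[2, ] <- 0; M2[, 2] <- 0; M2[1, 3] <- 10; M2[3, 1] <- 10
  cm2 <- dense_cm(M2, width = 2000)
  ct2 <- condensation(cm2, dom)
  expect_equal(ct2$n_fragments_used, 2)
  expect_equal(ct2$condensation, 10)
  expect_equal(ct2$n_pairs, 1L)
  # size flag
  dom_small <- tadscape:::new_domain_set(
    cbind(mk_dom(cm, 1, 2), score = 1, gamma_used = 0.9), "TAD", cm$axis)
  expect_false(condensation(cm, dom_small)$included)  # 4 kb < 5 kb
})

test_that("planted within-TAD boosts show up as condensation ratios", {
  des <- small_design(genome_mb = 1, depth = 3e6, seed = 71)
  fr <- make_fragment_map(des)
  tr <- plant_domains(des, fr)
  tr$tad_boost <- rep(c(3, 6), length.out = nrow(tr$tads))
  mat <- simulate_contact_matrix(des, fr, tr, seed = 72)
  ct <- condensation(mat, tr$tads)
  ok <- ct$included & !is.na(ct$condensation)
  m3 <- mean(ct$condensation[ok & tr$tad_boost == 3])
  m6 <- mean(ct$condensation[ok & tr$tad_boost == 6])
  expect_equal(m6 / m3, 2, tolerance = 0.25)
})

test_that("pair enrichment is exactly 1 on an expectation-valued matrix", {
  cm <- decay_cm(100)
  ex <- expected_by_distance(cm, binwidth = 200, max_distance = 10000)
  A <- cbind(mk_dom(cm, 5, 20), score = 1, gamma_used = 0.9)
  B <- cbind(mk_dom(cm, 21, 40), score = 1, gamma_used = 0.9)
  pe <- pair_enrichment(cm, A, B, ex)
  expect_equal(pe$ratio, 1.0, tolerance = 1e-9)
  expect_equal(pe$n_pairs_used + pe$n_pairs_skipped, 16L * 20L)
  # distance normalisation: adjacent and distant blocks both ratio 1
  Cfar <- cbind(mk_dom(cm, 70, 90), score = 1, gamma_used = 0.9)
  pe2 <- pair_enrichment(cm, A, Cfar, ex)
  expect_equal(pe2$ratio, 1.0, tolerance = 1e-9)
  expect_error(pair_enrichment(cm, A, A, ex), "disjoint")
})

test_that("a planted cross-block boost is recovered", {
  cm <- decay_cm(300, boost_block = list(100:140, 141:180), boost = 2)
  ex <- expected_by_distance(cm, binwidth = 200, max_distance = 30000)
  A <- cbind(mk_dom(cm, 100, 140), score = 1, gamma_used = 0.9)
  B <- cbind(mk_dom(cm, 141, 180), score = 1, gamma_used = 0.9)
  pe <- pair_enrichment(cm, A, B, ex)
  expect_equal(pe$ratio, 2.0, tolerance = 0.2)
})

test_that("neighbour type summary groups and bootstraps correctly", {
  enr <- data.frame(tad_a = 1:4, tad_b = 2:5, chrom = "c1",
                    ratio = 1, n_pairs_used = 10, n_pairs_skipped = 0)
  cls <- structure(data.frame(cluster = 1,
                              major_type = c("active", "active", "inactive",
                                             "inactive", "inactive")),
                   class = c("domain_class_table", "data.frame"))
  nts <- neighbor_type_summary(enr, cls, n_boot = 50, seed = 1)
  expect_true(all(nts$mean_ratio == 1))
  expect_setequal(nts$type_pair, c("A-A", "A-I", "I-I"))
  expect_false("P-P" %in% nts$type_pair)   # no polycomb pairs -> absent
  expect_equal(sum(nts$n_pairs), 4)
})

test_that("super-TAD contact contrast separates planted nesting", {
  des <- small_design(genome_mb = 2, depth = 5e6, seed = 73)
  fr <- make_fragment_map(des)
  tr <- plant_domains(des, fr)
  mat <- suppressWarnings(ice_normalize(simulate_contact_matrix(des, fr, tr)))
  ex <- expected_by_distance(mat)
  enr <- adjacent_pair_enrichment(mat, tr$tads, ex)
  nst <- nest_domains(tr$tads, tr$supertads)
  ctr <- supertad_contact_contrast(enr, nst)
  expect_gt(ctr$contrast, 1.2)      # super boost 2 on cross-TAD contacts
  # null: no super structure in the matrix
  des0 <- small_design(genome_mb = 2, depth = 5e6, seed = 74,
                       super_boost = 1, within_boost = 1,
                       neighbor_boost = c())
  tr0 <- plant_domains(des0, fr)
  mat0 <- suppressWarnings(ice_normalize(simulate_contact_matrix(des0, fr, tr0)))
  enr0 <- adjacent_pair_enrichment(mat0, tr0$tads,
                                   expected_by_distance(mat0))
  ctr0 <- supertad_contact_contrast(enr0, nest_domains(tr0$tads,
                                                       tr0$supertads))
  expect_equal(ctr0$contrast, 1, tolerance = 0.15)
})

test_that("condensation parity test behaves under equal planted boosts", {
  # balanced type frequencies: type labels carry no size information, so
  # equal boosts must give a null permutation test
  eqp <- c(A = 0.25, I = 0.25, P = 0.25, U = 0.25)
  des <- small_design(genome_mb = 1.5, depth = 4e6, seed = 75,
                      type_probs_super = eqp, type_probs_inter = eqp)
  fr <- make_fragment_map(des)
  tr <- plant_domains(des, fr)
  mat <- simulate_contact_matrix(des, fr, tr)
  ct <- condensation(mat, tr$tads)
  truthmap <- c(A = "active", I = "inactive", P = "polycomb",
                U = "undetermined")
  cls <- structure(data.frame(cluster = 1,
                              major_type = truthmap[tr$tad_type]),
                   class = c("domain_class_table", "data.frame"))
  out <- condensation_parity_test(ct, cls, n_perm = 300, seed = 3)
  expect_gt(out$p.value, 0.01)
  expect_lt(abs(out$observed_diff) / mean(out$group_means), 0.5)
})
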