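test_that("signed z-scores honor magnitude and direction", {
  expect_equal(signed_z(0.05, 1), 1.959964, tolerance = 1e-6)
  expect_equal(signed_z(0.05, -2.5), -1.959964, tolerance = 1e-6)
  expect_equal(signed_z(1, 7), 0)
  expect_error(signed_z(0, 1), "p must be")
  expect_error(signed_z(-0.1, 1), "p must be")
  # log-space path stays finite and accurate far below double range
  z_log <- signed_z(log(1e-320), 1, log_p = TRUE)
  expect_true(is.finite(z_log))
  expect_equal(z_log, abs(qnorm(1e-320 / 2)), tolerance = 1e-10)
  z_deep <- signed_z(-900 * log(10), 1, log_p = TRUE)  # p = 10^-900
  expect_gt(z_deep, 64); expect_lt(z_deep, 65)
})

test_that("the weighted meta statistic follows its printed algebra", {
  # identical studies reproduce the single-study p
  for (z in c(-2.3, 0, 1.7)) {
    m <- stouffer_meta(z, 500, z, 500)
    expect_equal(m$Z, z)
    expect_equal(m$meta_p, 2 * pnorm(-abs(z)), tolerance = 1e-14)
  }
  # direct arithmetic: (750*2 + 590*1) / 1340
  m2 <- stouffer_meta(2.0, 750, 1.0, 590)
  expect_equal(m2$Z, 2090 / 1340, tolerance = 1e-12)
  expect_equal(m2$meta_p, 2 * pnorm(-2090 / 1340), tolerance = 1e-14)
  # exact cancellation
  m3 <- stouffer_meta(1.5, 600, -1.5, 600)
  expect_equal(m3$Z, 0); expect_equal(m3$meta_p, 1)
  # cohort-swap symmetry is exact
  m4a <- stouffer_meta(2.2, 750, -0.8, 590)
  m4b <- stouffer_meta(-0.8, 590, 2.2, 750)
  expect_identical(m4a$meta_p, m4b$meta_p)
  expect_identical(m4a$Z, m4b$Z)
})

test_that("the weighted form is conservative relative to classical Stouffer", {
  for (z in c(0.5, 1, 2, 4, 8))
    for (n1 in c(100, 750)) for (n2 in c(590, 2000)) {
      if (n1 == n2) next
      w <- stouffer_meta(z, n1, z, n2)$Z
      cl <- stouffer_meta(z, n1, z, n2, method = "classical")$Z
      expect_lt(abs(w), abs(cl))
    }
  # equal n: weighted gives z itself, classical inflates by sqrt(2)
  expect_equal(stouffer_meta(2, 500, 2, 500, method = "classical")$Z,
               2 * sqrt(2), tolerance = 1e-12)
})

test_that("meta of null cohorts is conservative at alpha = 0.05", {
  set.seed(30)
  n_assoc <- 10000
  z1 <- rnorm(n_assoc); z2 <- rnorm(n_assoc)
  mp <- stouffer_meta(z1, 750, z2, 590)$meta_p
  expect_lte(mean(mp < 0.05), 0.05)
})

test_that("significance and Bonferroni helpers use strict inequality", {
  expect_true(call_significant(7.9e-10))
  expect_false(call_significant(8e-10))
  expect_equal(bonferroni_threshold(664913, 88), 0.05 / (664913 * 88))
  flags <- call_significant(c(1e-12, 1e-5, NA), threshold = 1e-8)
  expect_equal(flags, c(TRUE, FALSE, FALSE))
})

test_that("replication requires significance and direction in the other cohort", {
  resA <- data.frame(variant_id = c("v1", "v2", "v3", "v4"),
                     analyte = "a", p = c(1e-12, 1e-11, 1e-15, 0.5),
                     beta = c(1, -1, 0.5, 2))
  resB <- data.frame(variant_id = c("v1", "v2"),
                     analyte = "a", p = c(1e-8, 1e-8), beta = c(0.8, 1))
  rc <- replication_check(resA, resB, discovery_threshold = 1e-9)
  expect_equal(rc$m_discovery, 3)
  expect_equal(rc$replication_threshold, 0.05 / 3)
  tab <- rc$table
  expect_true(tab$replicated[tab$variant_id == "v1"])
  # v2: significant in B but opposite sign -> not replicated
  expect_false(tab$replicated[tab$variant_id == "v2"])
  # v3: absent in B -> unreplicated, flagged missing
  expect_false(tab$replicated[tab$variant_id == "v3"])
  expect_true(tab$missing_in_B[tab$variant_id == "v3"])
  expect_equal(rc$n_replicated, 1)
})

test_that("strong shared effects replicate across simulated cohorts", {
  cfg <- sim_config(seed = 31, n1 = 600, n2 = 600, n_variants = 40,
    maf_range = c(0.15, 0.5),
    analytes = list(
      analyte_spec("a1", causal_variants = "v0003", slopes = 0.6, censor_q = 0),
      analyte_spec("a2", causal_variants = "v0020", slopes = 0.6, censor_q = 0)))
  st <- simulate_study(cfg)
  d <- study_designs(st)
  scan <- function(b, X) rbind(
    scan_analyte(prep_analyte(b, "a1"), b$genotypes, X),
    scan_analyte(prep_analyte(b, "a2"), b$genotypes, X))
  s1 <- scan(st$cohort1, d$X1); s2 <- scan(st$cohort2, d$X2)
  rc <- replication_check(s1, s2, discovery_threshold = 1e-9)
  expect_gte(rc$m_discovery, 2)
  expect_gte(rc$n_replicated / rc$m_discovery, 0.95)
})

test_that("local/distant classification uses the 1 Mb rule", {
  am <- list(gene_chromosome = "7", gene_start = 5e6, gene_end = 5.2e6)
  mk <- function(chr, pos) list(chromosome = chr, position = pos)
  expect_equal(classify_local_distant(mk("7", 5e6 - 999999), am), "local")
  expect_equal(classify_local_distant(mk("7", 5e6 - 1000000), am), "local")
  expect_equal(classify_local_distant(mk("7", 5e6 - 1000001), am), "distant")
  expect_equal(classify_local_distant(mk("7", 5.1e6), am), "local")  # inside
  expect_equal(classify_local_distant(mk("7", 5.2e6 + 1e6 + 1), am), "distant")
  expect_equal(classify_local_distant(mk("9", 5e6), am), "distant")
  am_na <- list(gene_chromosome = NA, gene_start = NA, gene_end = NA)
  expect_equal(classify_local_distant(mk("7", 5e6), am_na), "unknown")
})

test_that("recursive conditioning: degenerate pool, proxies, two signals", {
  # K = 1: the single candidate is returned without a conditioning round
  cfg1 <- sim_config(seed = 32, n1 = 300, n2 = 250, n_variants = 10,
    maf_range = c(0.2, 0.5),
    analytes = list(analyte_spec("a1", causal_variants = "v0002",
                                 slopes = 0.7, censor_q = 0)))
  st1 <- simulate_study(cfg1)
  d1 <- study_designs(st1)
  co1 <- list(prepared = prep_analyte(st1$cohort1, "a1"),
              genotypes = st1$cohort1$genotypes, design = d1$X1,
              n = st1$cohort1$n)
  co2 <- list(prepared = prep_analyte(st1$cohort2, "a1"),
              genotypes = st1$cohort2$genotypes, design = d1$X2,
              n = st1$cohort2$n)
  r1 <- recursive_conditioning("a1", "v0002", co1, co2)
  expect_equal(r1$selected$variant_id, "v0002")
  expect_equal(r1$K, 1)

  # one causal variant with LD proxies: exactly one independent signal
  proxies <- sprintf("v%04d", 2:6)
  cfg2 <- sim_config(seed = 33, n1 = 500, n2 = 450, n_variants = 12,
    maf_range = c(0.2, 0.5),
    ld_blocks = list(list(seed_variant = "v0001", proxies = proxies,
                          copy_prob = sqrt(0.9))),
    analytes = list(analyte_spec("a1", causal_variants = "v0001",
                                 slopes = 0.7, censor_q = 0)))
  st2 <- simulate_study(cfg2)
  d2 <- study_designs(st2)
  mk <- function(st, d, a = "a1") list(
    list(prepared = prep_analyte(st$cohort1, a),
         genotypes = st$cohort1$genotypes, design = d$X1, n = st$cohort1$n),
    list(prepared = prep_analyte(st$cohort2, a),
         genotypes = st$cohort2$genotypes, design = d$X2, n = st$cohort2$n))
  cos <- mk(st2, d2)
  r2 <- recursive_conditioning("a1", c("v0001", proxies), cos[[1]], cos[[2]])
  expect_equal(nrow(r2$selected), 1)

  # two unlinked causal variants: exactly two signals, no high-r2 pair
  cfg3 <- sim_config(seed = 34, n1 = 500, n2 = 450, n_variants = 12,
    maf_range = c(0.2, 0.5),
    analytes = list(analyte_spec("a1",
      causal_variants = c("v0001", "v0008"), slopes = c(0.6, 0.6),
      censor_q = 0)))
  st3 <- simulate_study(cfg3)
  d3 <- study_designs(st3)
  cos3 <- mk(st3, d3)
  r3 <- recursive_conditioning("a1", sprintf("v%04d", 1:12),
                               cos3[[1]], cos3[[2]])
  expect_setequal(r3$selected$variant_id, c("v0001", "v0008"))
  g1 <- st3$cohort1$genotypes$dosage
  expect_lt(cor(g1[, "v0001"], g1[, "v0008"])^2, 0.95)
})

test_that("meta_scan joins cohorts and drops non-converged fits", {
  cfg <- sim_config(seed = 35, n1 = 200, n2 = 180, n_variants = 8,
    analytes = list(analyte_spec("a1", censor_q = 0)))
  st <- simulate_study(cfg)
  d <- study_designs(st)
  s1 <- scan_analyte(prep_analyte(st$cohort1, "a1"), st$cohort1$genotypes, d$X1)
  s2 <- scan_analyte(prep_analyte(st$cohort2, "a1"), st$cohort2$genotypes, d$X2)
  s1$converged[3] <- FALSE
  expect_message(mt <- meta_scan(s1, s2, st$cohort1$n, st$cohort2$n),
                 "non-converged")
  expect_equal(nrow(mt), 7)
  i <- 1
  expect_equal(mt$Z[i],
               (st$cohort1$n * mt$z1[i] + st$cohort2$n * mt$z2[i]) /
                 (st$cohort1$n + st$cohort2$n), tolerance = 1e-12)
  expect_equal(mt$meta_p, 2 * pnorm(-abs(mt$Z)), tolerance = 1e-14)
  expect_equal(mt$log10_meta_p, log10(mt$meta_p), tolerance = 1e-9)
})
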