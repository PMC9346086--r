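test_that("equilibrium frequency matches the closed form and guards its domain", {
  # no mutation, no polymorphism
  expect_equal(equilibrium_frequency(
    locus_params(0, 0, 0.02, 0.02, h = 0.25)), 0)
  # (2*1e-6 + 1e-6) / (2*0.02*0.25 + 0.02) = 1e-4
  expect_equal(equilibrium_frequency(
    locus_params(1e-6, 1e-6, 0.02, 0.02, h = 0.25)), 1e-4)
  # female-neutral locus: males alone hold the balance
  expect_equal(equilibrium_frequency(
    locus_params(1e-6, 1e-6, 0, 0.02, h = 0.25)), 1.5e-4)
  # neutral in both sexes: no balance exists
  expect_error(equilibrium_frequency(
    locus_params(1e-6, 1e-6, 0, 0, h = 0.25)), "denominator")
  # mutation pressure above 1% of the selection denominator warns
  expect_warning(equilibrium_frequency(
    locus_params(1e-3, 1e-3, 0.02, 0.02, h = 0.25)),
    "strong-selection")
})

test_that("per-locus survival factors follow the linearized model", {
  l <- locus_params(1e-6, 1e-6, 0.02, 0.02, h = 0.25,
                    alpha_f = 0.3, alpha_m = 0.3)
  expect_equal(locus_component_means(l, freq = 0),
               data.frame(w_f = 1, w_m = 1))
  # fully recessive mutations are invisible in heterozygous females
  l0 <- locus_params(1e-6, 1e-6, 0.02, 0.02, h = 0)
  expect_equal(locus_component_means(l0, freq = 0.1)$w_f, 1)
  w <- locus_component_means(l, freq = 1e-4)
  expect_equal(w$w_f, 1 - 2 * 0.25 * 0.02 * 0.3 * 1e-4)  # 1 - 3e-7
  expect_equal(w$w_m, 1 - 0.02 * 0.3 * 1e-4)             # 1 - 6e-7
  # a factor at or below zero invalidates the linearization
  lbad <- locus_params(1e-6, 1e-6, 1, 1, h = 0.5, alpha_f = 1,
                       alpha_m = 1)
  expect_error(locus_component_means(lbad, freq = 1), "invalid")
})

test_that("genome loads collapse to the summary formula for identical loci", {
  # mutation-free genome: no load in either sex
  quiet <- loci_collection(data.frame(
    mu_f = 0, mu_m = 0, s_f = 0.02, s_m = 0.02, h = 0.25,
    alpha_f = 0.3, alpha_m = 0.3))
  expect_equal(genome_loads_exact(quiet)$ratio, 1)
  # n identical equal-sex loci at h = 0.25: exact algebraic identity
  # with the summary form at U_X = n * mu
  for (n in c(1, 100, 5000)) {
    loci <- identical_loci(n)
    expect_equal(genome_loads_exact(loci)$ratio,
                 ratio_simplified(n * 1e-6, 0.25, 0.3),
                 tolerance = 1e-12)
  }
  expect_error(loci_collection(data.frame()), "at least one locus")
})

test_that("distributed dominance matches the second-order expansion", {
  loci <- uniform_h_loci(1e4)
  exact <- genome_loads_exact(loci)
  U_X <- sum(2 * loci$mu_f + loci$mu_m) / 3
  r2 <- ratio_baseline(U_X, mean(loci$h), stats::var(loci$h), 0.3)
  rel <- abs(log(exact$ratio) - log(r2)) / abs(log(r2))
  # the 4th-order Taylor remainder for h ~ U(0.1, 0.4) is ~1.3e-3;
  # the expansion is accurate to that order, not beyond
  expect_lt(rel, 2e-3)
  # with the generator's tighter default dominance spread the remainder
  # drops below 1e-3
  gen <- sample_loci(1e4, seed = 11)
  ach <- attr(gen, "achieved")
  r2g <- ratio_baseline(ach$U_X, ach$h_bar, ach$var_h, ach$alpha_bar)
  relg <- abs(log(genome_loads_exact(gen)$ratio) - log(r2g)) /
    abs(log(r2g))
  expect_lt(relg, 1e-3)
})

test_that("summary ratio formulas reproduce the printed worked values", {
  # Drosophila-like: U_X = 0.1, h = 0.25, alpha = 0.3
  expect_equal(round(ratio_simplified(0.1, 0.25, 0.3), 2), 1.03)
  expect_equal(ratio_simplified(0.1, 0.25, 0.3), exp(0.03),
               tolerance = 1e-12)
  # second-order correction
  expect_equal(ratio_baseline(0.1, 0.25, 0.01, 0.3),
               exp(3 * 0.1 * 0.3 * (1 / 3 + 0.08 / 3.375)),
               tolerance = 1e-12)
  # sex-differential selection, beta = 1.5
  expect_equal(round(ratio_sexdiff(0.1, 0.25, 0.1, 1.5), 4), 1.0075)
  # ZW bird case: U_Z = 0.132, label-reversed beta
  expect_equal(ratio_sexdiff(0.132, 0.25, 0.3, 1 / 1.5),
               exp(3 * 0.132 * 0.3 * 0.5 / (1 / 1.5 + 0.5)),
               tolerance = 1e-12)
  expect_equal(round(100 * (ratio_sexdiff(0.132, 0.25, 0.3, 1 / 1.5) - 1),
                     1), 5.2)
})

test_that("ratio formulas reduce to each other in the stated limits", {
  grid <- expand.grid(U = c(0.01, 0.1, 0.5), h = c(0, 0.1, 0.25, 0.45),
                      a = c(0.1, 0.3, 1))
  for (i in seq_len(nrow(grid))) {
    U <- grid$U[i]; h <- grid$h[i]; a <- grid$a[i]
    expect_equal(ratio_baseline(U, h, 0, a), ratio_simplified(U, h, a),
                 tolerance = 1e-14)
    expect_equal(ratio_sexdiff(U, h, a, 1), ratio_simplified(U, h, a),
                 tolerance = 1e-14)
    expect_equal(ratio_no_dosage_comp(U, h, a, 1),
                 ratio_simplified(U, h, a), tolerance = 1e-14)
  }
  # additive mutations: no effect
  expect_equal(ratio_simplified(0.3, 0.5, 0.3), 1)
  # fully recessive, survival-only selection: the exp(3*U_X) upper limit
  expect_equal(ratio_simplified(0.2, 0, 1), exp(3 * 0.2))
  # h above the partially recessive regime warns and predicts <= 1
  expect_warning(r <- ratio_simplified(0.1, 0.7, 0.3), "0.5")
  expect_lt(r, 1)
})

test_that("baseline ratio is monotone in each parameter", {
  h <- seq(0, 0.5, by = 0.05)
  r_h <- vapply(h, function(x) ratio_simplified(0.1, x, 0.3), 0)
  expect_true(all(diff(r_h) < 0))
  U <- seq(0, 1, by = 0.1)
  r_U <- vapply(U, function(x) ratio_simplified(x, 0.25, 0.3), 0)
  expect_true(all(diff(r_U) > 0))
  a <- seq(0, 1, by = 0.1)
  r_a <- vapply(a, function(x) ratio_simplified(0.1, 0.25, x), 0)
  expect_true(all(diff(r_a) > 0))
  expect_equal(ratio_simplified(0, 0.25, 0.3), 1)
  expect_equal(ratio_simplified(0.1, 0.25, 0), 1)
})

test_that("stronger selection on the heterogametic sex dampens the effect", {
  for (beta in c(1.2, 1.5, 2, 5)) {
    expect_lt(ratio_sexdiff(0.1, 0.25, 0.3, beta),
              ratio_simplified(0.1, 0.25, 0.3))
  }
  expect_error(ratio_sexdiff(0.1, 0.25, 0.3, 0), "positive")
  expect_error(ratio_sexdiff(0.1, 0.25, 0.3, -1), "positive")
})

test_that("sex-limited effects cancel or reverse the unguarded X", {
  expect_equal(ratio_sex_limited(0.1, 0.3, 0.3)$ratio, 1)
  r <- ratio_sex_limited(0.1, 0.1, 0.3)
  expect_equal(r$ratio, exp(0.03), tolerance = 1e-12)
  expect_equal(r$w_f, exp(-0.15 * 0.1))
  expect_equal(r$w_m, exp(-0.15 * 0.3))
  # survival relatively more important for female fitness: reversal
  expect_lt(ratio_sex_limited(0.1, 0.3, 0.1)$ratio, 1)
})

test_that("absent dosage compensation restricts and dampens the effect", {
  # fully recessive: no dampening at any k
  for (k in c(0.2, 0.5, 1)) {
    expect_equal(ratio_no_dosage_comp(0.1, 0, 1, k), exp(0.3),
                 tolerance = 1e-12)
  }
  for (k in c(0.3, 0.6, 0.9)) {
    for (h in c(0.05, 0.2, 0.4)) {
      r <- ratio_no_dosage_comp(0.1, h, 0.3, k)
      expect_lt(r, ratio_simplified(0.1, h, 0.3))
      # sign flips exactly where mean dominance crosses k/2
      if (h < k / 2) expect_gt(r, 1) else expect_lte(r, 1)
    }
  }
  expect_error(ratio_no_dosage_comp(0.1, 0.25, 0.3, 0), "k must")
  expect_error(ratio_no_dosage_comp(0.1, 0.25, 0.3, 1.2), "k must")
})

test_that("percent conventions are labelled and mutually consistent", {
  p <- ratio_percents(1.03)
  expect_named(p, c("excess", "deficit", "log_pct"))
  expect_equal(p[["excess"]], 3)
  expect_equal(p[["deficit"]], 100 * (1 - 1 / 1.03))
  expect_equal(p[["log_pct"]], 100 * log(1.03))
  # conventions agree to first order for small effects
  q <- ratio_percents(1.001)
  expect_equal(q[["excess"]], q[["log_pct"]], tolerance = 1e-3)
})

test_that("load results serialize to JSON with all conventions", {
  res <- genome_loads_exact(identical_loci(1000))
  path <- withr::local_tempfile(fileext = ".json")
  load_result_json(res, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$ratio, res$ratio, tolerance = 1e-12)
  expect_equal(back$w_hom, res$w_hom, tolerance = 1e-12)
  expect_equal(back$pct_log, res$pct$log_pct, tolerance = 1e-9)
  expect_true(all(c("pct_excess", "pct_deficit", "pct_log") %in%
                    names(back$conventions)))
})

test_that("loci collections round-trip through CSV", {
  loci <- sample_loci(25, h_sd = 0.05, s_cv = 0.3, alpha_sd = 0.1,
                      seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_loci(loci, path)
  back <- read_loci(path)
  expect_equal(as.data.frame(back), as.data.frame(loci),
               tolerance = 1e-12, ignore_attr = TRUE)
  # malformed parameter ranges are rejected on construction
  expect_error(loci_collection(data.frame(
    mu_f = 1e-6, mu_m = 1e-6, s_f = 1.5, s_m = 0.02, h = 0.25,
    alpha_f = 0.3, alpha_m = 0.3)), "s_f")
})
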