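test_that("estimate tables load, validate, and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rmu_fixture(), path, row.names = FALSE)
  rec <- load_rmu(path)
  expect_equal(nrow(rec), 6)
  expect_equal(nrow(attr(rec, "rejected")), 0)
  # a generated table round-trips losslessly
  g <- data.frame(group = c("mammal", "bird"), n_species = c(5, 4),
                  mean = c(2.5, 2), cv = c(0.15, 0.15))
  tb <- sample_rmu_table(g, estimates_per_species = c(2, 1), seed = 12)
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tb, p2, row.names = FALSE)
  back <- load_rmu(p2)
  expect_equal(back$estimate, tb$estimate, tolerance = 1e-12)
  expect_equal(back$species, tb$species)
  expect_equal(back$ci_low, tb$ci_low, tolerance = 1e-12)
})

test_that("invalid rows are rejected with line numbers, counts conserved", {
  bad <- rmu_fixture()
  bad$estimate[2] <- -1          # line 3 of the file
  bad$estimate[4] <- "not_a_number"
  bad$ci_low[5] <- 1.9           # bounds no longer bracket 1.5
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path, row.names = FALSE)
  expect_warning(rec <- load_rmu(path), "rejected")
  rej <- attr(rec, "rejected")
  expect_equal(nrow(rec) + nrow(rej), 6)
  expect_setequal(rej$line, c(3, 5, 6))
  expect_true(any(grepl("positive", rej$reason)))
  expect_true(any(grepl("not a number", rej$reason)))
  expect_true(any(grepl("bracket", rej$reason)))
  # column mapping bridges other dialects; missing columns error
  alt <- rmu_fixture()
  names(alt)[names(alt) == "estimate"] <- "Rmu_point"
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(alt, p3, row.names = FALSE)
  expect_error(load_rmu(p3), "missing required")
  expect_equal(nrow(load_rmu(p3, col_map = c(estimate = "Rmu_point"))), 6)
})

test_that("species averaging is an idempotent arithmetic mean", {
  ps <- species_average(rmu_fixture())
  expect_equal(ps$estimate[ps$species == "sp_a"], 3)  # mean of 2, 3, 4
  expect_equal(ps$estimate[ps$species == "sp_b"], 2.5)
  expect_equal(ps$n_estimates[ps$species == "sp_a"], 3)
  expect_equal(nrow(ps), 4)
  ps2 <- species_average(ps)
  expect_equal(ps2$estimate, ps$estimate)
  expect_equal(nrow(ps2), nrow(ps))
  # known per-species means from a generated table are recovered exactly
  g <- data.frame(group = "mammal", n_species = 6, mean = 2.5, cv = 0.2)
  tb <- sample_rmu_table(g, estimates_per_species = 3, seed = 9)
  ps3 <- species_average(tb)
  manual <- tapply(tb$estimate, tb$species, mean)
  expect_equal(ps3$estimate, as.numeric(manual[ps3$species]),
               tolerance = 1e-12)
})

test_that("exclusions filter with an audit trail before averaging", {
  rec <- rmu_fixture()
  kept <- apply_exclusions(rec, threshold = 10)
  expect_equal(nrow(kept), 5)
  audit <- attr(kept, "audit")
  expect_equal(audit$species, "sp_d")
  expect_match(audit$reason, "threshold")
  # empty spec is the identity
  same <- apply_exclusions(rec)
  expect_equal(nrow(same), nrow(rec))
  expect_equal(nrow(attr(same, "audit")), 0)
  # naming an absent record warns, never errors
  expect_warning(apply_exclusions(rec, exclude_species = "sp_missing"),
                 "absent")
  # excluding one estimate by (species, source) leaves the rest of the
  # species intact, so the outlier cannot contaminate the species mean
  one <- apply_exclusions(rec, exclude_species = data.frame(
    species = "sp_a", source = "study_3"))
  expect_equal(nrow(one), 5)
  avg <- species_average(one)
  expect_equal(avg$estimate[avg$species == "sp_a"], 2.5)  # mean of 2, 3
})

test_that("group summaries report counts, centers, and central ranges", {
  ps <- species_average(apply_exclusions(rmu_fixture(), threshold = 10))
  sm <- group_summary(ps)
  expect_equal(sort(sm$lineage_group), c("bird", "mammal"))
  expect_equal(sm$n[sm$lineage_group == "mammal"], 2)
  expect_equal(sm$mean[sm$lineage_group == "mammal"], 2.75)  # (3 + 2.5)/2
  expect_equal(sm$n[sm$lineage_group == "bird"], 1)
  expect_equal(sm$mean[sm$lineage_group == "bird"], 1.5)
  expect_error(group_summary(ps[0, ]), "empty")
  # single group collapses to one row
  expect_equal(nrow(group_summary(ps[ps$lineage_group == "bird", ])), 1)
})

test_that("the pipeline runs exclusions before averaging", {
  # a human-like outlier estimate must not contaminate the species mean:
  # sp_h has estimates (2, 20); excluding 20 first leaves mean 2
  rec <- data.frame(
    species = c("sp_h", "sp_h", "sp_x"),
    lineage_group = "mammal",
    estimate = c(2, 20, 3),
    ci_low = NA_real_, ci_high = NA_real_,
    method = "molecular", source = c("s1", "s2", "s3"),
    species_level = TRUE, stringsAsFactors = FALSE)
  out <- rmu_pipeline(rec, threshold = 10)
  expect_equal(out$n_species, 2)
  expect_equal(out$per_species$estimate[out$per_species$species == "sp_h"],
               2)
  expect_equal(nrow(out$audit), 1)
  # averaging first would have produced a contaminated mean of 11
  contaminated <- species_average(rec)
  expect_equal(
    contaminated$estimate[contaminated$species == "sp_h"], 11)
})
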