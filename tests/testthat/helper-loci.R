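# fixtures shared across test files

# n identical loci with equal-sex parameters
identical_loci <- function(n, mu = 1e-6, s = 0.02, h = 0.25, alpha = 0.3) {
  loci_collection(data.frame(
    mu_f = mu, mu_m = mu, s_f = s, s_m = s, h = rep(h, n),
    alpha_f = alpha, alpha_m = alpha
  ))
}

# loci with dominance drawn uniformly, everything else constant
uniform_h_loci <- function(n, h_min = 0.1, h_max = 0.4, mu = 1e-6,
                           s = 0.02, alpha = 0.3, seed = 42) {
  withr::with_seed(seed, {
    loci_collection(data.frame(
      mu_f = mu, mu_m = mu, s_f = s, s_m = s,
      h = stats::runif(n, h_min, h_max),
      alpha_f = alpha, alpha_m = alpha
    ))
  })
}

# small well-formed estimate table for the curation pipeline
rmu_fixture <- function() {
  data.frame(
    species = c("sp_a", "sp_a", "sp_a", "sp_b", "sp_c", "sp_d"),
    lineage_group = c("mammal", "mammal", "mammal", "mammal", "bird",
                      "other"),
    estimate = c(2, 3, 4, 2.5, 1.5, 20),
    ci_low = c(1.5, NA, 3.2, 2.0, 1.1, NA),
    ci_high = c(2.6, NA, 4.9, 3.1, 2.0, NA),
    method = c("molecular", "trio", "molecular", "molecular",
               "molecular", "molecular"),
    source = paste0("study_", 1:6),
    species_level = TRUE,
    stringsAsFactors = FALSE
  )
}
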