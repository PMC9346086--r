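#' Sample a synthetic collection of sex-linked loci
#'
#' Draws per-locus parameters with the independence structure the
#' genome-level approximations assume: dominance `h`, selection `s`, and
#' component effects `alpha` independently distributed across loci.
#' Dominance is drawn from a beta distribution rescaled to
#' `(h_min, h_max)` with the requested mean (default mean 0.25 on
#' `(0, 0.5)`, the partially recessive regime supported by
#' mutation-accumulation data); selection is either constant or
#' log-normal around `s_mean`; `alpha` constant or beta-distributed.
#'
#' Sex coupling: with `coupling = "beta"` the male parameters are tied
#' to the female ones by `s_m = beta * s_f` and
#' `alpha_m = alpha_f / beta`, enforcing the equal-viability-effect
#' constraint `alpha_f * s_f = alpha_m * s_m`; `coupling =
#' "independent"` leaves the sexes free (used for sex-limited-effect
#' fixtures).
#'
#' The achieved moments (`h_bar`, `var_h`, `alpha_bar`, and
#' `U_X = sum(2 mu_f + mu_m) / 3`) are attached as attribute
#' `"achieved"` so summary-level formulas can be evaluated at exactly
#' the moments the sample realizes.
#'
#' @param n_loci Number of loci (>= 1).
#' @param h_mean Target mean dominance coefficient.
#' @param h_sd Standard deviation of dominance; `0` gives the constant
#'   `h_mean`.
#' @param h_min,h_max Support of the dominance distribution.
#' @param s_mean Mean homozygous selection coefficient (females).
#' @param s_cv Coefficient of variation of `s`; `0` gives constant `s`.
#' @param mu_f,mu_m Per-locus mutation probabilities (recycled).
#' @param alpha_mean Mean component effect.
#' @param alpha_sd Standard deviation of `alpha`; `0` gives a constant.
#' @param beta Male-to-female selection ratio used by the `"beta"`
#'   coupling.
#' @param coupling `"beta"` (enforce `alpha_f s_f = alpha_m s_m`) or
#'   `"independent"`.
#' @param alpha_m_mean Mean male component effect for
#'   `coupling = "independent"` (defaults to `alpha_mean`).
#' @param seed Integer seed; the draw is a pure function of the spec and
#'   this seed (the caller's RNG state is untouched).
#' @return A loci collection with attribute `"achieved"`.
#' @export
#' @examples
#' loci <- sample_loci(1000, seed = 1)
#' attr(loci, "achieved")$h_bar  # close to 0.25
sample_loci <- function(n_loci, h_mean = 0.25, h_sd = 0.07,
                        h_min = 0, h_max = 0.5,
                        s_mean = 0.02, s_cv = 0,
                        mu_f = 1e-6, mu_m = 1e-6,
                        alpha_mean = 0.3, alpha_sd = 0,
                        beta = 1, coupling = c("beta", "independent"),
                        alpha_m_mean = alpha_mean, seed) {
  coupling <- match.arg(coupling)
  stopifnot(n_loci >= 1, h_min >= 0, h_max <= 1, h_min < h_max,
            s_mean > 0, s_cv >= 0, alpha_sd >= 0)
  if (h_mean <= h_min || h_mean >= h_max) {
    stop("h_mean must lie strictly inside (h_min, h_max)", call. = FALSE)
  }
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  withr::with_seed(seed, {
    h <- rbeta_scaled(n_loci, h_mean, h_sd, h_min, h_max)
    s_f <- if (s_cv == 0) rep(s_mean, n_loci) else {
      sdlog <- sqrt(log(1 + s_cv^2))
      stats::rlnorm(n_loci, meanlog = log(s_mean) - sdlog^2 / 2,
                    sdlog = sdlog)
    }
    s_f <- pmin(s_f, 1)
    alpha_f <- rbeta_scaled(n_loci, alpha_mean, alpha_sd, 0, 1)
    if (coupling == "beta") {
      s_m <- pmin(beta * s_f, 1)
      alpha_m <- pmin(alpha_f / beta, 1)
    } else {
      s_m <- s_f
      alpha_m <- rbeta_scaled(n_loci, alpha_m_mean, alpha_sd, 0, 1)
    }
    loci <- loci_collection(data.frame(
      locus_id = paste0("L", seq_len(n_loci)),
      mu_f = rep_len(mu_f, n_loci), mu_m = rep_len(mu_m, n_loci),
      s_f = s_f, s_m = s_m, h = h,
      alpha_f = alpha_f, alpha_m = alpha_m,
      stringsAsFactors = FALSE
    ))
    attr(loci, "achieved") <- list(
      h_bar = mean(h), var_h = stats::var(h),
      alpha_bar = mean(alpha_f),
      U_X = sum(2 * loci$mu_f + loci$mu_m) / 3
    )
    loci
  })
}

# beta draw rescaled to (lo, hi) with requested mean/sd on the original
# scale; sd = 0 degenerates to the point mass at the mean
rbeta_scaled <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  m <- (mean - lo) / (hi - lo)
  v <- (sd / (hi - lo))^2
  if (v >= m * (1 - m)) {
    stop(sprintf(
      "sd %.3g infeasible for a beta distribution with mean %.3g on (%.3g, %.3g)",
      sd, mean, lo, hi), call. = FALSE)
  }
  conc <- m * (1 - m) / v - 1
  lo + (hi - lo) * stats::rbeta(n, m * conc, (1 - m) * conc)
}

#' Sample a mock table of sex-biased mutation-rate estimates
#'
#' Emulates the structure of compiled literature tables of
#' \eqn{R_\mu = \bar\mu_m / \bar\mu_f}: several lineage groups with
#' different typical sex bias, multiple estimates for some species
#' (different studies or methods), interval bounds of varying width,
#' occasional missing bounds, and optional injected outliers. Point
#' estimates are log-normal within group with the requested arithmetic
#' group mean.
#'
#' @param groups A data frame with columns `group`, `n_species`, `mean`
#'   (arithmetic mean of \eqn{R_\mu}), and `cv` (coefficient of
#'   variation across species).
#' @param estimates_per_species Integer vector recycled across species:
#'   how many independent estimates each species gets.
#' @param ci_rel_width Half-width of the interval bounds relative to the
#'   estimate; `NA` bounds are produced for a fraction
#'   `missing_ci_prob` of rows (molecular-evolution estimates often
#'   lack usable intervals).
#' @param missing_ci_prob Probability a row carries no bounds.
#' @param outliers Optional data frame `species`, `group`, `estimate`
#'   appended verbatim as extra single-estimate species (e.g. one
#'   \eqn{R_\mu \sim 20} row to exercise outlier exclusion).
#' @param seed Integer seed.
#' @return A data frame in the published-estimate schema accepted by
#'   [load_rmu()]: `species`, `lineage_group`, `estimate`, `ci_low`,
#'   `ci_high`, `method`, `source`, `species_level`.
#' @export
sample_rmu_table <- function(groups,
                             estimates_per_species = 1,
                             ci_rel_width = 0.25,
                             missing_ci_prob = 0.3,
                             outliers = NULL, seed) {
  stopifnot(is.data.frame(groups),
            all(c("group", "n_species", "mean", "cv") %in% names(groups)))
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  stopifnot(all(groups$n_species >= 1), all(groups$mean > 0),
            all(groups$cv >= 0))
  withr::with_seed(seed, {
    rows <- list()
    for (g in seq_len(nrow(groups))) {
      grp <- groups$group[g]
      n_sp <- groups$n_species[g]
      mult <- rep_len(estimates_per_species, n_sp)
      cv <- groups$cv[g]
      sdlog <- sqrt(log(1 + cv^2))
      sp_true <- if (cv == 0) rep(groups$mean[g], n_sp) else
        stats::rlnorm(n_sp, log(groups$mean[g]) - sdlog^2 / 2, sdlog)
      for (i in seq_len(n_sp)) {
        sp <- sprintf("%s_sp%02d", grp, i)
        for (j in seq_len(mult[i])) {
          est <- sp_true[i] *
            (if (mult[i] > 1) exp(stats::rnorm(1, 0, 0.05)) else 1)
          has_ci <- stats::runif(1) >= missing_ci_prob
          rows[[length(rows) + 1L]] <- data.frame(
            species = sp, lineage_group = grp, estimate = est,
            ci_low = if (has_ci) est * (1 - ci_rel_width) else NA_real_,
            ci_high = if (has_ci) est * (1 + ci_rel_width) else NA_real_,
            method = if (j %% 2 == 0) "trio" else "molecular",
            source = sprintf("study_%s_%d", grp, j),
            species_level = TRUE,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    out <- do.call(rbind, rows)
    if (!is.null(outliers)) {
      stopifnot(all(c("species", "group", "estimate") %in% names(outliers)))
      extra <- data.frame(
        species = outliers$species, lineage_group = outliers$group,
        estimate = outliers$estimate, ci_low = NA_real_,
        ci_high = NA_real_, method = "molecular",
        source = "outlier_study", species_level = TRUE,
        stringsAsFactors = FALSE
      )
      out <- rbind(out, extra)
    }
    rownames(out) <- NULL
    out
  })
}
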