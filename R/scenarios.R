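#' Genome-level scenario for an unguarded-X prediction
#'
#' A scenario collects the genome-wide summary parameters that feed the
#' closed-form model: the haploid deleterious mutation rate `U_H`, the
#' sex-linked genome fraction `P_linked`, sex-biased mutation `R_mu`
#' (male/female per-site rates), the dominance moments `h_bar` and
#' `var_h`, the mean component effect in the homogametic sex
#' `alpha_hom`, the male-to-female selection ratio `beta` (always
#' expressed male/female regardless of system), and an optional
#' dosage-compensation scaling `dosage_k`.
#'
#' The `system` tag decides which mutation budget applies
#' (X for `"XY"` and `"haplodiploid"`, Z for `"ZW"`) and which sex is
#' homogametic in labels and in the orientation of `beta` — never the
#' algebra itself. Haplodiploids are modeled as an XY system whose whole
#' haploid genome is hemizygous in males (`P_linked = 1`).
#'
#' @param name Scenario label.
#' @param system `"XY"`, `"ZW"`, or `"haplodiploid"`.
#' @param U_H Haploid genomic deleterious mutation rate.
#' @param P_linked X- or Z-linked fraction of the haploid genome.
#' @param R_mu Male-to-female per-site mutation rate ratio.
#' @param h_bar,var_h Mean and variance of dominance coefficients.
#' @param alpha_hom Mean component effect in the homogametic sex.
#' @param beta Male-to-female selection ratio `s_m / s_f`.
#' @param dosage_k Hemizygous-expression scaling in `(0, 1]`; values
#'   below 1 model absent dosage compensation and are only defined for
#'   `beta = 1`.
#' @return An object of class `"genome_scenario"`.
#' @export
genome_scenario <- function(name, system = c("XY", "ZW", "haplodiploid"),
                            U_H, P_linked, R_mu = 1,
                            h_bar = 0.25, var_h = 0,
                            alpha_hom = 0.3, beta = 1, dosage_k = 1) {
  system <- match.arg(system)
  stopifnot(U_H >= 0, P_linked > 0, P_linked <= 1, R_mu > 0,
            h_bar >= 0, h_bar <= 1, var_h >= 0,
            alpha_hom >= 0, alpha_hom <= 1,
            dosage_k > 0, dosage_k <= 1)
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  structure(list(
    name = name, system = system, U_H = U_H, P_linked = P_linked,
    R_mu = R_mu, h_bar = h_bar, var_h = var_h, alpha_hom = alpha_hom,
    beta = beta, dosage_k = dosage_k
  ), class = "genome_scenario")
}

#' @export
print.genome_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s)\n", x$name, x$system))
  cat(sprintf("  U_H = %g, P_linked = %g, R_mu = %g\n",
              x$U_H, x$P_linked, x$R_mu))
  cat(sprintf("  h_bar = %g, var_h = %g, alpha_hom = %g, beta = %g, dosage_k = %g\n",
              x$h_bar, x$var_h, x$alpha_hom, x$beta, x$dosage_k))
  invisible(x)
}

#' Builtin taxon scenarios
#'
#' Named parameterizations for the taxa the model is usually applied to.
#' Mutation-rate and genome-fraction values follow published estimates:
#' `U_H = 0.5` (Drosophila-like, also C. elegans and mice) or `1.1`
#' (human-like), `P_X = 0.2` (Drosophila), `0.05` (mammals),
#' `P_Z = 0.1` (birds). All use `h_bar = 0.25`; `alpha_hom = 0.3` unless
#' noted.
#'
#' * `drosophila_baseline` — XY, equal-sex mutation and selection.
#' * `drosophila_sexdiff` — XY, `alpha_hom = 0.1`, selection 1.5-fold
#'   stronger in males.
#' * `mammal_baseline` — XY, human-like `U_H`, equal-sex rates.
#' * `bird_baseline` — ZW, no sex bias in mutation or selection.
#' * `bird_sexdiff` — ZW, strongly male-biased mutation (`R_mu = 4`)
#'   and selection 1.5-fold stronger in males (the homogametic sex).
#' * `haplodiploid` — whole haploid genome hemizygous in males.
#'
#' @return A named list of `genome_scenario` objects.
#' @export
builtin_scenarios <- function() {
  list(
    drosophila_baseline = genome_scenario(
      "drosophila_baseline", "XY", U_H = 0.5, P_linked = 0.2, R_mu = 1,
      h_bar = 0.25, alpha_hom = 0.3, beta = 1),
    drosophila_sexdiff = genome_scenario(
      "drosophila_sexdiff", "XY", U_H = 0.5, P_linked = 0.2, R_mu = 1,
      h_bar = 0.25, alpha_hom = 0.1, beta = 1.5),
    mammal_baseline = genome_scenario(
      "mammal_baseline", "XY", U_H = 1.1, P_linked = 0.05, R_mu = 1,
      h_bar = 0.25, alpha_hom = 0.3, beta = 1),
    bird_baseline = genome_scenario(
      "bird_baseline", "ZW", U_H = 1.1, P_linked = 0.1, R_mu = 1,
      h_bar = 0.25, alpha_hom = 0.3, beta = 1),
    bird_sexdiff = genome_scenario(
      "bird_sexdiff", "ZW", U_H = 1.1, P_linked = 0.1, R_mu = 4,
      h_bar = 0.25, alpha_hom = 0.3, beta = 1.5),
    haplodiploid = genome_scenario(
      "haplodiploid", "haplodiploid", U_H = 0.5, P_linked = 1, R_mu = 1,
      h_bar = 0.25, alpha_hom = 0.3, beta = 1)
  )
}

#' Fetch a builtin scenario by name
#'
#' @param name Scenario name; an unknown name raises an error listing
#'   the available scenarios.
#' @return A `genome_scenario`.
#' @export
get_scenario <- function(name) {
  reg <- builtin_scenarios()
  if (!name %in% names(reg)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[name]]
}

#' Load a scenario from a YAML or JSON config file
#'
#' The file maps field names of [genome_scenario()] to values; unknown
#' fields are an error so typos cannot silently fall back to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `genome_scenario`.
#' @export
read_scenario <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  allowed <- names(formals(genome_scenario))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop("unknown scenario fields in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(genome_scenario, cfg)
}

#' Predict the unguarded-X effect for a scenario
#'
#' Chains the mutation budget into the closed-form ratio: `U_linked`
#' comes from [ux_rate()] (XY, haplodiploid) or [uz_rate()] (ZW); the
#' ratio comes from [ratio_sexdiff()] with the heterogametic-over-
#' homogametic selection ratio set to `beta` under XY and `1/beta` under
#' ZW (the `beta` field is always male/female), or from
#' [ratio_no_dosage_comp()] when `dosage_k < 1` (defined for `beta = 1`
#' only; combining both is rejected because their interaction is not
#' defined in this model). Dominance variance (`var_h > 0`) routes
#' through [ratio_baseline()] and is likewise only defined for the
#' equal-sex baseline.
#'
#' @param scenario A `genome_scenario` (or builtin scenario name).
#' @return A `load_result` carrying `U_linked` and the scenario.
#' @export
#' @examples
#' predict_scenario("drosophila_baseline")$ratio  # ~1.03
predict_scenario <- function(scenario) {
  if (is.character(scenario)) scenario <- get_scenario(scenario)
  stopifnot(inherits(scenario, "genome_scenario"))
  s <- scenario
  U <- if (s$system == "ZW") {
    uz_rate(s$U_H, s$P_linked, s$R_mu)
  } else {
    ux_rate(s$U_H, s$P_linked, s$R_mu)
  }
  if (s$dosage_k < 1 && s$beta != 1) {
    stop("dosage_k < 1 combined with beta != 1 is not defined in this ",
         "model; pick one departure from the baseline", call. = FALSE)
  }
  if (s$var_h > 0 && (s$beta != 1 || s$dosage_k < 1)) {
    stop("var_h > 0 is only supported in the equal-sex baseline",
         call. = FALSE)
  }
  ratio <- if (s$dosage_k < 1) {
    ratio_no_dosage_comp(U, s$h_bar, s$alpha_hom, s$dosage_k)
  } else if (s$var_h > 0) {
    ratio_baseline(U, s$h_bar, s$var_h, s$alpha_hom)
  } else {
    beta_het_over_hom <- if (s$system == "ZW") 1 / s$beta else s$beta
    ratio_sexdiff(U, s$h_bar, s$alpha_hom, beta_het_over_hom)
  }
  # per-sex components: the homogametic exponent is -3*U*alpha*2h/(D+2h)
  # with D the heterozygous-vs-hemizygous denominator term (het/hom
  # selection ratio, or the dosage scaling k); the heterogametic
  # component then follows from the ratio so the identity
  # ratio = w_hom / w_het holds exactly
  D <- if (s$dosage_k < 1) s$dosage_k else
    if (s$system == "ZW") 1 / s$beta else s$beta
  log_w_hom <- -3 * U * s$alpha_hom * 2 * s$h_bar / (D + 2 * s$h_bar)
  log_w_het <- log_w_hom - log(ratio)
  res <- new_load_result(log_w_hom, log_w_het, system = s$system,
                         extra = list(U_linked = U, scenario = s))
  res
}

#' @export
predict.genome_scenario <- function(object, ...) predict_scenario(object)

#' Evaluate scenarios over a grid of dominance and component effects
#'
#' Runs [predict_scenario()] for every combination of scenario,
#' `h_bar`, and `alpha_hom`, holding each scenario's other parameters
#' fixed. This reproduces the standard sensitivity sweep: effect size as
#' a function of mean dominance for low and moderate component effects
#' across taxon parameterizations.
#'
#' @param scenarios A list of `genome_scenario` objects (or builtin
#'   names).
#' @param h_bar Numeric vector of mean dominance values in `[0, 0.5]`.
#' @param alpha_hom Numeric vector of component-effect means in `[0, 1]`.
#' @return A data frame (one row per scenario x `h_bar` x `alpha_hom`)
#'   with columns `scenario`, `system`, `h_bar`, `alpha`, `U_linked`,
#'   `ratio`, `pct_excess`, `pct_log`.
#' @export
sweep_scenarios <- function(scenarios, h_bar = seq(0, 0.5, by = 0.01),
                            alpha_hom = c(0.1, 0.3)) {
  if (length(scenarios) == 0 || length(h_bar) == 0 ||
      length(alpha_hom) == 0) {
    stop("empty sweep grid", call. = FALSE)
  }
  stopifnot(all(h_bar >= 0), all(h_bar <= 0.5),
            all(alpha_hom >= 0), all(alpha_hom <= 1))
  scenarios <- lapply(scenarios, function(s) {
    if (is.character(s)) get_scenario(s) else s
  })
  rows <- list()
  for (s in scenarios) {
    for (a in alpha_hom) {
      for (hb in h_bar) {
        s2 <- s
        s2$h_bar <- hb
        s2$alpha_hom <- a
        r <- predict_scenario(s2)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = s$name, system = s$system, h_bar = hb, alpha = a,
          U_linked = r$U_linked, ratio = r$ratio,
          pct_excess = r$pct$excess, pct_log = r$pct$log_pct,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
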