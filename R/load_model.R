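#' Percent renderings of a survival ratio
#'
#' The literature mixes three percent conventions when describing a
#' homogametic/heterogametic survival ratio \eqn{r}:
#' * `excess`: \eqn{100 (r - 1)} — "females live x% longer";
#' * `deficit`: \eqn{100 (1 - 1/r)} — "male survival reduced by x%";
#' * `log_pct`: \eqn{100 \ln r} — symmetric log-scale difference.
#' All three are returned, labelled, so reports can state which one they
#' use; they agree to first order for small effects.
#'
#' @param ratio Survival ratio (homogametic / heterogametic).
#' @return Named numeric vector with elements `excess`, `deficit`,
#'   `log_pct`.
#' @export
#' @examples
#' ratio_percents(1.03)
ratio_percents <- function(ratio) {
  stopifnot(is.numeric(ratio), all(ratio > 0))
  c(excess = 100 * (ratio - 1),
    deficit = 100 * (1 - 1 / ratio),
    log_pct = 100 * log(ratio))
}

new_load_result <- function(log_w_hom, log_w_het, system = "XY",
                            extra = list()) {
  ratio <- exp(log_w_hom - log_w_het)
  res <- c(list(
    w_hom = exp(log_w_hom),
    w_het = exp(log_w_het),
    ratio = ratio,
    pct = as.list(ratio_percents(ratio)),
    system = system,
    labels = sex_labels(system)
  ), extra)
  structure(res, class = "load_result")
}

sex_labels <- function(system) {
  switch(system,
    XY = c(hom = "female", het = "male"),
    ZW = c(hom = "male", het = "female"),
    haplodiploid = c(hom = "female", het = "male"),
    stop("unknown sex-chromosome system: ", system, call. = FALSE))
}

#' @export
print.load_result <- function(x, ...) {
  cat(sprintf("Sex-linked load (%s system)\n", x$system))
  cat(sprintf("  mean component value, homogametic (%s):   %.6f\n",
              x$labels[["hom"]], x$w_hom))
  cat(sprintf("  mean component value, heterogametic (%s): %.6f\n",
              x$labels[["het"]], x$w_het))
  cat(sprintf("  ratio (homogametic/heterogametic): %.4g\n", x$ratio))
  cat(sprintf("  percent: excess %.1f | deficit %.1f | log %.1f\n",
              x$pct$excess, x$pct$deficit, x$pct$log_pct))
  invisible(x)
}

#' Serialize a load result to JSON
#'
#' @param x A `load_result`.
#' @param path Optional path; when given the JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
load_result_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "load_result"))
  obj <- list(
    w_hom = x$w_hom, w_het = x$w_het, ratio = x$ratio,
    pct_excess = x$pct$excess, pct_deficit = x$pct$deficit,
    pct_log = x$pct$log_pct, system = x$system,
    conventions = list(
      pct_excess = "100*(ratio-1)",
      pct_deficit = "100*(1-1/ratio)",
      pct_log = "100*ln(ratio)"
    )
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Exact genome-wide multiplicative loads across sex-linked loci
#'
#' Assuming multiplicative fitness-component effects across loci at their
#' mutation-selection balance frequencies, the mean component values are
#' \deqn{\bar W_{f} = \exp\Big(-\sum_i 2 h_i s_{f,i} \alpha_{f,i}
#'   \frac{2\mu_{f,i}+\mu_{m,i}}{2 h_i s_{f,i}+s_{m,i}}\Big), \qquad
#'   \bar W_{m} = \exp\Big(-\sum_i s_{m,i} \alpha_{m,i}
#'   \frac{2\mu_{f,i}+\mu_{m,i}}{2 h_i s_{f,i}+s_{m,i}}\Big),}
#' and the unguarded-X effect is their ratio \eqn{\bar W_f/\bar W_m}.
#' Sums are accumulated in log space so that \eqn{10^4}–\eqn{10^6} tiny
#' per-locus terms do not cancel catastrophically.
#'
#' @param loci A loci collection.
#' @param system `"XY"`, `"ZW"`, or `"haplodiploid"` — controls sex labels
#'   in the result only, never the arithmetic.
#' @return A `load_result` with fields `w_hom`, `w_het`, `ratio`, `pct`.
#' @export
#' @examples
#' loci <- loci_collection(data.frame(
#'   mu_f = 1e-6, mu_m = 1e-6, s_f = 0.02, s_m = 0.02,
#'   h = 0.25, alpha_f = 0.3, alpha_m = 0.3))
#' genome_loads_exact(loci)
genome_loads_exact <- function(loci, system = "XY") {
  loci <- loci_collection(as.data.frame(loci))
  q <- equilibrium_frequency(loci)
  log_w_hom <- -sum(2 * loci$h * loci$s_f * loci$alpha_f * q)
  log_w_het <- -sum(loci$s_m * loci$alpha_m * q)
  new_load_result(log_w_hom, log_w_het, system = system)
}

check_ratio_domain <- function(U, h_bar, alpha_bar) {
  stopifnot(U >= 0, alpha_bar >= 0, alpha_bar <= 1, h_bar >= 0, h_bar <= 1)
  if (h_bar > 0.5) {
    warning("h_bar > 0.5: outside the partially recessive regime; ",
            "the predicted ratio is <= 1", call. = FALSE)
  }
}

#' Baseline unguarded-X ratio, first-order in dominance
#'
#' The simplest closed form for the female-to-male (homogametic to
#' heterogametic) survival ratio when mutation rates, selection, and
#' component effects are equal between the sexes and dominance variation
#' is negligible:
#' \deqn{\bar W_f/\bar W_m \approx \exp\Big(3 U_X \bar\alpha
#'   \frac{1-2\bar h}{1+2\bar h}\Big).}
#' At \eqn{\bar h = 0, \bar\alpha = 1} this reaches its upper limit
#' \eqn{\exp(3 U_X)}; additive mutations (\eqn{\bar h = 0.5}) give no
#' effect at all.
#'
#' @param U_X Deleterious mutation rate per sex-linked chromosome per
#'   generation.
#' @param h_bar Mean dominance coefficient of deleterious mutations.
#' @param alpha_bar Mean fraction of fitness effects acting through the
#'   focal component (survival/longevity).
#' @return The survival ratio (a scalar > 0).
#' @export
#' @examples
#' ratio_simplified(U_X = 0.1, h_bar = 0.25, alpha_bar = 0.3)  # ~1.03
ratio_simplified <- function(U_X, h_bar, alpha_bar) {
  check_ratio_domain(U_X, h_bar, alpha_bar)
  exp(3 * U_X * alpha_bar * (1 - 2 * h_bar) / (1 + 2 * h_bar))
}

#' Second-order unguarded-X ratio with dominance variance
#'
#' Taylor expansion of the exact load ratio to second order in
#' \eqn{h_i - \bar h} across loci:
#' \deqn{\bar W_f/\bar W_m \approx \exp\Big(3 U_X \bar\alpha
#'   \Big[\frac{1-2\bar h}{1+2\bar h} +
#'   \frac{8\,\mathrm{var}(h)}{(1+2\bar h)^3}\Big]\Big).}
#' With `var_h = 0` this reduces exactly to [ratio_simplified()].
#'
#' @inheritParams ratio_simplified
#' @param var_h Variance of dominance coefficients across loci (must obey
#'   the bounded-support limit `var_h <= h_bar * (1 - h_bar)`).
#' @return The survival ratio.
#' @export
ratio_baseline <- function(U_X, h_bar, var_h, alpha_bar) {
  check_ratio_domain(U_X, h_bar, alpha_bar)
  stopifnot(var_h >= 0, var_h <= h_bar * (1 - h_bar) + 1e-12)
  exp(3 * U_X * alpha_bar *
        ((1 - 2 * h_bar) / (1 + 2 * h_bar) +
           8 * var_h / (1 + 2 * h_bar)^3))
}

#' Unguarded-X ratio under sex-differential purifying selection
#'
#' When mutations affect viability similarly in the two sexes
#' (\eqn{\alpha_f s_f = \alpha_m s_m} per locus) but purifying selection
#' is stronger in the heterogametic sex by a constant factor
#' \eqn{\beta_{het/hom}}, the ratio becomes
#' \deqn{\bar W_{hom}/\bar W_{het} \approx \exp\Big(3 U \bar\alpha_{hom}
#'   \frac{1-2\bar h}{\beta_{het/hom}+2\bar h}\Big).}
#' Under XY, `beta_het_over_hom` is the usual male-to-female selection
#' ratio \eqn{\beta = s_m/s_f} and `alpha_hom` the female component
#' effect. Under ZW the sex labels reverse: pass
#' `beta_het_over_hom = s_f/s_m = 1/beta` and the male component effect —
#' [predict_scenario()] does this bookkeeping automatically. At
#' `beta_het_over_hom = 1` the expression reduces to
#' [ratio_simplified()]; stronger selection on the heterogametic sex
#' (\eqn{\beta > 1}) always dampens the effect.
#'
#' @param U Deleterious mutation rate per sex-linked chromosome.
#' @param h_bar Mean dominance coefficient.
#' @param alpha_hom Mean component effect in the homogametic sex.
#' @param beta_het_over_hom Mean selection coefficient in the
#'   heterogametic sex divided by that in the homogametic sex; must be
#'   positive.
#' @return The survival ratio (homogametic / heterogametic).
#' @export
#' @examples
#' ratio_sexdiff(U = 0.1, h_bar = 0.25, alpha_hom = 0.1,
#'               beta_het_over_hom = 1.5)  # ~1.0075
ratio_sexdiff <- function(U, h_bar, alpha_hom, beta_het_over_hom) {
  check_ratio_domain(U, h_bar, alpha_hom)
  if (beta_het_over_hom <= 0) {
    stop("beta_het_over_hom must be positive", call. = FALSE)
  }
  exp(3 * U * alpha_hom * (1 - 2 * h_bar) /
        (beta_het_over_hom + 2 * h_bar))
}

#' Unguarded-X ratio when half of loci have sex-limited effects
#'
#' In the idealized case where half the sex-linked loci affect only
#' female fitness and half only male fitness, dominance drops out
#' entirely and
#' \deqn{\bar W_f = e^{-\frac{3}{2} U_X \bar\alpha_f},\quad
#'       \bar W_m = e^{-\frac{3}{2} U_X \bar\alpha_m},\quad
#'       \bar W_f/\bar W_m = e^{\frac{3}{2} U_X(\bar\alpha_m-\bar\alpha_f)}.}
#' The effect vanishes when the component effects are equal and reverses
#' (ratio below one) when survival matters relatively more for female than
#' male fitness.
#'
#' @param U_X Sex-linked deleterious mutation rate.
#' @param alpha_f_bar,alpha_m_bar Mean component effects among the
#'   female-limited and male-limited loci.
#' @return List with `ratio`, `w_f`, and `w_m`.
#' @export
ratio_sex_limited <- function(U_X, alpha_f_bar, alpha_m_bar) {
  stopifnot(U_X >= 0,
            alpha_f_bar >= 0, alpha_f_bar <= 1,
            alpha_m_bar >= 0, alpha_m_bar <= 1)
  w_f <- exp(-1.5 * U_X * alpha_f_bar)
  w_m <- exp(-1.5 * U_X * alpha_m_bar)
  list(ratio = w_f / w_m, w_f = w_f, w_m = w_m)
}

#' Unguarded-X ratio without dosage compensation
#'
#' If hemizygous expression is not dosage-compensated, the fitness effect
#' of a mutation in the single-X sex may be reduced by a factor
#' \eqn{k \in (0, 1]} relative to its homozygous effect (selection
#' \eqn{k s} and survival effect \eqn{k s \alpha} in hemizygotes, female
#' effects unchanged). Propagating the scaling through the equilibrium
#' frequency and the loads gives
#' \deqn{\bar W_f/\bar W_m \approx \exp\Big(3 U_X \bar\alpha
#'   \frac{k-2\bar h}{k+2\bar h}\Big).}
#' Consequences: the effect survives only when \eqn{\bar h < k/2} (a more
#' restrictive dominance range than with full compensation), it is
#' strictly dampened for every \eqn{k < 1} unless mutations are fully
#' recessive, and at \eqn{k = 1} the baseline [ratio_simplified()] is
#' recovered.
#'
#' @inheritParams ratio_simplified
#' @param k Hemizygous-expression scaling factor in `(0, 1]`.
#' @return The survival ratio.
#' @export
ratio_no_dosage_comp <- function(U_X, h_bar, alpha_bar, k) {
  check_ratio_domain(U_X, h_bar, alpha_bar)
  if (k <= 0 || k > 1) stop("k must lie in (0, 1]", call. = FALSE)
  exp(3 * U_X * alpha_bar * (k - 2 * h_bar) / (k + 2 * h_bar))
}
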