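#' Exact two-sex allele-frequency recursion for an X-linked locus
#'
#' Deterministic brute-force check on every closed-form approximation in
#' the package. One generation of the life cycle (census at zygotes):
#' zygotes form by random union of eggs and sperm (females) or from eggs
#' alone (hemizygous males); viability selection acts with female
#' genotype fitnesses \eqn{1, 1 - h s_f, 1 - s_f} and male fitnesses
#' \eqn{1, 1 - s_m}; survivors produce gametes; one-way mutation
#' \eqn{A \to a} occurs in gametes at rate `mu_f` (eggs) and `mu_m`
#' (sperm). There is no back-mutation, matching mutation-selection-balance
#' convention.
#'
#' The update is exact:
#' \deqn{p_f' = \frac{p_e p_s (1 - s_f) + \tfrac12\left[p_e(1-p_s) +
#'   p_s(1-p_e)\right](1 - h s_f)}{\bar W_f}, \qquad
#'   p_m' = \frac{p_e (1 - s_m)}{1 - p_e s_m},}
#' followed by \eqn{p_e \gets p_f' + (1 - p_f')\mu_f} and
#' \eqn{p_s \gets p_m' + (1 - p_m')\mu_m}.
#'
#' All functions are vectorized over loci, so a whole collection iterates
#' as one set of vector operations.
#'
#' @param state An `equilibrium_state` as returned by
#'   [equilibrium_state()].
#' @param loci A loci collection with the same number of rows as the
#'   state has frequencies.
#' @return `recursion_step()`: the state advanced one generation.
#' @seealso [solve_equilibrium()], [validate_genome()]
#' @export
recursion_step <- function(state, loci) {
  loci <- loci_collection(as.data.frame(loci))
  p_e <- state$p_egg
  p_s <- state$p_sperm
  stopifnot(length(p_e) == nrow(loci))
  het <- p_e * (1 - p_s) + p_s * (1 - p_e)
  W_f <- 1 - loci$s_f * p_e * p_s - loci$h * loci$s_f * het
  if (any(W_f <= 0)) {
    stop("female mean fitness is zero: selection annihilates the cohort",
         call. = FALSE)
  }
  p_f <- (p_e * p_s * (1 - loci$s_f) + 0.5 * het * (1 - loci$h * loci$s_f)) /
    W_f
  p_m <- p_e * (1 - loci$s_m) / (1 - p_e * loci$s_m)
  new_e <- p_f + (1 - p_f) * loci$mu_f
  new_s <- p_m + (1 - p_m) * loci$mu_m
  equilibrium_state(
    p_egg = new_e, p_sperm = new_s,
    n_iter = state$n_iter + 1L,
    converged = state$converged,
    delta = pmax(abs(new_e - p_e), abs(new_s - p_s))
  )
}

#' Construct an allele-frequency state for the X-linked recursion
#'
#' @param p_egg,p_sperm Deleterious-allele frequencies among eggs and
#'   sperm (vectors of equal length, values in `[0, 1]`).
#' @param n_iter Iterations already applied.
#' @param converged Convergence flag(s).
#' @param delta Last absolute frequency change.
#' @return An object of class `"equilibrium_state"`; `p_X`, the pooled
#'   frequency among X chromosomes (females carry two), is
#'   `(2 * p_egg + p_sperm) / 3`.
#' @export
equilibrium_state <- function(p_egg, p_sperm, n_iter = 0L,
                              converged = FALSE, delta = NA_real_) {
  stopifnot(length(p_egg) == length(p_sperm),
            all(p_egg >= 0), all(p_egg <= 1),
            all(p_sperm >= 0), all(p_sperm <= 1))
  structure(list(
    p_egg = p_egg, p_sperm = p_sperm,
    p_X = (2 * p_egg + p_sperm) / 3,
    n_iter = as.integer(n_iter), converged = converged, delta = delta
  ), class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  n <- length(x$p_egg)
  cat(sprintf("X-linked equilibrium state (%d locus/loci)\n", n))
  cat(sprintf("  iterations: %d; converged: %s; max delta: %.3g\n",
              x$n_iter, all(x$converged), max(x$delta)))
  show <- utils::head(data.frame(p_egg = x$p_egg, p_sperm = x$p_sperm,
                                 p_X = x$p_X), 5)
  print(show, row.names = FALSE)
  if (n > 5) cat(sprintf("  ... %d more\n", n - 5))
  invisible(x)
}

#' Iterate the X-linked recursion to its mutation-selection equilibrium
#'
#' Repeatedly applies [recursion_step()] until the largest absolute
#' per-generation frequency change falls below `tol` in both gamete
#' pools, or `max_iter` is reached (non-convergence is flagged on the
#' returned state, not an error). By default iteration starts from the
#' closed-form frequency ([equilibrium_frequency()]) for speed; a cold
#' start from zero frequency is available for independence checks and
#' gives the same fixed point.
#'
#' @param loci A loci collection (all loci iterate simultaneously).
#' @param tol Absolute convergence tolerance on the per-generation change
#'   of both `p_egg` and `p_sperm`.
#' @param max_iter Iteration cap.
#' @param warm_start Start from the closed-form approximation (`TRUE`)
#'   or from `p = 0` (`FALSE`).
#' @return A converged (or flagged) `equilibrium_state`.
#' @export
#' @examples
#' l <- locus_params(1e-6, 1e-6, 0.02, 0.02, h = 0.25)
#' solve_equilibrium(l)$p_X  # ~1e-4, within 1% of the closed form
solve_equilibrium <- function(loci, tol = 1e-12, max_iter = 1e6,
                              warm_start = TRUE) {
  loci <- loci_collection(as.data.frame(loci))
  stopifnot(tol > 0)
  p0 <- if (warm_start) {
    suppressWarnings(pmin(equilibrium_frequency(loci), 1))
  } else {
    rep(0, nrow(loci))
  }
  state <- equilibrium_state(p_egg = p0, p_sperm = p0)
  for (i in seq_len(max_iter)) {
    state <- recursion_step(state, loci)
    if (max(state$delta) < tol) {
      state$converged <- TRUE
      return(state)
    }
  }
  state$converged <- FALSE
  state
}

#' Validate the closed-form genome loads against the exact recursion
#'
#' Solves the exact equilibrium for every locus, computes the per-sex
#' loads from the oracle frequencies,
#' \eqn{\bar W_f = \exp\sum_i \ln(1 - 2 h_i s_{f,i} \alpha_{f,i}\hat p_i)}
#' (males analogously with \eqn{s_m \alpha_m}), and compares the
#' resulting ratio against the three closed forms: the exact
#' multiplicative sum ([genome_loads_exact()]), the second-order Taylor
#' approximation ([ratio_baseline()]), and the first-order form
#' ([ratio_simplified()]), the latter two evaluated at the collection's
#' achieved moments (`U_X = sum(2 mu_f + mu_m) / 3`, sample mean and
#' variance of `h`, mean `alpha_f`).
#'
#' @param loci A loci collection; the Taylor comparisons presume
#'   equal-sex parameters per locus.
#' @param tol Convergence tolerance passed to [solve_equilibrium()].
#' @return A list of class `"genome_validation"`: oracle ratio, the three
#'   closed-form ratios, relative errors on the log-ratio scale, the
#'   maximum such error, and indices of any non-converged loci.
#' @export
validate_genome <- function(loci, tol = 1e-12) {
  loci <- loci_collection(as.data.frame(loci))
  st <- solve_equilibrium(loci, tol = tol)
  p_hat <- st$p_X
  log_w_f <- sum(log(1 - 2 * loci$h * loci$s_f * loci$alpha_f * p_hat))
  log_w_m <- sum(log(1 - loci$s_m * loci$alpha_m * p_hat))
  oracle_log_ratio <- log_w_f - log_w_m

  exact <- genome_loads_exact(loci)
  U_X <- sum(2 * loci$mu_f + loci$mu_m) / 3
  h_bar <- mean(loci$h)
  var_h <- stats::var(loci$h)
  if (is.na(var_h)) var_h <- 0
  alpha_bar <- mean(loci$alpha_f)
  r_taylor2 <- ratio_baseline(U_X, h_bar, var_h, alpha_bar)
  r_taylor1 <- ratio_simplified(U_X, h_bar, alpha_bar)

  rel_err <- function(r) {
    if (oracle_log_ratio == 0) return(abs(log(r)))
    abs(log(r) - oracle_log_ratio) / abs(oracle_log_ratio)
  }
  errs <- c(exact = rel_err(exact$ratio),
            taylor2 = rel_err(r_taylor2),
            taylor1 = rel_err(r_taylor1))
  structure(list(
    oracle_ratio = exp(oracle_log_ratio),
    oracle_w_f = exp(log_w_f),
    oracle_w_m = exp(log_w_m),
    exact_ratio = exact$ratio,
    taylor2_ratio = r_taylor2,
    taylor1_ratio = r_taylor1,
    achieved = list(U_X = U_X, h_bar = h_bar, var_h = var_h,
                    alpha_bar = alpha_bar),
    log_ratio_rel_err = errs,
    max_rel_err = max(errs[c("exact", "taylor2")]),
    non_converged = if (isTRUE(st$converged)) integer(0) else
      which(st$delta >= tol),
    all_converged = isTRUE(st$converged),
    n_iter = st$n_iter
  ), class = "genome_validation")
}

#' @export
print.genome_validation <- function(x, ...) {
  cat("Genome-load validation against the exact recursion\n")
  cat(sprintf("  oracle ratio: %.6f (converged: %s, %d iterations)\n",
              x$oracle_ratio, x$all_converged, x$n_iter))
  cat(sprintf("  closed-form ratios: exact %.6f | taylor2 %.6f | taylor1 %.6f\n",
              x$exact_ratio, x$taylor2_ratio, x$taylor1_ratio))
  cat(sprintf("  log-ratio relative errors: exact %.2e | taylor2 %.2e | taylor1 %.2e\n",
              x$log_ratio_rel_err["exact"], x$log_ratio_rel_err["taylor2"],
              x$log_ratio_rel_err["taylor1"]))
  invisible(x)
}
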