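#' Sex-chromosome deleterious mutation budgets
#'
#' Converts a haploid genomic deleterious mutation rate `U_H` (defined at
#' the autosomal average, where each sex's mutation rate gets equal
#' weight) into the rate for the X or Z chromosome, accounting for the
#' fraction of the haploid genome that is sex-linked (`P_X` or `P_Z`) and
#' for sex-biased mutation `R_mu` = male/female per-site rates:
#' \deqn{U_X = \frac{2(2 + R_\mu)}{3(1 + R_\mu)} U_H P_X, \qquad
#'       U_Z = \frac{2(1 + 2 R_\mu)}{3(1 + R_\mu)} U_H P_Z.}
#' An X spends two-thirds of its time in females, a Z two-thirds in
#' males, hence the opposite responses to male-biased mutation: with
#' `R_mu = 1` both reduce to `U_H * P`, while as `R_mu` grows `U_X`
#' falls toward `(2/3) U_H P_X` and `U_Z` rises toward `(4/3) U_H P_Z`.
#'
#' @param U_H Haploid genomic deleterious mutation rate per generation
#'   (non-negative).
#' @param P_X,P_Z Fraction of the haploid genome that is X-linked or
#'   Z-linked, in `(0, 1]`.
#' @param R_mu Ratio of male to female per-site mutation rates (positive).
#' @return The sex-linked deleterious mutation rate per chromosome per
#'   generation.
#' @export
#' @examples
#' ux_rate(U_H = 0.5, P_X = 0.2, R_mu = 1)   # 0.1
#' uz_rate(U_H = 1.1, P_Z = 0.1, R_mu = 4)   # 0.132
ux_rate <- function(U_H, P_X, R_mu = 1) {
  check_budget_args(U_H, P_X, R_mu)
  2 * (2 + R_mu) / (3 * (1 + R_mu)) * U_H * P_X
}

#' @rdname ux_rate
#' @export
uz_rate <- function(U_H, P_Z, R_mu = 1) {
  check_budget_args(U_H, P_Z, R_mu)
  2 * (1 + 2 * R_mu) / (3 * (1 + R_mu)) * U_H * P_Z
}

check_budget_args <- function(U_H, P, R_mu) {
  if (any(R_mu <= 0)) stop("R_mu must be positive", call. = FALSE)
  stopifnot(all(U_H >= 0), all(P > 0), all(P <= 1))
  invisible(TRUE)
}
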