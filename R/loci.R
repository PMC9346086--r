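#' Per-locus parameters for an X-linked (or Z-linked) deleterious mutation
#'
#' Bundles the seven quantities the load model needs for one biallelic
#' sex-linked locus: sex-specific per-generation mutation probabilities
#' (`mu_f` in eggs, `mu_m` in sperm), selection coefficients against the
#' mutant homozygote in the homogametic sex (`s_f`) and the hemizygote in
#' the heterogametic sex (`s_m`), the dominance coefficient `h`, and the
#' fraction of each sex's fitness effect that acts through the focal
#' fitness component, survival or longevity (`alpha_f`, `alpha_m`).
#'
#' Sex labels follow the XY convention ("f" = homogametic, "m" =
#' heterogametic); under ZW systems the labels are simply reversed, the
#' algebra is unchanged.
#'
#' @param mu_f,mu_m Mutation probabilities per generation, in `[0, 1)`.
#' @param s_f,s_m Selection coefficients, in `[0, 1]`.
#' @param h Dominance coefficient, in `[0, 1]` (overdominance excluded;
#'   values at or above 0.5 are outside the partially recessive regime the
#'   model targets and trigger a warning downstream).
#' @param alpha_f,alpha_m Component-effect fractions, in `[0, 1]`.
#' @param locus_id Optional identifier used in error messages.
#' @return A one-row locus collection (see [loci_collection()]).
#' @seealso [loci_collection()], [equilibrium_frequency()]
#' @export
#' @examples
#' locus_params(mu_f = 1e-6, mu_m = 1e-6, s_f = 0.02, s_m = 0.02,
#'              h = 0.25, alpha_f = 0.3, alpha_m = 0.3)
locus_params <- function(mu_f, mu_m, s_f, s_m, h,
                         alpha_f = 1, alpha_m = 1, locus_id = "L1") {
  loci_collection(data.frame(
    locus_id = locus_id, mu_f = mu_f, mu_m = mu_m,
    s_f = s_f, s_m = s_m, h = h,
    alpha_f = alpha_f, alpha_m = alpha_m,
    stringsAsFactors = FALSE
  ))
}

loci_columns <- c("locus_id", "mu_f", "mu_m", "s_f", "s_m",
                  "h", "alpha_f", "alpha_m")

#' Validate a collection of sex-linked loci
#'
#' A loci collection is a data frame with columns `locus_id`, `mu_f`,
#' `mu_m`, `s_f`, `s_m`, `h`, `alpha_f`, `alpha_m`, one row per locus.
#' The constructor checks the parameter ranges and attaches the class
#' `"uxg_loci"`; `n_loci()` returns the number of loci.
#'
#' @param x A data frame with the columns above (`locus_id` is filled in
#'   when absent).
#' @return `x`, validated, with class `c("uxg_loci", "data.frame")`.
#' @export
loci_collection <- function(x) {
  stopifnot(is.data.frame(x))
  if (nrow(x) < 1) stop("loci collection must contain at least one locus",
                        call. = FALSE)
  if (!("locus_id" %in% names(x))) {
    x$locus_id <- paste0("L", seq_len(nrow(x)))
  }
  missing <- setdiff(loci_columns, names(x))
  if (length(missing) > 0) {
    stop("loci collection is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- x[, loci_columns]
  chk <- function(v, lo, hi, nm, open_hi = FALSE) {
    bad <- !is.finite(x[[v]]) | x[[v]] < lo |
      (if (open_hi) x[[v]] >= hi else x[[v]] > hi)
    if (any(bad)) {
      stop(sprintf("%s out of range for loci: %s", nm,
                   paste(utils::head(x$locus_id[bad], 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  chk("mu_f", 0, 1, "mu_f", open_hi = TRUE)
  chk("mu_m", 0, 1, "mu_m", open_hi = TRUE)
  chk("s_f", 0, 1, "s_f")
  chk("s_m", 0, 1, "s_m")
  chk("h", 0, 1, "h")
  chk("alpha_f", 0, 1, "alpha_f")
  chk("alpha_m", 0, 1, "alpha_m")
  class(x) <- c("uxg_loci", "data.frame")
  x
}

#' @rdname loci_collection
#' @export
n_loci <- function(x) nrow(x)

#' Read or write a loci collection as CSV
#'
#' Plain CSV with header `locus_id, mu_f, mu_m, s_f, s_m, h, alpha_f,
#' alpha_m`; the on-disk interchange format for locus collections.
#'
#' @param path File path.
#' @param loci A loci collection.
#' @return `read_loci()` returns a validated loci collection;
#'   `write_loci()` returns `path` invisibly.
#' @export
read_loci <- function(path) {
  loci_collection(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_loci
#' @export
write_loci <- function(loci, path) {
  utils::write.csv(as.data.frame(loci), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Equilibrium frequency of a deleterious allele at an X-linked locus
#'
#' Mutation-selection balance frequency under strong selection relative to
#' mutation:
#' \deqn{\hat p = \frac{2\mu_f + \mu_m}{2 s_f h + s_m}.}
#' The numerator weights egg-borne mutation twice because females carry two
#' X copies; the denominator combines heterozygous selection in females
#' with hemizygous selection in males. The approximation presumes
#' \eqn{2\mu_f + \mu_m \ll 2 s_f h + s_m}; a warning is emitted when the
#' mutation pressure exceeds 1% of the selection denominator (the exact
#' recursion in [solve_equilibrium()] quantifies the error outside that
#' regime). A locus neutral in both sexes (zero denominator) has no
#' balance and is an error.
#'
#' @param loci A loci collection (vectorized over rows).
#' @return Numeric vector of equilibrium frequencies, one per locus.
#' @export
#' @examples
#' l <- locus_params(1e-6, 1e-6, 0.02, 0.02, h = 0.25)
#' equilibrium_frequency(l)  # 1e-4
equilibrium_frequency <- function(loci) {
  loci <- loci_collection(as.data.frame(loci))
  num <- 2 * loci$mu_f + loci$mu_m
  den <- 2 * loci$s_f * loci$h + loci$s_m
  zero <- den <= 0 & num > 0
  if (any(zero)) {
    stop("selection denominator 2*s_f*h + s_m is zero at loci with ",
         "nonzero mutation: ",
         paste(utils::head(loci$locus_id[zero], 5), collapse = ", "),
         call. = FALSE)
  }
  weak <- num > 0.01 * den & num > 0
  if (any(weak)) {
    warning(sprintf(
      "strong-selection approximation dubious at %d locus/loci (e.g. %s): 2*mu_f + mu_m > 0.01 * (2*s_f*h + s_m)",
      sum(weak), loci$locus_id[which(weak)[1]]), call. = FALSE)
  }
  ifelse(num == 0, 0, num / den)
}

#' Per-locus contribution to mean survival of each sex
#'
#' At frequency `freq` of the deleterious allele on X chromosomes, the
#' locus multiplies female mean survival by
#' \eqn{w_f = 1 - 2 h s_f \alpha_f \hat p} (heterozygous carriers, two
#' copies) and male mean survival by \eqn{w_m = 1 - s_m \alpha_m \hat p}
#' (hemizygous exposure). Factors at or below zero mean the linearized
#' per-locus model is invalid and raise an error rather than being
#' clamped.
#'
#' @param loci A loci collection.
#' @param freq Allele frequency, one value per locus (defaults to the
#'   mutation-selection balance frequency).
#' @return A data frame with columns `w_f` and `w_m`.
#' @export
locus_component_means <- function(loci, freq = equilibrium_frequency(loci)) {
  loci <- loci_collection(as.data.frame(loci))
  stopifnot(length(freq) == nrow(loci), all(freq >= 0), all(freq <= 1))
  w_f <- 1 - 2 * loci$h * loci$s_f * loci$alpha_f * freq
  w_m <- 1 - loci$s_m * loci$alpha_m * freq
  if (any(w_f <= 0) || any(w_m <= 0)) {
    stop("per-locus survival factor <= 0: the linearized multiplicative ",
         "model is invalid for these parameters", call. = FALSE)
  }
  data.frame(w_f = w_f, w_m = w_m)
}
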