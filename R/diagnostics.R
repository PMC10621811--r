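# Agreement and diagnostic-accuracy statistics for 2x2 cross-
# classifications of a reference test against the screener (index test).
#
# Conventions, chosen to match how such validation studies report results:
# * Cohen's kappa with the marginal null-variance significance test
#   (z = kappa / se0, where se0 is the standard error of kappa under
#   independence of the margins), two-sided normal p, no continuity
#   correction.
# * Wald (normal approximation) binomial confidence intervals with
#   z = 1.96, reported unclipped: bounds can leave [0, 1] at small n, and
#   are deliberately not truncated.

#' Construct a 2x2 contingency table
#'
#' Cell layout: `a` reference+/index+, `b` reference+/index-,
#' `c` reference-/index+, `d` reference-/index-.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param reference,index Labels for the two classifications.
#' @return A `contingency_2x2` object.
#' @export
contingency_2x2 <- function(a, b, c, d, reference = "reference",
                            index = "index") {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (sum(counts) < 1)
    stop("contingency table is empty", call. = FALSE)
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), n = as.integer(a + b + c + d),
                 reference = reference, index = index),
            class = "contingency_2x2")
}

#' Cross-classify two flag vectors
#'
#' @param reference_flags,index_flags Logical vectors over the same
#'   children; if named, names must agree (they are aligned by name).
#' @return A `contingency_2x2` of the joint outcomes.
#' @export
build_contingency <- function(reference_flags, index_flags,
                              reference = "reference", index = "index") {
  if (length(reference_flags) == 0L)
    stop("empty flag vectors", call. = FALSE)
  if (!is.null(names(reference_flags)) && !is.null(names(index_flags))) {
    if (!setequal(names(reference_flags), names(index_flags)))
      stop("reference and index flags cover different children", call. = FALSE)
    index_flags <- index_flags[names(reference_flags)]
  } else if (length(reference_flags) != length(index_flags)) {
    stop("flag vectors differ in length", call. = FALSE)
  }
  if (anyNA(reference_flags) || anyNA(index_flags))
    stop("flags must be TRUE/FALSE, not NA", call. = FALSE)
  contingency_2x2(sum(reference_flags & index_flags),
                  sum(reference_flags & !index_flags),
                  sum(!reference_flags & index_flags),
                  sum(!reference_flags & !index_flags),
                  reference = reference, index = index)
}

#' Cohen's kappa with the marginal null-variance test
#'
#' Observed agreement `po = (a + d) / n`; chance agreement `pe` from the
#' products of the row and column marginal proportions; kappa
#' `(po - pe) / (1 - pe)`.  The null standard error under independent
#' margins is
#' `se0 = sqrt(pe + pe^2 - sum_i p_i. * p_.i * (p_i. + p_.i)) / ((1 - pe) * sqrt(n))`,
#' giving `z = kappa / se0` and a two-sided normal p-value.  When `pe = 1`
#' (both margins degenerate) kappa is defined as 1 if `po = 1` and 0
#' otherwise, flagged `degenerate`, with no standard error.
#'
#' @param table A `contingency_2x2`.
#' @return An `agreement_stats` object: `kappa`, `po`, `pe`, `se0`, `z`,
#'   `p_value`, `n`, `band` (Landis-Koch interpretation) and `degenerate`.
#' @export
cohen_kappa <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  n <- table$n
  po <- (table$a + table$d) / n
  prow <- c(table$a + table$b, table$c + table$d) / n
  pcol <- c(table$a + table$c, table$b + table$d) / n
  pe <- sum(prow * pcol)
  if (1 - pe < .Machine$double.eps^0.5) {
    kappa <- if (po >= 1) 1 else 0
    return(structure(list(kappa = kappa, po = po, pe = pe, se0 = NA_real_,
                          z = NA_real_, p_value = NA_real_, n = n,
                          band = interpret_kappa(kappa), degenerate = TRUE),
                     class = "agreement_stats"))
  }
  kappa <- (po - pe) / (1 - pe)
  var0 <- (pe + pe^2 - sum(prow * pcol * (prow + pcol))) / (n * (1 - pe)^2)
  se0 <- sqrt(max(var0, 0))
  z <- if (se0 > 0) kappa / se0 else NA_real_
  p <- if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z))
  structure(list(kappa = kappa, po = po, pe = pe, se0 = se0, z = z,
                 p_value = p, n = n, band = interpret_kappa(kappa),
                 degenerate = FALSE),
            class = "agreement_stats")
}

#' Landis-Koch interpretation band for kappa
#'
#' @param kappa Numeric in `[-1, 1]`.
#' @return Character: `poor` (< 0), `slight` (0-0.20), `fair` (0.21-0.40),
#'   `moderate` (0.41-0.60), `substantial` (0.61-0.80) or
#'   `almost_perfect` (0.81-1).
#' @export
interpret_kappa <- function(kappa) {
  if (any(is.na(kappa)) || any(kappa < -1 - 1e-12) || any(kappa > 1 + 1e-12))
    stop("kappa must lie in [-1, 1]", call. = FALSE)
  ifelse(kappa < 0, "poor",
    ifelse(kappa <= 0.20, "slight",
      ifelse(kappa <= 0.40, "fair",
        ifelse(kappa <= 0.60, "moderate",
          ifelse(kappa <= 0.80, "substantial", "almost_perfect")))))
}

.binomial_rate <- function(k, m, z_level) {
  if (m < 1) {
    return(structure(list(estimate = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, numerator = k, denominator = m,
                          z_level = z_level,
                          status = "undefined: zero margin"),
                     class = "binomial_rate"))
  }
  p <- k / m
  half <- z_level * sqrt(p * (1 - p) / m)
  structure(list(estimate = p, ci_low = p - half, ci_high = p + half,
                 numerator = as.integer(k), denominator = as.integer(m),
                 z_level = z_level, status = "ok"),
            class = "binomial_rate")
}

#' Sensitivity and specificity with Wald confidence intervals
#'
#' Sensitivity `a / (a + b)` (reference-positives flagged by the index
#' test) and specificity `d / (c + d)` (reference-negatives not flagged),
#' each with the Wald interval `p +/- z * sqrt(p (1 - p) / m)`.  Bounds are
#' reported unclipped -- at small margins they can fall outside [0, 1] --
#' for fidelity with how such studies print them.  A zero margin yields an
#' explicit `undefined` status rather than a number.
#'
#' @param table A `contingency_2x2` with the reference test on the rows.
#' @param z_level Normal quantile for the interval (default 1.96).
#' @return List with `binomial_rate` elements `sensitivity` and
#'   `specificity`.
#' @export
sensitivity_specificity <- function(table, z_level = 1.96) {
  stopifnot(inherits(table, "contingency_2x2"))
  list(sensitivity = .binomial_rate(table$a, table$a + table$b, z_level),
       specificity = .binomial_rate(table$d, table$c + table$d, z_level))
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(paste(x$reference, c("+", "-")),
                              paste(x$index, c("+", "-"))))
  cat(sprintf("<contingency_2x2> n = %d\n", x$n))
  print(m)
  invisible(x)
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> kappa = %.3f (%s agreement), n = %d\n",
              x$kappa, gsub("_", " ", x$band), x$n))
  if (isTRUE(x$degenerate)) {
    cat("  degenerate margins: chance agreement is 1, no standard error\n")
  } else {
    cat(sprintf("  po = %.3f, pe = %.3f, se0 = %.4f, z = %.3f, p = %.3g\n",
                x$po, x$pe, x$se0, x$z, x$p_value))
  }
  invisible(x)
}

#' @export
print.binomial_rate <- function(x, ...) {
  if (x$status != "ok") {
    cat("<binomial_rate>", x$status, "\n")
  } else {
    cat(sprintf("<binomial_rate> %.3f (%d/%d), %d%% CI [%.3f, %.3f] (Wald, unclipped)\n",
                x$estimate, x$numerator, x$denominator,
                round(100 * (2 * pnorm(x$z_level) - 1)), x$ci_low, x$ci_high))
  }
  invisible(x)
}
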