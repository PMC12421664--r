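# Two-point complete-basis-set (CBS) and complete-PNO-space (CPS)
# extrapolation of scalar energies and whole matrix sets.
#
# CBS uses the standard two-point forms: the reference (mean-field) energy
# converges as E(n) = E_CBS + A exp(-alpha sqrt(n)) in the cardinal number n,
# the correlation energy as E(n) = E_CBS + B n^-beta. CPS is the affine
# two-point scheme E_CPS = E_X + F (E_Y - E_X) over energies at two successive
# T_CutPNO exponents (the looser threshold is X). All three are affine in
# (E_X, E_Y), so extrapolation commutes with any linear assembly of LED terms.

#' Default CBS coefficient table
#'
#' Two-point CBS exponents per basis family and cardinal pair, shipped as a
#' user-replaceable CSV (values optimized for the (aug)-cc-pVnZ family:
#' alpha = 4.420 / beta = 2.460 for the 2/3 pair, alpha = 5.460 /
#' beta = 3.050 for 3/4).
#'
#' @return Data frame with columns family, X, Y, alpha, beta.
#' @export
cbs_coefficient_table <- function() {
  utils::read.csv(system.file("extdata", "cbs_coefficients.csv",
                              package = "ledkit"),
                  stringsAsFactors = FALSE)
}

#' Extrapolation parameters
#'
#' @param kind `"CBS"` (basis-set) or `"CPS"` (PNO-space).
#' @param X,Y the two cardinal numbers (CBS) or T_CutPNO exponents (CPS);
#'   `Y > X`, and for CPS the thresholds are expected at successive exponents
#'   (Y = X + 1). `X` always denotes the smaller basis / looser threshold.
#' @param alpha,beta CBS exponents for the reference and correlation energies.
#'   When `NULL` they are looked up in [cbs_coefficient_table()] for
#'   `basis_family` and the (X, Y) pair.
#' @param F CPS multiplier (default 1.5, the two-point PNO scheme's value).
#' @param basis_family key into the coefficient table (default `"cc"`).
#' @return Object of class `led_extrap_params`.
#' @export
extrapolation_params <- function(kind = c("CBS", "CPS"), X, Y,
                                 alpha = NULL, beta = NULL, F = 1.5,
                                 basis_family = "cc") {
  kind <- match.arg(kind)
  stopifnot(Y > X)
  if (kind == "CBS" && (is.null(alpha) || is.null(beta))) {
    tab <- cbs_coefficient_table()
    row <- tab[tab$family == basis_family & tab$X == X & tab$Y == Y, ]
    if (nrow(row) == 0) {
      stop(sprintf("no CBS coefficients for family '%s' pair (%d/%d); ",
                   basis_family, X, Y),
           "pass alpha and beta explicitly", call. = FALSE)
    }
    if (is.null(alpha)) alpha <- row$alpha[1]
    if (is.null(beta)) beta <- row$beta[1]
  }
  if (kind == "CBS") stopifnot(alpha > 0, beta > 0)
  structure(list(kind = kind, X = X, Y = Y, alpha = alpha, beta = beta,
                 F = F, basis_family = basis_family),
            class = "led_extrap_params")
}

#' Two-point CBS extrapolation of a reference energy
#'
#' Solves `E(n) = E_CBS + A exp(-alpha sqrt(n))` through the two points
#' `(X, E_X)` and `(Y, E_Y)` and returns the complete-basis-set limit.
#'
#' @param e_x,e_y energies (Hartree) at cardinal numbers `params$X` and
#'   `params$Y`.
#' @param params an `led_extrap_params` of kind `"CBS"`.
#' @return E_CBS in Hartree.
#' @export
cbs_reference <- function(e_x, e_y, params) {
  stopifnot(params$kind == "CBS")
  gx <- exp(-params$alpha * sqrt(params$X))
  gy <- exp(-params$alpha * sqrt(params$Y))
  if (abs(gx - gy) < .Machine$double.eps * max(abs(gx), abs(gy), 1)) {
    stop("degenerate CBS reference parameters: basis weights coincide",
         call. = FALSE)
  }
  (e_x * gy - e_y * gx) / (gy - gx)
}

#' Two-point CBS extrapolation of a correlation energy
#'
#' Inverse-power form `E(n) = E_CBS + B n^-beta`, giving
#' `E_CBS = (X^beta E_X - Y^beta E_Y) / (X^beta - Y^beta)`.
#'
#' @inheritParams cbs_reference
#' @return E_CBS in Hartree.
#' @export
cbs_correlation <- function(e_x, e_y, params) {
  stopifnot(params$kind == "CBS")
  if (params$X == params$Y) stop("degenerate CBS parameters: X == Y",
                                 call. = FALSE)
  px <- params$X^params$beta
  py <- params$Y^params$beta
  (px * e_x - py * e_y) / (px - py)
}

#' Two-point CPS extrapolation
#'
#' Complete-PNO-space estimate `E_X + F (E_Y - E_X)` from energies at two
#' successive T_CutPNO exponents; `e_x` is the looser-threshold (smaller
#' exponent) energy.
#'
#' @inheritParams cbs_reference
#' @param params an `led_extrap_params` of kind `"CPS"`.
#' @return Extrapolated energy in Hartree.
#' @export
cps <- function(e_x, e_y, params) {
  stopifnot(params$kind == "CPS")
  e_x + params$F * (e_y - e_x)
}

REF_COMPONENTS <- c("elstat", "exch", "elprep_ref", "solv")
CORR_COMPONENTS <- c("no_disp", "disp", "elprep_corr")

#' Extrapolate a matrix set
#'
#' Applies the scalar two-point formulas cellwise: reference-level components
#' (electrostatics, exchange, solvation, reference part of the electronic
#' preparation) through [cbs_reference()]; correlation-level components
#' (non-dispersion, dispersion, correlation part of the electronic
#' preparation) through [cbs_correlation()]. Under CPS only the correlation
#' components are extrapolated; reference components pass through unchanged
#' from the tighter-threshold set (PNO truncation does not affect the
#' reference energy). The composite elprep and total components are recomputed
#' from the extrapolated parts; absent cells stay absent.
#'
#' Individual LED terms are extrapolated exactly like the parent reference and
#' correlation energies, which is well defined because both formulas are
#' affine.
#'
#' @param ms_x,ms_y `led_matrix_set`s at the smaller/larger cardinal (CBS) or
#'   looser/tighter threshold (CPS); labels, layout and absent masks must
#'   match.
#' @param params an `led_extrap_params`.
#' @return The extrapolated `led_matrix_set`.
#' @export
extrapolate_matrixset <- function(ms_x, ms_y, params) {
  if (!identical(ms_x$fragment_labels, ms_y$fragment_labels) ||
      !identical(ms_x$layout, ms_y$layout)) {
    stop("alignment error: matrix sets differ in labels or layout",
         call. = FALSE)
  }
  if (!identical(ms_x$absent, ms_y$absent)) {
    stop("alignment error: absent masks differ", call. = FALSE)
  }
  out <- ms_y
  comps <- names(ms_y$components)
  for (cc in intersect(comps, REF_COMPONENTS)) {
    out$components[[cc]] <- if (params$kind == "CBS") {
      cbs_reference(ms_x$components[[cc]], ms_y$components[[cc]], params)
    } else {
      ms_y$components[[cc]]
    }
  }
  for (cc in intersect(comps, CORR_COMPONENTS)) {
    out$components[[cc]] <- if (params$kind == "CBS") {
      cbs_correlation(ms_x$components[[cc]], ms_y$components[[cc]], params)
    } else {
      cps(ms_x$components[[cc]], ms_y$components[[cc]], params)
    }
  }
  out$components$elprep <- out$components$elprep_ref +
    out$components$elprep_corr
  eps_names <- intersect(c(LED_EPS_COMPONENTS, "solv"), comps)
  out$components$total <- out$components$elprep +
    Reduce(`+`, out$components[eps_names])
  if (out$layout == "fp") diag(out$components$total) <- 0
  for (cc in names(out$components)) out$components[[cc]][out$absent] <- 0
  out$provenance <- c(
    out$provenance,
    sprintf("%s(%s/%s) extrapolated%s", params$kind, params$X, params$Y,
            if (params$kind == "CBS") {
              sprintf(" (alpha=%.3f, beta=%.3f)", params$alpha, params$beta)
            } else sprintf(" (F=%.3f)", params$F)))
  out
}
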