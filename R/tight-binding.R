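#' Single-inhibitor dose-response series
#'
#' Container for rates measured at a ladder of inhibitor concentrations
#' under fixed assay conditions, possibly in the presence of a fixed
#' concentration of the second inhibitor.  Points are sorted by
#' concentration on ingestion; at least three distinct concentrations
#' are required for any downstream fit.
#'
#' @param conc_nM inhibitor concentrations (nM), one per measurement.
#' @param rate measured rates (uM per minute), same length.
#' @param inhibitor `"d"` (FdUMP, nucleotide site) or `"m"` (RTX,
#'   folate site).
#' @param co_conc_nM fixed concentration of the other inhibitor (nM).
#' @param replicate optional replicate index per measurement.
#' @param E_T total enzyme (nM).
#' @param D,M assay substrate/cofactor totals (uM).
#' @return A data frame of class `dose_response_series` with columns
#'   `conc_nM`, `rate`, `replicate` and metadata in attributes.
#' @export
dose_response_series <- function(conc_nM, rate, inhibitor = c("m", "d"),
                                 co_conc_nM = 0, replicate = NULL,
                                 E_T = 300, D = 120, M = 55) {
  inhibitor <- match.arg(inhibitor)
  if (length(conc_nM) != length(rate)) {
    stop("'conc_nM' and 'rate' must have the same length", call. = FALSE)
  }
  if (any(!is.finite(conc_nM)) || any(conc_nM < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(rate))) stop("rates must be finite", call. = FALSE)
  if (length(unique(conc_nM)) < 3L) {
    stop("at least 3 distinct inhibitor concentrations are required",
         call. = FALSE)
  }
  if (is.null(replicate)) replicate <- rep(1L, length(conc_nM))
  ord <- order(conc_nM, replicate)
  out <- data.frame(conc_nM = conc_nM[ord], rate = rate[ord],
                    replicate = replicate[ord])
  attr(out, "inhibitor") <- inhibitor
  attr(out, "co_conc_nM") <- co_conc_nM
  attr(out, "E_T") <- E_T
  attr(out, "D") <- D
  attr(out, "M") <- M
  class(out) <- c("dose_response_series", "data.frame")
  out
}

#' Morrison fractional activity for a tight-binding inhibitor
#'
#' Closed-form fractional activity `v/v0` for a single inhibitor whose
#' concentration is comparable to the enzyme concentration, so that
#' depletion of free inhibitor by binding cannot be neglected.  From
#' the binding quadratic:
#' `a = ((E_T - I_T - K_app) + sqrt((E_T - I_T - K_app)^2 +
#' 4 K_app E_T)) / (2 E_T)`.
#'
#' As `E_T -> 0` this reduces to the Michaelis-Menten hyperbola
#' `1/(1 + I/K_app)`; as `K_app -> 0` it becomes the stoichiometric
#' titration line `1 - I_T/E_T`.
#'
#' @param E_T total enzyme (nM), positive scalar.
#' @param I_T total inhibitor (nM), vectorised.
#' @param K_app apparent dissociation constant under the assay's
#'   substrate/cofactor competition (nM).
#' @return Fractional activity in (0, 1].
#' @export
morrison_activity <- function(E_T, I_T, K_app) {
  if (!is.numeric(E_T) || length(E_T) != 1L || !is.finite(E_T) || E_T <= 0) {
    stop("'E_T' must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(I_T)) || any(I_T < 0)) {
    stop("'I_T' must be finite and non-negative", call. = FALSE)
  }
  if (!is.finite(K_app) || K_app <= 0) {
    stop("'K_app' must be a single positive number", call. = FALSE)
  }
  b <- E_T - I_T - K_app
  (b + sqrt(b^2 + 4 * K_app * E_T)) / (2 * E_T)
}

#' Henderson linearization of tight-binding inhibition data
#'
#' Classical linear transform of depletion-regime inhibition data:
#' plotting `I_T / (1 - a)` against `1/a` (with `a = v/v0`) gives a
#' straight line with slope `K_app` and intercept `E_T`.  Exact on
#' noise-free Morrison data; on noisy data it is used only to seed the
#' nonlinear fit and as a diagnostic.
#'
#' @param series a [dose_response_series()].
#' @param v0 uninhibited rate; defaults to the mean rate at zero
#'   inhibitor, which must then be present in the series.
#' @return A list with the transformed points (`x`, `y`), the
#'   least-squares `slope` (K_app estimate, nM) and `intercept`
#'   (E_T estimate, nM).
#' @export
henderson_linearize <- function(series, v0 = NULL) {
  stopifnot(inherits(series, "dose_response_series"))
  if (is.null(v0)) {
    at0 <- series$rate[series$conc_nM == 0]
    if (length(at0) == 0L) {
      stop("no zero-inhibitor point present; supply 'v0'", call. = FALSE)
    }
    v0 <- mean(at0)
  }
  a <- series$rate / v0
  keep <- series$conc_nM > 0 & a < 1 & a > 0
  if (any(!keep)) {
    warning(sum(!keep), " point(s) with no measurable inhibition excluded ",
            "from the Henderson transform")
  }
  if (!any(keep)) stop("no usable points for linearization", call. = FALSE)
  x <- 1 / a[keep]
  y <- series$conc_nM[keep] / (1 - a[keep])
  fit <- stats::lm(y ~ x)
  list(x = x, y = y,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Tight-binding fit of a single-inhibitor dose-response series
#'
#' Nonlinear least squares of measured rates against
#' `v0 * morrison_activity(E_T, I, K_app)` with `v0` and `K_app` free.
#' Standard Dixon plots are curved in this regime, so the depletion-
#' corrected quadratic form is the primary estimator; the Henderson
#' linearization supplies starting values.  The intercept-derived
#' catalytic constant `k_cat = v0 / E_T` is reported alongside.
#'
#' @param series a [dose_response_series()].
#' @param weights optional `"none"` (default, homoscedastic) or
#'   `"relative"` (weights 1/rate^2 for multiplicative error).
#' @return An object of class `tight_binding_fit`: a list with
#'   `K_app`, `K_app_se`, `v0`, `v0_se`, `k_cat`, `converged`,
#'   `residual_norm` and the underlying `nls` fit.
#' @export
fit_single_inhibitor <- function(series, weights = c("none", "relative")) {
  stopifnot(inherits(series, "dose_response_series"))
  weights <- match.arg(weights)
  if (all(series$rate <= 0)) {
    stop("all rates are non-positive; nothing to fit", call. = FALSE)
  }
  E_T <- attr(series, "E_T")
  v0_guess <- if (any(series$conc_nM == 0)) {
    mean(series$rate[series$conc_nM == 0])
  } else {
    max(series$rate)
  }
  K_guess <- tryCatch(
    max(henderson_linearize(series, v0 = v0_guess)$slope, 1e-3),
    error = function(e) stats::median(series$conc_nM[series$conc_nM > 0])
  )
  use_weights <- weights == "relative"
  dat <- data.frame(conc = series$conc_nM, rate = series$rate)
  dat$wt <- if (use_weights) 1 / pmax(dat$rate, 1e-12)^2 else 1
  fit <- tryCatch(
    if (use_weights) {
      minpack.lm::nlsLM(
        rate ~ v0 * morrison_activity(E_T, conc, K_app),
        data = dat,
        start = list(v0 = v0_guess, K_app = K_guess),
        lower = c(v0 = 1e-12, K_app = 1e-9),
        weights = wt,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    } else {
      minpack.lm::nlsLM(
        rate ~ v0 * morrison_activity(E_T, conc, K_app),
        data = dat,
        start = list(v0 = v0_guess, K_app = K_guess),
        lower = c(v0 = 1e-12, K_app = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    },
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    stop("tight-binding fit did not converge: ", conditionMessage(fit),
         call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  out <- list(
    K_app = cf["K_app", "Estimate"],
    K_app_se = cf["K_app", "Std. Error"],
    v0 = cf["v0", "Estimate"],
    v0_se = cf["v0", "Std. Error"],
    k_cat = cf["v0", "Estimate"] / (E_T / 1000),
    E_T = E_T,
    converged = fit$convInfo$isConv,
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    fit = fit
  )
  class(out) <- "tight_binding_fit"
  out
}

#' @export
print.tight_binding_fit <- function(x, ...) {
  cat("Tight-binding (Morrison) fit\n")
  cat(sprintf("  K_app = %.4g +/- %.2g nM\n", x$K_app, x$K_app_se))
  cat(sprintf("  v0    = %.4g +/- %.2g uM/min (k_cat = %.3g /min at E_T = %g nM)\n",
              x$v0, x$v0_se, x$k_cat, x$E_T))
  cat(sprintf("  converged: %s, residual norm %.3g\n",
              x$converged, x$residual_norm))
  invisible(x)
}

#' Convert an apparent inhibition constant to a true dissociation constant
#'
#' Removes the substrate/cofactor competition folded into the apparent
#' constant measured in the assay.  With the binding polynomial of the
#' uninhibited pool `Z0 = 1 + D/K_D + (D/K_D)(M/K_M)`:
#' * the folate-site inhibitor (`"m"`) binds the ED complex, so
#'   `K_m = K_app * (D/K_D) / Z0` - independent of K_M';
#' * the nucleotide-site inhibitor (`"d"`) binds free enzyme and its
#'   complex recruits cofactor at K_M', so
#'   `K_d = K_app * (1 + M/K_M') / Z0`, which depends on the assumed
#'   K_M' only through the factor `(1 + M/K_M')` (see [rescale_Kd()]).
#'
#' @param K_app apparent constant from [fit_single_inhibitor()] (nM).
#' @param species `"d"` or `"m"`.
#' @param D,M assay totals (uM).
#' @param K_D,K_M Michaelis constants (uM).
#' @param KMp_mult assumed K_M'/K_M multiplier (only used for `"d"`).
#' @return True dissociation constant (nM).
#' @export
apparent_to_true <- function(K_app, species = c("m", "d"),
                             D = 120, M = 55, K_D = 10, K_M = 5,
                             KMp_mult = 1) {
  species <- match.arg(species)
  for (nm in c("K_app", "D", "M", "K_D", "K_M", "KMp_mult")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("'", nm, "' must be a single positive number", call. = FALSE)
    }
  }
  Z0 <- 1 + D / K_D + (D / K_D) * (M / K_M)
  if (species == "m") {
    K_app * (D / K_D) / Z0
  } else {
    K_app * (1 + M / (KMp_mult * K_M)) / Z0
  }
}

#' Rescale a FdUMP dissociation constant between K_M' assumptions
#'
#' The true K_d extracted from a tight-binding fit depends on the
#' unknown dissociation constant K_M' of the cofactor from the
#' FdUMP-occupied enzyme only through the factor `(1 + M/K_M')`:
#' `K_d_new = K_d_ref * (1 + M/K_M'_new) / (1 + M/K_M'_ref)`.
#' The identity holds when the assumption is unchanged and chains
#' transitively across assumptions.
#'
#' @param K_d_ref reference constant (nM).
#' @param KMp_ref,KMp_new reference and new K_M' values (uM).
#' @param M assay cofactor total (uM).
#' @return Rescaled constant (nM).
#' @examples
#' # anchored at 86 nM under K_M' = K_M = 5 uM, M = 55 uM:
#' rescale_Kd(86, KMp_ref = 5, KMp_new = 10, M = 55)  # ~47 nM
#' rescale_Kd(86, KMp_ref = 5, KMp_new = 2.5, M = 55) # ~164 nM
#' @export
rescale_Kd <- function(K_d_ref, KMp_ref, KMp_new, M) {
  for (nm in c("K_d_ref", "KMp_ref", "KMp_new", "M")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("'", nm, "' must be a single positive number", call. = FALSE)
    }
  }
  K_d_ref * (1 + M / KMp_new) / (1 + M / KMp_ref)
}
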