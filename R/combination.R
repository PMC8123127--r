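#' Dixon-type series of reciprocal rates
#'
#' Pairs reciprocal rates `1/v` with inhibitor concentrations.  Under
#' classical Michaelis-Menten conditions the plot is linear in the
#' inhibitor concentration; in the tight-binding regime it is curved,
#' and the diagnostic quantity becomes the slope of the tangent at the
#' origin (see [tangent_slope()]).
#'
#' @param conc_nM inhibitor concentrations (nM).
#' @param rate rates (uM per minute), strictly positive.
#' @param co_conc_nM fixed co-inhibitor concentration (nM).
#' @param inhibitor axis inhibitor id (`"d"` or `"m"`).
#' @return A data frame of class `dixon_series` with columns `conc_nM`
#'   and `inv_rate` (min per uM).
#' @export
dixon_series <- function(conc_nM, rate, co_conc_nM = 0,
                         inhibitor = c("d", "m")) {
  inhibitor <- match.arg(inhibitor)
  if (length(conc_nM) != length(rate)) {
    stop("'conc_nM' and 'rate' must have the same length", call. = FALSE)
  }
  bad <- which(!is.finite(rate) | rate <= 0)
  if (length(bad) > 0L) {
    stop("non-positive rate at point ", bad[1], " (conc ", conc_nM[bad[1]],
         " nM); reciprocal undefined", call. = FALSE)
  }
  ord <- order(conc_nM)
  out <- data.frame(conc_nM = conc_nM[ord], inv_rate = 1 / rate[ord])
  attr(out, "inhibitor") <- inhibitor
  attr(out, "co_conc_nM") <- co_conc_nM
  class(out) <- c("dixon_series", "data.frame")
  out
}

#' Tangent-at-origin slope of a curved Dixon plot
#'
#' Fits `1/v = a * exp(b * conc)` by nonlinear least squares over a
#' concentration window (default 0-100 nM) and returns the slope of
#' the tangent at the origin, `a * b`.  The exponent is constrained
#' non-negative since inhibition can only increase `1/v`.
#'
#' @param series a [dixon_series()].
#' @param window concentration range (nM) used for the fit.
#' @return A list with `slope` (tangent at origin), `a`, `b` and the
#'   number of points used.
#' @export
tangent_slope <- function(series, window = c(0, 100)) {
  stopifnot(inherits(series, "dixon_series"), length(window) == 2L)
  keep <- series$conc_nM >= window[1] & series$conc_nM <= window[2]
  if (sum(keep) < 3L) {
    stop("need at least 3 points inside the fit window [", window[1], ", ",
         window[2], "] nM", call. = FALSE)
  }
  dat <- data.frame(x = series$conc_nM[keep], y = series$inv_rate[keep])
  # log-linear seed; exact when the data are exactly exponential
  lf <- stats::lm(log(y) ~ x, data = dat)
  b0 <- max(unname(stats::coef(lf)[2]), 0)
  a0 <- exp(unname(stats::coef(lf)[1]))
  if (sqrt(mean(stats::resid(lf)^2)) < 1e-10) {
    # data are exactly exponential (incl. flat); the seed is the answer
    return(list(slope = a0 * b0, a = a0, b = b0, n = sum(keep)))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(b * x), data = dat,
                      start = list(a = a0, b = b0),
                      lower = c(a = 1e-12, b = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    stop("exponential fit of the Dixon plot failed: ",
         conditionMessage(fit), call. = FALSE)
  }
  a <- unname(stats::coef(fit)["a"])
  b <- unname(stats::coef(fit)["b"])
  list(slope = a * b, a = a, b = b, n = sum(keep))
}

#' Ratio of Dixon tangent slopes, combination over single agent
#'
#' Ratio of the tangent-at-origin slopes of a two-inhibitor Dixon plot
#' and the matching single-inhibitor plot, fitted over the same window.
#' A ratio above one is the signature of mutually non-exclusive
#' inhibitors acting synergistically; for mutually exclusive binding
#' the co-inhibitor leaves the tangent at the origin unchanged and the
#' ratio is one.
#'
#' @param combo a [dixon_series()] measured with the co-inhibitor
#'   present.
#' @param single the matching single-agent [dixon_series()].
#' @param window concentration window (nM) passed to [tangent_slope()].
#' @return The slope ratio (dimensionless).
#' @export
slope_ratio <- function(combo, single, window = c(0, 100)) {
  stopifnot(inherits(combo, "dixon_series"), inherits(single, "dixon_series"))
  if (!identical(attr(combo, "inhibitor"), attr(single, "inhibitor"))) {
    stop("both series must vary the same inhibitor", call. = FALSE)
  }
  s_combo <- tangent_slope(combo, window)$slope
  s_single <- tangent_slope(single, window)$slope
  if (s_single <= 0) {
    stop("single-agent tangent slope is zero; ratio undefined", call. = FALSE)
  }
  s_combo / s_single
}

#' Model closure mapping inhibitor dose to fractional inhibition
#'
#' Builds a function `dose -> fi = 1 - v/v0` from the equilibrium rate
#' law, for one inhibitor varied with the other fixed.  Used as the
#' invertible single-agent source for [dose_for_fraction()] and
#' [isobologram()].
#'
#' @param constants a [kinetic_constants()] object.
#' @param drug `"d"` or `"m"`: which inhibitor the dose refers to.
#' @param mix assay [mix_state()]; its `d`/`m` field for `drug` is
#'   overridden by the dose, the other inhibitor stays as given.
#' @return A function of `dose_nM` returning fractional inhibition.
#' @export
fi_model_source <- function(constants, drug = c("d", "m"),
                            mix = mix_state()) {
  drug <- match.arg(drug)
  v0 <- reaction_rate(constants, modify_mix(mix, d = 0, m = 0))
  function(dose_nM) {
    vapply(dose_nM, function(x) {
      mm <- if (drug == "d") modify_mix(mix, d = x, m = 0)
            else modify_mix(mix, d = 0, m = x)
      1 - reaction_rate(constants, mm) / v0
    }, numeric(1))
  }
}

#' Equi-effective dose for a given fractional inhibition
#'
#' Inverts a monotone dose-to-fractional-inhibition relationship.  For
#' a model closure (a function), the dose is found by bisection on the
#' log-dose scale to a relative tolerance of 1e-8; for an empirical
#' table (data frame with columns `dose` and `fi`), monotone log-linear
#' interpolation in dose is used.
#'
#' @param source either a function `dose -> fi`, monotone increasing,
#'   or a data frame with columns `dose` (nM) and `fi`.
#' @param fi target fractional inhibition, in (0, 1) and attainable.
#' @param interval search interval for the bisection (nM).
#' @return Dose in nM.
#' @export
dose_for_fraction <- function(source, fi, interval = c(1e-6, 1e10)) {
  if (!is.numeric(fi) || length(fi) != 1L || !is.finite(fi) ||
      fi <= 0 || fi >= 1) {
    stop("'fi' must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (is.function(source)) {
    lo <- log(interval[1]); hi <- log(interval[2])
    f_lo <- source(exp(lo)) - fi
    f_hi <- source(exp(hi)) - fi
    if (f_lo * f_hi > 0) {
      stop("fractional inhibition ", fi, " is not attainable within the ",
           "search interval", call. = FALSE)
    }
    root <- stats::uniroot(function(u) source(exp(u)) - fi, c(lo, hi),
                           tol = 1e-12)
    return(exp(root$root))
  }
  if (is.data.frame(source) && all(c("dose", "fi") %in% names(source))) {
    tab <- source[order(source$dose), ]
    if (any(diff(tab$fi) < 0)) {
      stop("empirical dose-fi table is not monotone in dose", call. = FALSE)
    }
    if (fi < min(tab$fi) || fi > max(tab$fi)) {
      stop("fractional inhibition ", fi, " outside the empirical range [",
           min(tab$fi), ", ", max(tab$fi), "]", call. = FALSE)
    }
    ld <- stats::approx(tab$fi, log(tab$dose), xout = fi, ties = mean)$y
    return(exp(ld))
  }
  stop("'source' must be a function or a data frame with columns ",
       "'dose' and 'fi'", call. = FALSE)
}

#' Loewe combination index
#'
#' `CI = D_AC/D_A + D_BC/D_B`, where `D_A` and `D_B` are the doses of
#' each drug that produce a given fractional inhibition alone and
#' `D_AC`, `D_BC` the doses producing the same inhibition in
#' combination.  CI = 1 corresponds to simple (dose) additivity,
#' CI < 1 to synergy, CI > 1 to antagonism.  The index is symmetric
#' under exchange of the drug labels.
#'
#' @param D_AC,D_BC combined doses (nM), non-negative; vectorised.
#' @param D_A,D_B single-agent equi-effective doses (nM), strictly
#'   positive.
#' @return Combination index (dimensionless).
#' @export
combination_index <- function(D_AC, D_A, D_BC, D_B) {
  if (any(!is.finite(c(D_AC, D_A, D_BC, D_B)))) {
    stop("all doses must be finite", call. = FALSE)
  }
  if (any(D_AC < 0) || any(D_BC < 0)) {
    stop("combined doses must be non-negative", call. = FALSE)
  }
  if (any(D_A <= 0) || any(D_B <= 0)) {
    stop("single-agent equi-effective doses must be strictly positive",
         call. = FALSE)
  }
  D_AC / D_A + D_BC / D_B
}

#' Isobologram analysis of dose combinations
#'
#' For each combination (doseA, doseB, fi), inverts the two single-
#' agent sources at that fractional inhibition and computes the Loewe
#' combination index.  Combinations whose fi is unattainable by a
#' single agent are flagged (`attainable = FALSE`, CI = NA), never
#' silently dropped.
#'
#' @param combinations data frame with columns `doseA`, `doseB` (nM)
#'   and `fi`.
#' @param source_A,source_B single-agent sources for drug A and drug B
#'   as accepted by [dose_for_fraction()].
#' @return A data frame with one row per combination: the inputs plus
#'   `D_A`, `D_B`, `CI` and `attainable`.
#' @export
isobologram <- function(combinations, source_A, source_B) {
  req <- c("doseA", "doseB", "fi")
  if (!is.data.frame(combinations) || !all(req %in% names(combinations))) {
    stop("'combinations' must be a data frame with columns doseA, doseB, fi",
         call. = FALSE)
  }
  n <- nrow(combinations)
  out <- combinations
  out$D_A <- out$D_B <- out$CI <- rep(NA_real_, n)
  out$attainable <- rep(TRUE, n)
  if (n == 0L) return(out)
  for (i in seq_len(n)) {
    res <- tryCatch({
      D_A <- dose_for_fraction(source_A, combinations$fi[i])
      D_B <- dose_for_fraction(source_B, combinations$fi[i])
      list(D_A = D_A, D_B = D_B,
           CI = combination_index(combinations$doseA[i], D_A,
                                  combinations$doseB[i], D_B))
    }, error = function(e) NULL)
    if (is.null(res)) {
      out$attainable[i] <- FALSE
    } else {
      out$D_A[i] <- res$D_A
      out$D_B[i] <- res$D_B
      out$CI[i] <- res$CI
    }
  }
  out
}
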