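#' Kinetic constants for the two-substrate, two-inhibitor hTS scheme
#'
#' Bundles the dissociation constants of the rapid-equilibrium binding
#' scheme in which the substrate dUMP (D) and the cofactor mTHF (M) bind
#' sequentially, the nucleotide-site inhibitor FdUMP (d) binds free
#' enzyme, and the folate-site inhibitor raltitrexed (m) binds only
#' after the nucleotide site is occupied.  Seven enzyme species arise:
#' E, ED, Ed, EDM, EDm, EdM and Edm.  Only EDM turns over; the
#' inhibitor-containing ternary complexes are dead ends.
#'
#' Units follow bench convention: substrate/cofactor constants in
#' micromolar, inhibitor constants in nanomolar.  Everything is stored
#' internally in nanomolar.  `K_mp = Inf` encodes mutually exclusive
#' binding of the two inhibitors (the Edm species is dropped).
#'
#' @param K_D dissociation constant of dUMP from E.D (uM).
#' @param K_M dissociation constant of mTHF from E.D.M (uM).
#' @param K_Mp dissociation constant of mTHF from E.d.M, i.e. binding of
#'   the cofactor to the FdUMP-occupied enzyme ("K_M prime", uM).
#' @param K_d dissociation constant of FdUMP from E.d (nM).
#' @param K_m dissociation constant of RTX from E.D.m (nM).
#' @param K_mp dissociation constant of RTX from E.d.m ("K_m prime",
#'   nM); may be `Inf` for mutually exclusive inhibitors.
#' @param k_cat catalytic rate constant (per minute).
#' @param E_T total enzyme concentration (nM).
#' @return An object of class `kinetic_constants` (a named list, all
#'   concentrations in nM).
#' @seealso [hts_constants()] for the literature parameter set,
#'   [species_distribution()], [reaction_rate()].
#' @export
kinetic_constants <- function(K_D, K_M, K_Mp = K_M, K_d, K_m, K_mp = K_m,
                              k_cat, E_T) {
  vals <- list(K_D = K_D, K_M = K_M, K_Mp = K_Mp, K_d = K_d, K_m = K_m,
               K_mp = K_mp, k_cat = k_cat, E_T = E_T)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    }
    if (nm != "K_mp" && !is.finite(v)) {
      stop("'", nm, "' must be finite", call. = FALSE)
    }
    if (v <= 0) stop("'", nm, "' must be strictly positive", call. = FALSE)
  }
  out <- list(
    K_D  = K_D * 1000,  # uM -> nM
    K_M  = K_M * 1000,
    K_Mp = K_Mp * 1000,
    K_d  = K_d,
    K_m  = K_m,
    K_mp = K_mp,
    k_cat = k_cat,
    E_T  = E_T
  )
  class(out) <- "kinetic_constants"
  out
}

#' Literature parameter set for hTS inhibition by FdUMP and raltitrexed
#'
#' Convenience constructor with the constants determined for the human
#' enzyme: Michaelis constants K_D = 10 uM (dUMP) and K_M = 5 uM (mTHF),
#' tight-binding constants K_d = 86 nM (FdUMP, under the K_M' = K_M
#' assumption) and K_m = 8 nM (RTX), k_cat = 80 per minute and 300 nM
#' enzyme.  By default simultaneous inhibitor binding with K_m' = K_m
#' and K_M' = K_M is assumed; pass `exclusive = TRUE` for the mutually
#' exclusive limit (K_m' = Inf).
#'
#' @param exclusive logical; drop the doubly-inhibited Edm species.
#' @param ... overrides forwarded to [kinetic_constants()].
#' @return A `kinetic_constants` object.
#' @export
hts_constants <- function(exclusive = FALSE, ...) {
  args <- list(K_D = 10, K_M = 5, K_Mp = 5, K_d = 86, K_m = 8, K_mp = 8,
               k_cat = 80, E_T = 300)
  dots <- list(...)
  args[names(dots)] <- dots
  if (exclusive) args$K_mp <- Inf
  do.call(kinetic_constants, args)
}

#' Assay mixture state
#'
#' Total concentrations of substrate, cofactor and the two inhibitors.
#' Substrate and cofactor are given in micromolar, inhibitors in
#' nanomolar (stored internally in nM).  Defaults are the standard
#' spectrophotometric assay conditions: 120 uM dUMP and 55 uM mTHF.
#'
#' @param D total dUMP (uM).
#' @param M total mTHF (uM).
#' @param d total FdUMP (nM).
#' @param m total raltitrexed (nM).
#' @return An object of class `mix_state` (all values in nM).
#' @export
mix_state <- function(D = 120, M = 55, d = 0, m = 0) {
  vals <- list(D = D, M = M, d = d, m = m)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("'", nm, "' must be a single finite non-negative number",
           call. = FALSE)
    }
  }
  out <- list(D = D * 1000, M = M * 1000, d = d, m = m)
  class(out) <- "mix_state"
  out
}

species_names <- c("E", "ED", "Ed", "EDM", "EDm", "EdM", "Edm")

# Binding-polynomial terms for the seven species, free concentrations in nM.
# With K_mp = Inf the Edm term is identically zero (0 * finite guarded).
partition_terms <- function(k, D, M, d, m) {
  edm <- if (is.finite(k$K_mp)) (d / k$K_d) * (m / k$K_mp) else 0
  c(E   = 1,
    ED  = D / k$K_D,
    Ed  = d / k$K_d,
    EDM = (D / k$K_D) * (M / k$K_M),
    EDm = (D / k$K_D) * (m / k$K_m),
    EdM = (d / k$K_d) * (M / k$K_Mp),
    Edm = edm)
}

#' Equilibrium distribution of enzyme species
#'
#' Fractions of the seven enzyme species under the rapid-equilibrium
#' (Michaelis-Menten) assumption that free ligand concentrations equal
#' totals.  Each fraction is the species' binding-polynomial term
#' divided by the partition function
#' `Z = 1 + D/K_D + d/K_d + (D/K_D)(M/K_M) + (D/K_D)(m/K_m) +
#' (d/K_d)(M/K_M') + (d/K_d)(m/K_m')`.
#'
#' @param constants a [kinetic_constants()] object.
#' @param mix a [mix_state()] object.
#' @return Named numeric vector of the fractions of E, ED, Ed, EDM,
#'   EDm, EdM and Edm; sums to one.
#' @examples
#' k <- hts_constants()
#' species_distribution(k, mix_state(D = 120, M = 55))
#' @export
species_distribution <- function(constants, mix) {
  stopifnot(inherits(constants, "kinetic_constants"),
            inherits(mix, "mix_state"))
  terms <- partition_terms(constants, mix$D, mix$M, mix$d, mix$m)
  terms / sum(terms)
}

#' Steady-state reaction rate of the inhibited enzyme
#'
#' Rate of dTMP formation under the rapid-equilibrium scheme: only the
#' substrate-cofactor ternary complex EDM is productive, so
#' `v = k_cat * E_T * fraction(EDM)`.
#'
#' @inheritParams species_distribution
#' @return Rate in uM per minute.
#' @examples
#' # uninhibited assay rate at saturating substrate/cofactor
#' reaction_rate(hts_constants(), mix_state())
#' @export
reaction_rate <- function(constants, mix) {
  f <- species_distribution(constants, mix)
  constants$k_cat * (constants$E_T / 1000) * f[["EDM"]]
}

#' Synergism quotient of a two-inhibitor combination
#'
#' Ratio of the rate decrease produced by the two inhibitors together
#' to the sum of the decreases produced by each alone at the same
#' concentrations:
#' `sq = (v_ni - v_dm) / (2 v_ni - v_d - v_m)`,
#' where `v_ni` is the uninhibited rate.  Values above one indicate
#' synergism, one additivity, below one antagonism.
#'
#' @inheritParams species_distribution
#' @param mix a [mix_state()] with both `d > 0` and `m > 0`.
#' @return The dimensionless quotient.
#' @export
synergism_quotient <- function(constants, mix) {
  stopifnot(inherits(constants, "kinetic_constants"),
            inherits(mix, "mix_state"))
  if (mix$d <= 0 || mix$m <= 0) {
    stop("synergism quotient requires both inhibitors present (d > 0, m > 0)",
         call. = FALSE)
  }
  base <- mix
  v_ni <- reaction_rate(constants, modify_mix(base, d = 0, m = 0))
  v_d  <- reaction_rate(constants, modify_mix(base, m = 0))
  v_m  <- reaction_rate(constants, modify_mix(base, d = 0))
  v_dm <- reaction_rate(constants, base)
  denom <- 2 * v_ni - v_d - v_m
  if (denom <= 1e-12 * v_ni) {
    stop("synergism quotient undefined: no net single-agent inhibition ",
         "(denominator ", format(denom), ")", call. = FALSE)
  }
  (v_ni - v_dm) / denom
}

# internal: replace fields of a mix_state keeping nM storage
modify_mix <- function(mix, D = NULL, M = NULL, d = NULL, m = NULL) {
  out <- mix
  if (!is.null(D)) out$D <- D
  if (!is.null(M)) out$M <- M
  if (!is.null(d)) out$d <- d
  if (!is.null(m)) out$m <- m
  out
}

# sq expressed purely in terms of i/K ratios and the K'/K multipliers;
# used by the parameter-space scan (only ratios enter the quotient).
sq_from_ratios <- function(rD, rM, rd, rm, KMp_mult = 1, Kmp_mult = 1) {
  z <- function(rd., rm.) {
    edm <- if (is.finite(Kmp_mult)) rd. * (rm. / Kmp_mult) else 0
    1 + rD + rd. + rD * rM + rD * rm. + rd. * (rM / KMp_mult) + edm
  }
  prod_term <- rD * rM  # EDM term, common numerator of all four rates
  v_ni <- prod_term / z(0, 0)
  v_d  <- prod_term / z(rd, 0)
  v_m  <- prod_term / z(0, rm)
  v_dm <- prod_term / z(rd, rm)
  denom <- 2 * v_ni - v_d - v_m
  if (denom <= 1e-12 * v_ni) return(NA_real_)
  (v_ni - v_dm) / denom
}

#' Parameter-space scan of the synergism quotient
#'
#' Tabulates the synergism quotient over a grid of concentration-to-
#' dissociation-constant ratios for the substrate (D/K_D), cofactor
#' (M/K_M) and the two inhibitors (d/K_d, m/K_m), under one or both
#' mechanistic assumptions: `"simultaneous"` binding of the inhibitors
#' (K_m' finite, default equal to K_m) or `"exclusive"` binding
#' (K_m' = Inf, the Edm species dropped).  The headline mechanistic
#' dichotomy: exclusive binding is always antagonistic (sq < 1),
#' while simultaneous binding can reach synergism.
#'
#' @param dKd,mKm,MKM,DKD numeric vectors of strictly positive ratios
#'   defining the grid (defaults 0.1, 1, 10; D/K_D defaults to 1).
#' @param KMp_mult K_M'/K_M multiplier(s) (default 1).
#' @param Kmp_mult K_m'/K_m multiplier(s) used in simultaneous mode
#'   (default 1).
#' @param modes character subset of `c("simultaneous", "exclusive")`.
#' @return A data frame with columns `dKd`, `mKm`, `DKD`, `MKM`,
#'   `KMp_mult`, `Kmp_mult`, `mode` and `sq`.
#' @export
sq_scan <- function(dKd = c(0.1, 1, 10), mKm = c(0.1, 1, 10),
                    MKM = c(0.1, 1, 10), DKD = 1,
                    KMp_mult = 1, Kmp_mult = 1,
                    modes = c("simultaneous", "exclusive")) {
  modes <- match.arg(modes, several.ok = TRUE)
  ratios <- list(dKd = dKd, mKm = mKm, MKM = MKM, DKD = DKD,
                 KMp_mult = KMp_mult, Kmp_mult = Kmp_mult)
  for (nm in names(ratios)) {
    v <- ratios[[nm]]
    if (length(v) == 0L) stop("empty grid for '", nm, "'", call. = FALSE)
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop("'", nm, "' must contain strictly positive finite ratios",
           call. = FALSE)
    }
  }
  grid <- expand.grid(dKd = dKd, mKm = mKm, DKD = DKD, MKM = MKM,
                      KMp_mult = KMp_mult, Kmp_mult = Kmp_mult,
                      mode = modes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$sq <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sq_from_ratios(g$DKD, g$MKM, g$dKd, g$mKm, g$KMp_mult,
                   if (g$mode == "exclusive") Inf else g$Kmp_mult)
  }, numeric(1))
  grid
}

#' Numerical equilibrium solver for the binding scheme
#'
#' Computes species concentrations either (a) under the rapid-
#' equilibrium approximation (free = total), as an independent check on
#' the closed-form [species_distribution()], or (b) with full ligand
#' depletion, solving the coupled mass-balance equations for the free
#' concentrations by a damped Newton iteration on the log scale.  The
#' depletion mode is the forward model under tight-binding conditions
#' where the inhibitor concentration is comparable to the enzyme
#' concentration and binding removes a non-negligible amount of free
#' inhibitor.
#'
#' @inheritParams species_distribution
#' @param with_depletion logical; solve the mass balances for free
#'   ligand rather than equating free with total.
#' @param tol relative residual tolerance of the mass balances.
#' @param max_iter maximum Newton iterations.
#' @return A list with `species` (named concentrations of the seven
#'   enzyme species, nM), `free` (free D, M, d, m, nM), `rate` (uM per
#'   minute), `converged` and `residual`.
#' @export
equilibrium_oracle <- function(constants, mix, with_depletion = FALSE,
                               tol = 1e-9, max_iter = 200L) {
  stopifnot(inherits(constants, "kinetic_constants"),
            inherits(mix, "mix_state"))
  k <- constants
  totals <- c(D = mix$D, M = mix$M, d = mix$d, m = mix$m)

  species_at <- function(free) {
    terms <- partition_terms(k, free[["D"]], free[["M"]], free[["d"]],
                             free[["m"]])
    E_free <- k$E_T / sum(terms)
    E_free * terms
  }
  bound_of <- function(sp) {
    c(D = sp[["ED"]] + sp[["EDM"]] + sp[["EDm"]],
      M = sp[["EDM"]] + sp[["EdM"]],
      d = sp[["Ed"]] + sp[["EdM"]] + sp[["Edm"]],
      m = sp[["EDm"]] + sp[["Edm"]])
  }

  if (!with_depletion) {
    sp <- species_at(totals)
    return(list(species = sp, free = totals,
                rate = k$k_cat * sp[["EDM"]] / 1000,
                converged = TRUE, residual = 0))
  }

  active <- names(totals)[totals > 0]
  free <- totals
  if (length(active) > 0L) {
    scale <- pmax(totals[active], k$E_T)
    resid <- function(u) {
      f <- totals
      f[active] <- exp(u)
      b <- bound_of(species_at(f))
      (totals[active] - f[active] - b[active]) / scale
    }
    # start from totals minus a conservative estimate of binding
    u <- log(pmax(totals[active] * 0.5, totals[active] - k$E_T,
                  1e-9 * pmax(totals[active], k$E_T)))
    r <- resid(u)
    iter <- 0L
    while (sqrt(sum(r^2)) > tol && iter < max_iter) {
      J <- pracma::jacobian(resid, u)
      step <- tryCatch(-solve(J, r), error = function(e) -r)
      lambda <- 1
      repeat {
        u_new <- u + lambda * step
        r_new <- resid(u_new)
        if (sqrt(sum(r_new^2)) < sqrt(sum(r^2)) || lambda < 1e-6) break
        lambda <- lambda / 2
      }
      u <- u_new
      r <- r_new
      iter <- iter + 1L
    }
    rnorm_final <- sqrt(sum(r^2))
    if (rnorm_final > tol) {
      stop("equilibrium solver did not converge: residual norm ",
           format(rnorm_final), " after ", iter, " iterations",
           call. = FALSE)
    }
    free[active] <- exp(u)
  }
  sp <- species_at(free)
  list(species = sp, free = free,
       rate = k$k_cat * sp[["EDM"]] / 1000,
       converged = TRUE,
       residual = if (length(active)) sqrt(sum(resid(log(free[active]))^2)) else 0)
}
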