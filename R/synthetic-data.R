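#' Simulate a spectrophotometric progress curve
#'
#' Generates an absorbance-at-340-nm trace for the initial-rate regime
#' of the hTS assay, in which dihydrofolate formed by oxidation of the
#' mTHF cofactor accumulates linearly over the observation window
#' (default 180 s): `A340(t) = A0 + eps * l * v * t` plus optional
#' Gaussian noise.  The underlying rate is computed from the
#' depletion-corrected equilibrium solver, so tight-binding inhibitor
#' sequestration is reflected in the trace.
#'
#' @param constants a [kinetic_constants()] object.
#' @param mix a [mix_state()] object.
#' @param duration_s observation window (s).
#' @param dt_s sampling interval (s).
#' @param A0 initial absorbance.
#' @param epsilon molar extinction coefficient of DHF at 340 nm
#'   (per mM per cm).
#' @param path_cm optical path length (cm).
#' @param noise_sd additive Gaussian noise, absorbance units.
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @return A data frame of class `progress_curve` with columns
#'   `time_s`, `A340`; the true rate (uM/min), `epsilon` and
#'   `path_cm` are stored as attributes.
#' @export
simulate_progress_curve <- function(constants, mix, duration_s = 180,
                                    dt_s = 2, A0 = 0, epsilon = 6.4,
                                    path_cm = 1, noise_sd = 0,
                                    seed = NULL) {
  if (duration_s <= 0) stop("'duration_s' must be positive", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is required for noisy simulation", call. = FALSE)
  }
  v <- equilibrium_oracle(constants, mix, with_depletion = TRUE)$rate
  t_s <- seq(0, duration_s, by = dt_s)
  # v in uM/min = 1e-3 mM/min; slope in AU per minute = eps * l * v * 1e-3
  slope_per_min <- epsilon * path_cm * v * 1e-3
  a <- A0 + slope_per_min * t_s / 60
  if (noise_sd > 0) {
    set.seed(seed)
    a <- a + stats::rnorm(length(a), 0, noise_sd)
  }
  out <- data.frame(time_s = t_s, A340 = a)
  attr(out, "true_rate") <- v
  attr(out, "epsilon") <- epsilon
  attr(out, "path_cm") <- path_cm
  class(out) <- c("progress_curve", "data.frame")
  out
}

#' Extract an initial rate from a progress curve
#'
#' Ordinary least-squares slope of absorbance against time over a
#' configurable window (default: the whole trace), converted to a
#' reaction rate via the extinction coefficient and path length.
#' Recovers the generating rate exactly on noise-free synthetic
#' curves.
#'
#' @param curve a [simulate_progress_curve()] output (or any data
#'   frame with `time_s`, `A340` and the optical attributes).
#' @param window optional time window (s) as `c(from, to)`.
#' @return Rate in uM per minute.
#' @export
rate_from_curve <- function(curve, window = NULL) {
  stopifnot(is.data.frame(curve), all(c("time_s", "A340") %in% names(curve)))
  dat <- curve
  if (!is.null(window)) {
    dat <- dat[dat$time_s >= window[1] & dat$time_s <= window[2], ]
  }
  if (nrow(dat) < 5L) {
    stop("need at least 5 time points to estimate a rate", call. = FALSE)
  }
  eps <- attr(curve, "epsilon"); if (is.null(eps)) eps <- 6.4
  path <- attr(curve, "path_cm"); if (is.null(path)) path <- 1
  slope_per_s <- unname(stats::coef(stats::lm(A340 ~ time_s, data = dat))[2])
  slope_per_s * 60 / (eps * path * 1e-3)
}

#' Default single-inhibitor concentration ladders
#'
#' Six-point designs spanning the assay ranges: 0-400 nM for the
#' folate-site inhibitor (RTX) and 0-1600 nM for the nucleotide-site
#' inhibitor (FdUMP).
#'
#' @param inhibitor `"m"` (RTX) or `"d"` (FdUMP).
#' @return Numeric vector of six concentrations (nM).
#' @export
default_design <- function(inhibitor = c("m", "d")) {
  inhibitor <- match.arg(inhibitor)
  if (inhibitor == "m") c(0, 25, 50, 100, 200, 400)
  else c(0, 100, 200, 400, 800, 1600)
}

#' Simulate a tight-binding dose-response plate
#'
#' Rates at a ladder of inhibitor concentrations (optionally with a
#' fixed co-inhibitor) computed from the depletion-corrected
#' equilibrium solver, replicated with multiplicative Gaussian noise.
#' Bit-reproducible for a given seed.
#'
#' @param constants a [kinetic_constants()] object.
#' @param inhibitor `"m"` or `"d"`: which inhibitor is varied.
#' @param conc_nM concentration ladder (nM); default the assay design
#'   from [default_design()].
#' @param co_conc_nM fixed concentration of the other inhibitor (nM).
#' @param D,M substrate and cofactor totals (uM).
#' @param replicates replicates per concentration.
#' @param noise_sd multiplicative noise, as a fraction of the rate
#'   (default 0.03).
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @return A [dose_response_series()] with one row per replicate
#'   measurement; the noise-free rates are in attribute `true_rates`.
#' @export
simulate_dose_response <- function(constants, inhibitor = c("m", "d"),
                                   conc_nM = NULL, co_conc_nM = 0,
                                   D = 120, M = 55, replicates = 3,
                                   noise_sd = 0.03, seed = NULL) {
  inhibitor <- match.arg(inhibitor)
  if (is.null(conc_nM)) conc_nM <- default_design(inhibitor)
  if (length(conc_nM) == 0L) stop("empty concentration design", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is required for noisy simulation", call. = FALSE)
  }
  true_rates <- vapply(conc_nM, function(cc) {
    mm <- if (inhibitor == "m") mix_state(D = D, M = M, d = co_conc_nM, m = cc)
          else mix_state(D = D, M = M, d = cc, m = co_conc_nM)
    equilibrium_oracle(constants, mm, with_depletion = TRUE)$rate
  }, numeric(1))
  conc_all <- rep(conc_nM, each = replicates)
  rate_all <- rep(true_rates, each = replicates)
  if (noise_sd > 0) {
    set.seed(seed)
    rate_all <- rate_all * (1 + stats::rnorm(length(rate_all), 0, noise_sd))
  }
  out <- dose_response_series(
    conc_nM = conc_all, rate = rate_all, inhibitor = inhibitor,
    co_conc_nM = co_conc_nM,
    replicate = rep(seq_len(replicates), times = length(conc_nM)),
    E_T = constants$E_T, D = D, M = M
  )
  attr(out, "true_rates") <- true_rates
  out
}

#' Simulate a cell-growth inhibition plate with known synergy
#'
#' Builds a long-format plate of percent-growth-inhibition
#' measurements from specified single-agent effects and per-condition
#' true synergism quotients.  The combination truth model inverts the
#' quotient definition - combined effect = sq x (sum of single
#' effects) - clipped at 100% (clipped rows are flagged); it exercises
#' the analysis pipeline rather than modelling interaction biology.
#'
#' @param single_effects data frame with columns `cell_line`, `drug`,
#'   `dose`, `effect` (fraction of control growth inhibition, 0-1).
#' @param combos data frame with columns `cell_line`, `drugA`,
#'   `doseA`, `drugB`, `doseB`, `schedule`, `sq` (true quotient, > 0).
#' @param replicates replicates per condition.
#' @param noise_sd multiplicative Gaussian noise on the percent scale
#'   (fraction of signal).
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @return A data frame with columns `cell_line`, `schedule`, `drugA`,
#'   `doseA`, `drugB`, `doseB`, `percent_inhibition`, `replicate`,
#'   `clipped`; single-agent rows carry `drugB = ""`, `doseB = 0`.
#' @export
simulate_cell_plate <- function(single_effects, combos, replicates = 3,
                                noise_sd = 0, seed = NULL) {
  req_s <- c("cell_line", "drug", "dose", "effect")
  req_c <- c("cell_line", "drugA", "doseA", "drugB", "doseB", "schedule",
             "sq")
  if (!is.data.frame(single_effects) || !all(req_s %in% names(single_effects))) {
    stop("'single_effects' needs columns ", paste(req_s, collapse = ", "),
         call. = FALSE)
  }
  if (!is.data.frame(combos) || !all(req_c %in% names(combos))) {
    stop("'combos' needs columns ", paste(req_c, collapse = ", "),
         call. = FALSE)
  }
  if (any(single_effects$effect < 0 | single_effects$effect > 1)) {
    stop("single-agent effects must be fractions in [0, 1]", call. = FALSE)
  }
  if (any(combos$sq <= 0)) stop("true sq must be positive", call. = FALSE)
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is required for noisy simulation", call. = FALSE)
  }
  lookup <- function(cell, drug, dose) {
    hit <- single_effects$cell_line == cell & single_effects$drug == drug &
      abs(single_effects$dose - dose) < 1e-9
    if (!any(hit)) {
      stop("no single-agent truth for ", drug, " ", dose, " on ", cell,
           call. = FALSE)
    }
    single_effects$effect[hit][1]
  }
  rows <- list()
  add <- function(cell, schedule, dA, doseA, dB, doseB, pct, clipped) {
    rows[[length(rows) + 1L]] <<- data.frame(
      cell_line = cell, schedule = schedule, drugA = dA, doseA = doseA,
      drugB = dB, doseB = doseB, percent_true = pct, clipped = clipped,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(single_effects))) {
    s <- single_effects[i, ]
    add(s$cell_line, "", s$drug, s$dose, "", 0, 100 * s$effect, FALSE)
  }
  for (i in seq_len(nrow(combos))) {
    cc <- combos[i, ]
    eA <- lookup(cc$cell_line, cc$drugA, cc$doseA)
    eB <- lookup(cc$cell_line, cc$drugB, cc$doseB)
    eff <- cc$sq * (eA + eB)
    clip <- eff > 1
    add(cc$cell_line, cc$schedule, cc$drugA, cc$doseA, cc$drugB, cc$doseB,
        100 * min(eff, 1), clip)
  }
  base <- do.call(rbind, rows)
  out <- base[rep(seq_len(nrow(base)), each = replicates), ]
  out$replicate <- rep(seq_len(replicates), times = nrow(base))
  out$percent_inhibition <- out$percent_true
  if (noise_sd > 0) {
    set.seed(seed)
    out$percent_inhibition <- out$percent_true *
      (1 + stats::rnorm(nrow(out), 0, noise_sd))
  }
  out$percent_true <- NULL
  rownames(out) <- NULL
  out
}

# hexagon of C atoms (bond radius 1.39 A) centred at `centre`, in the
# plane whose normal is obtained by rotating +z about the x axis
hexagon <- function(centre, tilt_deg = 0, radius = 1.39) {
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  pts <- cbind(radius * cos(th), radius * sin(th), 0)
  a <- tilt_deg * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  sweep(pts %*% t(Rx), 2, centre, "+")
}

#' Construct a toy ternary-complex structure with exact geometry
#'
#' Builds a minimal, fully synthetic coordinate model that mimics the
#' geometric motifs analysed in a real inhibitor ternary complex: two
#' planar six-membered rings (pyrimidine-like ligand ring `LGA`,
#' quinazoline-like ligand ring `LGB`) at an exact centroid separation
#' and interplanar angle, a fluorine probe at an exact distance from
#' an aromatic-wall carbon (Trp-like), and a ligand O / Asn-ND2
#' donor-acceptor pair at an exact hydrogen-bond distance.  Intended
#' as a test fixture for the contact-analysis operations; all
#' distances are exact by construction.
#'
#' @param ring_separation centroid-centroid distance of the two rings
#'   (Angstrom).
#' @param interplanar_angle angle between the two ring planes
#'   (degrees).
#' @param probe_distance F to aromatic-carbon distance (Angstrom).
#' @param hbond_distance ligand-O to Asn-ND2 distance (Angstrom).
#' @param path optional file path; when given the model is also
#'   written as a PDB file.
#' @return A `structure_model`; invisibly writes `path` if requested.
#' @export
toy_ternary_structure <- function(ring_separation = 3.5,
                                  interplanar_angle = 0,
                                  probe_distance = 3.5,
                                  hbond_distance = 2.9,
                                  path = NULL) {
  for (nm in c("ring_separation", "probe_distance", "hbond_distance")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0) {
      stop("'", nm, "' must be a positive distance", call. = FALSE)
    }
  }
  ringA <- hexagon(c(0, 0, 0), 0)
  ringB <- hexagon(c(0, 0, ring_separation), interplanar_angle)
  atoms <- list()
  add_atom <- function(chain, resno, resid, elety, element, x, y, z) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      chain = chain, resno = resno, insert = "", resid = resid,
      elety = elety, element = element, alt = "", occupancy = 1,
      x = x, y = y, z = z, stringsAsFactors = FALSE)
  }
  for (i in 1:6) add_atom("L", 1, "LGA", paste0("C", i), "C",
                          ringA[i, 1], ringA[i, 2], ringA[i, 3])
  add_atom("L", 1, "LGA", "O4", "O", 3, 0, 0)
  add_atom("L", 1, "LGA", "N3", "N", 3, 3, 0)
  add_atom("L", 1, "LGA", "F", "F", -3, 0, 0)
  for (i in 1:6) add_atom("L", 2, "LGB", paste0("C", i), "C",
                          ringB[i, 1], ringB[i, 2], ringB[i, 3])
  # aromatic-wall probe carbon (Trp-like) and an Asn acceptor/donor pair
  add_atom("A", 109, "TRP", "CZ2", "C", -3, 0, -probe_distance)
  add_atom("A", 226, "ASN", "ND2", "N", 3, 0, -hbond_distance)
  add_atom("A", 226, "ASN", "OD1", "O", 10, 10, -10)
  model <- do.call(rbind, atoms)
  attr(model, "entry") <- "toy-ternary-synthetic"
  class(model) <- c("structure_model", "data.frame")
  if (!is.null(path)) write_structure(model, path)
  model
}
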