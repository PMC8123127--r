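#' Percent cytotoxicity from crystal-violet absorbances
#'
#' Converts absorbance of a treated culture relative to the unexposed
#' control into percent growth inhibition: `100 * (1 - A_t/A_c)`.
#' The extracted-dye absorbance is proportional to cell number, so
#' equal absorbances mean zero cytotoxicity and zero absorbance means
#' complete kill.
#'
#' @param A_treated absorbance(s) of treated cultures.
#' @param A_control absorbance of the control culture, positive.
#' @return Percent growth inhibition (vectorised over `A_treated`).
#' @export
percent_cytotoxicity <- function(A_treated, A_control) {
  if (!is.numeric(A_control) || length(A_control) != 1L ||
      !is.finite(A_control) || A_control <= 0) {
    stop("'A_control' must be a single positive absorbance", call. = FALSE)
  }
  if (any(!is.finite(A_treated)) || any(A_treated < 0)) {
    stop("'A_treated' must be finite and non-negative", call. = FALSE)
  }
  100 * (1 - A_treated / A_control)
}

#' Cell-level synergism quotient
#'
#' Net growth-inhibitory effect of a drug combination divided by the
#' sum of the net individual effects:
#' `sq = effect_combination / (effect_A + effect_B)`.
#' A quotient above one indicates synergism, one additivity, below one
#' antagonism.  Effects are fractions of control growth inhibition
#' (0-1 scale); small negative measured effects are clamped to zero
#' (with a warning) before the quotient is formed.  The quotient is
#' invariant under rescaling all three effects by a common factor.
#'
#' @param effect_combination net combined effect (fraction).
#' @param effect_A,effect_B net single-agent effects (fractions).
#' @return The quotient, with the classification
#'   (`"synergistic"`/`"additive"`/`"antagonistic"`) attached as
#'   attribute `classification`.
#' @examples
#' cell_sq(0.452, 0.212, 0.264)  # ~0.95, slightly sub-additive
#' @export
cell_sq <- function(effect_combination, effect_A, effect_B) {
  eff <- c(effect_combination, effect_A, effect_B)
  if (any(!is.finite(eff))) stop("effects must be finite", call. = FALSE)
  if (any(eff < 0)) {
    warning("negative effect(s) clamped to 0 for the quotient")
    effect_combination <- max(effect_combination, 0)
    effect_A <- max(effect_A, 0)
    effect_B <- max(effect_B, 0)
  }
  denom <- effect_A + effect_B
  if (denom <= 0) {
    stop("synergism quotient undefined: summed single-agent effect is zero",
         call. = FALSE)
  }
  sq <- effect_combination / denom
  eps <- sqrt(.Machine$double.eps)
  attr(sq, "classification") <-
    if (sq > 1 + eps) "synergistic" else if (sq < 1 - eps) "antagonistic"
    else "additive"
  sq
}

#' Heatmap separation transform for synergism quotients
#'
#' Spreads the three response classes apart before clustering and
#' heatmap display: quotients below 0.9 have 10 subtracted, quotients
#' of 1.1 or more have 10 added, and the middle (near-additive) band
#' is left unchanged.  The transform is monotone within each band and
#' maps the bands to disjoint output ranges.
#'
#' @param sq synergism quotient(s), finite; vectorised.
#' @return Transformed value(s).
#' @export
heatmap_transform <- function(sq) {
  if (any(!is.finite(sq))) stop("'sq' must be finite", call. = FALSE)
  out <- sq
  out[sq < 0.9] <- sq[sq < 0.9] - 10
  out[sq >= 1.1] <- sq[sq >= 1.1] + 10
  out
}

#' Synergism-quotient matrix for a combination x cell-line design
#'
#' Arranges per-condition synergism quotients into a matrix with one
#' row per combination (drug pair, doses and administration schedule)
#' and one column per cell line, plus its heatmap-transformed twin
#' ready for external clustering.  Missing design cells become NA;
#' duplicated cells with conflicting quotients are an error.
#'
#' @param records data frame with columns `combination` (label),
#'   `cell_line` and `sq`.
#' @return A list with matrices `sq` and `transformed` (rows ordered
#'   by first appearance of each combination, columns by first
#'   appearance of each cell line).
#' @export
sq_matrix <- function(records) {
  req <- c("combination", "cell_line", "sq")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    stop("'records' must be a data frame with columns combination, ",
         "cell_line, sq", call. = FALSE)
  }
  rows <- unique(as.character(records$combination))
  cols <- unique(as.character(records$cell_line))
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  for (i in seq_len(nrow(records))) {
    r <- as.character(records$combination[i])
    c. <- as.character(records$cell_line[i])
    v <- records$sq[i]
    if (!is.na(m[r, c.]) && abs(m[r, c.] - v) > 1e-12) {
      stop("conflicting sq values for (", r, ", ", c., "): ",
           m[r, c.], " vs ", v, call. = FALSE)
    }
    m[r, c.] <- v
  }
  transformed <- m
  ok <- !is.na(m)
  transformed[ok] <- heatmap_transform(m[ok])
  list(sq = m, transformed = transformed)
}

#' Summarise a cell-plate measurement table into synergy records
#'
#' Averages replicate percent-inhibition measurements per condition,
#' then forms the synergism quotient of every combination against the
#' matching single-agent conditions on the same cell line.  Input
#' follows the long plate layout produced by [simulate_cell_plate()]:
#' single-agent rows carry one drug and dose, combination rows carry
#' both plus a schedule tag.
#'
#' @param plate data frame with columns `cell_line`, `schedule`
#'   (`""` for single agents), `drugA`, `doseA`, `drugB`, `doseB`,
#'   `percent_inhibition`, `replicate`.
#' @return A data frame of synergy records: `cell_line`, `schedule`,
#'   `combination` label, the mean effects (fractions) and `sq` with
#'   its `classification` and heatmap-`transformed` value.
#' @export
cell_synergy_table <- function(plate) {
  req <- c("cell_line", "schedule", "drugA", "doseA", "drugB", "doseB",
           "percent_inhibition")
  if (!is.data.frame(plate) || !all(req %in% names(plate))) {
    stop("'plate' must contain columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(plate$cell_line, plate$schedule, plate$drugA,
                     plate$doseA, plate$drugB, plate$doseB, drop = TRUE)
  agg <- stats::aggregate(plate$percent_inhibition, by = list(key = key),
                          FUN = mean)
  meta <- plate[!duplicated(key), req]
  meta <- meta[match(agg$key, key[!duplicated(key)]), ]
  meta$effect <- agg$x / 100
  is_combo <- meta$drugB != "" & !is.na(meta$drugB) & meta$doseB > 0
  singles <- meta[!is_combo, ]
  combos <- meta[is_combo, ]
  if (nrow(combos) == 0L) {
    stop("no combination rows found in the plate", call. = FALSE)
  }
  single_effect <- function(cell, drug, dose) {
    hit <- singles$cell_line == cell & singles$drugA == drug &
      abs(singles$doseA - dose) < 1e-9
    if (!any(hit)) {
      stop("missing single-agent condition: ", drug, " ", dose, " on ",
           cell, call. = FALSE)
    }
    mean(singles$effect[hit])
  }
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    cc <- combos[i, ]
    eA <- single_effect(cc$cell_line, cc$drugA, cc$doseA)
    eB <- single_effect(cc$cell_line, cc$drugB, cc$doseB)
    sq <- suppressWarnings(cell_sq(cc$effect, eA, eB))
    data.frame(cell_line = cc$cell_line, schedule = cc$schedule,
               combination = paste0(cc$drugA, cc$doseA, "+", cc$drugB,
                                    cc$doseB, "/", cc$schedule),
               effect_combination = cc$effect, effect_A = eA, effect_B = eB,
               sq = as.numeric(sq),
               classification = attr(sq, "classification"),
               transformed = heatmap_transform(as.numeric(sq)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
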