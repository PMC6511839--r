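AVOGADRO <- 6.02214076e23
DALTON_PER_BP <- 615  # average molecular weight of one double-stranded bp

#' Plasmid copy number from mass
#'
#' Absolute copy number of a double-stranded plasmid standard:
#' `weight (g/mol) = bp * 615 Da/bp`, so
#' `copies = mass / (bp * 615 / N_A)` with the SI-exact Avogadro
#' constant. Linear in mass and inverse-linear in plasmid size.
#'
#' @param plasmid_bp plasmid size in base pairs (> 0).
#' @param mass_g template mass in grams (>= 0). Both arguments recycle.
#' @return copy number (numeric).
#' @examples
#' copies_from_mass(5200, 1e-12)  # 1 pg of a 5.2 kb plasmid
#' @export
copies_from_mass <- function(plasmid_bp, mass_g) {
  if (any(plasmid_bp <= 0)) stop("plasmid size must be positive")
  if (any(mass_g < 0)) stop("mass must be non-negative")
  mass_g / (plasmid_bp * DALTON_PER_BP / AVOGADRO)
}

#' Fit a qPCR standard curve
#'
#' Least squares of crossing point (Cp) on `log10(concentration)` over
#' a dilution series. Valid qPCR chemistry gives a negative slope
#' (about -3.32 per decade at 100% efficiency).
#'
#' @param dilution_concs concentrations of the standards (> 0, at least
#'   3 points spanning more than one concentration).
#' @param cp_values measured Cp values.
#' @return list of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
fit_standard_curve <- function(dilution_concs, cp_values) {
  if (length(dilution_concs) != length(cp_values))
    stop("concentrations and Cp values must pair")
  if (length(dilution_concs) < 3L) stop("need at least 3 dilution points")
  if (any(dilution_concs <= 0)) stop("concentrations must be positive")
  if (length(unique(dilution_concs)) < 2L)
    stop("degenerate design: a single concentration cannot define a curve")
  lx <- log10(dilution_concs)
  fit <- lm(cp_values ~ lx)
  sl <- unname(coef(fit)[2L])
  if (is.finite(sl) && sl >= 0)
    warning("non-negative slope: check Cp orientation")
  structure(list(slope = sl, intercept = unname(coef(fit)[1L]),
                 r_squared = suppressWarnings(summary(fit))$r.squared,
                 n = length(cp_values)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: Cp = %.4g + %.4g * log10(conc), R^2 = %.4f (n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Quantify a sample from a standard curve
#'
#' Inverts the fitted line: `conc = 10^((cp - intercept) / slope)`.
#'
#' @param cp measured Cp value(s).
#' @param curve a `standard_curve` from [fit_standard_curve()].
#' @return concentration(s) in the units of the standards.
#' @export
quantify <- function(cp, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cp - curve$intercept) / curve$slope)
}

#' Impute missing quantification values
#'
#' Each missing entry is replaced by one tenth of the minimum observed
#' value of the same transcript (row). A transcript with no observed
#' value at all is an error.
#'
#' @param values numeric matrix (transcripts x replicates) or vector;
#'   missing entries are `NA`.
#' @return the completed matrix/vector.
#' @export
impute_missing <- function(values) {
  if (is.null(dim(values))) {
    if (all(is.na(values))) stop("no observed values to impute from")
    values[is.na(values)] <- min(values, na.rm = TRUE) / 10
    return(values)
  }
  m <- as.matrix(values)
  for (i in seq_len(nrow(m))) {
    miss <- is.na(m[i, ])
    if (all(miss)) stop("transcript with no observed values: row ", i)
    if (any(miss)) m[i, miss] <- min(m[i, !miss]) / 10
  }
  m
}
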