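# Cell inventory of one diatom-diazotroph association (DDA) and the
# conversion of cell volumes into elemental quotas.

#' @keywords internal
MOLAR_MASS_C <- 12.011 # g mol^-1; pg C -> pmol C conversion

#' Cell classes of the association
#'
#' One DDA comprises a single host diatom and a fixed number of
#' cyanobacterial trichomes, each trichome made of vegetative cells
#' (which photosynthesize but never fix N2) and heterocysts (which fix
#' N2 but never photosynthesize).
#'
#' @return Character vector of the three valid cell class labels.
#' @export
cell_classes <- function() c("diatom", "vegetative", "heterocyst")

#' Default allometric volume-to-carbon coefficients
#'
#' Power-law regressions `log10(pg C) = a + b * log10(V)` relating cell
#' volume (um^3) to carbon content. The diatom uses a large-diatom
#' regression (a = -0.933, b = 0.881); the cyanobacterial cells
#' (vegetative, heterocyst) use a general protist regression
#' (a = -0.665, b = 0.939). Both are overridable via the configuration
#' layer.
#'
#' @return Named list with one `list(log10_intercept, exponent)` entry
#'   per cell class.
#' @export
default_allometry <- function() {
  list(
    diatom     = list(log10_intercept = -0.933, exponent = 0.881),
    vegetative = list(log10_intercept = -0.665, exponent = 0.939),
    heterocyst = list(log10_intercept = -0.665, exponent = 0.939)
  )
}

validate_allometry <- function(coeffs) {
  if (!is.list(coeffs) || !all(cell_classes() %in% names(coeffs))) {
    stop("allometry must be a named list with entries for: ",
         paste(cell_classes(), collapse = ", "), call. = FALSE)
  }
  for (cl in cell_classes()) {
    co <- coeffs[[cl]]
    if (is.null(co$log10_intercept) || is.null(co$exponent)) {
      stop("allometry entry for '", cl,
           "' needs fields log10_intercept and exponent", call. = FALSE)
    }
    if (!is.finite(co$exponent) || co$exponent <= 0) {
      stop("allometry exponent for '", cl, "' must be > 0", call. = FALSE)
    }
  }
  invisible(coeffs)
}

check_count <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 1 || x != round(x)) {
    stop(name, " must be a positive integer, got ", deparse(x),
         call. = FALSE)
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x <= 0) {
    stop(name, " must be a positive number, got ", deparse(x),
         call. = FALSE)
  }
  as.numeric(x)
}

#' Define the cell inventory of one association
#'
#' Defaults follow typical observed morphology: one diatom hosting two
#' trichomes, each of four vegetative cells and one heterocyst, with
#' cell volumes 3493.5 / 18.8 / 61.0 um^3 for diatom, vegetative cell
#' and heterocyst respectively.
#'
#' @param n_trichomes Number of trichomes per diatom (positive integer).
#' @param vegetative_per_trichome Vegetative cells per trichome.
#' @param heterocysts_per_trichome Heterocysts per trichome.
#' @param volume_diatom,volume_vegetative,volume_heterocyst Per-cell
#'   volumes in um^3.
#' @return An object of class `dda_composition`.
#' @examples
#' dda_composition()
#' dda_composition(n_trichomes = 5)
#' @export
dda_composition <- function(n_trichomes = 2,
                            vegetative_per_trichome = 4,
                            heterocysts_per_trichome = 1,
                            volume_diatom = 3493.5,
                            volume_vegetative = 18.8,
                            volume_heterocyst = 61.0) {
  comp <- list(
    n_trichomes = check_count(n_trichomes, "n_trichomes"),
    vegetative_per_trichome =
      check_count(vegetative_per_trichome, "vegetative_per_trichome"),
    heterocysts_per_trichome =
      check_count(heterocysts_per_trichome, "heterocysts_per_trichome"),
    volume_diatom = check_positive(volume_diatom, "volume_diatom"),
    volume_vegetative = check_positive(volume_vegetative,
                                       "volume_vegetative"),
    volume_heterocyst = check_positive(volume_heterocyst,
                                       "volume_heterocyst")
  )
  structure(comp, class = "dda_composition")
}

#' @export
print.dda_composition <- function(x, ...) {
  cat("DDA composition: 1 diatom (", x$volume_diatom, " um^3), ",
      x$n_trichomes, " trichome(s) of ",
      x$vegetative_per_trichome, " vegetative (",
      x$volume_vegetative, " um^3) + ",
      x$heterocysts_per_trichome, " heterocyst(s) (",
      x$volume_heterocyst, " um^3)\n", sep = "")
  invisible(x)
}

#' Carbon quota of one cell from its volume
#'
#' Applies the allometric power law for the cell's class,
#' `pg C = 10^a * V^b`, and converts picograms of carbon to picomoles
#' (dividing by the molar mass of carbon, 12.011 g mol^-1).
#'
#' @param volume Cell volume in um^3 (> 0).
#' @param cell_class One of `cell_classes()`.
#' @param coeffs Allometric coefficients, as [default_allometry()].
#' @return Carbon quota in pmol C per cell.
#' @examples
#' carbon_quota_from_volume(3493.5, "diatom")   # ~ 12.9 pmol C
#' carbon_quota_from_volume(18.8, "vegetative") # ~ 0.28 pmol C
#' @export
carbon_quota_from_volume <- function(volume, cell_class,
                                     coeffs = default_allometry()) {
  cell_class <- match.arg(cell_class, cell_classes())
  validate_allometry(coeffs)
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    stop("volume must be positive, got ", deparse(volume), call. = FALSE)
  }
  co <- coeffs[[cell_class]]
  pg_c <- 10^(co$log10_intercept + co$exponent * log10(volume))
  pg_c / MOLAR_MASS_C
}

#' Per-association carbon and nitrogen quotas
#'
#' Pools per-cell quotas over the association: the diatom is one cell,
#' all vegetative cells form one pool, all heterocysts another. Nitrogen
#' quotas follow from a single C:N ratio applied uniformly (Redfield
#' 6.6:1 by default), so `QN = QC / rCN` in every compartment.
#'
#' @param comp A [dda_composition()].
#' @param coeffs Allometric coefficients, as [default_allometry()].
#' @param rCN Molar C:N ratio used for the C-to-N conversion (> 0).
#' @return An object of class `dda_quotas`: list with elements `QCD`,
#'   `QCV`, `QCH` (pmol C per association for diatom, pooled vegetative
#'   cells, pooled heterocysts), `QND`, `QNV`, `QNH` (pmol N) and `rCN`.
#' @examples
#' q <- build_quotas(dda_composition())
#' q$QCD / (q$QCD + q$QCV + q$QCH)  # diatom share of association C
#' @export
build_quotas <- function(comp, coeffs = default_allometry(), rCN = 6.6) {
  stopifnot(inherits(comp, "dda_composition"))
  rCN <- check_positive(rCN, "rCN")
  n_veg <- comp$n_trichomes * comp$vegetative_per_trichome
  n_het <- comp$n_trichomes * comp$heterocysts_per_trichome
  QCD <- carbon_quota_from_volume(comp$volume_diatom, "diatom", coeffs)
  QCV <- n_veg *
    carbon_quota_from_volume(comp$volume_vegetative, "vegetative", coeffs)
  QCH <- n_het *
    carbon_quota_from_volume(comp$volume_heterocyst, "heterocyst", coeffs)
  structure(
    list(QCD = QCD, QCV = QCV, QCH = QCH,
         QND = QCD / rCN, QNV = QCV / rCN, QNH = QCH / rCN,
         rCN = rCN),
    class = "dda_quotas"
  )
}

#' @export
print.dda_quotas <- function(x, digits = 4, ...) {
  cat("DDA quotas (per association):\n")
  m <- rbind(C = c(x$QCD, x$QCV, x$QCH), N = c(x$QND, x$QNV, x$QNH))
  colnames(m) <- c("diatom", "vegetative", "heterocyst")
  print(signif(m, digits))
  cat("units pmol; C:N =", x$rCN, "\n")
  invisible(x)
}

# total quotas, used throughout the balance equations
total_qc <- function(q) q$QCD + q$QCV + q$QCH
total_qn <- function(q) q$QND + q$QNV + q$QNH
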