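#' Scaffold strut material
#'
#' A solid-phase material description for lattice struts: the material
#' (not apparent) elastic modulus in MPa and Poisson ratio.
#'
#' @param name character name, e.g. "titanium".
#' @param elastic_modulus solid-phase Young's modulus in MPa, positive.
#' @param poisson_ratio dimensionless, in [0, 0.5).
#' @return An object of class `material`.
#' @examples
#' material("polyamide", 2000, 0.39)
#' @export
material <- function(name, elastic_modulus, poisson_ratio = 0.3) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(elastic_modulus) || elastic_modulus <= 0)
    stop("elastic_modulus must be > 0 (MPa)")
  if (!is.numeric(poisson_ratio) || poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("poisson_ratio must be in [0, 0.5)")
  structure(list(name = name,
                 elastic_modulus = as.numeric(elastic_modulus),
                 poisson_ratio = as.numeric(poisson_ratio)),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s: E = %g MPa, nu = %g\n",
              x$name, x$elastic_modulus, x$poisson_ratio))
  invisible(x)
}

## Canonical materials: commercially-pure titanium (E_s = 100 GPa) and
## laser-sintered polyamide PA12 (E_s = 2 GPa).
mat_titanium <- function() material("titanium", 100000, 0.34)
mat_polyamide <- function() material("polyamide", 2000, 0.39)

#' Scaffold design parameters
#'
#' The four study designs, identified by acronym:
#' \describe{
#'   \item{TC}{titanium control, octet truss, nominal porosity 0.6,
#'     unit cell scaled up by 1.3 relative to PB for metal sintering.}
#'   \item{TB}{titanium biomimetic, stochastic Poisson-disk lattice,
#'     nominal porosity 0.8, mean strut connectivity 4.5.}
#'   \item{PB}{polyamide biomimetic, octet truss, nominal porosity 0.45.}
#'   \item{PC}{polyamide control, orthogonal cubic grid, nominal
#'     porosity 0.35; compliant and strongly anisotropic off-axis.}
#' }
#' All designs are cylinders of 16 mm diameter and 15 mm height.
#' `reference_modulus` is the nominal axial apparent modulus (MPa) of the
#' design and `compliance_rank` orders designs from most compliant (1, PC)
#' to stiffest (4, TC); PB vs PC share the axial reference modulus and are
#' ordered by their direction-averaged modulus (the cubic grid collapses
#' off axis).
#'
#' @param acronym one of "TC", "TB", "PB", "PC".
#' @param unit_cell override the default unit cell edge length (mm);
#'   ignored for the stochastic generator.
#' @param cylinder_diameter,cylinder_height implant cylinder (mm).
#' @return An object of class `scaffold_design`.
#' @examples
#' scaffold_design("PB")
#' @export
scaffold_design <- function(acronym = c("TC", "TB", "PB", "PC"),
                            unit_cell = NULL,
                            cylinder_diameter = 16, cylinder_height = 15) {
  acronym <- match.arg(acronym)
  def <- switch(acronym,
    TC = list(material = mat_titanium(), generator = "octetruss",
              unit_cell = 3 * 1.3, nominal_porosity = 0.6,
              reference_modulus = 7100, compliance_rank = 4L),
    TB = list(material = mat_titanium(), generator = "stochastic",
              unit_cell = NA_real_, nominal_porosity = 0.8,
              reference_modulus = 1400, compliance_rank = 3L),
    PB = list(material = mat_polyamide(), generator = "octetruss",
              unit_cell = 3, nominal_porosity = 0.45,
              reference_modulus = 220, compliance_rank = 2L),
    PC = list(material = mat_polyamide(), generator = "cubic",
              unit_cell = 3, nominal_porosity = 0.35,
              reference_modulus = 220, compliance_rank = 1L))
  if (!is.null(unit_cell)) def$unit_cell <- unit_cell
  stopifnot(def$nominal_porosity > 0, def$nominal_porosity < 1)
  structure(c(list(acronym = acronym), def,
              list(cylinder_diameter = cylinder_diameter,
                   cylinder_height = cylinder_height)),
            class = "scaffold_design")
}

#' @export
print.scaffold_design <- function(x, ...) {
  cat(sprintf(
    "<scaffold_design> %s: %s %s, porosity %.2f, cylinder %g x %g mm\n",
    x$acronym, x$material$name, x$generator, x$nominal_porosity,
    x$cylinder_diameter, x$cylinder_height))
  invisible(x)
}

#' Compliance ordering of the four designs
#'
#' Rank 1 is the most compliant design (PC), rank 4 the stiffest (TC),
#' by direction-averaged apparent modulus.
#'
#' @param acronym character vector of design acronyms.
#' @return integer ranks.
#' @export
design_compliance_rank <- function(acronym) {
  ranks <- c(PC = 1L, PB = 2L, TB = 3L, TC = 4L)
  out <- ranks[acronym]
  if (anyNA(out)) stop("unknown design acronym")
  unname(out)
}

#' Nominal axial apparent modulus of a design (MPa)
#' @param acronym character vector of design acronyms.
#' @return numeric MPa.
#' @export
design_reference_modulus <- function(acronym) {
  mod <- c(TC = 7100, TB = 1400, PB = 220, PC = 220)
  out <- mod[acronym]
  if (anyNA(out)) stop("unknown design acronym")
  unname(out)
}
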