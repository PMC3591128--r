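# Constitutive laws for the motion-segment constituents: bilinear tension-only
# ligaments, linear tension-only annulus fibres (layer-wise moduli), the
# incompressible Mooney-Rivlin nucleus pulposus (with an elastic comparison
# variant), and elastic annulus ground substance / cartilage. Cards are
# transcriptions of the packaged YAML material tables.

#' Bilinear tension-only law
#'
#' Constructor for the piecewise-linear, tension-only stress-strain law used
#' for the spinal ligaments: stiffness `E1` up to the transition strain, `E2`
#' beyond it, zero stress in compression, stress continuous at the transition.
#'
#' @param E1 Low-strain Young modulus, MPa.
#' @param transition_strain Strain at which the stiffness changes
#'   (dimensionless, in (0, 1)).
#' @param E2 Modulus beyond the transition strain, MPa.
#' @return An object of class `lumbokin_bilinear`.
#' @export
bilinear_law <- function(E1, transition_strain, E2) {
  stopifnot(is.numeric(E1), is.numeric(E2), is.numeric(transition_strain))
  if (E1 <= 0 || E2 <= 0) stop("bilinear moduli must be positive", call. = FALSE)
  if (transition_strain <= 0 || transition_strain >= 1) {
    stop("transition_strain must lie in (0, 1)", call. = FALSE)
  }
  structure(list(E1 = E1, transition_strain = transition_strain, E2 = E2,
                 tension_only = TRUE),
            class = "lumbokin_bilinear")
}

#' Uniaxial stress of a bilinear tension-only law
#'
#' @param law A [bilinear_law()].
#' @param strain Numeric vector of strains (dimensionless).
#' @return Stress in MPa: 0 for nonpositive strains, `E1 * strain` up to the
#'   transition, `E1 * et + E2 * (strain - et)` beyond it.
#' @examples
#' all_law <- bilinear_law(7.8, 0.12, 20.0)
#' uniaxial_stress(all_law, c(-0.05, 0, 0.12, 0.2))
#' @export
uniaxial_stress <- function(law, strain) {
  stopifnot(inherits(law, "lumbokin_bilinear"), all(is.finite(strain)))
  et <- law$transition_strain
  ifelse(strain <= 0, 0,
         ifelse(strain <= et, law$E1 * strain,
                law$E1 * et + law$E2 * (strain - et)))
}

# strain-energy density (per unit volume, MPa) of the bilinear law
bilinear_energy <- function(law, strain) {
  et <- law$transition_strain
  ifelse(strain <= 0, 0,
         ifelse(strain <= et, 0.5 * law$E1 * strain^2,
                0.5 * law$E1 * et^2 + law$E1 * et * (strain - et) +
                  0.5 * law$E2 * (strain - et)^2))
}

#' Tension-only stress in an annulus fibre layer
#'
#' @param layer_index Integer 1..5, innermost to outermost material layer.
#' @param strain Numeric strain along the fibre direction.
#' @param card A [material_card()].
#' @return Stress in MPa, `max(0, E_layer * strain)`.
#' @export
fiber_stress <- function(layer_index, strain, card) {
  stopifnot(inherits(card, "lumbokin_card"))
  if (!layer_index %in% 1:5) {
    stop("layer_index must be in 1..5", call. = FALSE)
  }
  pmax(0, card$fiber_layers$E[layer_index] * strain)
}

#' Incompressible Mooney-Rivlin uniaxial response
#'
#' Cauchy stress of the incompressible Mooney-Rivlin solid under uniaxial
#' stretch: `sigma = 2 (C10 + C01 / lambda) (lambda^2 - 1/lambda)`.
#'
#' @param nucleus A nucleus description with components `C01` and `C10` (MPa),
#'   e.g. `material_card("healthy")$nucleus`.
#' @param stretch Principal stretch `lambda > 0`.
#' @return Cauchy stress, MPa; zero at `lambda = 1`.
#' @export
mooney_rivlin_uniaxial <- function(nucleus, stretch) {
  if (any(stretch <= 0)) stop("stretch must be positive", call. = FALSE)
  if (is.null(nucleus$C01) || is.null(nucleus$C10)) {
    stop("nucleus has no Mooney-Rivlin constants", call. = FALSE)
  }
  2 * (nucleus$C10 + nucleus$C01 / stretch) * (stretch^2 - 1 / stretch)
}

#' Load a material card
#'
#' Reads and validates a YAML material card. The packaged cards transcribe the
#' healthy and the degenerated-disc property tables; [material_card()] is the
#' shorthand for the packaged files.
#'
#' @param source `"healthy"` or `"degenerated"` (used for the packaged files
#'   and recorded on the card).
#' @param file Optional path to a YAML card; defaults to the packaged card for
#'   `source`.
#' @return An object of class `lumbokin_card`.
#' @export
load_card <- function(source = c("healthy", "degenerated"), file = NULL) {
  source <- match.arg(source)
  if (is.null(file)) {
    file <- system.file("extdata", paste0("materials_", source, ".yaml"),
                        package = "lumbokin", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(file)
  validate_card(raw)
}

#' @rdname load_card
#' @export
material_card <- function(source = c("healthy", "degenerated")) {
  load_card(match.arg(source))
}

validate_card <- function(raw) {
  needed <- c("annulus", "nucleus", "fiber_layers", "ligaments", "cartilage")
  miss <- setdiff(needed, names(raw))
  if (length(miss)) {
    stop("material card is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(raw$annulus$E) || raw$annulus$E <= 0) {
    stop("annulus modulus must be positive", call. = FALSE)
  }
  if (raw$annulus$nu <= 0 || raw$annulus$nu >= 0.5) {
    stop("annulus Poisson ratio must lie in (0, 0.5)", call. = FALSE)
  }
  fe <- as.numeric(raw$fiber_layers$E)
  if (length(fe) != 5 || any(fe <= 0)) {
    stop("fiber_layers$E must be five positive moduli", call. = FALSE)
  }
  if (any(diff(fe) <= 0)) {
    stop("fibre layer moduli must increase strictly with layer index",
         call. = FALSE)
  }
  raw$fiber_layers$E <- fe
  raw$ligaments <- lapply(raw$ligaments, function(lg) {
    bilinear_law(lg$E1, lg$transition_strain, lg$E2)
  })
  model <- raw$nucleus$model %||% "mooney_rivlin"
  if (model == "mooney_rivlin") {
    if (raw$nucleus$C01 <= 0 || raw$nucleus$C10 <= 0) {
      stop("Mooney-Rivlin constants must be positive", call. = FALSE)
    }
    raw$nucleus$penalty_bulk <- raw$nucleus$penalty_bulk %||% 2200
    raw$nucleus$incompressible <- TRUE
  } else if (model == "elastic") {
    if (raw$nucleus$E <= 0) stop("nucleus modulus must be positive", call. = FALSE)
    if (raw$nucleus$nu <= 0 || raw$nucleus$nu >= 0.5) {
      stop("elastic nucleus Poisson ratio must lie in (0, 0.5)", call. = FALSE)
    }
    raw$nucleus$incompressible <- FALSE
  } else {
    stop("unknown nucleus model: ", model, call. = FALSE)
  }
  structure(raw, class = "lumbokin_card")
}

#' Elastic comparison nucleus card
#'
#' Returns a copy of `card` whose nucleus is replaced by the compressible
#' elastic comparison material (default E = 1.0 MPa, nu = 0.49) used to check
#' that the incompressibility assumption holds: under the 400 N follower
#' preload the relative nucleus volume change stays below 0.6 %.
#'
#' @param card A [material_card()].
#' @param E,nu Elastic constants of the comparison material.
#' @return A `lumbokin_card`.
#' @export
comparison_card <- function(card = material_card("healthy"), E = 1.0, nu = 0.49) {
  stopifnot(inherits(card, "lumbokin_card"))
  card$nucleus <- list(model = "elastic", E = E, nu = nu, incompressible = FALSE)
  card$name <- paste0(card$name, "_elastic_comparison")
  card
}

# bulk and shear moduli of the nucleus model; the Mooney-Rivlin nucleus uses
# the volumetric penalty as its bulk modulus and mu = 2 (C10 + C01) in shear
nucleus_moduli <- function(nucleus) {
  if (isTRUE(nucleus$incompressible)) {
    list(K = nucleus$penalty_bulk, G = 2 * (nucleus$C10 + nucleus$C01))
  } else {
    list(K = nucleus$E / (3 * (1 - 2 * nucleus$nu)),
         G = nucleus$E / (2 * (1 + nucleus$nu)))
  }
}

# confined (oedometric) modulus of an elastic layer bonded between stiff
# endplates; used for the axial/bending annulus foundation terms
constrained_modulus <- function(E, nu) {
  E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))
}

#' @export
print.lumbokin_card <- function(x, ...) {
  cat("<lumbokin material card:", x$name %||% "unnamed", ">\n")
  cat("  annulus: E =", x$annulus$E, "MPa, nu =", x$annulus$nu, "\n")
  if (isTRUE(x$nucleus$incompressible)) {
    cat("  nucleus: Mooney-Rivlin incompressible, C01 =", x$nucleus$C01,
        ", C10 =", x$nucleus$C10, "MPa\n")
  } else {
    cat("  nucleus: elastic, E =", x$nucleus$E, "MPa, nu =", x$nucleus$nu, "\n")
  }
  cat("  fibre layers E:", paste(x$fiber_layers$E, collapse = ", "), "MPa\n")
  cat("  ligaments:", paste(names(x$ligaments), collapse = ", "), "\n")
  invisible(x)
}
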