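#' Compartment geometry
#'
#' A compartment is a named list describing one electrical section of the
#' cell: its shape (`"sphere"` or `"cylinder"`), dimensions in micrometres,
#' passive parameters and an optional membrane `area_scale` factor.  The
#' area scale captures the fact that the real dendritic brush is a folded
#' structure of dendrioles whose effective membrane area exceeds the area of
#' the equivalent cylinder.
#'
#' @param name compartment identifier.
#' @param shape `"sphere"` or `"cylinder"`.
#' @param length_um length in micrometres (unused for spheres).
#' @param diam_um diameter in micrometres.
#' @param area_scale multiplier applied to the geometric membrane area.
#' @param ra_ohm_cm axial resistivity in Ohm cm.
#' @param cm_uF_cm2 specific membrane capacitance in uF/cm2.
#' @return a `ubc_compartment` list.
#' @export
compartment <- function(name, shape = c("cylinder", "sphere"),
                        length_um = 0, diam_um,
                        area_scale = 1,
                        ra_ohm_cm = 100, cm_uF_cm2 = 1) {
  shape <- match.arg(shape)
  if (diam_um <= 0) stop("diameter must be positive")
  if (length_um < 0) stop("length must be non-negative")
  if (area_scale <= 0) stop("area_scale must be positive")
  structure(list(name = name, shape = shape, length_um = length_um,
                 diam_um = diam_um, area_scale = area_scale,
                 ra_ohm_cm = ra_ohm_cm, cm_uF_cm2 = cm_uF_cm2),
            class = "ubc_compartment")
}

#' Membrane area of a compartment
#'
#' Spheres use `pi * d^2`; cylinders use the lateral area `pi * d * L`
#' (no end caps: sections are either connected at their ends or represent
#' folded structures whose effective area is set through `area_scale`).
#' The `area_scale` factor multiplies the geometric area.
#'
#' @param comp a [compartment()].
#' @param scaled apply the compartment's `area_scale` (default `TRUE`).
#' @return area in um2.
#' @export
membrane_area <- function(comp, scaled = TRUE) {
  a <- switch(comp$shape,
    sphere = pi * comp$diam_um^2,
    cylinder = pi * comp$diam_um * comp$length_um
  )
  if (scaled) a * comp$area_scale else a
}

#' Axial coupling conductance between a compartment and its parent
#'
#' Series combination of the two half-compartment axial resistances,
#' `R_half = Ra * (L/2) / (pi r^2)`.  A sphere is treated as an
#' iso-potential node with zero internal axial resistance.
#'
#' @param child,parent [compartment()]s connected in the tree.
#' @return conductance in uS.
#' @export
axial_conductance <- function(child, parent) {
  r <- axial_half_resistance(child) + axial_half_resistance(parent)
  if (r <= 0) return(Inf)
  1 / r # uS = 1/MOhm
}

# half-compartment axial resistance in MOhm
axial_half_resistance <- function(comp) {
  if (comp$shape == "sphere") return(0)
  if (comp$diam_um <= 0) stop("zero diameter")
  r_cm <- comp$diam_um / 2 * 1e-4
  l_cm <- comp$length_um / 2 * 1e-4
  comp$ra_ohm_cm * l_cm / (pi * r_cm^2) * 1e-6
}

#' Build the canonical 13-compartment UBC morphology
#'
#' One spherical soma (8 um diameter), a dendritic shaft (50 x 2 um), the
#' brush (25.25 x 10 um cylinder whose area is scaled so that the
#' brush + shaft capacitance equals 12.7 pF, reflecting the folded
#' dendriolar membrane), five axon initial-segment compartments (0.5 um
#' long, diameters decreasing linearly 3.2 to 0.8 um) and five axonal
#' compartments (80 x 0.5 um, area-scaled so the axonal capacitance is
#' 2 pF).  Passive parameters: Ra = 100 Ohm cm, Cm = 1 uF/cm2.
#'
#' @param morph_cfg optional morphology block of a model config (list of
#'   per-compartment geometry entries); defaults to the packaged canonical
#'   configuration.
#' @return a `ubc_morphology` list with elements `compartments` (list of 13
#'   [compartment()]s), `parent` (integer vector, 0 for the root soma),
#'   `pipette` (access resistance, MOhm).
#' @export
build_canonical_ubc <- function(morph_cfg = NULL) {
  if (is.null(morph_cfg)) morph_cfg <- ubc_config()$morphology
  comps <- list()
  parent <- integer(0)
  add <- function(comp, par) {
    comps[[length(comps) + 1L]] <<- comp
    parent[length(parent) + 1L] <<- par
  }
  g <- morph_cfg
  add(compartment("soma", "sphere", diam_um = g$soma$diam_um), 0L)
  add(compartment("shaft", "cylinder", g$shaft$length_um, g$shaft$diam_um,
                  area_scale = g$shaft$area_scale), 1L)
  add(compartment("brush", "cylinder", g$brush$length_um, g$brush$diam_um,
                  area_scale = g$brush$area_scale), 2L)
  d_ais <- seq(g$ais$diam_first_um, g$ais$diam_last_um, length.out = g$ais$n_sections)
  par <- 1L
  for (i in seq_len(g$ais$n_sections)) {
    add(compartment(paste0("ais", i), "cylinder", g$ais$length_um, d_ais[i]), par)
    par <- length(comps)
  }
  for (i in seq_len(g$axon$n_sections)) {
    add(compartment(paste0("axon", i), "cylinder", g$axon$length_um,
                    g$axon$diam_um, area_scale = g$axon$area_scale), par)
    par <- length(comps)
  }
  m <- structure(list(compartments = comps, parent = parent,
                      pipette = list(access_resistance_mohm =
                                       g$pipette$access_resistance_mohm)),
                 class = "ubc_morphology")
  validate_morphology(m)
  m
}

validate_morphology <- function(m) {
  n <- length(m$compartments)
  stopifnot(length(m$parent) == n)
  # tree check: every non-root has a parent with smaller index, one root
  if (sum(m$parent == 0L) != 1L) stop("morphology must have exactly one root")
  if (any(m$parent >= seq_len(n))) stop("parents must precede children")
  invisible(m)
}

#' Per-compartment membrane capacitance
#' @param morph a `ubc_morphology`.
#' @return capacitance per compartment in pF.
#' @export
compartment_capacitance <- function(morph) {
  vapply(morph$compartments, function(cp) {
    membrane_area(cp) * 1e-8 * cp$cm_uF_cm2 * 1e6 # cm2 * uF/cm2 -> pF
  }, numeric(1))
}

#' @export
print.ubc_morphology <- function(x, ...) {
  caps <- compartment_capacitance(x)
  cat(sprintf("UBC morphology: %d compartments, total capacitance %.2f pF\n",
              length(x$compartments), sum(caps)))
  for (i in seq_along(x$compartments)) {
    cp <- x$compartments[[i]]
    cat(sprintf("  %-6s %-8s L=%6.2f um d=%5.2f um area=%8.2f um2 C=%6.3f pF\n",
                cp$name, cp$shape, cp$length_um, cp$diam_um,
                membrane_area(cp), caps[i]))
  }
  invisible(x)
}
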