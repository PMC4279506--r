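# Layered tissue model: geometry, wavelength-indexed optical properties, and
# depth/property lookup.  Lengths are stored in mm and optical coefficients in
# 1/cm (as conventionally tabulated); transport converts to 1/mm once per run.

#' Optical properties of a turbid medium at one wavelength
#'
#' @param mu_a absorption coefficient (1/cm), >= 0.
#' @param mu_s scattering coefficient (1/cm), >= 0.
#' @param g anisotropy factor (mean scattering cosine), in \code{[-1, 1]}.
#' @param n refractive index, >= 1.
#' @return An object of class \code{optical_properties} (a named list).
#' @export
#' @examples
#' optical_properties(mu_a = 55, mu_s = 450, g = 0.8, n = 1.34)
optical_properties <- function(mu_a, mu_s, g, n) {
  stopifnot(is.numeric(mu_a), is.numeric(mu_s), is.numeric(g), is.numeric(n))
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (mu_s < 0) stop("mu_s must be >= 0")
  if (g < -1 || g > 1) stop("g must lie in [-1, 1]")
  if (n < 1) stop("refractive index n must be >= 1")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("mu_a = %g 1/cm, mu_s = %g 1/cm, g = %g, n = %g\n",
              x$mu_a, x$mu_s, x$g, x$n))
  invisible(x)
}

.validate_property_table <- function(properties, name) {
  need <- c("wavelength_nm", "mu_a_percm", "mu_s_percm", "g", "n")
  if (!is.data.frame(properties) || !all(need %in% names(properties)))
    stop("layer '", name, "': properties must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (nrow(properties) < 1)
    stop("layer '", name, "': at least one property row is required")
  if (any(duplicated(properties$wavelength_nm)))
    stop("layer '", name, "': duplicated wavelength rows")
  if (any(properties$mu_a_percm < 0) || any(properties$mu_s_percm < 0))
    stop("layer '", name, "': mu_a and mu_s must be >= 0")
  if (any(properties$g < -1 | properties$g > 1))
    stop("layer '", name, "': g must lie in [-1, 1]")
  if (any(properties$n < 1))
    stop("layer '", name, "': refractive index must be >= 1")
  if (length(unique(properties$n)) != 1)
    stop("layer '", name, "': n must not vary with wavelength (dispersion ",
         "is not modelled)")
  properties[order(properties$wavelength_nm), , drop = FALSE]
}

#' Define a tissue layer
#'
#' @param name layer label (e.g. \code{"dermis"}).
#' @param thickness_mm layer thickness in mm, > 0.
#' @param properties data.frame with columns \code{wavelength_nm},
#'   \code{mu_a_percm}, \code{mu_s_percm}, \code{g}, \code{n} (one row per
#'   tabulated wavelength).  The refractive index must be constant across
#'   rows: dispersion is not modelled.
#' @param wavelength_independent if \code{TRUE} the layer has a single
#'   property row that applies at every simulation wavelength (as for the
#'   epidermis, whose properties vary negligibly over 800--900 nm).
#' @return An object of class \code{tissue_layer}.
#' @export
tissue_layer <- function(name, thickness_mm, properties,
                         wavelength_independent = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(thickness_mm) || thickness_mm <= 0)
    stop("layer '", name, "': thickness_mm must be > 0")
  properties <- .validate_property_table(properties, name)
  if (wavelength_independent && nrow(properties) != 1L)
    stop("layer '", name, "': a wavelength-independent layer must have ",
         "exactly one property row")
  structure(list(name = name,
                 thickness_mm = thickness_mm,
                 properties = properties,
                 wavelength_independent = isTRUE(wavelength_independent)),
            class = "tissue_layer")
}

#' Assemble an ordered stack of tissue layers
#'
#' Layers are ordered top (illuminated surface, z = 0) to bottom; layer i
#' occupies the half-open depth interval \[boundary_i, boundary_{i+1}).
#'
#' @param layers list of [tissue_layer()] objects, top to bottom.
#' @param n_above refractive index of the medium above the stack
#'   (default 1.0, air).
#' @param n_below refractive index below the last layer; defaults to the last
#'   layer's own index (matched boundary, no bottom-interface reflection).
#' @return An object of class \code{tissue_stack}.
#' @export
#' @examples
#' stack <- default_skin_stack()
#' stack_boundaries(stack)
tissue_stack <- function(layers, n_above = 1.0, n_below = NULL) {
  if (!is.list(layers) || length(layers) < 1L ||
      !all(vapply(layers, inherits, logical(1), "tissue_layer")))
    stop("layers must be a non-empty list of tissue_layer objects")
  if (!is.numeric(n_above) || n_above < 1) stop("n_above must be >= 1")
  n_last <- layers[[length(layers)]]$properties$n[1]
  if (is.null(n_below)) n_below <- n_last
  if (!is.numeric(n_below) || n_below < 1) stop("n_below must be >= 1")
  structure(list(layers = layers, n_above = n_above, n_below = n_below),
            class = "tissue_stack")
}

#' @export
print.tissue_stack <- function(x, ...) {
  b <- stack_boundaries(x)
  cat(sprintf("tissue_stack: %d layers (n_above = %g, n_below = %g)\n",
              length(x$layers), x$n_above, x$n_below))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  %d. %-10s z = [%g, %g) mm, %d wavelength row(s)%s\n",
                i, l$name, b[i], b[i + 1], nrow(l$properties),
                if (l$wavelength_independent) " [wavelength-independent]"
                else ""))
  }
  invisible(x)
}

#' Cumulative boundary depths of a stack
#'
#' @param stack a [tissue_stack()].
#' @return Numeric vector of length \code{nlayer + 1}: depths (mm) of the top
#'   of each layer plus the bottom of the last, starting at 0.
#' @export
stack_boundaries <- function(stack) {
  stopifnot(inherits(stack, "tissue_stack"))
  c(0, cumsum(vapply(stack$layers, `[[`, numeric(1), "thickness_mm")))
}

.resolve_layer <- function(stack, layer) {
  nms <- vapply(stack$layers, `[[`, character(1), "name")
  if (is.character(layer)) {
    idx <- match(layer, nms)
    if (is.na(idx)) stop("unknown layer '", layer, "'")
    return(idx)
  }
  idx <- as.integer(layer)
  if (is.na(idx) || idx < 1L || idx > length(stack$layers))
    stop("layer index out of range (1..", length(stack$layers), ")")
  idx
}

#' Look up layer optical properties at a wavelength
#'
#' Returns the tabulated row when the wavelength matches a table entry
#' exactly; otherwise mu_a, mu_s and g are linearly interpolated between the
#' two bracketing entries.  Wavelength-independent layers return their single
#' row at any wavelength.
#'
#' @param stack a [tissue_stack()].
#' @param layer layer index (1-based, top layer = 1) or layer name.
#' @param wavelength_nm wavelength in nm; must lie within the tabulated range
#'   of the layer (unless the layer is wavelength-independent).
#' @return An [optical_properties()] object (coefficients in 1/cm).
#' @export
#' @examples
#' properties_at(default_skin_stack(), "dermis", 900)
properties_at <- function(stack, layer, wavelength_nm) {
  stopifnot(inherits(stack, "tissue_stack"))
  idx <- .resolve_layer(stack, layer)
  l <- stack$layers[[idx]]
  p <- l$properties
  if (l$wavelength_independent)
    return(optical_properties(p$mu_a_percm[1], p$mu_s_percm[1], p$g[1], p$n[1]))
  wl <- p$wavelength_nm
  if (wavelength_nm < min(wl) || wavelength_nm > max(wl))
    stop(sprintf(
      "wavelength %g nm outside the tabulated range [%g, %g] for layer '%s'",
      wavelength_nm, min(wl), max(wl), l$name))
  interp <- function(col) approx(wl, p[[col]], xout = wavelength_nm)$y
  optical_properties(interp("mu_a_percm"), interp("mu_s_percm"),
                     interp("g"), p$n[1])
}

#' Layer containing a given depth
#'
#' Uses the half-open convention: layer i occupies
#' \[boundary_i, boundary_{i+1}), so a depth exactly on an interior boundary
#' belongs to the layer below it.
#'
#' @param stack a [tissue_stack()].
#' @param z depth in mm, \code{0 <= z <} bottom of the last layer.
#' @return 1-based layer index.
#' @export
layer_of_depth <- function(stack, z) {
  stopifnot(inherits(stack, "tissue_stack"), is.numeric(z), length(z) == 1L)
  if (z < 0) stop("depth z must be >= 0")
  b <- stack_boundaries(stack)
  if (z >= b[length(b)])
    stop(sprintf("depth %g mm is below the bottom of the stack (%g mm)",
                 z, b[length(b)]))
  findInterval(z, b)
}

# Table of the default four-layer skin model.  mu_a, mu_s in 1/cm.
.default_layer_tables <- function() {
  list(
    epidermis = list(
      thickness_mm = 0.065, independent = TRUE,
      props = data.frame(wavelength_nm = 850, mu_a_percm = 55,
                         mu_s_percm = 450, g = 0.8, n = 1.34)),
    dermis = list(
      thickness_mm = 1.25, independent = FALSE,
      props = data.frame(
        wavelength_nm = c(800, 825, 850, 875, 900),
        mu_a_percm = c(0.127, 0.121, 0.122, 0.122, 0.134),
        mu_s_percm = c(19.07, 18.24, 17.57, 16.98, 16.30),
        g = c(0.86, 0.87, 0.87, 0.88, 0.89),
        n = 1.55)),
    fat = list(
      thickness_mm = 12, independent = FALSE,
      props = data.frame(
        wavelength_nm = c(800, 825, 850, 875, 900),
        mu_a_percm = c(0.083, 0.085, 0.086, 0.091, 0.125),
        mu_s_percm = c(11.09, 11.12, 11.09, 10.97, 10.88),
        g = c(0.64, 0.63, 0.62, 0.60, 0.59),
        n = 1.45)),
    muscle = list(
      thickness_mm = 1.0e8, independent = FALSE,
      props = data.frame(
        wavelength_nm = c(800, 825, 850, 875, 900),
        mu_a_percm = c(0.284, 0.309, 0.343, 0.368, 0.393),
        mu_s_percm = c(6.60, 6.78, 6.60, 6.43, 6.32),
        g = c(0.85, 0.85, 0.85, 0.85, 0.85),
        n = 1.37)))
}

#' The default four-layer skin stack
#'
#' Epidermis (0.065 mm, wavelength-independent properties), dermis (1.25 mm),
#' subcutaneous fat (12 mm) and an effectively semi-infinite muscle layer
#' (1e8 mm), each with tabulated optical properties at 800, 825, 850, 875 and
#' 900 nm.  Air (n = 1.0) above; the bottom boundary is index-matched to
#' muscle.
#'
#' @return A [tissue_stack()] with four layers.
#' @export
#' @examples
#' default_skin_stack()
default_skin_stack <- function() {
  tabs <- .default_layer_tables()
  layers <- lapply(names(tabs), function(nm) {
    t <- tabs[[nm]]
    tissue_layer(nm, t$thickness_mm, t$props,
                 wavelength_independent = t$independent)
  })
  tissue_stack(layers, n_above = 1.0)
}

# Internal: per-layer transport coefficients in 1/mm at one wavelength,
# plus boundary depths, ready for the C++ kernel.
transport_coefficients <- function(stack, wavelength_nm) {
  props <- lapply(seq_along(stack$layers), function(i)
    properties_at(stack, i, wavelength_nm))
  list(
    mua_mm = vapply(props, function(p) p$mu_a / 10, numeric(1)),
    mus_mm = vapply(props, function(p) p$mu_s / 10, numeric(1)),
    g = vapply(props, `[[`, numeric(1), "g"),
    n = vapply(props, `[[`, numeric(1), "n"),
    boundaries = stack_boundaries(stack),
    layer_names = vapply(stack$layers, `[[`, character(1), "name"))
}
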