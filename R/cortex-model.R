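#' Geometric model of a flattened cortical sheet cut into serial sections
#'
#' The coordinate frame used throughout the package: `x` is the tangential
#' position within the flattened sheet (micrometres), `y` is depth from the
#' pial surface (micrometres), and `z` is derived from the serial-section
#' index via [section_to_z()]. Cortical areas are contiguous intervals on the
#' tangential axis; layers are half-open depth bands `[top, bottom)` that tile
#' the cortical depth from layer 1 to layer 6.
#'
#' @param section_thickness Section thickness in micrometres (default 80).
#' @param n_sections Number of serial coronal sections.
#' @param layers Data frame with columns `layer`, `top_um`, `bottom_um`
#'   ordered L1 to L6; bands must be disjoint and tile the depth range.
#' @param areas Named list of length-2 numeric vectors, the tangential
#'   `[min, max)` interval of each cortical area in micrometres. Intervals
#'   must not overlap.
#' @param subcortical Character vector of subcortical structure names that
#'   labeled somata may carry instead of a cortical area (no layer assigned).
#' @param hemispheres Valid hemisphere labels.
#'
#' @return An object of class `cortex_model`.
#' @examples
#' m <- cortex_model()
#' layer_of_depth(c(100, 500, 1600), m)
#' @export
cortex_model <- function(section_thickness = 80,
                         n_sections = 60,
                         layers = default_layers(),
                         areas = default_areas(),
                         subcortical = c("LGN", "pulvinar", "claustrum"),
                         hemispheres = c("ipsi", "contra")) {
  if (!is.numeric(section_thickness) || length(section_thickness) != 1 ||
      section_thickness <= 0)
    stop("section_thickness must be a single positive number (um)")
  if (!is.data.frame(layers) ||
      !all(c("layer", "top_um", "bottom_um") %in% names(layers)))
    stop("layers must be a data frame with columns layer, top_um, bottom_um")
  layers <- layers[order(layers$top_um), , drop = FALSE]
  if (any(layers$bottom_um <= layers$top_um))
    stop("every layer band must have bottom_um > top_um")
  if (nrow(layers) > 1 &&
      any(abs(layers$top_um[-1] - layers$bottom_um[-nrow(layers)]) > 1e-9))
    stop("layer bands must be disjoint and tile the depth range without gaps")
  ivs <- do.call(rbind, lapply(areas, function(v) v[1:2]))
  if (!is.null(ivs) && nrow(ivs) > 1) {
    o <- order(ivs[, 1])
    if (any(ivs[o, 1][-1] < ivs[o, 2][-nrow(ivs)]))
      stop("area intervals must not overlap within a section")
  }
  structure(list(section_thickness = section_thickness,
                 n_sections = as.integer(n_sections),
                 layers = layers,
                 areas = areas,
                 subcortical = subcortical,
                 hemispheres = hemispheres),
            class = "cortex_model")
}

#' @export
print.cortex_model <- function(x, ...) {
  cat("<cortex_model> ", x$n_sections, " sections x ", x$section_thickness,
      " um; areas: ", paste(names(x$areas), collapse = ", "),
      "; subcortical: ", paste(x$subcortical, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Depth bands (um from pia) for cat area 17; bottom of L6 near the
# 1800-2100 um range targeted by deep injections.
default_layers <- function() {
  data.frame(layer = c("L1", "L2", "L3", "L4", "L5", "L6"),
             top_um = c(0, 150, 350, 800, 1100, 1400),
             bottom_um = c(150, 350, 800, 1100, 1400, 1900),
             stringsAsFactors = FALSE)
}

default_areas <- function() {
  list(A17 = c(0, 12000), A18 = c(12000, 20000), A19 = c(20000, 24000))
}

layer_names <- function(model) model$layers$layer

#' Depth coordinate of a serial section
#'
#' Each coronal section contributes one section thickness to the
#' anteroposterior coordinate: `z = section_index * section_thickness`.
#'
#' @param section_index Integer section index (0-based), vectorised.
#' @param section_thickness Section thickness in micrometres (default 80).
#' @return Numeric z coordinate(s) in micrometres.
#' @examples
#' section_to_z(10)        # 800
#' section_to_z(7, 50)     # 350
#' @export
section_to_z <- function(section_index, section_thickness = 80) {
  if (any(section_index < 0)) stop("section_index must be >= 0")
  if (section_thickness <= 0) stop("section_thickness must be positive")
  section_index * section_thickness
}

#' Assign cortical layers from depth
#'
#' Uses the model's half-open depth bands `[top, bottom)`.
#'
#' @param y Depth(s) from pia in micrometres.
#' @param model A [cortex_model()].
#' @return Character vector of layer names (`NA` outside the cortical depth).
#' @export
layer_of_depth <- function(y, model) {
  ly <- model$layers
  idx <- findInterval(y, c(ly$top_um, ly$bottom_um[nrow(ly)]),
                      rightmost.closed = FALSE)
  out <- rep(NA_character_, length(y))
  ok <- idx >= 1 & idx <= nrow(ly) & y < ly$bottom_um[nrow(ly)]
  out[ok] <- ly$layer[idx[ok]]
  out
}

#' Look up the cortical area containing a tangential coordinate
#' @param x Tangential coordinate(s) in micrometres.
#' @param model A [cortex_model()].
#' @return Character vector of area names (`NA` between areas).
#' @export
area_of_x <- function(x, model) {
  out <- rep(NA_character_, length(x))
  for (a in names(model$areas)) {
    iv <- model$areas[[a]]
    out[x >= iv[1] & x < iv[2]] <- a
  }
  out
}

#' Serialize or restore a cortex model as YAML
#'
#' @param model A [cortex_model()].
#' @param path File path.
#' @return `read_cortex_model()` returns a `cortex_model`;
#'   `write_cortex_model()` returns `path` invisibly.
#' @export
write_cortex_model <- function(model, path) {
  obj <- unclass(model)
  obj$layers <- as.list(obj$layers)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_cortex_model
#' @export
read_cortex_model <- function(path) {
  obj <- yaml::read_yaml(path)
  cortex_model(section_thickness = obj$section_thickness,
               n_sections = obj$n_sections,
               layers = as.data.frame(obj$layers, stringsAsFactors = FALSE),
               areas = lapply(obj$areas, unlist),
               subcortical = unlist(obj$subcortical),
               hemispheres = unlist(obj$hemispheres))
}
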