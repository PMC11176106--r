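NEURON_COLUMNS <- c("id", "x_um", "y_um", "section_index", "area",
                    "hemisphere", "layer", "tracer", "in_injection_site")
INJECTION_COLUMNS <- c("id", "x_um", "y_um", "section_index", "layer",
                       "area", "volume_mm3", "tracer")

#' Read a table of retrogradely labeled somata
#'
#' Tables are tab-separated UTF-8 with a fixed header
#' (`id, x_um, y_um, section_index, area, hemisphere, layer, tracer,
#' in_injection_site`); lines starting with `#` are ignored. Records are
#' validated against the cortex model: unknown areas or layers are collected
#' into a single error naming each offending row and value, and somata whose
#' recorded layer disagrees with their depth under the model's bands are
#' reported in a warning (the recorded layer is kept — layer assignment on
#' the micrographs is authoritative, the depth check is a consistency audit).
#'
#' @param path Path to a TSV file.
#' @param model A [cortex_model()] used for validation.
#' @return A data frame of labeled neurons, row order preserved.
#' @seealso [write_neuron_table()]
#' @export
read_neuron_table <- function(path, model) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  missing <- setdiff(NEURON_COLUMNS, names(df))
  if (length(missing))
    stop("neuron table is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, NEURON_COLUMNS]
  for (col in c("x_um", "y_um", "section_index")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop("non-numeric ", col, " on row(s) ", paste(bad, collapse = ", "),
           ": ", paste(utils::head(v[bad], 3), collapse = ", "))
    }
  }
  df$in_injection_site <- as.logical(df$in_injection_site)
  validate_neurons(df, model)
  df
}

validate_neurons <- function(df, model) {
  valid_struct <- c(names(model$areas), model$subcortical)
  errors <- character(0)
  bad_area <- which(!df$area %in% valid_struct)
  for (i in bad_area)
    errors <- c(errors, sprintf("row %d: unknown area '%s'", i, df$area[i]))
  cortical <- df$area %in% names(model$areas)
  ok_layer <- ifelse(cortical, df$layer %in% layer_names(model),
                     is.na(df$layer) | df$layer %in% c("", "NA", "-"))
  for (i in which(!ok_layer))
    errors <- c(errors, sprintf("row %d: invalid layer '%s'", i, df$layer[i]))
  bad_hemi <- which(!df$hemisphere %in% model$hemispheres)
  for (i in bad_hemi)
    errors <- c(errors,
                sprintf("row %d: unknown hemisphere '%s'", i, df$hemisphere[i]))
  if (any(df$y_um < 0)) {
    i <- which(df$y_um < 0)
    errors <- c(errors, sprintf("row %d: negative depth y_um", i))
  }
  if (any(df$section_index >= model$n_sections)) {
    i <- which(df$section_index >= model$n_sections)
    errors <- c(errors,
                sprintf("row %d: section_index beyond model n_sections", i))
  }
  if (length(errors))
    stop("invalid neuron record(s):\n  ", paste(errors, collapse = "\n  "))
  # depth/layer consistency audit (cortical rows only)
  chk <- which(cortical & !is.na(df$layer) & df$layer != "")
  if (length(chk)) {
    expect <- layer_of_depth(df$y_um[chk], model)
    mism <- chk[!is.na(expect) & expect != df$layer[chk]]
    if (length(mism))
      warning(length(mism), " neuron(s) have a recorded layer inconsistent ",
              "with their depth (rows ",
              paste(utils::head(mism, 10), collapse = ", "),
              if (length(mism) > 10) ", ..." else "", ")")
  }
  invisible(df)
}

#' Write a labeled-neuron table as TSV
#'
#' Numeric coordinates are written with fixed formatting so that repeated
#' writes of the same data are byte-identical.
#'
#' @param neurons Data frame as returned by [read_neuron_table()].
#' @param path Output path.
#' @param header_comment Optional character vector written as leading
#'   `#`-prefixed comment lines (provenance).
#' @return `path`, invisibly.
#' @export
write_neuron_table <- function(neurons, path, header_comment = NULL) {
  df <- neurons[, NEURON_COLUMNS]
  df$x_um <- sprintf("%.3f", df$x_um)
  df$y_um <- sprintf("%.3f", df$y_um)
  df$in_injection_site <- ifelse(df$in_injection_site, "TRUE", "FALSE")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write an injection-site table
#'
#' TSV with header `id, x_um, y_um, section_index, layer, area, volume_mm3,
#' tracer`. Volumes must be positive (they define the sphere-equivalent
#' exclusion radius).
#'
#' @param path Path to a TSV file.
#' @param model A [cortex_model()] used for validation.
#' @return Data frame of injection sites.
#' @export
read_injection_table <- function(path, model) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(INJECTION_COLUMNS, names(df))
  if (length(missing))
    stop("injection table is missing column(s): ",
         paste(missing, collapse = ", "))
  df <- df[, INJECTION_COLUMNS]
  if (any(df$volume_mm3 <= 0)) stop("injection volumes must be positive (mm^3)")
  bad <- which(!df$area %in% c(names(model$areas), model$subcortical))
  if (length(bad))
    stop("unknown injection area on row(s) ", paste(bad, collapse = ", "))
  bad <- which(!df$layer %in% layer_names(model))
  if (length(bad))
    stop("invalid injection layer on row(s) ", paste(bad, collapse = ", "))
  df
}

#' @rdname read_injection_table
#' @param injections Data frame of injection sites.
#' @param header_comment Optional `#`-prefixed provenance lines.
#' @export
write_injection_table <- function(injections, path, header_comment = NULL) {
  df <- injections[, INJECTION_COLUMNS]
  df$x_um <- sprintf("%.3f", df$x_um)
  df$y_um <- sprintf("%.3f", df$y_um)
  df$volume_mm3 <- sprintf("%.6f", df$volume_mm3)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundle one animal's tracing data
#'
#' @param animal_id Identifier, e.g. `"cat1"`.
#' @param model A [cortex_model()].
#' @param neurons Labeled-neuron data frame.
#' @param injections Injection-site data frame.
#' @param sampling_plan Named integer vector of section sampling factors per
#'   structure class; neurons were marked on alternate sections for cortex
#'   and every fourth section for subcortical structures, so the defaults
#'   are `cortex = 2`, `subcortex = 4`.
#' @param border_injection Logical; injection sites at the area 17/18 border.
#' @param exclude_from_fln Logical; faintly labeled animals counted only near
#'   the injection site are kept out of FLN cohort summaries but remain in
#'   laminar-proportion summaries.
#' @return An object of class `animal_dataset`.
#' @export
animal_dataset <- function(animal_id, model, neurons, injections,
                           sampling_plan = c(cortex = 2L, subcortex = 4L),
                           border_injection = FALSE,
                           exclude_from_fln = FALSE) {
  if (any(sampling_plan < 1) || any(sampling_plan != round(sampling_plan)))
    stop("sampling factors must be positive integers")
  structure(list(animal_id = animal_id, model = model, neurons = neurons,
                 injections = injections,
                 sampling_plan = sampling_plan,
                 border_injection = isTRUE(border_injection),
                 exclude_from_fln = isTRUE(exclude_from_fln),
                 total_injection_volume = sum(injections$volume_mm3)),
            class = "animal_dataset")
}

#' @export
print.animal_dataset <- function(x, ...) {
  cat("<animal_dataset> ", x$animal_id, ": ", nrow(x$neurons),
      " labeled somata, ", nrow(x$injections), " injection site(s)",
      if (x$border_injection) " [border injection]" else "", "\n", sep = "")
  invisible(x)
}

#' Sphere-equivalent radius of an injection volume
#'
#' Radius in micrometres of the sphere whose volume equals the measured
#' injection volume: `(3V / 4 pi)^(1/3)`.
#'
#' @param volume_mm3 Volume(s) in cubic millimetres.
#' @return Radius in micrometres.
#' @examples
#' sphere_radius_um(0.524)  # ~ 500 um
#' @export
sphere_radius_um <- function(volume_mm3) {
  if (any(volume_mm3 <= 0)) stop("volume must be positive")
  1000 * (3 * volume_mm3 / (4 * pi))^(1/3)
}

#' Exclude tracer-filled somata inside the injection site
#'
#' Neurons within the tracer deposit are filled by local uptake rather than
#' retrograde transport, so they are removed before computing relative input
#' strengths. In `"flag"` mode the recorded `in_injection_site` flag is
#' authoritative; in `"radius"` mode (the fallback for synthetic data) a
#' neuron is dropped when its 3-D Euclidean distance to any site centre is
#' less than or equal to the site's sphere-equivalent radius.
#'
#' @param neurons Labeled-neuron data frame.
#' @param injections Injection-site data frame (required in radius mode).
#' @param mode `"flag"` or `"radius"`.
#' @param model A [cortex_model()] (for the section-to-z conversion in
#'   radius mode).
#' @return List with elements `kept` (data frame), `n_dropped` (integer).
#' @export
exclude_injection_neurons <- function(neurons, injections = NULL,
                                      mode = c("flag", "radius"),
                                      model = NULL) {
  mode <- match.arg(mode)
  if (mode == "flag") {
    drop <- neurons$in_injection_site %in% TRUE
  } else {
    if (is.null(injections) || nrow(injections) == 0 ||
        is.null(injections$volume_mm3))
      stop("radius mode requires injection sites with measured volumes")
    if (is.null(model)) stop("radius mode requires a cortex_model")
    th <- model$section_thickness
    radii <- sphere_radius_um(injections$volume_mm3)
    drop <- rep(FALSE, nrow(neurons))
    for (j in seq_len(nrow(injections))) {
      d <- sqrt((neurons$x_um - injections$x_um[j])^2 +
                (neurons$y_um - injections$y_um[j])^2 +
                (section_to_z(neurons$section_index, th) -
                 section_to_z(injections$section_index[j], th))^2)
      drop <- drop | d <= radii[j]
    }
  }
  list(kept = neurons[!drop, , drop = FALSE], n_dropped = sum(drop))
}
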