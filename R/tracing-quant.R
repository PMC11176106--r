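#' Sampling-factor correction of a raw neuron count
#'
#' Somata were marked on alternate sections for cortex and on every fourth
#' section for subcortical structures; the counted number is multiplied by
#' the section sampling factor to estimate the total.
#'
#' @param counted_n Non-negative raw count(s).
#' @param factor Positive integer sampling factor(s).
#' @return `counted_n * factor`.
#' @examples
#' apply_sampling_factor(100, 2)  # 200
#' apply_sampling_factor(25, 4)   # 100
#' @export
apply_sampling_factor <- function(counted_n, factor) {
  if (any(counted_n < 0)) stop("counted_n must be >= 0")
  if (any(factor < 1)) stop("sampling factor must be >= 1")
  counted_n * factor
}

structure_class <- function(area, model) {
  ifelse(area %in% model$subcortical, "subcortex", "cortex")
}

#' Tabulate labeled somata into a sampling-corrected count table
#'
#' Aggregates one animal's labeled somata by (hemisphere, area, layer,
#' injection-site membership), attaches the per-structure-class section
#' sampling factor, and computes `corrected_n = counted_n * sampling_factor`.
#'
#' @param dataset An [animal_dataset()].
#' @return A data frame with columns `animal`, `hemisphere`, `area`, `layer`,
#'   `in_injection_site`, `counted_n`, `sampling_factor`, `corrected_n`.
#' @export
count_table <- function(dataset) {
  stopifnot(inherits(dataset, "animal_dataset"))
  nn <- dataset$neurons
  layer <- ifelse(is.na(nn$layer) | nn$layer == "", "-", nn$layer)
  key <- paste(nn$hemisphere, nn$area, layer, nn$in_injection_site, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    animal = dataset$animal_id,
    hemisphere = vapply(parts, `[`, "", 1),
    area = vapply(parts, `[`, "", 2),
    layer = vapply(parts, `[`, "", 3),
    in_injection_site = vapply(parts, `[`, "", 4) == "TRUE",
    counted_n = as.integer(tab),
    stringsAsFactors = FALSE)
  cls <- structure_class(out$area, dataset$model)
  out$sampling_factor <- as.integer(dataset$sampling_plan[cls])
  out$corrected_n <- apply_sampling_factor(out$counted_n, out$sampling_factor)
  rownames(out) <- NULL
  out[order(out$hemisphere, out$area, out$layer), , drop = FALSE]
}

#' Pool count tables across a cohort of animals
#' @param datasets List of [animal_dataset()] objects.
#' @return Row-bound count table for the cohort.
#' @export
cohort_counts <- function(datasets) {
  do.call(rbind, lapply(datasets, count_table))
}

#' Fraction of labeled neurons (FLN)
#'
#' The FLN of a group (an area, or an area-layer combination) is the number
#' of labeled neurons in that group divided by the total number of labeled
#' neurons, computed per animal on sampling-corrected counts and — by
#' default — after excluding tracer-filled somata inside the injection site.
#'
#' @param counts Count table (see [count_table()]); may cover several animals.
#' @param by Grouping: `"area"` or `c("area", "layer")`. `hemisphere` is
#'   always part of the key so that ipsilateral and contralateral inputs are
#'   kept separate.
#' @param exclude_injection Drop rows flagged `in_injection_site` from both
#'   numerator and denominator (default `TRUE`).
#' @return An object of class `fln_table`: a data frame with one row per
#'   (animal, hemisphere, group), columns `fraction` and `corrected_n`, plus
#'   a `denominators` attribute (total corrected count per animal). Fractions
#'   sum to 1 over the full partition for every animal.
#' @examples
#' # counts 8000 / 1500 / 500 in three structures give FLN 0.80 / 0.15 / 0.05
#' @export
fln <- function(counts, by = "area", exclude_injection = TRUE) {
  by <- match.arg(paste(by, collapse = "_"),
                  c("area", "area_layer"))
  if (exclude_injection && "in_injection_site" %in% names(counts))
    counts <- counts[!counts$in_injection_site, , drop = FALSE]
  if (nrow(counts) == 0 || sum(counts$corrected_n) == 0)
    stop("no labeled neurons outside injection sites: FLN denominator is zero")
  keyvars <- if (by == "area") c("hemisphere", "area") else
    c("hemisphere", "area", "layer")
  agg <- stats::aggregate(counts["corrected_n"],
                          by = c(counts["animal"], counts[keyvars]),
                          FUN = sum)
  # complete the partition: a group labeled in any animal contributes a
  # zero fraction to animals where it received no label
  groups <- unique(agg[keyvars])
  full <- merge(data.frame(animal = unique(agg$animal)), groups)
  agg <- merge(full, agg, by = c("animal", keyvars), all.x = TRUE)
  agg$corrected_n[is.na(agg$corrected_n)] <- 0
  den <- tapply(agg$corrected_n, agg$animal, sum)
  if (any(den == 0)) stop("zero FLN denominator for animal(s): ",
                          paste(names(den)[den == 0], collapse = ", "))
  agg$fraction <- agg$corrected_n / as.numeric(den[agg$animal])
  agg <- agg[order(agg$animal, agg$hemisphere, agg$area), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, class = c("fln_table", "data.frame"),
            by = by, denominators = den)
}

#' @export
print.fln_table <- function(x, digits = 3, ...) {
  cat("FLN (", attr(x, "by"), "), ",
      length(attr(x, "denominators")), " animal(s)\n", sep = "")
  y <- as.data.frame(x)
  y$fraction <- round(y$fraction, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Per-layer proportions of labeled neurons within one area
#'
#' @param counts Count table covering one or more animals.
#' @param area Area name.
#' @param hemisphere Hemisphere to restrict to (default `"ipsi"`).
#' @param exclude_injection Drop injection-site somata first (default TRUE).
#' @return Data frame with one row per (animal, layer) and column `fraction`;
#'   per animal the fractions over L1..L6 sum to 1.
#' @export
laminar_proportions <- function(counts, area, hemisphere = "ipsi",
                                exclude_injection = TRUE) {
  if (exclude_injection && "in_injection_site" %in% names(counts))
    counts <- counts[!counts$in_injection_site, , drop = FALSE]
  sel <- counts$area == area & counts$hemisphere == hemisphere
  if (!any(sel)) stop("no labeled neurons in area '", area, "' (",
                      hemisphere, ")")
  counts <- counts[sel, , drop = FALSE]
  agg <- stats::aggregate(counts["corrected_n"],
                          by = counts[c("animal", "layer")], FUN = sum)
  # every layer appears for every animal: unlabeled layers count as zero
  full <- expand.grid(animal = unique(agg$animal),
                      layer = c("L1", "L2", "L3", "L4", "L5", "L6"),
                      stringsAsFactors = FALSE)
  agg <- merge(full, agg, by = c("animal", "layer"), all.x = TRUE)
  agg$corrected_n[is.na(agg$corrected_n)] <- 0
  den <- tapply(agg$corrected_n, agg$animal, sum)
  agg$fraction <- agg$corrected_n / as.numeric(den[agg$animal])
  agg <- agg[order(agg$animal, agg$layer), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Cohort summary of per-animal values
#'
#' Mean and sample standard deviation (n - 1 denominator) of per-animal
#' values over a subset of the cohort, matching the "mean +/- SD (N = k)"
#' reporting convention. SD is reported only when at least two animals enter
#' the summary.
#'
#' @param values Named numeric vector (names are animal ids) or data frame
#'   with columns `animal` and `value`.
#' @param subset Optional character vector of animal ids, or a logical/
#'   predicate function applied to `metadata` rows, selecting the animals to
#'   summarize. `NULL` keeps all.
#' @param metadata Optional data frame with one row per animal (column
#'   `animal` plus flags such as `border_injection`, `exclude_from_fln`,
#'   `total_injection_volume`, `tracer`) used when `subset` is a function.
#' @param label Description of the subset, carried into the summary.
#' @return An object of class `cohort_summary` with fields `mean`, `sd`,
#'   `n`, `label`, `values`.
#' @examples
#' summarize_across_animals(c(a = 0.6, b = 0.8, c = 1.0))  # 0.8 +/- 0.2
#' @export
summarize_across_animals <- function(values, subset = NULL, metadata = NULL,
                                     label = "all animals") {
  if (is.data.frame(values)) {
    v <- values$value
    names(v) <- values$animal
    values <- v
  }
  if (is.null(names(values)))
    names(values) <- paste0("animal", seq_along(values))
  keep <- names(values)
  if (is.function(subset)) {
    if (is.null(metadata)) stop("predicate subset requires metadata")
    sel <- subset(metadata)
    keep <- metadata$animal[sel]
  } else if (is.character(subset)) {
    keep <- subset
  } else if (is.logical(subset)) {
    keep <- names(values)[subset]
  }
  v <- values[names(values) %in% keep]
  if (length(v) == 0) stop("animal subset is empty")
  structure(list(mean = mean(v),
                 sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
                 n = length(v), label = label, values = v),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat(format(signif(x$mean, digits)),
      if (!is.na(x$sd)) paste0(" +/- ", format(signif(x$sd, digits))) else "",
      " (N = ", x$n, ", ", x$label, ")\n", sep = "")
  invisible(x)
}

#' Collapse a laminar profile into supra-, granular and infragranular thirds
#'
#' Supragranular = L1 + L2 + L3, granular = L4, infragranular = L5 + L6; the
#' triple sums to whatever the input layers sum to (1 for a full profile).
#'
#' @param fractions Named numeric vector with names among L1..L6.
#' @return Named numeric vector `c(supragranular, granular, infragranular)`.
#' @examples
#' supra_infra_split(c(L3 = 0.5, L4 = 0.3, L5 = 0.2))
#' @export
supra_infra_split <- function(fractions) {
  bad <- setdiff(names(fractions), c("L1", "L2", "L3", "L4", "L5", "L6"))
  if (length(bad)) stop("unknown layer name(s): ", paste(bad, collapse = ", "))
  g <- function(l) sum(fractions[names(fractions) %in% l])
  c(supragranular = g(c("L1", "L2", "L3")),
    granular = g("L4"),
    infragranular = g(c("L5", "L6")))
}
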