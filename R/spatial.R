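#' 3-D distance of each labeled soma to its nearest injection-site centre
#'
#' Distances are Euclidean in the straightened (x, y, z) frame, with z
#' obtained from the serial-section index ([section_to_z()]). The Euclidean
#' distance is not the length of the axon the tracer travelled; it measures
#' the physical spread of labeled somata. Ties between equidistant sites are
#' broken deterministically in favour of the lexicographically lowest
#' injection id.
#'
#' @param neurons Labeled-neuron data frame.
#' @param injections Injection-site data frame (at least one site).
#' @param model A [cortex_model()].
#' @return Data frame with columns `id`, `nearest_injection`, `distance_um`,
#'   `area`, `layer` (one row per neuron, input order preserved).
#' @examples
#' # a soma at (3, 4) in the same section as a site at the origin is 5 um away
#' @export
min_distance_to_injection <- function(neurons, injections, model) {
  if (is.null(injections) || nrow(injections) == 0)
    stop("at least one injection site is required")
  injections <- injections[order(injections$id), , drop = FALSE]
  th <- model$section_thickness
  nz <- section_to_z(neurons$section_index, th)
  d <- matrix(NA_real_, nrow(neurons), nrow(injections))
  for (j in seq_len(nrow(injections))) {
    d[, j] <- sqrt((neurons$x_um - injections$x_um[j])^2 +
                   (neurons$y_um - injections$y_um[j])^2 +
                   (nz - section_to_z(injections$section_index[j], th))^2)
  }
  best <- max.col(-d, ties.method = "first")
  data.frame(id = neurons$id,
             nearest_injection = injections$id[best],
             distance_um = d[cbind(seq_len(nrow(neurons)), best)],
             area = neurons$area,
             layer = neurons$layer,
             stringsAsFactors = FALSE)
}

#' The k most distant labeled neurons within an area
#'
#' Used to ask which layers hold the somata furthest from the injection
#' sites (e.g. the 30 most distant area 17 neurons per animal).
#'
#' @param records Distance records from [min_distance_to_injection()].
#' @param area Area to restrict to (`NULL` keeps all records).
#' @param k Number of records to return (default 30); if fewer exist, all
#'   are returned.
#' @return Records sorted by decreasing distance, at most `k` rows.
#' @export
top_k_distant <- function(records, area = NULL, k = 30) {
  if (k < 1) stop("k must be >= 1")
  if (!is.null(area)) records <- records[records$area == area, , drop = FALSE]
  records <- records[order(-records$distance_um), , drop = FALSE]
  utils::head(records, k)
}

#' Cohort summary of per-animal maximum distances
#'
#' For each animal the maximum soma-to-nearest-injection distance within the
#' area is taken; the cohort mean and sample SD of those maxima are returned.
#'
#' @param records_by_animal Distance records with an `animal` column, or a
#'   named list of per-animal record data frames.
#' @param area Area to restrict to (`NULL` keeps all).
#' @return A [summarize_across_animals()] `cohort_summary` of per-animal
#'   maxima (micrometres).
#' @export
max_distance_summary <- function(records_by_animal, area = NULL) {
  if (is.data.frame(records_by_animal)) {
    split_rec <- split(records_by_animal, records_by_animal$animal)
  } else split_rec <- records_by_animal
  maxima <- vapply(split_rec, function(r) {
    if (!is.null(area)) r <- r[r$area == area, , drop = FALSE]
    if (nrow(r) == 0) NA_real_ else max(r$distance_um)
  }, numeric(1))
  maxima <- maxima[!is.na(maxima)]
  if (length(maxima) == 0) stop("no distance records in area '", area, "'")
  summarize_across_animals(maxima,
                           label = paste0("max distance",
                                          if (!is.null(area))
                                            paste0(", ", area) else ""))
}

#' Detect periodic lateral clusters of labeled somata
#'
#' Labeled neurons lateral to the local column concentrate at the layer 3/4
#' border and, in the clearest cases, group into clusters 400-800 um wide
#' with centres 400-800 um apart. Somata within a depth band (by default the
#' lower-L3/upper-L4 band of the model) are projected onto the tangential
#' axis; a Gaussian kernel density estimate is computed and local maxima
#' whose topographic prominence exceeds a threshold become clusters. Cluster
#' width is the full width at half prominence (measured within the peak's
#' own basin) and spacings are the differences between successive centres.
#'
#' Prominence is measured locally — the drop from the peak to the shallower
#' adjacent density minimum — so the summit of one broad unclustered mode
#' has only noise-scale prominence. A peak qualifies when its prominence is
#' at least a quarter of its height, its height is at least 15% of the
#' density maximum (rejecting isolated far-tail bumps), and its width does
#' not exceed `max_width`. Uniform scatter therefore yields zero clusters.
#'
#' @param neurons Labeled-neuron data frame.
#' @param model A [cortex_model()].
#' @param depth_band Length-2 numeric, depth interval in um (default: lower
#'   half of L3 through the upper third of L4).
#' @param bandwidth Gaussian kernel bandwidth in um (default 150).
#' @param min_prominence Absolute minimum peak prominence in density units;
#'   `NULL` (default) uses the relative rule prominence >= height / 4.
#' @param max_width Maximum credible cluster width in um (default 1500,
#'   roughly twice the widest cluster reported).
#' @return Object of class `cluster_set`: list with `clusters` (data frame
#'   `center_um`, `width_um`, `prominence`), `spacing_um`, `depth_band`,
#'   `bandwidth`, `n_somata`. Empty band gives an empty cluster set.
#' @export
detect_border_clusters <- function(neurons, model, depth_band = NULL,
                                   bandwidth = 150, min_prominence = NULL,
                                   max_width = 1500) {
  if (is.null(depth_band)) {
    ly <- model$layers
    l3 <- ly[ly$layer == "L3", ]
    l4 <- ly[ly$layer == "L4", ]
    depth_band <- c((l3$top_um + l3$bottom_um) / 2,
                    l4$top_um + (l4$bottom_um - l4$top_um) / 3)
  }
  x <- neurons$x_um[neurons$y_um >= depth_band[1] &
                    neurons$y_um < depth_band[2]]
  empty <- structure(list(clusters = data.frame(center_um = numeric(0),
                                                width_um = numeric(0),
                                                prominence = numeric(0),
                                                height = numeric(0)),
                          spacing_um = numeric(0), depth_band = depth_band,
                          bandwidth = bandwidth, n_somata = length(x)),
                     class = "cluster_set")
  if (length(x) < 2) return(empty)
  den <- stats::density(x, bw = bandwidth, n = 1024, cut = 3)
  pk <- find_peaks(den$x, den$y)
  keep <- if (is.null(min_prominence)) pk$prominence >= pk$height / 4 else
    pk$prominence >= min_prominence
  keep <- keep & pk$width_um <= max_width & pk$height >= 0.15 * max(den$y)
  pk <- pk[keep, , drop = FALSE]
  if (nrow(pk) == 0) return(empty)
  pk <- pk[order(pk$center_um), , drop = FALSE]
  rownames(pk) <- NULL
  structure(list(clusters = pk,
                 spacing_um = diff(pk$center_um),
                 depth_band = depth_band, bandwidth = bandwidth,
                 n_somata = length(x)),
            class = "cluster_set")
}

# Local maxima of a sampled curve. Prominence here is local: the drop from
# the peak to the SHALLOWER of the two adjacent local minima (grid ends
# count as minima). A summit rising only marginally above its surroundings
# — the top of a broad unclustered mode, or a noise ripple — thus gets a
# small prominence even if it is the global maximum, while peaks separated
# by real inter-cluster dips keep a large one. Width is the full width at
# half prominence, scanned no further than the adjacent minima.
find_peaks <- function(x, y) {
  n <- length(y)
  is_max <- which(diff(sign(diff(y))) == -2) + 1
  is_min <- which(diff(sign(diff(y))) == 2) + 1
  if (!length(is_max))
    return(data.frame(center_um = numeric(0), width_um = numeric(0),
                      prominence = numeric(0), height = numeric(0)))
  out <- lapply(is_max, function(i) {
    h <- y[i]
    lmins <- is_min[is_min < i]
    lb <- if (length(lmins)) max(lmins) else 1L
    rmins <- is_min[is_min > i]
    rb <- if (length(rmins)) min(rmins) else n
    prom <- h - max(y[lb], y[rb])
    half <- h - prom / 2
    li <- i
    while (li > lb && y[li - 1] >= half) li <- li - 1
    ri <- i
    while (ri < rb && y[ri + 1] >= half) ri <- ri + 1
    data.frame(center_um = x[i], width_um = x[ri] - x[li],
               prominence = prom, height = h)
  })
  do.call(rbind, out)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set> ", nrow(x$clusters), " cluster(s) from ", x$n_somata,
      " somata in depth band [", x$depth_band[1], ", ", x$depth_band[2],
      ") um, bandwidth ", x$bandwidth, " um\n", sep = "")
  if (nrow(x$clusters)) {
    print(transform(x$clusters, center_um = round(center_um),
                    width_um = round(width_um),
                    prominence = signif(prominence, 3)), row.names = FALSE)
    if (length(x$spacing_um))
      cat("centre spacing (um):", paste(round(x$spacing_um), collapse = ", "),
          "\n")
  }
  invisible(x)
}
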