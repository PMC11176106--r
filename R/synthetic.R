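#' Configuration for the synthetic tracing-data generator
#'
#' The generator emulates the statistical structure of a layer-6 retrograde
#' tracing study in cat visual cortex: ~10 animals with 1-5 deep injection
#' sites, a few hundred to a few ten-thousand labeled somata per animal
#' dominated by the local area (weight ~0.81), a laminar profile of the
#' local label peaking in layer 3, periodic lateral clusters at the layer
#' 3/4 border (width 400-800 um, thickness 150-250 um, centre spacing
#' 400-800 um), 80 um serial sections, and alternate (cortex) or
#' every-fourth (subcortex) section sampling.
#'
#' @param seed Integer seed; together with the config it fully determines
#'   the dataset.
#' @param n_animals Number of animals (default 10).
#' @param n_neurons_range Range of sampling-corrected labeled-soma totals
#'   per animal (default 300 to 30000).
#' @param area_weights Data frame `area`, `hemisphere`, `weight`; weights
#'   must sum to 1 (tolerance 1e-9).
#' @param laminar_profiles Named list (by area) of named layer-fraction
#'   vectors for cortical areas.
#' @param cluster List with `width_range`, `thickness_range`,
#'   `spacing_range` (um) and `fraction`, the probability that a lateral
#'   L3/L4 soma of the local area belongs to a cluster rather than the
#'   diffuse background. The cluster fraction is a free parameter of the
#'   emulation (the anatomy is described only qualitatively); default 0.5.
#' @param injection List with `n_range` (sites per animal), `layer`,
#'   `volume_mm3` per site.
#' @param model A [cortex_model()].
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_animals = 10L,
                             n_neurons_range = c(300, 30000),
                             area_weights = default_area_weights(),
                             laminar_profiles = default_laminar_profiles(),
                             cluster = list(width_range = c(400, 800),
                                            thickness_range = c(150, 250),
                                            spacing_range = c(400, 800),
                                            fraction = 0.5),
                             injection = list(n_range = c(1L, 5L),
                                              layer = "L6",
                                              volume_mm3 = 0.19),
                             model = cortex_model()) {
  if (abs(sum(area_weights$weight) - 1) > 1e-9)
    stop("area weights must sum to 1")
  if (any(area_weights$weight < 0)) stop("area weights must be non-negative")
  stopifnot(all(n_neurons_range > 0), cluster$fraction >= 0,
            cluster$fraction <= 1)
  structure(list(seed = as.integer(seed), n_animals = as.integer(n_animals),
                 n_neurons_range = n_neurons_range,
                 area_weights = area_weights,
                 laminar_profiles = laminar_profiles,
                 cluster = cluster, injection = injection, model = model),
            class = "generator_config")
}

default_area_weights <- function() {
  data.frame(area = c("A17", "A18", "A19", "A17", "LGN"),
             hemisphere = c("ipsi", "ipsi", "ipsi", "contra", "ipsi"),
             weight = c(0.81, 0.12, 0.022, 0.02, 0.028),
             stringsAsFactors = FALSE)
}

default_laminar_profiles <- function() {
  list(A17 = c(L2 = 0.08, L3 = 0.41, L4 = 0.15, L5 = 0.08, L6 = 0.28),
       A18 = c(L2 = 0.06, L3 = 0.33, L4 = 0.37, L5 = 0.08, L6 = 0.16),
       A19 = c(L2 = 0.10, L3 = 0.30, L4 = 0.25, L5 = 0.15, L6 = 0.20),
       A17_contra = c(L2 = 0.15, L3 = 0.66, L4 = 0.17, L5 = 0.01, L6 = 0.01))
}

# Deterministic per-animal, per-stage seed so that the draws of one stage
# never depend on how many values another stage consumed.
substream_seed <- function(seed, animal_idx, stage) {
  offsets <- c(design = 1L, injections = 2L, structures = 3L, somata = 4L)
  (abs(seed) * 7919 + animal_idx * 104729 + offsets[[stage]] * 512927) %%
    2147483647L
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Generate a synthetic cohort of tracing datasets with known ground truth
#'
#' Per animal, structure totals are drawn from a multinomial over the
#' configured (area, hemisphere) weights at the corrected-total scale; the
#' emitted somata are the counted ones, obtained by deterministic
#' (systematic) section subsampling — counted = round(total / factor) with
#' section indices on the sampling grid — so that
#' `corrected = counted * factor` recovers the drawn totals up to rounding.
#' Within the local area, a configured fraction of L3/L4 somata is placed in
#' Gaussian clusters at periodic tangential centres around the injection
#' column; everything else is diffuse. Somata falling within the
#' sphere-equivalent radius of an injection site are flagged
#' `in_injection_site`.
#'
#' @param config A [generator_config()].
#' @return List with `animals` (list of [animal_dataset()]) and `truth`
#'   (per-animal realized totals, weights, cluster geometry), reproducible
#'   bit-identically from the config.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  model <- config$model
  w <- config$area_weights
  skey <- paste(w$area, w$hemisphere, sep = ":")
  cls <- structure_class(w$area, model)
  factors <- c(cortex = 2L, subcortex = 4L)
  animals <- vector("list", config$n_animals)
  truth <- vector("list", config$n_animals)
  a17 <- model$areas$A17
  for (ai in seq_len(config$n_animals)) {
    id <- sprintf("animal%02d", ai)
    set.seed(substream_seed(config$seed, ai, "design"))
    n_total <- round(runif1(config$n_neurons_range))
    n_inj <- if (diff(config$injection$n_range) == 0)
      config$injection$n_range[1] else
      sample(seq(config$injection$n_range[1], config$injection$n_range[2]), 1)
    spacing <- runif1(config$cluster$spacing_range)
    width <- runif1(config$cluster$width_range)
    thickness <- runif1(config$cluster$thickness_range)

    set.seed(substream_seed(config$seed, ai, "injections"))
    l6 <- model$layers[model$layers$layer == config$injection$layer, ]
    inj_x <- mean(a17) + stats::rnorm(n_inj, 0, 200)
    inj_sec <- pmin(pmax(round(model$n_sections / 2 +
                               seq_len(n_inj) - (n_inj + 1) / 2), 0),
                    model$n_sections - 1)
    injections <- data.frame(
      id = sprintf("%s_inj%d", id, seq_len(n_inj)),
      x_um = inj_x,
      y_um = stats::runif(n_inj, l6$top_um + 50, l6$bottom_um - 50),
      section_index = inj_sec,
      layer = config$injection$layer, area = "A17",
      volume_mm3 = config$injection$volume_mm3,
      tracer = "HRP", stringsAsFactors = FALSE)

    set.seed(substream_seed(config$seed, ai, "structures"))
    m <- as.integer(stats::rmultinom(1, n_total, w$weight))
    counted <- round(m / factors[cls])

    border <- model$layers$bottom_um[model$layers$layer == "L3"]
    centers <- sort(mean(inj_x) + spacing * setdiff(-4:4, 0) +
                    stats::rnorm(8, 0, spacing / 10))
    centers <- centers[centers > a17[1] & centers < a17[2]]

    set.seed(substream_seed(config$seed, ai, "somata"))
    rows <- vector("list", length(skey))
    for (si in seq_along(skey)) {
      nk <- counted[si]
      if (nk == 0) next
      area <- w$area[si]; hemi <- w$hemisphere[si]
      fac <- factors[cls[si]]
      sec <- fac * (sample.int(model$n_sections %/% fac, nk,
                               replace = TRUE) - 1L)
      if (cls[si] == "subcortex") {
        rows[[si]] <- data.frame(
          x_um = stats::runif(nk, 0, 2000),
          y_um = stats::runif(nk, 0, 1000),
          section_index = sec, area = area, hemisphere = hemi,
          layer = "-", stringsAsFactors = FALSE)
        next
      }
      pkey <- if (hemi == "contra") paste0(area, "_contra") else area
      prof <- config$laminar_profiles[[pkey]]
      if (is.null(prof)) prof <- config$laminar_profiles[[area]]
      layer <- sample(names(prof), nk, replace = TRUE, prob = prof)
      bands <- model$layers[match(layer, model$layers$layer), ]
      y <- stats::runif(nk, bands$top_um, bands$bottom_um)
      iv <- model$areas[[area]]
      x <- stats::runif(nk, iv[1], iv[2])
      if (area == "A17" && hemi == "ipsi") {
        # local label: column over the injection plus lateral L3/L4 band
        x <- pmin(pmax(mean(inj_x) + stats::rnorm(nk, 0, 1500), iv[1] + 1),
                  iv[2] - 1)
        lat <- layer %in% c("L3", "L4") &
          stats::runif(nk) < config$cluster$fraction & length(centers) > 0
        if (any(lat)) {
          ctr <- sample(centers, sum(lat), replace = TRUE)
          x[lat] <- ctr + stats::rnorm(sum(lat), 0, width / 4)
          y[lat] <- stats::runif(sum(lat), border - thickness / 2,
                                 border + thickness / 2)
          layer[lat] <- layer_of_depth(y[lat], model)
        }
      }
      rows[[si]] <- data.frame(x_um = x, y_um = y, section_index = sec,
                               area = area, hemisphere = hemi, layer = layer,
                               stringsAsFactors = FALSE)
    }
    nn <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    nn$id <- sprintf("%s_n%06d", id, seq_len(nrow(nn)))
    nn$tracer <- "HRP"
    radius <- sphere_radius_um(config$injection$volume_mm3)
    th <- model$section_thickness
    flag <- rep(FALSE, nrow(nn))
    for (j in seq_len(n_inj)) {
      d <- sqrt((nn$x_um - injections$x_um[j])^2 +
                (nn$y_um - injections$y_um[j])^2 +
                (section_to_z(nn$section_index, th) -
                 section_to_z(injections$section_index[j], th))^2)
      flag <- flag | d <= radius
    }
    nn$in_injection_site <- flag
    nn <- nn[, NEURON_COLUMNS]
    animals[[ai]] <- animal_dataset(id, model, nn, injections)
    truth[[ai]] <- list(animal = id, n_total = n_total,
                        weights = stats::setNames(w$weight, skey),
                        drawn_totals = stats::setNames(m, skey),
                        counted = stats::setNames(counted, skey),
                        cluster_centers = centers, spacing_um = spacing,
                        width_um = width, thickness_um = thickness,
                        n_injections = n_inj)
  }
  names(animals) <- names(truth) <- vapply(truth, `[[`, "", "animal")
  list(animals = animals, truth = truth)
}

#' Write a generated cohort to disk
#'
#' Emits per animal a neuron TSV and an injection TSV, plus one `truth.yaml`
#' with the ground-truth record; identical (config, seed) produce
#' byte-identical files.
#'
#' @param cohort Result of [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @param seed Seed recorded in the file headers.
#' @return Character vector of written paths, invisibly.
#' @export
write_dataset <- function(cohort, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (a in cohort$animals) {
    hdr <- sprintf("corticount synthetic dataset; animal=%s; seed=%s",
                   a$animal_id, seed)
    np <- file.path(dir, paste0(a$animal_id, "_neurons.tsv"))
    ip <- file.path(dir, paste0(a$animal_id, "_injections.tsv"))
    write_neuron_table(a$neurons, np, header_comment = hdr)
    write_injection_table(a$injections, ip, header_comment = hdr)
    paths <- c(paths, np, ip)
  }
  tp <- file.path(dir, "truth.yaml")
  yaml::write_yaml(lapply(cohort$truth, function(t) {
    t$weights <- as.list(t$weights)
    t$drawn_totals <- as.list(t$drawn_totals)
    t$counted <- as.list(t$counted)
    t
  }), tp)
  invisible(c(paths, tp))
}

#' Shift generator area weights for sensitivity sweeps
#'
#' @param config A [generator_config()].
#' @param deltas Named numeric vector of weight shifts, names matching
#'   `"area:hemisphere"` keys of the config's weight table; must sum to 0
#'   and keep every weight in `[0, 1]`.
#' @return A new config with shifted weights.
#' @export
perturb_truth <- function(config, deltas) {
  stopifnot(inherits(config, "generator_config"))
  w <- config$area_weights
  key <- paste(w$area, w$hemisphere, sep = ":")
  unknown <- setdiff(names(deltas), key)
  if (length(unknown))
    stop("unknown weight key(s): ", paste(unknown, collapse = ", "))
  if (abs(sum(deltas)) > 1e-12)
    stop("deltas must sum to 0 to stay on the simplex")
  w$weight <- w$weight + ifelse(key %in% names(deltas),
                                deltas[match(key, names(deltas))], 0)
  if (any(w$weight < 0) || any(w$weight > 1))
    stop("perturbed weights leave the simplex")
  config$area_weights <- w
  config
}

#' Baseline cell-type table and budget for the layer-6 accounting
#'
#' Reconstructs the baseline layer-6 budget from the printed numbers alone:
#' the assigned 30% of the layer total splits 57/20/11/10 across origins in
#' L6/L5/L4/L2-3. Those rounded percentages sum to 98; the remaining 2% of
#' the assigned synapses is the X/Y thalamocortical contribution, carried as
#' one aggregate afferent row so the assigned fraction is exactly 30%.
#' Superficial origins use the printed populations (8.25e6 spiny L2/3
#' cells, 8.74e6 spiny L4 cells) with per-cell counts derived as
#' `share * 0.3 * T / N`; deep origins use the printed per-cell counts
#' (p6(L5/6) 2378, p5(L5/6) 3109) with populations derived the same way.
#' By construction the resulting budget has exactly 70% unassigned and the
#' printed assigned split.
#'
#' @return List with `cell_types` (data frame ready for
#'   [write_cell_type_table()]), `total` (the reconstructed layer-6 total),
#'   and `budget` (a [layer_budget()]).
#' @examples
#' fx <- generate_budget_fixture()
#' unassigned_fraction(fx$budget)  # 0.70
#' @export
generate_budget_fixture <- function() {
  k <- budget_constants()
  Tl <- k$total_L6
  assigned_S <- k$assigned_split * k$assigned_fraction * Tl
  s_L23 <- assigned_S[["L2/3"]] / k$n_spiny_L23
  s_L4 <- assigned_S[["L4"]] / k$n_spiny_L4
  n_L5 <- assigned_S[["L5"]] / k$syn_per_cell[["p5(L5/6)"]]
  n_L6 <- assigned_S[["L6"]] / k$syn_per_cell[["p6(L5/6)"]]
  S_thal <- (1 - sum(k$assigned_split)) * k$assigned_fraction * Tl
  ct <- data.frame(
    name = c("L2/3 origin (p2/3)", "L4 origin (spiny L4)",
             "L5 origin (p5(L5/6))", "L6 origin (p6(L5/6))",
             "thalamocortical X/Y (aggregate)"),
    soma_layer = c("L2/3", "L4", "L5", "L6", "thalamus"),
    population = c(k$n_spiny_L23, k$n_spiny_L4, n_L5, n_L6, 1),
    syn_L6 = c(s_L23, s_L4, k$syn_per_cell[["p5(L5/6)"]],
               k$syn_per_cell[["p6(L5/6)"]], S_thal),
    stringsAsFactors = FALSE)
  list(cell_types = ct, total = Tl,
       budget = layer_budget(ct, "L6", Tl))
}

#' @rdname generate_budget_fixture
#' @export
baseline_budget <- function() generate_budget_fixture()$budget
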