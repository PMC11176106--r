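#' Printed constants of the layer-6 synaptic-budget analysis
#'
#' Every number used by the budget revision of the quantitative cat-V1
#' circuit diagram, with the total asymmetric-synapse count of layer 6
#' reconstructed from two printed quantities: the layer-2/3 pyramidal
#' population contributes 6.41e8 synapses to layer 6, and those synapses are
#' 10% of the 30% of layer-6 asymmetric synapses that the diagram assigns,
#' hence `T_L6 = 6.41e8 / (0.10 * 0.30) ~= 2.137e10`.
#'
#' @return Named list of constants:
#' \describe{
#'   \item{surface_area_mm2}{Total surface area of cat area 17 (399).}
#'   \item{section_thickness_um}{80.}
#'   \item{n_spiny_L23, n_spiny_L4}{Spiny neurons in layers 2/3 and 4
#'     (8.25e6, 8.74e6).}
#'   \item{syn_per_cell}{Per-cell synapses formed in layer 6 by the diagram's
#'     types: p2/3 78; mean of the three spiny layer-4 types 85; p5(L5/6)
#'     3109; p6(L5/6) 2378.}
#'   \item{p23_L6_synapses}{Printed population total for p2/3 in layer 6
#'     (6.41e8; the product 78 x 8.25e6 = 6.435e8 differs in the last digit
#'     because the printed per-cell count is rounded).}
#'   \item{assigned_fraction}{0.30 of layer-6 asymmetric synapses assigned.}
#'   \item{assigned_split}{Laminar origin of the assigned synapses:
#'     L6 0.57, L5 0.20, L4 0.11, L2/3 0.10.}
#'   \item{total_L6}{Reconstructed total asymmetric synapses in layer 6.}
#'   \item{local_fln}{Fraction of the layer-6 projection arising within
#'     area 17 (0.811).}
#' }
#' @export
budget_constants <- function() {
  assigned <- 0.30
  split <- c(L6 = 0.57, L5 = 0.20, L4 = 0.11, `L2/3` = 0.10)
  p23 <- 6.41e8
  list(surface_area_mm2 = 399,
       section_thickness_um = 80,
       n_spiny_L23 = 8.25e6,
       n_spiny_L4 = 8.74e6,
       syn_per_cell = c(`p2/3` = 78, `spiny L4 (mean)` = 85,
                        `p5(L5/6)` = 3109, `p6(L5/6)` = 2378),
       p23_L6_synapses = p23,
       assigned_fraction = assigned,
       assigned_split = split,
       total_L6 = infer_total_from_share(p23, split[["L2/3"]] * assigned),
       local_fln = 0.811)
}

#' Neurons under the full area from a surface density
#'
#' `N = density * area * proportion`: the count of cells under one square
#' millimetre of cortical surface is scaled by the total surface area and by
#' the proportion belonging to the cell type of interest.
#'
#' @param density Neurons per mm^2 of cortical surface.
#' @param area_mm2 Surface area in mm^2 (399 for cat area 17).
#' @param proportion Fraction of those neurons in the type (in `[0, 1]`).
#' @return Population size.
#' @export
population_from_density <- function(density, area_mm2, proportion = 1) {
  if (any(density < 0) || any(area_mm2 < 0) || any(proportion < 0))
    stop("inputs must be non-negative")
  if (any(proportion > 1)) stop("proportion must be <= 1")
  density * area_mm2 * proportion
}

#' Cell-type tables
#'
#' A cell-type table holds one row per excitatory neuron class: `name`,
#' `soma_layer`, `population`, and one `syn_L*` column per target layer with
#' the mean number of synapses a single cell of the type forms in that
#' layer. Stored as TSV with that fixed header.
#'
#' @param path File path.
#' @return `read_cell_type_table()`: data frame; `write_cell_type_table()`:
#'   `path` invisibly.
#' @export
read_cell_type_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("name", "soma_layer", "population")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("cell-type table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(df$population < 0)) stop("populations must be >= 0")
  syn <- grep("^syn_L", names(df), value = TRUE)
  if (!length(syn)) stop("cell-type table has no syn_L* column")
  if (any(as.matrix(df[syn]) < 0)) stop("per-cell synapse counts must be >= 0")
  df
}

#' @rdname read_cell_type_table
#' @param cell_types Cell-type data frame.
#' @param header_comment Optional `#`-prefixed provenance lines.
#' @export
write_cell_type_table <- function(cell_types, path, header_comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(cell_types, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Population synapse total of a cell type in a target layer
#'
#' `S(t, l) = N_t * s(t, l)`; a layer absent from the type's per-cell
#' synapse columns contributes zero.
#'
#' @param cell_types Cell-type data frame (see [read_cell_type_table()]).
#' @param target_layer Layer name, e.g. `"L6"`.
#' @return Named numeric vector of population synapse totals per type.
#' @examples
#' # 8.25e6 p2/3 cells at 78 synapses each: 6.435e8 synapses in layer 6
#' @export
population_synapses <- function(cell_types, target_layer) {
  col <- paste0("syn_", target_layer)
  s <- if (col %in% names(cell_types)) cell_types[[col]] else
    rep(0, nrow(cell_types))
  stats::setNames(cell_types$population * s, cell_types$name)
}

#' Reconstruct a layer's total synapse count from one population's share
#'
#' If a population's `S` synapses are a known fraction of the layer total,
#' the total is `T = S / share`. Used to rebuild the layer-6 total from the
#' printed p2/3 contribution (6.41e8) and its printed share (10% of the 30%
#' assigned).
#'
#' @param S Population synapse count.
#' @param share Fraction of the layer total in `(0, 1]`.
#' @return The implied total `T`.
#' @examples
#' infer_total_from_share(6.41e8, 0.10 * 0.30)  # ~2.137e10
#' @export
infer_total_from_share <- function(S, share) {
  if (share <= 0 || share > 1) stop("share must be in (0, 1]")
  S / share
}

#' Asymmetric-synapse budget of one target layer
#'
#' For each cell type the population synapse total `S(t, l) = N_t * s(t, l)`
#' is set against an independent estimate of the layer's total asymmetric
#' synapses `T_l` (defined as 100%). The assigned fraction is
#' `sum(S) / T_l`; the remainder is unassigned. An assigned fraction above 1
#' (as occurs for layers 2/3 in the source diagram) is reported with a
#' warning, not clamped.
#'
#' @param cell_types Cell-type data frame.
#' @param target_layer Target layer name.
#' @param total Independent total asymmetric synapses `T_l` (> 0).
#' @return Object of class `layer_budget`: list with `target_layer`,
#'   `total`, `per_type` (data frame of `S` and `share`), `assigned`,
#'   `unassigned`.
#' @export
layer_budget <- function(cell_types, target_layer, total) {
  if (total <= 0) stop("total must be positive")
  S <- population_synapses(cell_types, target_layer)
  assigned <- sum(S) / total
  u <- 1 - assigned
  if (u < 0)
    warning("assigned synapses exceed the independent total in ",
            target_layer, " (", round(assigned * 100, 1),
            "% assigned); unassigned fraction is negative")
  structure(list(target_layer = target_layer, total = total,
                 per_type = data.frame(name = names(S), S = as.numeric(S),
                                       share = as.numeric(S) / total,
                                       stringsAsFactors = FALSE),
                 assigned = assigned, unassigned = u),
            class = "layer_budget")
}

#' Unassigned fraction of a layer budget
#' @param budget A [layer_budget()].
#' @return `1 - assigned` (may be negative, with a warning raised when the
#'   budget was built).
#' @export
unassigned_fraction <- function(budget) {
  stopifnot(inherits(budget, "layer_budget"))
  budget$unassigned
}

#' @export
print.layer_budget <- function(x, ...) {
  cat("Asymmetric-synapse budget for ", x$target_layer,
      " (total ", format(x$total, digits = 4), " synapses)\n", sep = "")
  tab <- transform(x$per_type, S = signif(S, 4),
                   share_pct = round(share * 100, 1))
  print(tab[c("name", "S", "share_pct")], row.names = FALSE)
  cat(sprintf("assigned %.1f%%, unassigned %.1f%%\n",
              x$assigned * 100, x$unassigned * 100))
  invisible(x)
}

#' Per-cell synapse count implied by a target contribution
#'
#' Inverse of the budget arithmetic: for a population of `population` cells
#' to contribute the fraction `contribution` of the layer total `total`,
#' each cell must form `s = contribution * total / population` synapses
#' there.
#'
#' @param contribution Fraction of the layer total in `(0, 1)`.
#' @param total Layer total asymmetric synapses.
#' @param population Number of cells (> 0).
#' @return Synapses per cell.
#' @examples
#' k <- budget_constants()
#' solve_per_cell_synapses(0.300, k$total_L6, k$n_spiny_L23 / 3)  # ~2331
#' @export
solve_per_cell_synapses <- function(contribution, total, population) {
  if (population <= 0) stop("population must be positive")
  if (contribution <= 0 || contribution >= 1)
    stop("contribution must be in (0, 1)")
  contribution * total / population
}

#' Synapses needed to reduce the unassigned fraction to a target
#'
#' @param u_target Target unassigned fraction, below the budget's current
#'   unassigned fraction.
#' @param budget A [layer_budget()].
#' @return `(u_current - u_target) * total` additional synapses.
#' @export
additional_synapses_needed <- function(u_target, budget) {
  stopifnot(inherits(budget, "layer_budget"))
  if (u_target >= budget$unassigned)
    stop("u_target must be below the current unassigned fraction (",
         round(budget$unassigned, 3), ")")
  (budget$unassigned - u_target) * budget$total
}

#' Fold change of a per-cell synapse count over a baseline
#' @param s_new,s_baseline Per-cell synapse counts; baseline must be > 0.
#' @return `s_new / s_baseline`.
#' @examples
#' fold_change(2329, 78)  # ~29.9
#' @export
fold_change <- function(s_new, s_baseline) {
  if (any(s_baseline <= 0)) stop("baseline per-cell count must be positive")
  s_new / s_baseline
}

#' Declare a hypothetical cell type for a budget scenario
#'
#' A new type is a fraction of an existing spiny population in its soma
#' layer, and is specified by exactly one of: its contribution `c` to the
#' target-layer total, or its per-cell synapse count `s`.
#'
#' @param name Type name, e.g. `"p3(L6)"`.
#' @param soma_layer Soma layer of the type.
#' @param layer_population Spiny population of the soma layer.
#' @param population_fraction Fraction of that population the type makes up
#'   (in `(0, 1]`).
#' @param contribution Fraction of the target-layer total the type provides.
#' @param per_cell Synapses per cell in the target layer.
#' @return Object of class `new_cell_type`.
#' @export
new_cell_type <- function(name, soma_layer, layer_population,
                          population_fraction, contribution = NULL,
                          per_cell = NULL) {
  if (population_fraction <= 0 || population_fraction > 1)
    stop("population_fraction must be in (0, 1]")
  if (is.null(contribution) == is.null(per_cell))
    stop("specify exactly one of contribution or per_cell for '", name, "'")
  structure(list(name = name, soma_layer = soma_layer,
                 population = layer_population * population_fraction,
                 population_fraction = population_fraction,
                 contribution = contribution, per_cell = per_cell),
            class = "new_cell_type")
}

#' Budget scenario: add hypothetical cell types to a baseline budget
#'
#' Each new type's missing quantity is solved from the other (per-cell count
#' from contribution via [solve_per_cell_synapses()], or contribution from
#' `population * per_cell / total`), and the residual unassigned fraction is
#' recomputed. Shares of all baseline types, all new types, and the residual
#' sum to 1 exactly.
#'
#' @param baseline A [layer_budget()].
#' @param new_types List of [new_cell_type()] objects (possibly empty).
#' @return Object of class `budget_scenario`: list with `baseline`, `table`
#'   (data frame: `name`, `kind`, `population`, `per_cell`, `S`, `share`),
#'   `unassigned`, `additional_synapses` (total contributed by new types).
#' @examples
#' k <- budget_constants()
#' base <- baseline_budget()
#' sc <- scenario_report(base, list(
#'   new_cell_type("p3(L6)", "L3", k$n_spiny_L23, 1/3, contribution = 0.300),
#'   new_cell_type("sp4(L6)", "L4", k$n_spiny_L4, 1/4, contribution = 0.217)))
#' @export
scenario_report <- function(baseline, new_types = list()) {
  stopifnot(inherits(baseline, "layer_budget"))
  Tl <- baseline$total
  rows <- baseline$per_type
  base_tab <- data.frame(name = rows$name, kind = "baseline",
                         population = NA_real_, per_cell = NA_real_,
                         S = rows$S, share = rows$share,
                         stringsAsFactors = FALSE)
  new_tab <- do.call(rbind, lapply(new_types, function(nt) {
    stopifnot(inherits(nt, "new_cell_type"))
    if (!is.null(nt$contribution)) {
      s <- solve_per_cell_synapses(nt$contribution, Tl, nt$population)
      c_frac <- nt$contribution
    } else {
      s <- nt$per_cell
      c_frac <- nt$population * s / Tl
    }
    data.frame(name = nt$name, kind = "new", population = nt$population,
               per_cell = s, S = nt$population * s, share = c_frac,
               stringsAsFactors = FALSE)
  }))
  tab <- rbind(base_tab, new_tab)
  unassigned <- 1 - sum(tab$share)
  if (unassigned < -1e-9)
    warning("scenario over-assigns the layer total (unassigned ",
            round(unassigned * 100, 1), "%)")
  structure(list(baseline = baseline, table = tab, unassigned = unassigned,
                 additional_synapses = sum(new_tab$S)),
            class = "budget_scenario")
}

#' @export
print.budget_scenario <- function(x, ...) {
  cat("Budget scenario for ", x$baseline$target_layer, " (total ",
      format(x$baseline$total, digits = 4), " synapses)\n", sep = "")
  tab <- transform(x$table, S = signif(S, 4),
                   per_cell = round(per_cell),
                   share_pct = round(share * 100, 1))
  print(tab[c("name", "kind", "per_cell", "S", "share_pct")],
        row.names = FALSE)
  cat(sprintf("residual unassigned: %.1f%%", x$unassigned * 100), "\n")
  if (nrow(x$table[x$table$kind == "new", ]))
    cat("additional synapses from new types:",
        format(x$additional_synapses, digits = 4), "\n")
  invisible(x)
}
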