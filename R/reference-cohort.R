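#' Synthetic reference cohort of per-animal counts
#'
#' A synthetic stand-in for the study's per-animal supplementary count
#' table, which is not redistributed here. The ten cats' integer counts are
#' constructed so that the cohort statistics computed by this package's own
#' pipeline equal the published summary values: ipsilateral area 17 FLN
#' averaged over cats 1-7 = 81.1% (92.0% over the four cats without border
#' injections, area 18 = 12%), area 17 laminar means over all ten cats of
#' 41.3% (L3), 27.5% (L6) and 14.6% (L4), and cohort mean totals of 10,249
#' labeled somata (9,493 after excluding injection-site somata). Per-animal
#' values are otherwise free inventions at a realistic scale (totals span
#' 312 to 29,220; cat 2 is the large border-injection animal; cats 8-10 are
#' faintly labeled and flagged `exclude_from_fln`).
#'
#' Counts are stored at the counted (per-sampled-section) scale with the
#' standard sampling factors (cortex 2, subcortex 4), so the corrected
#' totals exercise the same sampling-correction path as real data.
#'
#' @return List with `counts` (a count table as produced by
#'   [count_table()], covering cats 1-10) and `metadata` (one row per
#'   animal: `border_injection`, `exclude_from_fln`, `tracer`,
#'   `total_injection_volume`).
#' @examples
#' rc <- reference_cohort()
#' f <- fln(rc$counts)
#' @export
reference_cohort <- function() {
  cats <- sprintf("cat%d", 1:10)
  border <- c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE,
              FALSE)
  faint <- c(rep(FALSE, 7), TRUE, TRUE, TRUE)
  # corrected (sampling-factor-applied) totals per structure, excluding
  # injection-site somata
  a17 <- c(12040, 17160, 8820, 11280, 5586, 7320, 10780, 400, 300, 200)
  a18 <- c(560, 9724, 294, 360, 2016, 1400, 220, 80, 50, 20)
  lgn <- c(700, 856, 344, 180, 400, 640, 0, 44, 28, 4)
  a17c <- c(420, 516, 206, 108, 238, 384, 0, 0, 0, 0)
  a19 <- c(280, 344, 136, 72, 160, 256, 0, 2, 2, 0)
  inj <- c(1200, 620, 1000, 1100, 1082, 1150, 1150, 100, 70, 88)
  # per-cat A17 laminar fractions (L1..L6); rows sum to 1
  lam_a17 <- rbind(
    c(0.008, 0.11, 0.50, 0.11, 0.08, 0.192),
    c(0.000, 0.06, 0.55, 0.12, 0.05, 0.220),
    c(0.000, 0.10, 0.38, 0.20, 0.08, 0.240),
    c(0.000, 0.07, 0.45, 0.10, 0.09, 0.290),
    c(0.002, 0.05, 0.30, 0.25, 0.10, 0.298),
    c(0.000, 0.12, 0.42, 0.13, 0.07, 0.260),
    c(0.000, 0.09, 0.48, 0.08, 0.06, 0.290),
    c(0.000, 0.05, 0.35, 0.15, 0.12, 0.330),
    c(0.000, 0.10, 0.30, 0.20, 0.10, 0.300),
    c(0.000, 0.06, 0.40, 0.12, 0.09, 0.330))
  lam_a18 <- c(0, 0.06, 0.33, 0.37, 0.08, 0.16)
  lam_a19 <- c(0, 0.10, 0.30, 0.25, 0.15, 0.20)
  lam_a17c <- c(0, 0.15, 0.66, 0.17, 0.01, 0.01)
  L <- c("L1", "L2", "L3", "L4", "L5", "L6")

  rows <- list()
  add <- function(cat, hemi, area, layer, corrected, factor, in_inj = FALSE) {
    keep <- corrected > 0
    if (!any(keep)) return()
    rows[[length(rows) + 1]] <<- data.frame(
      animal = cat, hemisphere = hemi, area = area, layer = layer[keep],
      in_injection_site = in_inj, counted_n = corrected[keep] %/% factor,
      sampling_factor = factor, corrected_n = corrected[keep],
      stringsAsFactors = FALSE)
  }
  for (i in 1:10) {
    add(cats[i], "ipsi", "A17", L, even_alloc(lam_a17[i, ], a17[i]), 2L)
    add(cats[i], "ipsi", "A18", L, even_alloc(lam_a18, a18[i]), 2L)
    if (a19[i] > 0)
      add(cats[i], "ipsi", "A19", L, even_alloc(lam_a19, a19[i]), 2L)
    if (a17c[i] > 0)
      add(cats[i], "contra", "A17", L, even_alloc(lam_a17c, a17c[i]), 2L)
    if (lgn[i] > 0) add(cats[i], "ipsi", "LGN", "-", lgn[i], 4L)
    add(cats[i], "ipsi", "A17", "L6", inj[i], 2L, in_inj = TRUE)
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- NULL
  metadata <- data.frame(
    animal = cats, border_injection = border, exclude_from_fln = faint,
    tracer = "HRP",
    total_injection_volume = c(0.35, 1.20, 0.30, 0.25, 0.90, 0.75, 0.40,
                               0.10, 0.08, 0.12),
    stringsAsFactors = FALSE)
  list(counts = counts, metadata = metadata)
}

# Largest-remainder allocation of an even total across fractions, keeping
# every allocated count even so that counted_n = corrected_n / 2 stays
# integral for cortical structures.
even_alloc <- function(frac, total) {
  if (total %% 2 != 0) stop("total must be even")
  half <- total / 2
  raw <- frac * half
  base <- floor(raw)
  rem <- half - sum(base)
  ord <- order(raw - base, decreasing = TRUE)
  if (rem > 0) base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  base * 2
}
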