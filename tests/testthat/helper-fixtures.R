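# Small in-code fixtures shared across test files.

tiny_model <- function() cortex_model(n_sections = 20)

# n somata with explicit fields; defaults give valid ipsilateral A17 rows
make_neurons <- function(n, x = 0, y = 500, section = 0, area = "A17",
                         hemisphere = "ipsi", layer = "L3",
                         in_inj = FALSE, id = NULL) {
  data.frame(id = if (is.null(id)) sprintf("n%03d", seq_len(n)) else id,
             x_um = rep_len(x, n), y_um = rep_len(y, n),
             section_index = rep_len(section, n),
             area = rep_len(area, n), hemisphere = rep_len(hemisphere, n),
             layer = rep_len(layer, n), tracer = "HRP",
             in_injection_site = rep_len(in_inj, n),
             stringsAsFactors = FALSE)
}

make_injections <- function(n = 1, x = 0, y = 1650, section = 0,
                            volume = 0.19) {
  data.frame(id = sprintf("inj%d", seq_len(n)),
             x_um = rep_len(x, n), y_um = rep_len(y, n),
             section_index = rep_len(section, n),
             layer = "L6", area = "A17",
             volume_mm3 = rep_len(volume, n), tracer = "HRP",
             stringsAsFactors = FALSE)
}

# count table row builder
make_counts <- function(animal, area, corrected, layer = "L3",
                        hemisphere = "ipsi", factor = 2L, in_inj = FALSE) {
  n <- max(length(area), length(corrected), length(layer))
  data.frame(animal = rep_len(animal, n),
             hemisphere = rep_len(hemisphere, n),
             area = rep_len(area, n), layer = rep_len(layer, n),
             in_injection_site = rep_len(in_inj, n),
             counted_n = rep_len(corrected, n) %/% rep_len(factor, n),
             sampling_factor = rep_len(factor, n),
             corrected_n = rep_len(corrected, n),
             stringsAsFactors = FALSE)
}
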