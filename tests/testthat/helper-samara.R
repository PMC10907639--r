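# shared fixture builders (all data generated in code)

make_morph <- function(id = "s1", species = "synthetic", mass_mg = 12,
                       span_mm = 30, chord_mm = 9, area_cm2 = 1.6) {
  data.frame(specimen_id = id, species = species, mass_mg = mass_mg,
             span_mm = span_mm, chord_mm = chord_mm, area_cm2 = area_cm2,
             stringsAsFactors = FALSE)
}

# a silhouette object from a raw 0/1 matrix
as_sil <- function(mask, scale = 0.1) {
  structure(list(mask = mask, scale = scale), class = "silhouette")
}

# brute-force span oracle: max distance over ALL foreground pixel-center
# pairs (no convex hull)
brute_span <- function(sil) {
  idx <- which(sil$mask == 1L, arr.ind = TRUE)
  pts <- cbind(idx[, "col"], idx[, "row"])
  max(stats::dist(pts)) * sil$scale
}

# zero-noise generator configuration
quiet_config <- function(n = 40, seed = 1, ...) {
  generator_config(n_specimens = n, noise_sd_V = 0, noise_sd_dynamics = 0,
                   seed = seed, ...)
}
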