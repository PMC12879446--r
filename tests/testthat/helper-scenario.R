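# Shared small scenarios, built once per test run and memoized.

.scenario_cache <- new.env(parent = emptyenv())

# Compact benchmark-style scenario: 3 region pairs on 24x20, 800 frames.
small_scenario <- function() {
  if (is.null(.scenario_cache$small)) {
    .scenario_cache$small <- simulate_scenario(
      seed = 7, shape = c(24L, 20L), n_regions_per_hemisphere = 3L,
      n_frames = 800L)
  }
  .scenario_cache$small
}

small_config <- function(...) {
  run_config(downsample_shape = c(24L, 20L), downsample_frame_rate_hz = 8,
             frame_rate_hz = 8, n_parcels = 12L, min_clusters = 4L, ...)
}

small_processed <- function() {
  if (is.null(.scenario_cache$small_hemo)) {
    sc <- small_scenario()
    .scenario_cache$small_hemo <-
      preprocess_stack(sc$raw, sc$mask, small_config())
  }
  .scenario_cache$small_hemo
}

small_parcellated <- function() {
  if (is.null(.scenario_cache$small_parc)) {
    .scenario_cache$small_parc <-
      suppressWarnings(parcellate(small_processed(), small_config()))
  }
  .scenario_cache$small_parc
}

# Ground-truth region membership over a hemo stack's in-mask pixels.
region_membership <- function(gt, hemo) {
  gt$region_map[which(as.vector(hemo$mask$brain))]
}

gt_region_labels <- function(gt) {
  data.frame(id = gt$region_labels$region,
             region = gt$region_labels$region,
             hemisphere = gt$region_labels$hemisphere)
}

gt_region_table <- function(gt) {
  region_table(data.frame(region = gt$region_labels$region,
                          name = gt$region_labels$name,
                          hemisphere = gt$region_labels$hemisphere))
}

# Adjusted Rand index between two labelings, ignoring zeros in `truth`.
ari_score <- function(labels, truth) {
  keep <- truth > 0L & labels > 0L
  mclust::adjustedRandIndex(labels[keep], truth[keep])
}
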