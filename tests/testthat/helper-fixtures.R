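# Shared fixtures: everything is generated in code at test time.

# A tiny atlas: n regions, >= 2 voxels each, a little background.
tiny_atlas <- function(n_regions = 3L, per = 4L) {
  n_vox <- (n_regions + 1L) * per
  labels <- integer(n_vox)
  labels[seq_len(n_regions * per)] <- rep(seq_len(n_regions), each = per)
  dimv <- c(n_vox, 1L, 1L)
  regions <- data.frame(
    region_id = seq_len(n_regions),
    region_name = paste0("r", seq_len(n_regions)),
    compartment = rep(c("cortex", "subcortex"),
                      length.out = n_regions),
    hemisphere = NA_character_, stringsAsFactors = FALSE)
  parcellation_atlas(array(labels, dimv), regions)
}

# A one-compartment atlas (all cortex) of n regions.
cortex_atlas <- function(n_regions = 20L) {
  a <- tiny_atlas(n_regions)
  a$regions$compartment <- "cortex"
  a
}

rmap <- function(values, atlas, quantity = "mean") {
  regional_map(values, atlas, quantity = quantity)
}

# Random positive mean/std pair on the default 154-region atlas pair.
random_study_maps <- function(atlas, seed = 1) {
  n <- nrow(atlas$regions)
  withr::with_seed(seed, {
    mu <- runif(n, 0.5, 5)
    sg <- runif(n, 0, 1)
    list(mean_map = regional_map(mu, atlas, "mean"),
         std_map = regional_map(sg, atlas, "std"))
  })
}

default_atlas <- synthetic_atlas()
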