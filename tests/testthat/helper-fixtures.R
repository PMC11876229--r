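# Shared desk-scale fixtures, built once per test run and memoized.
# 96-pixel crops with a 3x3 grid of 32-px cells (24-px patches, jitter
# 0..8) are the scaled-down analogue of the 512 / 170 / 150 / 20 study
# geometry: same structure, minutes-not-days runtimes.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

test_grid <- function() grid_spec(96L, 3L, 32L, 24L, 8L)

test_encoder <- function() encoder_spec(feature_dim = 32L)

# ~90 images, 60 patients, full default mixture at 96 px
small_dataset <- function() fixture("small_dataset", function() {
  generate_dataset(synthetic_config(n_patients = 60L, image_size = 96L,
                                    seed = 11L))
})

# the standard 31-class permutation set at test pool size
small_permset <- function() fixture("small_permset", function() {
  generate_permutation_set(n_extra = 30L, pool_size = 200L, seed = 5L)
})

# a valid 10-record toy manifest with 3 flagged records
toy_manifest <- function() {
  data.frame(
    patient_id = sprintf("P%02d", c(1, 1, 2, 3, 4, 5, 6, 7, 8, 9)),
    image_id = sprintf("I%02d", 1:10),
    view = "MLO",
    cancer = c(1L, 0L, 1L, 0L, 0L, 1L, 0L, 0L, 1L, 0L),
    finding = c("mass", "normal", "calcification", "normal", "distortion",
                "mass", "normal", "calcification", "mass", "normal"),
    density = rep(c("DB", "Not-DB"), 5),
    image_path = sprintf("images/I%02d.tiff", 1:10),
    mask_path = "",
    exclusion_flag = c("none", "artifact", "none", "none", "phyllodes",
                       "none", "none", "lesion_unidentifiable", "none",
                       "none"),
    stringsAsFactors = FALSE)
}
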