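# deterministic in-memory fixtures used across test files

# a tiny hand-written measurement table with known arithmetic
tiny_records <- function() {
  tibble::tibble(
    patient_id = c("p1", "p1", "p2"),
    shock_type = c("septic", "septic", "cardiogenic"),
    day = c(1L, 2L, 1L),
    tewl_forehead = c(10, 12, 8),
    tewl_upper_limb = c(7, 6, 5),
    tewl_lower_limb = c(6, 7, 5),
    tewl_trunk = c(7, 8, 6),
    weight_kg = c(70, 70, 85),
    height_cm = c(170, 170, 180),
    core_temp_c = c(37, 38, 36.5),
    ventilated = TRUE,
    svri = c(1500, 1300, 2900),
    parenteral_ml = c(4000, 4500, 3000),
    enteral_ml = c(100, 0, 400),
    urine_ml = c(800, 900, 1000),
    ultrafiltrate_ml = c(0, 500, 1500)
  )
}

# default synthetic cohort at a fixed seed
demo_cohort <- function(seed = 123) generate_cohort(cohort_config(seed = seed))

# a larger cohort with full SVRI coverage, ~n records on average
big_cohort <- function(seed, n_septic = 32, n_cardiogenic = 19, ...) {
  generate_cohort(cohort_config(
    n_septic = n_septic, n_cardiogenic = n_cardiogenic,
    svri_missing = c(septic = 0, cardiogenic = 0), seed = seed, ...
  ))
}
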