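## Shared fixtures, built lazily once per test run.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

## Default-resolution anatomy bundle (2 mm ventricles, 1.5 mm atria).
fx_bundle <- function() fx_get("bundle", function() build_anatomy_bundle())

## Small ventricular mesh for cheap geometry/field tests.
fx_small_vent <- function() fx_get("small_vent", function() {
  an <- default_anatomy(resolution = 3)
  assign_ventricular_fibers(build_ventricular_mesh(an))
})

fx_atrial <- function() fx_get("atrial", function() {
  cache_edges(build_atrial_mesh(default_anatomy()))
})

fx_sinus_bank <- function() fx_get("sinus_bank", function() {
  template_bank(default_params()$ms_sinus, seq(145, 255, by = 1))
})

## A single healthy record plus its configuration.
fx_sinus_record <- function() fx_get("sinus_record", function() {
  rows <- sample_case(1, 4242)
  cfg <- make_case_config("sinus", rows[1, ])
  generate_record(cfg, fx_bundle())
})

## Batches used by the acceptance tests.
fx_avb_records <- function(n = 50) fx_get("avb50", function() {
  generate_records("avblock", n, seed = 60601, anatomies = list(fx_bundle()))
})

fx_sinus_records <- function(n = 100) fx_get("sinus100", function() {
  generate_records("sinus", n, seed = 70701, anatomies = list(fx_bundle()))
})

## Beat-pair evaluation of the delineator against generator ground truth.
delineation_errors <- function(records, fiducial_names =
                                 c("P_on", "P_off", "QRS_on", "QRS_off",
                                   "T_off")) {
  errs <- stats::setNames(vector("list", length(fiducial_names)),
                          fiducial_names)
  for (rec in records) {
    gf <- global_fiducials(delineate_record(rec, "raw"))
    gt <- rec$fiducials
    for (j in seq_len(nrow(gf))) {
      i <- which.min(abs(gt$QRS_on - gf$QRS_on[j]))
      if (!length(i) || abs(gt$QRS_on[i] - gf$QRS_on[j]) > 150) next
      for (f in fiducial_names) {
        errs[[f]] <- c(errs[[f]], gf[[f]][j] - gt[[f]][i])
      }
    }
  }
  errs
}
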