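# Shared fixtures for the suite. The calibrated fixture is cheap to build
# but used everywhere; construct it once per test run.
fx <- calibrated_fixture()

scenario_ffs <- function(...) calibrated_scenario("FFS", fixture = fx, ...)
scenario_dpc <- function(...) calibrated_scenario("DPC", fixture = fx, ...)

# The eight one-way sensitivity settings of the published analysis: the
# three base-case parameters under each tariff mode, plus the procedure
# duration under each tariff mode with 2018 labour.
table4_settings <- list(
  list(tariff = "FFS", labour = "none",
       param = dsa_parameter("rft_proportion", 0.0356, c(0, 0.10))),
  list(tariff = "FFS", labour = "none",
       param = dsa_parameter("extraction_rate", 0.01, c(0, 0.02))),
  list(tariff = "FFS", labour = "none",
       param = dsa_parameter("dbs_post_hospital_days", 8, c(2, 10))),
  list(tariff = "FFS", labour = "2018",
       param = dsa_parameter("mrgfus_duration_hours", 4, c(2, 6))),
  list(tariff = "DPC", labour = "none",
       param = dsa_parameter("rft_proportion", 0.0356, c(0, 0.10))),
  list(tariff = "DPC", labour = "none",
       param = dsa_parameter("extraction_rate", 0.01, c(0, 0.02))),
  list(tariff = "DPC", labour = "none",
       param = dsa_parameter("dbs_post_hospital_days", 8, c(2, 10))),
  list(tariff = "DPC", labour = "2018",
       param = dsa_parameter("mrgfus_duration_hours", 4, c(2, 6)))
)

# A small hand-written catalog for unit tests of the catalog layer.
tiny_catalog <- function() {
  items <- rbind(
    cost_item("mri", "MRI scan", "pre", "imaging", 10000, 2, "FFS"),
    cost_item("fee", "Surgical fee", "procedure", "fee", 150000, 1, "FFS"),
    cost_item("fee", "Surgical fee (DPC)", "procedure", "fee", 120000, 1,
              "DPC"),
    cost_item("drug", "Anaesthetic", "procedure", "drug", 2500, 4,
              "drug_tariff"),
    cost_item("mri_premium", "Off-hours imaging premium", "pre", "premium",
              2000, 2, "FFS", parent_item = "mri")
  )
  catalog(items, schedules = list(
    stay = hosp_schedule(c(1, 4), c(3, Inf), c(10000, 8000))))
}
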