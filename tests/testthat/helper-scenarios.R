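# shared scenario builders for the test suite

glucose <- glucose_example()

# scenario with both populations identical (uninformative test)
identical_populations <- function(n = 200) {
  scenario(
    non_diseased = population_sample(1, 1, n),
    diseased     = population_sample(1, 1, n),
    measurement  = measurement_model(0.02, 50),
    threshold    = 1)
}

# near-asymptotic scenario: no measurement uncertainty, huge samples
near_exact_scenario <- function(n = 10000000L) {
  scenario(
    non_diseased = population_sample(0, 1, n),
    diseased     = population_sample(3, 0.8, n),
    measurement  = measurement_model(0, 50),
    threshold    = 1.5)
}

# rebuild a scenario with one field changed
with_um <- function(s, u_m) {
  scenario(s$non_diseased, s$diseased,
           measurement_model(u_m, s$measurement$n_u),
           s$threshold, s$confidence)
}

with_sizes <- function(s, n_nd, n_d) {
  scenario(population_sample(s$non_diseased$mean, s$non_diseased$sd, n_nd),
           population_sample(s$diseased$mean, s$diseased$sd, n_d),
           s$measurement, s$threshold, s$confidence)
}

propagate_all <- function(s) lapply(dam_ids(), propagate, s = s)

tmp_path <- function(name) tempfile(pattern = paste0(sub("\\..*$", "", name), "_"),
                                    fileext = sub("^[^.]*", "", name))
tmp_dir <- function() {
  d <- tempfile("cli_")
  dir.create(d)
  d
}
quiet <- function(expr) suppressMessages(expr)
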