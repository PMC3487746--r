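# shared objects for the suite
th_average <- persistence_threshold("average")
th_highest <- persistence_threshold("highest")
th_low <- persistence_threshold("low")

fixture_catalog <- function() read_catalog(pcrit_example_catalog())

# an ngm_state with a prescribed (mG, d) pair, so the proportional-effect
# constant c = d/mG is under test control
ngm_state_from_mg_d <- function(mG, d, p) {
  ngm_state(mA = mG + (1 - p) * d, mU = mG - p * d, p = p)
}
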