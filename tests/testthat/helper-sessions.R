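# shared heavy fixtures, computed once per test run
.session_cache <- new.env(parent = emptyenv())

cached_session <- function(key, maker) {
  if (is.null(.session_cache[[key]])) .session_cache[[key]] <- maker()
  .session_cache[[key]]
}

# full 30-trial default synthetic session, rendered and tracked at 5 Hz
default_session <- function() {
  cached_session("default", function()
    run_session(session_config(seed = 7,
      params = generator_params(frame_rate = 5))))
}

# same session at low angle noise, for end-to-end calibration checks
lownoise_session <- function() {
  cached_session("lownoise", function()
    run_session(session_config(seed = 7,
      params = generator_params(frame_rate = 5, sigma_theta = 0.2))))
}
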