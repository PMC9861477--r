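# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# a 4-channel toy montage: vertex plus three electrodes around it
toy_montage <- function() {
  montage(c("Cz", "A1", "A2", "A3"),
          rbind(c(0, 0, 1),
                c(sin(0.8), 0, cos(0.8)),
                c(-sin(0.8) * 0.5, sin(0.8) * 0.866, cos(0.8)),
                c(-sin(0.8) * 0.5, -sin(0.8) * 0.866, cos(0.8))))
}

# small two-group cohort: 4 patients, 10 s each, strong group effects
tiny_cohort <- function() {
  memo("tiny_cohort", function() {
    cfg <- sim_config(n_per_group = 2, duration = 10, seed = 301)
    list(cfg = cfg, cohort = simulate_cohort(cfg))
  })
}

# single short recording for preprocessing tests
tiny_recording <- function() {
  memo("tiny_recording", function() {
    cfg <- sim_config(n_per_group = 1, duration = 10, seed = 302)
    simulate_recording(cfg, "p1", "pre", "responder", seed = 55)
  })
}

random_epochs <- function(n_epochs, nch, len, rate = 256, seed = 77) {
  with_seed <- get("with_seed", asNamespace("eegoutcome"))
  with_seed(seed, {
    eps <- array(rnorm(n_epochs * nch * len), c(n_epochs, nch, len))
    epoch_set(eps, rate, paste0("ch", seq_len(nch)))
  })
}
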