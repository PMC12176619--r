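# Small configurations used across tests: enough neurons for the population
# analyses to have signal, short enough that a full session simulates in
# well under a second per seed.
small_config <- function(...) {
  sim_config(n_neurons = 60, ...)
}

# a cached default small session so independent tests don't re-simulate
small_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_session(small_config(), seed = 42)
    cache
  }
})

# regular 100-Hz spike train on [0, t_end): exactly one spike per 10-ms bin
regular_spikes <- function(t_end, bin = 0.01) {
  seq(bin / 2, t_end - bin / 2, by = bin)
}

# minimal hand-built event log: consumption with a few rewards, delay, stim
tiny_events <- function(n_per_port = 3, bouts = TRUE) {
  rew_t <- 300 + seq_len(2 * n_per_port) * 20
  ports <- rep(c("flavour", "water"), n_per_port)
  cons_end <- max(rew_t) + 1
  epochs <- list(consumption = epoch("consumption", 300, cons_end),
                 delay = epoch("delay", cons_end, cons_end + 1800))
  bt <- data.frame(onset = numeric(0), offset = numeric(0))
  if (bouts) {
    st <- cons_end + 1800
    epochs$stim <- epoch("stim", st, st + 600)
    on <- seq(st, st + 590, by = 6)
    bt <- data.frame(onset = on, offset = on + 3)
  }
  event_log(cues = data.frame(time = rew_t - 1, port = ports,
                              stringsAsFactors = FALSE),
            rewards = data.frame(time = rew_t, port = ports,
                                 stringsAsFactors = FALSE),
            bouts = bt, epochs = epochs)
}
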