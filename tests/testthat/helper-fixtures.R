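# Shared fixtures: small solver configs and a total-amount helper used by the
# conservation tests. All data are generated in code at test time.

cfg_fast <- function(stop_time = 48, dt = 0.1, start_time = -1, ...) {
  solver_config("rk4", start_time = start_time, stop_time = stop_time,
                dt = dt, ...)
}

# Total drug amount across a set of state columns at every output time.
total_amount <- function(traj, cols) {
  rowSums(as.matrix(traj[, cols, drop = FALSE]))
}

# Cumulative administered amount strictly before each output time (trajectory
# rows at a dose time hold the pre-dose state).
administered_before <- function(times, dose_tab) {
  vapply(times, function(t) sum(dose_tab$amount[dose_tab$time < t - 1e-12]),
         numeric(1))
}
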