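# Shared fixtures: everything is built in code, nothing is stored.

ref_params <- function(...) guinea_pig_4khz(...)

fig_groups <- function() figure_mode_groups()

hf_grid <- function(n = 400) frequency_grid(0.3, 3, n)

rel_err <- function(x, y) abs(x - y) / abs(y)

# ohc_series object with a known pure sinusoid, for fit-identity checks
fake_series <- function(amplitude, phase, omega_bar, cycles = 6L,
                        steps_per_cycle = 128L) {
  tau <- seq(0, cycles * 2 * pi / omega_bar,
             by = 2 * pi / (omega_bar * steps_per_cycle))
  structure(list(
    tau = tau,
    p = amplitude * cos(omega_bar * tau + phase),
    dp = -amplitude * omega_bar * sin(omega_bar * tau + phase),
    w = tau * 0, v = NULL,
    omega_bar = omega_bar, gamma = 0, fbar = 1, famp = 1,
    n_cycles = cycles, steps_per_cycle = steps_per_cycle,
    keep_cycles = cycles, groups = NULL),
    class = "ohc_series")
}
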