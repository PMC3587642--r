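# Shared fixtures, all built in code.

# one-species first-order decay ds/dt = -k * s (closed form s0 * exp(-k t))
decay_model <- function(k_upper = 10) {
  ode_model(
    name = "decay",
    state_names = "S",
    param_names = "k",
    rhs = function(state, params, t = 0, input = NULL) c(S = -params[[1]] * state[[1]]),
    initial_state = 2,
    observed = 1L,
    bounds = cbind(0, k_upper),
    default_params = c(k = 0.7),
    default_times = seq(0, 5, length.out = 20))
}

# two-species model with constant (zero-derivative) trajectories; handy for
# exact noise-law checks because the RMS equals the initial value
const_model <- function(values = c(2, 4)) {
  ode_model(
    name = "const",
    state_names = c("P", "Q"),
    param_names = "unused",
    rhs = function(state, params, t = 0, input = NULL) c(P = 0, Q = 0),
    initial_state = values,
    observed = 1:2,
    bounds = cbind(0, 1),
    default_params = c(unused = 0),
    default_times = seq(0, 1, length.out = 10))
}

# finite-time blow-up ds/dt = p * s^2; integration past 1/(p*s0) must fail
blowup_model <- function() {
  ode_model(
    name = "blowup",
    state_names = "S",
    param_names = "p",
    rhs = function(state, params, t = 0, input = NULL) c(S = params[[1]] * state[[1]]^2),
    initial_state = 1,
    observed = 1L,
    bounds = cbind(0, 100),
    default_params = c(p = 50),
    default_times = seq(0, 1, length.out = 10))
}

sphere <- function(x) sum(x^2)

sphere_config <- function(M = 2, ...) {
  efa_config(bounds = cbind(rep(-5, M), rep(5, M)), ...)
}
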