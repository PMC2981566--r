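# Shared fixtures: everything is generated in code at test time.

std_protocol <- function(direction = "left")
  stimulus_protocol(direction = direction)

quiet_noise <- function() noise_spec(velocity_sd = 0, qp_rate = 0)

noiseless_trial <- function(params = model_parameters(),
                            direction = "left", seed = 1)
  generate_trial(params, std_protocol(direction), quiet_noise(), seed = seed)

# Independent frequency-domain oracle for the full dynamic-model chain:
# eye velocity per unit head velocity at s = 2i*pi*f, written in direct
# complex arithmetic (no package transfer-function code).
oracle_gain_phase <- function(p, f) {
  s <- 2i * pi * f
  oto <- p$otolith$k * (1 + p$otolith$T_lead * s) / (1 + p$otolith$T_lag * s)
  lam <- if (is.finite(p$tvor_integrator_tc)) 1 / p$tvor_integrator_tc else 0
  path <- p$G_acc + p$G_i / (s + lam)
  geom <- (180 / pi) / p$distance
  ni <- 1 / (s + 1 / p$ni_tc)
  plant <- 1
  for (tc in p$plant_tc) plant <- plant / (1 + tc * s)
  # head acc = s * head vel; eye vel = s * eye pos
  H <- s * oto * path * geom * ni * plant * exp(-s * p$tau_delay) * s
  c(gain = Mod(H), phase = Arg(H) * 180 / pi)
}

# Minimal trial-shaped object for profile tests
flat_trial <- function(velocity, time = seq(0, 0.4, by = 0.001),
                       mask = FALSE) {
  structure(list(chair = NULL,
                 eye = data.frame(time = time,
                                  velocity = rep_len(velocity, length(time)),
                                  position = 0,
                                  mask = rep_len(mask, length(time))),
                 meta = list()),
            class = "tvor_trial")
}

named_fits <- function(...) {
  fits <- list(...)
  stats::setNames(fits, paste0("c", seq_along(fits)))
}
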