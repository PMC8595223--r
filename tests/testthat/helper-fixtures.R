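# shared fixtures: toy tube networks and synthetic featurised patients

tube_config <- function(length = 20, area = 0.5, c0 = 600, R1 = 1, R2 = 10,
                        C = 0.05, p_out = 0, period = 1,
                        waveform = list(type = "half_sine", mean_flow = 2,
                                        systole_fraction = 0.3),
                        sites = NULL, area_dist = area, rho = 1.06) {
  beta <- 2 * rho * c0^2 * sqrt(area)
  if (is.null(sites))
    sites <- list(
      list(name = "P1", side = "right", vessel = "tube", position = 0,
           quantity = "pressure"),
      list(name = "Q2", side = "right", vessel = "tube", position = 0.8,
           quantity = "flow"))
  list(
    units = list(length = "cm"),
    vessels = list(list(id = "tube", length = length, area_prox = area,
                        area_dist = area_dist, beta = beta)),
    junctions = list(),
    inlet = list(vessel = "tube", period = period, waveform = waveform),
    outlets = list(tube = list(R1 = R1, R2 = R2, C = C, p_out = p_out)),
    chains = list(),
    sites = sites)
}

# two-vessel toy network: parent bifurcating is not needed; a serial pair
two_vessel_config <- function() {
  list(
    vessels = list(
      list(id = "parent", length = 10, area_prox = 0.5, area_dist = 0.5,
           beta = 5e5),
      list(id = "child", length = 10, area_prox = 0.4, area_dist = 0.4,
           beta = 5e5)),
    junctions = list(list(parent = "parent", children = "child")),
    inlet = list(vessel = "parent", period = 1,
                 waveform = list(type = "half_sine", mean_flow = 2,
                                 systole_fraction = 0.3)),
    outlets = list(child = list(R1 = 1, R2 = 10, C = 0.05, p_out = 0)),
    chains = list(list(name = "CA", side = "none",
                       segments = c("parent", "child"))),
    sites = list(list(name = "P1", side = "right", vessel = "child",
                      position = 0.5, quantity = "pressure")))
}

# bifurcating Y network for junction mass-conservation checks
y_network_config <- function() {
  list(
    vessels = list(
      list(id = "trunk", length = 10, area_prox = 1.0, area_dist = 1.0,
           beta = 8e5),
      list(id = "left", length = 12, area_prox = 0.55, area_dist = 0.5,
           beta = 6e5),
      list(id = "right", length = 12, area_prox = 0.55, area_dist = 0.5,
           beta = 6e5)),
    junctions = list(list(parent = "trunk", children = c("left", "right"))),
    inlet = list(vessel = "trunk", period = 0.9,
                 waveform = list(type = "half_sine", mean_flow = 10,
                                 systole_fraction = 0.33)),
    outlets = list(left = list(R1 = 1, R2 = 8, C = 0.05, p_out = 0),
                   right = list(R1 = 1, R2 = 8, C = 0.05, p_out = 0)),
    chains = list(),
    sites = list(
      list(name = "Q1", side = "right", vessel = "trunk", position = 0.5,
           quantity = "flow"),
      list(name = "Q2", side = "right", vessel = "left", position = 0.5,
           quantity = "flow"),
      list(name = "Q3", side = "right", vessel = "right", position = 0.5,
           quantity = "flow")))
}

# synthetic featurised patients: waveforms built directly from band-limited
# harmonics, with a class-dependent perturbation on chosen measurements —
# lets classifier and bookkeeping tests run without the solver
synthetic_waveforms <- function(rngbase, diseased = FALSE,
                                signal = c("Q1"), strength = 1,
                                period = 0.9, n = 64L) {
  sites <- expand.grid(side = c("right", "left"),
                       name = c("P1", "P2", "P3", "Q1", "Q2", "Q3"),
                       stringsAsFactors = FALSE)
  sites$quantity <- ifelse(grepl("^P", sites$name), "pressure", "flow")
  sites$vessel <- "none"; sites$position <- 0.5
  sites <- sites[c("name", "side", "vessel", "position", "quantity")]
  tt <- (seq_len(n) - 1) / n
  samples <- sapply(seq_len(nrow(sites)), function(k) {
    base <- if (sites$quantity[k] == "pressure") 100 else 5
    amp <- if (sites$quantity[k] == "pressure") 20 else 3
    phi <- rngbase[k]   # patient-specific phase/offset source
    u <- base + 0.3 * amp * sin(phi) + amp * sin(2 * pi * tt) +
      0.3 * amp * cos(4 * pi * tt + 0.5 * phi) +
      0.15 * amp * sin(2 * pi * 3 * tt + 2 * phi) +
      0.08 * amp * cos(2 * pi * 5 * tt + 3 * phi) +
      0.1 * amp * phi * sin(6 * pi * tt)
    if (diseased && sites$name[k] %in% signal)
      u <- u + strength * amp * 0.5 * cos(2 * pi * tt + 0.7)
    u
  })
  colnames(samples) <- paste(sites$name,
                             ifelse(sites$side == "left", "L", "R"),
                             sep = "_")
  structure(list(samples = samples, period = period, n = n, sites = sites,
                 converged = TRUE, cycles = 1, residual = 0),
            class = "waveform_set")
}

synthetic_twin_pools <- function(n, signal = "Q1", strength = 1,
                                 seed = 1) {
  withr::with_seed(seed, {
    healthy <- lapply(seq_len(n), function(i) {
      base <- rnorm(12)
      structure(list(id = i, parameters = list(base = base),
                     label = "healthy", disease = NULL,
                     waveforms = synthetic_waveforms(base, FALSE)),
                class = "virtual_patient")
    })
    diseased <- lapply(seq_len(n), function(i) {
      base <- healthy[[i]]$parameters$base
      structure(list(id = i, parameters = list(base = base),
                     label = "diseased", disease = NULL,
                     waveforms = synthetic_waveforms(base, TRUE, signal,
                                                     strength)),
                class = "virtual_patient")
    })
    list(healthy = healthy, diseased = diseased)
  })
}
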