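MMHG <- 1333.22  # dyn/cm^2 per mmHg

#' Solver settings for the 1D pulse-wave model
#'
#' @param dx target spatial resolution, cm per cell.
#' @param cfl CFL number in (0, 1].
#' @param max_cycles maximum cardiac cycles to run (>= 2).
#' @param tol periodicity tolerance: relative L-infinity change between
#'   successive cycles, scaled by each site's pulse amplitude.
#' @param min_cycles minimum cycles before convergence may be declared.
#' @param rho blood density, g/cm^3.
#' @param mu blood viscosity, Poise.
#' @param gamma_profile velocity-profile order (friction
#'   `f = 2(gamma+2) pi mu / rho`, momentum correction
#'   `alpha = (gamma+2)/(gamma+1)`).
#' @param n_store samples per cycle recorded at measurement sites.
#' @param p_init initial uniform pressure, mmHg.
#' @param visc_k selective artificial-dissipation coefficient (0 disables;
#'   the default scheme is stable without it at the default resolution).
#' @param visc_gate dissipation sensor gate, dyn/cm^2.
#' @param lesion_refine spatial refinement factor applied to vessels of a
#'   diseased chain.
#' @param junction_total_pressure couple junctions by continuity of total
#'   pressure (default); `FALSE` uses static-pressure continuity.
#' @param ramp_cycles cycles over which the inflow amplitude is ramped up
#'   from rest (gentle start; ramp cycles are excluded from convergence).
#' @param balance_tol cycle volume-balance tolerance: the net stored
#'   volume per cycle must be below this fraction of the inflow volume
#'   before the run counts as periodic.
#' @return A `solver_settings` list.
#' @export
solver_settings <- function(dx = 0.5, cfl = 0.9, max_cycles = 20L,
                            tol = 1e-3, min_cycles = 4L, rho = 1.06,
                            mu = 0.04, gamma_profile = 9, n_store = 64L,
                            p_init = 75, visc_k = 0, visc_gate = 200,
                            lesion_refine = 2L, ramp_cycles = 2,
                            balance_tol = 0.02,
                            junction_total_pressure = TRUE) {
  stopifnot(cfl > 0, cfl <= 1, tol > 0, max_cycles >= 2, dx > 0,
            n_store > 2 * 11)
  structure(list(dx = dx, cfl = cfl, max_cycles = as.integer(max_cycles),
                 tol = tol, min_cycles = as.integer(min_cycles), rho = rho,
                 mu = mu, gamma_profile = gamma_profile,
                 n_store = as.integer(n_store), p_init = p_init,
                 visc_k = visc_k, visc_gate = visc_gate,
                 lesion_refine = as.integer(lesion_refine),
                 ramp_cycles = ramp_cycles, balance_tol = balance_tol,
                 junction_total_pressure = isTRUE(junction_total_pressure)),
            class = "solver_settings")
}

# periodic inflow waveform sampled on a fine grid (mL/s)
inflow_samples <- function(inlet, n = 512L) {
  wf <- inlet$waveform
  tt <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]  # fraction of period
  if (identical(wf$type, "half_sine")) {
    fs <- wf$systole_fraction
    peak <- wf$mean_flow * pi / (2 * fs)
    q <- ifelse(tt < fs, peak * sin(pi * tt / fs), 0)
  } else if (identical(wf$type, "table")) {
    q <- stats::approx(wf$t / inlet$period, wf$q, xout = tt, rule = 2)$y
  } else stop("unknown inflow waveform type ", wf$type)
  q
}

# Discretise the network for the C++ core. Serial (single-child) vessel
# connections are merged into one computational segment so that lesions —
# whose chains always span such connections — lie in segment interiors,
# where the scheme is conservative; only true branching junctions remain
# as coupled boundaries.
discretise_network <- function(net, settings) {
  vs <- net$vessels
  lesion <- net$disease
  ch <- if (!is.null(lesion))
    net$chains[[paste(lesion$chain, lesion$side, sep = ".")]] else NULL

  one_child <- vapply(net$junctions, function(j)
    length(j$children) == 1L, logical(1))
  serial_next <- stats::setNames(
    vapply(net$junctions[one_child], function(j) j$children[1], ""),
    vapply(net$junctions[one_child], `[[`, "", "parent"))
  serial_children <- unname(serial_next)

  # maximal serial paths, starting from vessels that are not the single
  # child of a serial connection
  heads <- setdiff(vs$id, serial_children)
  paths <- lapply(heads, function(h) {
    p <- h
    while (!is.na(serial_next[p[length(p)]]))
      p <- c(p, serial_next[[p[length(p)]]])
    p
  })
  seg_of <- stats::setNames(rep(seq_along(paths), lengths(paths)),
                            unlist(paths))

  lesion_area <- function(id, x) {  # x: local position(s) in one vessel
    i <- match(id, vs$id)
    Ad <- vs$area_prox[i] + (vs$area_dist[i] - vs$area_prox[i]) * x
    if (!is.null(ch) && id %in% ch$segments) {
      lens <- vs$length[match(ch$segments, vs$id)]
      before <- c(0, cumsum(lens))[match(id, ch$segments)]
      x_n <- (before + x * vs$length[i]) / ch$total_length
      Ad <- Ad * area_multiplier(pmin(pmax(x_n, 0), 1), lesion)
    }
    Ad
  }

  segs <- lapply(paths, function(p) {
    lens <- vs$length[match(p, vs$id)]
    L <- sum(lens)
    dxt <- settings$dx
    if (!is.null(ch) && any(p %in% ch$segments))
      dxt <- dxt / settings$lesion_refine
    n <- max(3L, as.integer(round(L / dxt)) + 1L)
    s <- seq(0, L, length.out = n)            # arc length along the path
    ends <- cumsum(lens)
    member <- findInterval(s, c(0, ends), rightmost.closed = TRUE)
    member <- pmin(member, length(p))
    local <- (s - c(0, ends)[member]) / lens[member]
    Ad <- vapply(seq_len(n), function(k)
      lesion_area(p[member[k]], local[k]), numeric(1))
    beta <- vs$beta[match(p[member], vs$id)]
    last <- p[length(p)]
    term <- last %in% net$terminals
    out <- list(dx = L / (n - 1L), Ad = Ad, beta = beta,
                terminal = term, members = p, lengths = lens)
    if (term) {
      o <- net$outlets[[last]]
      out$R1 <- o$R1 * MMHG; out$R2 <- o$R2 * MMHG
      out$C <- o$C / MMHG;   out$pout <- o$p_out * MMHG
    }
    out
  })

  # branching junctions in segment space: parent segment is the one whose
  # path ends at the junction parent vessel
  branching <- net$junctions[!one_child]
  jx <- lapply(branching, function(j)
    as.integer(c(seg_of[[j$parent]],
                 vapply(j$children, function(cid) seg_of[[cid]],
                        numeric(1))) - 1L))
  list(segs = segs, junctions = jx, seg_of = seg_of)
}

# site table with 0-based (segment, node) indices for the C++ core
site_index <- function(net, disc) {
  s <- net$sites
  vapply(seq_len(nrow(s)), function(k) {
    si <- disc$seg_of[[s$vessel[k]]]
    seg <- disc$segs[[si]]
    im <- match(s$vessel[k], seg$members)
    pos_cm <- c(0, cumsum(seg$lengths))[im] + s$position[k] * seg$lengths[im]
    node <- as.integer(round(pos_cm / seg$dx))
    c(si - 1L, node, as.integer(s$quantity[k] == "pressure"))
  }, integer(3)) |> t()
}

#' Simulate pulse-wave propagation to a periodic state
#'
#' Advances the nonlinear 1D blood-flow equations (mass and momentum with a
#' `sqrt(A)` tube law) from a uniform-pressure rest state until the
#' cycle-to-cycle periodicity residual at the measurement sites drops below
#' the tolerance, and returns the final converged cycle resampled to a
#' uniform grid.
#'
#' @param net an `arterial_network` (optionally carrying a lesion).
#' @param settings a [solver_settings()] object.
#' @param on_failure `"error"` (default) or `"return"`; with `"return"` a
#'   failed/unconverged run is returned with `converged = FALSE` instead of
#'   raising a condition.
#' @return A `waveform_set`: matrix of site samples over one period
#'   (pressures mmHg, flows mL/s), the period, and convergence diagnostics.
#' @export
simulate_network <- function(net, settings = solver_settings(), on_failure = "error") {
  stopifnot(inherits(net, "arterial_network"))
  disc <- discretise_network(net, settings)
  # reorder segments so the one containing the inlet root comes first
  root_seg <- disc$seg_of[[net$root]]
  ord <- order(seq_along(disc$segs) != root_seg)
  remap <- match(seq_along(disc$segs), ord)
  vx <- disc$segs[ord]
  jx <- lapply(disc$junctions, function(j) as.integer(remap[j + 1L] - 1L))
  disc$seg_of <- lapply(disc$seg_of, function(i) remap[i])
  disc$segs <- vx
  sites <- site_index(net, disc)

  sset <- list(rho = settings$rho, mu = settings$mu,
               gamma_profile = settings$gamma_profile, cfl = settings$cfl,
               tol = settings$tol, max_cycles = settings$max_cycles,
               min_cycles = settings$min_cycles,
               period = net$inlet$period, n_store = settings$n_store,
               p_ext = 0, p_init = settings$p_init * MMHG,
               visc_k = settings$visc_k, visc_gate = settings$visc_gate,
               junction_total_pressure = settings$junction_total_pressure,
               ramp_cycles = settings$ramp_cycles,
               balance_tol = settings$balance_tol,
               sites = sites)
  res <- .pw_solve(vx, jx, inflow_samples(net$inlet), sset)

  if (res$failed || !res$converged) {
    msg <- if (res$failed)
      "solver failed (negative area or unstable step)"
    else sprintf("no periodic convergence in %d cycles (residual %.3g)",
                 res$cycles, res$residual)
    if (identical(on_failure, "error"))
      stop(errorCondition(msg, class = "hemoscreen_solver_failure",
                          residual = res$residual))
  }
  nm <- paste(net$sites$name, ifelse(net$sites$side == "left", "L", "R"),
              sep = "_")
  samples <- res$samples
  colnames(samples) <- nm
  structure(list(samples = samples, period = net$inlet$period,
                 n = nrow(samples), sites = net$sites,
                 converged = res$converged, cycles = res$cycles,
                 residual = res$residual,
                 volume_balance = res$volume_balance,
                 max_junction_mass_err = res$max_junction_mass_err),
            class = "waveform_set")
}

#' @export
print.waveform_set <- function(x, ...) {
  cat("<waveform_set> ", ncol(x$samples), " series, ", x$n,
      " samples over T = ", x$period, " s; cycles = ", x$cycles,
      ", residual = ", signif(x$residual, 3), "\n", sep = "")
  invisible(x)
}

#' Cycle-to-cycle periodicity residual
#'
#' Maximum over sites and samples of the absolute difference between two
#' cycles, scaled by each site's pulse amplitude in the first cycle.
#' Zero for identical cycles.
#'
#' @param ws1,ws2 `waveform_set` objects on matching grids.
#' @return dimensionless residual.
#' @export
periodicity_residual <- function(ws1, ws2) {
  a <- ws1$samples; b <- ws2$samples
  if (!identical(dim(a), dim(b)) || !identical(colnames(a), colnames(b)))
    stop("waveform grids do not match")
  amp <- apply(a, 2, function(u) {
    d <- diff(range(u)); if (d < 1e-8) max(abs(u), 1e-8) else d
  })
  max(abs(sweep(b - a, 2, amp, "/")))
}
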