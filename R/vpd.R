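#' Variability configuration for healthy virtual subjects
#'
#' Inter-subject variability is emulated by global scale factors applied
#' to the reference network: cardiac period, inflow amplitude, vessel
#' reference areas, tube-law stiffness, outlet resistances and
#' compliances, plus a small left/right area asymmetry. Scales are drawn
#' independently and uniformly. A plausibility filter keeps only subjects
#' whose brachial pressures are physiological.
#'
#' @param t_range cardiac period band, s.
#' @param scale_width half-width of the uniform scale bands (0.2 means
#'   scales drawn from U(0.8, 1.2)).
#' @param asymmetry_width half-width of the per-side area asymmetry band.
#' @param systolic_range,diastolic_range brachial plausibility box, mmHg.
#' @param max_reject_rate abort if more than this fraction of candidate
#'   subjects fails the filter (signals mis-specified variability).
#' @return a `variability_config` list.
#' @export
variability_config <- function(t_range = c(0.7, 1.1), scale_width = 0.2,
                               asymmetry_width = 0.05,
                               systolic_range = c(90, 180),
                               diastolic_range = c(50, 100),
                               max_reject_rate = 0.5) {
  stopifnot(t_range[1] > 0, scale_width >= 0, scale_width < 1,
            asymmetry_width >= 0)
  structure(list(t_range = t_range, scale_width = scale_width,
                 asymmetry_width = asymmetry_width,
                 systolic_range = systolic_range,
                 diastolic_range = diastolic_range,
                 max_reject_rate = max_reject_rate),
            class = "variability_config")
}

draw_subject_parameters <- function(vc) {
  w <- vc$scale_width
  list(period = runif(1, vc$t_range[1], vc$t_range[2]),
       inflow_scale = runif(1, 1 - w, 1 + w),
       area_scale = runif(1, 1 - w, 1 + w),
       stiffness_scale = runif(1, 1 - w, 1 + w),
       resistance_scale = runif(1, 1 - w, 1 + w),
       compliance_scale = runif(1, 1 - w, 1 + w),
       asym_right = runif(1, 1 - vc$asymmetry_width, 1 + vc$asymmetry_width),
       asym_left = runif(1, 1 - vc$asymmetry_width, 1 + vc$asymmetry_width))
}

# apply subject scale factors to the reference network
subject_network <- function(net, par) {
  side <- ifelse(grepl("_r[0-9]*$", net$vessels$id), "right",
          ifelse(grepl("_l[0-9]*$", net$vessels$id), "left", "none"))
  asym <- ifelse(side == "right", par$asym_right,
          ifelse(side == "left", par$asym_left, 1))
  net$vessels$area_prox <- net$vessels$area_prox * par$area_scale * asym
  net$vessels$area_dist <- net$vessels$area_dist * par$area_scale * asym
  net$vessels$beta <- net$vessels$beta * par$stiffness_scale
  net$outlets <- lapply(net$outlets, function(o) {
    o$R1 <- o$R1 * par$resistance_scale
    o$R2 <- o$R2 * par$resistance_scale
    o$C <- o$C * par$compliance_scale
    o
  })
  net$inlet$period <- par$period
  net$inlet$waveform$mean_flow <-
    net$inlet$waveform$mean_flow * par$inflow_scale
  net$scales <- par
  net
}

passes_filter <- function(ws, vc) {
  p <- ws$samples[, "P2_R"]
  sys <- max(p); dia <- min(p)
  sys >= vc$systolic_range[1] && sys <= vc$systolic_range[2] &&
    dia >= vc$diastolic_range[1] && dia <= vc$diastolic_range[2]
}

#' Sample one healthy virtual subject
#'
#' Draws subject parameters, instantiates and simulates the network, and
#' accepts the subject only if the brachial-pressure plausibility filter
#' passes. Candidates failing the filter (or the solver) are redrawn.
#'
#' Uses R's global RNG; seed with [set.seed()].
#'
#' @param net reference `arterial_network`.
#' @param id subject id to assign.
#' @param vc a [variability_config()].
#' @param settings [solver_settings()].
#' @return a `virtual_patient` (healthy) with waveforms.
#' @export
sample_healthy_subject <- function(net, id = 1L,
                                   vc = variability_config(),
                                   settings = solver_settings()) {
  tries <- 0L; fails <- 0L
  repeat {
    tries <- tries + 1L
    par <- draw_subject_parameters(vc)
    snet <- subject_network(net, par)
    ws <- tryCatch(simulate_network(snet, settings),
                   hemoscreen_solver_failure = function(e) NULL)
    if (!is.null(ws) && passes_filter(ws, vc)) {
      return(structure(list(id = as.integer(id), parameters = par,
                            label = "healthy", disease = NULL,
                            waveforms = ws, rejected_draws = tries - 1L),
                       class = "virtual_patient"))
    }
    fails <- fails + 1L
    if (tries >= 20L && fails / tries > vc$max_reject_rate)
      stop("subject rejection rate ", signif(fails / tries, 2),
           " exceeds the configured cap; variability is mis-specified")
  }
}

#' Generate a virtual patient database
#'
#' For `form = "none"` returns `n` healthy subjects. For a disease form,
#' every returned patient is the diseased twin of a healthy subject: it
#' shares the subject's parameters exactly, carries a freshly sampled
#' lesion on the form's chain, and is re-simulated. The healthy twins are
#' returned alongside, so downstream dataset assembly can enforce twin
#' exclusivity. Subjects whose diseased simulation fails are dropped and
#' resampled (count capped at 5% of `n`).
#'
#' @param net reference `arterial_network`.
#' @param n number of (twin pairs of) patients.
#' @param form `"none"`, `"CAS"`, `"SAS"`, `"PAD"`, `"AAA"`, `"AAA-L"`.
#' @param seed integer seed for this database.
#' @param vc a [variability_config()].
#' @param settings [solver_settings()].
#' @param severity_bounds optional severity band override.
#' @param healthy optional pre-generated healthy cohort (list of
#'   `virtual_patient`) to reuse as twins; must have length >= `n`.
#' @return list with elements `healthy` (list, length n; empty for
#'   `form = "none"` inputs reused) and `diseased` (list, length n; `NULL`
#'   for `form = "none"`), plus `n_resampled`.
#' @export
generate_vpd <- function(net, n, form = "none", seed = 1L,
                         vc = variability_config(),
                         settings = solver_settings(),
                         severity_bounds = NULL, healthy = NULL) {
  stopifnot(n >= 1)
  form <- match.arg(form, c("none", "CAS", "SAS", "PAD", "AAA", "AAA-L"))
  info <- if (form == "none") NULL else disease_form_info(form)
  seeds <- spawn_seeds(seed, 4L * n)
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }
  resampled <- 0L
  max_fail <- max(1L, ceiling(0.05 * n))

  healthy_out <- vector("list", n)
  diseased_out <- if (form == "none") NULL else vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      hp <- if (!is.null(healthy) && resampled == 0L && i <= length(healthy))
        healthy[[i]]
      else with_seed(next_seed(),
                     sample_healthy_subject(net, id = i, vc = vc,
                                            settings = settings))
      hp$id <- as.integer(i)
      if (form == "none") { healthy_out[[i]] <- hp; break }
      spec <- with_seed(next_seed(),
                        sample_disease(form, severity_bounds))
      dnet <- apply_disease(subject_network(net, hp$parameters), spec)
      dst <- settings
      if (info$kind == "aneurysm")
        # a compliant sac fills slowly: allow more cycles up front
        dst$max_cycles <- max(dst$max_cycles, 40L)
      dws <- tryCatch(simulate_network(dnet, dst),
                      hemoscreen_solver_failure = function(e) NULL)
      if (is.null(dws)) {
        # adaptive retry: refine the lesion chain and allow more cycles
        # before giving up on this subject
        st2 <- dst
        st2$lesion_refine <- 2L * settings$lesion_refine
        st2$max_cycles <- dst$max_cycles + 20L
        dws <- tryCatch(simulate_network(dnet, st2),
                        hemoscreen_solver_failure = function(e) NULL)
      }
      if (is.null(dws)) {
        resampled <- resampled + 1L
        if (resampled > max_fail)
          stop("more than 5% of diseased simulations failed")
        healthy <- NULL   # force fresh draws from here on
        next
      }
      healthy_out[[i]] <- hp
      diseased_out[[i]] <- structure(
        list(id = hp$id, parameters = hp$parameters, label = "diseased",
             disease = spec, waveforms = dws),
        class = "virtual_patient")
      break
    }
  }
  list(healthy = healthy_out, diseased = diseased_out,
       form = form, n_resampled = resampled, seed = seed)
}

#' Assemble an ML dataset from twin-paired pools
#'
#' Step 1: a random half of the subjects enters with their healthy record;
#' the diseased twins of the complementary half enter with their diseased
#' record (so no subject appears with both labels). Step 2: the two are
#' pooled, giving an exactly 50/50 class balance. Step 3: the pool is
#' randomly split 2/3 train / 1/3 test, or 50/25/25
#' train/validation/test when `early_stopping = TRUE`.
#'
#' For odd pool sizes the healthy half is the floor.
#'
#' @param healthy,diseased equal-length twin-paired lists of
#'   `virtual_patient`.
#' @param seed integer seed for the split draws.
#' @param early_stopping reserve a validation partition.
#' @return an `ml_dataset`: lists `train`, `test` (and `validation`) of
#'   patients, plus the Step-2 `pool`.
#' @export
assemble_ml_dataset <- function(healthy, diseased, seed = 1L,
                                early_stopping = FALSE) {
  n <- length(healthy)
  stopifnot(n == length(diseased), n >= 2)
  hid <- vapply(healthy, `[[`, NA_integer_, "id")
  did <- vapply(diseased, `[[`, NA_integer_, "id")
  if (!identical(sort(hid), sort(did)))
    stop("pools are not twin-paired")
  with_seed(seed, {
    h_half <- sort(sample.int(n, floor(n / 2)))
    pool <- c(healthy[h_half], diseased[-h_half])
    m <- length(pool)
    perm <- sample.int(m)
    if (early_stopping) {
      n_tr <- floor(0.5 * m); n_va <- floor(0.25 * m)
      tr <- perm[seq_len(n_tr)]
      va <- perm[n_tr + seq_len(n_va)]
      te <- perm[(n_tr + n_va + 1):m]
      out <- list(train = pool[tr], validation = pool[va], test = pool[te])
    } else {
      n_te <- floor(m / 3)
      te <- perm[seq_len(n_te)]
      out <- list(train = pool[-te], test = pool[te])
    }
    out$pool <- pool
    out$seed <- seed
    out$early_stopping <- early_stopping
    class(out) <- "ml_dataset"
    check_twin_exclusivity(out)
    out
  })
}

check_twin_exclusivity <- function(ds) {
  ids <- vapply(ds$pool, `[[`, NA_integer_, "id")
  lab <- vapply(ds$pool, `[[`, "", "label")
  both <- tapply(lab, ids, function(x) length(unique(x)))
  if (any(both > 1)) stop("twin leakage: a subject appears with both labels")
  invisible(ds)
}

#' Five random resplits of one assembled pool
#'
#' All five datasets share the identical Step-2 pool; only the Step-3
#' train/test split differs (independent seeds). This mirrors validation
#' by repeated random resplitting, not disjoint-fold cross-validation.
#'
#' @param healthy,diseased twin-paired pools.
#' @param seed master seed; the Step-1 halving uses it directly and the
#'   five resplits use derived seeds.
#' @param folds number of resplits.
#' @param early_stopping propagate a validation partition.
#' @return list of `ml_dataset`s sharing one pool.
#' @export
fivefold_resplits <- function(healthy, diseased, seed = 1L, folds = 5L,
                              early_stopping = FALSE) {
  base <- assemble_ml_dataset(healthy, diseased, seed = seed,
                              early_stopping = early_stopping)
  sub <- spawn_seeds(seed, folds, stream = 1L)
  lapply(seq_len(folds), function(k)
    resplit_pool(base$pool, seed = sub[k], early_stopping = early_stopping))
}

# Step-3 only: resplit an existing Step-2 pool
resplit_pool <- function(pool, seed, early_stopping = FALSE) {
  m <- length(pool)
  with_seed(seed, {
    perm <- sample.int(m)
    if (early_stopping) {
      n_tr <- floor(0.5 * m); n_va <- floor(0.25 * m)
      out <- list(train = pool[perm[seq_len(n_tr)]],
                  validation = pool[perm[n_tr + seq_len(n_va)]],
                  test = pool[perm[(n_tr + n_va + 1):m]])
    } else {
      n_te <- floor(m / 3)
      out <- list(train = pool[perm[-seq_len(n_te)]],
                  test = pool[perm[seq_len(n_te)]])
    }
    out$pool <- pool
    out$seed <- seed
    out$early_stopping <- early_stopping
    class(out) <- "ml_dataset"
    out
  })
}
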