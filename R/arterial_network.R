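#' Load an arterial network from a structured config
#'
#' Reads a YAML (or already-parsed list) description of an arterial network:
#' vessel segments with tapering reference areas and tube-law stiffness,
#' parent-to-children connectivity, a single periodic-inflow inlet,
#' three-element Windkessel outlets on every terminal vessel, named disease
#' chains, and pressure/flow measurement sites. The packaged default
#' (`default_network()`) is a bilaterally symmetric reduced systemic network
#' hosting the four disease chains (carotid, subclavian, iliac-femoral-
#' popliteal, abdominal aortic) and six bilateral measurement sites.
#'
#' Units in the config are annotated explicitly: lengths in cm, areas in
#' cm^2, tube-law coefficient beta in dyn/cm, resistances in mmHg s/mL,
#' compliances in mL/mmHg, pressures in mmHg, time in s.
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @return An object of class `arterial_network`.
#' @export
load_network <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (fld in c("vessels", "junctions", "inlet", "outlets", "chains", "sites"))
    if (is.null(config[[fld]]))
      stop("network config is missing the '", fld, "' block")

  vessels <- do.call(rbind, lapply(config$vessels, function(v)
    data.frame(id = v$id, length = v$length, area_prox = v$area_prox,
               area_dist = v$area_dist, beta = v$beta,
               stringsAsFactors = FALSE)))
  if (anyDuplicated(vessels$id)) stop("duplicate vessel ids")
  if (any(vessels$length <= 0)) stop("vessel lengths must be positive")
  if (any(vessels$area_prox <= 0) || any(vessels$area_dist <= 0))
    stop("reference areas must be positive")
  if (any(vessels$beta <= 0)) stop("tube-law coefficients must be positive")

  junctions <- lapply(config$junctions, function(j)
    list(parent = j$parent, children = unlist(j$children)))
  ids <- vessels$id
  for (j in junctions) {
    if (!j$parent %in% ids) stop("junction parent '", j$parent, "' is not a vessel")
    miss <- setdiff(j$children, ids)
    if (length(miss)) stop("junction child '", miss[1], "' is not a vessel")
  }

  children <- unlist(lapply(junctions, `[[`, "children"))
  if (anyDuplicated(children)) stop("a vessel has more than one parent")
  parents <- vapply(junctions, `[[`, "", "parent")
  if (anyDuplicated(parents)) stop("a vessel appears as parent in two junctions")
  roots <- setdiff(ids, children)
  if (length(roots) != 1L)
    stop("network must have exactly one root (inlet) vessel; found: ",
         paste(roots, collapse = ", "))
  inlet <- config$inlet
  if (!identical(inlet$vessel, roots))
    stop("inlet vessel '", inlet$vessel, "' is not the root of the tree")
  if (is.null(inlet$period) || inlet$period <= 0)
    stop("inlet must declare a positive cardiac period")

  # connectivity: walk from root; every vessel must be reached (no cycles in
  # a tree with unique parents and a single root, but orphan subgraphs are
  # impossible only if all vessels are reachable)
  reach <- roots
  repeat {
    nxt <- unlist(lapply(junctions, function(j)
      if (j$parent %in% reach) j$children else NULL))
    nxt <- setdiff(nxt, reach)
    if (!length(nxt)) break
    reach <- c(reach, nxt)
  }
  if (length(setdiff(ids, reach)))
    stop("disconnected vessels: ", paste(setdiff(ids, reach), collapse = ", "))

  terminals <- setdiff(ids, parents)
  for (tv in terminals)
    if (is.null(config$outlets[[tv]]))
      stop("terminal vessel '", tv, "' has no outlet")
  outlets <- lapply(config$outlets, function(o) {
    o <- o[c("R1", "R2", "C", "p_out")]
    if (o$R1 < 0 || o$R2 < 0) stop("outlet resistances must be non-negative")
    if (o$C <= 0) stop("outlet compliance must be positive")
    o
  })
  names(outlets) <- names(config$outlets)

  chains <- lapply(config$chains, function(ch) {
    segs <- unlist(ch$segments)
    miss <- setdiff(segs, ids)
    if (length(miss))
      stop("chain ", ch$name, " references unknown segment '", miss[1], "'")
    # contiguity: each consecutive pair must be a parent->child edge
    if (length(segs) > 1) {
      for (k in seq_len(length(segs) - 1)) {
        ok <- any(vapply(junctions, function(j)
          j$parent == segs[k] && segs[k + 1] %in% j$children, logical(1)))
        if (!ok) stop("chain ", ch$name, " is not contiguous at '", segs[k], "'")
      }
    }
    tl <- sum(vessels$length[match(segs, vessels$id)])
    list(name = ch$name, side = ch$side, segments = segs, total_length = tl)
  })
  names(chains) <- vapply(chains, function(ch)
    paste(ch$name, ch$side, sep = "."), "")

  sites <- do.call(rbind, lapply(config$sites, function(s)
    data.frame(name = s$name, side = s$side, vessel = s$vessel,
               position = s$position, quantity = s$quantity,
               stringsAsFactors = FALSE)))
  if (any(!sites$vessel %in% ids))
    stop("measurement site on unknown vessel")
  if (any(sites$position < 0 | sites$position > 1))
    stop("site positions must lie in [0, 1]")
  badq <- (grepl("^P", sites$name) & sites$quantity != "pressure") |
          (grepl("^Q", sites$name) & sites$quantity != "flow")
  if (any(badq)) stop("site quantity does not match site name")

  net <- structure(list(
    vessels = vessels, junctions = junctions, inlet = inlet,
    outlets = outlets, chains = chains, sites = sites,
    terminals = terminals, root = roots, disease = NULL,
    scales = list()), class = "arterial_network")
  net
}

#' Packaged default reduced arterial network
#'
#' @return An `arterial_network` with all four disease chains (CA, SA, PA on
#'   both sides; AA midline) and the six bilateral measurement sites
#'   (carotid/brachial/radial pressure; carotid/brachial/femoral flow).
#' @export
default_network <- function() {
  load_network(system.file("extdata", "network_default.yaml",
                           package = "hemoscreen", mustWork = TRUE))
}

#' @export
print.arterial_network <- function(x, ...) {
  cat("<arterial_network> ", nrow(x$vessels), " vessels, ",
      length(x$junctions), " junctions, ",
      length(x$terminals), " outlets, ",
      length(x$chains), " chains, ",
      nrow(x$sites), " measurement sites\n", sep = "")
  if (!is.null(x$disease))
    cat("  lesion: ", x$disease$kind, " on ", x$disease$chain, ".",
        x$disease$side, " (S = ", signif(x$disease$severity, 4), ")\n", sep = "")
  invisible(x)
}

#' Map a normalised chain coordinate to (segment, local position)
#'
#' The chain coordinate `x_n` in [0, 1] is proportional to arc length along
#' the ordered segments of a disease chain. Segment boundaries map to the
#' downstream segment's local position 0 (deterministic tie-break).
#'
#' @param net an `arterial_network`.
#' @param chain chain name (`"CA"`, `"SA"`, `"PA"`, `"AA"`).
#' @param side `"right"`, `"left"`, or `"none"` (AA).
#' @param x_n normalised coordinate(s) in [0, 1].
#' @return data.frame with columns `segment` and `local` (fraction of the
#'   segment's own length).
#' @export
chain_coordinate <- function(net, chain, side = "none", x_n) {
  ch <- net$chains[[paste(chain, side, sep = ".")]]
  if (is.null(ch)) stop("unknown chain ", chain, ".", side)
  if (any(x_n < 0 | x_n > 1)) stop("x_n must lie in [0, 1]")
  lens <- net$vessels$length[match(ch$segments, net$vessels$id)]
  ends <- cumsum(lens)
  s <- x_n * ch$total_length
  # boundary tie-break: a coordinate equal to a segment end belongs to the
  # next (downstream) segment, except at the chain's far end
  idx <- findInterval(s, c(0, ends), rightmost.closed = TRUE,
                      left.open = FALSE)
  idx <- pmin(idx, length(lens))
  start <- c(0, ends)[idx]
  data.frame(segment = ch$segments[idx],
             local = (s - start) / lens[idx],
             stringsAsFactors = FALSE)
}

#' Reference area profile of a vessel, including any applied lesion
#'
#' Linear proximal-to-distal taper multiplied by the lesion's normalised
#' area profile where the vessel belongs to a diseased chain.
#'
#' @param net an `arterial_network`.
#' @param vessel vessel id.
#' @param x local positions in [0, 1] along the vessel.
#' @return reference areas (cm^2) at `x`.
#' @export
vessel_area_profile <- function(net, vessel, x) {
  i <- match(vessel, net$vessels$id)
  if (is.na(i)) stop("unknown vessel ", vessel)
  A <- net$vessels$area_prox[i] +
    (net$vessels$area_dist[i] - net$vessels$area_prox[i]) * x
  if (!is.null(net$disease)) {
    spec <- net$disease
    ch <- net$chains[[paste(spec$chain, spec$side, sep = ".")]]
    if (vessel %in% ch$segments) {
      lens <- net$vessels$length[match(ch$segments, net$vessels$id)]
      before <- c(0, cumsum(lens))[match(vessel, ch$segments)]
      x_n <- (before + x * net$vessels$length[i]) / ch$total_length
      A <- A * area_multiplier(x_n, spec)
    }
  }
  A
}
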