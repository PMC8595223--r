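#' Construct and validate a disease specification
#'
#' A lesion is a cosine-shaped perturbation of the reference area along one
#' disease chain: a stenosis multiplies the area by down to `1 - S` at the
#' lesion midpoint, an aneurysm by up to `1 + S`. The profile starts at
#' normalised chain coordinate `b`, ends at `e`, equals 1 at both ends, and
#' is symmetric about `(b + e)/2`.
#'
#' @param kind `"stenosis"` or `"aneurysm"`.
#' @param severity severity S; stenoses in [0.5, 0.95], aneurysms in the
#'   configured band (`severity_bounds`).
#' @param b,e normalised start/end locations, `0.1 <= b < e <= 0.9`,
#'   `e - b >= 0.1`.
#' @param r reference location used by the sequential sampler (optional for
#'   hand-built specs).
#' @param chain chain name (`"CA"`, `"SA"`, `"PA"`, `"AA"`).
#' @param side `"right"`, `"left"` or `"none"`.
#' @param severity_bounds admissible severity band used for validation.
#' @return A `disease_spec` object.
#' @export
disease_spec <- function(kind, severity, b, e, chain, side = "none",
                         r = (b + e) / 2,
                         severity_bounds = default_severity_bounds(kind)) {
  kind <- match.arg(kind, c("stenosis", "aneurysm"))
  if (!(b >= 0.1 - 1e-12 && b < e && e <= 0.9 + 1e-12))
    stop("lesion extent must satisfy 0.1 <= b < e <= 0.9")
  if (e - b < 0.1 - 1e-12)
    stop("lesion must span at least 10% of the chain length")
  if (severity < severity_bounds[1] - 1e-12 ||
      severity > severity_bounds[2] + 1e-12)
    stop("severity ", severity, " outside the admissible band [",
         severity_bounds[1], ", ", severity_bounds[2], "]")
  if (kind == "stenosis" && severity > 0.95 + 1e-12)
    stop("stenosis severity above 0.95 gives a near-closed lumen")
  structure(list(kind = kind, severity = severity, b = b, e = e, r = r,
                 chain = chain, side = side),
            class = "disease_spec")
}

#' Default severity bands per lesion kind
#'
#' Stenoses: 0.50-0.95 (haemodynamically significant to near-occlusion).
#' Aneurysms: 7.13-25.93 (4-6 cm AAA diameters against the reference
#' abdominal aortic areas); the low-severity variant uses 3.0-7.0.
#'
#' @param kind `"stenosis"` or `"aneurysm"`.
#' @param low_severity use the low-severity aneurysm band.
#' @return numeric length-2 vector.
#' @export
default_severity_bounds <- function(kind, low_severity = FALSE) {
  if (kind == "stenosis") return(c(0.5, 0.95))
  if (low_severity) c(3.0, 7.0) else c(7.13, 25.93)
}

#' Normalised area multiplier of a lesion
#'
#' Evaluates the cosine lesion profile at normalised chain coordinates:
#' 1 outside `[b, e]`; inside, `1 -+ S/2 +- (S/2) cos(2 pi (x_n - b)/(e - b))`
#' with the extremum `1 - S` (stenosis) or `1 + S` (aneurysm) at the lesion
#' midpoint, continuous with value 1 at `b` and `e`.
#'
#' @param x_n normalised chain coordinate(s) in [0, 1].
#' @param spec a `disease_spec`.
#' @return dimensionless area multipliers (strictly positive).
#' @export
area_multiplier <- function(x_n, spec) {
  if (any(x_n < 0 | x_n > 1)) stop("x_n must lie in [0, 1]")
  s <- spec$severity
  sgn <- if (spec$kind == "stenosis") -1 else 1
  inside <- x_n >= spec$b & x_n <= spec$e
  out <- rep(1, length(x_n))
  xi <- x_n[inside]
  out[inside] <- (1 + sgn * s / 2) -
    sgn * (s / 2) * cos(2 * pi * (xi - spec$b) / (spec$e - spec$b))
  out
}

#' Sequentially sample a disease specification
#'
#' Draws the lesion parameters from uniform distributions in sequence:
#' reference location `r ~ U(0.2, 0.8)`, start `b ~ U(0.1, r - 0.05)`,
#' end `e ~ U(r + 0.05, 0.9)` (which enforces a minimum lesion length of
#' 10% of the chain), then severity `S ~ U(bounds)`. For the bilateral
#' chains (CA, SA, PA) the side is drawn left/right with equal probability;
#' the abdominal aortic chain is midline.
#'
#' Uses R's global RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param form disease form: `"CAS"`, `"SAS"`, `"PAD"`, `"AAA"`, `"AAA-L"`.
#' @param severity_bounds override the severity band.
#' @return A `disease_spec`.
#' @export
sample_disease <- function(form, severity_bounds = NULL) {
  form <- match.arg(form, c("CAS", "SAS", "PAD", "AAA", "AAA-L"))
  info <- disease_form_info(form)
  if (is.null(severity_bounds)) severity_bounds <- info$bounds
  if (severity_bounds[1] >= severity_bounds[2])
    stop("degenerate severity bounds")
  r <- stats::runif(1, 0.2, 0.8)
  b <- stats::runif(1, 0.1, r - 0.05)
  e <- stats::runif(1, r + 0.05, 0.9)
  s <- stats::runif(1, severity_bounds[1], severity_bounds[2])
  side <- if (info$chain == "AA") "none" else
    sample(c("right", "left"), 1)
  disease_spec(info$kind, s, b, e, chain = info$chain, side = side, r = r,
               severity_bounds = severity_bounds)
}

disease_form_info <- function(form) {
  switch(form,
    "CAS"   = list(kind = "stenosis", chain = "CA",
                   bounds = default_severity_bounds("stenosis")),
    "SAS"   = list(kind = "stenosis", chain = "SA",
                   bounds = default_severity_bounds("stenosis")),
    "PAD"   = list(kind = "stenosis", chain = "PA",
                   bounds = default_severity_bounds("stenosis")),
    "AAA"   = list(kind = "aneurysm", chain = "AA",
                   bounds = default_severity_bounds("aneurysm")),
    "AAA-L" = list(kind = "aneurysm", chain = "AA",
                   bounds = default_severity_bounds("aneurysm", TRUE)),
    stop("unknown disease form ", form))
}

#' Apply a lesion to an arterial network
#'
#' Returns a copy of the network whose named chain carries the lesion's
#' area profile composed onto the chain segments' reference areas (the
#' composition is evaluated when the network is discretised for
#' simulation, and by [vessel_area_profile()]). All other segments are
#' untouched.
#'
#' @param net an `arterial_network`.
#' @param spec a `disease_spec`.
#' @return A diseased `arterial_network`.
#' @export
apply_disease <- function(net, spec) {
  stopifnot(inherits(net, "arterial_network"), inherits(spec, "disease_spec"))
  key <- paste(spec$chain, spec$side, sep = ".")
  if (is.null(net$chains[[key]]))
    stop("network has no chain ", key)
  if (!is.null(net$disease))
    stop("network already carries a lesion; one lesion per patient")
  net$disease <- spec
  net
}
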