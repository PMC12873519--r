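#' Stacked-conduit widening profile
#'
#' Describes a single tip-to-base xylem conduit column whose lumen diameter
#' widens with distance from the organ tip as a power law,
#' \eqn{D(x) = d_{ref} (x/x_{ref})^b}. The column is discretized into
#' cylindrical elements for Poiseuille resistance sums.
#'
#' @param d_ref Lumen diameter (um) at the reference distance `x_ref`.
#' @param x_ref Reference distance from the tip (mm).
#' @param b Dimensionless widening exponent (>= 0). `b = 0` is a
#'   constant-diameter tube; about 0.2 is typical of stems and about 0.4 of
#'   leaves.
#' @param x_min Distance from the tip of the first (distal-most) element (mm).
#' @param element_length Length of each cylindrical element (mm).
#' @param viscosity Dynamic viscosity, in whatever units the caller works in
#'   (resistances are then in matching arbitrary units). Default 1.
#'
#' @return An object of class `conduit_profile`.
#' @examples
#' cp <- conduit_profile(d_ref = 10, x_ref = 1, b = 0.2)
#' diameter_at(cp, 32) # 32^0.2 == 2, so 20 um
#' @export
conduit_profile <- function(d_ref, x_ref = 1, b = 0.2, x_min = 1,
                            element_length = 1, viscosity = 1) {
  for (nm in c("d_ref", "x_ref", "x_min", "element_length", "viscosity")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
  }
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b < 0)
    stop("'b' must be a single non-negative number", call. = FALSE)
  structure(
    list(d_ref = d_ref, x_ref = x_ref, b = b, x_min = x_min,
         element_length = element_length, viscosity = viscosity),
    class = "conduit_profile"
  )
}

#' @export
print.conduit_profile <- function(x, ...) {
  cat("Power-law conduit widening profile: D(x) = ", x$d_ref,
      " * (x/", x$x_ref, ")^", x$b, "  [um, x in mm]\n", sep = "")
  cat("  elements: length ", x$element_length, " mm starting at x_min = ",
      x$x_min, " mm; viscosity = ", x$viscosity, "\n", sep = "")
  invisible(x)
}

#' Conduit lumen diameter at a distance from the tip
#'
#' @param profile A [conduit_profile()].
#' @param x Distance(s) from the tip (mm); must be `>= profile$x_min`.
#' @return Diameter(s) in um: `d_ref * (x / x_ref)^b`.
#' @export
diameter_at <- function(profile, x) {
  stopifnot(inherits(profile, "conduit_profile"))
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric", call. = FALSE)
  if (any(x <= 0))
    stop("distance from tip must be positive; got x <= 0", call. = FALSE)
  if (any(x < profile$x_min))
    stop(sprintf("distance from tip must be >= x_min = %g mm", profile$x_min),
         call. = FALSE)
  profile$d_ref * (x / profile$x_ref)^profile$b
}

#' Poiseuille resistance of one cylindrical element
#'
#' Laminar-flow (Hagen-Poiseuille) resistance of a cylinder:
#' \eqn{R = 128 \mu \ell / (\pi d^4)}. Resistance falls with the fourth power
#' of lumen diameter, which is why modest widening buffers pathlength costs.
#'
#' @param d Lumen diameter (um).
#' @param length Element length (mm).
#' @param viscosity Dynamic viscosity (default 1; arbitrary units).
#' @return Resistance in matching arbitrary units.
#' @export
segment_resistance <- function(d, length, viscosity = 1) {
  if (any(!is.finite(d)) || any(d <= 0))
    stop("diameter must be positive", call. = FALSE)
  if (any(!is.finite(length)) || any(length <= 0))
    stop("length must be positive", call. = FALSE)
  if (!is.finite(viscosity) || viscosity <= 0)
    stop("viscosity must be positive", call. = FALSE)
  128 * viscosity * length / (pi * d^4)
}

#' Cumulative Poiseuille resistance along a widening conduit column
#'
#' Sums element resistances from the tip down to pathlength `L`, evaluating
#' each element's diameter at its midpoint (the midpoint rule keeps the sum
#' finite near the tip even when `4 b > 1`). With `b = 0` the result is exactly
#' linear in distance; with leaf-like widening (`b ~ 0.4`) the cumulative
#' resistance saturates, i.e. is nearly independent of pathlength.
#'
#' @param profile A [conduit_profile()].
#' @param L Total pathlength from the tip (mm); must allow at least one
#'   whole element beyond `x_min`.
#' @return A data frame of class `resistance_profile` with columns
#'   `distance_mm` (outer edge of each element) and `cumulative_resistance`.
#' @seealso [resistance_integral()] for the analytic continuum limit.
#' @export
cumulative_resistance <- function(profile, L) {
  stopifnot(inherits(profile, "conduit_profile"))
  el <- profile$element_length
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L))
    stop("'L' must be a single finite number", call. = FALSE)
  if (L < profile$x_min + el)
    stop(sprintf("pathlength L = %g mm is shorter than one element beyond x_min (need >= %g mm)",
                 L, profile$x_min + el), call. = FALSE)
  n <- floor((L - profile$x_min) / el)
  edges <- profile$x_min + el * seq_len(n)
  mids  <- edges - el / 2
  r <- segment_resistance(diameter_at(profile, mids), el, profile$viscosity)
  out <- data.frame(distance_mm = edges, cumulative_resistance = cumsum(r))
  class(out) <- c("resistance_profile", "data.frame")
  out
}

#' Analytic cumulative resistance of the widening column
#'
#' Continuum limit of [cumulative_resistance()]:
#' \deqn{R(L) = \int_{x_{min}}^{L} \frac{128\mu}{\pi D(x)^4} dx
#'   = \frac{128\mu\, x_{ref}^{4b}}{\pi d_{ref}^4}
#'     \cdot \frac{L^{1-4b} - x_{min}^{1-4b}}{1-4b}}
#' (with the logarithmic form at \eqn{4b = 1}).
#'
#' @inheritParams cumulative_resistance
#' @return The integral resistance from `x_min` to `L`.
#' @export
resistance_integral <- function(profile, L) {
  stopifnot(inherits(profile, "conduit_profile"))
  K <- 128 * profile$viscosity * profile$x_ref^(4 * profile$b) /
    (pi * profile$d_ref^4)
  a <- 1 - 4 * profile$b
  if (abs(a) < 1e-12) K * log(L / profile$x_min)
  else K * (L^a - profile$x_min^a) / a
}

#' Fourth-power conductance ratio of two conduits
#'
#' For equal-length cylindrical conduits under Poiseuille flow, conductance
#' scales as diameter to the fourth power, so the ratio of the second
#' conduit's conductance to the first's is `(d2/d1)^4`. Doubling the diameter
#' (10 to 20 um) yields a 16-fold conductance difference.
#'
#' @param d1,d2 Lumen diameters (um), both positive.
#' @return Dimensionless conductance ratio `(d2/d1)^4`.
#' @export
conductance_ratio <- function(d1, d2) {
  if (any(!is.finite(c(d1, d2))) || any(c(d1, d2) <= 0))
    stop("diameters must be positive", call. = FALSE)
  (d2 / d1)^4
}

#' Tip-diameter-vs-height power law
#'
#' Terminal twig conduit diameter as a function of plant height,
#' \eqn{D(H) = d_{ref} (H/h_{ref})^g}: the "ultra-widening" of terminal
#' conduits that can keep whole-path resistance constant during height growth.
#'
#' @param d_ref Tip diameter (um) at the reference height.
#' @param h_ref Reference height (m).
#' @param g Tip-diameter-vs-height exponent.
#' @return An object of class `tip_widening_law`.
#' @export
tip_widening_law <- function(d_ref = 10, h_ref = 1, g = 0.26) {
  if (!is.finite(d_ref) || d_ref <= 0) stop("'d_ref' must be positive", call. = FALSE)
  if (!is.finite(h_ref) || h_ref <= 0) stop("'h_ref' must be positive", call. = FALSE)
  if (!is.finite(g)) stop("'g' must be finite", call. = FALSE)
  structure(list(d_ref = d_ref, h_ref = h_ref, g = g),
            class = "tip_widening_law")
}

#' @export
print.tip_widening_law <- function(x, ...) {
  cat("Tip-diameter widening law: D(H) = ", x$d_ref, " * (H/", x$h_ref,
      ")^", x$g, "  [um, H in m]\n", sep = "")
  invisible(x)
}

#' Terminal conduit diameter at a given plant height
#'
#' @param law A [tip_widening_law()].
#' @param H Plant height(s) in m, positive.
#' @return Tip diameter(s) in um.
#' @examples
#' law <- tip_widening_law(d_ref = 10, h_ref = 1, g = 0.26)
#' tip_diameter_at_height(law, c(10, 20)) # ~18.2, ~21.8 um
#' @export
tip_diameter_at_height <- function(law, H) {
  stopifnot(inherits(law, "tip_widening_law"))
  if (any(!is.finite(H)) || any(H <= 0))
    stop("height must be positive", call. = FALSE)
  law$d_ref * (H / law$h_ref)^law$g
}

#' Exponent implied by two (height, tip diameter) anchor points
#'
#' Solves `d = d_ref * (H/h_ref)^g` for `g` through two observed pairs:
#' `g = log(d2/d1) / log(H2/H1)`.
#'
#' @param anchor1,anchor2 Numeric length-2 vectors `c(height_m, diameter_um)`.
#' @return The implied exponent.
#' @examples
#' implied_widening_exponent(c(1, 10), c(20, 21.8)) # ~0.26
#' @export
implied_widening_exponent <- function(anchor1, anchor2) {
  a1 <- as.numeric(anchor1); a2 <- as.numeric(anchor2)
  if (length(a1) != 2L || length(a2) != 2L)
    stop("anchors must be (height, diameter) pairs", call. = FALSE)
  if (any(!is.finite(c(a1, a2))) || any(c(a1, a2) <= 0))
    stop("heights and diameters must be positive", call. = FALSE)
  if (a1[1] == a2[1])
    stop("anchor heights must be distinct", call. = FALSE)
  log(a2[2] / a1[2]) / log(a2[1] / a1[1])
}

#' Tip diameter that balances cumulative resistance across heights
#'
#' Under a model family in which the unbuffered cumulative resistance of the
#' conductive path grows as \eqn{R(H, d) \propto H^c / d^4} (the whole
#' widening profile scaling multiplicatively with the tip diameter `d`),
#' finds the tip diameter at height `H` giving the same cumulative resistance
#' as the anchor individual. Solved by deterministic bisection on `log10(d)`
#' over `[d_ref/100, 100 d_ref]` to relative tolerance 1e-9; the closed form
#' is \eqn{d = d_{ref} (H/h_{ref})^{c/4}}. With `c = 1.04` the balanced tip
#' diameters at 10 m and 20 m anchored at (1 m, 10 um) are 18.2 and 21.8 um.
#'
#' @param c_exponent Height exponent of unbuffered resistance (>= 0).
#' @param H Target height (m).
#' @param h_ref,d_ref Anchor height (m) and tip diameter (um).
#' @return Balanced tip diameter (um) at height `H`.
#' @export
balance_tip_diameter <- function(c_exponent, H, h_ref = 1, d_ref = 10) {
  if (!is.finite(c_exponent) || c_exponent < 0)
    stop("'c_exponent' must be non-negative", call. = FALSE)
  if (!is.finite(H) || H <= 0) stop("'H' must be positive", call. = FALSE)
  if (!is.finite(h_ref) || h_ref <= 0 || !is.finite(d_ref) || d_ref <= 0)
    stop("anchor must be positive", call. = FALSE)
  # R(H, d) = H^c / d^4 on a log10 scale; root of f(ld) = log10 R(H, 10^ld) - log10 R(h_ref, d_ref)
  target <- c_exponent * log10(h_ref) - 4 * log10(d_ref)
  f <- function(ld) c_exponent * log10(H) - 4 * ld - target
  lo <- log10(d_ref) - 2
  hi <- log10(d_ref) + 2
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop(sprintf(
      "cannot bracket balanced diameter in [%g, %g] um (f(lo) = %g, f(hi) = %g); c = %g, H = %g",
      10^lo, 10^hi, flo, fhi, c_exponent, H), call. = FALSE)
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  10^root
}
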