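#' Count points in systematic-random optical dissectors
#'
#' Applies an optical-fractionator counting design to a point population:
#' sections of the measured thickness tile the z-axis and every
#' \code{1/ssf}-th is sampled (random start); within each sampled section a
#' systematic-random grid of counting frames is placed (random offset drawn
#' from \code{seed}); a point is counted iff it falls inside a frame
#' respecting the forbidden-line rule (left and bottom edges exclude) and
#' within the dissector height after the guard zone.
#'
#' @param points n x 3 matrix of positions (um), e.g. from
#'   \code{\link{generatePointPopulation}}.
#' @param design a \code{\linkS4class{FractionatorDesign}}.
#' @param seed RNG seed for the systematic-random offsets.
#' @return named integer vector of per-sampled-section counts Q_i (names =
#'   section index).
#' @export
countInDissectors <- function(points, design, seed = 1L) {
  stopifnot(is(design, "FractionatorDesign"))
  validObject(design)
  if (is(points, "GroundTruth")) points <- points@points
  set.seed(seed)
  t <- design@sectionThickness
  k <- max(1L, as.integer(round(1 / design@ssf)))
  s0 <- sample.int(k, 1) - 1L
  off <- stats::runif(2) * design@grid
  zoff <- design@guardZone
  h <- design@dissectorHeight

  if (nrow(points) == 0) return(stats::setNames(integer(0), character(0)))
  sec <- floor(points[, 3] / t)
  counted <- (sec %% k) == s0
  zloc <- points[, 3] - sec * t
  inZ <- zloc > zoff & zloc <= zoff + h
  relx <- (points[, 1] - off[1]) %% design@grid[1]
  rely <- (points[, 2] - off[2]) %% design@grid[2]
  inFrame <- relx > 0 & relx <= design@frame[1] &
             rely > 0 & rely <= design@frame[2]
  ok <- counted & inZ & inFrame
  secCounted <- sort(unique(sec[counted]))
  q <- vapply(secCounted, function(s) sum(ok & sec == s), integer(1))
  stats::setNames(q, secCounted)
}

#' Optical fractionator abundance estimate
#'
#' \code{N = sum(Q) / (ssf * asf * hsf)} with \code{asf} the frame-to-grid
#' area ratio and \code{hsf} the dissector-height-to-section-thickness
#' ratio.
#'
#' @param sumQ total counted objects (or the Q_i vector, which is summed).
#' @param design a \code{\linkS4class{FractionatorDesign}}.
#' @return estimated total number N.
#' @examples
#' d <- FractionatorDesign(frame = c(50, 50), grid = c(200, 200), ssf = 1/4,
#'                         dissectorHeight = 14, sectionThickness = 23.4)
#' fractionatorEstimate(100, d)
#' @export
fractionatorEstimate <- function(sumQ, design) {
  stopifnot(is(design, "FractionatorDesign"))
  validObject(design)
  sumQ <- sum(sumQ)
  if (sumQ < 0) stop("counts must be >= 0")
  asf <- prod(design@frame) / prod(design@grid)
  hsf <- design@dissectorHeight / design@sectionThickness
  if (design@ssf <= 0 || asf <= 0 || hsf <= 0)
    stop("sampling fractions must be > 0")
  sumQ / (design@ssf * asf * hsf)
}

#' Gundersen-Jensen coefficient of error of a fractionator count
#'
#' Combines the counting noise (\code{sum(Q)}) with the systematic variance
#' of the section series (smoothness class m = 1):
#' \code{VarSRS = (3 * (A - sum(Q)) - 4 * B + C) / 240} with
#' \code{A = sum(Qi^2)}, \code{B = sum(Qi * Qi+1)},
#' \code{C = sum(Qi * Qi+2)}; \code{CE = sqrt(sum(Q) + VarSRS) / sum(Q)}.
#'
#' @param Qi per-section counts in section order (>= 3 sections).
#' @return coefficient of error (dimensionless).
#' @export
fractionatorCE <- function(Qi) {
  if (length(Qi) < 3) stop("need counts from at least 3 sections")
  sq <- sum(Qi)
  if (sq == 0) stop("CE undefined for a zero total count")
  A <- sum(Qi^2)
  B <- sum(Qi[-length(Qi)] * Qi[-1])
  C <- sum(Qi[seq_len(length(Qi) - 2)] * Qi[-(1:2)])
  varSRS <- max(0, (3 * (A - sq) - 4 * B + C) / 240)
  sqrt(sq + varSRS) / sq
}

#' Cavalieri point-counting volume estimate
#'
#' \code{V = sum(Pi) * aF * T / ssf}: points per section times area per
#' point times block advance, corrected for the slice sampling fraction.
#'
#' @param Pi per-section point counts.
#' @param design a \code{\linkS4class{CavalieriDesign}} (aF in um^2, T in
#'   um).
#' @return volume in mm^3.
#' @examples
#' cavalieriVolume(100, CavalieriDesign(1e4, 60, ssf = 1/4))
#' @export
cavalieriVolume <- function(Pi, design) {
  stopifnot(is(design, "CavalieriDesign"))
  validObject(design)
  if (any(Pi < 0)) stop("point counts must be >= 0")
  sum(Pi) * design@areaPerPoint * design@blockAdvance / design@ssf / 1e9
}

#' Systematic-random probe placement presets
#'
#' Published probe spacings for imaging probes: rats were sampled on every
#' 4th section (240-um final spacing at a 60-um block advance) at 350-um xy
#' intervals; monkeys on every 8th section (320-um spacing at 40 um) at
#' 800-um intervals.
#'
#' @param species \code{"rat"} or \code{"macaque"}.
#' @return list with \code{sectionStep}, \code{blockAdvance} (um),
#'   \code{sectionSpacing} (um) and \code{xySpacing} (um).
#' @examples
#' probePlacement("rat")$sectionSpacing
#' @export
probePlacement <- function(species = c("rat", "macaque")) {
  species <- match.arg(species)
  if (species == "rat")
    list(sectionStep = 4L, blockAdvance = 60, sectionSpacing = 4 * 60,
         xySpacing = 350)
  else
    list(sectionStep = 8L, blockAdvance = 40, sectionSpacing = 8 * 40,
         xySpacing = 800)
}
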