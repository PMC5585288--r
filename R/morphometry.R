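#' Fiber length per neuron with a ratio confidence interval
#'
#' Normalizes a fiber length density by a neuron count density, giving the
#' average fiber length per neuron (mm). The 95% confidence interval of the
#' ratio of the two means is obtained by the MOVER method (method of
#' variance estimates recovery), recovering the ratio CI from the t-based
#' CIs of numerator and denominator.
#'
#' @param lengthDensity numeric vector of probe length densities (m/mm^3);
#'   a single value gives a degenerate CI.
#' @param neuronDensity numeric vector of neuron densities (per mm^3).
#' @param conf confidence level.
#' @return one-row data.frame: \code{ratio} (mm per neuron), \code{lower},
#'   \code{upper}.
#' @examples
#' lengthPerNeuron(28.3, 1e4)$ratio  # 2.83 mm per neuron
#' @export
lengthPerNeuron <- function(lengthDensity, neuronDensity, conf = 0.95) {
  if (any(neuronDensity <= 0)) stop("neuron density must be > 0")
  if (any(lengthDensity < 0)) stop("length density must be >= 0")
  ciMean <- function(v) {
    m <- mean(v)
    if (length(v) < 2 || stats::sd(v) == 0) return(c(m, m, m))
    hw <- stats::qt(1 - (1 - conf) / 2, length(v) - 1) *
      stats::sd(v) / sqrt(length(v))
    c(m, m - hw, m + hw)
  }
  num <- ciMean(lengthDensity * 1000)  # m/mm^3 -> mm/mm^3
  den <- ciMean(neuronDensity)
  ratio <- num[1] / den[1]
  # MOVER (Donner & Zou) ratio CI from the component CIs
  x <- num[1]; lx <- num[2]; ux <- num[3]
  y <- den[1]; ly <- den[2]; uy <- den[3]
  dL <- uy * (2 * y - uy)
  dU <- ly * (2 * y - ly)
  sL <- (x * y)^2 - lx * (2 * x - lx) * dL
  sU <- (x * y)^2 - ux * (2 * x - ux) * dU
  lower <- if (dL > 0) (x * y - sqrt(max(0, sL))) / dL else NA_real_
  upper <- if (dU > 0) (x * y + sqrt(max(0, sU))) / dU else NA_real_
  data.frame(ratio = ratio, lower = lower, upper = upper)
}

#' Log-binned, normalized fiber-diameter histograms per group
#'
#' Pools all diameters per group (e.g. species x nucleus) on shared
#' natural-log-spaced bins and normalizes by the group's total count, so
#' each group's proportions sum to 1. Per-bin across-probe means, sds and
#' probe numbers are retained for the bin-wise difference confidence
#' intervals.
#'
#' @param diameters data.frame with columns \code{diameter} (um),
#'   \code{probe} (probe identifier) and the grouping columns.
#' @param groupBy character vector of grouping column names.
#' @param edges bin edges (um), default \code{\link{logBinEdges}()}.
#' @return a \code{\linkS4class{DiameterHistogram}}.
#' @export
diameterHistogram <- function(diameters, groupBy = c("species", "nucleus"),
                              edges = logBinEdges()) {
  stopifnot(is.data.frame(diameters), "diameter" %in% names(diameters))
  if (nrow(diameters) == 0) stop("no diameters supplied")
  if (!all(groupBy %in% names(diameters)))
    stop("missing grouping columns: ",
         paste(setdiff(groupBy, names(diameters)), collapse = ", "))
  if (!"probe" %in% names(diameters)) diameters$probe <- 1L
  key <- interaction(diameters[groupBy], drop = TRUE, sep = ":")
  groups <- levels(key)
  nb <- length(edges) - 1L
  prop <- mMean <- mSd <- matrix(0, length(groups), nb,
                                 dimnames = list(groups, NULL))
  nPerGroup <- stats::setNames(numeric(length(groups)), groups)
  for (gi in seq_along(groups)) {
    d <- diameters[key == groups[gi], ]
    if (nrow(d) == 0) stop("empty group: ", groups[gi])
    prop[gi, ] <- binProportions(d$diameter, edges)
    probes <- split(d$diameter, d$probe)
    pp <- t(vapply(probes, binProportions, numeric(nb), edges = edges))
    mMean[gi, ] <- colMeans(pp)
    mSd[gi, ] <- if (nrow(pp) > 1) apply(pp, 2, stats::sd) else 0
    nPerGroup[gi] <- length(probes)
  }
  new("DiameterHistogram", edges = edges, proportions = prop,
      binMean = mMean, binSd = mSd, n = nPerGroup)
}

# proportion of values per bin; bin i covers (edges[i], edges[i+1]], a value
# on an edge belongs to the lower bin; normalized over the in-range values
# so the proportions sum to 1
binProportions <- function(x, edges) {
  if (length(x) == 0) return(numeric(length(edges) - 1))
  idx <- findInterval(x, edges, left.open = TRUE)
  idx[x == edges[1]] <- 1L
  tab <- tabulate(idx[idx >= 1 & idx <= length(edges) - 1],
                  nbins = length(edges) - 1)
  if (sum(tab) == 0) return(numeric(length(edges) - 1))
  tab / sum(tab)
}

#' Bin-wise histogram-difference confidence intervals
#'
#' For each bin i, the difference of the two group means with half-width
#' \code{t(1 - alpha/2, n1 + n2 - 2) * sqrt(2 * MSE / n12)}, where
#' \code{MSE = (sd1^2 + sd2^2) / 2} and \code{n12 = 2 / (1/n1 + 1/n2)} (the
#' joint, harmonic-mean sample size). Bins with fewer than two probes in
#' either group are flagged \code{NA}.
#'
#' @param hist a \code{\linkS4class{DiameterHistogram}}.
#' @param groupA,groupB group names (rownames of the histogram).
#' @param alpha significance level (default 0.01, i.e. 99% CI).
#' @return data.frame per bin: \code{binCentre} (um), \code{difference},
#'   \code{halfWidth}, \code{lower}, \code{upper}.
#' @export
histogramDifferenceCI <- function(hist, groupA, groupB, alpha = 0.01) {
  stopifnot(is(hist, "DiameterHistogram"))
  gs <- rownames(hist@proportions)
  if (!all(c(groupA, groupB) %in% gs)) stop("unknown group name")
  n1 <- hist@n[groupA]; n2 <- hist@n[groupB]
  diffCI(hist@binMean[groupA, ], hist@binSd[groupA, ], n1,
         hist@binMean[groupB, ], hist@binSd[groupB, ], n2,
         alpha = alpha,
         binCentre = sqrt(hist@edges[-1] * hist@edges[-length(hist@edges)]))
}

#' @rdname histogramDifferenceCI
#' @param mu1,sd1,n1,mu2,sd2,n2 per-bin means, sds and sample sizes of the
#'   two groups (vectors or scalars).
#' @param binCentre optional bin-centre annotation.
#' @export
diffCI <- function(mu1, sd1, n1, mu2, sd2, n2, alpha = 0.01,
                   binCentre = NULL) {
  if (any(n1 < 2) || any(n2 < 2)) {
    ok <- rep(n1 >= 2, length.out = length(mu1)) &
          rep(n2 >= 2, length.out = length(mu1))
  } else ok <- rep(TRUE, length(mu1))
  mse <- (sd1^2 + sd2^2) / 2
  n12 <- 2 / (1 / n1 + 1 / n2)
  tq <- stats::qt(1 - alpha / 2, n1 + n2 - 2)
  hw <- tq * sqrt(2 * mse / n12)
  hw[!ok] <- NA_real_
  d <- mu1 - mu2
  out <- data.frame(difference = d, halfWidth = hw, lower = d - hw,
                    upper = d + hw)
  if (!is.null(binCentre)) out <- cbind(binCentre = binCentre, out)
  out
}

#' Thin-to-thick diameter-count ratio
#'
#' Ratio of the histogram proportion at a thin reference diameter to that
#' at a thick reference diameter; captures the excess of thin over thick
#' fibers. Species presets follow the published reference diameters (rat:
#' 0.35 / 1.35 um; macaque: 0.41 / 2 um); the bin containing the stated
#' diameter is used, a value exactly on an edge belonging to the lower bin.
#' The ratio is invariant to overall histogram renormalization.
#'
#' @param hist a \code{\linkS4class{DiameterHistogram}}.
#' @param group group name (rowname).
#' @param species optional \code{"rat"}/\code{"macaque"} preset for the
#'   reference diameters.
#' @param thin,thick explicit reference diameters (um), overriding the
#'   preset.
#' @return the ratio (NA with a warning when the thick bin is empty).
#' @export
diameterRatio <- function(hist, group, species = NULL, thin = NULL,
                          thick = NULL) {
  stopifnot(is(hist, "DiameterHistogram"))
  if (!is.null(species)) {
    species <- match.arg(species, c("rat", "macaque"))
    preset <- if (species == "rat") c(0.35, 1.35) else c(0.41, 2)
    if (is.null(thin)) thin <- preset[1]
    if (is.null(thick)) thick <- preset[2]
  }
  if (is.null(thin) || is.null(thick))
    stop("give a species preset or explicit thin/thick diameters")
  p <- hist@proportions[group, ]
  bin <- function(d) {
    i <- findInterval(d, hist@edges, left.open = TRUE)
    if (d == hist@edges[1]) i <- 1L
    if (i < 1 || i > length(p)) stop("diameter outside the histogram range")
    i
  }
  pThick <- p[bin(thick)]
  if (pThick == 0) {
    warning("thick-diameter bin is empty; ratio undefined")
    return(NA_real_)
  }
  unname(p[bin(thin)] / pThick)
}

#' Two-factor ANOVA test battery for probe-level measures
#'
#' Fits a two-factor fixed-effects ANOVA (by default species x nucleus) on
#' a probe-level response, reports F, df and p per factor, runs a Student
#' t-test between the levels of the first factor, and Tukey HSD post hoc
#' comparisons. With unbalanced designs (unequal cell sizes) the sequential
#' sums of squares depend on factor order; this is flagged in the report.
#'
#' @param records data.frame of probe records.
#' @param response response column name.
#' @param factors two factor column names.
#' @param interaction include the interaction term (needs > 1 observation
#'   per cell).
#' @return list with elements \code{anova} (data.frame), \code{tTest}
#'   (htest or NULL), \code{tukey} and \code{notes}.
#' @export
testBattery <- function(records, response, factors = c("species", "nucleus"),
                        interaction = TRUE) {
  stopifnot(is.data.frame(records), response %in% names(records),
            all(factors %in% names(records)))
  f1 <- factor(records[[factors[1]]])
  f2 <- factor(records[[factors[2]]])
  if (nlevels(f1) < 2 || nlevels(f2) < 2)
    stop("each factor needs at least 2 levels")
  y <- records[[response]]
  notes <- character()
  cells <- table(f1, f2)
  if (any(cells == 0)) {
    notes <- c(notes, "empty cells: interaction dropped")
    interaction <- FALSE
  }
  if (interaction && all(cells <= 1))
    stop("interaction not estimable with one observation per cell")
  if (length(unique(as.vector(cells))) > 1)
    notes <- c(notes,
               "unbalanced design: sequential (type I) sums of squares")
  dat <- data.frame(y = y, f1 = f1, f2 = f2)
  form <- if (interaction) y ~ f1 * f2 else y ~ f1 + f2
  fit <- stats::aov(form, data = dat)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  rn[rn == "f1"] <- factors[1]
  rn[rn == "f2"] <- factors[2]
  rn[rn == "f1:f2"] <- paste(factors, collapse = ":")
  anovaTab <- data.frame(term = rn, df = tab$Df, F = tab$`F value`,
                         p = tab$`Pr(>F)`, row.names = NULL)
  tt <- if (nlevels(f1) == 2) stats::t.test(y ~ f1) else NULL
  tk <- tryCatch(stats::TukeyHSD(fit), error = function(e) NULL)
  list(anova = anovaTab, tTest = tt, tukey = tk, notes = notes)
}

#' Robust log-log regression of density on volume
#'
#' Iteratively reweighted robust linear fit (bisquare) of log10(density) on
#' log10(volume), as used for allometric density scaling; the slope is
#' compared against the -1/3 reference expected when wiring growth dilutes
#' neuron density.
#'
#' @param density,volume positive numeric vectors (>= 3 points).
#' @return list: \code{slope}, \code{intercept}, \code{r2} (squared
#'   correlation of observed and fitted log densities), \code{slopeSE}.
#' @examples
#' v <- 10^seq(0, 3, length.out = 8)
#' loglogRegression(v^(-1/3), v)$slope
#' @export
loglogRegression <- function(density, volume) {
  if (length(density) != length(volume) || length(density) < 2)
    stop("need matching vectors of at least 2 points")
  if (any(density <= 0) || any(volume <= 0))
    stop("density and volume must be > 0")
  x <- log10(volume)
  y <- log10(density)
  if (length(x) == 2) {
    slope <- diff(y) / diff(x)
    return(list(slope = slope, intercept = y[1] - slope * x[1], r2 = 1,
                slopeSE = NA_real_))
  }
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, maxit = 100)
  co <- stats::coef(fit)
  fitted <- co[1] + co[2] * x
  r2 <- if (stats::sd(fitted) == 0) NA_real_ else
    stats::cor(y, fitted)^2
  list(slope = unname(co[2]), intercept = unname(co[1]), r2 = r2,
       slopeSE = unname(sqrt(diag(stats::vcov(fit)))[2]))
}
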