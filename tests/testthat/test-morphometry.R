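test_that("length per neuron reproduces the ratio arithmetic", {
  # 28.3 m/mm^3 over 10^4 neurons/mm^3 -> 2.83 mm per neuron
  expect_equal(lengthPerNeuron(28.3, 1e4)$ratio, 2.83)
  # scale invariance of the ratio
  set.seed(1)
  dl <- rnorm(8, 25, 3); dn <- rnorm(8, 9000, 800)
  expect_equal(lengthPerNeuron(2 * dl, 2 * dn)$ratio,
               lengthPerNeuron(dl, dn)$ratio)
  z <- lengthPerNeuron(rep(0, 5), dn[1:5])
  expect_equal(z$ratio, 0)
  expect_equal(z$lower, 0, tolerance = 1e-9)
  expect_error(lengthPerNeuron(10, 0))
})

test_that("ratio CI contains the estimate and widens with dispersion", {
  set.seed(2)
  base <- rnorm(10, 25, 1)
  den <- rnorm(10, 1e4, 500)
  narrow <- lengthPerNeuron(base, den)
  wide <- lengthPerNeuron(mean(base) + (base - mean(base)) * 4, den)
  expect_true(narrow$lower <= narrow$ratio && narrow$ratio <= narrow$upper)
  expect_gt(wide$upper - wide$lower, narrow$upper - narrow$lower)
})

test_that("diameter histograms normalize per group on shared log bins", {
  d1 <- data.frame(diameter = 0.8, probe = 1, species = "rat",
                   nucleus = "LN")
  h <- diameterHistogram(d1)
  expect_equal(sum(h@proportions), 1)
  expect_equal(max(h@proportions), 1)    # single diameter: one bin holds all
  set.seed(3)
  x <- rlnorm(5000, log(0.8), 0.3)
  d2 <- data.frame(diameter = rep(x, 2), probe = rep(1:10, each = 500),
                   species = rep(c("rat", "macaque"), each = 5000),
                   nucleus = "LN")
  h2 <- diameterHistogram(d2)
  expect_equal(unname(rowSums(h2@proportions)), c(1, 1))
  expect_equal(h2@proportions[1, ], h2@proportions[2, ])  # identical samples
  # mode near the median for log-normal data on log-spaced bins
  modeBin <- which.max(h2@proportions[1, ])
  medBin <- findInterval(0.8, h2@edges)
  expect_lte(abs(modeBin - medBin), 1)
  expect_error(diameterHistogram(data.frame(diameter = 1)), "missing grouping")
})

test_that("histogram-difference CI matches the closed form", {
  out <- diffCI(0.10, 0.02, 50, 0.05, 0.02, 50, alpha = 0.01)
  expect_equal(out$difference, 0.05)
  expect_equal(out$halfWidth, qt(0.995, 98) * sqrt(2 * 4e-4 / 50),
               tolerance = 1e-12)
  expect_equal(out$halfWidth, 0.0105, tolerance = 0.002)
  # harmonic-mean identity at equal n
  expect_equal(2 / (1 / 50 + 1 / 50), 50)
  out2 <- diffCI(c(0.1, 0.2), c(0.02, 0.03), 50, c(0.1, 0.2),
                 c(0.02, 0.03), 50)
  expect_equal(out2$difference, c(0, 0))
  expect_equal(out2$lower, -out2$upper)
})

test_that("the bin-wise CI reaches its nominal coverage under Gaussian sampling", {
  set.seed(11)
  n <- 50; reps <- 4000
  x <- matrix(rnorm(n * reps, 0.1, 0.03), n)
  y <- matrix(rnorm(n * reps, 0.1, 0.03), n)
  sdc <- function(m) sqrt((colMeans(m^2) - colMeans(m)^2) * n / (n - 1))
  ci <- diffCI(colMeans(x), sdc(x), n, colMeans(y), sdc(y), n, alpha = 0.01)
  cover <- mean(ci$lower <= 0 & 0 <= ci$upper)
  expect_equal(cover, 0.99, tolerance = 0.021)
})

test_that("diameter ratio uses the species preset bins and is scale-free", {
  set.seed(4)
  d <- data.frame(diameter = c(rlnorm(6000, log(0.5), 0.4),
                               rlnorm(3000, log(1.6), 0.3)),
                  probe = 1:9, species = "macaque", nucleus = "LN")
  h <- diameterHistogram(d)
  g <- rownames(h@proportions)[1]
  r <- diameterRatio(h, g, species = "macaque")
  expect_equal(r, diameterRatio(h, g, thin = 0.41, thick = 2))
  expect_false(isTRUE(all.equal(r, diameterRatio(h, g, species = "rat"))))
  # equal proportions give ratio 1; 3:1 proportions give 3
  hh <- h
  hh@proportions[1, ] <- 1 / ncol(hh@proportions)
  expect_equal(diameterRatio(hh, g, species = "rat"), 1)
  # invariance under renormalization of the underlying counts
  d2 <- d[rep(seq_len(nrow(d)), 2), ]
  expect_equal(diameterRatio(diameterHistogram(d2), g, species = "macaque"),
               r)
})

test_that("two-factor ANOVA battery detects planted effects and flags degeneracy", {
  set.seed(5)
  nuclei <- c("MN", "AIN", "PIN", "LN")
  rec <- expand.grid(species = c("rat", "macaque"), nucleus = nuclei,
                     rep = 1:50)
  rec$y <- rnorm(nrow(rec), 10, 2)
  nullRep <- testBattery(rec, "y")
  expect_gt(nullRep$anova$p[1], 0.01)
  rec2 <- rec
  rec2$y <- rec2$y + ifelse(rec2$species == "macaque", 4, 0)  # 2 sd shift
  altRep <- testBattery(rec2, "y")
  expect_lt(altRep$anova$p[altRep$anova$term == "species"], 0.01)
  expect_equal(altRep$anova$df[altRep$anova$term == "species"], 1)
  expect_equal(altRep$anova$df[altRep$anova$term == "nucleus"], 3)
  expect_s3_class(altRep$tTest, "htest")
  expect_lt(altRep$tTest$p.value, 0.01)
  one <- expand.grid(species = c("rat", "macaque"), nucleus = nuclei)
  one$y <- rnorm(8)
  expect_error(testBattery(one, "y"), "one observation per cell")
})

test_that("robust log-log fits recover exact and outlier-contaminated power laws", {
  v <- 10^seq(0, 3, length.out = 10)
  fit <- loglogRegression(v^(-1 / 3), v)
  expect_equal(fit$slope, -1 / 3, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  # one gross outlier among 10 exact points barely moves the slope
  dens <- v^(-1 / 3); dens[4] <- dens[4] * 30
  expect_lt(abs(loglogRegression(dens, v)$slope - (-1 / 3)), 0.05)
  # two points: the exact line through both
  f2 <- loglogRegression(c(10, 1), c(1, 1000))
  expect_equal(f2$slope, -1 / 3, tolerance = 1e-12)
  expect_error(loglogRegression(c(-1, 1, 2), c(1, 2, 3)))
})
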