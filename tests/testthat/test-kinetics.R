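mmGrid <- c(0.05, 0.1, 0.25, 0.5, 1, 2, 3.5, 5)
hillGrid <- seq(1, 20, length.out = 10)

test_that("noiseless rate data is recovered to 1e-6 relative for all parameter sets", {
  pars <- pykKineticParameters()
  for (i in which(pars$substrate %in% c("ADP", "PEP"))) {
    p <- pars[i, ]
    isMM <- p$model == "MM"
    grid <- if (isMM) mmGrid else hillGrid
    d <- simulateRateData(p$model, p$vmax_U_per_mg, p$s50_mM,
                          hillN = ifelse(isMM, 1, p$hill_n),
                          substrate = grid, noiseCv = 0, seed = 1)
    fit <- if (isMM) fitMichaelisMenten(d) else fitHill(d)
    kp <- kineticParameters(fit)
    expect_true(fit@converged)
    expect_equal(kp[["vmax"]], p$vmax_U_per_mg, tolerance = 1e-6)
    expect_equal(kp[["s50"]], p$s50_mM, tolerance = 1e-6)
    if (!isMM) expect_equal(kp[["hill_n"]], p$hill_n, tolerance = 1e-6)
  }
})

test_that("the Hill fit reduces to Michaelis-Menten when n = 1", {
  d <- simulateRateData("MM", vmax = 10, s50 = 0.5, substrate = mmGrid,
                        noiseCv = 0, seed = 1)
  mm <- fitMichaelisMenten(d)
  hill <- fitHill(d)
  expect_equal(hill@vmax, mm@vmax, tolerance = 1e-6)
  expect_equal(hill@s50, mm@s50, tolerance = 1e-6)
  expect_equal(hill@hillN, 1, tolerance = 1e-6)

  # fitted curve is nondecreasing in substrate
  s <- seq(0, 25, length.out = 200)
  expect_true(all(diff(predictRate(hill, s)) >= -1e-12))
})

test_that("model selection prefers Hill only for cooperative data", {
  dHill <- simulateRateData("Hill", vmax = 14.1, s50 = 3.5, hillN = 3.7,
                            substrate = hillGrid, noiseCv = 0.03, seed = 2)
  selH <- selectKineticModel(dHill)
  expect_equal(selH$model, "Hill")

  dMM <- simulateRateData("MM", vmax = 21, s50 = 0.6, substrate = mmGrid,
                          noiseCv = 0.03, seed = 2)
  selM <- selectKineticModel(dMM)
  expect_equal(selM$model, "MM")
  expect_false(selM$low_confidence)

  dSparse <- simulateRateData("MM", vmax = 21, s50 = 0.6,
                              substrate = c(0.1, 0.5, 1, 5), noiseCv = 0.03,
                              replicates = 1, seed = 3)
  expect_true(selectKineticModel(dSparse)$low_confidence)
})

test_that("all-zero rates yield a flagged failure, not a silent fit", {
  d <- data.frame(substrate_mM = mmGrid, rate_U_per_mg = 0)
  expect_warning(fit <- fitMichaelisMenten(d), "failed")
  expect_false(fit@converged)
  expect_true(is.na(fit@vmax))
})

test_that("fits are invariant to row order and equivariant to unit rescaling", {
  d <- simulateRateData("Hill", vmax = 9.1, s50 = 8.6, hillN = 7.1,
                        substrate = hillGrid, noiseCv = 0.05, seed = 6)
  f1 <- fitHill(d)
  f2 <- fitHill(d[rev(seq_len(nrow(d))), ])
  expect_equal(kineticParameters(f1), kineticParameters(f2), tolerance = 1e-8)

  dScaled <- transform(d, rate_U_per_mg = rate_U_per_mg * 1000)
  f3 <- fitHill(dScaled)
  expect_equal(f3@vmax, f1@vmax * 1000, tolerance = 1e-6)
  expect_equal(f3@s50, f1@s50, tolerance = 1e-6)
  expect_equal(f3@hillN, f1@hillN, tolerance = 1e-6)
})

test_that("parameter recovery error shrinks as noise falls and replicates grow", {
  rmse <- function(noise, reps) {
    errs <- vapply(1:40, function(sd) {
      d <- simulateRateData("MM", vmax = 73.3, s50 = 0.2, substrate = mmGrid,
                            noiseCv = noise, replicates = reps, seed = sd)
      abs(fitMichaelisMenten(d)@vmax - 73.3) / 73.3
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  expect_lt(rmse(0.02, 3), rmse(0.10, 3))
  expect_lt(rmse(0.10, 9), rmse(0.10, 1))
})

test_that("turnover number applies the standard U/mg conversion per site", {
  expect_equal(turnoverNumber(73.3, 50000), 73.3 * 50000 / 60000)
  expect_equal(turnoverNumber(73.3, 50000), 61.08, tolerance = 1e-3)
  expect_equal(turnoverNumber(0, 50000), 0)
  expect_equal(turnoverNumber(10, 60000, sites = 2), 5)
  expect_error(turnoverNumber(10, -1), ">")

  # printed turnover numbers for the two isoenzymes stay >= 20-fold apart
  pars <- pykKineticParameters()
  k1 <- pars$kcat_per_s[pars$enzyme == "Pyk1" & pars$substrate == "ADP" &
                          pars$amp_mM == 1]
  k2 <- pars$kcat_per_s[pars$enzyme == "Pyk2" & pars$substrate == "ADP" &
                          pars$amp_mM == 1]
  expect_gte(k1 / k2, 20)
  expect_equal(round(k1 / k2, 1), 21.9)
})

test_that("catalytic efficiency is the kcat / S0.5 ratio and scales linearly", {
  expect_equal(catalyticEfficiency(100, 2), 50)
  expect_equal(catalyticEfficiency(200, 2), 2 * catalyticEfficiency(100, 2))
  expect_error(catalyticEfficiency(100, 0), ">")
})

test_that("activator dose-response recovers the activation parameters", {
  ampGrid <- c(0.001, 0.0025, 0.005, 0.01, 0.025, 0.05, 0.2, 1)
  d <- simulateRateData("Hill", vmax = 8.2, s50 = 0.01, hillN = 1,
                        substrate = ampGrid, noiseCv = 0, seed = 1)
  names(d)[1] <- "amp_mM"
  fit <- activationResponse(d)
  expect_equal(fit@vmax, 8.2, tolerance = 1e-6)
  expect_equal(fit@s50, 0.01, tolerance = 1e-6)

  # with a zero-activator baseline present, subtraction leaves a monotone
  # response through the origin
  d0 <- rbind(data.frame(amp_mM = 0, rate_U_per_mg = 0.4, replicate = 1), d)
  fit0 <- activationResponse(d0)
  s <- seq(0, 1, length.out = 100)
  expect_true(all(diff(predictRate(fit0, s)) >= -1e-12))
})

test_that("fold changes reproduce the reported activation ratios", {
  mk <- function(vmax, s50, n = 1) {
    d <- simulateRateData(if (n == 1) "MM" else "Hill", vmax, s50, n,
                          substrate = if (n == 1) mmGrid else hillGrid,
                          noiseCv = 0, seed = 1)
    if (n == 1) fitMichaelisMenten(d) else fitHill(d)
  }
  withAmp <- mk(73.3, 0.2)
  without <- mk(21.0, 0.6)
  expect_equal(as.numeric(foldChange(withAmp, without, "vmax")), 3.5)
  expect_equal(as.numeric(foldChange(without, withAmp, "s50")), 3.0)
  expect_equal(as.numeric(foldChange(withAmp, withAmp, "vmax")), 1.0)
  expect_equal(attr(foldChange(withAmp, without, "vmax"), "exact"),
               73.3 / 21.0, tolerance = 1e-4)

  zeroFit <- new("KineticFit", model = "MM", vmax = 0, s50 = 1, hillN = 1,
                 se = c(vmax = 0, s50 = 0, hill_n = 0), rss = 0,
                 converged = TRUE, nObs = 8L)
  expect_error(foldChange(withAmp, zeroFit, "vmax"), "denominator")
})
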