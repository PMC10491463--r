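test_that("force, area and stress conversions match SI arithmetic", {
  expect_equal(kcalPerMolAToPN(0), 0)
  expect_equal(kcalPerMolAToPN(2), 138.9539, tolerance = 1e-6)
  expect_equal(signif(kcalPerMolAToPN(2), 2), 140)
  expect_equal(kcalPerMolAToPN(1), 138.9539 / 2, tolerance = 1e-6)
  expect_error(kcalPerMolAToPN(-1), "nonnegative")
  # self-inverse round trip
  expect_equal(pNToKcalPerMolA(kcalPerMolAToPN(2)), 2, tolerance = 1e-12)
  expect_equal(round(circleArea(5), 2), 78.54)
  expect_equal(circleArea(1), pi, tolerance = 1e-7)
  expect_equal(circleArea(2) / circleArea(1), 4)
  # sigma0: independent SI recomputation 140e-12 N / 78.54e-20 m^2
  expect_equal(stressFromForce(140, 78.54), 140e-12 / 78.54e-20 / 1e9)
  expect_equal(stressFromForce(140, 78.54), 0.17825, tolerance = 1e-4)
  expect_equal(stressFromForce(0, 10), 0)
  expect_equal(stressFromForce(2 * 140, 78.54),
               2 * stressFromForce(140, 78.54))
  expect_error(stressFromForce(10, 0), "area")
})

test_that("Kelvin-Voigt strain follows its closed form", {
  s0 <- 0.17825
  expect_equal(kvStrain(0, 0.23, 0.12, s0), 0)
  expect_equal(kvStrain(1e6, 0.23, 0.12, s0), s0 / 0.23, tolerance = 1e-12)
  tau <- 0.12 / 0.23
  expect_equal(kvStrain(tau, 0.23, 0.12, s0),
               (s0 / 0.23) * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(engineeringStrain(0, 3), 0)
  expect_equal(engineeringStrain(3, 3), 1)
  # additivity under reference change: dL1/L0 + (dL2-dL1)/L0 = dL2/L0
  expect_equal(engineeringStrain(0.4, 2) + engineeringStrain(0.9 - 0.4, 2),
               engineeringStrain(0.9, 2))
  expect_error(engineeringStrain(1, 0), "L0")
})

test_that("noiseless creep curves round-trip all printed parameter pairs", {
  for (pars in list(c(0.23, 0.06), c(0.23, 0.094), c(0.23, 0.12))) {
    cc <- makeCreepCurve(E = pars[1], eta = pars[2], forcePN = 140,
                         areaA2 = 78.54, noiseSd = 0, nSamples = 1000)
    fit <- fitKelvinVoigt(cc)
    expect_lt(abs(fit@E - pars[1]) / pars[1], 1e-6)
    expect_lt(abs(fit@eta - pars[2]) / pars[2], 1e-6)
    expect_gt(fit@r2, 1 - 1e-12)
    # eta/E equals the 63.2%-rise time
    tau <- fit@eta / fit@E
    riseIdx <- which(cc@strain >= (1 - exp(-1)) * fit@sigma0 / fit@E)[1]
    expect_lt(abs(cc@time[riseIdx] - tau) / tau, 0.01)
  }
})

test_that("fitting tolerates noise and respects units and warnings", {
  # 1% noise: median bias below 1% for both parameters
  fits <- vapply(1:100, function(s) {
    cc <- makeCreepCurve(E = 0.23, eta = 0.12, noiseSd = 0.01 * 0.775,
                         nSamples = 400, seed = s)
    f <- fitKelvinVoigt(cc)
    c(f@E, f@eta)
  }, numeric(2))
  expect_lt(abs(median(fits[1, ]) - 0.23) / 0.23, 0.01)
  expect_lt(abs(median(fits[2, ]) - 0.12) / 0.12, 0.01)
  # time-unit invariance: an ns-axis curve fits to the same E, with eta
  # rescaled by the unit factor
  ccns <- makeCreepCurve(E = 0.23, eta = 60, timeUnit = "ns")
  fns <- fitKelvinVoigt(ccns)
  expect_equal(fns@timeUnit, "ns")
  expect_lt(abs(fns@E - 0.23) / 0.23, 1e-6)
  expect_lt(abs(fns@eta - 60) / 60, 1e-6)
  ccs <- creepCurve(ccns@time * 1e-9, ccns@strain, timeUnit = "s",
                    forcePN = ccns@force, areaA2 = ccns@area)
  fs <- fitKelvinVoigt(ccs)
  expect_lt(abs(fs@E - fns@E) / fns@E, 1e-6)
  expect_lt(abs(fs@eta - fns@eta * 1e-9) / (fns@eta * 1e-9), 1e-6)
  # short curve: plateau warning
  short <- makeCreepCurve(E = 0.23, eta = 0.12, duration = 0.5 * 0.12 / 0.23)
  expect_warning(fitKelvinVoigt(short), "retardation")
})

test_that("equivalent-chain reduction averages chain terminals", {
  one <- equivalentChain(matrix(c(0, 0, 0), 1), matrix(c(0, 0, 10), 1))
  expect_equal(one$nEnd, c(0, 0, 0))
  expect_equal(one$L0, 10)
  expect_equal(one$direction, c(0, 0, 1))
  # mirror-symmetric chains: endpoints land on the symmetry plane
  fx <- rbind(c(1, 2, 0), c(-1, 2, 0))
  st <- rbind(c(1, 2, 8), c(-1, 2, 8))
  mir <- equivalentChain(fx, st)
  expect_equal(mir$nEnd[1], 0)
  expect_equal(mir$cEnd[1], 0)
  # random chains equal the column-mean oracle
  set.seed(4)
  f4 <- matrix(rnorm(12), 4); s4 <- matrix(rnorm(12) + 6, 4)
  eq <- equivalentChain(f4, s4)
  expect_lt(max(abs(eq$nEnd - colMeans(f4))), 1e-12)
  expect_lt(max(abs(eq$cEnd - colMeans(s4))), 1e-12)
  expect_error(equivalentChain(f4, f4), "coincident")
})

test_that("PDB terminal reader feeds the equivalent chain", {
  skip_if_not_installed("bio3d")
  fx <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(2, 2, 0))
  st <- rbind(c(0, 0, 50), c(2, 0, 50), c(0, 2, 50), c(2, 2, 50))
  pdb <- tempfile(fileext = ".pdb")
  writeSyntheticPDB(pdb, fx, st)
  ends <- suppressWarnings(chainTerminalsFromPDB(pdb))
  expect_equal(nrow(ends$fixedEnds), 4L)
  eq <- equivalentChain(ends$fixedEnds, ends$steeredEnds)
  expect_equal(eq$nEnd, c(1, 1, 0), ignore_attr = TRUE)
  expect_equal(eq$L0, 50)
  expect_equal(eq$direction, c(0, 0, 1), ignore_attr = TRUE)
})
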