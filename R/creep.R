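#' Unit conversions and Kelvin-Voigt creep analysis
#'
#' Constant-force pulling of a protein domain produces a creep curve:
#' strain rising exponentially to a plateau. The Kelvin-Voigt solid (spring
#' E in parallel with dashpot eta) gives the closed form
#' \deqn{\varepsilon(t) = \frac{\sigma_0}{E}\,(1 - e^{-E t / \eta})}
#' with instantaneous stress \eqn{\sigma_0 = F / A}.
#'
#' @name kelvin-voigt
NULL

# Avogadro constant (1/mol), CODATA exact value
.N_AVOGADRO <- 6.02214076e23

#' Convert a pulling force from kcal/mol/Angstrom to pN
#'
#' \eqn{f \cdot 4184 / (N_A \cdot 10^{-10})} expressed in pN; the conversion
#' is self-inverse with [pNToKcalPerMolA()].
#'
#' @param f force in kcal/mol/Angstrom, nonnegative.
#' @return force in pN.
#' @examples
#' kcalPerMolAToPN(2)  # ~139 pN, the usual "140 pN" step force
#' @export
kcalPerMolAToPN <- function(f) {
  if (any(f < 0)) stop("force must be nonnegative")
  f * 4184 / (.N_AVOGADRO * 1e-10) * 1e12
}

#' @rdname kcalPerMolAToPN
#' @param fpN force in pN.
#' @export
pNToKcalPerMolA <- function(fpN) {
  if (any(fpN < 0)) stop("force must be nonnegative")
  fpN * 1e-12 * (.N_AVOGADRO * 1e-10) / 4184
}

#' Cross-sectional area of a circular section
#'
#' \eqn{\pi r^2} in Angstrom^2. The alpha-helix cross-section used for
#' stress normalization corresponds to r = 5 Angstrom (78.54 Angstrom^2).
#'
#' @param rA radius in Angstrom.
#' @return area in Angstrom^2.
#' @export
circleArea <- function(rA) {
  if (any(rA <= 0)) stop("radius must be positive")
  pi * rA^2
}

#' Instantaneous stress from force and cross-sectional area
#'
#' \eqn{\sigma_0 = F / A} with explicit SI conversion:
#' 1 pN / Angstrom^2 = 1e-12 N / 1e-20 m^2 = 1e8 Pa = 0.1 GPa.
#'
#' @param forcePN force in pN.
#' @param areaA2 area in Angstrom^2.
#' @return stress in GPa.
#' @examples
#' stressFromForce(140, 78.54)  # 0.17825 GPa
#' @export
stressFromForce <- function(forcePN, areaA2) {
  if (any(forcePN < 0)) stop("force must be nonnegative")
  if (any(areaA2 <= 0)) stop("area must be positive")
  (forcePN * 1e-12) / (areaA2 * 1e-20) / 1e9
}

#' Kelvin-Voigt creep strain
#'
#' Closed-form creep response \eqn{(\sigma_0/E)(1 - e^{-E t/\eta})}.
#'
#' @param t time (s or ns; eta must be in matching units).
#' @param E Young's modulus (GPa).
#' @param eta viscosity (GPa times the time unit).
#' @param sigma0 applied stress (GPa).
#' @return strain (dimensionless).
#' @export
kvStrain <- function(t, E, eta, sigma0) {
  stopifnot(E > 0, eta > 0, all(t >= 0))
  (sigma0 / E) * (1 - exp(-E * t / eta))
}

#' Engineering strain
#'
#' @param dL displacement (same length unit as L0).
#' @param L0 reference length, positive.
#' @return strain dL / L0.
#' @export
engineeringStrain <- function(dL, L0) {
  if (any(L0 <= 0)) stop("L0 must be positive")
  dL / L0
}

#' Construct a creep curve object
#'
#' @param time numeric, strictly increasing.
#' @param strain numeric engineering strain; alternatively supply
#'   \code{dL} and \code{L0}.
#' @param timeUnit "s" or "ns".
#' @param forcePN applied force (pN).
#' @param areaA2 cross-sectional area (Angstrom^2).
#' @param dL,L0 optional displacement trace and reference length in place
#'   of \code{strain}.
#' @return a [CreepCurve-class].
#' @export
creepCurve <- function(time, strain = NULL, timeUnit = "s", forcePN = 140,
                       areaA2 = 78.54, dL = NULL, L0 = NULL) {
  if (is.null(strain)) {
    if (is.null(dL) || is.null(L0))
      stop("supply strain, or dL together with L0")
    strain <- engineeringStrain(dL, L0)
  }
  new("CreepCurve", time = as.numeric(time), strain = as.numeric(strain),
      timeUnit = timeUnit, force = forcePN, area = areaA2)
}

#' Generate a synthetic Kelvin-Voigt creep curve
#'
#' Samples the closed-form creep response uniformly on [0, duration] and
#' adds Gaussian noise in strain units.
#'
#' @param E Young's modulus (GPa).
#' @param eta viscosity (GPa times time unit).
#' @param forcePN applied force (pN).
#' @param areaA2 cross-sectional area (Angstrom^2).
#' @param noiseSd Gaussian noise sd in strain units (0 for noiseless).
#' @param duration total time; the default spans five retardation times
#'   eta/E.
#' @param nSamples number of samples.
#' @param timeUnit "s" or "ns".
#' @param seed integer seed (ignored when noiseSd is 0).
#' @return a [CreepCurve-class].
#' @examples
#' cc <- makeCreepCurve(E = 0.23, eta = 0.12, forcePN = 140, areaA2 = 78.54)
#' fitKelvinVoigt(cc)
#' @export
makeCreepCurve <- function(E = 0.23, eta = 0.12, forcePN = 140,
                           areaA2 = 78.54, noiseSd = 0,
                           duration = 5 * eta / E, nSamples = 1000L,
                           timeUnit = "s", seed = 1L) {
  stopifnot(E > 0, eta > 0, forcePN > 0, areaA2 > 0, noiseSd >= 0,
            duration > 0, nSamples >= 2L)
  sigma0 <- stressFromForce(forcePN, areaA2)
  t <- seq(0, duration, length.out = nSamples)
  eps <- kvStrain(t, E, eta, sigma0)
  if (noiseSd > 0) {
    set.seed(seed)
    eps <- eps + rnorm(nSamples, sd = noiseSd)
  }
  creepCurve(t, eps, timeUnit = timeUnit, forcePN = forcePN, areaA2 = areaA2)
}

#' Fit the Kelvin-Voigt model to a creep curve
#'
#' Nonlinear least squares on the closed-form creep response with sigma0
#' fixed by the curve's force and area. E is initialized from the plateau
#' (sigma0 / final strain) and eta from the initial slope
#' (d strain/dt at 0 = sigma0/eta); the optimizer is Levenberg-Marquardt
#' with positivity bounds. The first sample is subtracted so the curve
#' starts at zero strain (baseline correction).
#'
#' @param curve a [CreepCurve-class].
#' @return a [KelvinVoigtParams-class]; \code{plateauReached} is FALSE
#'   (with a warning) when the curve spans fewer than two retardation
#'   times.
#' @export
fitKelvinVoigt <- function(curve) {
  stopifnot(is(curve, "CreepCurve"))
  t <- curve@time
  eps <- curve@strain - curve@strain[1]
  if (length(t) < 10L) stop("need at least 10 samples to fit")
  sigma0 <- stressFromForce(curve@force, curve@area)
  epsEnd <- mean(eps[t >= quantile(t, 0.9)])
  if (epsEnd <= 0) stop("zero or negative plateau strain; cannot initialize")
  E0 <- sigma0 / epsEnd
  idx <- which(t <= quantile(t, 0.1))
  if (length(idx) < 3L) idx <- seq_len(min(3L, length(t)))
  slope0 <- max(as.numeric(coef(lm(eps[idx] ~ t[idx]))[2]), 1e-12)
  eta0 <- sigma0 / slope0
  fit <- tryCatch(
    minpack.lm::nlsLM(eps ~ (sigma0 / E) * (1 - exp(-E * t / eta)),
                      start = list(E = E0, eta = eta0),
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e)
      stop(sprintf(
        "Kelvin-Voigt fit did not converge (starts E=%.4g, eta=%.4g): %s",
        E0, eta0, conditionMessage(e))))
  cf <- coef(fit)
  covm <- tryCatch(stats::vcov(fit), error = function(e)
    matrix(NA_real_, 2, 2))
  r2 <- 1 - sum(resid(fit)^2) / sum((eps - mean(eps))^2)
  tau <- cf["eta"] / cf["E"]
  plateau <- max(t) >= 2 * tau
  if (!plateau)
    warning("curve spans fewer than two retardation times; plateau extrapolated")
  new("KelvinVoigtParams", E = unname(cf["E"]), eta = unname(cf["eta"]),
      sigma0 = sigma0, cov = covm, r2 = r2, timeUnit = curve@timeUnit,
      plateauReached = plateau)
}

#' Reduce a multi-chain structure to its equivalent chain
#'
#' Averages the fixed-terminal and steered-terminal coordinates over all
#' chains to obtain a single representative chain: its endpoints, pulling
#' direction (unit vector from fixed to steered end) and reference length.
#'
#' @param fixedEnds matrix (chains x 3) of fixed-terminal coordinates
#'   (Angstrom), one row per chain.
#' @param steeredEnds matrix (chains x 3) of steered-terminal coordinates.
#' @return list with \code{nEnd}, \code{cEnd} (length-3), \code{direction}
#'   (unit vector) and \code{L0} (Angstrom).
#' @export
equivalentChain <- function(fixedEnds, steeredEnds) {
  fixedEnds <- rbind(fixedEnds); steeredEnds <- rbind(steeredEnds)
  stopifnot(ncol(fixedEnds) == 3L, ncol(steeredEnds) == 3L,
            nrow(fixedEnds) == nrow(steeredEnds), nrow(fixedEnds) >= 1L)
  nEnd <- colMeans(fixedEnds)
  cEnd <- colMeans(steeredEnds)
  d <- cEnd - nEnd
  L0 <- sqrt(sum(d^2))
  if (L0 == 0) stop("coincident mean endpoints: zero-length direction")
  list(nEnd = nEnd, cEnd = cEnd, direction = d / L0, L0 = L0)
}

#' Chain terminal coordinates from a PDB file
#'
#' Reads the C-alpha coordinates of the fixed and steered terminal residues
#' of each chain from a PDB file, for use with [equivalentChain()].
#' Requires the bio3d package.
#'
#' @param file path to a PDB file.
#' @param residues length-2 integer, fixed and steered residue numbers
#'   (default c(79, 222), the coiled-coil 1b domain terminals).
#' @param chains optional character vector of chain IDs to keep.
#' @return list with \code{fixedEnds} and \code{steeredEnds} matrices
#'   (chains x 3, Angstrom).
#' @export
chainTerminalsFromPDB <- function(file, residues = c(79L, 222L),
                                  chains = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("chainTerminalsFromPDB requires the bio3d package")
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  at <- at[at$elety == "CA", , drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  grab <- function(resno) {
    sel <- at[at$resno == resno, , drop = FALSE]
    if (!nrow(sel)) stop(sprintf("no CA atom for residue %d", resno))
    sel <- sel[order(sel$chain), , drop = FALSE]
    list(xyz = as.matrix(sel[, c("x", "y", "z")]), chain = sel$chain)
  }
  fx <- grab(residues[1]); st <- grab(residues[2])
  common <- intersect(fx$chain, st$chain)
  if (!length(common)) stop("no chain has both terminal residues")
  list(fixedEnds = fx$xyz[match(common, fx$chain), , drop = FALSE],
       steeredEnds = st$xyz[match(common, st$chain), , drop = FALSE],
       chains = common)
}
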