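## End-to-end orchestration: build -> scatter -> simulate -> spectra -> report.

#' Assemble and validate a pipeline configuration
#'
#' Defaults reproduce the study conditions: cell edge 8.3561 A, pattern
#' occupancy 0.83, a (111) slab of nominal 14 A thickness with 4 surface
#' hydroxyls and a 12 A solvent gap, slab octahedral occupancy 0.9 (36 of 40
#' octahedral sites kept, giving the [Fe52O76(OH)4] oxide), one chemisorbed
#' aminodialkoxysilane, 41 waters, 298 K, and a 15 ps production trajectory.
#' Every stochastic stage has an explicit seed.
#'
#' @param cellA,cellU cell edge (angstrom) and oxygen parameter
#' @param sof octahedral occupancy used for the scattering stage
#' @param slabSof octahedral occupancy realized in the slab (vacancy stage)
#' @param slabThickness,hydroxylCount,vacuum slab build parameters
#' @param nWaters,solvateDMin solvation parameters
#' @param meanN,sdN,Dmax,nClasses size distribution for the scattering stage
#' @param qMin,qMax,qStep,binWidth scattering grid parameters
#' @param temperature,gamma thermostat target (K) and friction (1/fs)
#' @param dt integration timestep (fs)
#' @param durationPs production (NVE) length in ps
#' @param equilibrationPs Langevin equilibration length in ps
#' @param sampleEvery store every this-many steps
#' @param bandLo,bandHi analysis band (1/cm)
#' @param seeds named list of integer seeds: vacancies, solvate, velocities,
#'   thermostat
#' @param trajectoryStride frame stride for the trajectory file written to
#'   the run directory
#' @return a validated configuration list (class "nanothermConfig")
#' @export
pipelineConfig <- function(cellA = 8.3561, cellU = 0.2549, sof = 0.83,
                           slabSof = 0.9, slabThickness = 14,
                           hydroxylCount = 4L, vacuum = 12, nWaters = 41L,
                           solvateDMin = 2.6, meanN = 2.1, sdN = 1.9,
                           Dmax = 40, nClasses = 40, qMin = 0.5, qMax = 12,
                           qStep = 0.005, binWidth = 0.01, temperature = 298,
                           gamma = 0.001, dt = 0.5, durationPs = 15,
                           equilibrationPs = 2, sampleEvery = 4L,
                           bandLo = 100, bandHi = 350,
                           seeds = list(vacancies = 11L, solvate = 12L,
                                        velocities = 13L, thermostat = 14L),
                           trajectoryStride = 100L) {
  config <- mget(names(formals()), environment())
  validatePipelineConfig(config)
  class(config) <- c("nanothermConfig", "list")
  config
}

#' @rdname pipelineConfig
#' @param config a configuration list
#' @return `config` invisibly; signals a validation error otherwise
#' @export
validatePipelineConfig <- function(config) {
  need <- names(formals(pipelineConfig))
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config validation: missing fields: ", paste(miss, collapse = ", "))
  pos <- c("cellA", "slabThickness", "vacuum", "solvateDMin", "meanN", "sdN",
           "Dmax", "qMin", "qMax", "qStep", "binWidth", "dt", "durationPs",
           "sampleEvery", "trajectoryStride")
  for (nm in pos)
    if (!is.numeric(config[[nm]]) || length(config[[nm]]) != 1L ||
        !is.finite(config[[nm]]) || config[[nm]] <= 0)
      stop("config validation: '", nm, "' must be a positive number")
  if (config$sof <= 0 || config$sof > 1 || config$slabSof <= 0 ||
      config$slabSof > 1)
    stop("config validation: occupancies must be in (0, 1]")
  if (config$temperature < 0 || config$gamma < 0 || config$equilibrationPs < 0)
    stop("config validation: temperature, gamma, equilibrationPs must be >= 0")
  if (config$bandLo < 0 || config$bandHi <= config$bandLo)
    stop("config validation: need 0 <= bandLo < bandHi")
  for (nm in c("vacancies", "solvate", "velocities", "thermostat"))
    if (!is.numeric(config$seeds[[nm]]))
      stop("config validation: stochastic stage '", nm, "' has no seed")
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' Unset fields fall back to the [pipelineConfig()] defaults; the merged
#' configuration is validated before it is returned.
#'
#' @param path YAML file
#' @return a validated configuration list
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("config validation: unknown fields: ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, raw)
}

.stage <- function(label, expr) {
  t0 <- proc.time()[3]
  out <- tryCatch(expr, error = function(e)
    stop("[", label, "] stage failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("[%s] done in %.1f s", label, proc.time()[3] - t0))
  out
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: build (slab + vacancies + silane + waters),
#' scatter (polydisperse Debye pattern), simulate (Langevin equilibration
#' followed by NVE production), spectra (VVACF power spectra of the tagged
#' atoms) and report (resonance overlap). All outputs plus a manifest with
#' package version, seeds and the configuration hash are written to `outDir`.
#' Re-running with an identical configuration reproduces identical outputs.
#'
#' @param config a configuration from [pipelineConfig()]
#' @param outDir run directory (created if absent)
#' @return invisibly, a list with the report, trajectory, pattern and paths
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run")) {
  validatePipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  cell <- spinelCell(a = config$cellA, u = config$cellU, f = config$sof)
  model <- .stage("build", {
    slab <- build111Slab(cell, thickness = config$slabThickness,
                         hydroxylCount = config$hydroxylCount,
                         vacuum = config$vacuum)
    slab <- assignVacancies(slab, f = config$slabSof,
                            seed = config$seeds$vacancies)
    slab <- attachSilane(slab)
    slab <- solvate(slab, nWaters = config$nWaters,
                    dMin = config$solvateDMin, seed = config$seeds$solvate)
    paths$model <- file.path(outDir, "model.extxyz")
    writeStructure(slab, paths$model, "extxyz")
    slab
  })

  pattern <- .stage("scatter", {
    q <- seq(config$qMin, config$qMax, by = config$qStep)
    pat <- populationPattern(cell,
                             sizeDistribution(config$meanN, config$sdN,
                                              config$Dmax),
                             q, nClasses = config$nClasses,
                             binWidth = config$binWidth)
    paths$pattern <- file.path(outDir, "pattern.txt")
    writePattern(pat, paths$pattern)
    pat
  })

  traj <- .stage("simulate", {
    top <- topologyFromSlab(model)
    vInit <- NULL
    nEq <- round(config$equilibrationPs * 1000 / config$dt)
    if (nEq > 0) {
      eq <- integrateLangevin(top,
                              thermostatSpec(config$temperature, config$gamma,
                                             config$seeds$thermostat),
                              dt = config$dt, nSteps = nEq,
                              sampleEvery = max(1L, nEq))
      top@positions <- eq@positions[, , nFrames(eq)]
      vInit <- eq@velocities[, , nFrames(eq)]
    }
    nProd <- round(config$durationPs * 1000 / config$dt)
    tr <- integrateNVE(top, dt = config$dt, nSteps = nProd,
                       Tinit = config$temperature,
                       seed = config$seeds$velocities,
                       sampleEvery = config$sampleEvery, vInit = vInit)
    paths$trajectory <- file.path(outDir, "trajectory.extxyz")
    writeTrajectory(tr, paths$trajectory, stride = config$trajectoryStride)
    tr
  })

  spectra <- .stage("spectra", {
    tagNames <- intersect(c("anchor_Fe", "amine_N", "subsurface_Fe"),
                          names(traj@tags))
    out <- list()
    for (tg in tagNames) {
      sp <- powerSpectrum(vvacf(traj, traj@tags[[tg]][1]))
      p <- file.path(outDir, paste0("spectrum_", tg, ".txt"))
      writeTwoColumn(sp, p)
      out[[tg]] <- sp
    }
    paths$spectra <- file.path(outDir, paste0("spectrum_", tagNames, ".txt"))
    out
  })

  report <- .stage("report", {
    rep <- resonanceReport(traj, bnd = band(config$bandLo, config$bandHi))
    paths$report <- writeOverlapReport(rep, file.path(outDir, "report"))
    rep
  })

  cfgPath <- file.path(outDir, "config.json")
  jsonlite::write_json(unclass(config), cfgPath, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    package = "nanotherm",
    version = as.character(utils::packageVersion("nanotherm")),
    rVersion = paste(R.version$major, R.version$minor, sep = "."),
    seeds = config$seeds,
    configHash = unname(tools::md5sum(cfgPath)),
    outputs = lapply(paths, basename))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(outDir = outDir, model = model, pattern = pattern,
                 trajectory = traj, spectra = spectra, report = report,
                 paths = paths))
}

#' Generate the small deterministic fixtures used by the test suite
#'
#' Writes (a) a 3-frame trajectory of a hydrogen-bonded water dimer network,
#' (b) a roughly 200-site nanocrystal cluster, and (c) a noiseless synthetic
#' scattering pattern, all derived from seeded code - no downloads, no stored
#' binaries.
#'
#' @param seed integer seed
#' @param dir output directory
#' @return named list of file paths
#' @export
generateFixtures <- function(seed = 1L, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ## (a) tiny trajectory with velocities
  top <- .waterDimerTopology()
  tr <- integrateNVE(top, dt = 0.4, nSteps = 3L, Tinit = 200, seed = seed)
  trajPath <- file.path(dir, "dimer_3frames.extxyz")
  writeTrajectory(tr, trajPath)
  ## (b) ~200-site cluster
  cl <- cutSphere(spinelCell(f = 0.83), D = 1.58)
  clusterPath <- file.path(dir, "cluster200.extxyz")
  writeStructure(cl, clusterPath, "extxyz")
  ## (c) noiseless pattern of the cluster
  pat <- debyeIntensity(cl, seq(0.5, 8, by = 0.02), mode = "histogram")
  patternPath <- file.path(dir, "pattern.txt")
  writePattern(pat, patternPath)
  list(trajectory = trajPath, cluster = clusterPath, pattern = patternPath)
}

## a 6-atom hydrogen-bonded water dimer as a minimal spring network
.waterDimerTopology <- function() {
  rOH <- 0.9572; ang <- 104.52 * pi / 180
  o1 <- c(0, 0, 0)
  h1 <- o1 + rOH * c(sin(ang / 2), cos(ang / 2), 0)
  h2 <- o1 + rOH * c(-sin(ang / 2), cos(ang / 2), 0)
  o2 <- c(0, 2.85, 0)
  h3 <- o2 + rOH * c(sin(ang / 2), cos(ang / 2), 0)
  h4 <- o2 + rOH * c(-sin(ang / 2), cos(ang / 2), 0)
  pos <- rbind(o1, h1, h2, o2, h3, h4)
  el <- c("O", "H", "H", "O", "H", "H")
  m <- .elementMass(el)
  kOH <- .kFromWavenumber(3600, prod(m[1:2]) / sum(m[1:2]))
  kHB <- .kFromWavenumber(180, prod(m[1:2]) / sum(m[1:2]))
  d <- function(i, j) sqrt(sum((pos[i, ] - pos[j, ])^2))
  springs <- data.frame(
    i = c(1L, 1L, 4L, 4L, 2L),
    j = c(2L, 3L, 5L, 6L, 4L),
    k = c(kOH, kOH, kOH, kOH, kHB),
    r0 = c(d(1, 2), d(1, 3), d(4, 5), d(4, 6), d(2, 4)),
    class = c(rep("covalent", 4), "hbond"),
    stringsAsFactors = FALSE)
  new("Topology", elements = el, masses = m, positions = pos,
      springs = springs, tags = list(water_O = c(1L, 4L)), box = numeric(0))
}
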