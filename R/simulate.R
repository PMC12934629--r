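#' SimulationConfig: parameters of the synthetic paired cohort
#'
#' Defines the study conditions emulated by the generator: a block-structured
#' correlation matrix (within-network coupling `wBase`, between-network
#' coupling `bBase`) shifted per state, a per-subject random effect added to
#' both couplings and shared across that subject's two conditions (which is
#' what makes the paired design more powerful than an unpaired one), a
#' per-state AR(1) temporal-smoothness coefficient, and optional additive
#' observation noise.
#'
#' @slot nRois,networkSizes,nFrames,nSubjects integers; `networkSizes` has 7
#'   entries summing to `nRois`.
#' @slot wBase,bBase baseline within/between-network correlations,
#'   `0 <= bBase < wBase < 1`.
#' @slot subjectSd SD of the per-subject coupling random effect.
#' @slot arPhiBaseline AR(1) coefficient of the baseline condition.
#' @slot states data.frame of altered states: `state`, `class`,
#'   `deltaWithin`, `deltaBetween`, `arPhi`, `noiseScale`.
#' @slot seed integer RNG seed.
#' @seealso [simulationConfig()], [defaultStates()], [simulateCohort()]
#' @export
setClass("SimulationConfig",
         slots = c(nRois = "integer", networkSizes = "integer",
                   nFrames = "integer", nSubjects = "integer",
                   wBase = "numeric", bBase = "numeric",
                   subjectSd = "numeric", arPhiBaseline = "numeric",
                   states = "data.frame", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@networkSizes) != 7L ||
      sum(object@networkSizes) != object@nRois)
    msg <- c(msg, "networkSizes must have 7 entries summing to nRois")
  if (any(object@networkSizes < 2L))
    msg <- c(msg, "every network needs >= 2 ROIs")
  if (!(object@bBase >= 0 && object@bBase < object@wBase && object@wBase < 1))
    msg <- c(msg, "need 0 <= bBase < wBase < 1")
  if (object@nFrames < 10L)
    msg <- c(msg, "nFrames must be >= 10 (two complexity windows of 5 TRs)")
  if (object@nSubjects < 3L)
    msg <- c(msg, "nSubjects must be >= 3 for paired tests")
  need <- c("state", "class", "deltaWithin", "deltaBetween", "arPhi",
            "noiseScale")
  if (!all(need %in% names(object@states)))
    msg <- c(msg, paste("states needs columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@states$state))
      msg <- c(msg, "duplicate state names")
    badc <- setdiff(object@states$class, c("psychedelic", "sleep", "sedation"))
    if (length(badc))
      msg <- c(msg, paste("unknown state class:", paste(badc, collapse = ", ")))
    if (any(abs(object@states$arPhi) >= 1) || abs(object@arPhiBaseline) >= 1)
      msg <- c(msg, "AR(1) coefficients must lie in (-1, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Default altered-state specifications
#'
#' The nine conscious states the generator emulates, with dose-graded coupling
#' shifts. Psychedelic states (LSD, PSIL, KTM, N2O) raise between-network and
#' lower within-network coupling and have faster dynamics (lower AR phi);
#' sleep (N1, N2) and propofol sedation (PPF1.9/2.4/2.7) lower both couplings
#' -- between-network proportionally more -- and have slower, more stereotyped
#' dynamics (higher AR phi). Magnitudes are graded with dose within each
#' class.
#'
#' @return data.frame with one row per altered state.
#' @examples
#' defaultStates()
#' @export
defaultStates <- function() {
  data.frame(
    state = c("LSD", "PSIL", "KTM", "N2O", "N1", "N2",
              "PPF1.9", "PPF2.4", "PPF2.7"),
    class = c(rep("psychedelic", 4), rep("sleep", 2), rep("sedation", 3)),
    deltaWithin  = c(-0.120, -0.082, -0.050, -0.030,
                     -0.028, -0.048, -0.072, -0.085, -0.095),
    deltaBetween = c( 0.175,  0.115,  0.068,  0.040,
                     -0.034, -0.058, -0.090, -0.120, -0.150),
    arPhi = c(0.13, 0.18, 0.22, 0.26, 0.35, 0.41, 0.46, 0.54, 0.62),
    noiseScale = 0,
    stringsAsFactors = FALSE)
}

#' Construct a simulation configuration
#'
#' Defaults are the package's reference study conditions: 70 ROIs in seven
#' networks of 10, 150 frames, 20 subjects per state, baseline couplings
#' `wBase = 0.45` / `bBase = 0.20`, subject-effect SD 0.02, baseline AR(1)
#' coefficient 0.30, and the nine [defaultStates()].
#'
#' @param nRois,networkSizes,nFrames,nSubjects cohort dimensions.
#' @param wBase,bBase,subjectSd,arPhiBaseline baseline coupling model.
#' @param states data.frame as returned by [defaultStates()].
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(seed = 1, nRois = 14, networkSizes = rep(2, 7),
#'                         nFrames = 40, nSubjects = 4)
#' @export
simulationConfig <- function(nRois = 70L, networkSizes = rep(10L, 7L),
                             nFrames = 150L, nSubjects = 20L,
                             wBase = 0.45, bBase = 0.20, subjectSd = 0.02,
                             arPhiBaseline = 0.30, states = defaultStates(),
                             seed) {
  if (missing(seed)) stop("a seed is required for any stochastic stage")
  new("SimulationConfig", nRois = as.integer(nRois),
      networkSizes = as.integer(networkSizes), nFrames = as.integer(nFrames),
      nSubjects = as.integer(nSubjects), wBase = wBase, bBase = bBase,
      subjectSd = subjectSd, arPhiBaseline = arPhiBaseline,
      states = states, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nRois, "ROIs,", object@nFrames, "frames,",
      object@nSubjects, "subjects/state,", nrow(object@states),
      "altered states\n")
  cat("  wBase =", object@wBase, " bBase =", object@bBase,
      " subjectSd =", object@subjectSd,
      " arPhiBaseline =", object@arPhiBaseline, "\n")
})

.clipCoupling <- function(x) pmin(pmax(x, -0.99), 0.99)

#' Block-structured state covariance
#'
#' Builds the ROI x ROI correlation matrix of one state for one subject:
#' within-network entries `clip(wBase + deltaWithin + subjectEffect)`,
#' between-network entries `clip(bBase + deltaBetween + subjectEffect)`
#' (clipped into (-0.99, 0.99)), unit diagonal. Positive definiteness is
#' verified via Cholesky; on failure a diagonal jitter of at most 1e-6 is
#' tried before erroring, so a silently distorted target correlation is
#' impossible.
#'
#' @param config a [SimulationConfig-class].
#' @param state a state name from `config@states$state`, or `"baseline"`.
#' @param subjectEffect scalar added to both couplings.
#' @return correlation matrix of dimension `nRois`.
#' @examples
#' cfg <- simulationConfig(seed = 1, nRois = 14, networkSizes = rep(2, 7),
#'                         nFrames = 40, nSubjects = 4)
#' S <- stateCovariance(cfg, "baseline")
#' S[1, 2] == cfg@wBase
#' @export
stateCovariance <- function(config, state, subjectEffect = 0) {
  stopifnot(is(config, "SimulationConfig"))
  if (identical(state, "baseline")) {
    dw <- 0; db <- 0
  } else {
    i <- match(state, config@states$state)
    if (is.na(i)) stop("unknown state: ", state)
    dw <- config@states$deltaWithin[i]
    db <- config@states$deltaBetween[i]
  }
  w <- .clipCoupling(config@wBase + dw + subjectEffect)
  b <- .clipCoupling(config@bBase + db + subjectEffect)
  n <- config@nRois
  S <- matrix(b, n, n)
  ends <- cumsum(config@networkSizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  for (k in seq_len(7L)) {
    idx <- starts[k]:ends[k]
    S[idx, idx] <- w
  }
  diag(S) <- 1
  for (jit in c(0, 1e-8, 1e-6)) {
    Sj <- S + diag(jit, n)
    ok <- tryCatch({ chol(Sj); TRUE }, error = function(e) FALSE)
    if (ok) return(Sj)
  }
  stop("state covariance for '", state,
       "' is not positive definite (after diagonal jitter up to 1e-6)")
}

## one recording: stationary AR(1) with marginal covariance S, then optional
## additive noise, then per-ROI standardization (zero mean, unit variance)
.simulateSeries <- function(S, nFrames, phi, noiseScale) {
  L <- chol(S)
  E <- matrix(rnorm(nFrames * ncol(S)), nFrames) %*% L
  if (phi != 0) {
    # x_t = phi x_{t-1} + sqrt(1-phi^2) e_t with x_1 = e_1 is stationary
    E[-1L, ] <- sqrt(1 - phi^2) * E[-1L, , drop = FALSE]
    X <- filter(E, phi, method = "recursive")
    X <- matrix(as.numeric(X), nFrames)
  } else X <- E
  if (noiseScale != 0)
    X <- X + noiseScale * matrix(rnorm(length(X)), nrow(X))
  scale(X)[, , drop = FALSE]
}

#' Simulate a paired baseline/altered cohort
#'
#' For every altered state and every subject, draws one subject-level coupling
#' effect (shared by that subject's two conditions), then one baseline and one
#' altered recording: stationary AR(1) series whose marginal covariance is the
#' state's block correlation matrix, plus optional additive observation noise,
#' each ROI finally standardized to zero mean and unit variance. Subjects are
#' independent across states, mirroring a multi-dataset design in which each
#' altered state is compared only with its own baseline.
#'
#' @param config a [SimulationConfig-class]; `config@seed` drives all draws,
#'   so identical configs give bit-identical cohorts.
#' @return a [StateCohort-class].
#' @examples
#' cfg <- simulationConfig(seed = 1, nRois = 14, networkSizes = rep(2, 7),
#'                         nFrames = 40, nSubjects = 4,
#'                         states = defaultStates()[c(1, 9), ])
#' coh <- simulateCohort(cfg)
#' manifest(coh)[1:4, ]
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed)
  part <- makePartition(config@nRois, config@networkSizes)
  series <- list()
  rows <- list()
  for (i in seq_len(nrow(config@states))) {
    st <- config@states[i, ]
    for (s in seq_len(config@nSubjects)) {
      subj <- sprintf("%s_S%02d", st$state, s)
      u <- rnorm(1L, 0, config@subjectSd)
      Sb <- stateCovariance(config, "baseline", u)
      Sa <- stateCovariance(config, st$state, u)
      idB <- paste0(subj, "_baseline")
      idA <- paste0(subj, "_altered")
      series[[idB]] <- .simulateSeries(Sb, config@nFrames,
                                       config@arPhiBaseline, 0)
      series[[idA]] <- .simulateSeries(Sa, config@nFrames, st$arPhi,
                                       st$noiseScale)
      colnames(series[[idB]]) <- colnames(series[[idA]]) <- roiIds(part)
      rows[[idB]] <- data.frame(id = idB, subject = subj, state = st$state,
                                class = st$class, condition = "baseline")
      rows[[idA]] <- data.frame(id = idA, subject = subj, state = st$state,
                                class = st$class, condition = "altered")
    }
  }
  new("StateCohort", series = series,
      manifest = do.call(rbind, c(rows, make.row.names = FALSE)),
      partition = part,
      params = list(config = config))
}

#' @rdname StateCohort-class
#' @aliases manifest,StateCohort-method
setMethod("manifest", "StateCohort", function(x) x@manifest)

#' @rdname StateCohort-class
setMethod("getSeries", "StateCohort", function(x, id) {
  if (!id %in% names(x@series)) stop("no recording with id: ", id)
  x@series[[id]]
})

#' @rdname StateCohort-class
setMethod("nRois", "StateCohort", function(x) nRois(x@partition))

setMethod("show", "StateCohort", function(object) {
  man <- object@manifest
  cat("StateCohort:", nrow(man), "recordings,",
      length(unique(man$state)), "states,",
      nRois(object@partition), "ROIs,",
      nrow(object@series[[1L]]), "frames\n")
})

#' Write / read a cohort as delimited text files
#'
#' `writeCohort` writes one TSV per recording (frames x ROIs with a header row
#' of ROI ids), a cohort manifest TSV (`id`, `subject`, `state`, `class`,
#' `condition`, `file`) and the partition TSV. `readCohort` reloads such a
#' directory.
#'
#' @param cohort a [StateCohort-class].
#' @param dir output directory (created if needed).
#' @return `writeCohort` returns `dir` invisibly; `readCohort` a
#'   [StateCohort-class].
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "StateCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "series"), showWarnings = FALSE)
  man <- cohort@manifest
  man$file <- file.path("series", paste0(man$id, ".tsv"))
  for (i in seq_len(nrow(man)))
    write.table(cohort@series[[man$id[i]]], file.path(dir, man$file[i]),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writePartition(cohort@partition, file.path(dir, "partition.tsv"))
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  man <- read.delim(file.path(dir, "manifest.tsv"), stringsAsFactors = FALSE)
  part <- readPartition(file.path(dir, "partition.tsv"))
  series <- lapply(seq_len(nrow(man)), function(i) {
    m <- as.matrix(read.delim(file.path(dir, man$file[i]), check.names = FALSE))
    if (!identical(colnames(m), roiIds(part)))
      stop("ROI columns of ", man$file[i], " do not match the partition")
    m
  })
  names(series) <- man$id
  new("StateCohort", series = series,
      manifest = man[setdiff(names(man), "file")], partition = part,
      params = list())
}
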