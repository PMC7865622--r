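# Shared fixtures for the suite. Everything is generated in code; cohort
# sizes are kept at desk scale so the default test run stays fast.

smallConfig <- function(nSubjects = 2L, armsPerSubject = 1L, seed = 11L, ...) {
  generatorConfig(nSubjects = nSubjects, armsPerSubject = armsPerSubject,
                  seed = seed, ...)
}

# One seeded default-parameter session, cached per test run.
sessionFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateSession(generatorConfig(), "S01", "right",
                                seed = 42L)$session
    cache
  }
})

# A small labelled feature matrix (2 subjects x 1 arm), cached.
featureMatrixFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- generateCohort(smallConfig())
      sessions <- lapply(coh, `[[`, "session")
      labeled <- lapply(sessions, function(s)
        labelRepetitions(s, detectRepetitions(s)))
      cache <<- buildFeatureMatrix(sessions, labeled)
    }
    cache
  }
})

# Hand-built session wrapping arbitrary channel values, for analytic cases.
syntheticSession <- function(values, channel = "acc_y", fs = 50,
                             boundaries = NULL, reportedRPE = NULL,
                             heartRate = 120) {
  n <- length(values)
  s <- data.frame(t = (seq_len(n) - 1) / fs)
  for (ch in c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z",
               "mag_x", "mag_y", "mag_z"))
    s[[ch]] <- 0
  s[[channel]] <- values
  s$heart_rate <- rep_len(heartRate, n)
  if (is.null(boundaries)) boundaries <- matrix(c(0L, n), ncol = 2L)
  if (is.null(reportedRPE)) reportedRPE <- rep(12L, nrow(boundaries))
  CurlSession(subjectId = "X01", arm = "right", samplingRate = fs,
              samples = s, setBoundaries = boundaries,
              reportedRPE = reportedRPE, dumbbellMass = 4.5)
}

sampleSkewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}

randomRotationMatrix <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
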