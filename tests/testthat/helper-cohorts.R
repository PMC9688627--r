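# Shared fixture builders: small montages and cohorts generated in code.

# 36 channels covering the effect region (FC2/AFz/F2) and a spread of
# other regions of the shipped map
testMontage <- function() {
  c("FC2", "AFz", "F2", "PO3", "Pz", "POz", "AF3", "F5", "AF8", "F6",
    "C1", "C2", "CPz", "Cz", "C3", "C4", "O1", "O2", "Oz", "PO4",
    "PO7", "PO8", "Iz", "AF4", "Fp2", "Fpz", "CP1", "P2", "P1", "P3",
    "P4", "P5", "P6", "TP8", "T7", "T8")
}

# 12 channels / several regions; cheap enough for repeated-seed tests
smallMontage <- function() {
  c("FC2", "AFz", "F2", "PO3", "Pz", "POz", "C1", "C2", "CPz", "Cz",
    "O1", "O2")
}

effectCohort <- function(nPerClass = 8, channels = smallMontage(),
                         seed = 1, betaSep = 0.5, duration = 17) {
  generateCohort(cohortSpec(
    nCtl = nPerClass, nDep = nPerClass, channels = channels,
    duration = duration, betaCtl = 1.0, betaDep = 1.0 + betaSep,
    alphaAmpCtl = 4, alphaAmpDep = 6, seed = seed))
}

nullCohort <- function(nPerClass = 8, channels = smallMontage(),
                       seed = 1, duration = 17) {
  generateCohort(cohortSpec(
    nCtl = nPerClass, nDep = nPerClass, channels = channels,
    duration = duration, betaCtl = 1.0, betaDep = 1.0,
    alphaAmpCtl = 4, alphaAmpDep = 4, seed = seed))
}

# separable 6-feature table for classifier tests: class shifts on two
# features, noise on the rest
separableFeatures <- function(n = 120, shift = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, featureNames()))
  X[, "DFA"] <- X[, "DFA"] + shift * y
  X[, "SpectEnt"] <- X[, "SpectEnt"] - shift * y
  data.frame(subject = sprintf("s%03d", seq_len(n)), window = 1L,
             y = y, X, stringsAsFactors = FALSE)
}
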