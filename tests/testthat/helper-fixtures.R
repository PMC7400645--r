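## small shared fixtures built in code

twoStateMatrix <- function(p = 0.1, q = 0.2, lag = 1) {
  new("TransitionMatrix",
      matrix = matrix(c(1 - p, p, q, 1 - q), 2, 2, byrow = TRUE),
      lag = lag)
}

identityMacro <- function(n) {
  new("MacrostateModel", microToMacro = seq_len(n), nMacro = as.integer(n),
      membership = diag(n), methodTag = "identity")
}

macroFromLabels <- function(labels) {
  labels <- as.integer(labels)
  k <- max(labels)
  new("MacrostateModel", microToMacro = labels, nMacro = k,
      membership = diag(k)[labels, , drop = FALSE], methodTag = "truth")
}

## minimal hand-built ensemble: coords is a list of atoms x 3 matrices
makeEnsemble <- function(coords, groups, labels = character()) {
  new("ConformationEnsemble", frames = coords, atomGroups = groups,
      stateLabels = labels)
}

## independent brute-force stationary vector by repeated squaring
bruteStationary <- function(Tm, pow = 22) {
  M <- Tm
  for (i in seq_len(pow)) M <- M %*% M
  colMeans(M)
}

## adjusted Rand index (independent of any clustering package)
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- ai * bj / n2
  (nij - exp_) / ((ai + bj) / 2 - exp_)
}
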