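# Shared fixtures, all generated in code.

# tiny hand-built table: 4 features x 6 samples, two classes
tinyTable <- function() {
  m <- rbind(
    F1 = c(10, 12, 11, 30, 32, 31),
    F2 = c(5, 5, 5, 5, 5, 5),
    F3 = c(0, 0, 2, 3, 0, 4),
    F4 = c(1, 2, 3, 4, 5, 6))
  colnames(m) <- paste0("S", 1:6)
  featureTable(m,
    sampleData = data.frame(chemotype = rep(c("A", "B"), each = 3),
                            dry_weight_mg = c(1, 2, 4, 1, 2, 4),
                            row.names = colnames(m)))
}

# small but realistic simulated design, fast enough for module tests
smallConfig <- function(seed = 1L, ...) {
  args <- list(nChemotypes = 3, nGenotypes = 6, nSamplesPerGenotype = 5,
               nFeatures = 60, fracChemotypeMarkers = 0.2,
               fracGenotypeMarkers = 0.1, effectSizeChemo = 2,
               effectSizeGeno = 2, fracClassExclusive = 0.3,
               noiseSigma = 0.4, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulationConfig, args)
}

fastControl <- function(nModels = 5, baseSeed = 1L) {
  ensembleControl(nModels = nModels, alphaGrid = c(0.1, 0.5, 0.9),
                  nLambda = 15, baseSeed = baseSeed)
}

# adjusted Rand index between two partitions (for cluster-recovery checks)
adjRandIndex <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  maxidx <- (sumi + sumj) / 2
  if (maxidx == expected) return(1)
  (sumij - expected) / (maxidx - expected)
}
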