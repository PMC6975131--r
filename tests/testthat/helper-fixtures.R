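## shared fixtures and small builders

## printed channel set of the seven-energy validation study
studyEnergies <- seq(6, 9, by = 0.5)
studyFresnel <- c(2.43, 2.64, 2.84, 3.04, 3.24, 3.45, 3.65) * 1e-4

## small smooth projected-density map (electrons/nm^2) on an n x n grid
smoothDensityMap <- function(n, amplitude = 5e4, width = 0.08) {
  x <- seq(-1, 1, length.out = n)
  amplitude * outer(x, x, function(a, b)
    exp(-(a^2 + b^2) / width) + 0.6 * exp(-((a - 0.3)^2 + (b + 0.2)^2) / (width / 2)))
}

## voxelized ball mask indices within an array of dims
ballVoxels <- function(center, radius, dims) {
  g <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                             seq_len(dims[3])))
  g[rowSums(sweep(g, 2, center)^2) <= radius^2, , drop = FALSE]
}

## lazily computed expensive fixtures, shared across acceptance blocks
.fixtureCache <- new.env(parent = emptyenv())

cachedStudy <- function() {
  if (is.null(.fixtureCache$study)) {
    cfg <- studyConfig(combinations = list())
    .fixtureCache$study <- runSimulationStudy(cfg)
  }
  .fixtureCache$study
}
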