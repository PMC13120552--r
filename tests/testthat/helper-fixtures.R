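# Small fixtures built in code: a uniform disc phantom and a tiny
# acquisition, used across the projector and reconstruction tests.

discSpec <- function(value = 1, radiusMm = 40, gridN = 64, fovMm = 128) {
  phantomSpec(data.frame(
    label = "DISC", xMm = 0, yMm = 0, aMm = radiusMm, bMm = radiusMm,
    angleDeg = 0, activityKbq = value * pi * radiusMm^2,
    surfaceAu = pi * radiusMm^2, specificActivity = value),
    gridN = gridN, fovMm = fovMm)
}

tinyConfig <- function(gridN = 64, fovMm = 128, nProjections = 16, ...) {
  acquisitionConfig(nProjections = nProjections, nBins = gridN,
                    binMm = fovMm / gridN, ...)
}

# Poisson log-likelihood of counts g under expectation lambda (bins with
# lambda = 0 and g = 0 contribute 0).
poissonLogLik <- function(g, lambda) {
  ok <- lambda > 0
  sum(g[ok] * log(lambda[ok]) - lambda[ok])
}
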