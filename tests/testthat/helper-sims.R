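# Shared simulations, computed once per test run.

.simCache <- new.env(parent = emptyenv())

cachedSims <- function() {
  if (is.null(.simCache$res)) {
    p36 <- defaultParameters("36.5C")
    p32 <- defaultParameters("32C")
    .simCache$res <- list(
      p36 = p36, p32 = p32,
      tr36 = integrateCulture(defaultDesign(shift = FALSE), p36),
      trShift = integrateCulture(defaultDesign(), p36, p32))
  }
  .simCache$res
}
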