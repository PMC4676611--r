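# Shared fixtures: tiny configurations and states built in code.

smallConfig <- function(n = 11L, counts = c(MM = 10L, OB = 10L, OC = 10L),
                        ...) {
  cfg <- defaultConfig()
  cfg$grid <- list(nx = n, ny = n, nz = n, spacing = 5)
  cfg$initial_counts <- as.list(counts)
  extra <- list(...)
  for (nm in names(extra)) cfg$parameters[[nm]] <- extra[[nm]]
  cfg
}

# one agent of each type on a 7^3 grid, well separated
triState <- function() {
  makeGridFixture(dims = c(7L, 7L, 7L),
                  agents = data.frame(type = c("MM", "OB", "OC"),
                                      i = c(2L, 4L, 6L),
                                      j = c(2L, 4L, 6L),
                                      k = c(2L, 4L, 6L)))
}

refParams <- function() defaultConfig()$parameters
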