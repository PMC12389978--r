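# Deterministic random fixtures built in code.

random_image <- function(nr, nc = nr, seed = 1) {
  set.seed(seed)
  matrix(runif(nr * nc), nr, nc)
}

random_gaussian_image <- function(nr, nc = nr, seed = 1) {
  set.seed(seed)
  matrix(rnorm(nr * nc), nr, nc)
}

# small phantom shared by pipeline tests
test_phantom <- function(size = 64) shepp_logan_phantom(size)
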