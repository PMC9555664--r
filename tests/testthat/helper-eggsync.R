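# build egg records whose volumes are exactly the requested values:
# width fixed, length solved from V = beta * L * W^2
eggs_from_volumes <- function(volumes, nest_id, species = "gull",
                              year = 2005, width_mm = 40) {
  beta <- eggsync::species_constants()[[species]]
  data.frame(species = species, year = year, nest_id = nest_id,
             length_mm = volumes / (beta * width_mm^2), width_mm = width_mm,
             stringsAsFactors = FALSE)
}

# a random row-stochastic 4x4 matrix with strictly positive entries (ergodic)
random_transition_matrix <- function() {
  m <- matrix(stats::rexp(16) + 0.05, 4, 4)
  m / rowSums(m)
}

# the four state conditions exactly as defined, used as an independent oracle
state_oracle <- function(a, b, c) {
  which(c(a > b && b <= c,
          a <= b && b <= c,
          a <= b && b > c,
          a > b && b > c))
}
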