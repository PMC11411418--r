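# delta-table constructors used across tests

zero_deltas <- function() {
  tibble::tibble(element = element_ids(), dR = 0, dG = 0, dB = 0)
}

random_deltas <- function(seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      element = element_ids(),
      dR = round(runif(12, -120, 120), 2),
      dG = round(runif(12, -120, 120), 2),
      dB = round(runif(12, -120, 120), 2)
    )
  })
}

# uniform spot-color table on the 0-255 scale
flat_colors <- function(R = 200, G = 200, B = 200) {
  tibble::tibble(element = element_ids(), R = R, G = G, B = B)
}
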