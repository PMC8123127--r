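# shared fixtures: literature constants and a unit-ratio parameter set
paper_k <- function(...) hts_constants(...)

# all six concentration/constant ratios equal to one
unit_ratio_k <- function(K_mp = 1000) {
  kinetic_constants(K_D = 1, K_M = 1, K_Mp = 1, K_d = 1000, K_m = 1000,
                    K_mp = K_mp, k_cat = 1, E_T = 1000)
}
unit_ratio_mix <- function() mix_state(D = 1, M = 1, d = 1000, m = 1000)

# random valid parameter set + mixture on a fixed RNG stream
random_case <- function() {
  k <- kinetic_constants(
    K_D = stats::runif(1, 0.5, 50), K_M = stats::runif(1, 0.5, 50),
    K_Mp = stats::runif(1, 0.5, 50), K_d = stats::runif(1, 1, 2000),
    K_m = stats::runif(1, 1, 2000), K_mp = stats::runif(1, 1, 2000),
    k_cat = stats::runif(1, 10, 150), E_T = stats::runif(1, 50, 600))
  mx <- mix_state(D = stats::runif(1, 1, 300), M = stats::runif(1, 1, 300),
                  d = stats::runif(1, 1, 3000), m = stats::runif(1, 1, 3000))
  list(k = k, mix = mx)
}
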