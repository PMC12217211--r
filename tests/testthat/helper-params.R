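# shared fixtures: packaged parameter sets and small simulation helpers

k24 <- table1_params("24h")$kinetics
k48 <- table1_params("48h")$kinetics
k96 <- table1_params("96h")$kinetics
pre24 <- table1_params("24h")$prefactors
pre48 <- table1_params("48h")$prefactors
pre96 <- table1_params("96h")$prefactors

# transition-free growing-only chain used for one-state and degenerate cases
pure_growth <- function(k_b = 0.002, v = 0.027) {
  tip_kinetics(k_b, v_G = v, v_S = 0, k_GS = 0, k_GP = 0, k_SG = 0,
               k_SP = 0, k_PG = 1, k_PS = 0, beta = 0)
}

random_kinetics <- function() {
  r <- stats::runif(6, 0.05, 1.5)
  tip_kinetics(k_b = stats::runif(1, 5e-4, 5e-3),
               v_G = stats::runif(1, 0.5, 2), v_S = stats::runif(1, 0.5, 2),
               k_GS = r[1], k_GP = r[2], k_SG = r[3], k_SP = r[4],
               k_PG = r[5], k_PS = r[6], beta = stats::runif(1, 0, 0.5))
}
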