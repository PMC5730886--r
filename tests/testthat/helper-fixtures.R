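# Shared fixtures and the independent propagation oracle.

# random but reproducible amide peak list
make_random_peaklist <- function(n = 10, seed = 1, sample_label = "apo") {
  withr::with_seed(seed, {
    codes <- c("A", "G", "I", "K", "L", "Q", "S", "T", "V")
    peak_list(
      data.frame(
        residue_number = seq_len(n),
        residue_code = sample(codes, n, replace = TRUE),
        shift_n = runif(n, 105, 130),
        shift_h = runif(n, 6.5, 9.5),
        height = runif(n, 1e5, 5e6)
      ),
      sample_label = sample_label
    )
  })
}

# small exchange system for propagator-level tests
make_exchange_params <- function(p_minor = 0.0068, k_ex = 63,
                                 shift = 120, dw = 2, r1 = 1.2,
                                 r2a = 10, r2b = 14, mhz = 700) {
  exchange_params(
    data.frame(residue = 1, shift_major_n = shift, delta_shift_n = dw),
    p_minor = p_minor, k_ex = k_ex, r1 = r1, r2_major = r2a,
    r2_minor = r2b, spectrometer_h_mhz = mhz
  )
}

# Fixed-step classical 4th-order Runge-Kutta integration of
# dm/dt = L m.  Written directly against the generator so it shares no
# code with either matrix-exponential path; the step is chosen from the
# generator norm so the integration error stays well below the
# comparison tolerance.
rk4_propagate <- function(m0, L, t_total, target = 0.01) {
  norm_l <- max(rowSums(abs(L)))
  n_steps <- max(64L, ceiling(t_total * norm_l / target))
  h <- t_total / n_steps
  m <- m0
  for (i in seq_len(n_steps)) {
    k1 <- L %*% m
    k2 <- L %*% (m + h / 2 * k1)
    k3 <- L %*% (m + h / 2 * k2)
    k4 <- L %*% (m + h * k3)
    m <- m + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  as.numeric(m)
}

# random valid two-state parameter draw for property-style tests
draw_valid_params <- function() {
  make_exchange_params(
    p_minor = runif(1, 0.002, 0.99),
    k_ex = runif(1, 20, 300),
    shift = runif(1, 110, 126),
    dw = runif(1, 0.5, 4) * sample(c(-1, 1), 1),
    r1 = runif(1, 1, 1.5),
    r2a = runif(1, 5, 15),
    r2b = runif(1, 5, 15)
  )
}
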