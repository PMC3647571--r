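# Shared fixtures: the two illustrative patient profiles, a minimal
# single-equation dynamic-panel generator with mean-stationary initial
# conditions, and a tiny hand-checkable panel.

low_risk_profile <- function()
  patient_profile(age_at_diagnosis = 60, female = 1, smoker = 0,
                  hba1c = 7.00, sbp = 138.00, bmi = 27.00,
                  tchdl = 4.50, ldl = 3.00)

high_risk_profile <- function()
  patient_profile(age_at_diagnosis = 60, female = 0, smoker = 1,
                  hba1c = 7.00, sbp = 138.00, bmi = 32.00,
                  tchdl = 4.50, ldl = 3.00)

# y_it = alpha y_{i,t-1} + beta x_it + mu_i + nu_it with x predetermined-like
# (drawn independently); baselines carry mu_i/(1-alpha) so the levels-
# equation instruments are valid.
gen_ar1_panel <- function(n = 500, T = 7, alpha = 0.5, beta = 0.3,
                          sigma_mu = 0.5, sigma_nu = 0.5, const = 2) {
  mu <- stats::rnorm(n, 0, sigma_mu)
  y0 <- const / (1 - alpha) + mu / (1 - alpha) + stats::rnorm(n, 0, 0.7)
  x <- matrix(stats::rnorm(n * (T + 1)), n)
  Y <- matrix(NA_real_, n, T + 1)
  Y[, 1] <- y0
  for (t in seq_len(T))
    Y[, t + 1] <- const + alpha * Y[, t] + beta * x[, t + 1] + mu +
      stats::rnorm(n, 0, sigma_nu)
  data.frame(patient_id = rep(seq_len(n), each = T + 1),
             duration = rep(0:T, n),
             y = as.vector(t(Y)), x = as.vector(t(x)))
}

# three-patient toy panel with a gap and a single-observation patient
toy_panel <- function() {
  data.frame(
    patient_id = c(1, 1, 1, 2, 2, 3),
    duration   = c(1, 2, 3, 1, 3, 2),
    y          = c(7.0, 6.5, 6.5, 5.0, 4.0, 9.9))
}
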