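# Shared fixtures, all generated in code.

# frozen NWS oracle: (T degF, RH %) -> heat index degF, computed by direct
# arithmetic evaluation of the simple formula / Rothfusz polynomial and the
# two humidity adjustments, independently of the package implementation
nws_oracle <- data.frame(
  t = c(35, 70, 75, 60, 78, 85, 90, 96, 105, 100, 96, 110, 82, 86, 80),
  rh = c(50, 50, 80, 20, 40, 60, 50, 65, 40, 10, 8, 5, 90, 95, 100),
  hi = c(35, 69.05, 75.96, 56.64, 77.38,
         89.251256, 94.596941, 121.031629, 121.478080,
         94.122483, 89.781058, 101.401740,
         91.991678, 108.526762, 89.287853))

# fixed crossbasis used across tests: heat percentile x PM2.5 (ug/m3)
test_crossbasis <- function() {
  crossbasis_spec(
    basis_spec("bspline", df = 3, boundary = c(0, 100), reference = 50),
    basis_spec("bspline", df = 3, boundary = c(1, 40), reference = 5))
}

# separable synergistic truth on the crossbasis scale: interaction block is
# k * outer(c1, c2) so the interaction term equals k * g1(heat) * g2(pm)
# with both g increasing
synergy_beta <- function(k = 2.3, main = 0.05) {
  c1 <- c(0, 0.5, 1); c2 <- c(0, 0.5, 1)
  c(rep(main, 3), rep(main, 3), as.vector(t(k * outer(c1, c2))))
}

# hand-rolled conditional log-likelihood for a single numeric covariate,
# used as the independent oracle for the Newton fitter
oracle_cloglik <- function(b, x, sid, case) {
  sum(vapply(split(seq_along(x), sid), function(i) {
    x[i][case[i] == 1] * b - log(sum(exp(x[i] * b)))
  }, numeric(1)))
}

# draw one case per stratum with probability softmax(b * x), by direct
# per-stratum sampling (independent of the package's generator)
draw_cases <- function(x, sid, b) {
  case <- numeric(length(x))
  for (i in split(seq_along(x), sid)) {
    w <- exp(b * x[i])
    case[i[sample.int(length(i), 1, prob = w / sum(w))]] <- 1
  }
  case
}

# minimal admission record constructor
adm_row <- function(id, admit, discharge = NULL, dx = "DX001",
                    source = "er", snf = FALSE, zip = "Z00001") {
  admit <- as.Date(admit)
  discharge <- if (is.null(discharge)) admit + 3 else as.Date(discharge)
  data.frame(enrollee_id = id, admit_date = admit,
             discharge_date = discharge, dx_codes = dx,
             source_code = source, snf_flag = snf, zip = zip,
             stringsAsFactors = FALSE)
}
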