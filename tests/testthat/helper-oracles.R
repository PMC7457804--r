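# Independent brute-force oracle for the CAL-based Sullivan sum: an explicit
# double loop over Lexis diagonals, sharing no code with the package
# internals beyond the surface's long-form columns. With pi = 0 it is a
# brute-force CAL.
oracle_hcal <- function(surface, reference_year, pi_by_age,
                        a0_rule = "keyfitz", close_with_exposure = TRUE) {
  om <- max(surface$age)
  lookup <- tapply(surface$rate, list(surface$age, surface$year), identity)
  rate_at <- function(x, y) lookup[as.character(x), as.character(y)]
  a0_of <- function(m0) {
    if (a0_rule == "keyfitz") min(0.5, 0.07 + 1.7 * m0) else 0.3
  }
  q_of <- function(m, a) min(1, max(0, m / (1 + (1 - a) * m)))
  total <- 0
  for (x in 0:om) {
    p <- 1
    if (x > 0) {
      for (a in 0:(x - 1)) {
        m <- rate_at(a, reference_year - x + a)
        aa <- if (a == 0) a0_of(m) else 0.5
        p <- p * (1 - q_of(m, aa))
      }
    }
    m_now <- rate_at(x, reference_year)
    if (x == om) {
      L <- if (close_with_exposure && m_now > 0) p / m_now else 0
    } else {
      aa <- if (x == 0) a0_of(m_now) else 0.5
      q <- q_of(m_now, aa)
      L <- p * (1 - q) + aa * p * q
    }
    total <- total + (1 - pi_by_age[x + 1]) * L
  }
  total
}

# trapezoidal integral of a survivorship curve over its age grid
trapezoid <- function(p) sum((p[-1] + p[-length(p)]) / 2)

# a small stationary surface built by hand (not via the generator)
flat_surface <- function(mu, omega = 20, years = 2000:2005) {
  mortality_surface(
    tidyr::expand_grid(year = years, age = 0:omega) |>
      dplyr::mutate(rate = mu)
  )
}
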