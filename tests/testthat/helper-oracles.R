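# Independent brute-force evaluations of the pooling formulas, written
# as scalar accumulation loops so they share no code with the package's
# vectorized implementation.

oracle_iv <- function(y, v, random = FALSE) {
  k <- length(y)
  num <- den <- 0
  for (i in seq_len(k)) {
    num <- num + y[i] / v[i]
    den <- den + 1 / v[i]
  }
  est_fixed <- num / den
  tau2 <- 0
  if (random && k > 1) {
    q <- sw <- sw2 <- 0
    for (i in seq_len(k)) {
      q <- q + (y[i] - est_fixed)^2 / v[i]
      sw <- sw + 1 / v[i]
      sw2 <- sw2 + 1 / v[i]^2
    }
    tau2 <- max(0, (q - (k - 1)) / (sw - sw2 / sw))
  }
  num <- den <- 0
  for (i in seq_len(k)) {
    w <- 1 / (v[i] + if (random) tau2 else 0)
    num <- num + w * y[i]
    den <- den + w
  }
  list(est = num / den, se = sqrt(1 / den), tau2 = tau2)
}

# tables: list of c(a, n1, c, n2), assumed free of zero cells
oracle_mh <- function(tables, measure) {
  sr <- ss <- sp <- 0
  spr <- sps <- sqr <- sqs <- 0
  w <- wd <- vnum <- 0
  for (tb in tables) {
    a <- tb[1]; n1 <- tb[2]; cc <- tb[3]; n2 <- tb[4]
    b <- n1 - a; d <- n2 - cc; nn <- n1 + n2
    if (measure == "RR") {
      sr <- sr + a * n2 / nn
      ss <- ss + cc * n1 / nn
      sp <- sp + (n1 * n2 * (a + cc) - a * cc * nn) / nn^2
    } else if (measure == "OR") {
      r <- a * d / nn; s <- b * cc / nn
      p <- (a + d) / nn; q <- (b + cc) / nn
      sr <- sr + r; ss <- ss + s
      spr <- spr + p * r; sps <- sps + p * s
      sqr <- sqr + q * r; sqs <- sqs + q * s
    } else {
      w <- w + n1 * n2 / nn
      wd <- wd + (n1 * n2 / nn) * (a / n1 - cc / n2)
      vnum <- vnum + (a * b * n2^3 + cc * d * n1^3) / (n1 * n2 * nn^2)
    }
  }
  if (measure == "RR") {
    list(est = log(sr / ss), se = sqrt(sp / (sr * ss)))
  } else if (measure == "OR") {
    vr <- spr / (2 * sr^2) + (sps + sqr) / (2 * sr * ss) + sqs / (2 * ss^2)
    list(est = log(sr / ss), se = sqrt(vr))
  } else {
    list(est = wd / w, se = sqrt(vnum / w^2))
  }
}

rand_effects <- function(k) {
  lapply(seq_len(k), function(i)
    effect_estimate(stats::rnorm(1), stats::runif(1, 0.05, 2)))
}

# a 2x2 table with no zero cell
rand_table <- function() {
  repeat {
    n1 <- sample(20:100, 1); n2 <- sample(20:100, 1)
    a <- stats::rbinom(1, n1, stats::runif(1, 0.1, 0.6))
    cc <- stats::rbinom(1, n2, stats::runif(1, 0.1, 0.6))
    if (a > 0 && cc > 0 && a < n1 && cc < n2)
      return(c(a, n1, cc, n2))
  }
}

make_dich_study <- function(id, a, n1, cc, n2, labels = character()) {
  study_record(id, outcome_dichotomous(a, n1, cc, n2), labels = labels)
}

make_cont_study <- function(id, m_t, m_c, n = 50, sd = 1, labels = character()) {
  study_record(id, outcome_continuous(m_t, sd, n, m_c, sd, n), labels = labels)
}
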