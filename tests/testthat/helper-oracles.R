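# Independent straight-line oracles, written directly from the model
# definitions and kept free of the package's belief/likelihood code
# paths so they can serve as brute-force references.

# Build a session data frame from plain vectors (NA choice = missed).
make_session <- function(choice, outcome, subject = "t01",
                         schedule_id = "hand") {
  n <- length(choice)
  data.frame(
    subject = subject,
    trial = seq_len(n),
    block = ceiling(seq_len(n) / 50),
    choice = as.integer(choice),
    outcome = as.numeric(outcome),
    rt_s = ifelse(is.na(choice), NA_real_, 0.6),
    missed = as.integer(is.na(choice)),
    schedule_id = schedule_id,
    stringsAsFactors = FALSE
  )
}

# Brute-force per-trial trace of the eight model variants.
# learning: "delta" or "bayes"; rule: "SM","SME","SMP","SMEP";
# bonus_on: "sd" or "variance" (bayes; delta uses the recency count).
# Returns list(log_lik, probs [trials x 4]).
oracle_trace <- function(choice, outcome, learning, rule,
                         alpha = 0, beta = 0, phi = 0, rho = 0,
                         lambda = 0.9836, theta = 50, sd_d = 2.8,
                         sd_o = 4, q0 = 50,
                         v0 = 2.8^2 / (1 - 0.9836^2),
                         bonus_on = "sd") {
  nb <- 4
  n <- length(choice)
  Q <- rep(q0, nb)
  V <- rep(v0, nb)
  tsc <- rep(0, nb)
  last <- NA
  ll <- 0
  probs <- matrix(NA_real_, n, nb)
  for (t in seq_len(n)) {
    logit <- numeric(nb)
    for (i in 1:nb) {
      logit[i] <- beta * Q[i]
      if (rule %in% c("SME", "SMEP")) {
        u <- if (learning == "bayes") {
          if (bonus_on == "sd") sqrt(V[i]) else V[i]
        } else {
          tsc[i]
        }
        logit[i] <- logit[i] + phi * u
      }
      if (rule %in% c("SMP", "SMEP") && !is.na(last) && i == last) {
        logit[i] <- logit[i] + rho
      }
    }
    ex <- exp(logit - max(logit))
    p <- ex / sum(ex)
    probs[t, ] <- p
    if (!is.na(choice[t])) {
      c_t <- choice[t]
      ll <- ll + log(p[c_t])
      if (learning == "delta") {
        Q[c_t] <- Q[c_t] + alpha * (outcome[t] - Q[c_t])
      } else {
        k <- V[c_t] / (V[c_t] + sd_o^2)
        Q[c_t] <- Q[c_t] + k * (outcome[t] - Q[c_t])
        V[c_t] <- (1 - k) * V[c_t]
      }
      tsc <- tsc + 1
      tsc[c_t] <- 0
      last <- c_t
    } else {
      tsc <- tsc + 1
    }
    if (learning == "bayes") {
      for (i in 1:nb) {
        Q[i] <- lambda * Q[i] + (1 - lambda) * theta
        V[i] <- lambda^2 * V[i] + sd_d^2
      }
    }
  }
  list(log_lik = ll, probs = probs)
}

# Straight-line re-implementation of the three choice-type definitions.
oracle_classify <- function(q, choice, learning, variances = NULL,
                            trials_since = NULL) {
  if (is.na(choice)) return("missed")
  if (q[choice] >= max(q) - 1e-9) return("exploit")
  non_best <- which(q < max(q) - 1e-9)
  crit <- if (learning == "bayes") variances[non_best] else
    trials_since[non_best]
  target <- non_best[which.max(crit)]
  if (choice == target) "directed" else "random"
}

# Spearman rho by direct rank arithmetic (tie-corrected via mean ranks).
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
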