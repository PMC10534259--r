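# Independent brute-force implementations used as oracles. These are
# deliberately written as plain scalar loops over the model's
# definitional equations, sharing no code with the package internals.

# Elementwise-loop version of the elasticity response:
# dq_{j,g} = q_{j,g} * sum_k eps_{jk} dp_k
naive_elasticity_loop <- function(dp, E, q) {
  dq <- q * 0
  for (j in seq_len(nrow(q))) {
    pct <- 0
    for (k in seq_len(ncol(E))) pct <- pct + E[j, k] * dp[k]
    for (g in seq_len(ncol(q))) dq[j, g] <- q[j, g] * pct
  }
  dq
}

# Brute-force multi-state life table: one cohort at a time, one year at
# a time, one disease at a time. Uses only the model's definitions:
# rates -> probabilities via 1 - exp(-rate); illness-death submodel per
# disease; total mortality = other-cause (all-cause net of the disease
# deaths implied by the spec prevalence) + current modelled disease
# mortality; morbidity = prevalence-weighted disability (adult cohorts
# only); person-years by midpoint; HAPY = L * (1 - Y).
oracle_life_table <- function(population, diseases, mortality, dbmi,
                              n_years = 99) {
  ng <- nrow(population)
  nd <- length(diseases)
  if (length(dbmi) == 1) dbmi <- rep(dbmi, ng)
  hapy <- alive <- py <- matrix(0, n_years, ng)
  incident <- prevy <- matrix(0, n_years, nd,
                              dimnames = list(NULL, names(diseases)))
  for (g in seq_len(ng)) {
    sx <- population$sex[g]
    a0 <- population$age[g]
    N <- population$count[g]
    ell <- 1
    S <- C <- numeric(nd)
    for (d in seq_len(nd)) {
      C[d] <- diseases[[d]]$prevalence[as.character(a0), sx]
      S[d] <- 1 - C[d]
    }
    for (t in 0:(n_years - 1)) {
      a <- a0 + t
      if (a > 100 || ell <= 0) break
      ar <- as.character(a)
      m_oth <- mortality[ar, sx]
      for (d in seq_len(nd))
        m_oth <- m_oth - diseases[[d]]$prevalence[ar, sx] *
          diseases[[d]]$case_fatality[ar, sx]
      m_oth <- max(m_oth, 0)

      Y <- 0; qdis <- 0
      newS <- newC <- numeric(nd)
      for (d in seq_len(nd)) {
        tot <- S[d] + C[d]
        prev <- if (tot > 0) C[d] / tot else 0
        Y <- Y + prev * diseases[[d]]$disability_weight
        pif_d <- 1 - exp(diseases[[d]]$log_rr_per_bmi * dbmi[g])
        p_i <- 1 - exp(-(diseases[[d]]$incidence[ar, sx] * (1 - pif_d)))
        p_f <- 1 - exp(-diseases[[d]]$case_fatality[ar, sx])
        qdis <- qdis + prev * p_f
        incident[t + 1, d] <- incident[t + 1, d] +
          N * ell * (if (tot > 0) S[d] / tot else 0) * p_i
        newC[d] <- C[d] * (1 - p_f) + S[d] * p_i
        newS[d] <- S[d] * (1 - p_i)
      }
      q_tot <- min((1 - exp(-m_oth)) + qdis, 1)
      ell_new <- ell * (1 - q_tot)
      L <- (ell + ell_new) / 2
      alive[t + 1, g] <- N * ell
      py[t + 1, g] <- N * L
      hapy[t + 1, g] <- N * L * (1 - min(Y, 0.999))
      for (d in seq_len(nd)) {
        tot <- S[d] + C[d]
        prevy[t + 1, d] <- prevy[t + 1, d] +
          N * L * (if (tot > 0) C[d] / tot else 0)
      }
      S <- newS; C <- newC; ell <- ell_new
      if (a == 100) ell <- 0
    }
  }
  list(alive = alive, person_years = py, hapy = hapy,
       incident = incident, prev_years = prevy)
}
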