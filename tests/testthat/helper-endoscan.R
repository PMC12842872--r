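# Shared fixtures and independent oracles, built in code.

# tiny balanced cohort: K groups of n_per, optional covariates
tiny_sample_table <- function(K = 5, n_per = 4, seed = 1) {
  set.seed(seed)
  n <- K * n_per
  st <- data.frame(
    sample_id = sprintf("T%03d", seq_len(n)),
    endophenotype = rep(seq_len(K), each = n_per),
    age = stats::rnorm(n, 9, 2),
    sex = rep_len(c(0, 1), n),
    stringsAsFactors = FALSE)
  for (j in 1:10) st[[paste0("pc", j)]] <- stats::rnorm(n)
  st
}

tiny_genotypes <- function(dosage, ids = NULL, chrom = "1") {
  nv <- nrow(dosage)
  if (is.null(ids)) ids <- sprintf("v%03d", seq_len(nv))
  genotype_matrix(
    data.frame(id = ids, chrom = chrom, pos = 1000L * seq_len(nv),
               ref = "A", alt = "G", stringsAsFactors = FALSE),
    sprintf("T%03d", seq_len(ncol(dosage))), dosage)
}

# independent HWE oracle: Levene-Haldane recurrence over heterozygote counts
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  nB <- 2 * n - nA
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  probs <- numeric(length(hets))
  probs[1] <- 1
  if (length(hets) > 1) {
    for (i in 2:length(hets)) {
      h <- hets[i]                       # from h-2 hets to h hets
      aa_prev <- (nA - (h - 2)) / 2
      bb_prev <- (nB - (h - 2)) / 2
      probs[i] <- probs[i - 1] * 4 * aa_prev * bb_prev / (h * (h - 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# independent least-squares oracle: explicit normal equations
ols_oracle <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  sse <- sum((y - X %*% beta)^2)
  list(beta = drop(beta), sse = sse)
}

# partial-F oracle from explicit residual sums of squares
partialF_oracle <- function(y, group, covars = NULL) {
  g <- factor(group)
  K <- nlevels(g)
  G <- stats::model.matrix(~g)
  Xf <- if (is.null(covars)) G else cbind(G, covars)
  Xr <- if (is.null(covars)) G[, 1, drop = FALSE]
  else cbind(G[, 1, drop = FALSE], covars)
  sse_f <- ols_oracle(Xf, y)$sse
  sse_r <- ols_oracle(Xr, y)$sse
  df1 <- K - 1
  df2 <- length(y) - ncol(Xf)
  Fv <- ((sse_r - sse_f) / df1) / (sse_f / df2)
  list(F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

# logistic log-likelihood for the 2-parameter (intercept, slope) model
logit_loglik <- function(par, y, x) {
  eta <- par[1] + par[2] * x
  sum(y * eta - log1p(exp(eta)))
}
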