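# shared fixtures and independent oracles, built in code at test time

zs <- function(x) (x - mean(x)) / sd(x)

# from-scratch normal-equations OLS for the age coefficient: standardized
# outcome/age, z-scored continuous covariates, binary covariates as coded
oracle_age_fit <- function(data, outcome, covariates = character()) {
  cols <- c("age", outcome, covariates)
  d <- data[complete.cases(data[cols]), ]
  X <- cbind(`(Intercept)` = 1, age = zs(d$age))
  for (cv in covariates) {
    x <- d[[cv]]
    X <- cbind(X, if (length(unique(x)) <= 2) x else zs(x))
  }
  y <- zs(d[[outcome]])
  xtx_inv <- solve(t(X) %*% X)
  coefs <- xtx_inv %*% t(X) %*% y
  resid <- y - X %*% coefs
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * diag(xtx_inv))
  t_age <- unname(coefs["age", 1] / se["age"])
  list(beta = unname(coefs["age", 1]), se = unname(se["age"]),
       p = 2 * pt(-abs(t_age), df), df = df, n = nrow(X))
}

# small default cohort used across tests
tiny_cohort <- function(n = 120, seed = 1, ...) {
  generate_cohort(cohort_config(n = n, seed = seed, ...))
}
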