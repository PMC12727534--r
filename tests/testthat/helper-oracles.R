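# Independent oracles used to cross-check the package implementations.
# Each is coded directly from the defining formula, never by calling the
# code path it checks.

# OLS via the normal equations, solved in closed form
ols_normal_equations <- function(signal, reference) {
  n <- length(reference)
  sx <- sum(reference)
  sy <- sum(signal)
  sxx <- sum(reference^2)
  sxy <- sum(reference * signal)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

sse_of_fit <- function(signal, reference, fit) {
  sum((signal - (fit[["slope"]] * reference + fit[["intercept"]]))^2)
}

# Exact two-sided rank-sum p by full enumeration of all group assignments
ranksum_enumeration <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(n, na)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Sequential sums of squares via explicit design-matrix projections
anova_projection_oracle <- function(y, A, B) {
  proj_ss <- function(X, y) {
    fit <- lm.fit(X, y)
    sum(fit$fitted.values^2)
  }
  X0 <- matrix(1, length(y), 1)
  XA <- model.matrix(~A)
  XAB <- model.matrix(~A + B)
  XABI <- model.matrix(~A * B)
  ss_total <- sum(y^2)
  ss0 <- proj_ss(X0, y)
  ssA <- proj_ss(XA, y) - ss0
  ssB <- proj_ss(XAB, y) - proj_ss(XA, y)
  ssAB <- proj_ss(XABI, y) - proj_ss(XAB, y)
  ss_res <- ss_total - proj_ss(XABI, y)
  c(A = ssA, B = ssB, `A:B` = ssAB, residual = ss_res)
}

# Pooled two-sample t from the textbook closed form
pooled_t_closed_form <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  c(t = tstat, df = df, p = 2 * pt(abs(tstat), df, lower.tail = FALSE))
}

# Peak of the transient kernel after boxcar smoothing of width w seconds,
# from the closed-form antiderivative of the double exponential
attenuated_peak <- function(amplitude, tau_rise, tau_decay, w) {
  kmax <- max(exp(-seq(0, 5 * tau_decay, by = 1e-4) / tau_decay) -
              exp(-seq(0, 5 * tau_decay, by = 1e-4) / tau_rise))
  K <- function(t) (-tau_decay * exp(-t / tau_decay) +
                    tau_rise * exp(-t / tau_rise)) / kmax
  if (w <= 0) return(abs(amplitude))
  g <- function(t) (K(pmax(t + w / 2, 0)) - K(pmax(t - w / 2, 0))) / w
  abs(amplitude) * max(g(seq(0, 5 * tau_decay, by = 1e-3)))
}
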