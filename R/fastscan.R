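# Vectorized per-SNP association scans.
#
# A GWAS of M independent SNPs against one trait is M simple regressions
# (intercept + dosage). Fitting them one glm() at a time is the bottleneck
# of every simulation study here, so the linear scan is done in closed form
# and the logistic scan by IRLS batched across all SNPs at once; both are
# tested for equality with lm()/glm() and glm.fit() remains the per-column
# fallback when a column fails to converge.

# closed-form simple linear regression of y on each column of G
linear_scan <- function(G, y) {
  n <- length(y)
  stopifnot(nrow(G) == n)
  sg <- colSums(G)
  sgg <- colSums(G * G)
  sy <- sum(y)
  sgy <- colSums(G * y)
  sxx <- sgg - sg^2 / n
  sxy <- sgy - sg * sy / n
  syy <- sum(y^2) - sy^2 / n
  beta <- sxy / sxx
  sse <- pmax(syy - beta^2 * sxx, 0)
  se <- sqrt(sse / (n - 2) / sxx)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(beta = beta, se = se, p = p)
}

# batched IRLS for per-SNP logistic regression (intercept + dosage)
logistic_scan <- function(G, y, max_iter = 30L, tol = 1e-8) {
  n <- length(y)
  m <- ncol(G)
  stopifnot(nrow(G) == n, all(y %in% c(0, 1)))
  b0 <- rep(stats::qlogis(max(min(mean(y), 1 - 1e-10), 1e-10)), m)
  b1 <- rep(0, m)
  GG <- G * G
  converged <- rep(FALSE, m)
  for (it in seq_len(max_iter)) {
    eta <- sweep(G * rep(b1, each = n), 2L, b0, "+")
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    wz <- w * z
    sw <- colSums(w)
    swx <- colSums(w * G)
    swxx <- colSums(w * GG)
    swz <- colSums(wz)
    swxz <- colSums(wz * G)
    det <- sw * swxx - swx^2
    b0_new <- (swxx * swz - swx * swxz) / det
    b1_new <- (sw * swxz - swx * swz) / det
    step <- pmax(abs(b0_new - b0), abs(b1_new - b1))
    b0 <- b0_new
    b1 <- b1_new
    converged <- is.finite(step) & step < tol
    if (all(converged)) break
  }
  # SE of the slope from the inverse weighted information matrix
  eta <- sweep(G * rep(b1, each = n), 2L, b0, "+")
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  sw <- colSums(w)
  swx <- colSums(w * G)
  swxx <- colSums(w * GG)
  det <- sw * swxx - swx^2
  se <- sqrt(sw / det)
  res <- data.frame(beta = b1, se = se,
                    p = 2 * stats::pnorm(-abs(b1 / se)))
  bad <- which(!converged | !is.finite(res$beta) | !is.finite(res$se))
  for (j in bad) {  # fall back to glm.fit for pathological columns
    fit <- tryCatch(
      stats::glm.fit(cbind(1, G[, j]), y, family = stats::binomial()),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      res$beta[j] <- NA_real_; res$se[j] <- NA_real_; res$p[j] <- NA_real_
    } else {
      sm <- chol2inv(chol(crossprod(cbind(1, G[, j]) *
                                      sqrt(fit$weights))))
      res$beta[j] <- fit$coefficients[2L]
      res$se[j] <- sqrt(sm[2L, 2L])
      res$p[j] <- 2 * stats::pnorm(-abs(res$beta[j] / res$se[j]))
    }
  }
  res
}
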