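# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# Curvature magnitude of the circle circumscribing three consecutive
# points (Menger curvature): 4 * area / (product of side lengths).
circumcircle_curvature <- function(x, y, step = 1) {
  n <- length(x)
  idx <- (1 + step):(n - step)
  vapply(idx, function(i) {
    ax <- x[i - step]; ay <- y[i - step]
    bx <- x[i]; by <- y[i]
    cx <- x[i + step]; cy <- y[i + step]
    area2 <- abs((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
    ab <- sqrt((bx - ax)^2 + (by - ay)^2)
    bc <- sqrt((cx - bx)^2 + (cy - by)^2)
    ca <- sqrt((ax - cx)^2 + (ay - cy)^2)
    if (ab * bc * ca == 0) return(NA_real_)
    2 * area2 / (ab * bc * ca)
  }, numeric(1))
}

# Explicit sum-formula Pearson correlation (no call to cor()).
sum_formula_correlation <- function(u, w) {
  n <- length(u)
  mu <- sum(u) / n
  mw <- sum(w) / n
  num <- sum((u - mu) * (w - mw))
  den <- sqrt(sum((u - mu)^2) * sum((w - mw)^2))
  num / den
}

# Brute-force windowed SI oracle: recompute windows and correlations from
# a kinematic series with explicit loops and sum formulas.
si_window_oracle <- function(kin, window = 0.030, v_floor = 1e-3) {
  idx <- floor((kin$t - kin$t[1]) / window)
  out <- numeric(0)
  for (w in sort(unique(idx))) {
    sel <- which(idx == w & is.finite(kin$k) & abs(kin$k) > 0 &
                   kin$v > v_floor)
    if (length(sel) < 3) { out <- c(out, NA_real_); next }
    lk <- log(abs(kin$k[sel])); lv <- log(kin$v[sel])
    if (sd(lk) == 0 || sd(lv) == 0) { out <- c(out, NA_real_); next }
    out <- c(out, sum_formula_correlation(lk, lv))
  }
  out
}

# Nakagawa-Schielzeth pseudo-R2 recomputed from first principles: fixed
# predictor via explicit matrix multiply, sample variance by sum formula.
pseudo_r2_oracle <- function(fit) {
  X <- as.matrix(lme4::getME(fit$fit, "X"))
  b <- as.numeric(lme4::fixef(fit$fit))
  eta <- as.numeric(X %*% b)
  n <- length(eta)
  var_f <- sum((eta - mean(eta))^2) / (n - 1)
  vc <- as.data.frame(lme4::VarCorr(fit$fit))
  var_g <- sum(vc$vcov[vc$grp == "group_id"])
  var_p <- sum(vc$vcov[vc$grp == "participant_id"])
  var_e <- vc$vcov[vc$grp == "Residual"]
  tot <- var_f + var_g + var_p + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_g + var_p) / tot)
}
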