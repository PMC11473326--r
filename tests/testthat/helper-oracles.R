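# Independent oracles used to cross-check the implementation.

# Balanced-ANOVA method-of-moments variance components for one condition
# (lines x blocks, one observation per cell).  For balanced data these
# equal the REML estimates when both are interior.
anova_varcomp <- function(d) {
  stopifnot(all(table(d$line, d$block) == 1))
  r <- length(unique(d$block))
  l <- length(unique(d$line))
  grand <- mean(d$value)
  line_means <- tapply(d$value, d$line, mean)
  block_means <- tapply(d$value, d$block, mean)
  ss_line <- r * sum((line_means - grand)^2)
  ss_block <- l * sum((block_means - grand)^2)
  ss_tot <- sum((d$value - grand)^2)
  ss_err <- ss_tot - ss_line - ss_block
  ms_line <- ss_line / (l - 1)
  ms_err <- ss_err / ((l - 1) * (r - 1))
  c(var_G = max((ms_line - ms_err) / r, 0), var_error = ms_err,
    ms_line = ms_line, ms_error = ms_err)
}

# Direct evaluation of the restricted log-likelihood of the combined
# model y = X beta + Z1 g + Z2 gxp + e (dense matrix algebra), plus a
# bounded optimizer over the three variance components.
reml_loglik_direct <- function(y, X, Z1, Z2, vG, vGxP, vE) {
  n <- length(y); p <- qr(X)$rank
  V <- vG * tcrossprod(Z1) + vGxP * tcrossprod(Z2) + diag(vE, n)
  ch <- chol(V)
  Vi <- chol2inv(ch)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  res <- y - X %*% beta
  quad <- drop(t(res) %*% Vi %*% res)
  -0.5 * (2 * sum(log(diag(ch))) + determinant(XtVX)$modulus[1] +
            quad + (n - p) * log(2 * pi))
}

reml_oracle_combined <- function(d) {
  y <- d$value
  X <- stats::model.matrix(~ condition + condition:block, d)
  X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]
  Z1 <- stats::model.matrix(~ 0 + line, d)
  d$lc <- interaction(d$line, d$condition)
  Z2 <- stats::model.matrix(~ 0 + lc, d)
  obj <- function(logv) {
    v <- exp(logv)
    -reml_loglik_direct(y, X, Z1, Z2, v[1], v[2], v[3])
  }
  v0 <- rep(log(stats::var(y) / 3), 3)
  opt <- stats::optim(v0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  list(varcomp = stats::setNames(exp(opt$par),
                                 c("var_G", "var_GxP", "var_error")),
       loglik = -opt$value,
       loglik_at = function(vG, vGxP, vE)
         reml_loglik_direct(y, X, Z1, Z2, vG, vGxP, vE))
}

# O(n^3) UPGMA agglomeration oracle: returns merge heights in order and
# the cophenetic distance matrix.
upgma_oracle <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  heights <- numeric(0)
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  W <- D
  diag(W) <- Inf
  W[!active, ] <- Inf
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- W[idx, idx, drop = FALSE]
    k <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- idx[min(k)]; j <- idx[max(k)]
    h <- W[i, j]
    heights <- c(heights, h)
    for (a in members[[i]]) for (b in members[[j]]) {
      coph[a, b] <- coph[b, a] <- h
    }
    # size-weighted average distance to the merged cluster
    for (m in idx) {
      if (m == i || m == j) next
      W[i, m] <- W[m, i] <-
        (sizes[i] * W[i, m] + sizes[j] * W[j, m]) / (sizes[i] + sizes[j])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    W[j, ] <- W[, j] <- Inf
  }
  list(heights = heights, cophenetic = coph)
}

# Regression-R^2 VIF oracle (lm route, independent of the solve() path).
vif_oracle <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

# Small balanced single-condition phenotype table from explicit effects.
make_condition_table <- function(line_effects, block_effects, resid,
                                 mu = 0, trait = "T", condition = "C1") {
  l <- length(line_effects); r <- length(block_effects)
  stopifnot(length(resid) == l * r)
  d <- expand.grid(line = sprintf("L%02d", seq_len(l)),
                   block = sprintf("B%d", seq_len(r)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$condition <- condition
  d$trait <- trait
  d$value <- mu + line_effects[match(d$line, unique(d$line))] +
    block_effects[match(d$block, unique(d$block))] + resid
  d[, c("line", "condition", "block", "trait", "value")]
}
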