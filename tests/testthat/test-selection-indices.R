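make_panel <- function(n = 30, k = 4, seed = 61, rho = 0.5) {
  set.seed(seed)
  f <- rnorm(n)
  X <- sapply(seq_len(k), function(j) rho * f + sqrt(1 - rho^2) * rnorm(n))
  dimnames(X) <- list(sprintf("L%02d", seq_len(n)), paste0("t", seq_len(k)))
  X
}

test_that("relative trait values are elementwise ratios with a zero guard", {
  A <- make_panel(); B <- A * 2
  expect_equal(relative_trait_values(A, A), A / A)
  expect_true(all(relative_trait_values(A, B) == 0.5))
  B2 <- B; B2[3, 2] <- 1e-12
  expect_error(relative_trait_values(A, B2), "L03.*t2")
  expect_error(relative_trait_values(A, B[, c(2, 1, 3, 4)]),
               "share lines and traits")
})

test_that("PCA retains by the Kaiser rule with contribution rates over total variance", {
  # exactly orthogonal, mean-centred traits: identity spectrum, all kept
  set.seed(61)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(40 * 4), 40, 4))))[, 2:5]
  Z <- normalize_blups(q)
  p <- pca_kaiser(Z)
  expect_equal(unname(p$eigenvalues), rep(1, 4), tolerance = 1e-8)
  expect_true(all(p$retained))
  expect_equal(unname(p$cr), rep(0.25, 4), tolerance = 1e-8)

  # 2 traits with correlation r: eigenvalues 1 + r and 1 - r
  set.seed(62)
  x <- rnorm(100)
  Z2 <- normalize_blups(cbind(a = x, b = 0.8 * x + 0.6 * rnorm(100)))
  r <- cor(Z2)[1, 2]
  p2 <- pca_kaiser(Z2)
  expect_equal(unname(p2$eigenvalues), c(1 + r, 1 - r), tolerance = 1e-10)
  expect_equal(unname(p2$retained), c(TRUE, FALSE))
  expect_equal(unname(p2$cr[1]), (1 + r) / 2, tolerance = 1e-10)

  # trace conservation on random panels
  for (s in 1:5) {
    Z3 <- normalize_blups(make_panel(seed = 100 + s, k = 5))
    p3 <- pca_kaiser(Z3)
    expect_equal(sum(p3$eigenvalues), 5, tolerance = 1e-10)
    expect_equal(sum(p3$cr), 1, tolerance = 1e-10)
  }
  expect_error(pca_kaiser(matrix(rnorm(8), 4, 2)[, 1, drop = FALSE]),
               "2 traits")
  expect_error(pca_kaiser(matrix(rnorm(6), 2, 3)), "more lines")
})

test_that("component orientation makes uniformly large lines score positively", {
  Z <- normalize_blups(make_panel(seed = 63, rho = 0.7))
  p <- pca_kaiser(Z)
  expect_true(all(colSums(p$loadings) >= 0))
  # a line dominating every trait has a positive PC1 score
  i <- which.max(rowSums(Z))
  expect_gt(p$scores[i, 1], 0)
})

test_that("LPTI ranks a uniformly most-tolerant line first", {
  set.seed(64)
  A <- make_panel(seed = 64, rho = 0.6)
  B <- matrix(abs(rnorm(length(A), 10, 1)), nrow(A),
              dimnames = dimnames(A))
  # make line L01 uniformly the largest on the relative scale
  rel_boost <- A
  rel_boost["L01", ] <- apply(A, 2, max) + 2
  lpti <- compute_lpti(rel_boost * B, B)  # ratios recover rel_boost
  expect_equal(names(which.max(lpti)), "L01")
})

test_that("LPPI is a centred weighted sum of zero-mean scores", {
  A <- make_panel(seed = 65)
  lppi <- compute_lppi(A)
  expect_equal(mean(lppi), 0, tolerance = 1e-10)
  expect_error(compute_lppi(A[, 1, drop = FALSE]), "2 traits")
  # constant relative profiles are a documented degenerate case
  expect_error(compute_lpti(A, A), "constant")
})

test_that("a single retained component reduces the index to CR * PC1", {
  set.seed(66)
  f <- rnorm(50)
  X <- sapply(1:4, function(j) f + 0.2 * rnorm(50))
  dimnames(X) <- list(sprintf("L%02d", 1:50), paste0("t", 1:4))
  p <- pca_kaiser(normalize_blups(X))
  expect_equal(sum(p$retained), 1)
  lppi <- compute_lppi(X)
  expect_equal(unname(as.numeric(lppi)), unname(p$cr[1] * p$scores[, 1]),
               tolerance = 1e-10)
  expect_equal(order(lppi), order(p$scores[, 1]))
})

test_that("indices are invariant to affine rescaling of input traits", {
  A <- make_panel(seed = 67)
  scale_mat <- function(M) sweep(sweep(M, 2, c(2, 0.5, 10, 1), "*"),
                                 2, c(1, -3, 100, 0), "+")
  expect_equal(compute_lppi(scale_mat(A)), compute_lppi(A),
               tolerance = 1e-8)
})

test_that("quadrant classification partitions the panel", {
  lpti <- c(a = 1, b = 1, c = -1, d = -1, e = 0)
  lppi <- c(a = 1, b = -1, c = 1, d = -1, e = 0)
  g <- classify_groups(lpti, lppi)
  expect_equal(as.character(g[c("a", "b", "c", "d")]),
               c("TG", "TP", "SG", "SP"))
  expect_equal(as.character(g[["e"]]), "SP")  # boundary -> sensitive/poor
  set.seed(68)
  for (i in 1:20) {
    x <- rnorm(25); y <- rnorm(25)
    expect_equal(sum(table(classify_groups(x, y))), 25)
  }
})

test_that("top/bottom selection equals the rank-sum oracle and breaks ties by label", {
  set.seed(69)
  n <- 20
  lpti <- setNames(rnorm(n), sprintf("L%02d", 1:n))
  lppi <- setNames(rnorm(n), sprintf("L%02d", 1:n))
  sel <- select_lines(lpti, lppi, top_k = 6, bottom_k = 3)
  rs <- rank(-lpti) + rank(-lppi)
  oracle_top <- names(sort(rs))[1:6]
  expect_setequal(sel$line[sel$selected_top], oracle_top)
  oracle_bottom <- names(sort(rs, decreasing = TRUE))[1:3]
  expect_setequal(sel$line[sel$selected_bottom], oracle_bottom)

  expect_equal(sum(select_lines(lpti, lppi, 0, 0)$selected_top), 0)
  expect_error(select_lines(lpti, lppi, top_k = 21), "more lines")

  # deterministic alphabetical tie-break on equal rank sums
  tie_lpti <- c(B = 1, A = 1, C = 0)
  tie_lppi <- c(B = 1, A = 1, C = 0)
  s <- select_lines(tie_lpti, tie_lppi, top_k = 1, bottom_k = 1)
  expect_equal(s$line[s$selected_top], "A")
})

test_that("LPTI recovers a latent tolerance factor", {
  set.seed(70)
  n <- 120
  factor_true <- rnorm(n)
  lines <- sprintf("L%03d", 1:n)
  # relative values driven by the latent factor plus noise (sd 0.3 signal)
  rel <- sapply(1:5, function(j) 1 + 0.2 * factor_true +
                  0.2 * 0.3 * rnorm(n))
  dimnames(rel) <- list(lines, paste0("t", 1:5))
  B <- matrix(rnorm(n * 5, 50, 5), n, 5, dimnames = dimnames(rel))
  lpti <- compute_lpti(rel * B, B)
  expect_gt(cor(lpti, factor_true, method = "spearman"), 0.9)
})

test_that("panels built with dependent tolerance and performance show positively correlated indices", {
  set.seed(71)
  n <- 100
  quality <- rnorm(n)  # drives performance under stress AND maintenance
  lines <- sprintf("L%03d", 1:n)
  nap <- sapply(1:5, function(j) 10 + 2 * quality + rnorm(n))
  ap <- sapply(1:5, function(j) 15 + 0.5 * quality + rnorm(n))
  dimnames(nap) <- dimnames(ap) <- list(lines, paste0("t", 1:5))
  idx <- index_table(nap, ap, top_k = 10, bottom_k = 5)
  expect_gt(cor(idx$lpti, idx$lppi), 0)
  expect_equal(sum(table(factor(idx$group,
                                levels = c("TG", "SG", "TP", "SP")))), n)
  expect_equal(sum(idx$selected_top), 10)
  expect_equal(sum(idx$selected_bottom), 5)
})
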