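test_that("robust Z-score normalization follows the median/NIQR rule", {
  da <- tibble::tibble(a = c(1, 1, 1, 1))
  pa <- robust_z_fit(da, cols = "a")
  expect_true(pa$degenerate)
  expect_equal(robust_z_normalize(da, cols = "a")$a, rep(0, 4))

  df <- tibble::tibble(b = as.numeric(1:100), c = rnorm(100))
  params <- robust_z_fit(df, cols = c("b", "c"))
  expect_false(any(params$degenerate))
  expect_equal(params$niqr, 0.7414 * params$iqr)   # exact by construction

  norm <- robust_z_normalize(df, cols = c("b", "c"))
  # hand-computed: type-7 quartiles of 1..100 are 25.75 / 75.25
  expect_equal(norm$b[100], (100 - 50.5) / (0.7414 * 49.5), tolerance = 1e-12)
  expect_equal(norm$b[100], 1.3489, tolerance = 1e-4)
  # independent quantile oracle: sort-and-interpolate by hand
  s <- sort(df$c)
  q25 <- s[25] + 0.75 * (s[26] - s[25])  # h = (n-1)p+1 = 75.25 -> here 25.75
  q75 <- s[75] + 0.25 * (s[76] - s[75])
  med <- (s[50] + s[51]) / 2
  expect_equal(norm$c, (df$c - med) / (0.7414 * (q75 - q25)), tolerance = 1e-12)

  # every non-degenerate column: output median exactly 0, output NIQR exactly 1
  withr::with_seed(4, {
    for (i in 1:5) {
      x <- tibble::tibble(v = rcauchy(53))
      z <- robust_z_normalize(x, cols = "v")$v
      expect_equal(median(z), 0)
      q <- quantile(z, c(0.25, 0.75), type = 7, names = FALSE)
      expect_equal(0.7414 * (q[2] - q[1]), 1, tolerance = 1e-12)
    }
  })
  expect_error(robust_z_fit(tibble::tibble(v = NA_real_), cols = "v"), "empty")
})

test_that("Kruskal-Wallis matches the rank-sum formula", {
  # no-ties fixture, hand computation: H = 12/(9*10) * (6^2+15^2+24^2)/3 - 3*10
  kw <- kruskal_wallis(c(1:3, 4:6, 7:9), rep(c("a", "b", "c"), each = 3))
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2)

  expect_equal(kruskal_wallis(rep(5, 9), rep(c("a", "b", "c"), each = 3))$statistic, 0)

  # independent oracle with ties: explicit tie-corrected rank formula
  withr::with_seed(6, {
    x <- round(rnorm(30), 1)           # forces ties
    g <- rep(c("a", "b", "c"), each = 10)
    r <- rank(x)
    N <- length(x)
    H <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / 10) - 3 * (N + 1)
    ties <- table(x)
    H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
    expect_equal(kruskal_wallis(x, g)$statistic, H, tolerance = 1e-10)
  })
  expect_error(kruskal_wallis(1:3, rep("a", 3)), "2 nonempty groups")
})

test_that("Mann-Whitney U and exact p match enumeration", {
  # identical multisets: U = n1 n2 / 2
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$statistic, 4.5)

  # disjoint samples: U = 0; exact two-sided p = 2/20
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 0.1, tolerance = 1e-12)

  # enumeration oracle over all C(6,3) assignments for random tie-free data
  withr::with_seed(9, {
    a <- rnorm(3); b <- rnorm(3)
    u_stat <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    got <- mann_whitney(a, b)
    expect_equal(got$statistic, u_stat)
    pool <- c(a, b)
    combos <- combn(6, 3)
    u_all <- apply(combos, 2, function(idx) {
      sum(outer(pool[idx], pool[-idx], ">"))
    })
    mu <- length(a) * length(b) / 2
    p_oracle <- mean(abs(u_all - mu) >= abs(u_stat - mu) - 1e-12)
    expect_equal(got$p_value, p_oracle, tolerance = 1e-10)
  })
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("metric screening retains by omnibus significance", {
  withr::with_seed(10, {
    n <- 60
    labels <- factor(rep(c("novice", "intermediate", "novice2"), each = 20),
                     levels = c("novice", "intermediate", "novice2"))
    # build a feature table with one strongly separated metric among noise
    df <- tibble::tibble(
      trial_id = as.character(1:n), participant_id = as.character(1:n),
      task = "task1_dissection", n_prior_surgeries = 0L,
      label3 = factor(rep(c("novice", "intermediate", "expert"), each = 20),
                      levels = c("novice", "intermediate", "expert")),
      label2 = assign_group2(rep(0L, n)),
      strong = rep(c(0, 3, 6), each = 20) + rnorm(n, 0, 0.5),
      noise1 = rnorm(n), noise2 = rnorm(n))
    scr <- screen_metrics(df, alpha = 0.05)
    expect_true(scr$retained[scr$metric == "strong"])
    # pairwise columns only filled for retained metrics
    expect_true(all(is.na(scr$p_novice_intermediate[!scr$retained])))
    expect_false(anyNA(scr$p_novice_expert[scr$retained]))

    # alpha at the boundary retains everything with continuous data
    scr_all <- screen_metrics(df, alpha = 0.999999)
    expect_true(all(scr_all$retained))
  })
})

test_that("PCA of normalized metrics has the documented structure", {
  withr::with_seed(14, {
    # one varying column among constants: PC1 explains everything
    df1 <- tibble::tibble(a = rnorm(20), b = rep(1, 20), c = rep(2, 20))
    p1 <- pca_fit(df1, cols = c("a", "b", "c"))
    expect_equal(p1$explained_variance[1], 1)

    # perfectly correlated pair: second eigenvalue 0
    x <- rnorm(20)
    p2 <- pca_fit(tibble::tibble(a = x, b = 2 * x), cols = c("a", "b"))
    expect_equal(p2$sdev[2], 0, tolerance = 1e-12)

    # loadings are eigenvector * sqrt(eigenvalue) of the sample covariance
    m <- matrix(rnorm(30 * 4), 30, 4)
    df3 <- tibble::as_tibble(as.data.frame(m)); names(df3) <- letters[1:4]
    p3 <- pca_fit(df3, cols = letters[1:4])
    eig <- eigen(cov(m))
    want <- sweep(eig$vectors, 2, sqrt(pmax(eig$values, 0)), `*`)
    got <- as.matrix(p3$loadings[, -1])
    for (j in 1:4) {
      expect_equal(abs(got[, j]), abs(want[, j]), tolerance = 1e-8,
                   ignore_attr = TRUE)
      # sign convention: each component's largest-magnitude loading positive
      expect_gt(got[which.max(abs(got[, j])), j], 0)
    }
    # scores are uncorrelated and reconstruct the centered data
    sc <- as.matrix(p3$scores)
    cv <- cov(sc)
    expect_equal(cv - diag(diag(cv)), matrix(0, 4, 4), tolerance = 1e-10,
                 ignore_attr = TRUE)
    recon <- sc %*% t(p3$rotation)
    expect_equal(recon, scale(m, scale = FALSE), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(sum(p3$explained_variance), 1)

    # planted two-factor structure is recovered in the leading components
    n <- 120
    f1 <- rnorm(n); f2 <- rnorm(n)
    eff <- sapply(1:3, function(i) 3 * f1 + rnorm(n, 0, 0.3))
    spd <- sapply(1:3, function(i) 3 * f2 + rnorm(n, 0, 0.3))
    df4 <- tibble::as_tibble(as.data.frame(cbind(eff, spd)))
    names(df4) <- c(paste0("eff", 1:3), paste0("spd", 1:3))
    norm4 <- robust_z_normalize(df4, cols = names(df4))
    p4 <- pca_fit(norm4, cols = names(df4))
    l <- as.matrix(p4$loadings[, c("PC1", "PC2")])
    rownames(l) <- p4$loadings$metric
    for (pc in 1:2) {
      ld <- abs(l[, pc])
      top <- names(sort(ld, decreasing = TRUE))[1:3]
      # the three top loadings belong to one factor family...
      expect_true(all(startsWith(top, "eff")) || all(startsWith(top, "spd")))
      # ...and the other family's loadings are small cross-loadings
      other <- setdiff(rownames(l), top)
      expect_lt(max(ld[other]), 0.3 * max(ld))
    }

    # NIQR scaling admits loadings above 1 for heavy-tailed metrics
    heavy <- tibble::tibble(h = rcauchy(200), g = rnorm(200))
    nh <- robust_z_normalize(heavy, cols = c("h", "g"))
    ph <- pca_fit(nh, cols = c("h", "g"))
    expect_gt(max(abs(as.matrix(ph$loadings[, -1]))), 1)
  })
})
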