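# Independent brute-force agreement oracle: literal per-subject evaluation of
# the weighted-count definitions, kept free of the package's vectorized path.
oracle_ac2 <- function(responses, K = 3) {
  # responses: subjects x raters matrix, NA = missing
  W <- outer(seq_len(K), seq_len(K),
             function(k, l) 1 - choose(abs(k - l) + 1, 2) / choose(K, 2))
  n <- nrow(responses)
  pa_terms <- c(); pik <- matrix(NA, n, K)
  for (i in seq_len(n)) {
    resp <- responses[i, !is.na(responses[i, ])]
    ri <- length(resp)
    if (ri < 1) next
    r_ik <- vapply(seq_len(K), function(k) sum(resp == k), numeric(1))
    pik[i, ] <- r_ik / ri
    if (ri >= 2) {
      rstar <- as.vector(W %*% r_ik)
      pa_terms <- c(pa_terms, sum(r_ik * (rstar - 1)) / (ri * (ri - 1)))
    }
  }
  pa <- mean(pa_terms)
  pk <- colMeans(pik, na.rm = TRUE)
  pe <- (sum(W) / (K * (K - 1))) * sum(pk * (1 - pk))
  list(pa = pa, pe = pe, ac2 = (pa - pe) / (1 - pe))
}

test_that("ordinal weights follow the combination formula", {
  expect_equal(ordinal_weights(3),
               matrix(c(1, 2/3, 0, 2/3, 1, 2/3, 0, 2/3, 1), 3, 3))
  expect_equal(ordinal_weights(2), diag(2))
  for (K in 2:6) {
    W <- ordinal_weights(K)
    expect_equal(diag(W), rep(1, K))
    expect_equal(W, t(W))
  }
  expect_error(ordinal_weights(1), "at least 2")
})

test_that("AC2 matches hand computation and the brute-force oracle", {
  # 4 subjects, 2 raters: ((1,1),(2,2),(3,3),(1,2))
  resp <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2))
  r <- gwet_ac2(resp, K = 3)
  expect_equal(r$pa, (1 + 1 + 1 + 2/3) / 4, tolerance = 1e-12)
  expect_equal(r$pe, (17/3) / 6 * (2 * 0.375 * 0.625 + 0.25 * 0.75),
               tolerance = 1e-12)
  expect_equal(r$ac2, 0.7808219, tolerance = 1e-6)
  orc <- oracle_ac2(resp)
  expect_equal(r$pa, orc$pa, tolerance = 1e-12)
  expect_equal(r$pe, orc$pe, tolerance = 1e-12)
  expect_equal(r$ac2, orc$ac2, tolerance = 1e-12)

  # random missing-data cases against the oracle
  set.seed(202)
  for (rep in 1:10) {
    m <- matrix(sample(1:3, 12 * 5, replace = TRUE), 12, 5)
    m[runif(60) < 0.25] <- NA
    m[1, ] <- c(2, rep(NA, 4))   # a single-rated subject contributes to pe only
    r <- gwet_ac2(m, K = 3)
    orc <- oracle_ac2(m)
    expect_equal(r$pa, orc$pa, tolerance = 1e-12)
    expect_equal(r$pe, orc$pe, tolerance = 1e-12)
    expect_equal(r$ac2, orc$ac2, tolerance = 1e-12)
    # defining identity, and the result is internally consistent
    expect_equal(r$ac2, (r$pa - r$pe) / (1 - r$pe), tolerance = 1e-12)
  }
})

test_that("perfect agreement gives pa = 1 and AC2 = 1", {
  resp <- matrix(rep(c(1, 2, 3, 2, 1), 4), 5, 4)
  r <- gwet_ac2(resp, K = 3)
  expect_equal(r$pa, 1)
  expect_equal(r$ac2, 1)
})

test_that("AC2 is invariant under reversal of the ordinal scale", {
  set.seed(7)
  m <- matrix(sample(1:3, 40, replace = TRUE), 10, 4)
  r1 <- gwet_ac2(m, K = 3)
  r2 <- gwet_ac2(4 - m, K = 3)
  expect_equal(r1$ac2, r2$ac2, tolerance = 1e-12)
  expect_equal(r1$pa, r2$pa, tolerance = 1e-12)
})

test_that("degenerate ratings raise the documented errors", {
  expect_error(gwet_ac2(rbind(c(1, NA), c(2, NA), c(3, NA)), K = 3),
               "pa undefined")
})

test_that("benchmark labels reproduce the published reliability scale", {
  expect_equal(benchmark_label(0.74), "substantial")
  expect_equal(benchmark_label(0.11), "poor")
  expect_equal(benchmark_label(0.20), "poor")      # closed boundary
  expect_equal(benchmark_label(0.205), "poor")     # rounded to 2 dp first
  expect_equal(benchmark_label(0.21), "fair")
  expect_equal(benchmark_label(c(0.41, 0.60, 0.61, 0.81, 1.0)),
               c("moderate", "moderate", "substantial", "excellent", "excellent"))
  expect_equal(benchmark_label(-0.3), "poor")
})

test_that("Stuart-Maxwell reduces to McNemar for 2x2 and is zero on symmetry", {
  # symmetric tables: no marginal shift
  for (K in 2:4) {
    t <- matrix(3, K, K); diag(t) <- 10
    r <- stuart_maxwell(t)
    expect_equal(r$chi2, 0, tolerance = 1e-12)
    expect_equal(r$p, 1)
  }
  # closed-form equality over all 2x2 off-diagonal pairs
  for (b in 0:20) for (cc in 0:20) {
    if (b + cc == 0) next
    r <- stuart_maxwell(matrix(c(5, cc, b, 7), 2, 2, byrow = TRUE))
    expect_equal(r$chi2, (b - cc)^2 / (b + cc), tolerance = 1e-10)
    expect_equal(r$dof, 1L)
  }
  # the 3-level scale tests on 2 degrees of freedom
  t3 <- matrix(c(10, 3, 1, 2, 12, 4, 1, 2, 9), 3, 3, byrow = TRUE)
  r3 <- stuart_maxwell(t3)
  expect_equal(r3$dof, 2L)
  expect_equal(r3$p, stats::pchisq(r3$chi2, 2, lower.tail = FALSE))
  # uninvolved categories are collapsed out
  t_pad <- rbind(cbind(t3, 0), c(0, 0, 0, 6))
  expect_equal(stuart_maxwell(t_pad)$dof, 2L)
  expect_equal(stuart_maxwell(t_pad)$chi2, r3$chi2, tolerance = 1e-12)

  expect_error(stuart_maxwell(matrix(c(1, -1, 2, 1), 2, 2)), "non-negative")
})

test_that("Spearman correlation handles the limiting and exact cases", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:4, 1:5), "equal length")

  # exact p equals full enumeration (independent oracle via cor on ranks)
  set.seed(31)
  for (rep in 1:4) {
    n <- 6
    x <- sample(100, n); y <- sample(100, n)
    got <- spearman_cor(x, y)
    expect_equal(got$method, "exact")
    perms <- fwtract:::permutations_of(n)
    rho_obs <- cor(rank(x), rank(y))
    rho_all <- apply(perms, 1, function(p) cor(rank(x), p))
    expect_equal(got$p, mean(abs(rho_all) >= abs(rho_obs) - 1e-12),
                 tolerance = 1e-12)
    # and agrees with the reference exact implementation
    ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }

  # ties or larger n fall back to the t approximation
  expect_equal(spearman_cor(c(1, 1, 2, 3, 4), c(2, 3, 1, 5, 4))$method, "t")
  expect_equal(spearman_cor(rnorm(20), rnorm(20))$method, "t")
})

test_that("p-value adjustment is Bonferroni by default, Holm by flag", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.06, 0.09))
  expect_equal(adjust_pvalues(0.04), 0.04)               # m = 1: unchanged
  expect_equal(adjust_pvalues(c(0.4, 0.5)), c(0.8, 1.0)) # capped at 1
  expect_equal(adjust_pvalues(c(0.01, 0.04), method = "holm"),
               stats::p.adjust(c(0.01, 0.04), "holm"))
})

test_that("the ratings simulator produces the configured survey", {
  # forced agreement
  rt <- simulate_ratings(10, 5, c(0, 0, 1), seed = 4)
  expect_equal(gwet_ac2(rt)$ac2, 1)

  # chance-level agreement under uniform responding
  rt_u <- simulate_ratings(200, 2, rep(1/3, 3), seed = 8)
  expect_lt(abs(gwet_ac2(rt_u)$ac2), 0.1)

  # missing rate close to nominal
  rt_m <- simulate_ratings(100, 10, c(0.2, 0.3, 0.5), missing_rate = 0.3,
                           seed = 15)
  frac_missing <- 1 - nrow(rt_m$data) / 1000
  expect_lt(abs(frac_missing - 0.3), 0.05)

  # determinism
  expect_identical(simulate_ratings(20, 4, c(0.5, 0.3, 0.2), 0.2, seed = 99)$data,
                   simulate_ratings(20, 4, c(0.5, 0.3, 0.2), 0.2, seed = 99)$data)
})

test_that("ratings tables accept labels and the CSV round-trips", {
  df <- data.frame(item = "i1", subject = c("s1", "s1", "s2", "s2"),
                   rater = c("r1", "r2", "r1", "r2"),
                   response = c("True", "Partially True", "False", ""))
  rt <- ratings_table(df)
  expect_equal(rt$data$response, c(3L, 2L, 1L))   # blank dropped

  f <- tempfile(fileext = ".csv")
  sim <- simulate_ratings(12, 6, c(0.1, 0.2, 0.7), missing_rate = 0.1, seed = 2)
  utils::write.csv(sim$data, f, row.names = FALSE)
  back <- read_ratings(f)
  expect_equal(back$data, sim$data)

  rep <- survey_report(sim)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$ac2, (rep$pa - rep$pe) / (1 - rep$pe), tolerance = 1e-12)
})
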