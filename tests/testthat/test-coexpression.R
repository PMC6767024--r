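make_prototype_profiles <- function(n_per = 30, noise_sd = 0.1, seed = 1) {
  # 8 well-separated prototypes in 4-dim profile space: up or down in each
  # of the four genotypes
  protos <- rbind(diag(4) * 2 - 0.5, -(diag(4) * 2 - 0.5))
  set.seed(seed)
  prof <- protos[rep(1:8, each = n_per), ] +
    matrix(rnorm(8 * n_per * 4, 0, noise_sd), 8 * n_per, 4)
  rownames(prof) <- sprintf("g%03d", seq_len(8 * n_per))
  colnames(prof) <- c("parent1", "parent2", "hybrid1", "hybrid2")
  list(profiles = prof, label = rep(1:8, each = n_per))
}

test_that("a 1x1 grid collapses all genes into one module at the mean profile", {
  d <- make_prototype_profiles()
  m <- train_som(d$profiles, rows = 1, cols = 1, epochs = 10, seed = 1)
  a <- assign_modules(m, d$profiles)
  expect_true(all(a$unit == 1))
  expect_equal(as.vector(m$codebook), unname(colMeans(d$profiles)),
               tolerance = 1e-8)
})

test_that("a 1x2 grid splits two separated clusters like exhaustive 2-means", {
  set.seed(2)
  n <- 10
  prof <- rbind(matrix(rnorm(20, 5, 0.2), 5, 4),
                matrix(rnorm(20, -5, 0.2), 5, 4))
  rownames(prof) <- sprintf("g%02d", 1:n)
  # exhaustive 2-means oracle: best of all 2-partitions by within-cluster SS
  best <- NULL; best_ss <- Inf
  for (mask in 1:(2^n - 2)) {
    part <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    ss <- sum(scale(prof[part, , drop = FALSE], scale = FALSE)^2) +
      sum(scale(prof[!part, , drop = FALSE], scale = FALSE)^2)
    if (ss < best_ss) { best_ss <- ss; best <- part }
  }
  m <- train_som(prof, rows = 1, cols = 2, epochs = 30, seed = 1)
  a <- assign_modules(m, prof)
  split1 <- a$unit == a$unit[1]
  expect_true(all(split1 == best) || all(split1 == !best))
})

test_that("batch training does not end worse than it started (quantization error)", {
  d <- make_prototype_profiles()
  m <- train_som(d$profiles, epochs = 40, seed = 2)
  expect_lte(m$qe[40], m$qe[1])
})

test_that("SOM training is deterministic given the seed", {
  d <- make_prototype_profiles()
  m1 <- train_som(d$profiles, seed = 7)
  m2 <- train_som(d$profiles, seed = 7)
  expect_identical(m1$codebook, m2$codebook)
})

test_that("module assignment maps exact codebook matches and breaks ties low", {
  d <- make_prototype_profiles()
  m <- train_som(d$profiles, seed = 1)
  a <- assign_modules(m, m$codebook)
  expect_equal(unname(a$unit), seq_len(nrow(m$codebook)))
  # two-unit map: the codebook midpoint is equidistant -> lowest unit wins
  set.seed(3)
  prof2 <- rbind(matrix(rnorm(20, 4, 0.1), 5, 4), matrix(rnorm(20, -4, 0.1), 5, 4))
  rownames(prof2) <- sprintf("g%02d", 1:10)
  m2 <- train_som(prof2, rows = 1, cols = 2, epochs = 20, seed = 1)
  mid <- matrix((m2$codebook[1, ] + m2$codebook[2, ]) / 2, 1)
  rownames(mid) <- "tie"
  expect_equal(unname(assign_modules(m2, mid)$unit), 1L)
})

test_that("co-module screening returns TFs sharing the anchor's unit", {
  d <- make_prototype_profiles()
  m <- train_som(d$profiles, seed = 1)
  a <- assign_modules(m, d$profiles)
  anchor <- "g001"
  mates <- names(a$unit)[a$unit == a$unit[[anchor]]]
  tfs <- c("g002", "g003", "g004", "g100")  # g100 sits on another prototype
  got <- co_module_candidates(a, anchor, tfs)
  expect_setequal(got[[anchor]], intersect(setdiff(mates, anchor), tfs))
  expect_false("g100" %in% got[[anchor]])
  # an anchor alone in its unit yields an empty set
  solo_prof <- rbind(d$profiles, solo = c(10, -10, 10, -10))
  a2 <- assign_modules(m, solo_prof)
  if (sum(a2$unit == a2$unit[["solo"]]) == 1)
    expect_length(co_module_candidates(a2, "solo", tfs)$solo, 0)
  expect_error(co_module_candidates(a, "nope", tfs), "not in the module")
})

test_that("correlation p-values match the t transformation and its quadrature oracle", {
  expect_equal(round(correlation_p(0.978, 4), 3), 0.022)
  expect_equal(correlation_p(0, 10), 1)
  expect_equal(correlation_p(1, 5), 0)
  # quadrature oracle: integrate the t density for r = 0.5, n = 12
  r <- 0.5; n <- 12
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  dens <- function(x) dt(x, df = n - 2)
  p_quad <- 2 * integrate(dens, tval, Inf)$value
  expect_equal(correlation_p(r, n), p_quad, tolerance = 1e-6)
  expect_error(correlation_p(0.5, 2), "n >= 3")
})

test_that("correlation_p decreases in |r| and in n", {
  rs <- seq(0.1, 0.9, by = 0.1)
  ps <- correlation_p(rs, 10)
  expect_true(all(diff(ps) < 0))
  ns <- c(4, 6, 10, 20, 50)
  pn <- correlation_p(0.5, ns)
  expect_true(all(diff(pn) < 0))
})

test_that("correlation matrix is symmetric with unit diagonal and hand-checked entries", {
  prof <- rbind(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8), z = c(4, 3, 2, 1))
  cm <- correlation_matrix(prof)
  expect_equal(cm$r["x", "y"], 1)
  expect_equal(cm$r["x", "z"], -1)
  expect_equal(cm$r, t(cm$r))
  expect_true(all(diag(cm$r) == 1))
  # hand covariance-formula check on a 4-point pair
  a <- c(1, 3, 2, 5); b <- c(2, 3, 7, 4)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  cm2 <- correlation_matrix(rbind(a = a, b = b, c = c(1, 1, 2, 1)))
  expect_equal(cm2$r["a", "b"], r_hand)
  long <- correlation_long(cm2)
  expect_equal(nrow(long), 3)
  expect_equal(long$r[long$a == "a" & long$b == "b"], r_hand)
})
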