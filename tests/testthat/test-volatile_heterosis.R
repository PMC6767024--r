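test_that("internal-standard quantification follows the area-ratio formula", {
  expect_equal(quantify_internal_standard(1000, 1000, 1.5, 5), 300)
  expect_equal(quantify_internal_standard(0, 1000, 1.5, 5), 0)
  expect_equal(quantify_internal_standard(2000, 1000, 1.5, 5), 600)
  expect_error(quantify_internal_standard(100, 0, 1.5, 5), "division")
  expect_error(quantify_internal_standard(100, 100, 1.5, 0), "division")
})

test_that("class_sum adds per-compound means within a class and genotype", {
  means <- read.delim(system.file("extdata", "tea_volatile_means.tsv",
                                  package = "teaheterosis"))
  expect_equal(class_sum(means, "monoterpene", "HGY"), 1500.79)
  expect_equal(class_sum(means, "sesquiterpene", "HGY"), 42.58)
  # replicate-level input: means over replicates are summed
  tab <- data.frame(compound = rep(c("a", "b"), each = 2), class = "GLV",
                    genotype = "X", concentration = c(1, 3, 10, 30))
  expect_equal(class_sum(tab, "GLV", "X"), 2 + 20)
  expect_warning(out <- class_sum(tab, "missing", "X"), "sum is 0")
  expect_equal(out, 0)
})

test_that("MPV and OPV match the defining formulas and hand values", {
  expect_equal(round(mid_parent_heterosis(432.93, 400.67, 284.18), 2), 26.43)
  expect_equal(round(mid_parent_heterosis(1500.79, 766.43, 916.7), 2), 78.33)
  expect_equal(round(over_high_parent_heterosis(1500.79, 766.43, 916.7), 2), 63.72)
  expect_equal(round(over_high_parent_heterosis(24.98, 22.28, 16.18), 2), 12.12)
  # midpoint and high-parent fixed points
  expect_equal(mid_parent_heterosis((400 + 300) / 2, 400, 300), 0)
  expect_equal(over_high_parent_heterosis(400, 400, 300), 0)
  expect_error(mid_parent_heterosis(10, 1, -1), "undefined")
})

test_that("MPV >= OPV and both are symmetric in the parents", {
  set.seed(42)
  for (i in 1:500) {
    x <- runif(3, 0.01, 1000)
    expect_gte(mid_parent_heterosis(x[1], x[2], x[3]),
               over_high_parent_heterosis(x[1], x[2], x[3]))
    expect_equal(mid_parent_heterosis(x[1], x[2], x[3]),
                 mid_parent_heterosis(x[1], x[3], x[2]))
    expect_equal(over_high_parent_heterosis(x[1], x[2], x[3]),
                 over_high_parent_heterosis(x[1], x[3], x[2]))
  }
})

test_that("letter display separates groups exactly where Welch tests do", {
  # four identical groups share one letter
  g <- list(a = c(5, 5.1, 4.9), b = c(5, 5.1, 4.9),
            c = c(5, 5.1, 4.9), d = c(5, 5.1, 4.9))
  expect_equal(unname(letter_groups(g)), rep("a", 4))
  # two clearly different groups get distinct letters; reference Welch p
  x <- c(100, 105, 95); y <- c(1, 1.05, 0.95)
  expect_lt(t.test(x, y)$p.value, 0.05)
  expect_equal(sort(unname(letter_groups(list(hi = x, lo = y)))), c("a", "b"))
  expect_error(letter_groups(list(a = 1, b = c(1, 2))), "replicates")
})

test_that("insert-absorb letters reproduce the chained A~B, B~C, A!=C case", {
  # hand-built significance structure via group data chosen so that only the
  # extreme pair differs (checked against pairwise Welch p-values)
  A <- c(9, 10, 11); B <- c(7.4, 8.4, 9.4); C <- c(6, 7, 8)
  stopifnot(t.test(A, B)$p.value > 0.05, t.test(B, C)$p.value > 0.05,
            t.test(A, C)$p.value < 0.05)
  lets <- letter_groups(list(A = A, B = B, C = C))
  expect_equal(unname(lets), c("a", "ab", "b"))
})

test_that("letter assignment is stable under group relabeling", {
  g <- list(a = c(100, 104, 96), b = c(1, 1.1, 0.9), c = c(1.05, 1, 0.95))
  l1 <- letter_groups(g)
  l2 <- letter_groups(rev(g))
  # partition structure identical: same groups share letters
  share <- function(l, i, j) any(strsplit(l[[i]], "")[[1]] %in% strsplit(l[[j]], "")[[1]])
  for (i in names(g)) for (j in names(g))
    expect_equal(share(l1, i, j), share(l2, i, j))
})

test_that("heterosis table recovers planted volatile heterosis at cv -> 0", {
  vt <- generate_volatile_table(
    list(mono = c(parent1 = 400, parent2 = 300, hybrid1 = 437.5, hybrid2 = 437.5)),
    cv = 0, n_replicates = 3, seed = 1)
  ht <- volatile_heterosis_table(vt, hybrids = c("hybrid1", "hybrid2"),
                                 parents = c("parent1", "parent2"))
  expect_equal(ht$MPV, c(25, 25))  # (437.5 - 350)/350 * 100
  # midpoint hybrid has zero MPV
  vt2 <- generate_volatile_table(list(mono = c(400, 300, 350, 350)), cv = 0, seed = 1)
  ht2 <- volatile_heterosis_table(vt2, c("hybrid1", "hybrid2"),
                                  c("parent1", "parent2"))
  expect_equal(ht2$MPV, c(0, 0))
})

test_that("summarize_volatiles reports means, sds and letters per compound and class sum", {
  vt <- generate_volatile_table(list(mono = c(400, 300, 900, 900),
                                     sesq = c(10, 10, 10, 10)),
                                cv = 0.05, n_replicates = 3, seed = 4)
  sv <- summarize_volatiles(vt)
  expect_true(all(c("Sum (mono)", "Sum (sesq)") %in% sv$compound))
  expect_equal(nrow(sv), 4 * 4)  # 2 compounds + 2 sums, 4 genotypes each
  hyb <- sv[sv$compound == "mono_cmp1" & sv$genotype == "hybrid1", ]
  expect_equal(hyb$mean, 900, tolerance = 0.2)
  # hybrids significantly above parents -> different letters
  lets <- sv[sv$compound == "mono_cmp1", ]
  expect_false(lets$letter[lets$genotype == "hybrid1"] ==
                 lets$letter[lets$genotype == "parent2"])
})
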