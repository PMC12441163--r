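test_that("CPM normalization equalizes library-size differences", {
  m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  norm <- cpm_normalize(m)
  # s2 has exactly twice the depth with identical underlying rates
  expect_equal(norm[, 1], norm[, 2])
  # equal library sizes preserve count ratios exactly
  m2 <- cbind(a = c(10, 30), b = c(20, 20))
  n2 <- cpm_normalize(m2, lib_size = c(40, 40))
  expect_equal(n2[1, ] / n2[2, ], m2[1, ] / m2[2, ])
  expect_error(cpm_normalize(m, lib_size = c(0, 10)), "library size")
})

test_that("fold change is the pseudocounted ratio of means", {
  norm <- rbind(gA = c(1790, 1790, 10, 10),
                gB = c(17900, 17900, 100, 100),
                gzero = c(0, 0, 0, 0))
  design <- c("m", "m", "c", "c")
  fc <- fold_change(norm, design, "m", "c")
  expect_equal(unname(fc["gA"]), 1791 / 11)
  # when means dwarf the pseudocount the ratio approaches 179
  expect_lt(abs(fc["gB"] / 179 - 1), 0.01)
  expect_equal(unname(fc["gzero"]), 1)   # all-zero gene: fold 1
  expect_error(fold_change(norm, design, "m", "x"), "not present")
})

test_that("BH adjustment matches a brute-force step-up implementation", {
  bh_brute <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
    q <- numeric(m)
    q[o] <- pmin(q_sorted, 1)
    q
  }
  set.seed(42)
  for (r in 1:10) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, "BH"), bh_brute(p))
  }
})

test_that("q-values are monotone non-decreasing in p", {
  grp <- rep(c("m", "c"), each = 3)
  cnt <- simulate_counts(500, grp, dispersion = 0.1, seed = 9)
  deg <- test_deg(cpm_normalize(cnt), grp, line_a = "m", line_b = "c")
  ok <- deg$tested & !is.na(deg$p_value)
  o <- order(deg$p_value[ok])
  expect_true(all(diff(deg$q_value[ok][o]) >= -1e-12))
})

test_that("the per-gene ANOVA path equals the pooled two-sample t test", {
  set.seed(4)
  norm <- matrix(rlnorm(5 * 8, 4, 1), nrow = 5,
                 dimnames = list(paste0("g", 1:5), NULL))
  design <- rep(c("m", "c"), each = 4)
  deg <- test_deg(norm, design, line_a = "m", line_b = "c",
                  method = "anova")
  logm <- log2(norm + 1)
  for (i in 1:5) {
    tt <- t.test(logm[i, design == "m"], logm[i, design == "c"],
                 var.equal = TRUE)
    expect_equal(deg$p_value[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("constant genes are reported untested and non-significant", {
  norm <- rbind(flat = rep(5, 4), varying = c(1, 2, 40, 40))
  deg <- test_deg(norm, rep(c("m", "c"), each = 2), line_a = "m",
                  line_b = "c", method = "anova")
  expect_false(deg$tested[1])
  expect_true(is.na(deg$p_value[1]))
  expect_equal(deg$q_value[1], 1)
  expect_false(deg$significant[1])
  expect_error(test_deg(norm, c("m", "m", "m", "c")), ">= 2 replicates")
})

test_that("pathway summaries count planted direction correctly", {
  res <- data.frame(gene = paste0("g", 1:6),
                    fold_change = c(8, 4, 0.2, 1, 2, 3),
                    log2_fold = log2(c(8, 4, 0.2, 1, 2, 3)),
                    p_value = 0.001, q_value = c(.01, .01, .01, .9, .9, .9),
                    significant = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                    tested = TRUE)
  empty <- summarize_pathway(res, data.frame(gene = character(0),
                                             pathway = character(0)))
  expect_identical(nrow(empty), 0L)
  map <- data.frame(gene = paste0("g", 1:4),
                    pathway = c("flavonoid", "flavonoid", "flavonoid",
                                "other"))
  pw <- summarize_pathway(res, map)
  fl <- pw[pw$pathway == "flavonoid", ]
  expect_equal(fl$n_up, 2)
  expect_equal(fl$n_down, 1)
  expect_equal(fl$median_fold, 4)
})

test_that("planted pathway effects order the two mutant lines", {
  grp <- rep(c("ma", "mb", "c"), each = 3)
  planted <- data.frame(gene = 1:5, group = rep(c("ma", "mb"), c(2, 3))[1:5],
                        fold = c(10, 10, 40, 40, 40), base_mean = 100)
  planted <- rbind(planted,
                   transform(planted, group = ifelse(group == "ma",
                                                     "mb", "ma"),
                             fold = ifelse(group == "ma", 40, 10)))
  cnt <- simulate_counts(300, grp, planted = planted[1:5, ],
                         dispersion = 0.05, seed = 15)
  norm <- cpm_normalize(cnt)
  fa <- fold_change(norm, grp, "ma", "c")
  fb <- fold_change(norm, grp, "mb", "c")
  # genes planted up only in mb show the larger fold there
  mb_genes <- 3:5
  expect_true(all(fb[mb_genes] > fa[mb_genes]))
})
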