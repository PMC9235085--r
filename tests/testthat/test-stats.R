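test_that("group summaries match a two-pass reference computation", {
  set.seed(31)
  v <- rnorm(40, 5, 2)
  s <- summarize_group(v, "demo")
  expect_equal(s$mean, sum(v) / 40, tolerance = 1e-12)
  expect_equal(s$sd, sqrt(sum((v - mean(v))^2) / 39), tolerance = 1e-12)
  expect_equal(s$sd_pop, sqrt(sum((v - mean(v))^2) / 40), tolerance = 1e-12)
  expect_true(s$min <= s$mean && s$mean <= s$max)
  single <- summarize_group(3.3)
  expect_equal(single$mean, 3.3)
  expect_equal(single$sd, 0)
  expect_error(summarize_group(numeric(0)), "non-empty")
})

test_that("U statistic identities hold", {
  r <- mann_whitney_u(1:3, 4:6)
  expect_equal(r$U, 0) # complete separation
  set.seed(32)
  for (i in 1:20) {
    x <- runif(sample(2:8, 1)); y <- runif(sample(2:8, 1))
    r <- mann_whitney_u(x, y)
    expect_equal(r$U1 + r$U2, r$n1 * r$n2)
    expect_equal(r$U, min(r$U1, r$U2))
    expect_true(r$p > 0 && r$p <= 1)
  }
})

test_that("exact p matches exhaustive enumeration for small tie-free samples", {
  set.seed(33)
  for (i in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2, sample(c(0, 1), 1))
    r <- mann_whitney_u(x, y)
    expect_equal(r$method, "exact")
    expect_equal(r$p, enum_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("U is invariant under strictly monotone transforms", {
  set.seed(34)
  x <- rlnorm(9); y <- rlnorm(14, 0.5)
  r1 <- mann_whitney_u(x, y)
  for (f in list(log, sqrt, function(v) v^3 + 1)) {
    r2 <- mann_whitney_u(f(x), f(y))
    expect_equal(r2$U, r1$U)
    expect_equal(r2$p, r1$p)
  }
})

test_that("ties and large samples route to the corrected normal approximation", {
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  r <- mann_whitney_u(x, y)
  expect_equal(r$method, "normal-approximation")
  expect_true(r$p > 0 && r$p <= 1)
  # large sample: n1*n2 > 400
  set.seed(35)
  r2 <- mann_whitney_u(rnorm(15), rnorm(103))
  expect_equal(r2$method, "normal-approximation")
  # tied-data U still satisfies the rank-sum identity with midranks
  expect_equal(r$U1 + r$U2, r$n1 * r$n2)
})

test_that("identical groups give p = 1 and group comparison reports verdicts", {
  # identical tie-free values in both groups is impossible; use disjoint
  # interleaved samples drawn from one distribution
  set.seed(36)
  a <- data.frame(cosine = rnorm(10, 0.96, 0.01),
                  mean_error_mm = rnorm(10, 0.5, 0.1))
  cmp0 <- compare_groups(a, a)
  expect_false(any(cmp0$significant)) # same data: no difference detectable
  b <- data.frame(cosine = a$cosine - 0.2, mean_error_mm = a$mean_error_mm + 5)
  cmp1 <- compare_groups(a, b)
  expect_true(all(cmp1$significant))
  expect_s3_class(cmp1$tests$cosine, "u_test")
})

test_that("rendered tables have the expected shape and are deterministic", {
  set.seed(37)
  su <- data.frame(subunit = rep(1:5, each = 4),
                   cosine = runif(20, 0.9, 1),
                   mean_error_mm = runif(20, 0.3, 0.9))
  cases <- clinical_cases()
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  t1 <- render_tables(su, cases, dir1)
  t2 <- render_tables(su, cases, dir2)
  expect_equal(nrow(t1$table1), 6) # subunits I-V + overall
  expect_equal(t1$table1$subunit, c("I", "II", "III", "IV", "V", "overall"))
  expect_equal(nrow(t1$table2), 16) # 15 cases + average row
  expect_equal(t1$table2$case[16], "average")
  expect_identical(readLines(file.path(dir1, "table2.csv")),
                   readLines(file.path(dir2, "table2.csv")))
  expect_match(t1$table1_md, "^\\| subunit")
})

test_that("the packaged clinical table aggregates to the published averages", {
  cases <- clinical_cases()
  expect_equal(nrow(cases), 15)
  t2 <- render_tables(case_results = cases)$table2
  expect_equal(t2$cosine_similarity[16], "0.96")
  expect_equal(t2$mean_error_mm[16], "0.48")
})
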