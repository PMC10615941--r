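test_that("uniform population copies easy into hard bit-identically", {
  p <- sample_uniform_population(50, seed = 42)
  expect_equal(nrow(p), 100)
  e <- p[p$condition == "easy", ]
  h <- p[p$condition == "hard", ]
  for (col in c("v", "a", "t0"))
    expect_identical(e[[col]], h[[col]][match(e$participant, h$participant)])
  expect_true(all(p$a > 0) && all(p$t0 > 0))
})

test_that("uniform population moments match the generating ranges", {
  p <- sample_uniform_population(10000, seed = 7)
  e <- p[p$condition == "easy", ]
  # 4 SE bands around the uniform means
  expect_lt(abs(mean(e$v) - 2), 4 * (4 / sqrt(12)) / sqrt(10000))
  expect_lt(abs(mean(e$a) - 1.25), 4 * (1.5 / sqrt(12)) / sqrt(10000))
  expect_lt(abs(mean(e$t0) - 0.35), 4 * (0.3 / sqrt(12)) / sqrt(10000))
})

test_that("generation is reproducible and prefix-stable in n", {
  a <- sample_uniform_population(30, seed = 9)
  b <- sample_uniform_population(30, seed = 9)
  expect_identical(a, b)
  big <- sample_uniform_population(60, seed = 9)
  small_e <- a[a$condition == "easy", ]
  big_e <- big[big$condition == "easy" & big$participant <= 30, ]
  expect_identical(small_e$v, big_e$v)
})

test_that("degenerate and invalid populations are handled", {
  expect_equal(nrow(sample_uniform_population(0)), 0)
  expect_error(sample_uniform_population(5, ranges = list(v = c(2, 1))),
               "invalid range")
})

test_that("manipulated populations have the stated correlation and effect", {
  p <- sample_manipulated_population(2000, "v", "small", seed = 3)
  e <- p[p$condition == "easy", ]
  h <- p[p$condition == "hard", ]
  h <- h[match(e$participant, h$participant), ]
  expect_lt(abs(cor(e$v, h$v) - 0.5), 3 * (1 - 0.25) / sqrt(2000))
  # non-manipulated parameters stay bit-identical
  expect_identical(e$a, h$a)
  expect_identical(e$t0, h$t0)
  expect_true(all(p$v > 0))

  p2 <- sample_manipulated_population(5000, "t0", "large", seed = 4)
  d <- p2$t0[p2$condition == "hard"] - p2$t0[p2$condition == "easy"]
  # mean difference 0.430 - 0.350; SD of the paired difference is 0.1 at rho 0.5
  expect_lt(abs(mean(d) - 0.08), 4 * 0.1 / sqrt(5000))
})

test_that("all-three manipulation varies every parameter", {
  p <- sample_manipulated_population(200, effect = "large", all_three = TRUE,
                                     seed = 5)
  e <- p[p$condition == "easy", ]
  h <- p[p$condition == "hard", ]
  h <- h[match(e$participant, h$participant), ]
  for (col in c("v", "a", "t0"))
    expect_true(all(e[[col]] != h[[col]]))
})

test_that("perfectly correlated identical marginals give zero difference", {
  set.seed(1)
  xy <- replicate(50, diffscoresim:::rbvn_positive(2, 2, 1, 1, 1))
  expect_equal(xy[1, ], xy[2, ], tolerance = 1e-12)
})

test_that("correlated-difference populations recover the generating rho", {
  for (rho in c(-0.7, 0.7)) {
    p <- sample_diffcorr_population(1000, rho, seed = 11)
    e <- p[p$condition == "easy", ]
    h <- p[p$condition == "hard", ]
    h <- h[match(e$participant, h$participant), ]
    expect_identical(e$v, h$v) # drift never differs
    r <- cor(h$a - e$a, h$t0 - e$t0)
    expect_lt(abs(r - rho), 3 * (1 - rho^2) / sqrt(1000))
    expect_true(all(h$a > 0) && all(h$t0 >= 0))
  }
})

test_that("vanishing difference SDs reduce to the no-difference design", {
  p <- sample_diffcorr_population(20, 0, sd_a_diff = 1e-12,
                                  sd_t0_diff = 1e-12, seed = 2)
  e <- p[p$condition == "easy", ]
  h <- p[p$condition == "hard", ]
  h <- h[match(e$participant, h$participant), ]
  expect_equal(h$a, e$a, tolerance = 1e-9)
  expect_equal(h$t0, e$t0, tolerance = 1e-9)
})

test_that("LBA population respects b > A and is condition-identical", {
  p <- sample_lba_uniform_population(500, seed = 8)
  expect_true(all(p$b > p$A))
  expect_true(all(p$v >= 1 & p$v <= 4))
  e <- p[p$condition == "easy", ]
  h <- p[p$condition == "hard", ]
  h <- h[match(e$participant, h$participant), ]
  for (col in c("v", "A", "b", "t0")) expect_identical(e[[col]], h[[col]])
})
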