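test_that("separable classes give the widest-gap midpoint cut", {
  t1 <- learn_threshold(c(1, 2, 3), c(5, 6, 7))
  expect_equal(as.numeric(t1), 4.0)
  expect_equal(attr(t1, "score"), 6L)
})

test_that("overlapping classes maximize correct classifications", {
  t2 <- learn_threshold(c(1, 2, 3, 10), c(4, 5, 6, 7))
  expect_equal(as.numeric(t2), 3.5)
  expect_equal(attr(t2, "score"), 7L)
})

test_that("score ties break to the widest run, then the lowest-valued one", {
  t3 <- learn_threshold(c(1, 3, 5), c(2, 4, 6))
  expect_equal(as.numeric(t3), 1.5)
  expect_equal(attr(t3, "score"), 4L)
})

test_that("learned cut always matches the brute-force candidate scan", {
  set.seed(101)
  for (i in 1:200) {
    n_lo <- sample(1:50, 1)
    n_hi <- sample(1:50, 1)
    lo <- round(stats::rnorm(n_lo, 0, 3), sample(0:2, 1))
    hi <- round(stats::rnorm(n_hi, sample(-2:4, 1), 3), sample(0:2, 1))
    t_star <- learn_threshold(lo, hi)
    expect_equal(attr(t_star, "score"), as.integer(brute_force_best_score(lo, hi)))
    expect_equal(sum(lo < as.numeric(t_star)) + sum(hi > as.numeric(t_star)),
                 as.integer(attr(t_star, "score")))
  }
})

test_that("the best score is at least the one-sided classification baseline", {
  set.seed(7)
  for (i in 1:50) {
    lo <- stats::runif(sample(1:20, 1))
    hi <- stats::runif(sample(1:20, 1))
    expect_gte(attr(learn_threshold(lo, hi), "score"), max(length(lo), length(hi)))
  }
})

test_that("duplicating a correctly classified point never lowers the score", {
  set.seed(8)
  for (i in 1:25) {
    lo <- stats::rnorm(10)
    hi <- stats::rnorm(10, 1)
    t0 <- learn_threshold(lo, hi)
    correct_lo <- lo[lo < as.numeric(t0)]
    if (length(correct_lo) == 0) next
    t1 <- learn_threshold(c(lo, correct_lo[1]), hi)
    expect_gte(attr(t1, "score"), attr(t0, "score"))
  }
})

test_that("empty or non-finite sample sets are rejected", {
  expect_error(learn_threshold(numeric(0), 1), "nonempty")
  expect_error(learn_threshold(1, numeric(0)), "nonempty")
  expect_error(learn_threshold(c(1, NA), c(2, 3)), "finite")
})

test_that("patch sampling is exhaustive, constant-faithful and seed-reproducible", {
  img <- uniform_image(c(120, 80, 40), 30, 30)
  one_patch <- data.frame(row = 3, col = 4)
  s <- extract_patch_samples(img, one_patch, patch_size = 20, channel = "Cb",
                             class_label = "body", n_samples = 400, seed = 1)
  expect_equal(nrow(s), 400)
  expect_equal(length(unique(s$value)), 1L)  # uniform color: all values equal

  # exhaustive draw covers every pixel of a variegated patch exactly once
  img2 <- array(0L, dim = c(30, 30, 3))
  img2[, , 1] <- matrix(seq(0, 255, length.out = 900) |> round() |> as.integer(),
                        30, 30)
  s2 <- extract_patch_samples(img2, one_patch, 20, "Cb", "litter",
                              n_samples = 400, seed = 2)
  plane <- extract_component(img2, "Cb")
  expect_setequal(s2$value, as.numeric(plane[3:22, 4:23]))

  two <- data.frame(row = c(1, 10), col = c(1, 10))
  a <- extract_patch_samples(img2, two, 20, "b", "body", 100, seed = 9)
  b <- extract_patch_samples(img2, two, 20, "b", "body", 100, seed = 9)
  expect_identical(a, b)
})

test_that("patch bounds and sample-size preconditions are enforced", {
  img <- uniform_image(c(1, 2, 3), 10, 10)
  expect_error(extract_patch_samples(img, data.frame(row = 5, col = 5),
                                     patch_size = 8, channel = "Cb",
                                     class_label = "body", n_samples = 4),
               "bounds")
  expect_error(extract_patch_samples(img, data.frame(row = 1, col = 1),
                                     patch_size = 5, channel = "Cb",
                                     class_label = "body", n_samples = 26),
               "n_samples")
})

test_that("threshold sets separate well-separated Gaussian classes between the means", {
  set.seed(21)
  mk <- function(ch, cls, mu, sd) tibble::tibble(value = stats::rnorm(100, mu, sd),
                                                 channel = ch, class = cls)
  # class means at least 5 sigma apart on every channel
  samples <- dplyr::bind_rows(
    mk("b", "litter", 0, 1), mk("b", "body", 10, 1),
    mk("Cb", "body", 100, 1), mk("Cb", "litter", 128, 1),
    mk("Q", "body", -0.1, 0.02), mk("Q", "feeder", 0.1, 0.02))
  ths <- learn_threshold_set(samples)
  expect_gt(ths$T_b, 0); expect_lt(ths$T_b, 10)
  expect_gt(ths$T_Cb, 100); expect_lt(ths$T_Cb, 128)
  expect_gt(ths$T_Q, -0.1); expect_lt(ths$T_Q, 0.1)
  # perfectly separated 100-vs-100 classes classify all 200 samples
  expect_true(all(tidy(ths)$score <= 200L))
  expect_equal(tidy(ths)$score[tidy(ths)$channel == "Cb"], 200L)
})

test_that("threshold learning is invariant to sample order", {
  set.seed(31)
  mk <- function(ch, cls, mu) tibble::tibble(value = stats::rnorm(60, mu, 2),
                                             channel = ch, class = cls)
  samples <- dplyr::bind_rows(
    mk("b", "litter", 0), mk("b", "body", 8),
    mk("Cb", "body", 95), mk("Cb", "litter", 125),
    mk("Q", "body", -0.05), mk("Q", "feeder", 0.08))
  shuffled <- samples[sample(nrow(samples)), ]
  expect_equal(tidy(learn_threshold_set(samples)),
               tidy(learn_threshold_set(shuffled)))
})
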