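cfg_small <- entropy_config(scales = 1:4)

test_that("coarse-graining averages non-overlapping windows and drops the remainder", {
  sig6 <- multichannel_signal(c(1, 2, 3, 4, 5, 6))
  expect_equal(as.numeric(unclass(coarse_grain(sig6, 2))), c(1.5, 3.5, 5.5))

  sig7 <- multichannel_signal(c(1, 2, 3, 4, 5, 6, 7))
  expect_equal(as.numeric(unclass(coarse_grain(sig7, 3))), c(2, 5))

  # scale 1 is the identity
  x <- random_signal(11)
  expect_equal(unclass(coarse_grain(x, 1)), unclass(x), ignore_attr = TRUE)

  # multichannel windows average per channel
  two <- multichannel_signal(list(c(1, 3, 5, 7), c(0, 2, 4, 6)))
  expect_equal(unclass(coarse_grain(two, 2)),
               matrix(c(2, 1, 6, 5), nrow = 2), ignore_attr = TRUE)

  expect_error(coarse_grain(sig6, 0), ">= 1")
  expect_error(coarse_grain(sig6, 5), "fewer than 2")
})

test_that("phase-space reconstruction enumerates composite delay vectors", {
  uni <- multichannel_signal(c(1, 2, 3, 4))
  expect_equal(phase_space(uni, m = 2, tau = 1),
               rbind(c(1, 2), c(2, 3), c(3, 4)))

  bi <- multichannel_signal(list(c(1, 2, 3), c(10, 20, 30)))
  expect_equal(phase_space(bi, m = 2, tau = 1),
               rbind(c(1, 2, 10, 20), c(2, 3, 20, 30)))

  # m=3, tau=2 on 5 samples leaves a single vector: too short
  expect_error(phase_space(multichannel_signal(1:5), m = 3, tau = 2), "need >= 2")
})

test_that("pairwise distances cover all distinct pairs under the chosen metric", {
  expect_equal(pairwise_distances(rbind(c(0, 0), c(3, 4))), 4)          # chebyshev
  expect_equal(pairwise_distances(rbind(c(0, 0), c(3, 4)), "euclidean"), 5)
  expect_equal(pairwise_distances(rbind(c(1, 1), c(1, 1))), 0)
  expect_length(pairwise_distances(matrix(rnorm(12), 3)), 3)            # V(V-1)/2
  d <- pairwise_distances(matrix(rnorm(40), 8))
  expect_true(all(d >= 0))
})

test_that("fuzzy similarity is a decaying membership on (0, 1]", {
  expect_equal(fuzzy_similarity(0, r = 0.5, n = 2), 1)
  expect_equal(fuzzy_similarity(1, r = 1, n = 2), exp(-1))
  d <- sort(runif(50, 0, 3))
  mu <- fuzzy_similarity(d, r = 0.3, n = 2)
  expect_true(all(mu > 0 & mu <= 1))
  expect_true(all(diff(mu) <= 0))          # monotone decreasing
  expect_error(fuzzy_similarity(1, r = 0, n = 2), "r must be")
  expect_error(fuzzy_similarity(1, r = 1, n = -1), "n must be")
})

test_that("empirical pdf bins over [0,1], normalizes, and sends edges upward", {
  expect_equal(empirical_pdf(c(0.1, 0.9), B = 2), c(0.5, 0.5))
  expect_equal(empirical_pdf(rep(0.37, 10), B = 4), c(0, 1, 0, 0))
  expect_equal(empirical_pdf(c(0.5), B = 2), c(0, 1))   # interior edge -> higher bin
  expect_equal(empirical_pdf(c(1), B = 8)[8], 1)        # 1.0 -> last bin
  for (seed in 1:5) {
    p <- empirical_pdf(withr::with_seed(seed, runif(100)), B = 16)
    expect_equal(sum(p), 1)
  }
  expect_error(empirical_pdf(numeric(0), 4), "at least one")
  expect_error(empirical_pdf(c(0.5, 1.2), 4), "\\[0, 1\\]")
})

test_that("entropy matches the brute-force oracle on random small signals", {
  for (seed in 1:12) {
    x <- random_signal(seed)
    for (s in 1:4) {
      expect_equal(mm_mdisten(x, s, cfg_small),
                   oracle_mm_mdisten(unclass(x), s = s),
                   tolerance = 1e-12)
    }
  }
})

test_that("entropy is normalized, deterministic, and rejects degenerate input", {
  x <- random_signal(3)
  v <- mm_mdisten(x, 1)
  expect_identical(v, mm_mdisten(x, 1))     # bit-identical rerun
  expect_true(v >= 0 && v <= 1)
  flat <- multichannel_signal(rep(2.5, 50))
  expect_error(mm_mdisten(flat, 1), "degenerate input")
})

test_that("entropy is invariant to channel order and positive amplitude scaling", {
  for (seed in 1:6) {
    x <- random_signal(seed, n_channels = 3, n_samples = 80)
    perm <- multichannel_signal(unclass(x)[c(2, 3, 1), ])
    scaled <- multichannel_signal(unclass(x) * 7.3)
    for (s in c(1, 3)) {
      expect_equal(mm_mdisten(perm, s, cfg_small), mm_mdisten(x, s, cfg_small),
                   tolerance = 1e-12)
      expect_equal(mm_mdisten(scaled, s, cfg_small), mm_mdisten(x, s, cfg_small),
                   tolerance = 1e-12)
    }
  }
})

test_that("entropy profiles cover every configured scale and flag infeasible ones", {
  x <- random_signal(5, n_channels = 2, n_samples = 400)
  prof <- entropy_profile(x)
  expect_s3_class(prof, "entropy_profile")
  expect_s3_class(prof, "tbl_df")
  expect_equal(prof$scale, 1:15)
  expect_true(all(prof$entropy >= 0 & prof$entropy <= 1))
  expect_equal(prof$entropy[1], mm_mdisten(x, 1))

  short <- random_signal(6, n_channels = 1, n_samples = 40)
  expect_error(entropy_profile(short, entropy_config(scales = c(1, 2, 19))),
               "scale 19")
})

test_that("profile CSV output has scale,entropy columns", {
  x <- random_signal(7, n_channels = 1, n_samples = 60)
  prof <- entropy_profile(x, entropy_config(scales = 1:3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("scale", "entropy"))
  expect_equal(back$entropy, prof$entropy, tolerance = 1e-12)
})
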