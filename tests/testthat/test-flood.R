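test_that("shift_to_positive forces a global minimum of exactly 1", {
  out <- shift_to_positive(matrix(c(-3, 2, 0, 5), 2))
  expect_identical(out$values, matrix(c(1, 6, 4, 9), 2))
  expect_equal(out$shift, -4)
  already <- matrix(c(1, 2, 3, 4), 2)
  expect_identical(shift_to_positive(already)$values, already)
  set.seed(61)
  m <- matrix(rnorm(200, sd = 10), 20)
  sh <- shift_to_positive(m)
  expect_equal(min(sh$values), 1)
  expect_equal(diff(as.vector(sh$values)), diff(as.vector(m)),
               tolerance = 1e-12)
  expect_error(shift_to_positive(matrix(c(1, NA), 1)), "finite")
})

test_that("control-fitted standardisation maps controls to mean 0 sd 1", {
  set.seed(62)
  ctrl <- matrix(stats::rlnorm(500 * 4, 2, 0.5), 500,
                 dimnames = list(NULL, c("A", "B", "C", "D")))
  params <- fit_preprocess(ctrl)
  z <- preprocess(ctrl, params)
  expect_equal(unname(colMeans(z)), rep(0, 4), tolerance = 1e-8)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4), tolerance = 1e-8)
  # response pools standardised with control params keep their offsets
  resp <- ctrl * 3
  expect_true(all(abs(colMeans(preprocess(resp, params))) > 0.1))
})

test_that("the two-event worked case gives mean 2 and sd sqrt(2)", {
  params <- fit_preprocess(matrix(c(10, 1000), 2,
                                  dimnames = list(NULL, "M")))
  expect_equal(unname(params$mean), 2)
  expect_equal(unname(params$sd), sqrt(2))
})

test_that("zero-variance markers are reported by name", {
  m <- cbind(A = c(1, 2, 3), B = c(5, 5, 5))
  expect_error(fit_preprocess(m), "B")
  expect_error(fit_preprocess(cbind(A = c(-1, 2))), "positive")
})

test_that("response variance on an untouched marker is fully recovered", {
  set.seed(63)
  n <- 2000
  ctrl <- cbind(A = rnorm(n), B = rnorm(n), C = rnorm(n) * 1e-3)
  resp <- cbind(A = rnorm(n) * 0.01, B = rnorm(n) * 0.01, C = rnorm(n))
  model <- fit_flood(ctrl, resp, k_c = 2, k_r = 1)
  expect_equal(abs(model$response_loadings[, 1]), c(A = 0, B = 0, C = 1),
               tolerance = 1e-3)
  expect_gt(model$explained[1], 0.999)
})

test_that("loadings and eigenvalue shares match a dense eigen oracle", {
  set.seed(64)
  ctrl <- matrix(rnorm(6 * 3), 6, dimnames = list(NULL, c("A", "B", "C")))
  resp <- matrix(rnorm(6 * 3, sd = 2), 6,
                 dimnames = list(NULL, c("A", "B", "C")))
  model <- fit_flood(ctrl, resp, k_c = 1, k_r = 2)
  # oracle built from svd-based projector, independent of fit_flood's path
  sv <- svd(scale(ctrl, scale = FALSE))
  pc <- sv$v[, 1, drop = FALSE] * sign(sv$v[abs(sv$v[, 1]) ==
                                              max(abs(sv$v[, 1])), 1])
  proj <- diag(3) - pc %*% t(pc)
  defl <- resp %*% proj
  ev <- eigen(stats::cov(defl), symmetric = TRUE)
  shares <- ev$values / sum(ev$values)
  expect_equal(unname(model$explained), shares[1:2], tolerance = 1e-8)
  for (j in 1:2) {
    v <- ev$vectors[, j]
    v <- v * sign(v[which.max(abs(v))])
    expect_equal(unname(model$response_loadings[, j]), unname(v),
                 tolerance = 1e-8)
  }
})

test_that("deflated response cells are orthogonal to control loadings", {
  set.seed(65)
  ctrl <- matrix(rnorm(500 * 6), 500, dimnames = list(NULL, LETTERS[1:6]))
  resp <- matrix(rnorm(500 * 6, 1), 500, dimnames = list(NULL, LETTERS[1:6]))
  model <- fit_flood(ctrl, resp, k_c = 3, k_r = 2)
  pc <- model$control_loadings
  defl <- resp - resp %*% pc %*% t(pc)
  expect_lt(max(abs(defl %*% pc)), 1e-8)
  expect_lt(max(abs(t(model$response_loadings) %*% pc)), 1e-8)
  # loadings orthonormal within each block
  expect_equal(t(pc) %*% pc, diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(t(model$response_loadings) %*% model$response_loadings,
               diag(2), tolerance = 1e-10, ignore_attr = TRUE)
  # explained fractions non-increasing, summing to at most one
  expect_true(all(diff(model$explained) <= 1e-12))
  expect_lte(sum(model$explained), 1)
})

test_that("a known injected shift direction is recovered within 5 degrees", {
  set.seed(66)
  p <- 10
  markers <- paste0("M", seq_len(p))
  n <- 6000
  ctrl <- matrix(rnorm(n * p), n, dimnames = list(NULL, markers))
  v <- rnorm(p); v <- v / sqrt(sum(v^2))
  strength <- rnorm(n, 0, 2)  # response-specific variance along v
  resp <- matrix(rnorm(n * p, sd = 0.3), n,
                 dimnames = list(NULL, markers)) + outer(strength, v)
  model <- fit_flood(ctrl, resp, k_c = 2, k_r = 2)
  pc <- model$control_loadings
  v_defl <- v - pc %*% (t(pc) %*% v)
  v_defl <- v_defl / sqrt(sum(v_defl^2))
  cosang <- abs(sum(model$response_loadings[, 1] * v_defl))
  expect_gte(cosang, cos(5 * pi / 180))
})

test_that("projection is the deflated matrix product with near-zero control mean", {
  set.seed(67)
  ctrl <- matrix(rnorm(800 * 5), 800, dimnames = list(NULL, LETTERS[1:5]))
  ctrl <- scale(ctrl, scale = FALSE)  # standardised controls have mean 0
  resp <- matrix(rnorm(800 * 5, 0.5), 800,
                 dimnames = list(NULL, LETTERS[1:5]))
  model <- fit_flood(ctrl, resp, k_c = 2, k_r = 2)
  sc <- project(ctrl, model)
  expect_equal(unname(colMeans(sc)), c(0, 0), tolerance = 1e-10)
  pc <- model$control_loadings
  manual <- (resp - resp %*% pc %*% t(pc)) %*% model$response_loadings
  expect_equal(project(resp, model), manual, tolerance = 1e-12)
})

test_that("repeated fits on identical data are bit-identical", {
  set.seed(68)
  ctrl <- matrix(rnorm(300 * 4), 300, dimnames = list(NULL, LETTERS[1:4]))
  resp <- matrix(rnorm(300 * 4, 1), 300, dimnames = list(NULL, LETTERS[1:4]))
  m1 <- fit_flood(ctrl, resp, k_c = 1, k_r = 2)
  m2 <- fit_flood(ctrl, resp, k_c = 1, k_r = 2)
  expect_identical(m1$response_loadings, m2$response_loadings)
  expect_identical(m1$benchmark$threshold, m2$benchmark$threshold)
})

test_that("marker and event permutations leave the model equivariant", {
  set.seed(69)
  markers <- LETTERS[1:5]
  ctrl <- matrix(rnorm(400 * 5), 400, dimnames = list(NULL, markers))
  resp <- matrix(rnorm(400 * 5, 0.8), 400, dimnames = list(NULL, markers))
  model <- fit_flood(ctrl, resp, k_c = 1, k_r = 2)
  perm <- c(3, 1, 5, 2, 4)
  model_p <- fit_flood(ctrl[, perm], resp[, perm], k_c = 1, k_r = 2)
  expect_equal(model_p$explained, model$explained, tolerance = 1e-10)
  expect_equal(model_p$response_loadings[markers[perm], ],
               model$response_loadings[markers[perm], ], tolerance = 1e-8)
  rows <- sample(nrow(resp))
  expect_equal(project(resp[rows, ], model),
               project(resp, model)[rows, ], tolerance = 1e-12)
})

test_that("benchmark regions hold their empirical coverage", {
  set.seed(70)
  sc <- matrix(rnorm(4000 * 2), 4000, dimnames = list(NULL, c("RC1", "RC2")))
  region <- benchmark_region(sc, coverage = 0.80)
  inside <- overlap_fraction(sc, region)
  expect_lt(abs(inside - 0.80), 1 / nrow(sc) + 1e-12)
  # large standard bivariate normal: radius approaches the chi-square quantile
  big <- matrix(rnorm(2e5 * 2), ncol = 2)
  r <- benchmark_region(big, 0.80)
  expect_equal(r$threshold, stats::qchisq(0.80, df = 2), tolerance = 0.02)
  expect_error(benchmark_region(sc, coverage = 1.0), "open interval")
  expect_error(benchmark_region(sc[1:20, ], 0.8), ">= 50")
  degen <- cbind(rnorm(100), 0)
  expect_error(benchmark_region(degen, 0.8), "degenerate benchmark")
})

test_that("overlap drops to near zero for far-translated clouds", {
  set.seed(71)
  sc <- matrix(rnorm(3000 * 2), 3000)
  region <- benchmark_region(sc, 0.80)
  far <- sweep(sc, 2, c(12, 0), `+`)
  expect_lt(overlap_fraction(far, region), 0.01)
  expect_error(overlap_fraction(sc[0, , drop = FALSE], region), "empty")
})

test_that("biplot export writes round-trippable tables and figures", {
  set.seed(72)
  ctrl <- matrix(rnorm(500 * 4), 500, dimnames = list(NULL, LETTERS[1:4]))
  resp <- matrix(rnorm(500 * 4, 0.5), 500, dimnames = list(NULL, LETTERS[1:4]))
  model <- fit_flood(ctrl, resp, k_c = 1, k_r = 2)
  dir <- withr::local_tempdir()
  scores <- list(s1 = project(ctrl, model), s2 = project(resp, model))
  report <- export_biplot(model, scores, dir)
  expect_true(file.exists(file.path(dir, "loadings.tsv")))
  expect_true(file.exists(file.path(dir, "biplot_s1.pdf")))
  load <- utils::read.table(file.path(dir, "loadings.tsv"), header = TRUE,
                            sep = "\t", check.names = FALSE)
  expect_equal(load$RC1, unname(model$response_loadings[, 1]),
               tolerance = 1e-8)
  # vector lengths are the Euclidean norms of the loading rows
  expect_equal(load$length, sqrt(rowSums(model$response_loadings^2)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # angles between exported vectors equal arccos of normalised dot products
  L <- as.matrix(load[, c("RC1", "RC2")])
  dots <- (L %*% t(L))[1, 2] / (load$length[1] * load$length[2])
  direct <- sum(model$response_loadings[1, ] * model$response_loadings[2, ]) /
    prod(sqrt(rowSums(model$response_loadings[1:2, ]^2)))
  expect_equal(acos(pmin(pmax(dots, -1), 1)),
               acos(pmin(pmax(direct, -1), 1)), tolerance = 1e-8)
  expect_equal(report$inside_control[1],
               overlap_fraction(scores$s1, model$benchmark))
  p <- autoplot(model, scores$s2)
  expect_s3_class(p, "ggplot")
})

test_that("rank-deficient requests are rejected", {
  set.seed(73)
  ctrl <- matrix(rnorm(100 * 3), 100, dimnames = list(NULL, c("A", "B", "C")))
  resp_flat <- cbind(A = rnorm(100), B = 0 * rnorm(100) + 1, C = rnorm(100) * 0 + 2)
  colnames(resp_flat) <- c("A", "B", "C")
  expect_error(fit_flood(ctrl, resp_flat, k_c = 1, k_r = 2),
               "rank deficiency")
  expect_error(fit_flood(ctrl, resp_flat, k_c = 3, k_r = 1), "exceed")
})
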