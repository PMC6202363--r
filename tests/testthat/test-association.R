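# minimal analysis stubs: only the fields the association functions read
stub_analysis <- function(pd, mp_set, thickness, choroid = NA_real_,
                          oct_set = mp_set, icga_set = mp_set) {
  structure(list(
    eye = structure(list(
      thickness = list(total_retinal_um = thickness,
                       subfoveal_choroid_um = choroid)), class = "mp_eye"),
    pd = structure(pd, class = "mp_pd"),
    sets = list(mp = mp_set, oct = oct_set, icga = icga_set)),
    class = "mp_eye_analysis")
}

test_that("a perfect linear relation gives R^2 = 1 with a negative slope", {
  ids <- 0:9
  analyses <- lapply(1:6, function(i) {
    thk <- rep(NA_real_, 56); thk[ids + 1] <- 250 + 10 * i
    pd <- rep(0, 56); pd[ids + 1] <- -0.1 * (250 + 10 * i)
    stub_analysis(pd, ids, thk)
  })
  a <- pd_thickness_association(analyses, "abnormal")
  expect_equal(a$r_squared, 1, tolerance = 1e-12)
  expect_equal(a$slope_sign, "negative")
  expect_equal(a$n_eyes, 6)
})

test_that("regression matches the closed form on three points", {
  ids <- 0L
  xs <- c(100, 200, 400); ys <- c(-1, -2, -5)
  analyses <- lapply(1:3, function(i) {
    thk <- rep(NA_real_, 56); thk[1] <- xs[i]
    pd <- rep(0, 56); pd[1] <- ys[i]
    stub_analysis(pd, ids, thk)
  })
  a <- pd_thickness_association(analyses, "abnormal")
  b <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
  r2 <- b^2 * sum((xs - mean(xs))^2) / sum((ys - mean(ys))^2)
  expect_equal(a$slope, b, tolerance = 1e-12)
  expect_equal(a$r_squared, r2, tolerance = 1e-12)
})

test_that("mean R^2 under independence is about 1/(n-1)", {
  set.seed(53)
  n <- 10
  r2 <- replicate(400, {
    xs <- rnorm(n); ys <- rnorm(n)
    fit <- lm.fit(cbind(1, xs), ys)
    1 - sum(fit$residuals^2) / sum((ys - mean(ys))^2)
  })
  expect_equal(mean(r2), 1 / (n - 1), tolerance = 0.025)
  # the package computes the same quantity through its own path
  ids <- 0:4
  analyses <- lapply(1:n, function(i) {
    thk <- rep(NA_real_, 56); thk[ids + 1] <- rnorm(1, 300, 30)
    pd <- rep(0, 56); pd[ids + 1] <- rnorm(1, -3, 1)
    stub_analysis(pd, ids, thk)
  })
  a <- pd_thickness_association(analyses, "abnormal")
  expect_gte(a$r_squared, 0)
  expect_lte(a$r_squared, 1)
})

test_that("concordant-region pairing can be cleaner than abnormal-region", {
  # concordant region = three-way intersection; built so the abnormal sum
  # adds noisy extra locations while the concordant core is exact
  set.seed(57)
  analyses <- lapply(1:20, function(i) {
    core <- 0:7
    extra <- sample(8:20, 6)
    thk <- rep(NA_real_, 56)
    thk[core + 1] <- 250 + 5 * i
    thk[extra + 1] <- rnorm(6, 280, 40)
    pd <- rep(0, 56)
    pd[core + 1] <- -0.2 * (250 + 5 * i)
    pd[extra + 1] <- rnorm(6, -5, 8)
    stub_analysis(pd, mp_set = c(core, extra), thickness = thk,
                  oct_set = core, icga_set = core)
  })
  r2_ab <- pd_thickness_association(analyses, "abnormal")$r_squared
  r2_cc <- pd_thickness_association(analyses, "concordant")$r_squared
  expect_gt(r2_cc, r2_ab)
})

test_that("thickness-free or empty regions are rejected", {
  empty <- stub_analysis(rep(0, 56), integer(0), rep(NA_real_, 56))
  expect_error(pd_thickness_association(list(empty, empty, empty)),
               "non-empty")
  expect_error(pd_thickness_association(list(empty)), "non-empty")
})

test_that("choroid association handles constant regressors and calibrates", {
  ids <- 0:3
  const <- lapply(1:5, function(i) {
    pd <- rep(-i, 56)
    stub_analysis(pd, ids, rep(NA_real_, 56), choroid = 251)
  })
  a <- choroid_pd_association(const, the_grid)
  expect_equal(a$r_squared, 0)
  expect_equal(a$slope_sign, "zero")
  # type-I error of the test under zero coupling at a typical cohort size
  set.seed(61)
  rej <- replicate(1000, {
    x <- rnorm(21, 251, 100); y <- rnorm(21, -3, 1.5)
    fit <- lm.fit(cbind(1, x), y)
    rss <- sum(fit$residuals^2); tss <- sum((y - mean(y))^2)
    f <- (tss - rss) / (rss / 19)
    pf(f, 1, 19, lower.tail = FALSE) < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.02)
  # perfect coupling through the package path
  perfect <- lapply(1:6, function(i) {
    pd <- rep(0, 56)
    central <- which(the_grid$locations$ecc <= 1.4)
    pd[central] <- -0.02 * (200 + 10 * i)
    stub_analysis(pd, ids, rep(NA_real_, 56), choroid = 200 + 10 * i)
  })
  expect_equal(choroid_pd_association(perfect, the_grid)$r_squared, 1,
               tolerance = 1e-12)
  expect_error(choroid_pd_association(const, the_grid, max_ecc = 0.1),
               "configuration error")
})

test_that("associations are invariant to eye order and unit rescaling", {
  set.seed(67)
  ids <- 0:9
  analyses <- lapply(1:8, function(i) {
    thk <- rep(NA_real_, 56); thk[ids + 1] <- rnorm(10, 280, 20)
    pd <- rep(0, 56); pd[ids + 1] <- rnorm(10, -4, 2)
    stub_analysis(pd, ids, thk)
  })
  a1 <- pd_thickness_association(analyses, "abnormal")
  a2 <- pd_thickness_association(rev(analyses), "abnormal")
  expect_equal(a1$r_squared, a2$r_squared, tolerance = 1e-12)
  scaled <- lapply(analyses, function(s) {
    s$eye$thickness$total_retinal_um <- s$eye$thickness$total_retinal_um / 1000
    s
  })
  a3 <- pd_thickness_association(scaled, "abnormal")
  expect_equal(a3$r_squared, a1$r_squared, tolerance = 1e-9)
  expect_equal(a3$slope_sign, a1$slope_sign)
})
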