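# Effects coding, OLS regressions and Spearman correlation, checked
# against independent oracles (closed forms, lm(), cor.test()).

test_that("effects coding follows the 1 / -1 / 0 pattern", {
  D <- effects_code(c("s1", "s2", "s3"))
  expect_equal(unname(D), rbind(c(1, 0), c(0, 1), c(-1, -1)))
  ids <- rep(sprintf("p%02d", 1:25), each = 2)
  D25 <- effects_code(ids)
  expect_equal(ncol(D25), 24)
  # balanced design: columns sum to zero
  expect_true(all(colSums(D25[!duplicated(ids), , drop = FALSE]) == 0))
  expect_equal(ncol(effects_code(rep("only", 4))), 0)
})

test_that("noiseless linear outcomes are recovered exactly", {
  set.seed(2)
  tab <- expand.grid(subject_id = sprintf("S%02d", 1:10),
                     co = c(3.3, 4.4, 5.5), rep = 1:3,
                     stringsAsFactors = FALSE)
  tab$sysp <- runif(nrow(tab), 1, 2.3)
  tab$revp <- runif(nrow(tab), 0, 1)
  tab$t_m <- 10 - 2.43 * tab$co
  r <- fit_waveform_model(tab)
  expect_equal(unname(r$coefficients["co"]), -2.43, tolerance = 1e-10)
  expect_equal(unname(r$coefficients["sysp"]), 0, tolerance = 1e-10)
  expect_equal(unname(r$coefficients["revp"]), 0, tolerance = 1e-10)
  expect_equal(r$adj_r2, 1, tolerance = 1e-10)
  # subject offsets land in the effects, not the slopes
  off <- stats::setNames(seq(-4.5, 4.5, by = 1), sprintf("S%02d", 1:10))
  tab2 <- tab
  tab2$t_m <- tab2$t_m + off[tab2$subject_id]
  r2 <- fit_waveform_model(tab2)
  expect_equal(unname(r2$coefficients["co"]), -2.43, tolerance = 1e-10)
  expect_equal(unname(r2$coefficients["(Intercept)"]),
               unname(r$coefficients["(Intercept)"]), tolerance = 1e-10)
  expect_equal(unname(r2$subject_effects), unname(off), tolerance = 1e-8)
  expect_equal(sum(r2$subject_effects), 0, tolerance = 1e-8)
  # permutation invariance
  perm <- sample(nrow(tab))
  r3 <- fit_waveform_model(tab[perm, ])
  expect_equal(r3$coefficients, r$coefficients, tolerance = 1e-10)
})

test_that("OLS inference agrees with lm() on a noisy fixture", {
  set.seed(4)
  tab <- expand.grid(subject_id = sprintf("S%d", 1:8),
                     co = c(3.3, 4.4, 5.5), wt = 1:3,
                     stringsAsFactors = FALSE)
  tab$sysp <- runif(nrow(tab), 1, 2.3)
  tab$revp <- runif(nrow(tab), 0, 1)
  tab$t_m <- 30 - 2 * tab$co - 1.2 * tab$sysp + rnorm(nrow(tab))
  r <- fit_waveform_model(tab)
  D <- effects_code(tab$subject_id)
  lmfit <- lm(t_m ~ co + sysp + revp + D, data = tab)
  sm <- summary(lmfit)
  expect_equal(unname(r$coefficients),
               unname(coef(lmfit)[1:4]), tolerance = 1e-9)
  expect_equal(unname(r$se), unname(sm$coefficients[1:4, 2]),
               tolerance = 1e-9)
  expect_equal(unname(r$p), unname(sm$coefficients[1:4, 4]),
               tolerance = 1e-9)
  expect_equal(r$adj_r2, sm$adj.r.squared, tolerance = 1e-9)
  # residuals orthogonal to every design column
  X <- cbind(1, tab$co, tab$sysp, tab$revp, D)
  expect_lt(max(abs(crossprod(X, r$residuals))),
            1e-8 * max(abs(tab$t_m)))
})

test_that("the rheology factorial model recovers its generating terms", {
  tab <- expand.grid(subject_id = sprintf("S%d", 1:6),
                     hct = c(0.274, 0.455, 0.604),
                     rheology = c("newtonian", "quemada"),
                     stringsAsFactors = FALSE)
  tab$t_m <- 1 + 0.65 * tab$hct * 100
  r <- fit_rheology_model(tab)
  expect_equal(unname(r$coefficients["hct"]), 0.65, tolerance = 1e-10)
  expect_equal(unname(r$coefficients["d_n"]), 0, tolerance = 1e-9)
  expect_equal(unname(r$coefficients["hct_x_dn"]), 0, tolerance = 1e-10)
  # pure interaction
  tab$t_m <- 2 + 0.3 * tab$hct * 100 * (tab$rheology == "quemada")
  r2 <- fit_rheology_model(tab)
  expect_equal(unname(r2$coefficients["hct"]), 0, tolerance = 1e-10)
  expect_equal(unname(r2$coefficients["hct_x_dn"]), 0.3, tolerance = 1e-10)
  # centering the covariate only shifts the intercept
  tab$t_m <- 1 + 0.65 * tab$hct * 100
  tabc <- tab
  tabc$hct <- tabc$hct - mean(tabc$hct)
  r3 <- fit_rheology_model(tabc)
  expect_equal(unname(r3$coefficients["hct"]),
               unname(r$coefficients["hct"]), tolerance = 1e-9)
})

test_that("rank-deficient designs raise a collinearity error", {
  tab <- expand.grid(subject_id = sprintf("S%d", 1:4), co = c(3.3, 4.4),
                     stringsAsFactors = FALSE)
  tab$sysp <- tab$co * 2          # exactly collinear with co
  tab$revp <- 1
  tab$t_m <- 1
  expect_error(fit_waveform_model(tab), "collinearity")
})

test_that("spearman matches the Sum d^2 formula and base R on tied data", {
  expect_equal(spearman(1:5, 1:5)$rho, 1)
  expect_equal(spearman(1:5, 5:1)$rho, -1)
  # worked example: d = (-1, 1, -1, 1, 0), Sum d^2 = 4
  expect_equal(spearman(1:5, c(2, 1, 4, 3, 5))$rho, 1 - 6 * 4 / (5 * 24))
  set.seed(8)
  for (i in 1:1000) {
    n <- sample(4:9, 1)
    x <- sample(1:4, n, replace = TRUE)   # heavy ties
    y <- sample(1:4, n, replace = TRUE)
    s <- suppressWarnings(spearman(x, y))
    if (is.na(s$rho)) {
      expect_true(length(unique(x)) == 1 || length(unique(y)) == 1)
    } else {
      expect_equal(s$rho, suppressWarnings(
        cor.test(x, y, method = "spearman")$estimate[[1]]),
        tolerance = 1e-12)
    }
  }
  expect_warning(spearman(c(1, 1, 1), c(1, 2, 3)), "zero rank variance")
})
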