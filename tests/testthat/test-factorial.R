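test_that("Yates sweep basics", {
  # constant responses: the mean, and no effects
  y <- yates_effects(rep(7.5, 8))
  expect_equal(attr(y, "mean"), 7.5)
  expect_true(all(abs(y$effect) < 1e-12))
  # a pure main effect of A: +d at high, -d at low
  d <- 3.2
  a_level <- rep(c(-1, 1), 4)            # standard order, A fastest
  y2 <- yates_effects(10 + d * a_level)
  expect_equal(y2$effect[y2$term == "A"], 2 * d)
  expect_true(all(abs(y2$effect[y2$term != "A"]) < 1e-12))
  expect_error(yates_effects(1:6), "power of two")
})

test_that("Yates effects equal saturated +/-1 regression coefficients", {
  set.seed(42)
  for (k in 2:3) {
    for (rep_i in 1:5) {
      y <- rnorm(2 ^ k, sd = 10)
      ye <- yates_effects(y)
      codes <- expand.grid(rep(list(c(-1, 1)), k))
      names(codes) <- LETTERS[1:k]
      # saturated +/-1-coded linear model as the independent oracle
      fml <- stats::as.formula(paste("y ~", paste(names(codes),
                                                  collapse = " * ")))
      fit <- lm(fml, data = cbind(y = y, codes))
      cf <- coef(fit)
      expect_equal(attr(ye, "mean"), unname(cf["(Intercept)"]),
                   tolerance = 1e-10)
      for (i in seq_len(nrow(ye))) {
        nm <- ye$term[i]
        expect_equal(ye$half_effect[i], unname(cf[nm]), tolerance = 1e-10)
        expect_equal(ye$effect[i], 2 * unname(cf[nm]), tolerance = 1e-10)
      }
    }
  }
})

test_that("effects are invariant to a constant shift; mean is not", {
  set.seed(7)
  y <- rnorm(8)
  e1 <- yates_effects(y)
  e2 <- yates_effects(y + 100)
  expect_equal(e1$effect, e2$effect, tolerance = 1e-12)
  expect_equal(attr(e2, "mean"), attr(e1, "mean") + 100)
})

test_that("corner responses are recovered from mean and half-effects", {
  set.seed(13)
  y <- rnorm(8, 50, 5)
  ye <- yates_effects(y)
  codes <- expand.grid(A = c(-1, 1), B = c(-1, 1), C = c(-1, 1))
  recon <- rep(attr(ye, "mean"), 8)
  for (i in seq_len(nrow(ye))) {
    fs <- strsplit(ye$term[i], ":")[[1]]
    contrib <- Reduce(`*`, lapply(fs, function(f) codes[[f]]))
    recon <- recon + ye$half_effect[i] * contrib
  }
  expect_equal(recon, y, tolerance = 1e-10)
})

test_that("run_design executes corners plus centre and finds curvature", {
  # a purely linear synthetic response: zero nonlinearity gap
  des <- factorial_design(list(x = c(-1, 0, 1), y = c(10, 20, 30),
                               z = c(0, 5, 10)))
  lin <- run_design(des, function(lv) lv,
                    responses = list(val = function(r)
                      2 * r$x + 0.5 * r$y - r$z + 4))
  expect_equal(nrow(lin$runs), 8)
  expect_equal(unname(lin$nonlinearity["val"]), 0, tolerance = 1e-10)
  expect_equal(lin$effects$val$effect[lin$effects$val$term == "x"], 4)
  # a quadratic response shows a nonzero gap
  quad <- run_design(des, function(lv) lv,
                     responses = list(val = function(r) r$x ^ 2))
  expect_equal(unname(quad$nonlinearity["val"]), -1, tolerance = 1e-10)
  # a failing simulator names the design point
  expect_error(run_design(des, function(lv) stop("boom"),
                          responses = list(v = function(r) 0)),
               "design point 1")
})
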