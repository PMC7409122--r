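test_that("responses are analyte/IS ratios with invalid-IS flagging", {
    expect_equal(computeResponse(0, 5000)$y, 0)
    expect_equal(computeResponse(5000, 5000)$y, 1)
    expect_equal(computeResponse(1234, 617)$y, 2)
    r <- computeResponse(c(10, 10), c(0, 5))
    expect_false(r$valid[1]); expect_true(is.na(r$y[1]))
    expect_equal(r$y[2], 2)
    expect_error(computeResponse(-1, 5), ">= 0")
})

test_that("the weighted fit reproduces exact lines and excludes zeros", {
    x <- rep(as.numeric(calLevels()), each = 2)
    fit <- fitWeightedLinear(x, 0.002 * x)
    expect_equal(calIntercept(fit), 0, tolerance = 1e-12)
    expect_equal(calSlope(fit), 0.002, tolerance = 1e-12)
    expect_equal(calR2(fit), 1)
    # zero-concentration points never enter the fit
    fit0 <- fitWeightedLinear(c(0, x), c(99, 0.002 * x))
    expect_equal(calSlope(fit0), 0.002, tolerance = 1e-12)
    expect_equal(nrow(fit0@points), length(x))
    # two points: interpolation, r2 = 1
    fit2 <- fitWeightedLinear(c(5, 1000), c(1, 200))
    expect_equal(calR2(fit2), 1)
    expect_equal(backCalculate(fit2, 1), 5, tolerance = 1e-9)
    expect_error(fitWeightedLinear(c(10, 10), c(1, 2)), "singular")
})

test_that("1/x^2 weighting down-weights a high-level outlier", {
    x <- as.numeric(calLevels())
    y <- 0.002 * x
    y[x == 1000] <- 0.002 * 1000 * 1.5  # +50% outlier at the top level
    wfit <- fitWeightedLinear(x, y)
    ufit <- stats::lm(y ~ x)
    expect_lt(abs(calSlope(wfit) - 0.002),
              abs(unname(coef(ufit)[2]) - 0.002))
})

test_that("weighted parameters match the normal-equation oracle", {
    set.seed(42)
    for (i in 1:5) {
        n <- sample(4:12, 1)
        x <- sort(stats::runif(n, 1, 1000))
        y <- 0.1 + 0.003 * x + stats::rnorm(n, 0, 0.05)
        fit <- fitWeightedLinear(x, y)
        W <- diag(1 / x^2)
        X <- cbind(1, x)
        beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
        expect_equal(calIntercept(fit), beta[1], tolerance = 1e-8)
        expect_equal(calSlope(fit), beta[2], tolerance = 1e-8)
        # weighted r2 against its definition
        res <- y - X %*% beta
        yw <- sum(y / x^2) / sum(1 / x^2)
        r2 <- 1 - sum(res^2 / x^2) / sum((y - yw)^2 / x^2)
        expect_equal(calR2(fit), r2, tolerance = 1e-8)
    }
})

test_that("back-calculation inverts the model and keeps negatives", {
    fit <- fitWeightedLinear(c(5, 1000), c(1.5, 1000.5))  # a=1.5? no: line
    a <- calIntercept(fit); b <- calSlope(fit)
    expect_equal(backCalculate(fit, a), 0)
    expect_equal(backCalculate(fit, a + 2 * b), 2, tolerance = 1e-9)
    expect_lt(backCalculate(fit, a - b), 0)  # reported as-is, not clamped
    # round trip for arbitrary positive x
    for (x in c(0.5, 5, 123.4, 1000))
        expect_equal(backCalculate(fit, a + b * x), x, tolerance = 1e-9)
    bad <- fit; bad@slope <- -1
    expect_error(backCalculate(bad, 1), "slope")
})

test_that("curve acceptance applies the 75%/6-level bias rules", {
    x <- rep(as.numeric(calLevels()), each = 4)
    lv <- rep(names(calLevels()), each = 4)
    mkfit <- function(y) evaluateCalibration(
        fitWeightedLinear(x, y, level = lv))
    # noiseless: everything accepted
    fit <- mkfit(0.002 * x)
    expect_true(fit@verdict)
    expect_equal(fit@acceptedLevels, 8L)
    expect_equal(fit@standardsFraction, 1)
    # one level biased +30%: level rejected, curve still accepted (7/8)
    y <- 0.002 * x; y[lv == "CAL20"] <- y[lv == "CAL20"] * 1.3
    fit <- mkfit(y)
    lvl <- attr(fit@backCalc, "levels")
    expect_false(lvl$accepted[lvl$level == "CAL20"])
    expect_equal(fit@acceptedLevels, 7L)
    expect_true(fit@verdict)
    # three levels far off: 5/8 = 62.5% < 75% -> rejected
    y <- 0.002 * x
    for (l in c("CAL20", "CAL50", "CAL100"))
        y[lv == l] <- y[lv == l] * 1.6
    fit <- mkfit(y)
    expect_false(fit@verdict)
})

test_that("the fitted slope recovers the generator slope under 5% noise", {
    inst <- fastInstrument()
    lay <- buildBatchLayout("validation")
    lay <- lay[lay$role == "CAL", ]
    sig <- signalModel(replicateCv = 0.05, spotHeterogeneity = 0.2,
                       interferentIntensity = 0)
    # reference slope: the noiseless response per ng/mL of the same pipeline
    sig0 <- noiselessSignal(interferentIntensity = 0)
    a0 <- simulateSpot(lay[1, ], inst, sig0, seed = 1)
    b0 <- (mobA(a0, analyteWindow()) / mobA(a0, isWindow())) /
        lay$nominal_conc_ng_per_mL[1]
    rel <- vapply(1:15, function(s) {
        acqs <- simulateBatch(lay, inst, sig, seed = 100 + s)
        resp <- extractResponses(acqs, lay, "MobA")
        fit <- fitWeightedLinear(resp$nominal_conc_ng_per_mL, resp$y)
        abs(calSlope(fit) - b0) / b0
    }, numeric(1))
    expect_lt(stats::median(rel), 0.05)
})
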