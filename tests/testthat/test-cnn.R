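test_that("cnnConfig validates the hyper-parameter ranges", {
    expect_error(cnnConfig(nConvLayers = 4), "2 or 3")
    expect_error(cnnConfig(learningRate = 1e-7), "learningRate")
    expect_error(cnnConfig(learningRate = 0.1), "learningRate")
    expect_error(cnnConfig(dropout = 1), "dropout")
    expect_error(cnnConfig(epochs = 0), "epochs")
    cfg <- cnnConfig()
    expect_identical(cfg$filters, c(32L, 48L, 64L))
    expect_identical(cfg$kernels, c(3L, 4L, 5L))
    expect_identical(cfg$poolType, "max")
})

test_that("ablateConfig produces the four study variants", {
    cfg <- cnnConfig()
    expect_identical(ablateConfig(cfg, "RSCF")$filters, c(16L, 24L, 32L))
    expect_identical(ablateConfig(cfg, "VPS")$poolType, "avg")
    expect_identical(ablateConfig(cfg, "VKS")$kernels, rep(3L, 3))
    expect_identical(ablateConfig(cfg, "VKS", kernelSize = 5)$kernels,
                     rep(5L, 3))
    expect_identical(ablateConfig(cfg, "RFCL")$hiddenUnits, 0L)
    expect_error(ablateConfig(cfg, "nope"), "unknown ablation")
})

test_that("bceLoss matches the definition and clamps", {
    expect_equal(bceLoss(c(1, 0), c(0.8, 0.4)),
                 -mean(c(log(0.8), log(0.6))))
    expect_true(is.finite(bceLoss(1, 0)))
})

test_that("im2col and col2im are adjoint", {
    withSeed(4, {
        A <- array(rnorm(3 * 10 * 2), c(3, 10, 2))
        Y <- matrix(rnorm(3 * 8 * 3 * 2), 3 * 8, 3 * 2)
    })
    Xc <- dbpWET:::im2col(A, 3)
    back <- dbpWET:::col2im(Y, 3, 10, 2, 3)
    expect_equal(sum(Xc * Y), sum(A * back), tolerance = 1e-12)
})

test_that("width-2 pooling handles ties and odd tails", {
    A <- array(c(1, 2, 2, 1, 5, 0, 9), c(1, 7, 1))   # position 7 is dropped
    pf <- dbpWET:::poolForward(A, "max")
    expect_equal(as.numeric(pf$out), c(2, 2, 5))
    dP <- array(c(1, 1, 1), c(1, 3, 1))
    dA <- dbpWET:::poolBackward(dP, pf, "max")
    ## the tie at positions 3/4 routes the gradient to the first element
    expect_equal(as.numeric(dA), c(0, 1, 1, 0, 1, 0, 0))
    pa <- dbpWET:::poolForward(A, "avg")
    expect_equal(as.numeric(pa$out), c(1.5, 1.5, 2.5))
})

test_that("batch normalisation standardises channels and tracks stats", {
    withSeed(5, A <- array(rnorm(8 * 6 * 3, mean = 2, sd = 3), c(8, 6, 3)))
    run <- list(mean = numeric(3), var = rep(1, 3))
    bn <- dbpWET:::bnForward(A, gamma = rep(1, 3), beta = rep(0, 3),
                             running = run, training = TRUE)
    M <- bn$out; dim(M) <- c(48, 3)
    expect_equal(colMeans(M), rep(0, 3), tolerance = 1e-8)
    expect_equal(apply(M, 2, function(v) mean(v^2)), rep(1, 3),
                 tolerance = 1e-3)                       # biased var + eps
    expect_false(identical(bn$running$mean, run$mean))
    ## eval mode uses the provided running stats
    bn2 <- dbpWET:::bnForward(A, rep(1, 3), rep(0, 3), bn$running,
                              training = FALSE)
    expect_false(identical(bn2$out, bn$out))
})

test_that("buildCNN validates that the width survives the stack", {
    expect_error(buildCNN(4, cnnConfig()), "smaller than kernel")
    m <- withSeed(1, buildCNN(200, cnnConfig()))
    expect_identical(dim(m$params$conv1.W), c(3L, 32L))
    expect_identical(dim(m$params$conv2.W), c(4L * 32L, 48L))
    expect_identical(dim(m$params$conv3.W), c(5L * 48L, 64L))
    expect_identical(m$mapWidths, c(99L, 48L, 22L))
    expect_identical(nrow(m$params$dense.W), 22L * 64L)
})

test_that("the compiled batch step matches the R reference exactly", {
    withSeed(6, {
        X <- matrix(rnorm(10 * 40), 10, 40)
        y <- rbinom(10, 1, 0.5)
    })
    for (cfg in list(cnnConfig(nConvLayers = 2, filters = c(3L, 4L),
                               kernels = c(3L, 4L), dropout = 0,
                               learningRate = 1e-3, hiddenUnits = 6L),
                     cnnConfig(nConvLayers = 2, filters = c(3L, 4L),
                               kernels = c(3L, 3L), dropout = 0,
                               learningRate = 1e-3, batchNorm = FALSE,
                               poolType = "avg", hiddenUnits = 0L))) {
        model <- withSeed(8, buildCNN(ncol(X), cfg))
        fwR <- dbpWET:::forwardCNN(model, X, training = TRUE)
        grR <- dbpWET:::backwardCNN(fwR, y)
        res <- dbpWET:::cnnBatchStep(model, X, y)
        expect_equal(as.numeric(res$prob), fwR$prob, tolerance = 1e-12)
        for (nm in names(grR))
            expect_equal(unname(as.matrix(res$grads[[nm]]))[, ],
                         unname(as.matrix(grR[[nm]]))[, ], tolerance = 1e-12)
        pR <- dbpWET:::forwardCNN(model, X, training = FALSE)$prob
        expect_equal(dbpWET:::cnnInferProb(model, X), pR, tolerance = 1e-12)
    }
})

test_that("analytic gradients match finite differences", {
    withSeed(7, {
        X <- matrix(rnorm(6 * 24), 6, 24)
        y <- rbinom(6, 1, 0.5)
    })
    cfg <- cnnConfig(nConvLayers = 2, filters = c(2L, 3L),
                     kernels = c(3L, 3L), dropout = 0,
                     learningRate = 1e-3, hiddenUnits = 4L)
    model <- withSeed(9, buildCNN(ncol(X), cfg))
    res <- dbpWET:::cnnBatchStep(model, X, y)
    lossAt <- function(m) {
        ## training-mode forward (batch statistics), as in the backward pass
        fw <- dbpWET:::forwardCNN(m, X, training = TRUE)
        bceLoss(y, fw$prob)
    }
    eps <- 1e-5
    for (nm in c("conv1.W", "conv2.gamma", "dense.W", "out.W", "out.b")) {
        p <- model$params[[nm]]
        idx <- if (length(p) > 3) c(1L, length(p) %/% 2L, length(p)) else 1L
        for (i in idx) {
            mp <- model; mp$params[[nm]][i] <- p[i] + eps
            mm <- model; mm$params[[nm]][i] <- p[i] - eps
            num <- (lossAt(mp) - lossAt(mm)) / (2 * eps)
            expect_equal(as.numeric(res$grads[[nm]])[i], num,
                         tolerance = 1e-4)
        }
    }
})

test_that("trainCNN is seeded, learns, and predicts deterministically", {
    d <- separableData(n = 30, p = 24, shift = 2.5, seed = 31)
    cfg <- cnnConfig(nConvLayers = 2, filters = c(4L, 6L),
                     kernels = c(3L, 3L), learningRate = 1e-2,
                     epochs = 40, batchSize = 10, valFraction = 0, seed = 3)
    m1 <- trainCNN(d$X, d$y, cfg)
    m2 <- trainCNN(d$X, d$y, cfg)
    expect_identical(m1$params, m2$params)
    expect_lt(tail(m1$lossTrace, 1), m1$lossTrace[1])
    p <- predictProba(m1, d$X)
    expect_true(all(p > 0 & p < 1))
    expect_gt(rocAUC(d$y, p), 0.9)
    expect_error(predictProba(m1, d$X[, 1:10]), "does not match")
    expect_error(trainCNN(d$X, rep(1L, 30), cfg), "single-class")
})

test_that("early stopping halts before the epoch cap and keeps best weights", {
    d <- separableData(n = 40, p = 24, shift = 2.5, seed = 32)
    cfg <- cnnConfig(nConvLayers = 2, filters = c(4L, 6L),
                     kernels = c(3L, 3L), learningRate = 1e-2,
                     epochs = 200, batchSize = 16, valFraction = 0.2,
                     patience = 3, seed = 5)
    m <- trainCNN(d$X, d$y, cfg)
    expect_lt(length(m$lossTrace), 200)
    expect_length(m$valTrace, length(m$lossTrace))
})

test_that("gridSearchCNN ranks configurations by CV AUC", {
    d <- separableData(n = 30, p = 24, shift = 2.5, seed = 33)
    grid <- list(
        cnnConfig(nConvLayers = 2, filters = c(4L, 6L), kernels = c(3L, 3L),
                  learningRate = 1e-3, epochs = 6, valFraction = 0),
        cnnConfig(nConvLayers = 2, filters = c(4L, 6L), kernels = c(3L, 3L),
                  learningRate = 1e-6, epochs = 6, valFraction = 0))
    gs <- gridSearchCNN(d$X, d$y, grid, cvSeed = 2, k = 3)
    expect_identical(nrow(gs$table), 2L)
    expect_identical(gs$best$learningRate,
                     grid[[gs$bestIndex]]$learningRate)
    expect_gte(gs$table$AUC[gs$bestIndex], max(gs$table$AUC))
})
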