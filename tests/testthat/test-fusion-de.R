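test_that("deConfig validates its parameters", {
    expect_error(deConfig(N = 3), "population size")
    expect_error(deConfig(Gmax = 0), "Gmax")
    expect_error(deConfig(CR = 0), "CR")
    expect_error(deConfig(CR = 1), "CR")
    cfg <- deConfig()
    expect_identical(cfg$N, 20L)
    expect_identical(cfg$Gmax, 1000L)
    expect_equal(cfg$CR, 0.5)
    expect_equal(cfg$F, 0.5)
})

test_that("deMutate clips to bounds and needs 4 members", {
    pop <- matrix(runif(20, 0, 1), 5, 4)
    withSeed(1, {
        for (r in 1:20) {
            mv <- deMutate(pop, i = 1, F = 5, lower = 0, upper = 1)
            expect_true(all(mv >= 0 & mv <= 1))
        }
    })
    expect_error(deMutate(pop[1:3, ], 1, 0.5), "at least 4")
})

test_that("deCrossover always inherits at least one mutant component", {
    target <- rep(0, 6); mutant <- rep(1, 6)
    withSeed(2, {
        for (r in 1:50) {
            trial <- deCrossover(target, mutant, CR = 0.01)
            expect_gte(sum(trial == 1), 1)
        }
    })
})

test_that("deSelect is greedy with ties to the trial", {
    s <- deSelect(c(0, 0), c(1, 1), fTarget = 0.5, fTrial = 0.5)
    expect_identical(s$vector, c(1, 1))
    s2 <- deSelect(c(0, 0), c(1, 1), fTarget = 0.4, fTrial = 0.5)
    expect_identical(s2$vector, c(0, 0))
    expect_error(deSelect(c(0), c(1), NaN, 0.1), "non-finite")
})

test_that("deOptimize minimises a quadratic with a monotone trace", {
    res <- deOptimize(function(w) sum((w - 0.6)^2), D = 2,
                      config = deConfig(Gmax = 150, seed = 9))
    expect_length(res$trace, 151)
    expect_true(all(diff(res$trace) <= 0))
    expect_lt(max(abs(res$best - 0.6)), 0.05)
    expect_equal(res$bestFitness, sum((res$best - 0.6)^2))
})

test_that("fuseFeatures scales blocks and restores the canonical order", {
    fx <- deFitnessFixture(seed = 4, nPerClass = 5, dimPerBlock = 3)
    shuffled <- fx$blocks[c(2, 3, 1)]          # fasttext, cbow, glove
    w <- c(fasttext = 0.2, cbow = 0.5, glove = 1)
    fused <- fuseFeatures(shuffled, w)
    expect_identical(names(fused@blockWidths),
                     c("glove", "fasttext", "cbow"))
    expect_equal(fused@weights, c(1, 0.2, 0.5))
    expect_equal(featureMatrix(fused)[, 1:3],
                 featureMatrix(fx$blocks[[1]]) * 1)
    expect_equal(featureMatrix(fused)[, 4:6],
                 featureMatrix(fx$blocks[[2]]) * 0.2)
    bad <- fx$blocks
    bad[[2]] <- new("FeatureBlock",
                    matrix = featureMatrix(bad[[2]])[1:4, ],
                    encoder = "fasttext")
    expect_error(fuseFeatures(bad, c(1, 1, 1)), "mismatching row counts")
})

test_that("the fusion fitness is deterministic and rewards signal", {
    fx <- deFitnessFixture(seed = 6)
    fit <- makeFusionFitness(fx$blocks, fx$labels, cvSeed = 2)
    w <- c(0.7, 0.2, 0.1)
    expect_identical(fit(w), fit(w))
    expect_gte(fit(w), 0); expect_lte(fit(w), 1)
    ## weight on the informative block beats weight on noise
    expect_lt(fit(c(1, 0, 0)), fit(c(0, 1, 0)))
    expect_error(makeFusionFitness(fx$blocks, rep(1L, 120)),
                 "single-class")
})

test_that("learnFusionWeights puts its weight on the informative block", {
    fx <- deFitnessFixture(seed = 11)
    fw <- learnFusionWeights(fx$blocks, fx$labels,
                             config = deConfig(Gmax = 30, seed = 1),
                             cvSeed = 3)
    expect_s4_class(fw$fused, "FusedFeatures")
    expect_gt(fw$weights[1], max(fw$weights[2:3]))
    expect_equal(dim(featureMatrix(fw$fused)), c(120L, 60L))
})

test_that("writeDEResult serialises weights and trace as JSON", {
    res <- deOptimize(function(w) sum(w^2), D = 2,
                      config = deConfig(Gmax = 5, seed = 1))
    f <- tempfile(fileext = ".json")
    writeDEResult(res, f, config = deConfig(Gmax = 5, seed = 1))
    parsed <- jsonlite::read_json(f, simplifyVector = TRUE)
    expect_equal(parsed$weights, res$best, tolerance = 1e-12)
    expect_length(parsed$trace, 6)
    expect_identical(parsed$config$Gmax, 5L)
})
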