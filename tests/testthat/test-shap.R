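test_that("exact Shapley values of a linear model are analytic", {
    ## for f(x) = sum c_j x_j, phi_j = c_j * (x_j - mean(bg_j))
    withSeed(1, {
        bg <- matrix(rnorm(50 * 5), 50, 5,
                     dimnames = list(NULL, paste0("f", 1:5)))
        x <- rnorm(5)
    })
    cf <- c(2, -1, 0.5, 0, 3)
    model <- function(Z) as.numeric(Z %*% cf)
    phi <- exactShapley(model, bg, x)
    expect_equal(as.numeric(phi), unname(cf * (x - colMeans(bg))),
                 tolerance = 1e-12)
    expect_identical(names(phi), colnames(bg))
    ## efficiency: phi0 + sum(phi) = f(x)
    expect_equal(attr(phi, "phi0") + sum(phi), model(matrix(x, 1)),
                 tolerance = 1e-12)
    ## dummy axiom: the zero-coefficient feature gets exactly zero
    expect_identical(unname(phi[4]), 0)
})

test_that("exact enumeration is capped at 15 features", {
    bg <- matrix(0, 2, 16)
    expect_error(exactShapley(function(Z) rowSums(Z), bg, rep(1, 16)),
                 "capped at 15")
})

test_that("sampled Shapley is seeded, efficient and near-exact", {
    withSeed(2, {
        bg <- matrix(rnorm(30 * 4), 30, 4)
        x <- rnorm(4)
    })
    model <- function(Z) Z[, 1] * Z[, 2] + Z[, 3]^2
    s1 <- sampledShapley(model, bg, x, nPermutations = 1000, seed = 5)
    s2 <- sampledShapley(model, bg, x, nPermutations = 1000, seed = 5)
    expect_identical(s1, s2)
    expect_equal(attr(s1, "phi0") + sum(s1), model(matrix(x, 1)),
                 tolerance = 1e-9)
    ex <- exactShapley(model, bg, x)
    expect_lt(max(abs(s1 - ex)), 0.05)
})

test_that("shapExplain aggregates instances additively", {
    withSeed(3, {
        bg <- matrix(rnorm(20 * 3), 20, 3)
        X <- matrix(rnorm(4 * 3), 4, 3)
    })
    model <- function(Z) as.numeric(Z %*% c(1, 2, -1))
    ex <- shapExplain(model, bg, X, method = "exact")
    expect_s4_class(ex, "ShapExplanation")
    expect_equal(dim(ex@phi), c(4L, 3L))
    expect_equal(ex@phi0 + rowSums(ex@phi), ex@fx, tolerance = 1e-9)
})

test_that("globalImportance sums |phi| and breaks ties by index", {
    phi <- rbind(c(1, -2, 1), c(-1, 0, 1))
    rk <- globalImportance(phi)
    expect_equal(unname(rk@importance), c(2, 2, 2))
    expect_identical(rk@rankOrder, 1:3)       # all tied -> ascending index
    phi2 <- rbind(c(0.5, 3, 0.5))
    expect_identical(globalImportance(phi2)@rankOrder[1], 2L)
    expect_error(globalImportance(matrix(numeric(0), 0, 0)), "empty")
    expect_error(globalImportance(rbind(c(1, NA))), "non-finite")
})

test_that("rankFeatures surfaces the informative columns", {
    d <- separableData(n = 60, p = 10, shift = 3, seed = 21)
    rk <- rankFeatures(d$X, d$y, seed = 1, nrounds = 30)
    expect_s4_class(rk, "FeatureRanking")
    expect_true(all(1:3 %in% rk@rankOrder[1:5]))
    rk2 <- rankFeatures(d$X, d$y, seed = 1, nrounds = 30)
    expect_identical(rk@importance, rk2@importance)
    expect_error(rankFeatures(d$X, rep(1L, 60)), "single-class")
})

test_that("sampled surrogate ranking agrees on the top features", {
    d <- separableData(n = 30, p = 6, shift = 3, seed = 22)
    rk <- rankFeatures(d$X, d$y, seed = 2, nrounds = 15, method = "sampled",
                       backgroundSize = 15, nPermutations = 20)
    expect_true(any(1:3 %in% rk@rankOrder[1:3]))
})

test_that("selectTopK and selectionGrid respect the feature count", {
    rk <- globalImportance(rbind(c(1, 5, 3, 2)))
    expect_identical(selectTopK(rk, 2), c(2L, 3L))
    expect_error(selectTopK(rk, 9), "exceeds feature count")
    expect_identical(selectionGrid(600), seq(200L, 450L, 50L))
    expect_identical(selectionGrid(320), c(200L, 250L, 300L))
    expect_identical(selectionGrid(120), 120L)
})

test_that("writeRanking emits a rank-ordered TSV", {
    rk <- globalImportance(rbind(c(1, 5, 3)))
    f <- tempfile(fileext = ".tsv")
    writeRanking(rk, f)
    tab <- read.delim(f)
    expect_identical(tab$feature, c("f2", "f3", "f1"))
    expect_identical(tab$rank, 1:3)
})
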