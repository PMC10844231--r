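## 1-D convolutional binary classifier. The fused/selected feature vector is
## treated as a length-L single-channel signal; each conv block is
## convolution (valid padding, stride 1) -> optional batch normalisation ->
## ReLU -> width-2 pooling -> dropout; then flatten -> dense ReLU ->
## logistic output. Trained with Adam on binary cross-entropy. All tensors
## are base-R arrays (B x L x C); convolutions run as im2col matrix products.

#' CNN configuration
#'
#' Defaults follow the reference architecture: three convolutional layers
#' with 32/48/64 filters and kernel sizes 3/4/5, ReLU hidden activations,
#' a logistic output, batch normalisation and dropout, Adam at learning
#' rate 1e-5.
#'
#' @param nConvLayers 2 or 3 convolution blocks.
#' @param filters Filter counts per block.
#' @param kernels Kernel sizes per block.
#' @param dropout Dropout rate (applied after each pool and the hidden
#'   dense layer).
#' @param learningRate Adam learning rate, within [1e-6, 1e-2].
#' @param batchSize Mini-batch size.
#' @param epochs Maximum training epochs.
#' @param batchNorm Use batch normalisation in each conv block.
#' @param poolType `"max"` (default) or `"avg"`, width-2 stride-2.
#' @param hiddenUnits Penultimate dense layer width (0 = none).
#' @param valFraction Fraction of training data held out for early stopping
#'   (0 disables early stopping).
#' @param patience Early-stopping patience in epochs.
#' @param seed Training seed (NULL = use the ambient RNG state).
#' @return A list of class `CNNConfig`.
#' @export
cnnConfig <- function(nConvLayers = 3L, filters = c(32L, 48L, 64L),
                      kernels = c(3L, 4L, 5L), dropout = 0.3,
                      learningRate = 1e-5, batchSize = 32L, epochs = 300L,
                      batchNorm = TRUE, poolType = c("max", "avg"),
                      hiddenUnits = 64L, valFraction = 0.1, patience = 30L,
                      seed = NULL) {
    poolType <- match.arg(poolType)
    if (!nConvLayers %in% c(2L, 3L))
        stopf("nConvLayers must be 2 or 3")
    if (learningRate < 1e-6 || learningRate > 1e-2)
        stopf("learningRate must lie in [1e-6, 1e-2]")
    if (dropout < 0 || dropout >= 1) stopf("dropout must lie in [0, 1)")
    if (epochs < 1) stopf("epochs must be >= 1")
    filters <- rep_len(as.integer(filters), nConvLayers)
    kernels <- rep_len(as.integer(kernels), nConvLayers)
    structure(list(nConvLayers = as.integer(nConvLayers), filters = filters,
                   kernels = kernels, dropout = dropout,
                   learningRate = learningRate,
                   batchSize = as.integer(batchSize),
                   epochs = as.integer(epochs), batchNorm = batchNorm,
                   poolType = poolType, hiddenUnits = as.integer(hiddenUnits),
                   valFraction = valFraction, patience = as.integer(patience),
                   seed = seed),
              class = "CNNConfig")
}

#' Ablation variants of a CNN configuration
#'
#' `RSCF` halves every filter count; `VPS` switches max-pooling to
#' average-pooling; `VKS` sets all kernels to one size; `RFCL` removes the
#' penultimate dense layer (idempotent).
#'
#' @param cfg A [cnnConfig()].
#' @param variant One of `"RSCF"`, `"VPS"`, `"VKS"`, `"RFCL"`.
#' @param kernelSize Kernel size used by `VKS` (default 3).
#' @return The modified config.
#' @export
ablateConfig <- function(cfg, variant, kernelSize = 3L) {
    stopifnot(inherits(cfg, "CNNConfig"))
    switch(variant,
        RSCF = { cfg$filters <- pmax(1L, cfg$filters %/% 2L); cfg },
        VPS  = { cfg$poolType <- "avg"; cfg },
        VKS  = { cfg$kernels <- rep(as.integer(kernelSize),
                                    cfg$nConvLayers); cfg },
        RFCL = { cfg$hiddenUnits <- 0L; cfg },
        stopf("unknown ablation variant '%s'", variant))
}

#' Binary cross-entropy
#'
#' `-(1/N) sum y log(p) + (1 - y) log(1 - p)`, with probabilities clamped
#' away from 0/1.
#'
#' @param y Binary labels.
#' @param p Predicted probabilities.
#' @return Scalar loss.
#' @export
bceLoss <- function(y, p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
}

## ---- layer primitives ------------------------------------------------------

## A: B x L x C -> (B*Lout) x (k*C) patch matrix, rows ordered (b, pos).
im2col <- function(A, k) {
    B <- dim(A)[1]; L <- dim(A)[2]; C <- dim(A)[3]
    Lout <- L - k + 1L
    Xc <- matrix(0, B * Lout, k * C)
    for (j in seq_len(k)) {
        slice <- A[, j:(j + Lout - 1L), , drop = FALSE]
        dim(slice) <- c(B * Lout, C)
        Xc[, ((j - 1L) * C + 1L):(j * C)] <- slice
    }
    Xc
}

col2im <- function(dXc, B, L, C, k) {
    Lout <- L - k + 1L
    dA <- array(0, c(B, L, C))
    for (j in seq_len(k)) {
        part <- dXc[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
        dim(part) <- c(B, Lout, C)
        dA[, j:(j + Lout - 1L), ] <- dA[, j:(j + Lout - 1L), , drop = FALSE] + part
    }
    dA
}

poolForward <- function(A, type) {
    B <- dim(A)[1]; L <- dim(A)[2]; C <- dim(A)[3]
    Lp <- L %/% 2L
    if (Lp == 0) stopf("feature map too short to pool")
    A1 <- A[, seq.int(1L, 2L * Lp, 2L), , drop = FALSE]
    A2 <- A[, seq.int(2L, 2L * Lp, 2L), , drop = FALSE]
    if (type == "max") {
        mask <- A1 >= A2              # ties route to the first element
        list(out = pmax(A1, A2), mask = mask, L = L)
    } else {
        list(out = (A1 + A2) / 2, mask = NULL, L = L)
    }
}

poolBackward <- function(dP, cache, type) {
    B <- dim(dP)[1]; Lp <- dim(dP)[2]; C <- dim(dP)[3]
    dA <- array(0, c(B, cache$L, C))
    if (type == "max") {
        dA[, seq.int(1L, 2L * Lp, 2L), ] <- dP * cache$mask
        dA[, seq.int(2L, 2L * Lp, 2L), ] <- dP * !cache$mask
    } else {
        dA[, seq.int(1L, 2L * Lp, 2L), ] <- dP / 2
        dA[, seq.int(2L, 2L * Lp, 2L), ] <- dP / 2
    }
    dA
}

## Channel-wise batch normalisation over the (batch, position) axes,
## vectorised as a (B*L) x C matrix.
bnForward <- function(A, gamma, beta, running, training, momentum = 0.9,
                      eps = 1e-5) {
    dims <- dim(A); C <- dims[3]
    M <- A; dim(M) <- c(dims[1] * dims[2], C)
    if (training) {
        mu <- colMeans(M)
        v <- colMeans(M * M) - mu^2
        v[v < 0] <- 0
        running$mean <- momentum * running$mean + (1 - momentum) * mu
        running$var  <- momentum * running$var  + (1 - momentum) * v
    } else {
        mu <- running$mean; v <- running$var
    }
    invsd <- 1 / sqrt(v + eps)
    n <- nrow(M)
    xhat <- (M - rep(mu, each = n)) * rep(invsd, each = n)
    out <- xhat * rep(gamma, each = n) + rep(beta, each = n)
    dim(out) <- dims
    list(out = out, cache = list(xhat = xhat, invsd = invsd, dims = dims),
         running = running)
}

bnBackward <- function(dY, cache, gamma) {
    dims <- cache$dims
    dM <- dY; dim(dM) <- c(dims[1] * dims[2], dims[3])
    xhat <- cache$xhat
    dGamma <- colSums(dM * xhat)
    dBeta <- colSums(dM)
    n <- nrow(dM)
    dxhat <- dM * rep(gamma, each = n)
    dA <- (dxhat - rep(colMeans(dxhat), each = n) -
           xhat * rep(colMeans(dxhat * xhat), each = n)) *
          rep(cache$invsd, each = n)
    dim(dA) <- dims
    list(dA = dA, dGamma = dGamma, dBeta = dBeta)
}

## ---- model construction ----------------------------------------------------

#' Build an untrained CNN
#'
#' Validates that the input width survives every conv + pool stage, and
#' initialises weights (He-style for ReLU layers).
#'
#' @param inputDim Width of the input feature vector.
#' @param cfg A [cnnConfig()].
#' @return A `TrainedCNN`-shaped list (untrained weights) of class
#'   `cnnModel`.
#' @export
buildCNN <- function(inputDim, cfg = cnnConfig()) {
    stopifnot(inherits(cfg, "CNNConfig"))
    L <- as.integer(inputDim); Cin <- 1L
    params <- list(); running <- list(); shapes <- integer(0)
    for (l in seq_len(cfg$nConvLayers)) {
        k <- cfg$kernels[l]; Fl <- cfg$filters[l]
        if (L < k)
            stopf("input width %d smaller than kernel %d at conv layer %d",
                  L, k, l)
        fanIn <- k * Cin
        params[[paste0("conv", l, ".W")]] <-
            matrix(rnorm(fanIn * Fl, sd = sqrt(2 / fanIn)), fanIn, Fl)
        params[[paste0("conv", l, ".b")]] <- numeric(Fl)
        if (cfg$batchNorm) {
            params[[paste0("conv", l, ".gamma")]] <- rep(1, Fl)
            params[[paste0("conv", l, ".beta")]] <- numeric(Fl)
            running[[l]] <- list(mean = numeric(Fl), var = rep(1, Fl))
        }
        L <- (L - k + 1L) %/% 2L
        if (L < 1L) stopf("feature map vanishes after conv block %d", l)
        shapes <- c(shapes, L)
        Cin <- Fl
    }
    flat <- L * Cin
    if (cfg$hiddenUnits > 0) {
        params[["dense.W"]] <- matrix(rnorm(flat * cfg$hiddenUnits,
                                            sd = sqrt(2 / flat)),
                                      flat, cfg$hiddenUnits)
        params[["dense.b"]] <- numeric(cfg$hiddenUnits)
        outIn <- cfg$hiddenUnits
    } else outIn <- flat
    params[["out.W"]] <- matrix(rnorm(outIn, sd = sqrt(1 / outIn)), outIn, 1)
    params[["out.b"]] <- 0
    structure(list(params = params, running = running, config = cfg,
                   inputDim = as.integer(inputDim), mapWidths = shapes,
                   center = NULL, scale = NULL, lossTrace = numeric(0)),
              class = "cnnModel")
}

forwardCNN <- function(model, X, training = FALSE) {
    cfg <- model$config; params <- model$params
    B <- nrow(X)
    A <- array(X, c(B, ncol(X), 1L))
    caches <- list()
    for (l in seq_len(cfg$nConvLayers)) {
        k <- cfg$kernels[l]
        Xc <- im2col(A, k)
        Z <- Xc %*% params[[paste0("conv", l, ".W")]]
        Z <- Z + rep(params[[paste0("conv", l, ".b")]], each = nrow(Z))
        Lout <- dim(A)[2] - k + 1L
        Zarr <- array(Z, c(B, Lout, ncol(Z)))
        cache <- list(Xc = Xc, inDim = dim(A))
        if (cfg$batchNorm) {
            bn <- bnForward(Zarr, params[[paste0("conv", l, ".gamma")]],
                            params[[paste0("conv", l, ".beta")]],
                            model$running[[l]], training)
            if (training) model$running[[l]] <- bn$running
            cache$bn <- bn$cache
            Zarr <- bn$out
        }
        cache$preRelu <- Zarr
        Zarr <- pmax(Zarr, 0)
        pool <- poolForward(Zarr, cfg$poolType)
        cache$pool <- pool
        A <- pool$out
        if (training && cfg$dropout > 0) {
            mask <- array(runif(length(A)) >= cfg$dropout, dim(A))
            A <- A * mask / (1 - cfg$dropout)
            cache$drop <- mask
        }
        caches[[l]] <- cache
    }
    flatDim <- prod(dim(A)[-1])
    Aflat <- matrix(A, B, flatDim)
    hiddenCache <- NULL
    if (cfg$hiddenUnits > 0) {
        Zh <- Aflat %*% params$dense.W
        Zh <- Zh + rep(params$dense.b, each = nrow(Zh))
        H <- pmax(Zh, 0)
        if (training && cfg$dropout > 0) {
            maskH <- matrix(runif(length(H)) >= cfg$dropout, nrow(H))
            H <- H * maskH / (1 - cfg$dropout)
        } else maskH <- NULL
        hiddenCache <- list(Aflat = Aflat, Zh = Zh, maskH = maskH, H = H)
        outIn <- H
    } else outIn <- Aflat
    z <- as.numeric(outIn %*% params$out.W) + params$out.b
    prob <- 1 / (1 + exp(-z))
    list(prob = prob, caches = caches, Aflat = Aflat, Adim = dim(A),
         hidden = hiddenCache, outIn = outIn, model = model)
}

backwardCNN <- function(fw, y) {
    model <- fw$model; cfg <- model$config; params <- model$params
    B <- length(y)
    grads <- list()
    dz <- (fw$prob - y) / B                       # dL/dz for BCE + sigmoid
    grads$out.W <- crossprod(fw$outIn, dz)
    grads$out.b <- sum(dz)
    dOutIn <- matrix(dz, ncol = 1) %*% t(params$out.W)
    if (cfg$hiddenUnits > 0) {
        h <- fw$hidden
        dH <- dOutIn
        if (!is.null(h$maskH)) dH <- dH * h$maskH / (1 - cfg$dropout)
        dZh <- dH * (h$Zh > 0)
        grads$dense.W <- crossprod(h$Aflat, dZh)
        grads$dense.b <- colSums(dZh)
        dAflat <- dZh %*% t(params$dense.W)
    } else dAflat <- dOutIn
    dA <- array(dAflat, fw$Adim)
    for (l in rev(seq_len(cfg$nConvLayers))) {
        cache <- fw$caches[[l]]
        if (!is.null(cache$drop))
            dA <- dA * cache$drop / (1 - cfg$dropout)
        dZ <- poolBackward(dA, cache$pool, cfg$poolType)
        dZ <- dZ * (cache$preRelu > 0)
        if (cfg$batchNorm) {
            bb <- bnBackward(dZ, cache$bn,
                             params[[paste0("conv", l, ".gamma")]])
            grads[[paste0("conv", l, ".gamma")]] <- bb$dGamma
            grads[[paste0("conv", l, ".beta")]] <- bb$dBeta
            dZ <- bb$dA
        }
        dZmat <- matrix(dZ, dim(dZ)[1] * dim(dZ)[2], dim(dZ)[3])
        grads[[paste0("conv", l, ".W")]] <- crossprod(cache$Xc, dZmat)
        grads[[paste0("conv", l, ".b")]] <- colSums(dZmat)
        dXc <- dZmat %*% t(params[[paste0("conv", l, ".W")]])
        dims <- cache$inDim
        dA <- col2im(dXc, dims[1], dims[2], dims[3], cfg$kernels[l])
    }
    grads
}

adamInit <- function(params)
    list(m = lapply(params, function(p) p * 0),
         v = lapply(params, function(p) p * 0), t = 0L)

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
    state$t <- state$t + 1L
    for (nm in names(grads)) {
        g <- grads[[nm]]
        state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
        state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
        mhat <- state$m[[nm]] / (1 - beta1^state$t)
        vhat <- state$v[[nm]] / (1 - beta2^state$t)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    list(params = params, state = state)
}

## ---- training and prediction -----------------------------------------------

## The R primitives above are the readable reference implementation; the
## hot path (per-batch forward+backward and inference forward) runs in C++
## (src/cnn_ops.cpp) with identical semantics. Tests assert agreement.

poolCode <- function(type) if (type == "max") 0L else 1L

cnnBatchStep <- function(model, Xb, yb, training = TRUE) {
    cfg <- model$config
    cpp_cnn_batch(model$params, model$running, Xb, as.numeric(yb),
                  cfg$kernels, cfg$filters, cfg$batchNorm,
                  poolCode(cfg$poolType), cfg$dropout, cfg$hiddenUnits,
                  training, 0.9, 1e-5)
}

cnnInferProb <- function(model, X) {
    cfg <- model$config
    as.numeric(cpp_cnn_forward(model$params, model$running, X,
                               cfg$kernels, cfg$filters, cfg$batchNorm,
                               poolCode(cfg$poolType), cfg$hiddenUnits,
                               1e-5)$prob)
}

#' Train the CNN
#'
#' Minimises binary cross-entropy with Adam; mini-batches with seeded
#' shuffling; dropout and batch statistics are active only during training.
#' When `valFraction > 0` a stratified validation split drives early
#' stopping (best-validation weights are restored).
#'
#' @param X n x L feature matrix.
#' @param y Binary labels (both classes required).
#' @param cfg A [cnnConfig()].
#' @param model Optional pre-built [buildCNN()] model (its config wins).
#' @return A `cnnModel` with trained weights, `lossTrace` (mean training
#'   batch loss per epoch) and `valTrace` when early stopping is on.
#' @export
trainCNN <- function(X, y, cfg = cnnConfig(), model = NULL) {
    X <- as.matrix(X); y <- as.integer(y)
    if (length(unique(y)) < 2) stopf("training labels are single-class")
    withSeed(cfg$seed, {
        if (is.null(model)) model <- buildCNN(ncol(X), cfg)
        cfg <- model$config
        model$center <- colMeans(X)
        model$scale <- apply(X, 2, sd)
        model$scale[model$scale == 0] <- 1
        Xs <- scale(X, model$center, model$scale)
        valIdx <- integer(0)
        if (cfg$valFraction > 0 && cfg$patience < cfg$epochs) {
            for (cls in unique(y)) {
                idx <- which(y == cls)
                nv <- max(1L, round(length(idx) * cfg$valFraction))
                valIdx <- c(valIdx, sample(idx, nv))
            }
        }
        trIdx <- setdiff(seq_len(nrow(Xs)), valIdx)
        opt <- adamInit(model$params)
        bestVal <- Inf; bestParams <- model$params
        bestRunning <- model$running; wait <- 0L
        lossTrace <- numeric(0); valTrace <- numeric(0)
        for (ep in seq_len(cfg$epochs)) {
            ord <- trIdx[sample.int(length(trIdx))]
            nb <- ceiling(length(ord) / cfg$batchSize)
            batches <- split(ord, rep(seq_len(nb),
                                      each = cfg$batchSize)[seq_along(ord)])
            if (length(batches) > 1 &&
                length(batches[[nb]]) == 1L && cfg$batchNorm) {
                batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
                batches[[nb]] <- NULL
            }
            epLoss <- 0
            for (bidx in batches) {
                res <- cnnBatchStep(model, Xs[bidx, , drop = FALSE], y[bidx])
                model$running <- res$running
                epLoss <- epLoss +
                    bceLoss(y[bidx], as.numeric(res$prob)) * length(bidx)
                upd <- adamStep(model$params, res$grads, opt,
                                cfg$learningRate)
                model$params <- upd$params
                opt <- upd$state
            }
            lossTrace <- c(lossTrace, epLoss / length(ord))
            if (length(valIdx)) {
                pv <- cnnInferProb(model, Xs[valIdx, , drop = FALSE])
                vl <- bceLoss(y[valIdx], pv)
                valTrace <- c(valTrace, vl)
                if (vl < bestVal - 1e-9) {
                    bestVal <- vl; bestParams <- model$params
                    bestRunning <- model$running; wait <- 0L
                } else {
                    wait <- wait + 1L
                    if (wait >= cfg$patience) break
                }
            }
        }
        if (length(valIdx)) {
            model$params <- bestParams
            model$running <- bestRunning
        }
        model$lossTrace <- lossTrace
        model$valTrace <- valTrace
    })
    model
}

#' Predict class probabilities
#'
#' Deterministic: dropout is inactive and batch normalisation uses the
#' running statistics accumulated during training.
#'
#' @param model A trained `cnnModel`.
#' @param X Matrix whose width equals the trained input width.
#' @return Probability vector in (0, 1); the hard label convention is
#'   `1 iff p >= 0.5`.
#' @export
predictProba <- function(model, X) {
    stopifnot(inherits(model, "cnnModel"))
    X <- as.matrix(X)
    if (ncol(X) != model$inputDim)
        stopf("input width %d does not match trained width %d",
              ncol(X), model$inputDim)
    if (!is.null(model$center))
        X <- scale(X, model$center, model$scale)
    cnnInferProb(model, X)
}

#' CNN classifier factory
#'
#' Adapts [trainCNN()]/[predictProba()] to the classifier-factory contract
#' used by [crossValidate()]: any object exposing the same contract can
#' replace the CNN in the pipeline.
#'
#' @param cfg A [cnnConfig()].
#' @return `function(X, y)` returning `function(Xnew) -> probabilities`.
#' @export
cnnClassifier <- function(cfg = cnnConfig()) {
    force(cfg)
    function(X, y) {
        model <- trainCNN(X, y, cfg)
        function(Xnew) predictProba(model, Xnew)
    }
}

#' Grid search over CNN configurations
#'
#' Evaluates each configuration by stratified k-fold cross-validation (folds
#' fixed by `cvSeed`) and returns the best by AUC, ties broken by higher
#' accuracy then smaller learning rate.
#'
#' @param X,y Features and binary labels.
#' @param grid List of [cnnConfig()] objects.
#' @param cvSeed Fold seed.
#' @param k Folds.
#' @return List: `best` (config), `table` (one row per config with CV
#'   metrics), `reports` (full [MetricReport-class] per config).
#' @export
gridSearchCNN <- function(X, y, grid, cvSeed = 1L, k = 5L) {
    stopifnot(length(grid) >= 1)
    reports <- lapply(grid, function(cfg)
        crossValidate(X, y, cnnClassifier(cfg), k = k, seed = cvSeed))
    tab <- do.call(rbind, lapply(seq_along(grid), function(i) {
        m <- metrics(reports[[i]])
        data.frame(config = i, learningRate = grid[[i]]$learningRate,
                   AUC = m["AUC"], ACC = m["ACC"], Sen = m["Sen"],
                   Spe = m["Spe"], MCC = m["MCC"], row.names = NULL)
    }))
    ord <- order(-tab$AUC, -tab$ACC, tab$learningRate)
    list(best = grid[[ord[1]]], bestIndex = ord[1], table = tab,
         reports = reports)
}
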