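# Minimal feed-forward neural networks for tabular genotype features:
# dense ReLU stacks and pre-activation residual stacks, trained by
# mini-batch Adam on the logistic loss with AUC-based early stopping on a
# held-out validation split. Written in plain matrix algebra: desk-scale
# problems (thousands of samples, a few thousand features) do not need a
# deep-learning runtime, and a self-contained implementation keeps fits
# bit-reproducible under a seed.

.relu <- function(z) z * (z > 0)

.mlpInit <- function(pIn, width, nLayers, residual, seed) {
    set.seed(seed)
    he <- function(nin, nout) matrix(stats::rnorm(nin * nout,
                                                  sd = sqrt(2 / nin)),
                                     nin, nout)
    if (!residual) {
        dims <- c(pIn, rep(width, nLayers))
        W <- lapply(seq_len(nLayers), function(l) he(dims[l], dims[l + 1]))
        b <- lapply(seq_len(nLayers), function(l) numeric(width))
    } else {
        ## layer 1 projects input to width; each block adds 2 layers
        nBlocks <- (nLayers - 1L) %/% 2L
        W <- c(list(he(pIn, width)),
               unlist(lapply(seq_len(nBlocks), function(k)
                   list(he(width, width), he(width, width))),
                   recursive = FALSE))
        b <- lapply(seq_along(W), function(l) numeric(width))
    }
    list(W = W, b = b, wOut = stats::rnorm(width, sd = sqrt(1 / width)),
         bOut = 0, residual = residual, nLayers = nLayers, width = width)
}

.mlpForward <- function(par, X, keep = FALSE) {
    if (!par$residual) {
        A <- list(X)
        for (l in seq_along(par$W))
            A[[l + 1L]] <- .relu(sweep(A[[l]] %*% par$W[[l]], 2,
                                       par$b[[l]], "+"))
        h <- A[[length(A)]]
        z <- drop(h %*% par$wOut) + par$bOut
        out <- list(p = sigmoid(z))
        if (keep) out$A <- A
    } else {
        h <- .relu(sweep(X %*% par$W[[1L]], 2, par$b[[1L]], "+"))
        cache <- list(list(h = h))
        nBlocks <- (length(par$W) - 1L) %/% 2L
        for (k in seq_len(nBlocks)) {
            iA <- 2L * k; iB <- 2L * k + 1L
            t1 <- .relu(h)
            u <- .relu(sweep(t1 %*% par$W[[iA]], 2, par$b[[iA]], "+"))
            h <- h + sweep(u %*% par$W[[iB]], 2, par$b[[iB]], "+")
            cache[[k + 1L]] <- list(h = h, t1 = t1, u = u)
        }
        t2 <- .relu(h)
        z <- drop(t2 %*% par$wOut) + par$bOut
        out <- list(p = sigmoid(z))
        if (keep) { out$cache <- cache; out$t2 <- t2 }
    }
    out
}

.mlpGrad <- function(par, X, y) {
    n <- nrow(X)
    fw <- .mlpForward(par, X, keep = TRUE)
    dz <- (fw$p - y) / n
    gW <- vector("list", length(par$W)); gb <- gW
    if (!par$residual) {
        A <- fw$A
        h <- A[[length(A)]]
        gwOut <- drop(crossprod(h, dz)); gbOut <- sum(dz)
        dA <- outer(dz, par$wOut)  # n x width
        for (l in rev(seq_along(par$W))) {
            dZ <- dA * (A[[l + 1L]] > 0)
            gW[[l]] <- crossprod(A[[l]], dZ)
            gb[[l]] <- colSums(dZ)
            if (l > 1L) dA <- dZ %*% t(par$W[[l]])
        }
    } else {
        cache <- fw$cache
        nBlocks <- length(cache) - 1L
        hFin <- cache[[nBlocks + 1L]]$h
        dT2 <- outer(dz, par$wOut)
        gwOut <- drop(crossprod(fw$t2, dz)); gbOut <- sum(dz)
        dH <- dT2 * (hFin > 0)
        for (k in rev(seq_len(nBlocks))) {
            iA <- 2L * k; iB <- 2L * k + 1L
            cc <- cache[[k + 1L]]
            gW[[iB]] <- crossprod(cc$u, dH)
            gb[[iB]] <- colSums(dH)
            dU <- dH %*% t(par$W[[iB]])
            dZA <- dU * (cc$u > 0)
            gW[[iA]] <- crossprod(cc$t1, dZA)
            gb[[iA]] <- colSums(dZA)
            dT1 <- dZA %*% t(par$W[[iA]])
            hPrev <- cache[[k]]$h
            dH <- dH + dT1 * (hPrev > 0)  # identity path + block path
        }
        dZ1 <- dH * (cache[[1L]]$h > 0)
        gW[[1L]] <- crossprod(X, dZ1)
        gb[[1L]] <- colSums(dZ1)
    }
    list(gW = gW, gb = gb, gwOut = gwOut, gbOut = gbOut)
}

# Adam on the flattened parameter list.
mlpFit <- function(X, y, nLayers = 3L, width = 64L, residual = FALSE,
                   epochs = 40L, batch = 128L, lr = 1e-3,
                   valFrac = 0.1, patience = 5L, seed = 1L) {
    stopifnot(nLayers >= 1L)
    if (residual && nLayers %% 2L == 0L)
        stop("residual networks require an odd number of hidden layers")
    set.seed(seed)
    n <- nrow(X)
    nVal <- max(2L, floor(valFrac * n))
    vi <- sample.int(n, nVal)
    Xv <- X[vi, , drop = FALSE]; yv <- y[vi]
    Xt <- X[-vi, , drop = FALSE]; yt <- y[-vi]
    if (length(unique(yv)) < 2L || length(unique(yt)) < 2L)
        stop("both classes required in train and validation splits")
    par <- .mlpInit(ncol(X), width, nLayers, residual,
                    deriveSeed(seed, "init"))
    m <- v <- NULL
    b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8; t <- 0
    best <- list(auc = -Inf, par = par, epoch = 0L)
    for (ep in seq_len(epochs)) {
        idx <- sample.int(nrow(Xt))
        starts <- seq(1L, nrow(Xt), by = batch)
        for (s in starts) {
            bi <- idx[s:min(s + batch - 1L, nrow(Xt))]
            gr <- .mlpGrad(par, Xt[bi, , drop = FALSE], yt[bi])
            flat <- c(unlist(gr$gW), unlist(gr$gb), gr$gwOut, gr$gbOut)
            if (is.null(m)) { m <- numeric(length(flat)); v <- m }
            t <- t + 1
            m <- b1 * m + (1 - b1) * flat
            v <- b2 * v + (1 - b2) * flat^2
            step <- lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + epsA)
            ## unflatten and apply
            off <- 0L
            for (l in seq_along(par$W)) {
                len <- length(par$W[[l]])
                par$W[[l]] <- par$W[[l]] - matrix(step[off + seq_len(len)],
                                                  nrow(par$W[[l]]))
                off <- off + len
            }
            for (l in seq_along(par$b)) {
                len <- length(par$b[[l]])
                par$b[[l]] <- par$b[[l]] - step[off + seq_len(len)]
                off <- off + len
            }
            len <- length(par$wOut)
            par$wOut <- par$wOut - step[off + seq_len(len)]
            par$bOut <- par$bOut - step[off + len + 1L]
        }
        aucV <- aucScore(.mlpForward(par, Xv)$p, yv)
        if (aucV > best$auc + 1e-6) {
            best <- list(auc = aucV, par = par, epoch = ep)
        } else if (ep - best$epoch >= patience) break
    }
    structure(list(par = best$par, valAUC = best$auc,
                   epochs = best$epoch), class = "snpml_mlp")
}

mlpPredict <- function(fit, X) .mlpForward(fit$par, X)$p
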