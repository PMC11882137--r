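# Internal minimal 3-D conv-net engine (im2col + GEMM kernels in src/).
# Volumes are arrays dim (X, Y, Z, C); conv weights are (27*Cin) x Cout
# matrices; everything runs on R doubles so training is deterministic given
# the seed on a single thread.

nnInitConv <- function(cin, cout) {
    # He-normal initialization for ReLU stacks
    list(W = matrix(stats::rnorm(27 * cin * cout, 0, sqrt(2 / (27 * cin))),
                    nrow = 27 * cin, ncol = cout),
         b = numeric(cout))
}

nnInitDense <- function(nin, nout) {
    list(W = matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout),
         b = numeric(nout))
}

nnConvF <- function(x, layer, stride) {
    cpp_conv3_fwd(x, dim(x), layer$W, layer$b, as.integer(stride))
}

nnConvB <- function(x, layer, gy, stride) {
    cpp_conv3_bwd(x, dim(x), layer$W, as.numeric(gy), as.integer(stride))
}

nnRelu <- function(x) {
    x[x < 0] <- 0
    x
}

nnReluB <- function(act, g) {
    g[act <= 0] <- 0
    g
}

# Numerically stable binary cross-entropy with logits; returns mean loss and
# the gradient w.r.t. the logits. `pos_weight` rescales the positive-class
# term (class-balance reweighting for sparse lesion voxels).
nnBceLogits <- function(z, y, pos_weight = 1) {
    sp <- pmax(z, 0) - z * y + log1p(exp(-abs(z))) # softplus-based per-element CE
    w <- 1 + (pos_weight - 1) * y
    loss <- mean(w * sp)
    grad <- (w * stats::plogis(z) - pos_weight * y) / length(z)
    list(loss = loss, grad = grad)
}

# Flatten/unflatten a nested parameter list for the optimizers.
nnParamNames <- function(params) {
    unlist(lapply(names(params), function(nm) paste0(nm, ".", c("W", "b"))))
}

nnZeroLike <- function(params) {
    lapply(params, function(l) list(W = l$W * 0, b = l$b * 0))
}

nnSgdStep <- function(params, grads, state, lr, momentum = 0.9, wd = 0) {
    for (nm in names(params)) {
        for (s in c("W", "b")) {
            g <- grads[[nm]][[s]]
            if (s == "W" && wd > 0) g <- g + wd * params[[nm]][[s]]
            state[[nm]][[s]] <- momentum * state[[nm]][[s]] + g
            params[[nm]][[s]] <- params[[nm]][[s]] - lr * state[[nm]][[s]]
        }
    }
    list(params = params, state = state)
}

nnAdamStep <- function(params, grads, state, lr, wd = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
    state$t <- state$t + 1
    bc1 <- 1 - beta1^state$t
    bc2 <- 1 - beta2^state$t
    for (nm in names(params)) {
        for (s in c("W", "b")) {
            g <- grads[[nm]][[s]]
            if (s == "W" && wd > 0) g <- g + wd * params[[nm]][[s]]
            state$m[[nm]][[s]] <- beta1 * state$m[[nm]][[s]] + (1 - beta1) * g
            state$v[[nm]][[s]] <- beta2 * state$v[[nm]][[s]] + (1 - beta2) * g^2
            mhat <- state$m[[nm]][[s]] / bc1
            vhat <- state$v[[nm]][[s]] / bc2
            params[[nm]][[s]] <- params[[nm]][[s]] - lr * mhat / (sqrt(vhat) + eps)
        }
    }
    list(params = params, state = state)
}

nnAddGrads <- function(a, b) {
    for (nm in names(b)) {
        a[[nm]]$W <- a[[nm]]$W + b[[nm]]$W
        a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b
    }
    a
}

# ---- U-Net (depth 3, stride-2 encoder, nearest-neighbour decoder) ----

unetInitParams <- function(base_channels) {
    c1 <- base_channels
    list(
        e1 = nnInitConv(1L, c1),       # stride 2
        e2 = nnInitConv(c1, 2L * c1),  # stride 2
        bn = nnInitConv(2L * c1, 2L * c1),
        d2 = nnInitConv(3L * c1, c1),  # after skip concat
        hd = nnInitConv(c1 + 1L, 1L)   # decoder features + full-res input skip
    )
}

unetForward <- function(params, x) {
    e1 <- nnRelu(nnConvF(x, params$e1, 2L))
    e2 <- nnRelu(nnConvF(e1, params$e2, 2L))
    bn <- nnRelu(nnConvF(e2, params$bn, 1L))
    u2 <- cpp_upsample2_fwd(bn, dim(bn))
    cat2 <- array(c(u2, e1), dim = c(dim(u2)[1:3], dim(u2)[4] + dim(e1)[4]))
    d2 <- nnRelu(nnConvF(cat2, params$d2, 1L))
    u1 <- cpp_upsample2_fwd(d2, dim(d2))
    cat1 <- array(c(u1, x), dim = c(dim(u1)[1:3], dim(u1)[4] + 1L))
    logits <- nnConvF(cat1, params$hd, 1L)
    list(x = x, e1 = e1, e2 = e2, bn = bn, u2 = u2, cat2 = cat2,
         d2 = d2, u1 = u1, cat1 = cat1, logits = logits)
}

unetBackward <- function(params, cache, gLogits) {
    bhd <- nnConvB(cache$cat1, params$hd, gLogits, 1L)
    gCat1 <- array(bhd$gx, dim = dim(cache$cat1))
    gU1full <- gCat1[, , , seq_len(dim(cache$d2)[4]), drop = FALSE]
    gU1 <- cpp_upsample2_bwd(as.numeric(gU1full), dim(cache$d2))
    gD2 <- nnReluB(cache$d2, array(gU1, dim = dim(cache$d2)))
    bd2 <- nnConvB(cache$cat2, params$d2, gD2, 1L)
    cu <- dim(cache$u2)[4]
    gCat <- array(bd2$gx, dim = dim(cache$cat2))
    gU2 <- gCat[, , , seq_len(cu), drop = FALSE]
    gE1skip <- gCat[, , , cu + seq_len(dim(cache$e1)[4]), drop = FALSE]
    gBn <- cpp_upsample2_bwd(as.numeric(gU2), dim(cache$bn))
    gBn <- nnReluB(cache$bn, array(gBn, dim = dim(cache$bn)))
    bbn <- nnConvB(cache$e2, params$bn, gBn, 1L)
    gE2 <- nnReluB(cache$e2, array(bbn$gx, dim = dim(cache$e2)))
    be2 <- nnConvB(cache$e1, params$e2, gE2, 2L)
    gE1 <- nnReluB(cache$e1, array(be2$gx, dim = dim(cache$e1)) + gE1skip)
    be1 <- nnConvB(cache$x, params$e1, gE1, 2L)
    list(
        e1 = list(W = be1$gw, b = be1$gb),
        e2 = list(W = be2$gw, b = be2$gb),
        bn = list(W = bbn$gw, b = bbn$gb),
        d2 = list(W = bd2$gw, b = bd2$gb),
        hd = list(W = bhd$gw, b = bhd$gb)
    )
}

# ---- shared-weight backbone CNN (4 inputs -> concat pooled embeddings) ----

cnnInitParams <- function(channels, feature_dim, n_outputs) {
    list(
        c1 = nnInitConv(1L, channels[1]),          # stride 2
        c2 = nnInitConv(channels[1], channels[2]), # stride 2
        c3 = nnInitConv(channels[2], feature_dim), # stride 2
        fc = nnInitDense(4L * feature_dim, n_outputs)
    )
}

# Forward one input group (single-channel volume) through the shared backbone.
cnnBackboneF <- function(params, x) {
    a1 <- nnRelu(nnConvF(x, params$c1, 2L))
    a2 <- nnRelu(nnConvF(a1, params$c2, 2L))
    a3 <- nnRelu(nnConvF(a2, params$c3, 2L))
    nvox <- prod(dim(a3)[1:3])
    emb <- colSums(matrix(a3, nrow = nvox)) / nvox # global average pool
    list(x = x, a1 = a1, a2 = a2, a3 = a3, emb = emb, nvox = nvox)
}

cnnBackboneB <- function(params, cache, gEmb) {
    d3 <- dim(cache$a3)
    gA3 <- array(rep(gEmb / cache$nvox, each = cache$nvox), dim = d3)
    gA3 <- nnReluB(cache$a3, gA3)
    b3 <- nnConvB(cache$a2, params$c3, gA3, 2L)
    gA2 <- nnReluB(cache$a2, array(b3$gx, dim = dim(cache$a2)))
    b2 <- nnConvB(cache$a1, params$c2, gA2, 2L)
    gA1 <- nnReluB(cache$a1, array(b2$gx, dim = dim(cache$a1)))
    b1 <- nnConvB(cache$x, params$c1, gA1, 2L)
    list(
        c1 = list(W = b1$gw, b = b1$gb),
        c2 = list(W = b2$gw, b = b2$gb),
        c3 = list(W = b3$gw, b = b3$gb)
    )
}

# Forward a full 4-channel subject tensor; returns caches per input group,
# the raw and normalized embeddings and the 4 logits. `bn` holds running
# mean/variance of the embedding (batch-normalization with online statistics;
# pooled lesion signals are minuscule relative to the CT channels, and the
# normalization is what puts them on the head's learning scale). Statistics
# are treated as constants in the backward pass, the standard inference-mode
# approximation.
cnnForward <- function(params, tensor, dropout_mask = NULL, bn = NULL) {
    caches <- lapply(1:4, function(ch) {
        x <- tensor[, , , ch, drop = FALSE]
        cnnBackboneF(params, x)
    })
    embRaw <- unlist(lapply(caches, `[[`, "emb"))
    emb <- if (is.null(bn)) embRaw
           else (embRaw - bn$mean) / sqrt(bn$var + 1e-5)
    if (!is.null(dropout_mask)) emb <- emb * dropout_mask
    logits <- as.numeric(emb %*% params$fc$W + params$fc$b)
    list(caches = caches, emb_raw = embRaw, emb = emb, logits = logits)
}

cnnBackward <- function(params, fwd, gLogits, dropout_mask = NULL, bn = NULL) {
    gFcW <- outer(fwd$emb, gLogits)
    gFcB <- gLogits
    gEmb <- as.numeric(params$fc$W %*% gLogits)
    if (!is.null(dropout_mask)) gEmb <- gEmb * dropout_mask
    if (!is.null(bn)) gEmb <- gEmb / sqrt(bn$var + 1e-5)
    fdim <- length(gEmb) / 4L
    grads <- NULL
    for (i in 1:4) {
        gi <- cnnBackboneB(params, fwd$caches[[i]], gEmb[(i - 1L) * fdim + seq_len(fdim)])
        grads <- if (is.null(grads)) gi else nnAddGrads(grads, gi)
    }
    c(grads, list(fc = list(W = gFcW, b = gFcB)))
}

# Exponential-moving-average update of the embedding statistics.
cnnBnUpdate <- function(bn, embRaw, momentum = 0.1) {
    if (is.null(bn$n)) bn$n <- 0L
    if (bn$n == 0L) {
        bn$mean <- embRaw
        bn$var <- rep(1, length(embRaw))
    } else {
        bn$mean <- (1 - momentum) * bn$mean + momentum * embRaw
        bn$var <- (1 - momentum) * bn$var + momentum * (embRaw - bn$mean)^2
    }
    bn$n <- bn$n + 1L
    bn
}
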