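# A minimal reverse-mode tape for the fixed network graphs used here.
# Forward helpers append op records (with the caches their backward needs)
# to the tape; tapeBackward() walks the records in reverse and accumulates
# parameter gradients. Tensors are (H, W, C, N) arrays throughout.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

tapeNew <- function(params, state, training = FALSE) {
  tp <- new.env(parent = emptyenv())
  tp$params <- params
  tp$state <- state
  tp$training <- training
  tp$vals <- list()
  tp$ops <- list()
  tp$n <- 0L
  tp
}

tapePut <- function(tp, x) {
  tp$n <- tp$n + 1L
  tp$vals[[tp$n]] <- x
  tp$n
}

tapeVal <- function(tp, id) tp$vals[[id]]

tapeRecord <- function(tp, op, inputs, out, pname = NA_character_, extra = list()) {
  tp$ops[[length(tp$ops) + 1L]] <- list(op = op, inputs = inputs, out = out,
                                        pname = pname, extra = extra)
  out
}

# per-channel sum over (H, W, N) of an (H, W, C, N) array
chSum <- function(x) {
  d <- dim(x)
  A <- array(x, c(d[1] * d[2], d[3], d[4]))
  m <- colSums(A)                      # C x N
  if (is.null(dim(m))) m else rowSums(m)
}

# broadcast a per-channel vector back to (H, W, C, N)
chExpand <- function(v, d) {
  aperm(array(v, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
}

opConv <- function(tp, xid, pname, stride, pad) {
  force(xid)
  x <- tp$vals[[xid]]
  y <- cpp_conv_fw(x, tp$params[[paste0(pname, ".w")]],
                   tp$params[[paste0(pname, ".b")]], stride, pad)
  out <- tapePut(tp, y)
  tapeRecord(tp, "conv", xid, out, pname, list(stride = stride, pad = pad))
}

opBN <- function(tp, xid, pname) {
  force(xid)
  x <- tp$vals[[xid]]
  d <- dim(x)
  gamma <- tp$params[[paste0(pname, ".gamma")]]
  beta <- tp$params[[paste0(pname, ".beta")]]
  if (tp$training) {
    M <- d[1] * d[2] * d[4]
    mu <- chSum(x) / M
    xc <- x - chExpand(mu, d)
    v <- chSum(xc * xc) / M
    invstd <- 1 / sqrt(v + BN_EPS)
    xhat <- xc * chExpand(invstd, d)
    # running statistics (biased variance, as cached for inference)
    mk <- paste0(pname, ".mean"); vk <- paste0(pname, ".var")
    tp$state[[mk]] <- (1 - BN_MOMENTUM) * tp$state[[mk]] + BN_MOMENTUM * mu
    tp$state[[vk]] <- (1 - BN_MOMENTUM) * tp$state[[vk]] + BN_MOMENTUM * v
    y <- xhat * chExpand(gamma, d) + chExpand(beta, d)
    out <- tapePut(tp, y)
    tapeRecord(tp, "bn", xid, out, pname,
               list(xhat = xhat, invstd = invstd, M = M))
  } else {
    invstd <- 1 / sqrt(tp$state[[paste0(pname, ".var")]] + BN_EPS)
    scale <- gamma * invstd
    shift <- beta - tp$state[[paste0(pname, ".mean")]] * scale
    y <- x * chExpand(scale, d) + chExpand(shift, d)
    out <- tapePut(tp, y)
    tapeRecord(tp, "bn_eval", xid, out, pname, list(scale = scale))
  }
}

opReLU <- function(tp, xid) {
  force(xid)
  y <- tp$vals[[xid]]
  y[y < 0] <- 0
  out <- tapePut(tp, y)
  tapeRecord(tp, "relu", xid, out)
}

opMaxPool <- function(tp, xid, kernel, stride, pad) {
  force(xid)
  x <- tp$vals[[xid]]
  r <- cpp_maxpool_fw(x, kernel, stride, pad)
  out <- tapePut(tp, r$y)
  tapeRecord(tp, "maxpool", xid, out,
             extra = list(argmax = r$argmax, H = dim(x)[1], W = dim(x)[2]))
}

opUpsample <- function(tp, xid, Ho, Wo) {
  force(xid)
  x <- tp$vals[[xid]]
  y <- cpp_resize_bilinear_fw(x, as.integer(Ho), as.integer(Wo))
  out <- tapePut(tp, y)
  tapeRecord(tp, "upsample", xid, out, extra = list(H = dim(x)[1], W = dim(x)[2]))
}

opConcat <- function(tp, aid, bid) {
  force(aid); force(bid)
  a <- tp$vals[[aid]]; b <- tp$vals[[bid]]
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2], da[4] == db[4])
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  out <- tapePut(tp, y)
  tapeRecord(tp, "concat", c(aid, bid), out, extra = list(ca = da[3], cb = db[3]))
}

opAdd <- function(tp, aid, bid) {
  force(aid); force(bid)
  out <- tapePut(tp, tp$vals[[aid]] + tp$vals[[bid]])
  tapeRecord(tp, "add", c(aid, bid), out)
}

# y = sum_l w[l] * x_l (all x_l same shape); pname names the weight vector
opMerge <- function(tp, xids, pname) {
  w <- tp$params[[pname]]
  stopifnot(length(w) == length(xids))
  y <- tp$vals[[xids[1]]] * w[1]
  if (length(xids) > 1)
    for (l in 2:length(xids)) y <- y + tp$vals[[xids[l]]] * w[l]
  out <- tapePut(tp, y)
  tapeRecord(tp, "merge", xids, out, pname)
}

# seeds: list mapping value id (integer) -> gradient array of the same shape.
# Returns the flat named list of parameter gradients (zero-filled entries
# omitted; missing names mean no gradient flowed there).
tapeBackward <- function(tp, seeds) {
  grads <- vector("list", tp$n)
  for (id in names(seeds)) {
    i <- as.integer(id)
    grads[[i]] <- if (is.null(grads[[i]])) seeds[[id]] else grads[[i]] + seeds[[id]]
  }
  pg <- list()
  addP <- function(name, g) {
    pg[[name]] <<- if (is.null(pg[[name]])) g else pg[[name]] + g
  }
  addV <- function(i, g) {
    grads[[i]] <<- if (is.null(grads[[i]])) g else grads[[i]] + g
  }
  for (rec in rev(tp$ops)) {
    g <- grads[[rec$out]]
    if (is.null(g)) next
    switch(rec$op,
      conv = {
        x <- tp$vals[[rec$inputs[1]]]
        w <- tp$params[[paste0(rec$pname, ".w")]]
        r <- cpp_conv_bw(x, w, g, rec$extra$stride, rec$extra$pad)
        addV(rec$inputs[1], r$dx)
        addP(paste0(rec$pname, ".w"), r$dw)
        addP(paste0(rec$pname, ".b"), as.numeric(r$db))
      },
      bn = {
        xhat <- rec$extra$xhat
        d <- dim(xhat)
        gamma <- tp$params[[paste0(rec$pname, ".gamma")]]
        M <- rec$extra$M
        dxhat <- g * chExpand(gamma, d)
        s1 <- chSum(dxhat)
        s2 <- chSum(dxhat * xhat)
        dx <- chExpand(rec$extra$invstd / M, d) *
          (M * dxhat - chExpand(s1, d) - xhat * chExpand(s2, d))
        addV(rec$inputs[1], dx)
        addP(paste0(rec$pname, ".gamma"), chSum(g * xhat))
        addP(paste0(rec$pname, ".beta"), chSum(g))
      },
      bn_eval = {
        addV(rec$inputs[1], g * chExpand(rec$extra$scale, dim(g)))
      },
      relu = {
        y <- tp$vals[[rec$out]]
        addV(rec$inputs[1], g * (y > 0))
      },
      maxpool = {
        addV(rec$inputs[1],
             cpp_maxpool_bw(g, rec$extra$argmax, rec$extra$H, rec$extra$W))
      },
      upsample = {
        addV(rec$inputs[1], cpp_resize_bilinear_bw(g, rec$extra$H, rec$extra$W))
      },
      concat = {
        ca <- rec$extra$ca; cb <- rec$extra$cb
        addV(rec$inputs[1], g[, , seq_len(ca), , drop = FALSE])
        addV(rec$inputs[2], g[, , ca + seq_len(cb), , drop = FALSE])
      },
      add = {
        addV(rec$inputs[1], g)
        addV(rec$inputs[2], g)
      },
      merge = {
        w <- tp$params[[rec$pname]]
        dw <- numeric(length(w))
        for (l in seq_along(rec$inputs)) {
          addV(rec$inputs[l], g * w[l])
          dw[l] <- sum(g * tp$vals[[rec$inputs[l]]])
        }
        addP(rec$pname, dw)
      },
      stop("unknown op: ", rec$op)
    )
    grads[rec$out] <- list(NULL)   # free as soon as consumed (keep list length)
  }
  pg
}
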