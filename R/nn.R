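# Minimal computational-graph engine for the segmenter.
#
# Feature maps are stored as C x (H*W*B) matrices, pixels column-major
# (index = h + (w-1)*H) and samples blocked, so convolutions reduce to one
# BLAS matrix product over an im2col gather. Spatial gather plans are cached
# per (H, W, kernel, stride, dilation, batch) in the network environment.

conv_out_dim <- function(n, stride) (n - 1L) %/% stride + 1L  # "same" padding

# spatial gather plan: (k*k) x (Hout*Wout) input indices, 0 marks padding
conv_plan <- function(H, W, k, stride, dilation) {
  pad <- dilation * (k - 1L) %/% 2L
  Hout <- conv_out_dim(H, stride); Wout <- conv_out_dim(W, stride)
  oh <- rep(seq_len(Hout), times = Wout)
  ow <- rep(seq_len(Wout), each = Hout)
  P <- matrix(0L, k * k, Hout * Wout)
  for (j in seq_len(k)) {
    for (i in seq_len(k)) {
      ih <- (oh - 1L) * stride - pad + (i - 1L) * dilation + 1L
      iw <- (ow - 1L) * stride - pad + (j - 1L) * dilation + 1L
      ok <- ih >= 1L & ih <= H & iw >= 1L & iw <= W
      idx <- integer(length(oh))
      idx[ok] <- ih[ok] + (iw[ok] - 1L) * H
      P[i + (j - 1L) * k, ] <- idx
    }
  }
  list(P = P, Hout = Hout, Wout = Wout, pad = pad)
}

# expand a spatial plan over a batch: per tap, column indices into
# cbind(x, 0) of size C x (H*W*B + 1); the appended zero column absorbs pads
gather_plan <- function(plan, B, H, W) {
  npix <- as.integer(H * W)
  nout <- plan$Hout * plan$Wout
  zcol <- npix * B + 1L
  taps <- nrow(plan$P)
  g <- vector("list", taps)
  for (t in seq_len(taps)) {
    base <- rep.int(plan$P[t, ], B)
    off <- rep((seq_len(B) - 1L) * npix, each = nout)
    gt <- as.integer(base + off)
    gt[base == 0L] <- zcol
    g[[t]] <- gt
  }
  list(g = g, nout = nout)
}

cached_plan <- function(net, H, W, k, stride, dilation) {
  key <- sprintf("p_%d_%d_%d_%d_%d", H, W, k, stride, dilation)
  v <- get0(key, envir = net$cache, ifnotfound = NULL)
  if (is.null(v)) {
    v <- conv_plan(H, W, k, stride, dilation)
    assign(key, v, envir = net$cache)
  }
  v
}

cached_gather <- function(net, plan, B, H, W, k, stride, dilation) {
  key <- sprintf("g_%d_%d_%d_%d_%d_%d", H, W, k, stride, dilation, B)
  v <- get0(key, envir = net$cache, ifnotfound = NULL)
  if (is.null(v)) {
    v <- gather_plan(plan, B, H, W)
    assign(key, v, envir = net$cache)
  }
  v
}

im2col <- function(x, C, k, gp) {
  ws_im2col(x, gp$g, C)
}

col2im <- function(dcols, C, k, gp, ncols_x) {
  ws_col2im(dcols, gp$g, C, as.integer(ncols_x))
}

# bilinear interpolation matrix (half-pixel centers) for integer upscaling
upsample_matrix <- function(n_in, factor) {
  n_out <- n_in * factor
  src <- (seq_len(n_out) - 0.5) / factor - 0.5
  i0 <- floor(src)
  w1 <- src - i0
  i0c <- pmin(pmax(i0, 0), n_in - 1)
  i1c <- pmin(pmax(i0 + 1, 0), n_in - 1)
  Wm <- matrix(0, n_out, n_in)
  for (r in seq_len(n_out)) {
    Wm[r, i0c[r] + 1] <- Wm[r, i0c[r] + 1] + (1 - w1[r])
    Wm[r, i1c[r] + 1] <- Wm[r, i1c[r] + 1] + w1[r]
  }
  Wm
}

cached_upsample <- function(net, n_in, factor, prefix) {
  key <- sprintf("u_%s_%d_%d", prefix, n_in, factor)
  v <- get0(key, envir = net$cache, ifnotfound = NULL)
  if (is.null(v)) {
    v <- upsample_matrix(n_in, factor)
    assign(key, v, envir = net$cache)
  }
  v
}

# apply M (n_out x n_dim) along one spatial axis of x (C x H*W*B)
# axis 1 = rows (H), axis 2 = cols (W)
apply_axis <- function(x, C, H, W, B, M, axis) {
  n_out <- nrow(M)
  if (axis == 1) {
    # columns of x are (h fastest); reshape to H x (W*B*C)
    A <- matrix(t(x), H, W * B * C)   # t(x): (H*W*B) x C column-major
    Y <- M %*% A                      # n_out x (W*B*C)
    out <- t(matrix(Y, n_out * W * B, C))
    list(x = out, H = n_out)
  } else {
    # bring W to the front: array (H, W, B*C) -> aperm
    A <- array(t(x), c(H, W, B * C))
    A <- matrix(aperm(A, c(2, 1, 3)), W, H * B * C)
    Y <- M %*% A                      # n_out x (H*B*C)
    out <- aperm(array(Y, c(n_out, H, B * C)), c(2, 1, 3))
    list(x = t(matrix(out, H * n_out * B, C)), W = n_out)
  }
}

upsample_forward <- function(net, v, factor, prefix) {
  Wr <- cached_upsample(net, v$H, factor, paste0(prefix, "r"))
  Wc <- cached_upsample(net, v$W, factor, paste0(prefix, "c"))
  C <- nrow(v$x)
  s1 <- apply_axis(v$x, C, v$H, v$W, v$B, Wr, 1)
  s2 <- apply_axis(s1$x, C, s1$H, v$W, v$B, Wc, 2)
  list(x = s2$x, H = s1$H, W = s2$W, B = v$B)
}

upsample_backward <- function(net, dv, in_H, in_W, factor, prefix) {
  Wr <- cached_upsample(net, in_H, factor, paste0(prefix, "r"))
  Wc <- cached_upsample(net, in_W, factor, paste0(prefix, "c"))
  C <- nrow(dv$x)
  s1 <- apply_axis(dv$x, C, dv$H, dv$W, dv$B, t(Wc), 2)
  s2 <- apply_axis(s1$x, C, dv$H, s1$W, dv$B, t(Wr), 1)
  list(x = s2$x, H = s2$H, W = s1$W, B = dv$B)
}

## ---- network construction -------------------------------------------------

nn_new <- function(seed) {
  net <- new.env(parent = emptyenv())
  net$ops <- list()
  net$params <- list()
  net$state <- list()
  net$cache <- new.env(parent = emptyenv())
  net$seed <- as.integer(seed)
  net
}

add_op <- function(net, type, inp = integer(0), ...) {
  force(inp)   # nested constructors must register before this op takes an id
  id <- length(net$ops) + 1L
  net$ops[[id]] <- c(list(id = id, type = type, inp = inp), list(...))
  id
}

he_init <- function(fan_in, n) {
  stats::rnorm(n, 0, sqrt(2 / fan_in))
}

add_conv <- function(net, inp, cin, cout, k = 3, stride = 1, dilation = 1,
                     name) {
  wname <- paste0(name, ".W"); bname <- paste0(name, ".b")
  net$params[[wname]] <- matrix(he_init(cin * k * k, cout * cin * k * k),
                                cout, cin * k * k)
  net$params[[bname]] <- numeric(cout)
  add_op(net, "conv", inp, k = k, stride = stride, dilation = dilation,
         cin = cin, cout = cout, W = wname, b = bname)
}

add_bn <- function(net, inp, ch, name) {
  gname <- paste0(name, ".g"); bname <- paste0(name, ".be")
  net$params[[gname]] <- rep(1, ch)
  net$params[[bname]] <- numeric(ch)
  net$state[[paste0(name, ".rm")]] <- numeric(ch)
  net$state[[paste0(name, ".rv")]] <- rep(1, ch)
  net$state[[paste0(name, ".ini")]] <- FALSE
  add_op(net, "bn", inp, ch = ch, g = gname, be = bname,
         rm = paste0(name, ".rm"), rv = paste0(name, ".rv"),
         ini = paste0(name, ".ini"))
}

add_relu <- function(net, inp) add_op(net, "relu", inp)
add_add <- function(net, a, b) add_op(net, "add", c(a, b))
add_concat <- function(net, ids) add_op(net, "concat", ids)
add_gpool <- function(net, inp) add_op(net, "gpool", inp)
add_broadcast <- function(net, small, ref) add_op(net, "broadcast",
                                                  c(small, ref))
add_upsample <- function(net, inp, factor, name) {
  add_op(net, "upsample", inp, factor = factor, name = name)
}

# conv + batchnorm + relu
add_cbr <- function(net, inp, cin, cout, k = 3, stride = 1, dilation = 1,
                    name) {
  c1 <- add_conv(net, inp, cin, cout, k, stride, dilation, name)
  b1 <- add_bn(net, c1, cout, paste0(name, ".bn"))
  add_relu(net, b1)
}

## ---- forward / backward ---------------------------------------------------

avg_matrix <- function(net, npix, B) {
  key <- sprintf("avg_%d_%d", npix, B)
  v <- get0(key, envir = net$cache, ifnotfound = NULL)
  if (is.null(v)) {
    v <- matrix(0, npix * B, B)
    v[cbind(seq_len(npix * B), rep(seq_len(B), each = npix))] <- 1 / npix
    assign(key, v, envir = net$cache)
  }
  v
}

nn_forward <- function(net, x_val, train = FALSE, momentum = 0.1) {
  vals <- vector("list", length(net$ops))
  caches <- vector("list", length(net$ops))
  for (op in net$ops) {
    v <- switch(op$type,
      input = x_val,
      conv = {
        inv <- vals[[op$inp]]
        if (op$k == 1L && op$stride == 1L) {
          # pointwise convolution: plain matrix product, no gather
          y <- net$params[[op$W]] %*% inv$x + net$params[[op$b]]
          caches[[op$id]] <- list(pointwise = TRUE,
                                  in_dims = c(inv$H, inv$W, inv$B))
          list(x = y, H = inv$H, W = inv$W, B = inv$B)
        } else {
          plan <- cached_plan(net, inv$H, inv$W, op$k, op$stride, op$dilation)
          gp <- cached_gather(net, plan, inv$B, inv$H, inv$W, op$k, op$stride,
                              op$dilation)
          cols <- im2col(inv$x, op$cin, op$k, gp)
          y <- net$params[[op$W]] %*% cols + net$params[[op$b]]
          caches[[op$id]] <- list(cols = cols, gp = gp,
                                  in_dims = c(inv$H, inv$W, inv$B),
                                  ncols_x = ncol(inv$x))
          list(x = y, H = plan$Hout, W = plan$Wout, B = inv$B)
        }
      },
      bn = {
        inv <- vals[[op$inp]]
        x <- inv$x
        if (train) {
          mu <- rowMeans(x)
          va <- rowMeans(x * x) - mu * mu
          # the first update seeds the running stats with the batch stats
          mom <- if (isTRUE(net$state[[op$ini]])) momentum else 1
          net$state[[op$rm]] <- (1 - mom) * net$state[[op$rm]] + mom * mu
          net$state[[op$rv]] <- (1 - mom) * net$state[[op$rv]] + mom * va
          net$state[[op$ini]] <- TRUE
        } else {
          mu <- net$state[[op$rm]]
          va <- net$state[[op$rv]]
        }
        ivstd <- 1 / sqrt(va + 1e-5)
        xhat <- (x - mu) * ivstd
        y <- xhat * net$params[[op$g]] + net$params[[op$be]]
        caches[[op$id]] <- list(xhat = xhat, ivstd = ivstd)
        list(x = y, H = inv$H, W = inv$W, B = inv$B)
      },
      relu = {
        inv <- vals[[op$inp]]
        y <- inv$x
        neg <- y < 0
        y[neg] <- 0
        caches[[op$id]] <- list(neg = neg)
        list(x = y, H = inv$H, W = inv$W, B = inv$B)
      },
      add = {
        a <- vals[[op$inp[1]]]; b <- vals[[op$inp[2]]]
        list(x = a$x + b$x, H = a$H, W = a$W, B = a$B)
      },
      concat = {
        parts <- vals[op$inp]
        list(x = do.call(rbind, lapply(parts, `[[`, "x")),
             H = parts[[1]]$H, W = parts[[1]]$W, B = parts[[1]]$B)
      },
      gpool = {
        inv <- vals[[op$inp]]
        S <- avg_matrix(net, inv$H * inv$W, inv$B)
        caches[[op$id]] <- list(dims = c(inv$H, inv$W, inv$B))
        list(x = inv$x %*% S, H = 1L, W = 1L, B = inv$B)
      },
      broadcast = {
        sm <- vals[[op$inp[1]]]; ref <- vals[[op$inp[2]]]
        npix <- ref$H * ref$W
        caches[[op$id]] <- list(npix = npix)
        list(x = sm$x[, rep(seq_len(ref$B), each = npix), drop = FALSE],
             H = ref$H, W = ref$W, B = ref$B)
      },
      upsample = {
        inv <- vals[[op$inp]]
        caches[[op$id]] <- list(in_H = inv$H, in_W = inv$W)
        upsample_forward(net, inv, op$factor, op$name)
      },
      stop(sprintf("unknown op type %s", op$type)))
    vals[[op$id]] <- v
  }
  list(vals = vals, caches = caches)
}

nn_backward <- function(net, fw, dout) {
  nops <- length(net$ops)
  dvals <- vector("list", nops)
  dvals[[nops]] <- dout
  grads <- list()
  addg <- function(name, g) {
    grads[[name]] <<- if (is.null(grads[[name]])) g else grads[[name]] + g
  }
  addv <- function(id, d) {
    dvals[[id]] <<- if (is.null(dvals[[id]])) d else {
      d2 <- dvals[[id]]; d2$x <- d2$x + d$x; d2
    }
  }
  for (op in rev(net$ops)) {
    d <- dvals[[op$id]]
    if (is.null(d)) next
    switch(op$type,
      input = NULL,
      conv = {
        ca <- fw$caches[[op$id]]
        if (isTRUE(ca$pointwise)) {
          addg(op$W, tcrossprod(d$x, fw$vals[[op$inp]]$x))
          addg(op$b, rowSums(d$x))
          dx <- crossprod(net$params[[op$W]], d$x)
        } else {
          addg(op$W, tcrossprod(d$x, ca$cols))
          addg(op$b, rowSums(d$x))
          dcols <- crossprod(net$params[[op$W]], d$x)
          dx <- col2im(dcols, op$cin, op$k, ca$gp, ca$ncols_x)
        }
        addv(op$inp, list(x = dx, H = ca$in_dims[1], W = ca$in_dims[2],
                          B = ca$in_dims[3]))
      },
      bn = {
        ca <- fw$caches[[op$id]]
        N <- ncol(d$x)
        addg(op$g, rowSums(d$x * ca$xhat))
        addg(op$be, rowSums(d$x))
        dxhat <- d$x * net$params[[op$g]]
        s1 <- rowSums(dxhat)
        s2 <- rowSums(dxhat * ca$xhat)
        dx <- (ca$ivstd / N) * (N * dxhat - s1 - ca$xhat * s2)
        addv(op$inp, list(x = dx, H = d$H, W = d$W, B = d$B))
      },
      relu = {
        ca <- fw$caches[[op$id]]
        dx <- d$x
        dx[ca$neg] <- 0
        addv(op$inp, list(x = dx, H = d$H, W = d$W, B = d$B))
      },
      add = {
        addv(op$inp[1], d)
        addv(op$inp[2], d)
      },
      concat = {
        r0 <- 0L
        for (iid in op$inp) {
          ch <- nrow(fw$vals[[iid]]$x)
          addv(iid, list(x = d$x[(r0 + 1L):(r0 + ch), , drop = FALSE],
                         H = d$H, W = d$W, B = d$B))
          r0 <- r0 + ch
        }
      },
      gpool = {
        ca <- fw$caches[[op$id]]
        S <- avg_matrix(net, ca$dims[1] * ca$dims[2], ca$dims[3])
        addv(op$inp, list(x = tcrossprod(d$x, S), H = ca$dims[1],
                          W = ca$dims[2], B = ca$dims[3]))
      },
      broadcast = {
        ca <- fw$caches[[op$id]]
        inv <- fw$vals[[op$inp[1]]]
        S <- avg_matrix(net, ca$npix, d$B) * ca$npix
        addv(op$inp[1], list(x = d$x %*% S, H = 1L, W = 1L, B = d$B))
      },
      upsample = {
        ca <- fw$caches[[op$id]]
        addv(op$inp, c(upsample_backward(net, d, ca$in_H, ca$in_W,
                                         op$factor, op$name)[1],
                       list(H = ca$in_H, W = ca$in_W, B = d$B)))
      })
  }
  grads
}

## ---- loss and optimizer ---------------------------------------------------

col_max <- function(m) {
  mx <- m[1, ]
  for (r in seq_len(nrow(m))[-1]) mx <- pmax(mx, m[r, ])
  mx
}

softmax_probs <- function(logits) {
  C <- nrow(logits)
  ex <- exp(logits - rep(col_max(logits), each = C))
  ex / rep(colSums(ex), each = C)
}

# per-pixel softmax cross-entropy; labels are 0-based integers
softmax_ce <- function(logits, labels) {
  p <- softmax_probs(logits)
  N <- ncol(logits)
  sel <- cbind(labels + 1L, seq_len(N))
  loss <- -mean(log(pmax(p[sel], 1e-12)))
  dlogits <- p
  dlogits[sel] <- dlogits[sel] - 1
  list(loss = loss, dlogits = dlogits / N, probs = p)
}

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(opt = opt, params = params)
}
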