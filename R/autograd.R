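# Minimal reverse-mode differentiation engine.
#
# Image batches are numeric arrays of dim (H, W, N, C).  A tape records
# operation nodes in creation order; backward() replays them in reverse.
# Nodes and parameters are environments so gradients accumulate in place.
# Parameters persist across tapes (they are leaves with optimizer state);
# nodes live only as long as their tape.

tapeNew <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 64L)
  e$n <- 0L
  e
}

agParam <- function(val) {
  p <- new.env(parent = emptyenv())
  p$val <- val
  p$grad <- NULL
  # zero-length so the optimizer always allocates fresh buffers on first use
  # (its updates are in place and must never touch a shared constant)
  p$m <- numeric(0); p$v <- numeric(0); p$t <- 0L
  class(p) <- "agParam"
  p
}

agNode <- function(tape, val, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$backward <- backward
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[tape$n]] <- nd
  }
  class(nd) <- "agNode"
  nd
}

agLeaf <- function(tape, val) agNode(tape, val, backward = NULL)

agAccum <- function(x, g) {
  if (is.null(x$grad)) x$grad <- g else x$grad <- x$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar node; seed is the loss-scaling factor.
agBackward <- function(tape, node, seed = 1) {
  node$grad <- seed
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

agValue <- function(x) if (inherits(x, "agNode") || inherits(x, "agParam")) x$val else x

# ---- convolution ----------------------------------------------------------

convOutSide <- function(s, k, stride, pad) (s + 2L * pad - k) %/% stride + 1L

# w: agParam with val of dim (k, k, Cin, Cout); b: agParam of length Cout or
# NULL.  Optional spectral normalization divides the kernel by a power-
# iteration estimate of its largest singular value (persistent u vector on
# the parameter; updated only when updateU, so evaluation stays stateless).
agConv2d <- function(tape, x, w, b = NULL, stride = 1L, pad = 0L,
                     spectral = FALSE, nPower = 1L, updateU = TRUE) {
  xv <- agValue(x)
  d <- dim(xv)
  wd <- dim(w$val)
  k <- wd[1]; Cin <- wd[3]; Cout <- wd[4]
  if (d[4] != Cin)
    stop(sprintf("input has %d channels but the convolution expects %d", d[4], Cin))
  Wmat <- matrix(w$val, ncol = Cout)
  sn <- NULL
  if (spectral) {
    sn <- snNormalize(Wmat, w, nPower = nPower, updateU = updateU)
    Wmat <- sn$Wbar
  }
  Ho <- convOutSide(d[1], k, stride, pad); Wo <- convOutSide(d[2], k, stride, pad)
  cols <- .im2col(xv, d[1], d[2], d[3], Cin, k, stride, pad)
  out <- crossprod(cols, Wmat)
  if (!is.null(b) && any(b$val != 0))
    out <- out + rep(b$val, each = nrow(out))
  dim(out) <- c(Ho, Wo, d[3], Cout)
  node <- agNode(tape, out, backward = function(g) {
    gm <- g
    dim(gm) <- c(length(g) %/% Cout, Cout)
    dWbar <- cols %*% gm
    if (!is.null(b)) agAccum(b, colSums(gm))
    dW <- if (spectral) snBackward(dWbar, sn) else dWbar
    dim(dW) <- wd
    agAccum(w, dW)
    if (inherits(x, "agNode")) {
      dcols <- tcrossprod(Wmat, gm)
      agAccum(x, .col2im(dcols, d[1], d[2], d[3], Cin, k, stride, pad))
    }
  })
  node
}

# Transposed convolution; w of dim (k, k, Cout, Cin) so that the op is the
# exact adjoint of agConv2d with the same stride/pad.
agConvT2d <- function(tape, x, w, b = NULL, stride = 2L, pad = 1L) {
  xv <- agValue(x)
  d <- dim(xv)
  wd <- dim(w$val)
  k <- wd[1]; Cout <- wd[3]; Cin <- wd[4]
  if (d[4] != Cin)
    stop(sprintf("input has %d channels but the transposed convolution expects %d",
                 d[4], Cin))
  Ho <- (d[1] - 1L) * stride - 2L * pad + k
  Wo <- (d[2] - 1L) * stride - 2L * pad + k
  Wmat <- matrix(w$val, ncol = Cin)             # (k*k*Cout) x Cin
  xmat <- xv
  dim(xmat) <- c(length(xv) %/% Cin, Cin)       # (Hi*Wi*N) x Cin
  cols <- tcrossprod(Wmat, xmat)                # (k*k*Cout) x (Hi*Wi*N)
  outv <- .col2im(cols, Ho, Wo, d[3], Cout, k, stride, pad)
  if (!is.null(b) && any(b$val != 0)) {
    dim(outv) <- NULL
    outv <- outv + rep(b$val, each = Ho * Wo * d[3])
    dim(outv) <- c(Ho, Wo, d[3], Cout)
  }
  agNode(tape, outv, backward = function(g) {
    gcols <- .im2col(g, Ho, Wo, d[3], Cout, k, stride, pad)
    dW <- gcols %*% xmat
    dim(dW) <- wd
    agAccum(w, dW)
    if (!is.null(b)) {
      gb <- g
      dim(gb) <- c(length(g) %/% Cout, Cout)
      agAccum(b, colSums(gb))
    }
    if (inherits(x, "agNode")) {
      dx <- crossprod(gcols, Wmat)
      dim(dx) <- d
      agAccum(x, dx)
    }
  })
}

# ---- spectral normalization helpers ---------------------------------------

snNormalize <- function(Wmat, w, nPower = 1L, updateU = TRUE) {
  Cout <- ncol(Wmat)
  u <- w$u
  if (is.null(u)) u <- withr::with_seed(771L, rnorm(Cout))
  u <- u / sqrt(sum(u^2))
  v <- NULL
  for (i in seq_len(nPower)) {
    v <- Wmat %*% u
    v <- v / sqrt(sum(v^2) + 1e-12)
    u <- crossprod(Wmat, v)
    u <- u / sqrt(sum(u^2) + 1e-12)
  }
  sigma <- as.numeric(crossprod(v, Wmat %*% u))
  if (!is.finite(sigma) || sigma <= 1e-12) sigma <- 1
  if (updateU) w$u <- as.numeric(u)
  list(Wbar = Wmat / sigma, sigma = sigma, u = as.numeric(u), v = as.numeric(v))
}

snBackward <- function(dWbar, sn) {
  inner <- sum(dWbar * sn$Wbar)
  dWbar / sn$sigma - (inner / sn$sigma) * (sn$v %o% sn$u)
}

# ---- normalization and pointwise ops --------------------------------------

agInstanceNorm <- function(tape, x, eps = 1e-5) {
  xv <- agValue(x)
  d <- dim(xv)
  HW <- d[1] * d[2]; NC <- d[3] * d[4]
  m <- xv
  dim(m) <- c(HW, NC)
  mu <- .colMeans(m, HW, NC)
  xc <- m - rep(mu, each = HW)
  sd <- sqrt(.colMeans(xc * xc, HW, NC) + eps)
  xhat <- xc / rep(sd, each = HW)
  y <- xhat
  dim(y) <- d
  agNode(tape, y, backward = function(g) {
    if (!inherits(x, "agNode")) return(invisible(NULL))
    gm <- g
    dim(gm) <- c(HW, NC)
    t1 <- .colMeans(gm, HW, NC)
    t2 <- .colMeans(gm * xhat, HW, NC)
    dx <- (gm - rep(t1, each = HW) - xhat * rep(t2, each = HW)) /
      rep(sd, each = HW)
    dim(dx) <- d
    agAccum(x, dx)
  })
}

agLeakyRelu <- function(tape, x, slope = 0.2) {
  xv <- agValue(x)
  fac <- (xv > 0) + slope * (xv <= 0)
  agNode(tape, xv * fac, backward = function(g) {
    if (inherits(x, "agNode")) agAccum(x, g * fac)
  })
}

agRelu <- function(tape, x) agLeakyRelu(tape, x, slope = 0)

agTanh <- function(tape, x) {
  y <- tanh(agValue(x))
  agNode(tape, y, backward = function(g) {
    if (inherits(x, "agNode")) agAccum(x, g * (1 - y^2))
  })
}

agDropout <- function(tape, x, rate, train = TRUE) {
  xv <- agValue(x)
  if (!train || rate <= 0) {
    return(agNode(tape, xv, backward = function(g) {
      if (inherits(x, "agNode")) agAccum(x, g)
    }))
  }
  mask <- array((runif(length(xv)) >= rate) / (1 - rate), dim(xv))
  agNode(tape, xv * mask, backward = function(g) {
    if (inherits(x, "agNode")) agAccum(x, g * mask)
  })
}

agConcatChannels <- function(tape, x, y) {
  xv <- agValue(x); yv <- agValue(y)
  d <- dim(xv)
  cx <- d[4]; cy <- dim(yv)[4]
  agNode(tape, array(c(xv, yv), c(d[1], d[2], d[3], cx + cy)),
         backward = function(g) {
    nx <- length(xv)
    if (inherits(x, "agNode")) agAccum(x, array(g[seq_len(nx)], d))
    if (inherits(y, "agNode"))
      agAccum(y, array(g[-seq_len(nx)], c(d[1], d[2], d[3], cy)))
  })
}

# Unit-normalize the channel vector at every spatial location (LPIPS style).
agChannelNormalize <- function(tape, x, eps = 1e-10) {
  xv <- agValue(x)
  d <- dim(xv)
  m <- matrix(xv, prod(d[1:3]), d[4])
  nrm <- sqrt(rowSums(m^2) + eps)
  y <- m / nrm
  agNode(tape, array(y, d), backward = function(g) {
    if (!inherits(x, "agNode")) return(invisible(NULL))
    gm <- matrix(g, prod(d[1:3]), d[4])
    dx <- gm / nrm - y * (rowSums(gm * y) / nrm)
    agAccum(x, array(dx, d))
  })
}

# ---- scalar reductions ----------------------------------------------------

agMeanAbsDiff <- function(tape, x, y) {
  xv <- agValue(x); yv <- agValue(y)
  diff <- xv - yv
  n <- length(diff)
  agNode(tape, mean(abs(diff)), backward = function(g) {
    s <- g * sign(diff) / n
    if (inherits(x, "agNode")) agAccum(x, s)
    if (inherits(y, "agNode")) agAccum(y, -s)
  })
}

agMseToConst <- function(tape, x, target) {
  xv <- agValue(x)
  diff <- xv - target
  n <- length(diff)
  agNode(tape, mean(diff^2), backward = function(g) {
    if (inherits(x, "agNode")) agAccum(x, g * 2 * diff / n)
  })
}

# Squared-difference distance of one feature stage: w * sum((a-b)^2) spread
# over spatial locations and batch (mean over H, W, N; sum over channels).
agStageDistance <- function(tape, a, b, wgt = 1) {
  av <- agValue(a); bv <- agValue(b)
  d <- dim(av)
  scale <- wgt / prod(d[1:3])
  diff <- av - bv
  agNode(tape, scale * sum(diff^2), backward = function(g) {
    s <- g * scale * 2 * diff
    if (inherits(a, "agNode")) agAccum(a, s)
    if (inherits(b, "agNode")) agAccum(b, -s)
  })
}

# Weighted sum of scalar nodes.
agWeightedSum <- function(tape, nodes, weights = rep(1, length(nodes))) {
  vals <- vapply(nodes, agValue, numeric(1))
  agNode(tape, sum(vals * weights), backward = function(g) {
    for (i in seq_along(nodes))
      if (inherits(nodes[[i]], "agNode")) agAccum(nodes[[i]], g * weights[i])
  })
}

# ---- optimizer ------------------------------------------------------------

adamStep <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     gradScale = 1) {
  for (p in params) {
    if (is.null(p$grad)) next
    if (length(p$m) != length(p$val)) {
      p$m <- numeric(length(p$val))
      p$v <- numeric(length(p$val))
    }
    p$t <- p$t + 1L
    .adamUpdate(p$val, p$grad, p$m, p$v, p$t, lr, beta1, beta2, eps, gradScale)
  }
  invisible(NULL)
}

zeroGrads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
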