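# Compact modular CNN engine. A "module" is a list with $params (nested
# named lists of numeric arrays), $fw(params, x, train) -> list(y, cache)
# and $bw(params, cache, dy) -> list(dx, grads); grads mirrors params.
# Feature maps are H x W x C arrays; gradients are exact (the whole engine
# is finite-difference checked in the test suite).

as_map <- function(x) {
  if (length(dim(x)) == 3L) x else array(x, c(dim(x), 1L))
}

nn_conv <- function(k, cin, cout, stride = 1L, pad = NULL,
                    init_sd = NULL) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  if (is.null(init_sd)) init_sd <- sqrt(2 / (k * k * cin))
  params <- list(
    W = matrix(stats::rnorm(k * k * cin * cout, sd = init_sd),
               k * k * cin, cout),
    b = numeric(cout))
  list(
    params = params,
    fw = function(p, x, train = FALSE) {
      list(y = cpp_conv2d_fw(x, p$W, p$b, k, stride, pad),
           cache = list(x = x))
    },
    bw = function(p, cache, dy) {
      g <- cpp_conv2d_bw(cache$x, p$W, dy, k, stride, pad)
      list(dx = g$dx, grads = list(W = g$dW, b = as.numeric(g$db)))
    })
}

nn_inorm <- function(c, eps = 1e-5) {
  list(
    params = list(gamma = rep(1, c), beta = numeric(c)),
    fw = function(p, x, train = FALSE) {
      d <- dim(x)
      n <- d[1] * d[2]
      m <- matrix(x, n, d[3])
      mu <- colMeans(m)
      v <- colMeans(m * m) - mu * mu
      istd <- 1 / sqrt(v + eps)
      xhat <- (m - rep(mu, each = n)) * rep(istd, each = n)
      y <- xhat * rep(p$gamma, each = n) + rep(p$beta, each = n)
      list(y = array(y, d), cache = list(xhat = xhat, istd = istd, d = d))
    },
    bw = function(p, cache, dy) {
      d <- cache$d
      n <- d[1] * d[2]
      dym <- matrix(dy, n, d[3])
      xhat <- cache$xhat
      dgamma <- colSums(dym * xhat)
      dbeta <- colSums(dym)
      dxhat <- dym * rep(p$gamma, each = n)
      dx <- (dxhat - rep(colMeans(dxhat), each = n) -
               xhat * rep(colMeans(dxhat * xhat), each = n)) *
        rep(cache$istd, each = n)
      list(dx = array(dx, d), grads = list(gamma = dgamma, beta = dbeta))
    })
}

nn_relu <- function() {
  list(
    params = list(),
    fw = function(p, x, train = FALSE) {
      y <- pmax(x, 0)
      list(y = y, cache = list(pos = x > 0, d = dim(x)))
    },
    bw = function(p, cache, dy) {
      list(dx = array(dy * cache$pos, cache$d), grads = list())
    })
}

nn_maxpool <- function() {
  list(
    params = list(),
    fw = function(p, x, train = FALSE) {
      r <- cpp_maxpool2_fw(x)
      list(y = r$y, cache = list(idx = r$idx, H = dim(x)[1], W = dim(x)[2]))
    },
    bw = function(p, cache, dy) {
      list(dx = cpp_maxpool2_bw(dy, cache$idx, cache$H, cache$W),
           grads = list())
    })
}

nn_upsample <- function() {
  list(
    params = list(),
    fw = function(p, x, train = FALSE) {
      list(y = cpp_upsample2_fw(x), cache = NULL)
    },
    bw = function(p, cache, dy) {
      list(dx = cpp_upsample2_bw(dy), grads = list())
    })
}

nn_sigmoid <- function(z) 1 / (1 + exp(-z))

# Spatial and channel squeeze-and-excitation: the channel branch gates
# each channel by a two-layer bottleneck on globally pooled features; the
# spatial branch gates each pixel by a sigmoid 1x1 convolution; outputs
# are summed.
nn_scse <- function(c, reduction = 2L) {
  cr <- max(1L, c %/% reduction)
  params <- list(
    Wc1 = matrix(stats::rnorm(c * cr, sd = sqrt(2 / c)), cr, c),
    bc1 = numeric(cr),
    Wc2 = matrix(stats::rnorm(cr * c, sd = sqrt(2 / cr)), c, cr),
    bc2 = numeric(c),
    Ws = matrix(stats::rnorm(c, sd = sqrt(1 / c)), c, 1),
    bs = 0)
  list(
    params = params,
    fw = function(p, x, train = FALSE) {
      d <- dim(x)
      n <- d[1] * d[2]
      m <- matrix(x, n, d[3])
      z <- colMeans(m)                       # C
      h1 <- pmax(as.numeric(p$Wc1 %*% z + p$bc1), 0)
      s <- nn_sigmoid(as.numeric(p$Wc2 %*% h1 + p$bc2))  # channel gate
      q <- as.numeric(m %*% p$Ws) + p$bs     # H*W spatial logit
      t <- nn_sigmoid(q)                     # spatial gate
      y <- m * rep(s, each = n) + m * t
      list(y = array(y, d),
           cache = list(m = m, z = z, h1 = h1, s = s, t = t, d = d))
    },
    bw = function(p, cache, dy) {
      d <- cache$d
      n <- d[1] * d[2]
      dym <- matrix(dy, n, d[3])
      m <- cache$m
      # channel branch
      dm <- dym * rep(cache$s, each = n)
      ds <- colSums(dym * m)
      dz2 <- ds * cache$s * (1 - cache$s)
      dh1 <- as.numeric(t(p$Wc2) %*% dz2) * (cache$h1 > 0)
      dz <- as.numeric(t(p$Wc1) %*% dh1)
      dm <- dm + matrix(dz / n, n, d[3], byrow = TRUE)
      # spatial branch
      dm <- dm + dym * cache$t
      dt <- rowSums(dym * m)
      dq <- dt * cache$t * (1 - cache$t)
      dm <- dm + dq %*% t(p$Ws)
      grads <- list(
        Wc1 = outer(dh1, cache$z),
        bc1 = dh1,
        Wc2 = outer(dz2, cache$h1),
        bc2 = dz2,
        Ws = matrix(as.numeric(t(m) %*% dq), ncol = 1),
        bs = sum(dq))
      list(dx = array(dm, d), grads = grads)
    })
}

nn_seq <- function(mods) {
  list(
    params = lapply(mods, `[[`, "params"),
    mods = mods,
    fw = function(p, x, train = FALSE) {
      caches <- vector("list", length(mods))
      for (i in seq_along(mods)) {
        r <- mods[[i]]$fw(p[[i]], x, train)
        x <- r$y
        caches[[i]] <- r$cache
      }
      list(y = x, cache = caches)
    },
    bw = function(p, cache, dy) {
      grads <- vector("list", length(mods))
      for (i in rev(seq_along(mods))) {
        r <- mods[[i]]$bw(p[[i]], cache[[i]], dy)
        dy <- r$dx
        grads[[i]] <- r$grads
      }
      list(dx = dy, grads = grads)
    })
}

# conv -> instance norm -> relu
nn_cir <- function(k, cin, cout, stride = 1L) {
  nn_seq(list(nn_conv(k, cin, cout, stride), nn_inorm(cout), nn_relu()))
}

# Residual block: conv-IN-relu-conv-IN plus (projected) skip, relu, then
# optional SCse attention.
nn_resblock <- function(cin, cout, stride = 1L, attention = TRUE) {
  main <- nn_seq(list(nn_conv(3L, cin, cout, stride), nn_inorm(cout),
                      nn_relu(), nn_conv(3L, cout, cout), nn_inorm(cout)))
  project <- (cin != cout) || (stride != 1L)
  skip <- if (project) {
    nn_seq(list(nn_conv(1L, cin, cout, stride), nn_inorm(cout)))
  } else NULL
  relu <- nn_relu()
  att <- if (attention) nn_scse(cout) else NULL
  params <- list(main = main$params)
  if (project) params$skip <- skip$params
  if (attention) params$att <- att$params
  list(
    params = params,
    fw = function(p, x, train = FALSE) {
      rm_ <- main$fw(p$main, x, train)
      if (project) {
        rs <- skip$fw(p$skip, x, train)
        sum_ <- rm_$y + rs$y
        skip_cache <- rs$cache
      } else {
        sum_ <- rm_$y + x
        skip_cache <- NULL
      }
      rr <- relu$fw(list(), sum_, train)
      cache <- list(main = rm_$cache, skip = skip_cache, relu = rr$cache)
      y <- rr$y
      if (attention) {
        ra <- att$fw(p$att, y, train)
        y <- ra$y
        cache$att <- ra$cache
      }
      list(y = y, cache = cache)
    },
    bw = function(p, cache, dy) {
      grads <- list()
      if (attention) {
        ra <- att$bw(p$att, cache$att, dy)
        dy <- ra$dx
        grads$att <- ra$grads
      }
      dr <- relu$bw(list(), cache$relu, dy)$dx
      rm_ <- main$bw(p$main, cache$main, dr)
      grads$main <- rm_$grads
      if (project) {
        rs <- skip$bw(p$skip, cache$skip, dr)
        grads$skip <- rs$grads
        dx <- rm_$dx + rs$dx
      } else {
        dx <- rm_$dx + dr
      }
      # reorder to match params order (main, skip, att)
      g <- list(main = grads$main)
      if (project) g$skip <- grads$skip
      if (attention) g$att <- grads$att
      list(dx = dx, grads = g)
    })
}

# ---- parameter-tree utilities -------------------------------------------

ptree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) ptree_map(f, x)) else f(a)
}

ptree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- ptree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

ptree_zeros <- function(a) ptree_map(function(x) x * 0, a)

ptree_count <- function(a) {
  if (is.list(a)) sum(vapply(a, ptree_count, numeric(1))) else length(a)
}

# In-place-style SGD with momentum and decoupled-from-loss L2 weight decay
# applied to weights (classic SGD weight decay: grad + wd * param).
sgd_step <- function(params, grads, velocity, lr, momentum = 0.9,
                     weight_decay = 0) {
  upd <- function(p, g, v) {
    v_new <- momentum * v + g + weight_decay * p
    list(p = p - lr * v_new, v = v_new)
  }
  # walk the three trees together
  walk <- function(p, g, v) {
    if (is.list(p)) {
      pn <- p; vn <- v
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], v[[i]])
        pn[[i]] <- r$p; vn[[i]] <- r$v
      }
      list(p = pn, v = vn)
    } else {
      upd(p, g, v)
    }
  }
  walk(params, grads, velocity)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      pn <- p; mn <- m; vn <- v
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        pn[[i]] <- r$p; mn[[i]] <- r$m; vn[[i]] <- r$v
      }
      list(p = pn, m = mn, v = vn)
    } else {
      g <- g + weight_decay * p
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

adam_init <- function(params) {
  list(m = ptree_zeros(params), v = ptree_zeros(params), t = 0)
}
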