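#' @useDynLib abpwave, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# A compact 1-D convolutional network engine.
#
# Signals are (channels, length, batch) arrays. A forward pass records a tape
# of nodes; nn_backward() replays it in reverse, accumulating parameter
# gradients. Convolution forward/backward run in C++ (single-precision
# im2col + gemm); everything element-wise stays vectorized in R.
# ---------------------------------------------------------------------------

nn_tape <- function(params) {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$params <- params
  env$pgrads <- new.env(parent = emptyenv())
  env
}

tp_push <- function(tape, val, parents = integer(), backward = NULL) {
  id <- length(tape$nodes) + 1L
  tape$nodes[[id]] <- list(id = id, val = val, parents = parents,
                           backward = backward)
  tape$nodes[[id]]
}

tp_input <- function(tape, val) tp_push(tape, val)

tp_acc_pgrad <- function(tape, name, g) {
  cur <- tape$pgrads[[name]]
  tape$pgrads[[name]] <- if (is.null(cur)) g else cur + g
}

# parameter initialisers -----------------------------------------------------

nn_params <- function() new.env(parent = emptyenv())

init_conv <- function(params, name, c_in, c_out, k) {
  sd <- sqrt(2 / (c_in * k))
  params[[paste0(name, ".w")]] <- matrix(stats::rnorm(c_out * c_in * k, sd = sd),
                                         nrow = c_out)
  params[[paste0(name, ".b")]] <- rep(0, c_out)
  invisible(params)
}

init_upconv2 <- function(params, name, c_in, c_out) {
  sd <- sqrt(2 / c_in)
  params[[paste0(name, ".w")]] <- matrix(stats::rnorm(2 * c_out * c_in, sd = sd),
                                         nrow = 2 * c_out)
  params[[paste0(name, ".b")]] <- rep(0, c_out)
  invisible(params)
}

init_prelu <- function(params, name, c_out, alpha0 = 0.25) {
  params[[paste0(name, ".a")]] <- rep(alpha0, c_out)
  invisible(params)
}

init_dense <- function(params, name, d_in, d_out) {
  sd <- sqrt(2 / d_in)
  params[[paste0(name, ".w")]] <- matrix(stats::rnorm(d_out * d_in, sd = sd),
                                         nrow = d_out)
  params[[paste0(name, ".b")]] <- rep(0, d_out)
  invisible(params)
}

# ops ------------------------------------------------------------------------

op_conv <- function(tape, x, name, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  w <- tape$params[[paste0(name, ".w")]]
  b <- tape$params[[paste0(name, ".b")]]
  y <- cpp_conv1d_fw(x$val, w, b, k, stride, pad, name)
  tp_push(tape, y, parents = x$id, backward = function(grad, tape, parents) {
    bw <- cpp_conv1d_bw(parents[[1]]$val, w, grad, k, stride, pad, name)
    tp_acc_pgrad(tape, paste0(name, ".w"), bw$dw)
    tp_acc_pgrad(tape, paste0(name, ".b"), bw$db)
    list(bw$dx)
  })
}

op_upconv2 <- function(tape, x, name) {
  w <- tape$params[[paste0(name, ".w")]]
  b <- tape$params[[paste0(name, ".b")]]
  y <- cpp_upconv2_fw(x$val, w, b)
  tp_push(tape, y, parents = x$id, backward = function(grad, tape, parents) {
    bw <- cpp_upconv2_bw(parents[[1]]$val, w, grad)
    tp_acc_pgrad(tape, paste0(name, ".w"), bw$dw)
    tp_acc_pgrad(tape, paste0(name, ".b"), bw$db)
    list(bw$dx)
  })
}

op_prelu <- function(tape, x, name) {
  a <- tape$params[[paste0(name, ".a")]]   # per-channel alpha (dim 1)
  y <- cpp_prelu_fw(x$val, a)
  tp_push(tape, y, parents = x$id, backward = function(grad, tape, parents) {
    bw <- cpp_prelu_bw(parents[[1]]$val, a, grad)
    tp_acc_pgrad(tape, paste0(name, ".a"), bw$da)
    list(bw$dx)
  })
}

op_relu <- function(tape, x) {
  y <- pmax(x$val, 0)
  dim(y) <- dim(x$val)
  tp_push(tape, y, parents = x$id, backward = function(grad, tape, parents) {
    g <- grad
    g[parents[[1]]$val <= 0] <- 0
    list(g)
  })
}

op_add <- function(tape, a, b) {
  tp_push(tape, a$val + b$val, parents = c(a$id, b$id),
          backward = function(grad, tape, parents) list(grad, grad))
}

op_concat <- function(tape, a, b) {
  da <- dim(a$val); db <- dim(b$val)
  y <- array(0, c(da[1] + db[1], da[2], da[3]))
  y[seq_len(da[1]), , ] <- a$val
  y[da[1] + seq_len(db[1]), , ] <- b$val
  tp_push(tape, y, parents = c(a$id, b$id),
          backward = function(grad, tape, parents) {
            list(grad[seq_len(da[1]), , , drop = FALSE],
                 grad[da[1] + seq_len(db[1]), , , drop = FALSE])
          })
}

# global average pool over time: (C, L, N) -> (C, N)
op_gap <- function(tape, x) {
  d <- dim(x$val)
  y <- apply(x$val, 3L, rowMeans)
  y <- matrix(y, nrow = d[1])
  tp_push(tape, y, parents = x$id, backward = function(grad, tape, parents) {
    d <- dim(parents[[1]]$val)
    g <- array(rep(grad / d[2], each = 1), c(d[1], 1, d[3]))
    list(array(g[, rep(1, d[2]), , drop = FALSE], d))
  })
}

op_dense <- function(tape, x, name) {
  w <- tape$params[[paste0(name, ".w")]]
  b <- tape$params[[paste0(name, ".b")]]
  y <- w %*% x$val + b
  tp_push(tape, y, parents = x$id, backward = function(grad, tape, parents) {
    tp_acc_pgrad(tape, paste0(name, ".w"), grad %*% t(parents[[1]]$val))
    tp_acc_pgrad(tape, paste0(name, ".b"), rowSums(grad))
    list(t(w) %*% grad)
  })
}

op_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$val))
  tp_push(tape, y, parents = x$id, backward = function(grad, tape, parents) {
    yv <- 1 / (1 + exp(-parents[[1]]$val))
    list(grad * yv * (1 - yv))
  })
}

# backward -------------------------------------------------------------------

nn_backward <- function(tape, out, grad_out) {
  n <- length(tape$nodes)
  grads <- vector("list", n)
  grads[[out$id]] <- grad_out
  for (i in seq(n, 1L)) {
    node <- tape$nodes[[i]]
    g <- grads[[i]]
    if (is.null(g) || is.null(node$backward)) next
    parents <- lapply(node$parents, function(p) tape$nodes[[p]])
    pg <- node$backward(g, tape, parents)
    for (j in seq_along(node$parents)) {
      pid <- node$parents[[j]]
      grads[[pid]] <- if (is.null(grads[[pid]])) pg[[j]] else grads[[pid]] + pg[[j]]
    }
    grads[i] <- list(NULL)  # release memory without shifting indices
  }
  invisible(tape$pgrads)
}

# Nadam ----------------------------------------------------------------------
# Nesterov-momentum Adam with the Keras-style momentum schedule
# mu_t = beta1 * (1 - 0.5 * 0.96^(t * schedule_decay)).

nadam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      schedule_decay = 0.004, eps = 1e-7) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2
  st$schedule_decay <- schedule_decay; st$eps <- eps
  st$t <- 0L
  st$m_schedule <- 1
  st$m <- new.env(parent = emptyenv())
  st$v <- new.env(parent = emptyenv())
  st
}

nadam_step <- function(opt, grads) {
  opt$t <- opt$t + 1L
  t <- opt$t
  mu_t  <- opt$beta1 * (1 - 0.5 * 0.96^(t * opt$schedule_decay))
  mu_t1 <- opt$beta1 * (1 - 0.5 * 0.96^((t + 1) * opt$schedule_decay))
  m_sched_new <- opt$m_schedule * mu_t
  m_sched_next <- m_sched_new * mu_t1
  opt$m_schedule <- m_sched_new
  for (name in ls(grads)) {
    g <- grads[[name]]
    p <- opt$params[[name]]
    m <- opt$m[[name]]; if (is.null(m)) m <- g * 0
    v <- opt$v[[name]]; if (is.null(v)) v <- g * 0
    g_hat <- g / (1 - m_sched_new)
    m <- opt$beta1 * m + (1 - opt$beta1) * g
    v <- opt$beta2 * v + (1 - opt$beta2) * g * g
    m_hat <- m / (1 - m_sched_next)
    v_hat <- v / (1 - opt$beta2^t)
    m_bar <- (1 - mu_t) * g_hat + mu_t1 * m_hat
    opt$params[[name]] <- p - opt$lr * m_bar / (sqrt(v_hat) + opt$eps)
    opt$m[[name]] <- m
    opt$v[[name]] <- v
  }
  invisible(opt)
}

# snapshot / restore of a parameter environment (for early-stopping restore)
params_snapshot <- function(params) {
  out <- list()
  for (n in ls(params)) out[[n]] <- params[[n]]
  out
}

params_restore <- function(params, snap) {
  for (n in names(snap)) params[[n]] <- snap[[n]]
  invisible(params)
}

.onLoad <- function(libname, pkgname) {
  cpp_tune_allocator()
}
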