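# Forward and backward passes of the encoder-decoder network.  Feature maps
# are (channels x voxels) matrices in array order (x fastest); heavy kernels
# (convolution, pooling, upsampling) live in C++, normalization/softmax and
# the chain rule bookkeeping in R.

IN_EPS <- 1e-5

instnorm_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  s <- sqrt(v + IN_EPS)
  xhat <- xc / s
  list(y = xhat * g + b, xhat = xhat, s = s)
}

instnorm_backward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- rowSums(dy * xhat)
  db <- rowSums(dy)
  dxhat <- dy * g
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / cache$s
  list(dx = dx, dg = dg, db = db)
}

conv_block_forward <- function(params, name, x, dims) {
  w <- params[[paste0(name, "_w")]]
  k <- as.integer(round((ncol(w) / nrow(x))^(1 / 3)))
  z <- cpp_conv3d_forward(x, dims[1], dims[2], dims[3], w,
                          params[[paste0(name, "_b")]], k, k, k)
  nc <- instnorm_forward(z, params[[paste0(name, "_ng")]],
                         params[[paste0(name, "_nb")]])
  a <- nc$y
  a[a < 0] <- 0
  list(out = a, x = x, z = z, norm = nc, relu_mask = nc$y > 0, k = k)
}

conv_block_backward <- function(params, name, cache, dout, dims, grads,
                                need_dx = TRUE) {
  dy <- dout
  dy[!cache$relu_mask] <- 0
  nb <- instnorm_backward(dy, cache$norm, params[[paste0(name, "_ng")]])
  grads[[paste0(name, "_ng")]] <- nb$dg
  grads[[paste0(name, "_nb")]] <- nb$db
  k <- cache$k
  cb <- cpp_conv3d_backward(cache$x, nb$dx, dims[1], dims[2], dims[3],
                            params[[paste0(name, "_w")]], k, k, k, need_dx)
  grads[[paste0(name, "_w")]] <- cb$dW
  grads[[paste0(name, "_b")]] <- as.numeric(cb$db)
  list(grads = grads, dx = if (need_dx) cb$dX else NULL)
}

# Full forward pass.  Returns softmax probabilities and, when
# `keep_cache = TRUE`, everything needed for the backward pass.
nn_forward <- function(model, x, dims, keep_cache = FALSE) {
  spec <- model$spec
  params <- model$params
  L <- spec$levels
  cache <- list(dims = list(), enc = list(), dec = list())
  skips <- list()
  cur <- x
  cur_dims <- dims
  for (i in seq_len(L)) {
    b1 <- conv_block_forward(params, sprintf("enc%d_conv1", i), cur, cur_dims)
    b2 <- conv_block_forward(params, sprintf("enc%d_conv2", i), b1$out, cur_dims)
    if (keep_cache) cache$enc[[i]] <- list(b1 = b1, b2 = b2, dims = cur_dims)
    if (i < L) {
      skips[[i]] <- b2$out
      pf <- spec$pool_schedule[, i]
      mp <- cpp_maxpool3d_forward(b2$out, cur_dims[1], cur_dims[2], cur_dims[3],
                                  pf[1], pf[2], pf[3])
      if (keep_cache) cache$enc[[i]]$argmax <- mp$argmax
      cur <- mp$Y
      cur_dims <- cur_dims %/% pf
    } else {
      cur <- b2$out
    }
  }
  for (i in rev(seq_len(L - 1))) {
    pf <- spec$pool_schedule[, i]
    up_dims <- cur_dims * pf
    up <- cpp_upsample3d_forward(cur, cur_dims[1], cur_dims[2], cur_dims[3],
                                 pf[1], pf[2], pf[3])
    cat_in <- rbind(up, skips[[i]])
    b1 <- conv_block_forward(params, sprintf("dec%d_conv1", i), cat_in, up_dims)
    b2 <- conv_block_forward(params, sprintf("dec%d_conv2", i), b1$out, up_dims)
    if (keep_cache) {
      cache$dec[[i]] <- list(b1 = b1, b2 = b2, dims = up_dims,
                             coarse_dims = cur_dims, n_up = nrow(up))
    }
    cur <- b2$out
    cur_dims <- up_dims
  }
  logits <- cpp_conv3d_forward(cur, cur_dims[1], cur_dims[2], cur_dims[3],
                               params$out_conv_w, params$out_conv_b, 1L, 1L, 1L)
  m <- Reduce(pmax, asplit(logits, 1))
  e <- exp(sweep(logits, 2, m))
  probs <- sweep(e, 2, colSums(e), "/")
  if (keep_cache) {
    cache$out_in <- cur
    cache$out_dims <- cur_dims
  }
  list(probs = probs, cache = if (keep_cache) cache else NULL)
}

# Backward pass from the gradient w.r.t. the softmax *probabilities*.
# Returns a named list of parameter gradients.
nn_backward <- function(model, fw, dprobs) {
  spec <- model$spec
  params <- model$params
  probs <- fw$probs
  cache <- fw$cache
  L <- spec$levels
  grads <- list()
  # softmax jacobian: dZ_c = P_c * (dP_c - sum_j dP_j P_j)
  dz <- probs * sweep(dprobs, 2, colSums(dprobs * probs))
  od <- cache$out_dims
  cb <- cpp_conv3d_backward(cache$out_in, dz, od[1], od[2], od[3],
                            params$out_conv_w, 1L, 1L, 1L, TRUE)
  grads$out_conv_w <- cb$dW
  grads$out_conv_b <- as.numeric(cb$db)
  # decoder, shallowest level first; dcur starts as the gradient at the
  # level-1 decoder output and ends as the gradient at the bottom output
  dcur <- cb$dX
  dskips <- vector("list", L - 1)
  for (i in seq_len(L - 1)) {
    dc <- cache$dec[[i]]
    r <- conv_block_backward(params, sprintf("dec%d_conv2", i), dc$b2, dcur,
                             dc$dims, grads)
    grads <- r$grads
    r <- conv_block_backward(params, sprintf("dec%d_conv1", i), dc$b1, r$dx,
                             dc$dims, grads)
    grads <- r$grads
    pf <- spec$pool_schedule[, i]
    dup <- r$dx[seq_len(dc$n_up), , drop = FALSE]
    dskips[[i]] <- r$dx[-seq_len(dc$n_up), , drop = FALSE]
    dcur <- cpp_upsample3d_backward(dup, dc$coarse_dims[1], dc$coarse_dims[2],
                                    dc$coarse_dims[3], pf[1], pf[2], pf[3])
  }
  # encoder, deepest level first; dcur is the gradient at the block output
  # after pooling (or at the bottom output for i == L)
  for (i in rev(seq_len(L))) {
    ec <- cache$enc[[i]]
    dout <- if (i == L) {
      dcur
    } else {
      cpp_maxpool3d_backward(dcur, ec$argmax, prod(ec$dims)) + dskips[[i]]
    }
    r <- conv_block_backward(params, sprintf("enc%d_conv2", i), ec$b2, dout,
                             ec$dims, grads)
    grads <- r$grads
    r <- conv_block_backward(params, sprintf("enc%d_conv1", i), ec$b1, r$dx,
                             ec$dims, grads, need_dx = i > 1)
    grads <- r$grads
    dcur <- r$dx
  }
  grads
}
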