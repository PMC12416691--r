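# Minimal fully-connected network with analytic gradients. The backbone is
# described by a string such as "mlp:32-16" (two ReLU hidden layers of 32
# and 16 units feeding 2 sigmoid outputs). Exact input gradients are
# available for saliency maps and for the loss-masking checks.

#' @keywords internal
parse_backbone <- function(descriptor) {
  if (!grepl("^mlp:", descriptor))
    stop("unsupported backbone descriptor: ", descriptor)
  spec <- sub("^mlp:", "", descriptor)
  if (spec == "") return(integer(0))
  as.integer(strsplit(spec, "-")[[1]])
}

#' @keywords internal
nn_init <- function(descriptor, input_dim, n_out = 2L, seed = 1L) {
  hidden <- parse_backbone(descriptor)
  dims <- c(input_dim, hidden, n_out)
  with_seed(seed, {
    W <- lapply(seq_len(length(dims) - 1), function(i) {
      matrix(stats::rnorm(dims[i] * dims[i + 1], 0, sqrt(2 / dims[i])),
             dims[i], dims[i + 1])
    })
    b <- lapply(dims[-1], function(d) numeric(d))
    list(W = W, b = b, descriptor = descriptor, input_dim = input_dim)
  })
}

#' @keywords internal
nn_forward <- function(net, X) {
  L <- length(net$W)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  for (i in seq_len(L)) {
    Z <- sweep(acts[[i]] %*% net$W[[i]], 2, net$b[[i]], "+")
    acts[[i + 1]] <- if (i < L) pmax(Z, 0) else Z
  }
  list(logits = acts[[L + 1]], acts = acts)
}

#' @keywords internal
nn_backward <- function(net, fwd, dlogits) {
  # returns gradients for weights/biases and with respect to the input
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dlogits
  for (i in L:1) {
    gW[[i]] <- crossprod(fwd$acts[[i]], delta)
    gb[[i]] <- colSums(delta)
    if (i > 1) {
      delta <- (delta %*% t(net$W[[i]])) * (fwd$acts[[i]] > 0)
    } else {
      dX <- delta %*% t(net$W[[1]])
    }
  }
  list(gW = gW, gb = gb, dX = dX)
}

#' @keywords internal
sigmoid <- function(z) 1 / (1 + exp(-z))

#' @keywords internal
n_params <- function(net) {
  sum(vapply(net$W, length, 0)) + sum(vapply(net$b, length, 0))
}
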