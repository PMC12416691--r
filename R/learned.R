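# Trainable dual-output lesion scorer. Each subimage receives two sigmoid
# outputs: p_exist (a lesion is present: score 0.5 or 1.0) and p_abnormal
# (the lesion shows features insufficient for a full point: score 0.5).
# A 0.5-score label is encoded [1, 1]; 1.0 as [1, 0]; 0.0 as [0, -] with
# the abnormality loss masked, since an absent lesion offers no basis for
# abnormality assessment.

#' Encode a lesion score as a dual-output training target
#'
#' @param s lesion score: 0, 0.5 or 1 (N/A must be filtered out upstream,
#'   as in the source data where ambiguous lesions are excluded)
#' @return list with `exist`, `abnormal` (0/1) and `abnormal_masked`
#' @export
encode_label <- function(s) {
  if (length(s) != 1 || is.na(s))
    stop("N/A labels are excluded from training; filter before encoding")
  if (!s %in% c(0, 0.5, 1)) stop("score must be 0, 0.5 or 1")
  if (s == 1) list(exist = 1, abnormal = 0, abnormal_masked = FALSE)
  else if (s == 0.5) list(exist = 1, abnormal = 1, abnormal_masked = FALSE)
  else list(exist = 0, abnormal = 0, abnormal_masked = TRUE)
}

#' Decode a dual prediction into a lesion score
#'
#' @param p list or numeric with `p_exist` and `p_abnormal`
#' @param thresholds list with `t_exist`, `t_abnormal` (see
#'   [pick_thresholds()]); defaults to 0.5/0.5
#' @return 0, 0.5 or 1
#' @export
decode_prediction <- function(p, thresholds = list(t_exist = 0.5,
                                                   t_abnormal = 0.5)) {
  pe <- if (is.list(p)) p$p_exist else p[1]
  pa <- if (is.list(p)) p$p_abnormal else p[2]
  if (pe < thresholds$t_exist) 0.0
  else if (pa >= thresholds$t_abnormal) 0.5
  else 1.0
}

#' @keywords internal
encode_label_matrix <- function(scores) {
  enc <- lapply(scores, encode_label)
  list(target = cbind(exist = vapply(enc, `[[`, 0, "exist"),
                      abnormal = vapply(enc, `[[`, 0, "abnormal")),
       masked = vapply(enc, `[[`, TRUE, "abnormal_masked"))
}

#' Training configuration for the dual-output scorer
#'
#' Optimization follows the source protocol (SGD, learning rate 5e-3,
#' weight decay 1e-5, focal loss with inverse-proportion class weights and
#' sigmoid activations, abnormality loss masked on 0.0-scored tiles); the
#' default epoch count is reduced to desk scale.
#'
#' @param epochs passes over the training set (>= 1)
#' @param learning_rate SGD step size
#' @param weight_decay L2 penalty coefficient added to the gradient
#' @param focal_gamma focusing exponent of the focal loss (0 = plain
#'   weighted cross-entropy)
#' @param batch_size minibatch size
#' @param backbone descriptor string, see `"mlp:32-16"`
#' @param augment list of augmentation flags: `flips`, `shifts`,
#'   `rotation`, `rescale`, `blur_noise`; set to `NULL` to disable all
#' @param shift_frac,rotation_deg,rescale_range,blur_max augmentation
#'   magnitudes (fractions of tile size, degrees, scale range, blur sigma)
#' @param early_stop_patience epochs without held-out improvement before
#'   stopping (NULL disables)
#' @param seed RNG seed controlling init, shuffling and augmentation
#' @return list of class `train_config`
#' @export
train_config <- function(epochs = 30L, learning_rate = 5e-3,
                         weight_decay = 1e-5, focal_gamma = 2,
                         batch_size = 64L, backbone = "mlp:32-16",
                         augment = list(flips = TRUE, shifts = TRUE,
                                        rotation = TRUE, rescale = TRUE,
                                        blur_noise = TRUE),
                         shift_frac = 0.1, rotation_deg = 10,
                         rescale_range = c(0.9, 1.1), blur_max = 1,
                         early_stop_patience = NULL, seed = 1L) {
  stopifnot(epochs >= 1, learning_rate > 0, weight_decay >= 0,
            focal_gamma >= 0, batch_size >= 1)
  structure(as.list(environment()), class = "train_config")
}

#' Masked focal loss for dual sigmoid outputs
#'
#' Binary focal loss `-w (1 - p_t)^gamma log(p_t)` per output, with class
#' weights proportional to inverse class frequency; abnormality terms of
#' masked (0.0-scored) samples are dropped from the abnormality mean. The
#' total is the sum of the two per-output means. At `gamma = 0` and unit
#' weights this reduces to mean binary cross-entropy per output.
#'
#' @param prob n x 2 matrix of predicted probabilities (exist, abnormal)
#' @param target n x 2 matrix of 0/1 targets
#' @param masked logical n-vector: abnormality term excluded when TRUE
#' @param gamma focusing exponent
#' @param class_weights list with `exist` and `abnormal`, each c(w0, w1)
#' @return scalar loss
#' @export
masked_focal_loss <- function(prob, target, masked = rep(FALSE, nrow(prob)),
                              gamma = 2,
                              class_weights = list(exist = c(1, 1),
                                                   abnormal = c(1, 1))) {
  if (!nrow(prob)) stop("empty batch")
  stopifnot(identical(dim(prob), dim(target)), length(masked) == nrow(prob))
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  term <- function(j, keep, w) {
    pt <- target[keep, j] * p[keep, j] + (1 - target[keep, j]) * (1 - p[keep, j])
    wv <- ifelse(target[keep, j] == 1, w[2], w[1])
    mean(-wv * (1 - pt)^gamma * log(pt))
  }
  le <- term(1, rep(TRUE, nrow(prob)), class_weights$exist)
  keep_a <- !masked
  la <- if (any(keep_a)) term(2, keep_a, class_weights$abnormal) else 0
  le + la
}

#' @keywords internal
focal_grad_logits <- function(prob, target, masked, gamma, class_weights) {
  # d(loss)/d(logit): w * s * (1-pt)^gamma * (gamma * pt * log(pt) - (1-pt))
  # with s = +1 for target 1, -1 for target 0; masked abnormality terms 0
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  n <- nrow(p)
  g <- matrix(0, n, 2)
  for (j in 1:2) {
    w <- if (j == 1) class_weights$exist else class_weights$abnormal
    pt <- target[, j] * p[, j] + (1 - target[, j]) * (1 - p[, j])
    s <- 2 * target[, j] - 1
    wv <- ifelse(target[, j] == 1, w[2], w[1])
    g[, j] <- wv * s * (1 - pt)^gamma * (gamma * pt * log(pt) - (1 - pt))
  }
  g[, 1] <- g[, 1] / n
  keep <- !masked
  g[masked, 2] <- 0
  g[keep, 2] <- g[keep, 2] / max(sum(keep), 1)
  g
}

#' @keywords internal
inverse_proportion_weights <- function(target, masked) {
  w <- function(y) {
    n <- length(y)
    c(n / (2 * max(sum(y == 0), 1)), n / (2 * max(sum(y == 1), 1)))
  }
  list(exist = w(target[, 1]), abnormal = w(target[!masked, 2]))
}

#' @keywords internal
augment_tile <- function(px, cfg) {
  a <- cfg$augment
  if (is.null(a)) return(px)
  n <- nrow(px)
  if (isTRUE(a$flips)) {
    if (stats::runif(1) < 0.5) px <- px[, n:1]
    if (stats::runif(1) < 0.5) px <- px[n:1, ]
  }
  if (isTRUE(a$shifts)) {
    mx <- max(1, round(cfg$shift_frac * n))
    dr <- sample(-mx:mx, 1); dc <- sample(-mx:mx, 1)
    out <- matrix(stats::median(px[c(1, n), ]), n, n)
    sr <- max(1, 1 + dr):min(n, n + dr); sc <- max(1, 1 + dc):min(n, n + dc)
    out[sr, sc] <- px[sr - dr, sc - dc]
    px <- out
  }
  heavy <- c(if (isTRUE(a$rotation)) "rotation",
             if (isTRUE(a$rescale)) "rescale")
  if (length(heavy) && stats::runif(1) < 0.5) {
    op <- if (length(heavy) == 1) heavy else
      heavy[sample.int(2, 1)]
    fill <- stats::median(px[c(1, n), ])
    ctr <- (n + 1) / 2
    grid_r <- rep(seq_len(n), times = n) - ctr
    grid_c <- rep(seq_len(n), each = n) - ctr
    if (op == "rotation") {
      th <- stats::runif(1, -cfg$rotation_deg, cfg$rotation_deg) * pi / 180
      sr <- ctr + cos(th) * grid_r - sin(th) * grid_c
      sc <- ctr + sin(th) * grid_r + cos(th) * grid_c
    } else {
      f <- stats::runif(1, cfg$rescale_range[1], cfg$rescale_range[2])
      sr <- ctr + grid_r / f
      sc <- ctr + grid_c / f
    }
    v <- bilinear_many(px, sr, sc)
    oob <- sr < 1 | sr > n | sc < 1 | sc > n
    v[oob] <- fill
    px <- matrix(v, n, n)
  }
  if (isTRUE(a$blur_noise)) {
    if (stats::runif(1) < 0.5) {
      px <- blur_tile(px, stats::runif(1, 0.2, cfg$blur_max))
    } else {
      px <- px + matrix(stats::rnorm(n * n, 0, 0.01), n, n)
    }
  }
  px
}

#' @keywords internal
blur_tile <- function(px, sigma) {
  # separable Gaussian as cached banded matrix products (sigma quantized
  # to 0.1 steps; boundary rows renormalized)
  if (sigma <= 0) return(px)
  sigma <- max(round(sigma, 1), 0.1)
  n <- nrow(px)
  key <- sprintf("blurmat_%d_%.1f", n, sigma)
  K <- .pq_env[[key]]
  if (is.null(K)) {
    K <- outer(seq_len(n), seq_len(n), function(i, j)
      stats::dnorm(i - j, sd = sigma))
    K[abs(row(K) - col(K)) > ceiling(3 * sigma)] <- 0
    K <- K / rowSums(K)
    .pq_env[[key]] <- K
  }
  K %*% px %*% t(K)
}

#' Train the dual-output lesion scorer
#'
#' Seeded, reproducible SGD training on subimage tiles. Tiles scored N/A
#' must be filtered out beforehand. Returns a `phantom_scorer` whose
#' `predict()` yields (p_exist, p_abnormal) pairs.
#'
#' @param subs list of `subimage` objects (or bare 56 x 56 matrices)
#' @param scores numeric vector of lesion scores in \{0, 0.5, 1\}
#' @param config a [train_config()]
#' @param val_subs,val_scores optional held-out set used for early
#'   stopping and the loss trace
#' @return object of class `phantom_scorer` with the fitted network,
#'   per-epoch `history`, `class_weights`, and decision `thresholds`
#'   (initialized at 0.5/0.5)
#' @export
train_scorer <- function(subs, scores, config = train_config(),
                         val_subs = NULL, val_scores = NULL) {
  if (!length(subs)) stop("empty training data")
  if (length(subs) != length(scores)) stop("subs/scores length mismatch")
  if (any(is.na(scores))) stop("N/A-scored tiles must be excluded")
  mats <- lapply(subs, function(s) if (is.list(s)) s$pixels else s)
  d <- nrow(mats[[1]])
  enc <- encode_label_matrix(scores)
  if (length(unique(enc$target[, 1])) < 2)
    warning("existence output has a single class; training is degenerate")
  cw <- inverse_proportion_weights(enc$target, enc$masked)
  net <- nn_init(config$backbone, d * d, 2L, seed = config$seed)
  n <- length(mats)
  X_plain <- t(vapply(mats, as.vector, numeric(d * d)))
  has_val <- !is.null(val_subs)
  if (has_val) {
    Xv <- t(vapply(val_subs, function(s)
      as.vector(if (is.list(s)) s$pixels else s), numeric(d * d)))
    encv <- encode_label_matrix(val_scores)
  }
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_val <- Inf; best_net <- net; wait <- 0L
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      X <- if (is.null(config$augment)) X_plain else
        t(vapply(mats, function(m)
          as.vector(augment_tile(m, config)), numeric(d * d)))
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        fwd <- nn_forward(net, X[idx, , drop = FALSE])
        prob <- sigmoid(fwd$logits)
        tgt <- enc$target[idx, , drop = FALSE]
        msk <- enc$masked[idx]
        ep_loss <- ep_loss + masked_focal_loss(prob, tgt, msk,
                                               config$focal_gamma, cw)
        nb <- nb + 1
        dz <- focal_grad_logits(prob, tgt, msk, config$focal_gamma, cw)
        gr <- nn_backward(net, fwd, dz)
        for (i in seq_along(net$W)) {
          net$W[[i]] <- net$W[[i]] - config$learning_rate *
            (gr$gW[[i]] + config$weight_decay * net$W[[i]])
          net$b[[i]] <- net$b[[i]] - config$learning_rate * gr$gb[[i]]
        }
      }
      vl <- NA_real_
      if (has_val) {
        pv <- sigmoid(nn_forward(net, Xv)$logits)
        vl <- masked_focal_loss(pv, encv$target, encv$masked,
                                config$focal_gamma, cw)
        if (vl < best_val - 1e-6) {
          best_val <- vl; best_net <- net; wait <- 0L
        } else if (!is.null(config$early_stop_patience)) {
          wait <- wait + 1L
          if (wait >= config$early_stop_patience) {
            history <- rbind(history, data.frame(
              epoch = ep, train_loss = ep_loss / nb, val_loss = vl))
            break
          }
        }
      }
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = ep_loss / nb, val_loss = vl))
    }
  })
  if (has_val && !is.null(config$early_stop_patience)) net <- best_net
  structure(list(net = net, config = config, class_weights = cw,
                 history = history,
                 thresholds = list(t_exist = 0.5, t_abnormal = 0.5)),
            class = "phantom_scorer")
}

#' Predict dual probabilities for subimages
#'
#' @param object a `phantom_scorer`
#' @param subs list of `subimage` objects (or matrices), or a single one
#' @param ... unused
#' @return data frame with columns `p_exist`, `p_abnormal`
#' @export
predict.phantom_scorer <- function(object, subs, ...) {
  if (inherits(subs, "subimage") || is.matrix(subs)) subs <- list(subs)
  X <- t(vapply(subs, function(s)
    as.vector(if (is.list(s)) s$pixels else s),
    numeric(object$net$input_dim)))
  pr <- sigmoid(nn_forward(object$net, X)$logits)
  data.frame(p_exist = pr[, 1], p_abnormal = pr[, 2])
}

#' @export
print.phantom_scorer <- function(x, ...) {
  cat(sprintf("<phantom_scorer> backbone %s (%d parameters), %d epochs trained\n",
              x$net$descriptor, n_params(x$net), nrow(x$history)))
  invisible(x)
}

#' Decoded-score function of a trained scorer
#'
#' @param scorer a `phantom_scorer`
#' @param thresholds decision thresholds (defaults to the scorer's)
#' @return function mapping a `subimage` to a score in \{0, 0.5, 1\}
#' @export
learned_scorer_fn <- function(scorer, thresholds = scorer$thresholds) {
  function(sub) {
    p <- predict.phantom_scorer(scorer, sub)
    decode_prediction(list(p_exist = p$p_exist[1],
                           p_abnormal = p$p_abnormal[1]), thresholds)
  }
}

#' Gradient saliency map of one output for one tile
#'
#' First-order (Taylor) attribution: the absolute gradient of the selected
#' output probability with respect to each input pixel.
#'
#' @param scorer a `phantom_scorer`
#' @param sub a `subimage` or bare matrix
#' @param output "exist" or "abnormal"
#' @return matrix of |gradient| values, same shape as the tile
#' @export
saliency_map <- function(scorer, sub, output = c("exist", "abnormal")) {
  output <- match.arg(output)
  j <- if (output == "exist") 1L else 2L
  px <- if (is.list(sub)) sub$pixels else sub
  X <- matrix(as.vector(px), 1)
  fwd <- nn_forward(scorer$net, X)
  p <- sigmoid(fwd$logits)
  dz <- matrix(0, 1, 2)
  dz[1, j] <- p[1, j] * (1 - p[1, j])  # d p / d logit
  gr <- nn_backward(scorer$net, fwd, dz)
  matrix(abs(gr$dX), nrow(px), ncol(px))
}

#' Normalize saliency maps for display
#'
#' Scales heatmaps to a common ceiling fixed at twice the 99.5th
#' percentile of the saliency values pooled within a lesion type, then
#' clips to \[0,1\].
#'
#' @param maps list of saliency matrices from tiles of one lesion type
#' @return list of matrices in \[0,1\]
#' @export
normalize_saliency <- function(maps) {
  ceiling_val <- 2 * stats::quantile(unlist(maps), 0.995, names = FALSE)
  if (ceiling_val <= 0) ceiling_val <- 1
  lapply(maps, function(m) pmin(m / ceiling_val, 1))
}

#' Probability curves under controlled lesion manipulations
#'
#' Re-renders one lesion across a manipulation sweep (all other lesions at
#' full visibility) and records the scorer's dual probabilities at each
#' step, with threshold-crossing annotations. Manipulations: fiber break
#' position, fiber visible length, joint speck count/opacity ramp, mass
#' deformation (loss of circular contour), and mass rescale.
#'
#' @param scorer a `phantom_scorer`
#' @param cell grid cell (1..16) of the manipulated lesion
#' @param manipulation one of "fiber_break_position", "fiber_length",
#'   "speck_count_opacity", "mass_deformation", "mass_rescale"
#' @param steps number of sweep steps (0 returns the single base state)
#' @param layout layout map
#' @param thresholds decision thresholds for the annotations
#' @param spec_args extra arguments for the rendered [phantom_spec()]
#'   (e.g. `noise_sigma = 0`)
#' @return data frame with `step`, `param`, `p_exist`, `p_abnormal`,
#'   `above_exist`, `above_abnormal`, `decoded`
#' @export
interpretation_sweep <- function(scorer, cell,
                                 manipulation = c("fiber_break_position",
                                                  "fiber_length",
                                                  "speck_count_opacity",
                                                  "mass_deformation",
                                                  "mass_rescale"),
                                 steps = 9, layout = phantom_layout(),
                                 thresholds = scorer$thresholds,
                                 spec_args = list(noise_sigma = 0, seed = 1L)) {
  manipulation <- match.arg(manipulation)
  row <- layout$cells[cell, ]
  type_needed <- switch(manipulation,
                        fiber_break_position = "fiber", fiber_length = "fiber",
                        speck_count_opacity = "specks",
                        mass_deformation = "mass", mass_rescale = "mass")
  if (row$lesion_type != type_needed)
    stop("manipulation '", manipulation, "' needs a ", type_needed,
         " cell, got ", row$lesion_type)
  params <- if (steps <= 0) NA_real_ else switch(manipulation,
    fiber_break_position = seq(0.15, 0.85, length.out = steps),
    fiber_length = seq(0, 1, length.out = steps),
    speck_count_opacity = seq(0, 1, length.out = steps),
    mass_deformation = seq(1, 0.2, length.out = steps),
    mass_rescale = seq(1, 1 / 3, length.out = steps))
  make_lesion <- function(v) {
    if (steps <= 0 || is.na(v))
      return(lesion_params(row$lesion_type, row$rank, layout = layout))
    switch(manipulation,
      fiber_break_position = lesion_params("fiber", row$rank, visibility = 1,
                                           break_positions = v, layout = layout),
      fiber_length = lesion_params("fiber", row$rank, visibility = v,
                                   layout = layout),
      speck_count_opacity = lesion_params("specks", row$rank,
        visibility = pmin(pmax(6 * v - (0:5), 0), 1), layout = layout),
      mass_deformation = lesion_params("mass", row$rank, visibility = v,
                                       layout = layout),
      mass_rescale = {
        p <- lesion_params("mass", row$rank, visibility = 1, layout = layout)
        p$size_scale <- v
        p
      })
  }
  params <- if (steps <= 0) NA_real_ else params
  out <- lapply(seq_len(max(steps, 1)), function(i) {
    v <- if (steps <= 0) NA_real_ else params[i]
    lesions <- full_visibility_lesions(layout)
    lesions[[cell]] <- make_lesion(v)
    spec <- do.call(phantom_spec,
                    c(list(lesions = lesions), spec_args))
    tile <- split_grid(render_standardized(spec, layout), layout)[[cell]]
    p <- predict.phantom_scorer(scorer, tile)
    data.frame(step = i, param = v, p_exist = p$p_exist,
               p_abnormal = p$p_abnormal)
  })
  res <- do.call(rbind, out)
  res$above_exist <- res$p_exist >= thresholds$t_exist
  res$above_abnormal <- res$p_abnormal >= thresholds$t_abnormal
  res$decoded <- mapply(function(pe, pa)
    decode_prediction(list(p_exist = pe, p_abnormal = pa), thresholds),
    res$p_exist, res$p_abnormal)
  res
}
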