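test_that("dual-output label encoding and decoding round-trip exactly", {
  expect_equal(encode_label(0.5)[c("exist", "abnormal")],
               list(exist = 1, abnormal = 1))
  expect_equal(encode_label(1)[c("exist", "abnormal")],
               list(exist = 1, abnormal = 0))
  e0 <- encode_label(0)
  expect_equal(e0$exist, 0)
  expect_true(e0$abnormal_masked)
  expect_false(encode_label(1)$abnormal_masked)
  expect_error(encode_label(NA), "N/A")
  expect_error(encode_label(0.7), "score must be")
  # decode(encode(s)) == s reading targets as hard probabilities
  th <- list(t_exist = 0.5, t_abnormal = 0.5)
  for (s in c(0, 0.5, 1)) {
    e <- encode_label(s)
    expect_equal(decode_prediction(list(p_exist = e$exist,
                                        p_abnormal = e$abnormal), th), s)
  }
  expect_equal(decode_prediction(list(p_exist = 0.9, p_abnormal = 0.1), th), 1)
  expect_equal(decode_prediction(list(p_exist = 0.9, p_abnormal = 0.9), th), 0.5)
  expect_equal(decode_prediction(list(p_exist = 0.1, p_abnormal = 0.9), th), 0)
})

test_that("focal loss reduces to hand-computed cross-entropy at gamma zero", {
  prob <- matrix(c(0.8, 0.3, 0.6,
                   0.2, 0.9, 0.5), ncol = 2)
  tgt <- matrix(c(1, 0, 1,
                  0, 1, 1), ncol = 2)
  msk <- rep(FALSE, 3)
  # hand computation: mean BCE per output, summed
  bce_e <- -mean(log(c(0.8, 1 - 0.3, 0.6)))
  bce_a <- -mean(log(c(1 - 0.2, 0.9, 0.5)))
  expect_equal(masked_focal_loss(prob, tgt, msk, gamma = 0), bce_e + bce_a,
               tolerance = 1e-12)
  # perfect predictions drive the loss to zero
  perfect <- masked_focal_loss(tgt, tgt, msk, gamma = 2)
  expect_lt(perfect, 1e-5)
  # loss decreases as predictions approach the targets elementwise
  l1 <- masked_focal_loss(matrix(c(0.6, 0.4), 1), matrix(c(1, 0), 1), FALSE)
  l2 <- masked_focal_loss(matrix(c(0.9, 0.1), 1), matrix(c(1, 0), 1), FALSE)
  expect_lt(l2, l1)
  expect_gte(l2, 0)
  expect_error(masked_focal_loss(prob[0, , drop = FALSE],
                                 tgt[0, , drop = FALSE], logical(0)),
               "empty")
})

test_that("masking removes the abnormality term and its gradient entirely", {
  # batch of 0.0-scored tiles: the loss ignores the abnormality output
  enc <- encode_label_matrix_for_test <- function(s) {
    e <- lapply(s, encode_label)
    list(t = cbind(vapply(e, `[[`, 0, "exist"),
                   vapply(e, `[[`, 0, "abnormal")),
         m = vapply(e, `[[`, TRUE, "abnormal_masked"))
  }
  z <- enc(c(0, 0, 0))
  pa <- matrix(c(0.2, 0.5, 0.7, 0.1, 0.5, 0.9), ncol = 2)
  pb <- pa; pb[, 2] <- c(0.99, 0.01, 0.5)
  expect_equal(masked_focal_loss(pa, z$t, z$m),
               masked_focal_loss(pb, z$t, z$m))
  # analytic logit gradient matches finite differences; masked entries zero
  mix <- enc(c(1, 0.5, 0, 1))
  logits <- matrix(c(0.3, -1, 0.5, 2, -0.4, 1.2, 0, -2), ncol = 2)
  cw <- list(exist = c(1.3, 0.8), abnormal = c(0.9, 2.1))
  g <- phantomqa:::focal_grad_logits(phantomqa:::sigmoid(logits), mix$t,
                                     mix$m, 2, cw)
  f <- function(z) masked_focal_loss(phantomqa:::sigmoid(z), mix$t, mix$m,
                                     2, cw)
  h <- 1e-6
  for (i in seq_along(logits)) {
    zp <- logits; zp[i] <- zp[i] + h
    zm <- logits; zm[i] <- zm[i] - h
    expect_equal(g[i], (f(zp) - f(zm)) / (2 * h), tolerance = 1e-5)
  }
  expect_identical(g[3, 2], 0)  # the 0.0-labelled sample, abnormality head
})

test_that("training is seeded-reproducible and flags degenerate labels", {
  d <- demo_scorer(1)
  sub <- d$train$subs[1:60]; sc <- d$train$scores[1:60]
  cfg <- train_config(epochs = 3, seed = 7, augment = NULL)
  s1 <- train_scorer(sub, sc, cfg)
  s2 <- train_scorer(sub, sc, cfg)
  expect_identical(s1$history, s2$history)
  expect_identical(s1$net$W, s2$net$W)
  expect_warning(train_scorer(sub[sc == 1][1:10], rep(1, 10), cfg),
                 "single class")
  expect_error(train_scorer(list(), numeric(0)), "empty")
  expect_error(train_scorer(sub, rep(NA_real_, 60)), "excluded")
})

test_that("saliency is zero for a constant scorer and |w| for a linear one", {
  net0 <- phantomqa:::nn_init("mlp:", 3136, seed = 1)
  net0$W[[1]][] <- 0
  s0 <- structure(list(net = net0,
                       thresholds = list(t_exist = 0.5, t_abnormal = 0.5)),
                  class = "phantom_scorer")
  tile <- matrix(runif(3136), 56, 56)
  expect_true(all(saliency_map(s0, tile, "exist") == 0))
  netl <- phantomqa:::nn_init("mlp:", 3136, seed = 2)
  sl <- structure(list(net = netl,
                       thresholds = list(t_exist = 0.5, t_abnormal = 0.5)),
                  class = "phantom_scorer")
  sal <- saliency_map(sl, tile, "abnormal")
  p <- predict(sl, tile)$p_abnormal
  expect_equal(as.vector(sal),
               abs(netl$W[[1]][, 2]) * p * (1 - p), tolerance = 1e-12)
})

test_that("saliency concentrates on the lesion region of fiber tiles", {
  lay <- test_layout()
  d <- demo_scorer(1)
  spec <- phantom_spec(noise_sigma = 0, seed = 4)
  tiles <- split_grid(render_standardized(spec, lay), lay)
  ratios <- vapply(1:6, function(cl) {
    g <- lesion_geometry(lay, cl)
    sal <- saliency_map(d$scorer, tiles[[cl]], "exist")
    n <- nrow(sal)
    rr <- matrix(rep(1:n, n), n); cc <- t(rr)
    perp <- c(g$dir[2], -g$dir[1])
    dr <- rr - g$center[1]; dc <- cc - g$center[2]
    along <- dr * g$dir[1] + dc * g$dir[2]
    poff <- abs(dr * perp[1] + dc * perp[2])
    mask <- poff <= (g$width / 2 + 5) & abs(along) <= (g$length / 2 + 5)
    (sum(sal[mask]) / sum(sal)) / mean(mask)
  }, 0)
  # saliency density inside the dilated fiber mask exceeds the tile-average
  # density (fully-connected backbones concentrate less sharply than
  # convolutional ones; the density ratio is the architecture-independent
  # localization statement)
  expect_true(all(ratios > 1.2))
  expect_gt(mean(ratios), 1.35)
})

test_that("manipulation sweeps recover the guideline response patterns", {
  lay <- test_layout()
  d <- demo_scorer(1)
  sw <- interpretation_sweep(d$scorer, 1, "fiber_length", steps = 9,
                             layout = lay)
  expect_equal(nrow(sw), 9)
  # lesion presence rises with visible length; the decoded path walks
  # 0.0 -> 0.5 -> 1.0 as in the guideline
  expect_gt(cor(sw$param, sw$p_exist, method = "spearman"), 0.9)
  expect_equal(sw$decoded[1], 0)
  expect_equal(sw$decoded[9], 1)
  expect_true(0.5 %in% sw$decoded)
  expect_true(all(diff(sw$decoded) >= 0))
  # existence rises before abnormality falls: at the first step where the
  # lesion is called present, abnormality is still high
  first_exist <- which(sw$above_exist)[1]
  expect_gt(sw$p_abnormal[first_exist], d$scorer$thresholds$t_abnormal)
  # speck ramp: empty cell decodes 0.0, full group 1.0, 0.5 in between
  sw2 <- interpretation_sweep(d$scorer, 7, "speck_count_opacity",
                              steps = 13, layout = lay)
  expect_equal(sw2$decoded[1], 0)
  expect_equal(sw2$decoded[13], 1)
  expect_true(0.5 %in% sw2$decoded)
  # mass deformation: abnormality stays below threshold for the circular
  # mass and rises above it once the contour drops under three quarters
  sw3 <- interpretation_sweep(d$scorer, 12, "mass_deformation", steps = 7,
                              layout = lay)
  expect_lt(sw3$p_abnormal[sw3$param == 1],
            d$scorer$thresholds$t_abnormal)
  expect_true(all(sw3$p_abnormal[sw3$param < 0.7] >
                    d$scorer$thresholds$t_abnormal))
  expect_gt(max(sw3$p_abnormal), 0.9)
  # zero-step sweep returns the single base prediction
  sw0 <- interpretation_sweep(d$scorer, 1, "fiber_length", steps = 0,
                              layout = lay)
  expect_equal(nrow(sw0), 1)
  expect_error(interpretation_sweep(d$scorer, 1, "mass_deformation"),
               "needs a mass")
})
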