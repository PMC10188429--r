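#' Vision Transformer configuration
#'
#' Architectural and training hyperparameters. Two presets are provided:
#' the full-scale preset (`vit_config_full()`: 224-pixel images, 16-pixel
#' patches, embedding 512, depth 12, 8 heads, mlp ratio 4, batch 64,
#' learning rate 0.001, 5 epochs) and a desk-scale preset
#' (`vit_config_desk()`: 64-pixel images, 8-pixel patches, embedding 64,
#' depth 2, 4 heads, mlp ratio 2, batch 32) sized so the full pipeline
#' trains in seconds on one CPU core.
#'
#' @param image_side Input image side in pixels; divisible by `patch_side`.
#' @param patch_side Patch side in pixels.
#' @param embed_dim Token embedding dimension; divisible by `heads`.
#' @param depth Number of transformer blocks.
#' @param heads Number of attention heads.
#' @param mlp_ratio Width multiplier of the feed-forward hidden layer.
#' @param n_classes Number of output classes (2).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param epochs Training epochs (>= 1).
#' @param seed Integer seed controlling initialisation and shuffling.
#' @return An object of class `vit_config`.
#' @export
vit_config <- function(image_side = 224, patch_side = 16, embed_dim = 512,
                       depth = 12, heads = 8, mlp_ratio = 4, n_classes = 2,
                       batch_size = 64, learning_rate = 0.001, epochs = 5,
                       seed = 1) {
  if (image_side %% patch_side != 0) {
    stopf("image_side %d not divisible by patch_side %d", image_side, patch_side)
  }
  if (embed_dim %% heads != 0) {
    stopf("embed_dim %d not divisible by heads %d", embed_dim, heads)
  }
  if (epochs < 1) stopf("epochs must be >= 1")
  structure(list(image_side = image_side, patch_side = patch_side,
                 embed_dim = embed_dim, depth = depth, heads = heads,
                 mlp_ratio = mlp_ratio, n_classes = n_classes,
                 batch_size = batch_size, learning_rate = learning_rate,
                 epochs = epochs, seed = seed),
            class = "vit_config")
}

#' @rdname vit_config
#' @param ... Overrides passed to [vit_config()].
#' @export
vit_config_full <- function(...) {
  do.call(vit_config, utils::modifyList(
    list(image_side = 224, patch_side = 16, embed_dim = 512, depth = 12,
         heads = 8, mlp_ratio = 4, n_classes = 2, batch_size = 64,
         learning_rate = 0.001, epochs = 5), list(...)))
}

#' @rdname vit_config
#' @export
vit_config_desk <- function(...) {
  do.call(vit_config, utils::modifyList(
    list(image_side = 64, patch_side = 8, embed_dim = 64, depth = 2,
         heads = 4, mlp_ratio = 2, n_classes = 2, batch_size = 32,
         learning_rate = 0.001, epochs = 5), list(...)))
}

n_patches <- function(cfg) (cfg$image_side %/% cfg$patch_side)^2

# Linear pixel indices of each patch (row-major patch grid, row-major
# flattening inside the patch), computed once per config.
patch_index_matrix <- function(cfg) {
  S <- cfg$image_side; P <- cfg$patch_side; g <- S %/% P
  idx <- matrix(0L, nrow = g * g, ncol = P * P)
  k <- 0L
  for (pr in seq_len(g)) for (pc in seq_len(g)) {
    k <- k + 1L
    rows <- (pr - 1L) * P + seq_len(P)
    cols <- (pc - 1L) * P + seq_len(P)
    # row-major within the patch: iterate rows, then columns
    idx[k, ] <- as.integer(outer(cols - 1L, rows, function(c0, r) c0 * S + r))
  }
  idx
}

#' Split an image into flattened non-overlapping patches
#'
#' Patches are taken in row-major order over the patch grid and each is
#' flattened row-major to a vector of length `patch_side^2`; reassembling
#' the rows in the same order reproduces the image exactly.
#'
#' @param img A `wave_image` (or bare numeric matrix) with side
#'   `cfg$image_side`.
#' @param cfg A [vit_config()].
#' @return `(image_side/patch_side)^2 x patch_side^2` matrix.
#' @export
patchify <- function(img, cfg) {
  px <- if (inherits(img, "wave_image")) img$pixels else img
  if (!is.matrix(px) || nrow(px) != cfg$image_side || ncol(px) != cfg$image_side) {
    stopf("image side %s does not match cfg$image_side %d",
          paste(dim(px), collapse = "x"), cfg$image_side)
  }
  idx <- patch_index_matrix(cfg)
  matrix(px[as.vector(idx)], nrow = nrow(idx), ncol = ncol(idx))
}

# Stack patchified images into one ((B*np) x patch^2) matrix.
stack_patches <- function(images, cfg) {
  idx <- patch_index_matrix(cfg)
  np <- nrow(idx); pp <- ncol(idx)
  out <- matrix(0, length(images) * np, pp)
  for (i in seq_along(images)) {
    px <- if (inherits(images[[i]], "wave_image")) images[[i]]$pixels else images[[i]]
    if (nrow(px) != cfg$image_side || ncol(px) != cfg$image_side) {
      stopf("image %d side %s does not match cfg$image_side %d",
            i, paste(dim(px), collapse = "x"), cfg$image_side)
    }
    out[((i - 1L) * np + 1L):(i * np), ] <- matrix(px[as.vector(idx)], np, pp)
  }
  out
}

#' Initialise Vision Transformer parameters
#'
#' Linear-layer weights use scaled-normal (He/Xavier-style) initialisation,
#' N(0, 1/fan_in), so that with layer-normalised unit-variance inputs the
#' pre-activations have order-one scale and the GELU nonlinearity is
#' engaged from the first step; class token and positional embeddings are
#' drawn N(0, 0.02^2); biases and layer-norm shifts start at 0, layer-norm
#' scales at 1. Deterministic given `cfg$seed`.
#'
#' @param cfg A [vit_config()].
#' @return Named flat list of parameter arrays (class `vit_params`).
#' @export
vit_init <- function(cfg) {
  D <- cfg$embed_dim; P2 <- cfg$patch_side^2; H <- cfg$mlp_ratio * D
  Tn <- n_patches(cfg) + 1L
  rn <- function(r, c) matrix(stats::rnorm(r * c, sd = 1 / sqrt(r)), r, c)
  sm <- function(r, c) matrix(stats::rnorm(r * c, sd = 0.02), r, c)
  p <- with_seed(cfg$seed, {
    p <- list(patch_w = rn(P2, D), patch_b = numeric(D),
              cls = sm(1, D), pos = sm(Tn, D))
    for (l in seq_len(cfg$depth)) {
      b <- list(ln1_g = rep(1, D), ln1_b = numeric(D),
                wq = rn(D, D), bq = numeric(D), wk = rn(D, D), bk = numeric(D),
                wv = rn(D, D), bv = numeric(D), wo = rn(D, D), bo = numeric(D),
                ln2_g = rep(1, D), ln2_b = numeric(D),
                w1 = rn(D, H), b1 = numeric(H), w2 = rn(H, D), b2 = numeric(D))
      names(b) <- sprintf("b%d.%s", l, names(b))
      p <- c(p, b)
    }
    # small-scale head init keeps the initial loss at the ln(2) chance level
    c(p, list(lnf_g = rep(1, D), lnf_b = numeric(D),
              head_w = sm(D, cfg$n_classes), head_b = numeric(cfg$n_classes)))
  })
  structure(p, class = "vit_params")
}

#' Closed-form parameter count for a configuration
#'
#' @param cfg A [vit_config()].
#' @return Integer number of scalar parameters.
#' @export
vit_param_count <- function(cfg) {
  D <- cfg$embed_dim; P2 <- cfg$patch_side^2; H <- cfg$mlp_ratio * D
  Tn <- n_patches(cfg) + 1L; C <- cfg$n_classes
  per_block <- 2 * D + 4 * (D * D + D) + 2 * D + (D * H + H) + (H * D + D)
  (P2 * D + D) + D + Tn * D + cfg$depth * per_block + 2 * D + (D * C + C)
}

# Add a per-column constant to every row (bias add without sweep()'s
# aperm overhead; relies on column-major recycling).
row_add <- function(x, b) x + rep(b, each = nrow(x))
row_mul <- function(x, g) x * rep(g, each = nrow(x))

layernorm_fwd <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = row_add(row_mul(xhat, g), b), xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, cache, g) {
  dxhat <- row_mul(dy, g)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) -
                       cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

softmax_rows <- function(x) {
  rmax <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - rmax)
  e / rowSums(e)
}

gelu <- function(x) x * stats::pnorm(x)
# derivative given x and cached Phi = pnorm(x)
gelu_grad_cached <- function(x, Phi) Phi + x * exp(-0.5 * x * x) / sqrt(2 * pi)
gelu_grad <- function(x) gelu_grad_cached(x, stats::pnorm(x))

# Core forward pass on a pre-patchified batch.
# Xp: (B*np) x patch^2. Returns logits/probs plus caches for backprop.
vit_forward_core <- function(params, Xp, B, cfg, keep_cache = FALSE,
                             keep_attn = FALSE, pos_scale = 1) {
  D <- cfg$embed_dim; np <- n_patches(cfg); Tn <- np + 1L
  dh <- D %/% cfg$heads; scale <- 1 / sqrt(dh)
  # standard image normalization: recentre [0,1] intensities to [-1,1]
  emb <- row_add((2 * Xp - 1) %*% params$patch_w, params$patch_b)
  X <- matrix(0, B * Tn, D)
  cls_rows <- (seq_len(B) - 1L) * Tn + 1L
  X[cls_rows, ] <- matrix(params$cls, B, D, byrow = TRUE)
  X[-cls_rows, ] <- emb
  X <- X + pos_scale * params$pos[rep(seq_len(Tn), B), , drop = FALSE]

  cache <- if (keep_cache) list(Xp = Xp, B = B) else NULL
  attn_all <- if (keep_attn) vector("list", cfg$depth) else NULL
  blocks <- vector("list", cfg$depth)

  for (l in seq_len(cfg$depth)) {
    pn <- function(nm) params[[sprintf("b%d.%s", l, nm)]]
    blk <- list(X_in = X)
    ln1 <- layernorm_fwd(X, pn("ln1_g"), pn("ln1_b"))
    Q <- row_add(ln1$y %*% pn("wq"), pn("bq"))
    K <- row_add(ln1$y %*% pn("wk"), pn("bk"))
    V <- row_add(ln1$y %*% pn("wv"), pn("bv"))
    O <- matrix(0, B * Tn, D)
    A_list <- vector("list", B)
    for (b in seq_len(B)) {
      rb <- ((b - 1L) * Tn + 1L):(b * Tn)
      A_heads <- vector("list", cfg$heads)
      for (h in seq_len(cfg$heads)) {
        chc <- ((h - 1L) * dh + 1L):(h * dh)
        Qh <- Q[rb, chc, drop = FALSE]
        Kh <- K[rb, chc, drop = FALSE]
        A <- softmax_rows(Qh %*% t(Kh) * scale)
        if (!all(is.finite(A))) {
          stopf("non-finite attention weights in block %d", l)
        }
        O[rb, chc] <- A %*% V[rb, chc, drop = FALSE]
        A_heads[[h]] <- A
      }
      A_list[[b]] <- A_heads
    }
    attn_out <- row_add(O %*% pn("wo"), pn("bo"))
    X <- X + attn_out
    ln2 <- layernorm_fwd(X, pn("ln2_g"), pn("ln2_b"))
    H1 <- row_add(ln2$y %*% pn("w1"), pn("b1"))
    Phi <- stats::pnorm(H1)
    Hg <- H1 * Phi
    mlp_out <- row_add(Hg %*% pn("w2"), pn("b2"))
    X_mid <- X
    X <- X + mlp_out
    if (!all(is.finite(X))) stopf("non-finite activations after block %d", l)
    if (keep_cache) {
      blk$ln1 <- ln1; blk$Q <- Q; blk$K <- K; blk$V <- V; blk$O <- O
      blk$A <- A_list; blk$X_mid <- X_mid; blk$ln2 <- ln2
      blk$H1 <- H1; blk$Hg <- Hg; blk$Phi <- Phi
      blocks[[l]] <- blk
    }
    if (keep_attn) attn_all[[l]] <- A_list
  }
  lnf <- layernorm_fwd(X, params$lnf_g, params$lnf_b)
  cls_out <- lnf$y[cls_rows, , drop = FALSE]
  logits <- row_add(cls_out %*% params$head_w, params$head_b)
  probs <- softmax_rows(logits)
  if (keep_cache) {
    cache$blocks <- blocks; cache$lnf <- lnf; cache$cls_rows <- cls_rows
    cache$X_final <- X
  }
  list(logits = logits, probs = probs, cache = cache, attention = attn_all)
}

# Full backward pass; returns gradients as a flat list parallel to params.
vit_backward_core <- function(params, fwd, y_onehot, cfg) {
  cache <- fwd$cache
  B <- cache$B; D <- cfg$embed_dim; Tn <- n_patches(cfg) + 1L
  dh <- D %/% cfg$heads; scale <- 1 / sqrt(dh)
  cls_rows <- cache$cls_rows
  grads <- list()

  dlogits <- (fwd$probs - y_onehot) / B
  cls_out <- cache$lnf$y[cls_rows, , drop = FALSE]
  grads$head_w <- crossprod(cls_out, dlogits)
  grads$head_b <- colSums(dlogits)
  d_lnf_y <- matrix(0, B * Tn, D)
  d_lnf_y[cls_rows, ] <- dlogits %*% t(params$head_w)
  bw <- layernorm_bwd(d_lnf_y, cache$lnf, params$lnf_g)
  grads$lnf_g <- bw$dg; grads$lnf_b <- bw$db
  dX <- bw$dx

  for (l in rev(seq_len(cfg$depth))) {
    pn <- function(nm) params[[sprintf("b%d.%s", l, nm)]]
    gn <- function(nm) sprintf("b%d.%s", l, nm)
    blk <- cache$blocks[[l]]

    # MLP branch: X = X_mid + gelu(LN2(X_mid) W1 + b1) W2 + b2
    d_mlp_out <- dX
    grads[[gn("w2")]] <- crossprod(blk$Hg, d_mlp_out)
    grads[[gn("b2")]] <- colSums(d_mlp_out)
    dHg <- d_mlp_out %*% t(pn("w2"))
    dH1 <- dHg * gelu_grad_cached(blk$H1, blk$Phi)
    grads[[gn("w1")]] <- crossprod(blk$ln2$y, dH1)
    grads[[gn("b1")]] <- colSums(dH1)
    d_ln2_y <- dH1 %*% t(pn("w1"))
    bw2 <- layernorm_bwd(d_ln2_y, blk$ln2, pn("ln2_g"))
    grads[[gn("ln2_g")]] <- bw2$dg; grads[[gn("ln2_b")]] <- bw2$db
    dX <- dX + bw2$dx   # residual

    # Attention branch: X_mid = X_in + (O wo + bo)
    d_attn_out <- dX
    grads[[gn("wo")]] <- crossprod(blk$O, d_attn_out)
    grads[[gn("bo")]] <- colSums(d_attn_out)
    dO <- d_attn_out %*% t(pn("wo"))
    dQ <- matrix(0, B * Tn, D); dK <- matrix(0, B * Tn, D)
    dV <- matrix(0, B * Tn, D)
    for (b in seq_len(B)) {
      rb <- ((b - 1L) * Tn + 1L):(b * Tn)
      for (h in seq_len(cfg$heads)) {
        chc <- ((h - 1L) * dh + 1L):(h * dh)
        A <- blk$A[[b]][[h]]
        dOh <- dO[rb, chc, drop = FALSE]
        Vh <- blk$V[rb, chc, drop = FALSE]
        dA <- dOh %*% t(Vh)
        dV[rb, chc] <- crossprod(A, dOh)
        dS <- A * (dA - rowSums(dA * A))
        dQ[rb, chc] <- dS %*% blk$K[rb, chc, drop = FALSE] * scale
        dK[rb, chc] <- crossprod(dS, blk$Q[rb, chc, drop = FALSE]) * scale
      }
    }
    ln1y <- blk$ln1$y
    grads[[gn("wq")]] <- crossprod(ln1y, dQ); grads[[gn("bq")]] <- colSums(dQ)
    grads[[gn("wk")]] <- crossprod(ln1y, dK); grads[[gn("bk")]] <- colSums(dK)
    grads[[gn("wv")]] <- crossprod(ln1y, dV); grads[[gn("bv")]] <- colSums(dV)
    d_ln1_y <- dQ %*% t(pn("wq")) + dK %*% t(pn("wk")) + dV %*% t(pn("wv"))
    bw1 <- layernorm_bwd(d_ln1_y, blk$ln1, pn("ln1_g"))
    grads[[gn("ln1_g")]] <- bw1$dg; grads[[gn("ln1_b")]] <- bw1$db
    dX <- dX + bw1$dx   # residual
  }

  # embedding stage
  grads$pos <- rowsum(dX, rep(seq_len(Tn), B))
  dimnames(grads$pos) <- NULL
  grads$cls <- matrix(colSums(dX[cls_rows, , drop = FALSE]), 1, D)
  demb <- dX[-cls_rows, , drop = FALSE]
  grads$patch_w <- crossprod(2 * cache$Xp - 1, demb)
  grads$patch_b <- colSums(demb)
  grads
}

labels_to_int <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels))
  ifelse(labels == "delirium", 1L, 0L)
}

image_labels <- function(images) {
  vapply(images, function(im) im$source$label %||% NA_character_, "")
}

#' Forward pass: class probabilities for a batch of images
#'
#' @param params A `vit_params` list from [vit_init()] or [vit_train()].
#' @param images List of `wave_image` (or bare matrices) of the configured
#'   side.
#' @param cfg The matching [vit_config()].
#' @param return_attention Also return per-block, per-image, per-head
#'   attention weight matrices.
#' @return Matrix `B x n_classes` of probabilities (rows sum to 1), with
#'   attribute `"attention"` when requested.
#' @export
vit_forward <- function(params, images, cfg, return_attention = FALSE) {
  Xp <- stack_patches(images, cfg)
  fwd <- vit_forward_core(params, Xp, length(images), cfg,
                          keep_attn = return_attention)
  out <- fwd$probs
  if (return_attention) attr(out, "attention") <- fwd$attention
  out
}

#' Train the Vision Transformer
#'
#' Cross-entropy loss minimised with Adam (beta1 0.9, beta2 0.999) over
#' shuffled mini-batches. The run is a deterministic function of
#' `(images, labels, cfg)`: initialisation and shuffling use `cfg$seed`.
#' After each epoch the loss and the training accuracy are recorded from a
#' fresh forward pass over the full training set.
#'
#' @param images List of `wave_image`s.
#' @param cfg A [vit_config()].
#' @param labels Optional labels (character `"delirium"`/`"control"` or
#'   0/1 integers with delirium = 1); defaults to each image's provenance
#'   label.
#' @return List with `params` (`vit_params`), `trace` (data.frame epoch /
#'   loss / train_accuracy) and `cfg`.
#' @export
vit_train <- function(images, cfg, labels = NULL) {
  if (is.null(labels)) labels <- image_labels(images)
  y <- labels_to_int(labels)
  if (anyNA(y)) stopf("training images carry missing labels")
  if (length(unique(y)) < 2) stopf("training set must contain both classes")
  if (min(table(y)) < 2) stopf("need at least 2 examples per class")
  N <- length(images)
  Xp_all <- stack_patches(images, cfg)
  np <- n_patches(cfg)
  Y <- matrix(0, N, cfg$n_classes); Y[cbind(seq_len(N), y + 1L)] <- 1

  params <- vit_init(cfg)
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  step <- 0L
  lr <- cfg$learning_rate; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- data.frame(epoch = integer(), loss = numeric(),
                      train_accuracy = numeric())

  eval_full <- function() {
    # batched evaluation of loss/accuracy on the training set
    tot_loss <- 0; n_correct <- 0L
    for (start in seq(1L, N, by = cfg$batch_size)) {
      idx <- start:min(start + cfg$batch_size - 1L, N)
      rows <- as.vector(outer(seq_len(np), (idx - 1L) * np, `+`))
      fwd <- vit_forward_core(params, Xp_all[rows, , drop = FALSE],
                              length(idx), cfg)
      p_true <- fwd$probs[cbind(seq_along(idx), y[idx] + 1L)]
      tot_loss <- tot_loss - sum(log(pmax(p_true, 1e-12)))
      pred <- max.col(fwd$probs, ties.method = "first") - 1L
      n_correct <- n_correct + sum(pred == y[idx])
    }
    c(loss = tot_loss / N, acc = n_correct / N)
  }

  with_seed(cfg$seed, {
    params <- vit_init(cfg)   # init under the managed RNG stream
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(N)
      for (start in seq(1L, N, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, N)]
        rows <- as.vector(outer(seq_len(np), (idx - 1L) * np, `+`))
        fwd <- vit_forward_core(params, Xp_all[rows, , drop = FALSE],
                                length(idx), cfg, keep_cache = TRUE)
        grads <- vit_backward_core(params, fwd,
                                   Y[idx, , drop = FALSE], cfg)
        step <- step + 1L
        corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
        for (nm in names(params)) {
          g <- grads[[nm]]
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g * g
          params[[nm]] <- params[[nm]] -
            lr * (m[[nm]] / corr1) / (sqrt(v[[nm]] / corr2) + eps)
        }
      }
      ev <- eval_full()
      trace <- rbind(trace, data.frame(epoch = ep, loss = ev[["loss"]],
                                       train_accuracy = ev[["acc"]]))
    }
  })
  list(params = structure(params, class = "vit_params"),
       trace = trace, cfg = cfg)
}

#' Predict labels for wave images
#'
#' Argmax of the forward probabilities; exact ties are broken toward the
#' negative (control) class and flagged.
#'
#' @param fit Either the list returned by [vit_train()] or a `vit_params`
#'   object (then `cfg` must be given).
#' @param images List of `wave_image`s.
#' @param cfg A [vit_config()]; taken from `fit` when omitted.
#' @return List with integer `labels` (1 = delirium), character
#'   `class` labels, `probs` matrix, and logical `tie` flags.
#' @export
vit_predict <- function(fit, images, cfg = NULL) {
  if (is.list(fit) && !is.null(fit$params)) {
    params <- fit$params; cfg <- cfg %||% fit$cfg
  } else {
    params <- fit
    if (is.null(cfg)) stopf("cfg must be supplied with bare parameters")
  }
  probs <- vit_forward(params, images, cfg)
  tie <- abs(probs[, 2] - probs[, 1]) < 1e-12
  labels <- as.integer(probs[, 2] > probs[, 1] & !tie)
  if (any(tie)) {
    message(sprintf("%d tied prediction(s) broken toward the control class",
                    sum(tie)))
  }
  list(labels = labels, class = ifelse(labels == 1L, "delirium", "control"),
       probs = probs, tie = tie)
}

#' Serialize / restore a trained model
#'
#' Parameters go to a single portable binary (RDS); the configuration and
#' training trace go to a JSON sidecar next to it.
#'
#' @param fit Result of [vit_train()].
#' @param path Path of the binary parameter file (`.rds`).
#' @return `vit_save` invisibly returns `path`; `vit_load` returns a list
#'   with `params`, `cfg`, `trace`.
#' @export
vit_save <- function(fit, path) {
  saveRDS(fit$params, path)
  sidecar <- list(config = fit$cfg[setdiff(names(fit$cfg), NULL)],
                  trace = fit$trace)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname vit_save
#' @export
vit_load <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- do.call(vit_config, side$config)
  list(params = structure(readRDS(path), class = "vit_params"),
       cfg = cfg, trace = side$trace)
}
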