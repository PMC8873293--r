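#' Model architecture configuration
#'
#' Describes the dual-branch 3D U-Net: a shared encoder-decoder whose final
#' feature map feeds two 1x1x1 heads, one predicting the liver outer
#' boundary (sigmoid) and one the 9-class voxelwise segment probabilities
#' (softmax over background + S1..S8).
#'
#' @param base_channels channels at the first resolution level; doubled at
#'   each deeper level.
#' @param depth number of resolution levels (>= 2).
#' @param num_classes always 9 (background + 8 Couinaud segments).
#' @param boundary_head logical; include the auxiliary boundary branch.
#' @param norm logical; include batch-normalization layers.
#' @return a `model_config` list.
#' @export
model_config <- function(base_channels = 16L, depth = 4L, num_classes = 9L,
                         boundary_head = TRUE, norm = TRUE) {
  stopifnot(depth >= 2L, num_classes == 9L, base_channels >= 1L)
  structure(list(base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 num_classes = as.integer(num_classes),
                 boundary_head = isTRUE(boundary_head),
                 norm = isTRUE(norm)),
            class = "model_config")
}

#' Training configuration
#'
#' Defaults follow the reference schedule: SGD, initial learning rate 1e-3
#' decayed by 0.1 every 50 epochs, batch size 8, 150 epochs, Dice loss on
#' both heads with equal weights.
#'
#' @param lr_initial initial learning rate.
#' @param lr_decay_factor multiplicative decay.
#' @param lr_decay_every_epochs epochs between decays.
#' @param epochs total training epochs.
#' @param batch_size patches per SGD step.
#' @param loss_weights length-2 `(w_seg, w_boundary)`, nonnegative, not
#'   both zero.
#' @param momentum SGD momentum (0 disables).
#' @param nesterov use the Nesterov momentum update.
#' @param foreground_fraction fraction of training patches centred on a
#'   random liver voxel (the rest are uniform sliding-window offsets).
#' @param patches_per_case training patches sampled per case per epoch.
#' @param seed integer; seeds initialization and patch sampling.
#' @return a `train_config` list.
#' @export
train_config <- function(lr_initial = 1e-3, lr_decay_factor = 0.1,
                         lr_decay_every_epochs = 50L, epochs = 150L,
                         batch_size = 8L, loss_weights = c(1, 1),
                         momentum = 0.9, nesterov = TRUE,
                         foreground_fraction = 0.8,
                         patches_per_case = 2L, seed = 1L) {
  stopifnot(lr_initial > 0, epochs >= 1L, batch_size >= 1L,
            length(loss_weights) == 2L, all(loss_weights >= 0),
            sum(loss_weights) > 0, patches_per_case >= 1L)
  structure(list(lr_initial = lr_initial, lr_decay_factor = lr_decay_factor,
                 lr_decay_every_epochs = as.integer(lr_decay_every_epochs),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 loss_weights = as.numeric(loss_weights),
                 momentum = momentum, nesterov = isTRUE(nesterov),
                 foreground_fraction = foreground_fraction,
                 patches_per_case = as.integer(patches_per_case),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' `lr_initial * lr_decay_factor^floor(epoch / lr_decay_every_epochs)` with
#' 0-based epochs: 1e-3 at epoch 0, 1e-4 at epoch 50, 1e-5 at epoch 100
#' under the defaults.
#'
#' @param config a [train_config()].
#' @param epoch 0-based epoch index, `0 <= epoch < epochs`.
#' @return the learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  if (epoch < 0 || epoch >= config$epochs) {
    stop("epoch out of range [0, ", config$epochs, ")")
  }
  config$lr_initial *
    config$lr_decay_factor^(epoch %/% config$lr_decay_every_epochs)
}

level_channels <- function(config) {
  config$base_channels * 2L^(seq_len(config$depth) - 1L)
}

layer_specs <- function(config) {
  ch <- level_channels(config)
  specs <- list()
  for (i in seq_len(config$depth)) {
    cin <- if (i == 1L) 1L else ch[i - 1L]
    specs[[paste0("enc", i, "_1")]] <- c(cin, ch[i])
    specs[[paste0("enc", i, "_2")]] <- c(ch[i], ch[i])
  }
  for (i in rev(seq_len(config$depth - 1L))) {
    # a 1x1 up-projection halves the upsampled channels before the concat
    specs[[paste0("dec", i, "_1")]] <- c(2L * ch[i], ch[i])
    specs[[paste0("dec", i, "_2")]] <- c(ch[i], ch[i])
  }
  specs
}

#' Build (initialize) the network
#'
#' Creates the parameter set of the dual-branch 3D U-Net with seeded He
#' initialization. Two builds with the same seed are identical.
#'
#' @param config a [model_config()].
#' @param seed integer seed for the initial parameters.
#' @return a `unet3d` handle: list with `params`, `state` (normalization
#'   running moments) and `config`.
#' @export
build_network <- function(config, seed = 1L) {
  with_seed(seed, {
    specs <- layer_specs(config)
    params <- list()
    state <- list()
    for (nm in names(specs)) {
      cin <- specs[[nm]][1]; cout <- specs[[nm]][2]
      params[[nm]] <- list(W = he_init(cout, cin, 3L), b = numeric(cout),
                           gamma = rep(1, cout), beta = numeric(cout))
      state[[nm]] <- list(rm = numeric(cout), rv = rep(1, cout))
    }
    ch <- level_channels(config)
    for (i in rev(seq_len(config$depth - 1L))) {
      params[[paste0("up", i)]] <- list(W = he_init(ch[i], ch[i + 1L], 1L),
                                        b = numeric(ch[i]))
    }
    ch1 <- config$base_channels
    params$head_seg <- list(W = he_init(config$num_classes, ch1, 1L),
                            b = numeric(config$num_classes))
    if (config$boundary_head) {
      params$head_bnd <- list(W = he_init(1L, ch1, 1L), b = numeric(1L))
    }
    structure(list(params = params, state = state, config = config),
              class = "unet3d")
  })
}

#' @export
print.unet3d <- function(x, ...) {
  np <- sum(vapply(unlist(x$params, recursive = FALSE), length, 0L))
  cat(sprintf("<unet3d> depth %d, base %d channels, %d parameters%s\n",
              x$config$depth, x$config$base_channels, np,
              if (x$config$boundary_head) ", dual head" else ""))
  invisible(x)
}

# conv -> (bn) -> relu, with cache for backprop
cbr_fwd <- function(handle, nm, x, training) {
  p <- handle$params[[nm]]
  z <- conv_fwd(x, p$W, p$b, 3L)
  cache <- list(x = x, z = z)
  if (handle$config$norm) {
    r <- bn_fwd(z, p$gamma, p$beta, handle$state[[nm]], training)
    handle$state[[nm]] <- r$state
    cache$bn <- r$cache
    cache$pre_relu <- r$y
  } else {
    cache$pre_relu <- z
  }
  list(y = relu_fwd(cache$pre_relu), cache = cache, handle = handle)
}

cbr_bwd <- function(handle, nm, dy, cache, grads) {
  p <- handle$params[[nm]]
  dpre <- relu_bwd(dy, cache$pre_relu)
  if (handle$config$norm) {
    bb <- bn_bwd(dpre, p$gamma, cache$bn)
    grads[[nm]]$gamma <- grads[[nm]]$gamma + bb$dgamma
    grads[[nm]]$beta <- grads[[nm]]$beta + bb$dbeta
    dz <- bb$dx
  } else {
    dz <- dpre
  }
  cb <- conv_bwd(cache$x, p$W, dz, 3L)
  grads[[nm]]$W <- grads[[nm]]$W + cb$dW
  grads[[nm]]$b <- grads[[nm]]$b + cb$db
  list(dx = cb$dx, grads = grads)
}

#' Forward pass of the network
#'
#' @param handle a `unet3d` from [build_network()].
#' @param x 3D array (a z-scored patch); spatial dims must be divisible by
#'   `2^(depth - 1)`.
#' @param training logical; use per-patch normalization statistics and
#'   return a backprop cache.
#' @return list with `seg_probs` (4D, softmax over classes),
#'   `boundary_prob` (3D, sigmoid; `NULL` without the boundary head),
#'   `seg_logits`, `bnd_logits`, and (when training) `cache` and the
#'   updated `handle`.
#' @export
net_forward <- function(handle, x, training = FALSE) {
  cfg <- handle$config
  d <- dim(x)
  if (any(d[1:3] %% 2L^(cfg$depth - 1L) != 0L)) {
    stop("shape error: patch dims must be divisible by 2^(depth-1)")
  }
  h <- array(x, c(d, 1L))
  cache <- list()
  skips <- list()
  for (i in seq_len(cfg$depth)) {
    for (j in 1:2) {
      nm <- paste0("enc", i, "_", j)
      r <- cbr_fwd(handle, nm, h, training)
      handle <- r$handle
      cache[[nm]] <- r$cache
      h <- r$y
    }
    if (i < cfg$depth) {
      skips[[i]] <- h
      pr <- pool_fwd(h)
      cache[[paste0("pool", i)]] <- list(idx = pr$idx, n_in = pr$n_in,
                                         in_dim = dim(h))
      h <- pr$y
    }
  }
  for (i in rev(seq_len(cfg$depth - 1L))) {
    up_in <- upsample_fwd(h)
    pu <- handle$params[[paste0("up", i)]]
    up <- conv_fwd(up_in, pu$W, pu$b, 1L)
    cache[[paste0("up", i)]] <- up_in
    nch_up <- dim(up)[4]
    h <- array(c(up, skips[[i]]), c(dim(up)[1:3], nch_up + dim(skips[[i]])[4]))
    cache[[paste0("cat", i)]] <- nch_up
    for (j in 1:2) {
      nm <- paste0("dec", i, "_", j)
      r <- cbr_fwd(handle, nm, h, training)
      handle <- r$handle
      cache[[nm]] <- r$cache
      h <- r$y
    }
  }
  cache$features <- h
  seg_logits <- conv_fwd(h, handle$params$head_seg$W,
                         handle$params$head_seg$b, 1L)
  out <- list(seg_probs = softmax4(seg_logits), seg_logits = seg_logits,
              boundary_prob = NULL, bnd_logits = NULL)
  if (cfg$boundary_head) {
    bl <- conv_fwd(h, handle$params$head_bnd$W, handle$params$head_bnd$b, 1L)
    out$bnd_logits <- bl
    out$boundary_prob <- array(1 / (1 + exp(-bl)), d)
  }
  if (training) {
    out$cache <- cache
    out$handle <- handle
  }
  out
}

net_backward <- function(handle, cache, d_seg_logits, d_bnd_logits) {
  cfg <- handle$config
  grads <- zero_grads(handle)
  h <- cache$features
  cbs <- conv_bwd(h, handle$params$head_seg$W, d_seg_logits, 1L)
  grads$head_seg$W <- cbs$dW
  grads$head_seg$b <- cbs$db
  dh <- cbs$dx
  if (cfg$boundary_head && !is.null(d_bnd_logits)) {
    cbb <- conv_bwd(h, handle$params$head_bnd$W, d_bnd_logits, 1L)
    grads$head_bnd$W <- cbb$dW
    grads$head_bnd$b <- cbb$db
    dh <- dh + cbb$dx
  }
  dskips <- list()
  for (i in seq_len(cfg$depth - 1L)) {
    for (j in 2:1) {
      nm <- paste0("dec", i, "_", j)
      r <- cbr_bwd(handle, nm, dh, cache[[nm]], grads)
      grads <- r$grads
      dh <- r$dx
    }
    ncat <- cache[[paste0("cat", i)]]
    nch <- dim(dh)[4]
    dup <- dh[, , , seq_len(ncat), drop = FALSE]
    dskips[[i]] <- dh[, , , (ncat + 1L):nch, drop = FALSE]
    nmu <- paste0("up", i)
    cu <- conv_bwd(cache[[nmu]], handle$params[[nmu]]$W, dup, 1L)
    grads[[nmu]]$W <- cu$dW
    grads[[nmu]]$b <- cu$db
    dh <- upsample_bwd(cu$dx)
  }
  for (i in rev(seq_len(cfg$depth))) {
    if (i < cfg$depth) {
      pc <- cache[[paste0("pool", i)]]
      dh <- pool_bwd(dh, pc, pc$in_dim)
      dh <- dh + dskips[[i]]
    }
    for (j in 2:1) {
      nm <- paste0("enc", i, "_", j)
      r <- cbr_bwd(handle, nm, dh, cache[[nm]], grads)
      grads <- r$grads
      dh <- r$dx
    }
  }
  grads
}

zero_grads <- function(handle) {
  lapply(handle$params, function(p) {
    lapply(p, function(v) if (is.matrix(v)) v * 0 else numeric(length(v)))
  })
}

#' Liver boundary target
#'
#' The one-voxel-thick shell of a binary mask: the mask minus its
#' six-connected erosion. This is the supervision target of the auxiliary
#' boundary branch.
#'
#' @param liver_mask binary [vol_grid()] or 3D array.
#' @return binary array of the same shape.
#' @export
boundary_target <- function(liver_mask) {
  m <- if (inherits(liver_mask, "vol_grid")) liver_mask$data else liver_mask
  (m > 0 & !erode6(m)) * 1
}

#' Multiclass Dice loss
#'
#' `1 - mean_c (2 sum(p_c t_c) + eps) / (sum p_c + sum t_c + eps)` averaged
#' over foreground classes only (channels 2..C when C > 1; the single
#' channel of a binary problem otherwise). Classes absent from the target
#' contribute through the smoothing term rather than being skipped.
#'
#' @param pred_probs array of predicted probabilities in `[0, 1]`; last dim
#'   indexes classes when 4D.
#' @param target_onehot array of the same shape with one-hot (or binary)
#'   targets.
#' @param smooth smoothing constant eps.
#' @return scalar loss in `[0, 1]` (up to eps terms).
#' @export
dice_loss <- function(pred_probs, target_onehot, smooth = 1e-5) {
  if (!identical(dim(pred_probs), dim(target_onehot))) {
    stop("shape mismatch between prediction and target")
  }
  cls <- dice_classes(pred_probs)
  terms <- vapply(cls, function(c4) {
    p <- slice4(pred_probs, c4)
    t <- slice4(target_onehot, c4)
    (2 * sum(p * t) + smooth) / (sum(p) + sum(t) + smooth)
  }, 0)
  1 - mean(terms)
}

dice_classes <- function(a) {
  if (length(dim(a)) == 4L && dim(a)[4] > 1L) 2L:dim(a)[4] else 1L
}

slice4 <- function(a, c4) {
  if (length(dim(a)) == 4L) a[, , , c4] else a
}

# gradient of dice_loss w.r.t. pred_probs
dice_loss_grad <- function(pred_probs, target_onehot, smooth = 1e-5) {
  cls <- dice_classes(pred_probs)
  g <- array(0, dim(pred_probs))
  nc <- length(cls)
  for (c4 in cls) {
    p <- slice4(pred_probs, c4)
    t <- slice4(target_onehot, c4)
    num <- 2 * sum(p * t) + smooth
    den <- sum(p) + sum(t) + smooth
    gc <- -(2 * t * den - num) / den^2 / nc
    if (length(dim(pred_probs)) == 4L) g[, , , c4] <- gc else g <- gc
  }
  g
}

onehot_labels <- function(lab_arr, num_classes) {
  d <- dim(lab_arr)
  oh <- array(0, c(d, num_classes))
  for (c4 in seq_len(num_classes)) {
    oh[, , , c4] <- (lab_arr == c4 - 1L) * 1
  }
  oh
}

# loss and logit gradients for one patch
patch_loss_and_grads <- function(fw, lab_patch, bnd_patch, weights,
                                 num_classes, smooth = 1e-5) {
  oh <- onehot_labels(lab_patch, num_classes)
  l_seg <- dice_loss(fw$seg_probs, oh, smooth)
  gp <- dice_loss_grad(fw$seg_probs, oh, smooth)
  # backprop through the softmax
  p <- fw$seg_probs
  dp <- dim(p)
  pm <- matrix(p, ncol = dp[4])
  gm <- matrix(gp, ncol = dp[4])
  inner <- rowSums(gm * pm)
  d_seg <- array(weights[1] * pm * (gm - inner), dp)
  l_bnd <- NA_real_
  d_bnd <- NULL
  if (!is.null(fw$boundary_prob)) {
    pb <- fw$boundary_prob
    l_bnd <- dice_loss(pb, bnd_patch, smooth)
    gb <- dice_loss_grad(pb, bnd_patch, smooth)
    d_bnd <- array(weights[2] * gb * pb * (1 - pb), c(dim(pb), 1L))
  }
  list(loss_seg = l_seg, loss_bnd = l_bnd,
       loss = weights[1] * l_seg +
         (if (is.na(l_bnd)) 0 else weights[2] * l_bnd),
       d_seg = d_seg, d_bnd = d_bnd)
}

prepare_training_case <- function(case, pre_cfg) {
  img <- resample_to_spacing(case$image, pre_cfg$target_spacing_mm,
                             "linear")
  lab <- resample_to_spacing(case$labels, pre_cfg$target_spacing_mm)
  img <- clip_intensities(img, pre_cfg$clip_percentiles)
  img <- zscore_normalize(img)
  a <- img$data
  l <- lab$data
  d <- dim(a)
  ps <- pre_cfg$patch_shape
  pad_lo <- pmax(0L, as.integer(floor((ps - d) / 2)))
  pad_hi <- pmax(0L, ps - d - pad_lo)
  if (any(pad_lo + pad_hi > 0L)) {
    pa <- array(0, d + pad_lo + pad_hi)
    pl <- array(0L, d + pad_lo + pad_hi)
    ii <- Map(function(o, k) o + seq_len(k), pad_lo, d)
    pa[ii[[1]], ii[[2]], ii[[3]]] <- a
    pl[ii[[1]], ii[[2]], ii[[3]]] <- l
    a <- pa
    l <- pl
  }
  list(img = a, lab = l, bnd = boundary_target(l > 0),
       liver = which(l > 0), dim = dim(a))
}

# one training patch offset (0-based): either centred on a random liver
# voxel (clamped to the volume) or a uniform sliding-window offset
draw_offset <- function(pc, ps, fg_fraction, grid_offsets) {
  if (runif(1) < fg_fraction && length(pc$liver)) {
    v <- arrayInd(pc$liver[sample.int(length(pc$liver), 1L)], pc$dim)
    pmin(pmax(as.integer(v) - 1L - ps %/% 2L, 0L), pc$dim - ps)
  } else {
    grid_offsets[[sample.int(length(grid_offsets), 1L)]]
  }
}

#' Train the dual-branch 3D U-Net
#'
#' End-to-end SGD training with Dice loss on both heads. Patches are drawn
#' each epoch from the sliding-window grid of every case (seeded), so the
#' offsets seen in training match those used at inference. Aborts with a
#' diagnostic if the loss becomes non-finite.
#'
#' @param cases list of `phantom_case` objects or `list(image, labels)`
#'   pairs on a common spacing.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param pre_cfg a [preprocess_config()]; its `patch_shape` and overlap
#'   define the training patch grid.
#' @param verbose print per-epoch losses.
#' @param checkpoint_dir optional directory for periodic checkpoints.
#' @param checkpoint_every epochs between checkpoints.
#' @return list with the trained `handle` and `history` (data.frame of
#'   epoch, lr, loss, loss_seg, loss_boundary).
#' @export
train_segmenter <- function(cases, model_cfg, train_cfg,
                            pre_cfg = preprocess_config(),
                            verbose = FALSE, checkpoint_dir = NULL,
                            checkpoint_every = 10L) {
  stopifnot(length(cases) >= 1L)
  handle <- build_network(model_cfg, seed = train_cfg$seed)
  prepped <- lapply(cases, prepare_training_case, pre_cfg = pre_cfg)
  # common sliding-window offsets (cases share the phantom grid shape)
  sw <- sliding_window_patches(prepped[[1]]$img, pre_cfg$patch_shape,
                               pre_cfg$patch_overlap_fraction)
  offsets <- lapply(sw$patches, `[[`, "offset")
  ps <- pre_cfg$patch_shape
  vel <- zero_grads(handle)
  history <- data.frame()
  with_seed(train_cfg$seed * 7919L + 13L, {
    for (epoch in seq_len(train_cfg$epochs) - 1L) {
      lr <- lr_at_epoch(train_cfg, epoch)
      sched <- lapply(seq_along(prepped), function(ci) {
        lapply(seq_len(train_cfg$patches_per_case), function(j) {
          list(ci = ci,
               off = draw_offset(prepped[[ci]], ps,
                                 train_cfg$foreground_fraction, offsets))
        })
      })
      sched <- unlist(sched, recursive = FALSE)
      sched <- sched[sample.int(length(sched))]
      # repetition sampling when the batch exceeds the schedule
      if (length(sched) < train_cfg$batch_size) {
        sched <- sched[sample.int(length(sched), train_cfg$batch_size,
                                  replace = TRUE)]
      }
      nb <- length(sched) %/% train_cfg$batch_size
      ep_losses <- ep_seg <- ep_bnd <- c()
      for (b in seq_len(max(nb, 1L))) {
        rows <- sched[((b - 1L) * train_cfg$batch_size + 1L):
                        min(b * train_cfg$batch_size, length(sched))]
        acc <- zero_grads(handle)
        for (r in seq_along(rows)) {
          pc <- prepped[[rows[[r]]$ci]]
          off <- rows[[r]]$off
          ix <- off[1] + seq_len(ps[1]); iy <- off[2] + seq_len(ps[2])
          iz <- off[3] + seq_len(ps[3])
          fw <- net_forward(handle, pc$img[ix, iy, iz], training = TRUE)
          handle <- fw$handle
          pl <- patch_loss_and_grads(fw, pc$lab[ix, iy, iz],
                                     pc$bnd[ix, iy, iz],
                                     train_cfg$loss_weights,
                                     model_cfg$num_classes)
          if (!is.finite(pl$loss)) {
            stop("training aborted: non-finite loss at epoch ", epoch,
                 " (lr ", lr, ")")
          }
          g <- net_backward(handle, fw$cache, pl$d_seg, pl$d_bnd)
          acc <- add_grads(acc, g, 1 / length(rows))
          ep_losses <- c(ep_losses, pl$loss)
          ep_seg <- c(ep_seg, pl$loss_seg)
          ep_bnd <- c(ep_bnd, pl$loss_bnd)
        }
        upd <- sgd_update(handle$params, vel, acc, lr, train_cfg$momentum,
                          train_cfg$nesterov)
        handle$params <- upd$params
        vel <- upd$vel
      }
      history <- rbind(history, data.frame(
        epoch = epoch, lr = lr, loss = mean(ep_losses),
        loss_seg = mean(ep_seg), loss_boundary = mean(ep_bnd)))
      if (verbose) {
        message(sprintf("epoch %3d  lr %.1e  loss %.4f (seg %.4f, bnd %.4f)",
                        epoch, lr, mean(ep_losses), mean(ep_seg),
                        mean(ep_bnd)))
      }
      if (!is.null(checkpoint_dir) &&
          (epoch + 1L) %% checkpoint_every == 0L) {
        dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(list(handle = handle, epoch = epoch, history = history),
                file.path(checkpoint_dir,
                          sprintf("checkpoint_epoch%03d.rds", epoch)))
      }
    }
  })
  list(handle = handle, history = history)
}

add_grads <- function(acc, g, w) {
  for (nm in names(acc)) {
    for (f in names(acc[[nm]])) {
      acc[[nm]][[f]] <- acc[[nm]][[f]] + w * g[[nm]][[f]]
    }
  }
  acc
}

sgd_update <- function(params, vel, grads, lr, momentum,
                       nesterov = FALSE) {
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      g <- grads[[nm]][[f]]
      v <- momentum * vel[[nm]][[f]] + g
      vel[[nm]][[f]] <- v
      step <- if (nesterov) g + momentum * v else v
      params[[nm]][[f]] <- params[[nm]][[f]] - lr * step
    }
  }
  list(params = params, vel = vel)
}

#' Predict a Couinaud label map for a volume
#'
#' Full inference pipeline: resample to the target spacing, clip and
#' z-score, tile with sliding windows, run the network on each patch, fuse
#' the per-patch softmax probabilities by averaging, take the voxelwise
#' argmax, and resample the labels back to the native grid (nearest
#' neighbour).
#'
#' @param volume a [vol_grid()] image at native spacing.
#' @param handle a trained `unet3d`.
#' @param pre_cfg a [preprocess_config()].
#' @param keep_largest keep only the largest connected component of each
#'   predicted segment, reassigning stray voxels to their next most
#'   probable class (standard segmentation post-processing).
#' @return list with `labels` (a [label_map()] on the input grid) and
#'   `probs` (fused class probabilities on the preprocessed grid).
#' @export
predict_segments <- function(volume, handle, pre_cfg = preprocess_config(),
                             keep_largest = TRUE) {
  rs <- resample_to_spacing(volume, pre_cfg$target_spacing_mm, "linear")
  img <- zscore_normalize(clip_intensities(rs, pre_cfg$clip_percentiles))
  sw <- sliding_window_patches(img$data, pre_cfg$patch_shape,
                               pre_cfg$patch_overlap_fraction)
  preds <- lapply(sw$patches, function(p) {
    fw <- net_forward(handle, p$data, training = FALSE)
    list(probs = fw$seg_probs, offset = p$offset)
  })
  fused <- fuse_patch_predictions(preds, sw$padded_dim)
  nc <- dim(fused)[4]
  # crop symmetric padding back to the preprocessed grid, then resample
  # the class probabilities (trilinear) to the native grid before the
  # argmax, which avoids nearest-neighbour quantization of the boundaries
  d <- dim(img$data)
  nd <- dim(volume$data)
  native_probs <- matrix(0, prod(nd), nc)
  for (c4 in seq_len(nc)) {
    pc <- fused[sw$pad[1] + seq_len(d[1]), sw$pad[2] + seq_len(d[2]),
                sw$pad[3] + seq_len(d[3]), c4]
    pv <- vol_grid(array(pc, d), img$spacing, img$origin)
    native_probs[, c4] <- resample_onto(pv, nd, volume$spacing,
                                        volume$origin, "linear")
  }
  lab <- array(max.col(native_probs, ties.method = "first") - 1L, nd)
  if (keep_largest) {
    lab <- keep_largest_components(lab, native_probs)
  }
  list(labels = label_map(lab, volume$spacing, volume$origin),
       probs = fused)
}

# Keep the largest 26-connected component per foreground class; stray
# voxels move to their next most probable class (repeated until stable
# or a bounded number of sweeps).
keep_largest_components <- function(lab, probs, max_sweeps = 3L) {
  nd <- dim(lab)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (cls in 1:8) {
      comp <- label_components(lab == cls, 26L)
      ncomp <- max(comp)
      if (ncomp <= 1L) next
      sizes <- tabulate(comp[comp > 0], ncomp)
      drop <- which(comp > 0 & comp != which.max(sizes))
      if (!length(drop)) next
      changed <- TRUE
      p <- probs[drop, , drop = FALSE]
      p[, cls + 1L] <- -Inf
      lab[drop] <- max.col(p, ties.method = "first") - 1L
    }
    if (!changed) break
  }
  array(lab, nd)
}
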