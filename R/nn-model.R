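#' Network configuration
#'
#' Describes the bottleneck residual network and its training settings. The
#' backbone has four stages of bottleneck units (1x1 reduce, 3x3, 1x1
#' expand, each convolution followed by batch normalization and ReLU); the
#' first unit of stages 2-4 downsamples with stride 2 and a projection skip
#' path, every other unit carries an identity skip. A strided stem
#' convolution plus max pooling maps the single-channel probes-x-d input
#' into the first stage; global average pooling and a linear head of width
#' `num_classes` close the network.
#'
#' Defaults: Adam at learning rate
#' 1e-5, batch size 16, early stopping after 10 epochs without validation
#' improvement, class weighting off. [network_config_resnet101()] is the
#' full-scale ResNet-101 preset (blocks `[3, 4, 23, 3]`, stage widths 64/128/256/512
#' with expansion 4 — the stage-4 bottleneck then reduces 1024 channels to
#' 512 and expands to 2048); tests and laptop-scale work use far narrower
#' settings.
#'
#' @param block_counts Integer vector of 4 bottleneck-unit counts.
#' @param input_shape Length-2 integer vector `(probes, d)`.
#' @param num_classes Number of output classes `C`.
#' @param stem_channels Channels out of the stem convolution.
#' @param base_width Inner (reduced) width of stage 1; stage `i` uses
#'   `base_width * 2^(i-1)`.
#' @param expansion Output-width multiplier of each bottleneck unit.
#' @param freeze_blocks Stages (counted from the input, stem included with
#'   stage 1) held fixed during fine-tuning, 0-4.
#' @param learning_rate,batch_size,patience,max_epochs Adam step size,
#'   minibatch size, early-stopping patience (epochs), epoch cap.
#' @param val_fraction Stratified fraction of the training data held out
#'   for early stopping.
#' @param seed Integer seed for initialization and training order.
#' @param class_weighting Weight the loss by inverse class frequency
#'   (`N_total / N_c`, normalized to mean 1)?
#' @return A `network_config` list.
#' @export
network_config <- function(block_counts = c(1, 1, 1, 1),
                           input_shape = c(200, 8),
                           num_classes = 2,
                           stem_channels = 8,
                           base_width = 4,
                           expansion = 2,
                           freeze_blocks = 2,
                           learning_rate = 1e-5,
                           batch_size = 16,
                           patience = 10,
                           max_epochs = 100,
                           val_fraction = 0.1,
                           seed = 1,
                           class_weighting = FALSE) {
  block_counts <- as.integer(block_counts)
  if (length(block_counts) != 4 || any(block_counts < 1)) {
    abort_mt("block_counts must be 4 positive integers.", "construction_error")
  }
  if (freeze_blocks < 0 || freeze_blocks > 4) {
    abort_mt("freeze_blocks must lie in 0..4.", "construction_error")
  }
  if (learning_rate <= 0) abort_mt("learning_rate must be positive.", "construction_error")
  structure(
    list(block_counts = block_counts, input_shape = as.integer(input_shape),
         num_classes = as.integer(num_classes),
         stem_channels = as.integer(stem_channels),
         base_width = as.integer(base_width), expansion = as.integer(expansion),
         freeze_blocks = as.integer(freeze_blocks),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         patience = as.integer(patience), max_epochs = as.integer(max_epochs),
         val_fraction = val_fraction, seed = as.integer(seed),
         class_weighting = isTRUE(class_weighting)),
    class = "network_config"
  )
}

#' @rdname network_config
#' @param ... Overrides passed on to [network_config()].
#' @export
network_config_resnet101 <- function(...) {
  args <- list(...)
  defaults <- list(block_counts = c(3, 4, 23, 3), stem_channels = 64,
                   base_width = 64, expansion = 4, input_shape = c(6585, 128),
                   learning_rate = 1e-5, batch_size = 16, patience = 10)
  do.call(network_config, utils::modifyList(defaults, args))
}

## Module naming: stem.conv, stem.bn, s{i}.u{j}.{conv1,bn1,conv2,bn2,conv3,bn3,
## dsconv,dsbn}, head.fc. Stage of a module drives the freezing contract.

module_stage <- function(name) {
  if (startsWith(name, "stem")) return(0L)
  if (startsWith(name, "head")) return(5L)
  as.integer(substr(name, 2, 2))
}

#' Build an untrained bottleneck residual network
#'
#' Constructs the network described by a [network_config()] with seeded
#' He-normal initialization, so identical seeds give bit-identical initial
#' parameters. See [network_config()] for the architecture.
#'
#' @param cfg A [network_config()].
#' @param class_names Optional ordered label vocabulary (length
#'   `num_classes`); defaults to `class1..classC`.
#' @return A `trained_model` object (untrained): module list, config, label
#'   vocabulary, empty training log.
#' @export
build_network <- function(cfg, class_names = NULL) {
  stopifnot(inherits(cfg, "network_config"))
  if (is.null(class_names)) {
    class_names <- paste0("class", seq_len(cfg$num_classes))
  }
  if (length(class_names) != cfg$num_classes) {
    abort_mt("class_names length must equal num_classes.", "construction_error")
  }
  with_seed(cfg$seed, {
    mods <- list()
    mods[["stem.conv"]] <- new_conv(1L, cfg$stem_channels, 3L, 3L, 2L, 1L)
    mods[["stem.bn"]] <- new_bn(cfg$stem_channels)
    mods[["stem.pool"]] <- new_maxpool(3L, 3L, 2L, 1L)
    cin <- cfg$stem_channels
    units <- list()
    for (i in 1:4) {
      w <- cfg$base_width * 2L^(i - 1L)
      cout <- w * cfg$expansion
      for (j in seq_len(cfg$block_counts[i])) {
        stride <- if (i > 1 && j == 1) 2L else 1L
        has_ds <- (j == 1) && (stride > 1L || cin != cout)
        pre <- sprintf("s%d.u%d", i, j)
        mods[[paste0(pre, ".conv1")]] <- new_conv(cin, w, 1L, 1L, 1L, 0L)
        mods[[paste0(pre, ".bn1")]] <- new_bn(w)
        mods[[paste0(pre, ".conv2")]] <- new_conv(w, w, 3L, 3L, stride, 1L)
        mods[[paste0(pre, ".bn2")]] <- new_bn(w)
        mods[[paste0(pre, ".conv3")]] <- new_conv(w, cout, 1L, 1L, 1L, 0L)
        mods[[paste0(pre, ".bn3")]] <- new_bn(cout)
        if (has_ds) {
          mods[[paste0(pre, ".dsconv")]] <- new_conv(cin, cout, 1L, 1L, stride, 0L)
          mods[[paste0(pre, ".dsbn")]] <- new_bn(cout)
        }
        units[[length(units) + 1]] <- list(stage = i, unit = j, prefix = pre,
                                           stride = stride, has_ds = has_ds)
        cin <- cout
      }
    }
    mods[["head.fc"]] <- new_dense(cin, cfg$num_classes)
    structure(
      list(modules = mods, units = units, cfg = cfg,
           class_names = class_names, feature_dim = cin,
           training_log = tibble::tibble(), geom = new.env(parent = emptyenv()),
           trained = FALSE),
      class = "trained_model"
    )
  })
}

#' @export
print.trained_model <- function(x, ...) {
  np <- sum(vapply(x$modules, function(m) {
    sum(vapply(m$params, length, numeric(1)))
  }, numeric(1)))
  cat(sprintf(
    "<trained_model> bottleneck residual net: blocks [%s], input %dx%d, %d classes, %s params%s\n",
    paste(x$cfg$block_counts, collapse = ","), x$cfg$input_shape[1],
    x$cfg$input_shape[2], x$cfg$num_classes, format(np, big.mark = ","),
    if (x$trained) sprintf(", trained %d epochs", nrow(x$training_log)) else " (untrained)"
  ))
  invisible(x)
}

# Forward pass. x: array (N, H, W, 1). Returns logits, pooled features,
# the updated model (BN running stats move in train mode), and (optionally)
# caches for backprop.
model_forward <- function(model, x, train = FALSE, need_cache = FALSE) {
  mods <- model$modules
  caches <- if (need_cache) list() else NULL
  run_conv <- function(name, x) {
    ly <- mods[[name]]
    d <- dim(x)
    g <- get_geom(model, name, d[2], d[3], d[4], ly$kh, ly$kw, ly$stride, ly$pad)
    out <- conv_forward(ly, x, g)
    if (need_cache) caches[[name]] <<- out$cache
    out$y
  }
  run_bn <- function(name, x) {
    out <- bn_forward(mods[[name]], x, train)
    mods[[name]] <<- out$layer
    if (need_cache) caches[[name]] <<- out$cache
    out$y
  }
  run_relu <- function(name, x) {
    out <- relu_forward(x)
    if (need_cache) caches[[name]] <<- out$cache
    out$y
  }
  h <- run_conv("stem.conv", x)
  h <- run_bn("stem.bn", h)
  h <- run_relu("stem.relu", h)
  ply <- mods[["stem.pool"]]
  d <- dim(h)
  g <- get_geom(model, "stem.pool", d[2], d[3], d[4], ply$kh, ply$kw, ply$stride, ply$pad)
  pout <- maxpool_forward(ply, h, g)
  if (need_cache) caches[["stem.pool"]] <- pout$cache
  h <- pout$y
  for (u in model$units) {
    p <- u$prefix
    identity <- h
    r <- run_conv(paste0(p, ".conv1"), h)
    r <- run_bn(paste0(p, ".bn1"), r)
    r <- run_relu(paste0(p, ".relu1"), r)
    r <- run_conv(paste0(p, ".conv2"), r)
    r <- run_bn(paste0(p, ".bn2"), r)
    r <- run_relu(paste0(p, ".relu2"), r)
    r <- run_conv(paste0(p, ".conv3"), r)
    r <- run_bn(paste0(p, ".bn3"), r)
    if (u$has_ds) {
      identity <- run_conv(paste0(p, ".dsconv"), identity)
      identity <- run_bn(paste0(p, ".dsbn"), identity)
    }
    h <- r + identity
    h <- run_relu(paste0(p, ".reluout"), h)
  }
  gout <- gap_forward(h)
  if (need_cache) caches[["gap"]] <- gout$cache
  pooled <- gout$y
  fout <- dense_forward(mods[["head.fc"]], pooled)
  if (need_cache) caches[["head.fc"]] <- fout$cache
  model$modules <- mods
  list(model = model, logits = fout$y, pooled = pooled, caches = caches)
}

# Backward pass from dlogits. Returns param grads (flat list keyed
# "module.param") and optionally the input gradient. Stages whose modules
# are all frozen are skipped entirely once no downstream consumer needs
# their dx (unless need_input_grad).
model_backward <- function(model, caches, dlogits, need_input_grad = FALSE) {
  mods <- model$modules
  grads <- list()
  fb <- dense_backward(mods[["head.fc"]], caches[["head.fc"]], dlogits,
                       want_dw = !isTRUE(mods[["head.fc"]]$frozen))
  if (!is.null(fb$grads)) {
    grads[["head.fc.W"]] <- fb$grads$W
    grads[["head.fc.b"]] <- fb$grads$b
  }
  dh <- gap_backward(caches[["gap"]], fb$dx)
  bconv <- function(name, dy, want_dx = TRUE) {
    ly <- mods[[name]]
    g <- model$geom[[name]]
    fro <- isTRUE(ly$frozen)
    out <- conv_backward(ly, caches[[name]], dy, g, want_dw = !fro, want_dx = want_dx)
    if (!is.null(out$grads)) grads[[paste0(name, ".W")]] <<- out$grads$W
    out$dx
  }
  bbn <- function(name, dy, want_dx = TRUE) {
    ly <- mods[[name]]
    fro <- isTRUE(ly$frozen)
    out <- bn_backward(ly, caches[[name]], dy, want_dw = !fro, want_dx = want_dx)
    if (!is.null(out$grads)) {
      grads[[paste0(name, ".gamma")]] <<- out$grads$gamma
      grads[[paste0(name, ".beta")]] <<- out$grads$beta
    }
    out$dx
  }
  # deepest frozen stage below which backprop can stop (stem freezes with
  # stage 1, so any freeze_blocks >= 1 also covers the stem)
  fb_n <- model$cfg$freeze_blocks
  frozen_active <- isTRUE(model$frozen_active)
  stop_below <- if (frozen_active && fb_n >= 1L && !need_input_grad) fb_n else -1L
  for (ui in rev(seq_along(model$units))) {
    u <- model$units[[ui]]
    if (u$stage <= stop_below) break
    p <- u$prefix
    dh <- relu_backward(caches[[paste0(p, ".reluout")]], dh)
    d_identity <- dh
    dr <- bbn(paste0(p, ".bn3"), dh)
    dr <- bconv(paste0(p, ".conv3"), dr)
    dr <- relu_backward(caches[[paste0(p, ".relu2")]], dr)
    dr <- bbn(paste0(p, ".bn2"), dr)
    dr <- bconv(paste0(p, ".conv2"), dr)
    dr <- relu_backward(caches[[paste0(p, ".relu1")]], dr)
    dr <- bbn(paste0(p, ".bn1"), dr)
    # the unit's input feeds conv1 and the skip path
    dr <- bconv(paste0(p, ".conv1"), dr)
    if (u$has_ds) {
      dds <- bbn(paste0(p, ".dsbn"), d_identity)
      dds <- bconv(paste0(p, ".dsconv"), dds)
      dh <- dr + dds
    } else {
      dh <- dr + d_identity
    }
  }
  dx <- NULL
  if (0L > stop_below || need_input_grad) {
    ply <- model$modules[["stem.pool"]]
    g <- model$geom[["stem.pool"]]
    dh <- maxpool_backward(ply, caches[["stem.pool"]], dh, g)
    dh <- relu_backward(caches[["stem.relu"]], dh)
    dh <- bbn("stem.bn", dh)
    dh <- bconv("stem.conv", dh, want_dx = need_input_grad)
    dx <- dh
  }
  list(grads = grads, dx = dx)
}

## Flat parameter access ------------------------------------------------

model_param_paths <- function(model, trainable_only = TRUE) {
  out <- character(0)
  for (nm in names(model$modules)) {
    m <- model$modules[[nm]]
    for (pn in names(m$params)) out <- c(out, paste0(nm, ".", pn))
    if (!trainable_only) {
      for (sn in names(m$state)) out <- c(out, paste0(nm, ".", sn))
    }
  }
  out
}

model_get_param <- function(model, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  nm <- paste(parts[-length(parts)], collapse = ".")
  pn <- parts[length(parts)]
  m <- model$modules[[nm]]
  m$params[[pn]] %||% m$state[[pn]]
}

model_set_param <- function(model, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  nm <- paste(parts[-length(parts)], collapse = ".")
  pn <- parts[length(parts)]
  if (pn %in% names(model$modules[[nm]]$params)) {
    model$modules[[nm]]$params[[pn]] <- value
  } else {
    model$modules[[nm]]$state[[pn]] <- value
  }
  model
}

model_snapshot <- function(model) {
  lapply(model$modules, function(m) list(params = m$params, state = m$state))
}

model_restore <- function(model, snap) {
  for (nm in names(snap)) {
    model$modules[[nm]]$params <- snap[[nm]]$params
    model$modules[[nm]]$state <- snap[[nm]]$state
  }
  model
}

#' Per-stage parameter checksums
#'
#' Order-weighted checksums of every parameter (and batch-norm running
#' statistic) grouped by network stage: `stem`, `stage1`..`stage4`, `head`.
#' Used to verify the block-freezing contract: stages frozen during
#' fine-tuning keep bit-identical checksums.
#'
#' @param model A `trained_model`.
#' @return Named numeric vector of checksums.
#' @export
stage_checksums <- function(model) {
  keys <- c(stem = 0L, stage1 = 1L, stage2 = 2L, stage3 = 3L, stage4 = 4L,
            head = 5L)
  out <- stats::setNames(numeric(length(keys)), names(keys))
  for (nm in names(model$modules)) {
    st <- module_stage(nm)
    lab <- names(keys)[match(st, keys)]
    m <- model$modules[[nm]]
    for (v in c(m$params, m$state)) {
      out[lab] <- out[lab] + param_checksum(v)
    }
  }
  out
}
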