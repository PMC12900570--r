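# Training loop: Adam, the step-decay schedules for learning rate and
# deep-supervision weight, early stopping on mean validation Dice, and
# prediction / batch evaluation helpers.

#' Training configuration
#'
#' Defaults mirror the published protocol: Adam at 1e-3 decayed to 80%
#' every 30 epochs; deep supervision weight 0.4 decayed by 0.8 every 30
#' epochs; early stopping monitors the mean validation Dice of vertebra and
#' disc.
#'
#' @param lr initial learning rate
#' @param lr_decay,decay_every step decay factor / interval (epochs)
#' @param ds_alpha0,ds_decay deep-supervision weight schedule
#' @param max_epochs training epochs
#' @param patience early-stopping patience in epochs (0 disables)
#' @param loss a [loss_config()]
#' @param deep_supervision enable auxiliary heads
#' @param seed RNG seed for shuffling
#' @return list of class `train_config`
#' @export
train_config <- function(lr = 1e-3, lr_decay = 0.8, decay_every = 30L,
                         ds_alpha0 = 0.4, ds_decay = 0.8, max_epochs = 100L,
                         patience = 20L, loss = loss_config(),
                         deep_supervision = TRUE, seed = 1L) {
  structure(list(lr = lr, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every),
                 ds_alpha0 = ds_alpha0, ds_decay = ds_decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), loss = loss,
                 deep_supervision = isTRUE(deep_supervision),
                 seed = as.integer(seed)), class = "train_config")
}

#' Learning rate at a (0-based) epoch: lr0 * decay^floor(epoch / every)
#' @param epoch 0-based epoch index
#' @param cfg a [train_config()]
#' @export
lr_schedule <- function(epoch, cfg = train_config()) {
  cfg$lr * cfg$lr_decay^(epoch %/% cfg$decay_every)
}

#' Deep-supervision weight at a (0-based) epoch
#' @inheritParams lr_schedule
#' @export
ds_alpha_schedule <- function(epoch, cfg = train_config()) {
  cfg$ds_alpha0 * cfg$ds_decay^(epoch %/% cfg$decay_every)
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim_of(p$value))),
       v = lapply(params, function(p) array(0, dim = dim_of(p$value))),
       t = 0L)
}

adam_step <- function(params, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    p$value <- p$value - lr * (state$m[[i]] / bc1) /
      (sqrt(state$v[[i]] / bc2) + eps)
  }
  state
}

# nearest-neighbour downsampling of an integer label volume by 2^k
downsample_labels <- function(labels, factor) {
  d <- dim(labels)
  od <- as.integer(d %/% factor)
  array(as.integer(.cpp_resize3d(labels, as.integer(d), od, 0L)), dim = od)
}

#' Bundle one training/validation case
#'
#' @param x (1, n_modalities, D, H, W) input array (standardized channels)
#' @param labels (D, H, W) integer array under the three-class scheme
#' @return list consumed by [train_model()]
#' @export
as_case <- function(x, labels) {
  stopifnot(length(dim(x)) == 5L, identical(dim(x)[3:5], dim(labels)))
  list(x = x, labels = labels)
}

case_target <- function(case, n_classes) one_hot(case$labels, n_classes)

mean_fg_dice <- function(prob, labels) {
  pred <- apply(prob[1, , , , , drop = FALSE], c(3, 4, 5), which.max) - 1L
  (dsc(labels == 1L, pred == 1L) + dsc(labels == 2L, pred == 2L)) / 2
}

#' Train a model
#'
#' Seeded, epoch-based training with per-case (batch 1) Adam updates of the
#' hybrid frequency-domain-aware Tversky loss, optional deep supervision,
#' the step-decay schedules, and early stopping on the mean validation Dice
#' (vertebra + disc). Aborts with diagnostics on non-finite loss.
#'
#' @param model a [build_model()]
#' @param train_cases list of cases: each `list(x = (1,nmod,D,H,W) array,
#'   labels = (D,H,W) integer array)` under the three-class scheme
#' @param cfg a [train_config()]
#' @param val_cases optional validation cases for early stopping
#' @param log_file optional path receiving JSON-lines epoch logs
#' @param verbose print one line per epoch
#' @return list(model, logs) where `logs` is a data.frame with one row per
#'   epoch (epoch, lr, ds_alpha, loss, val_dice)
#' @export
train_model <- function(model, train_cases, cfg = train_config(),
                        val_cases = NULL, log_file = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "seg_model"), inherits(cfg, "train_config"))
  if (length(train_cases) == 0L) stop("train_model: empty dataset")
  n_classes <- model$cfg$n_classes
  params <- collect_params(model)
  state <- adam_state(params)
  targets <- lapply(train_cases, case_target, n_classes = n_classes)
  aux_targets <- NULL
  if (cfg$deep_supervision && length(model$ds_heads)) {
    aux_targets <- lapply(train_cases, function(case)
      lapply(model$ds_heads, function(h) {
        fac <- 2L^(4L - h$stage)
        one_hot(downsample_labels(case$labels, fac), n_classes)
      }))
  }
  logs <- list()
  best <- -Inf; best_epoch <- -1L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs) - 1L) {
      lr <- lr_schedule(epoch, cfg)
      alpha <- ds_alpha_schedule(epoch, cfg)
      order_ <- sample.int(length(train_cases))
      ep_loss <- 0
      for (ci in order_) {
        case <- train_cases[[ci]]
        ad_zero_grad(params)
        out <- model_forward_node(model, ad_const(case$x),
                                  with_aux = !is.null(aux_targets))
        loss <- hfd_tversky_node(out$prob, targets[[ci]], cfg$loss)
        if (!is.null(aux_targets)) {
          for (k in seq_along(out$aux)) {
            la <- hfd_tversky_node(out$aux[[k]]$prob,
                                   aux_targets[[ci]][[k]], cfg$loss)
            loss <- ad_add(loss, ad_mul(la, alpha))
          }
        }
        lv <- ad_value(loss)
        if (!is.finite(lv))
          stop(sprintf(paste0("train_model: non-finite loss (%g) at epoch ",
                              "%d, case %d; aborting"), lv, epoch, ci))
        ad_backward(loss)
        state <- adam_step(params, state, lr)
        ep_loss <- ep_loss + lv
      }
      ep_loss <- ep_loss / length(train_cases)
      val_dice <- NA_real_
      if (!is.null(val_cases) && length(val_cases)) {
        val_dice <- mean(vapply(val_cases, function(case)
          mean_fg_dice(model_forward(model, case$x)$prob, case$labels),
          numeric(1)))
      }
      row <- list(epoch = epoch, lr = lr, ds_alpha = alpha, loss = ep_loss,
                  val_dice = val_dice)
      logs[[length(logs) + 1L]] <- row
      if (!is.null(log_file))
        cat(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), "\n",
            sep = "", file = log_file, append = TRUE)
      if (verbose)
        message(sprintf("epoch %3d lr %.2e alpha %.3f loss %.4f val %.4f",
                        epoch, lr, alpha, ep_loss, val_dice))
      if (!is.na(val_dice) && cfg$patience > 0L) {
        if (val_dice > best + 1e-6) { best <- val_dice; best_epoch <- epoch }
        else if (epoch - best_epoch >= cfg$patience) break
      }
    }
  })
  logs <- do.call(rbind, lapply(logs, as.data.frame))
  list(model = model, logs = logs)
}

#' Segment a volume pair with a trained model
#'
#' @param model a trained `seg_model`
#' @param vol `volume_pair` (or a ready (1, nmod, D, H, W) array)
#' @param standardize z-score the channels before inference (default TRUE;
#'   matches the preprocessing used in training)
#' @return `label_volume` under the three-class scheme (argmax labels)
#' @export
predict_volume <- function(model, vol, standardize = TRUE) {
  if (inherits(vol, "volume_pair")) {
    zs <- function(v) if (standardize) (v - mean(v)) / (stats::sd(v) + 1e-12) else v
    chans <- switch(model$cfg$modality,
                    t1t2 = list(zs(vol$t1), zs(vol$t2)),
                    t1 = list(zs(vol$t1)), t2 = list(zs(vol$t2)))
    d <- dim(chans[[1]])
    x <- array(0, dim = c(1L, length(chans), d))
    for (i in seq_along(chans)) x[1, i, , , ] <- chans[[i]]
    spacing <- vol$spacing
  } else {
    x <- vol; spacing <- c(1, 1, 1)
  }
  prob <- model_forward(model, x)$prob
  lab <- apply(prob[1, , , , , drop = FALSE], c(3, 4, 5), which.max) - 1L
  structure(list(labels = array(as.integer(lab), dim = dim(lab)),
                 scheme = "THREE_CLASS", n_vertebrae = 5L, spacing = spacing),
            class = "label_volume")
}

#' Evaluate predicted against ground-truth masks case by case
#'
#' Both directories must contain case subdirectories (or flat .nii.gz mask
#' files) with identical names; each mask is compared with
#' [evaluate_case()] and per-case plus aggregate rows are returned (and
#' optionally written as CSV).
#'
#' @param pred_dir,gt_dir directories of predictions / ground truth
#' @param out_csv optional output CSV path
#' @return data.frame with one row per case per class plus mean/sd rows
#' @export
evaluate_dirs <- function(pred_dir, gt_dir, out_csv = NULL) {
  find_masks <- function(dir) {
    subs <- list.dirs(dir, recursive = FALSE)
    if (length(subs)) {
      paths <- file.path(subs, "mask.nii.gz")
      names(paths) <- basename(subs)
    } else {
      paths <- list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
      names(paths) <- sub("\\.nii(\\.gz)?$", "", basename(paths))
    }
    paths[file.exists(paths)]
  }
  preds <- find_masks(pred_dir); gts <- find_masks(gt_dir)
  cases <- intersect(names(preds), names(gts))
  if (!length(cases)) stop("evaluate_dirs: no matching cases")
  rows <- list()
  for (cs in cases) {
    gp <- read_nifti(gts[[cs]]); pp <- read_nifti(preds[[cs]])
    ga <- array(as.integer(round(gp$data)), dim = dim(gp$data))
    pa <- array(as.integer(round(pp$data)), dim = dim(pp$data))
    if (max(ga) > 2L) ga <- to_three_class(structure(
      list(labels = ga, scheme = "TEN_CLASS", n_vertebrae = 5L,
           spacing = gp$spacing), class = "label_volume"))$labels
    if (max(pa) > 2L) pa <- to_three_class(structure(
      list(labels = pa, scheme = "TEN_CLASS", n_vertebrae = 5L,
           spacing = pp$spacing), class = "label_volume"))$labels
    rep_ <- evaluate_case(ga, pa, spacing = gp$spacing)
    df <- as.data.frame(rep_)
    df$class <- rownames(rep_); df$case <- cs
    rows[[cs]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  agg <- do.call(rbind, lapply(split(out, out$class), function(g)
    data.frame(dsc = mean(g$dsc), iou = mean(g$iou),
               hd95 = mean(g$hd95, na.rm = TRUE),
               assd = mean(g$assd, na.rm = TRUE),
               class = g$class[1], case = "AGGREGATE_MEAN")))
  out <- rbind(out, agg)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
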