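# Full network assembly: dual four-stage encoders -> position-aware
# attention fusion -> anatomy-graph enhancement -> four depth-aware
# progressive upsampling stages -> softmax classification head, with
# optional deep-supervision heads on intermediate decoder stages.

#' Model configuration
#'
#' @param modality "t1t2" (dual encoders), "t1" or "t2" (single encoder)
#' @param n_classes output classes (default 3: background/vertebra/disc;
#'   10 selects the fine-grained head)
#' @param profile "paper" (stage widths 32-256, node width 128) or "test"
#'   (reduced widths 3-24 for CPU-scale runs)
#' @param channels,d_state,d_conv,n_kernels,h_dim override profile defaults
#' @param directions scan directions ("depth" only = sagittal ablation)
#' @param use_tdmamba,use_gcn,use_paaf component switches for ablations
#' @param ds_stages decoder stages carrying deep-supervision heads
#' @param seed initialization seed
#' @return list of class `model_config`
#' @export
model_config <- function(modality = c("t1t2", "t1", "t2"), n_classes = 3L,
                         profile = c("paper", "test"), channels = NULL,
                         d_state = NULL, d_conv = NULL, n_kernels = NULL,
                         h_dim = NULL,
                         directions = c("depth", "height", "width"),
                         use_tdmamba = TRUE, use_gcn = TRUE, use_paaf = TRUE,
                         ds_stages = c(2L, 3L), seed = 1L) {
  modality <- match.arg(modality)
  profile <- match.arg(profile)
  def <- if (profile == "paper")
    list(channels = c(32L, 64L, 128L, 256L), d_state = c(8L, 8L, 16L, 16L),
         d_conv = c(3L, 3L, 5L, 5L), n_kernels = 4L, h_dim = 128L)
  else
    list(channels = c(3L, 6L, 12L, 24L), d_state = c(3L, 3L, 3L, 3L),
         d_conv = c(3L, 3L, 3L, 3L), n_kernels = 2L, h_dim = 24L)
  structure(list(
    modality = modality, n_classes = as.integer(n_classes), profile = profile,
    channels = as.integer(channels %||% def$channels),
    d_state = as.integer(rep_len(d_state %||% def$d_state, 4L)),
    d_conv = as.integer(rep_len(d_conv %||% def$d_conv, 4L)),
    n_kernels = as.integer(n_kernels %||% def$n_kernels),
    h_dim = as.integer(h_dim %||% def$h_dim),
    directions = directions, use_tdmamba = isTRUE(use_tdmamba),
    use_gcn = isTRUE(use_gcn), use_paaf = isTRUE(use_paaf),
    ds_stages = as.integer(ds_stages), seed = as.integer(seed)
  ), class = "model_config")
}

#' Build the segmentation network
#'
#' @param cfg a [model_config()]
#' @return module tree of class `seg_model`
#' @export
build_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  nmod <- if (cfg$modality == "t1t2") 2L else 1L
  ch <- cfg$channels
  with_seed(cfg$seed, {
    enc_cfg <- function() encoder_config(
      1L, ch, cfg$d_state, cfg$d_conv, cfg$n_kernels, cfg$directions,
      cfg$use_tdmamba, seed = sample.int(1e6, 1))
    encoders <- lapply(seq_len(nmod), function(i) new_see_encoder(enc_cfg()))
    skip_fuse <- if (nmod == 2L) lapply(1:4, function(s) list(
      w = init_conv_w(ch[s], 2L * ch[s], 1L), b = init_zeros(ch[s]))) else NULL
    paaf <- if (cfg$use_paaf)
      new_paaf(ch[4], cfg$d_state[4], n_modalities = nmod,
               seed = sample.int(1e6, 1)) else NULL
    bottle_fuse <- if (!cfg$use_paaf && nmod == 2L) list(
      w = init_conv_w(ch[4], 2L * ch[4], 1L), b = init_zeros(ch[4])) else NULL
    graph <- if (cfg$use_gcn)
      new_graph_module(ch[4], cfg$h_dim, seed = sample.int(1e6, 1)) else NULL
    dec_in <- c(ch[4], ch[3], ch[2], ch[1])
    dec_skip <- c(ch[4], ch[3], ch[2], ch[1])
    dec_out <- c(ch[3], ch[2], ch[1], ch[1])
    dapu <- lapply(1:4, function(s)
      new_dapu(dec_in[s], dec_skip[s], dec_out[s], seed = sample.int(1e6, 1)))
    head <- list(w = init_conv_w(cfg$n_classes, ch[1], 1L),
                 b = init_zeros(cfg$n_classes))
    ds_heads <- lapply(cfg$ds_stages, function(s) list(
      stage = s, w = init_conv_w(cfg$n_classes, dec_out[s], 1L),
      b = init_zeros(cfg$n_classes)))
    structure(list(cfg = cfg, n_modalities = nmod, encoders = encoders,
                   skip_fuse = skip_fuse, paaf = paaf,
                   bottle_fuse = bottle_fuse, graph = graph, dapu = dapu,
                   head = head, ds_heads = ds_heads),
              class = "seg_model")
  })
}

#' Number of trainable scalars in a model
#' @param model a `seg_model` (or any module list)
#' @return integer parameter count
#' @export
count_parameters <- function(model) {
  sum(vapply(collect_params(model), function(p) length(p$value), numeric(1)))
}

model_forward_node <- function(model, x, with_aux = FALSE) {
  d <- dim_of(ad_value(x))
  if (d[2] != model$n_modalities)
    stop(sprintf("model_forward: expected %d input channels, got %d",
                 model$n_modalities, d[2]))
  if (any(d[3:5] %% 16L != 0L))
    stop(sprintf(paste0("model_forward: spatial dims (%d,%d,%d) must be ",
                        "divisible by 16 (four x2 downsampling stages)"),
                 d[3], d[4], d[5]))
  encs <- lapply(seq_len(model$n_modalities), function(i)
    see_forward_node(model$encoders[[i]], ad_slice_ch(x, i)))
  if (model$n_modalities == 2L) {
    skips <- lapply(1:4, function(s)
      ad_conv3d(ad_concat(list(encs[[1]]$skips[[s]], encs[[2]]$skips[[s]]), 2L),
                model$skip_fuse[[s]]$w, model$skip_fuse[[s]]$b))
    bott <- if (!is.null(model$paaf))
      paaf_node(model$paaf, encs[[1]]$bottleneck, encs[[2]]$bottleneck)
    else
      ad_conv3d(ad_concat(list(encs[[1]]$bottleneck, encs[[2]]$bottleneck), 2L),
                model$bottle_fuse$w, model$bottle_fuse$b)
  } else {
    skips <- encs[[1]]$skips
    bott <- if (!is.null(model$paaf)) paaf_node(model$paaf, encs[[1]]$bottleneck)
            else encs[[1]]$bottleneck
  }
  if (!is.null(model$graph)) bott <- graph_enhance_node(model$graph, bott)
  cur <- bott
  stage_outs <- vector("list", 4L)
  for (s in 1:4) {
    cur <- dapu_node(model$dapu[[s]], cur, skips[[5L - s]])
    stage_outs[[s]] <- cur
  }
  prob <- ad_softmax_ch(ad_conv3d(cur, model$head$w, model$head$b))
  aux <- NULL
  if (with_aux && length(model$ds_heads))
    aux <- lapply(model$ds_heads, function(h) list(
      stage = h$stage,
      prob = ad_softmax_ch(ad_conv3d(stage_outs[[h$stage]], h$w, h$b))))
  list(prob = prob, aux = aux)
}

#' Network forward pass
#'
#' @param model a [build_model()]
#' @param x (B, n_modalities, D, H, W) array; D, H, W divisible by 16
#' @param with_aux also return deep-supervision head outputs
#' @return list with `prob` ((B, n_classes, D, H, W) voxel probabilities)
#'   and, when requested, `aux` (list of stage/prob pairs at reduced
#'   resolution)
#' @export
model_forward <- function(model, x, with_aux = FALSE) {
  stopifnot(inherits(model, "seg_model"))
  x <- as_feature_map(x)
  r <- model_forward_node(model, ad_const(x), with_aux)
  out <- list(prob = ad_value(r$prob))
  if (with_aux) out$aux <- lapply(r$aux, function(a)
    list(stage = a$stage, prob = ad_value(a$prob)))
  out
}
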