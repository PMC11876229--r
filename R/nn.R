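# Compact CNN engine: stride-2 3x3 conv blocks with ReLU, global average
# pooling, and Adam. All parameters live in a flat named list of numeric
# arrays so optimizer state and encoder transfer are simple bookkeeping.

K_CONV <- 3L
STRIDE <- 2L
PAD <- 1L

#' Encoder architecture specification
#'
#' Describes the shared convolutional encoder used by both the context-free
#' network (pretext task) and the binary classifier (downstream task). The
#' default `small_cnn` is a 4-block stride-2 CNN with global average pooling,
#' sized so that full pipelines run on one CPU core; the field-standard
#' large encoder (`resnet50`) is accepted as a name for pluggable external
#' weights but is not constructed by this package.
#'
#' @param name Encoder family; only `"small_cnn"` is buildable here.
#' @param feature_dim Width of the pooled feature vector (equals the channel
#'   count of the last convolutional block).
#' @param input_channels 1 for grayscale (default) or 3 when replicating
#'   gray input to match 3-channel external weights.
#' @param init `"random"` or `"file:<path>"` pointing at a checkpoint written
#'   by [save_checkpoint()] whose encoder parameters are loaded.
#' @param channels Channel widths of the conv blocks; the last entry must
#'   equal `feature_dim`.
#' @param input_pool Integer average-pooling factor applied to the input
#'   image before the first conv block (1 = none). Reduces compute for
#'   large crops without changing the parameter shapes.
#' @return An object of class `encoder_spec`.
#' @export
encoder_spec <- function(name = "small_cnn", feature_dim = 32L,
                         input_channels = 1L, init = "random",
                         channels = NULL, input_pool = 1L) {
  name <- match.arg(name, c("small_cnn", "resnet50"))
  if (is.null(channels)) channels <- c(8L, 16L, 32L, as.integer(feature_dim))
  channels <- as.integer(channels)
  if (channels[length(channels)] != feature_dim)
    stop("last channel width must equal feature_dim", call. = FALSE)
  if (!input_channels %in% c(1L, 3L))
    stop("input_channels must be 1 or 3", call. = FALSE)
  if (!(identical(init, "random") || grepl("^file:", init)))
    stop("init must be \"random\" or \"file:<path>\"", call. = FALSE)
  structure(list(name = name, feature_dim = as.integer(feature_dim),
                 input_channels = as.integer(input_channels), init = init,
                 channels = channels, input_pool = as.integer(input_pool)),
            class = "encoder_spec")
}

# He-uniform init for one conv layer, seeded by the caller's RNG state
init_conv <- function(c_in, c_out) {
  fan_in <- K_CONV * K_CONV * c_in
  lim <- sqrt(6 / fan_in)
  list(W = array(stats::runif(K_CONV * K_CONV * c_in * c_out, -lim, lim),
                 dim = c(K_CONV, K_CONV, c_in, c_out)),
       b = numeric(c_out))
}

init_linear <- function(d_in, d_out) {
  lim <- sqrt(6 / d_in)
  list(W = matrix(stats::runif(d_in * d_out, -lim, lim), d_in, d_out),
       b = numeric(d_out))
}

# Flat parameter list for the encoder: enc1.W, enc1.b, ...
init_encoder_params <- function(spec) {
  stopifnot(inherits(spec, "encoder_spec"))
  if (spec$name != "small_cnn")
    stop("encoder '", spec$name, "' is not buildable in this package; ",
         "supply external weights through a checkpoint file", call. = FALSE)
  p <- list()
  c_in <- spec$input_channels
  for (i in seq_along(spec$channels)) {
    l <- init_conv(c_in, spec$channels[i])
    p[[paste0("enc", i, ".W")]] <- l$W
    p[[paste0("enc", i, ".b")]] <- l$b
    c_in <- spec$channels[i]
  }
  p
}

encoder_param_names <- function(params) grep("^enc", names(params), value = TRUE)

n_enc_layers <- function(params) length(grep("^enc[0-9]+\\.W$", names(params)))

# mean-pool a matrix by integer factor f (trailing rows/cols dropped)
avg_pool2 <- function(x, f) {
  if (f <= 1L) return(x)
  h <- (nrow(x) %/% f) * f; w <- (ncol(x) %/% f) * f
  x <- x[seq_len(h), seq_len(w), drop = FALSE]
  hi <- h %/% f; wi <- w %/% f
  a <- array(x, c(f, hi, f, wi))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}

as_weight_mat <- function(W) {
  d <- dim(W)
  matrix(W, nrow = d[1] * d[2] * d[3], ncol = d[4])
}

enc_weight_lists <- function(params) {
  L <- n_enc_layers(params)
  list(Ws = lapply(seq_len(L), function(i)
         as_weight_mat(params[[paste0("enc", i, ".W")]])),
       bs = lapply(seq_len(L), function(i) params[[paste0("enc", i, ".b")]]))
}

# Forward through the conv stack (single C++ call). Returns pooled
# features and, when keep = TRUE, the input cube and per-layer
# pre-activations needed for backprop and Grad-CAM.
encoder_forward <- function(params, spec, x, keep = FALSE, wl = NULL) {
  x <- avg_pool2(x, spec$input_pool)
  a <- array(x, c(nrow(x), ncol(x), 1L))
  if (spec$input_channels == 3L) a <- a[, , c(1L, 1L, 1L), drop = FALSE]
  if (is.null(wl)) wl <- enc_weight_lists(params)
  fw <- enc_fwd(a, wl$Ws, wl$bs, K_CONV, STRIDE, PAD, keep)
  list(features = as.numeric(fw$features), last = fw$last,
       x0 = if (keep) a else NULL,
       preacts = if (keep) fw$preacts else NULL)
}

# Backprop grad of a scalar loss w.r.t. pooled features down the conv stack.
# Returns per-parameter grads plus, when keep_act_grads, the gradient w.r.t.
# each layer's post-activation output (used by Grad-CAM).
encoder_backward <- function(params, spec, cache, gfeat,
                             keep_act_grads = FALSE, wl = NULL) {
  if (is.null(wl)) wl <- enc_weight_lists(params)
  L <- length(wl$Ws)
  bw <- enc_bwd(cache$x0, cache$preacts, wl$Ws, gfeat, K_CONV, STRIDE, PAD,
                keep_act_grads)
  grads <- list()
  for (i in seq_len(L)) {
    grads[[paste0("enc", i, ".W")]] <-
      array(bw$gWs[[i]], dim = dim(params[[paste0("enc", i, ".W")]]))
    grads[[paste0("enc", i, ".b")]] <- as.numeric(bw$gbs[[i]])
  }
  list(grads = grads,
       act_grads = if (keep_act_grads) bw$act_grads else NULL)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# elementwise sum of two structurally identical grad lists
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
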