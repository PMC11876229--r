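# Architecture contracts: the shared-weight context-free network (CFN)
# that classifies which permutation scrambled the 9 patches, and the
# single-stream binary classifier that inherits the CFN's encoder.

model_params_seeded <- function(seed, fn) {
  withr::with_seed(seed, fn())
}

load_init_encoder <- function(spec, seed) {
  if (grepl("^file:", spec$init)) {
    path <- sub("^file:", "", spec$init)
    ck <- load_checkpoint(path)
    check_spec_compatible(ck$spec, spec)
    ck$params[encoder_param_names(ck$params)]
  } else {
    model_params_seeded(seed, function() init_encoder_params(spec))
  }
}

check_spec_compatible <- function(a, b) {
  if (!identical(a$channels, b$channels) ||
      a$input_channels != b$input_channels ||
      a$feature_dim != b$feature_dim)
    stop("encoder specs are incompatible (channels/feature_dim differ)",
         call. = FALSE)
  invisible(TRUE)
}

#' Build the context-free network for permutation classification
#'
#' One shared encoder is applied to each of the 9 patches independently
#' (one parameter set regardless of patch count); per-patch features pass
#' through a shared linear projection with ReLU and are concatenated in
#' fixed slot order into a final fully connected layer producing one logit
#' per permutation class.
#'
#' @param spec An [encoder_spec()].
#' @param n_classes Size of the permutation set (default 31).
#' @param n_patches Patches per puzzle (9 for the 3x3 grid).
#' @param proj_dim Width of the shared per-patch projection.
#' @param seed Seed for parameter initialization.
#' @return An object of class `cfn_model`.
#' @export
build_cfn <- function(spec, n_classes = 31L, n_patches = 9L, proj_dim = 32L,
                      seed = 1L) {
  stopifnot(inherits(spec, "encoder_spec"))
  params <- load_init_encoder(spec, seed)
  extra <- model_params_seeded(seed + 1L, function() {
    p <- init_linear(spec$feature_dim, proj_dim)
    h <- init_linear(n_patches * proj_dim, n_classes)
    list(proj.W = p$W, proj.b = p$b, head.W = h$W, head.b = h$b)
  })
  structure(list(spec = spec, params = c(params, extra),
                 n_classes = as.integer(n_classes),
                 n_patches = as.integer(n_patches),
                 proj_dim = as.integer(proj_dim)),
            class = "cfn_model")
}

#' Forward pass of the CFN
#'
#' @param model A `cfn_model`.
#' @param patches List of `n_patches` equally sized matrices in slot order
#'   (e.g. `puzzle$patches`).
#' @param keep Keep per-patch caches for backprop?
#' @return List with `logits` (length `n_classes`), `probs`, `features`
#'   (matrix, one column per patch, pre-projection), and `cache` when
#'   `keep`.
#' @export
cfn_forward <- function(model, patches, keep = FALSE) {
  stopifnot(inherits(model, "cfn_model"))
  if (length(patches) != model$n_patches)
    stop("expected ", model$n_patches, " patches", call. = FALSE)
  p <- model$params
  caches <- if (keep) vector("list", length(patches)) else NULL
  wl <- enc_weight_lists(p)
  feats <- matrix(0, model$spec$feature_dim, length(patches))
  projs <- matrix(0, model$proj_dim, length(patches))
  for (j in seq_along(patches)) {
    fw <- encoder_forward(p, model$spec, patches[[j]], keep = keep, wl = wl)
    feats[, j] <- fw$features
    projs[, j] <- pmax(drop(crossprod(p$proj.W, fw$features)) + p$proj.b, 0)
    if (keep) caches[[j]] <- fw
  }
  concat <- as.vector(projs)
  logits <- drop(crossprod(p$head.W, concat)) + p$head.b
  list(logits = logits, probs = softmax(logits), features = feats,
       cache = if (keep) list(enc = caches, projs = projs, feats = feats,
                              concat = concat) else NULL)
}

# gradient of CE loss w.r.t. all CFN parameters for one sample
cfn_backward <- function(model, fwd, glogits) {
  p <- model$params
  cache <- fwd$cache
  grads <- list(head.W = outer(cache$concat, glogits),
                head.b = glogits)
  gconcat <- drop(p$head.W %*% glogits)
  gproj <- matrix(gconcat, model$proj_dim, model$n_patches)
  gproj <- gproj * (cache$projs > 0)
  grads$proj.W <- matrix(0, nrow(p$proj.W), ncol(p$proj.W))
  grads$proj.b <- numeric(length(p$proj.b))
  enc_grads <- NULL
  wl <- enc_weight_lists(p)
  for (j in seq_len(model$n_patches)) {
    f <- cache$enc[[j]]$features
    grads$proj.W <- grads$proj.W + outer(f, gproj[, j])
    grads$proj.b <- grads$proj.b + gproj[, j]
    gfeat <- drop(p$proj.W %*% gproj[, j])
    bw <- encoder_backward(p, model$spec, cache$enc[[j]], gfeat, wl = wl)
    enc_grads <- acc_grads(enc_grads, bw$grads)
  }
  c(grads, enc_grads)
}

#' Build the binary cancer classifier
#'
#' Single-stream encoder (same specification as the CFN's, so trained
#' pretext weights transfer without shape mismatch) followed by global
#' average pooling and a fully connected layer producing one logit;
#' the score is its logistic transform.
#'
#' @param spec An [encoder_spec()].
#' @param seed Seed for parameter initialization.
#' @return An object of class `classifier_model`.
#' @export
build_classifier <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "encoder_spec"))
  params <- load_init_encoder(spec, seed)
  extra <- model_params_seeded(seed + 1L, function() {
    h <- init_linear(spec$feature_dim, 1L)
    list(head.W = h$W, head.b = h$b)
  })
  structure(list(spec = spec, params = c(params, extra)),
            class = "classifier_model")
}

#' Forward pass of the classifier
#'
#' @param model A `classifier_model`.
#' @param image Numeric matrix (one grayscale crop).
#' @param keep Keep caches for backprop / Grad-CAM?
#' @return List with `logit`, `score` (logistic of the logit), `features`,
#'   and `cache` when `keep`.
#' @export
classifier_forward <- function(model, image, keep = FALSE) {
  stopifnot(inherits(model, "classifier_model"))
  fw <- encoder_forward(model$params, model$spec, image, keep = keep)
  logit <- drop(crossprod(model$params$head.W, fw$features)) +
    model$params$head.b
  list(logit = logit, score = stats::plogis(logit), features = fw$features,
       cache = if (keep) fw else NULL)
}

classifier_backward <- function(model, fwd, glogit) {
  f <- fwd$cache$features
  grads <- list(head.W = matrix(f * glogit, ncol = 1L),
                head.b = glogit)
  gfeat <- drop(model$params$head.W) * glogit
  bw <- encoder_backward(model$params, model$spec, fwd$cache, gfeat)
  c(grads, bw$grads)
}

#' Score a batch of images with the classifier
#'
#' @param model A `classifier_model`.
#' @param images List of matrices.
#' @return Numeric vector of scores in (0, 1), order-preserving.
#' @export
predict_classifier <- function(model, images) {
  vapply(images, function(x) classifier_forward(model, x)$score, 0)
}

#' Transfer a trained encoder into a classifier
#'
#' Copies the encoder parameters from a CFN (or any model / checkpoint
#' file carrying a compatible encoder) into the classifier, leaving the
#' classifier's freshly initialized head untouched.
#'
#' @param source A `cfn_model`, `classifier_model`, or path to a
#'   checkpoint written by [save_checkpoint()].
#' @param target A `classifier_model`.
#' @return The target with its encoder parameters replaced.
#' @export
transfer_encoder <- function(source, target) {
  stopifnot(inherits(target, "classifier_model"))
  if (is.character(source)) source <- load_checkpoint(source)
  check_spec_compatible(source$spec, target$spec)
  enc <- source$params[encoder_param_names(source$params)]
  for (nm in names(enc)) {
    if (!identical(dim(target$params[[nm]]), dim(enc[[nm]])) &&
        !identical(length(target$params[[nm]]), length(enc[[nm]])))
      stop("encoder parameter shape mismatch at ", nm, call. = FALSE)
    target$params[[nm]] <- enc[[nm]]
  }
  target
}

#' Save / load a model checkpoint
#'
#' Single-file serialized parameter map with the embedded encoder spec,
#' used both for encoder transfer between tasks and for supplying
#' externally pre-initialized weights.
#'
#' @param model A `cfn_model` or `classifier_model`.
#' @param path Destination file.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(spec = model$spec, params = model$params,
               class = class(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("no checkpoint at ", path, call. = FALSE)
  readRDS(path)
}
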