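# Training loops for the pretext (31-way permutation classification) and
# downstream (binary cancer) tasks, plus the four pipeline arms of the
# study design: IN-Jig, Scratch-Jig, IN, Scratch. Every loop is fully
# seeded; identical configs reproduce identical parameters.

#' Training configuration
#'
#' Mirrors the study's optimization settings: Adam with learning rate
#' 0.001 and weight decay 0, cross-entropy loss, batch size 128 for the
#' jigsaw pretext and 64 for fine-tuning, 100 epochs (scalable down for
#' desk-scale runs).
#'
#' @param task `"jigsaw"` or `"finetune"`.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 coefficient (the study uses 0).
#' @param batch_size Mini-batch size; defaults by task.
#' @param epochs Training epochs.
#' @param seed Integer seed covering shuffling, label draws and jitter.
#' @return An object of class `train_config`.
#' @export
train_config <- function(task = c("jigsaw", "finetune"),
                         learning_rate = 0.001, weight_decay = 0,
                         batch_size = NULL, epochs = 100L, seed = 1L) {
  task <- match.arg(task)
  if (is.null(batch_size)) batch_size <- if (task == "jigsaw") 128L else 64L
  if (learning_rate <= 0 || batch_size < 1L || epochs < 0L)
    stop("learning_rate and batch_size must be positive, epochs >= 0",
         call. = FALSE)
  structure(list(task = task, learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Train the CFN on the jigsaw pretext task
#'
#' Each step draws a training image, a uniform permutation label and fresh
#' jitter, builds the gapped puzzle and minimizes cross-entropy over the
#' permutation classes with Adam. The per-epoch history records mean loss
#' and training accuracy.
#'
#' @param model A `cfn_model`.
#' @param images List of square matrices matching `grid$image_size`.
#' @param permset A `permutation_set` with `model$n_classes` rows.
#' @param cfg A `train_config` with `task = "jigsaw"`.
#' @param grid A `grid_spec` compatible with the images and
#'   `model$n_patches`.
#' @return List with `model` (trained) and `history` (data frame epoch /
#'   loss / accuracy).
#' @export
train_jigsaw <- function(model, images, permset, cfg, grid = grid_spec()) {
  stopifnot(inherits(model, "cfn_model"), inherits(cfg, "train_config"))
  if (cfg$task != "jigsaw") stop("cfg$task must be 'jigsaw'", call. = FALSE)
  if (length(images) == 0L) stop("no training images", call. = FALSE)
  if (nrow(permset$perms) != model$n_classes)
    stop("permutation set size does not match model classes", call. = FALSE)
  n_class <- model$n_classes
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric())
  if (cfg$epochs == 0L) return(list(model = model, history = history))
  withr::local_seed(cfg$seed)
  opt <- adam_init(model$params)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(length(images))
    ep_loss <- 0; ep_hits <- 0L
    done <- 0L
    while (done < length(ord)) {
      idx <- ord[(done + 1L):min(done + cfg$batch_size, length(ord))]
      done <- done + length(idx)
      bgrads <- NULL
      for (i in idx) {
        lab <- sample.int(n_class, 1L) - 1L
        pz <- sample_puzzle(images[[i]], lab, permset, grid)
        fw <- cfn_forward(model, pz$patches, keep = TRUE)
        pr <- fw$probs
        loss <- -log(max(pr[lab + 1L], 1e-12))
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", ep,
               call. = FALSE)
        ep_loss <- ep_loss + loss
        ep_hits <- ep_hits + as.integer(which.max(fw$logits) == lab + 1L)
        gl <- pr; gl[lab + 1L] <- gl[lab + 1L] - 1
        bgrads <- acc_grads(bgrads, cfn_backward(model, fw, gl))
      }
      st <- adam_step(model$params, scale_grads(bgrads, 1 / length(idx)),
                      opt, cfg$learning_rate, cfg$weight_decay)
      model$params <- st$params
      opt <- st$state
    }
    history <- rbind(history, data.frame(epoch = ep,
                                         loss = ep_loss / length(ord),
                                         accuracy = ep_hits / length(ord)))
  }
  list(model = model, history = history)
}

#' Jigsaw-task accuracy of a model
#'
#' Samples `n_samples` puzzles (uniform image, uniform label, fresh
#' jitter) and reports the fraction whose argmax logit equals the true
#' permutation class.
#'
#' @inheritParams train_jigsaw
#' @param n_samples Number of sampled puzzles.
#' @param seed Integer seed.
#' @return Accuracy in \[0, 1\].
#' @export
evaluate_jigsaw_accuracy <- function(model, images, permset, n_samples = 100L,
                                     seed = 1L, grid = grid_spec()) {
  if (n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  withr::local_seed(seed)
  hits <- 0L
  n_class <- nrow(permset$perms)
  for (s in seq_len(n_samples)) {
    i <- sample.int(length(images), 1L)
    lab <- sample.int(n_class, 1L) - 1L
    pz <- sample_puzzle(images[[i]], lab, permset, grid)
    fw <- cfn_forward(model, pz$patches)
    hits <- hits + as.integer(which.max(fw$logits) == lab + 1L)
  }
  hits / n_samples
}

#' Fine-tune the binary cancer classifier
#'
#' Minimizes binary cross-entropy on the cancer label over the supplied
#' crops with Adam, fully seeded.
#'
#' @param model A `classifier_model`.
#' @param images List of matrices.
#' @param labels Binary vector (0/1), same length as `images`; both
#'   classes must be present.
#' @param cfg A `train_config` with `task = "finetune"`.
#' @return List with `model` and `history` (epoch / loss / auc on the
#'   training scores of that epoch).
#' @export
train_classifier <- function(model, images, labels, cfg) {
  stopifnot(inherits(model, "classifier_model"), inherits(cfg, "train_config"))
  if (cfg$task != "finetune") stop("cfg$task must be 'finetune'", call. = FALSE)
  labels <- as.integer(labels)
  if (length(images) != length(labels))
    stop("images and labels differ in length", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  history <- data.frame(epoch = integer(), loss = numeric(), auc = numeric())
  if (cfg$epochs == 0L) return(list(model = model, history = history))
  withr::local_seed(cfg$seed)
  opt <- adam_init(model$params)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(length(images))
    ep_loss <- 0
    scores <- numeric(length(images))
    done <- 0L
    while (done < length(ord)) {
      idx <- ord[(done + 1L):min(done + cfg$batch_size, length(ord))]
      done <- done + length(idx)
      bgrads <- NULL
      for (i in idx) {
        fw <- classifier_forward(model, images[[i]], keep = TRUE)
        p <- fw$score
        y <- labels[i]
        loss <- -(y * log(max(p, 1e-12)) + (1 - y) * log(max(1 - p, 1e-12)))
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", ep,
               call. = FALSE)
        ep_loss <- ep_loss + loss
        scores[i] <- p
        bgrads <- acc_grads(bgrads, classifier_backward(model, fw, p - y))
      }
      st <- adam_step(model$params, scale_grads(bgrads, 1 / length(idx)),
                      opt, cfg$learning_rate, cfg$weight_decay)
      model$params <- st$params
      opt <- st$state
    }
    history <- rbind(history,
                     data.frame(epoch = ep, loss = ep_loss / length(ord),
                                auc = roc_auc(scores, labels)$auc))
  }
  list(model = model, history = history)
}

#' Pipeline arm of the pretraining comparison
#'
#' The four arms of the study: `IN-Jig` (externally pre-initialized
#' encoder + jigsaw pretext + fine-tuning), `Scratch-Jig` (random init +
#' jigsaw pretext + fine-tuning), `IN` (externally pre-initialized
#' encoder + fine-tuning), `Scratch` (random init + fine-tuning). Arms
#' with external initialization require a checkpoint file of compatible
#' encoder weights, e.g. one produced by [pretrain_rotation()].
#'
#' @param name One of `"IN-Jig"`, `"Scratch-Jig"`, `"IN"`, `"Scratch"`.
#' @param weights_file Checkpoint path for the externally initialized
#'   arms.
#' @return An object of class `pipeline_arm`.
#' @export
pipeline_arm <- function(name = c("IN-Jig", "Scratch-Jig", "IN", "Scratch"),
                         weights_file = NULL) {
  name <- match.arg(name)
  pre_init <- name %in% c("IN-Jig", "IN")
  if (pre_init && is.null(weights_file))
    stop(name, " requires a weights_file with pre-initialized encoder ",
         "parameters", call. = FALSE)
  structure(list(name = name,
                 encoder_init = if (pre_init) paste0("file:", weights_file)
                                else "random",
                 jigsaw_pretraining = name %in% c("IN-Jig", "Scratch-Jig")),
            class = "pipeline_arm")
}

#' Run one pipeline arm under a patient-grouped split plan
#'
#' For each requested (trial, fold): optionally jigsaw-pretrains on that
#' fold's training images only, transfers the encoder into a fresh
#' classifier, fine-tunes on the training images, and scores the
#' validation images. Pre-training never sees validation patients; an
#' intersection between training and validation patient sets aborts the
#' run.
#'
#' @param arm A [pipeline_arm()].
#' @param data List with `manifest` and `images` as returned by
#'   [generate_dataset()] (images keyed by image_id).
#' @param permset A `permutation_set` (needed for jigsaw arms).
#' @param cfg_pretext,cfg_finetune [train_config()]s for the two stages.
#' @param splits A `split_plan` from [grouped_kfold()].
#' @param grid A `grid_spec` matching the image size.
#' @param encoder An [encoder_spec()]; its `init` field is overridden by
#'   the arm.
#' @param trials,folds Optional integer subsets of the plan's trials and
#'   folds to run (defaults: all).
#' @return Data frame with one row per scored validation image: image_id,
#'   patient_id, trial, fold, score, label, finding, density.
#' @export
run_arm <- function(arm, data, permset, cfg_pretext, cfg_finetune, splits,
                    grid = grid_spec(), encoder = encoder_spec(),
                    trials = NULL, folds = NULL) {
  stopifnot(inherits(arm, "pipeline_arm"), inherits(splits, "split_plan"))
  manifest <- data$manifest
  if (is.null(trials)) trials <- seq_len(splits$trials)
  if (is.null(folds)) folds <- seq_len(splits$k)
  spec <- encoder
  spec$init <- arm$encoder_init
  out <- list()
  for (tr in trials) {
    asg <- splits$assignment[splits$assignment$trial == tr, ]
    for (fd in folds) {
      val_pat <- asg$patient_id[asg$fold == fd]
      train_pat <- asg$patient_id[asg$fold != fd]
      if (length(intersect(val_pat, train_pat)))
        stop("protocol error: patient appears in both training and ",
             "validation sets", call. = FALSE)
      tr_rows <- manifest[manifest$patient_id %in% train_pat, ]
      va_rows <- manifest[manifest$patient_id %in% val_pat, ]
      stage_seed <- cfg_finetune$seed + 1000L * tr + 10L * fd
      tr_imgs <- data$images[tr_rows$image_id]
      # one encoder draw per (trial, fold), shared by pretext and
      # fine-tuning so that a 0-epoch pretext degenerates exactly to the
      # corresponding no-pretext arm
      enc_params <- load_init_encoder(spec, stage_seed)
      if (arm$jigsaw_pretraining) {
        cfn <- build_cfn(encoder, n_classes = nrow(permset$perms),
                         n_patches = grid$grid_n^2, seed = stage_seed)
        cfn$params[names(enc_params)] <- enc_params
        cfg_p <- cfg_pretext
        cfg_p$seed <- stage_seed + 1L
        cfn <- train_jigsaw(cfn, tr_imgs, permset, cfg_p, grid)$model
        enc_params <- cfn$params[encoder_param_names(cfn$params)]
      }
      clf <- build_classifier(encoder, seed = stage_seed + 2L)
      clf$params[names(enc_params)] <- enc_params
      cfg_f <- cfg_finetune
      cfg_f$seed <- stage_seed + 3L
      clf <- train_classifier(clf, tr_imgs, tr_rows$cancer, cfg_f)$model
      scores <- predict_classifier(clf, data$images[va_rows$image_id])
      out[[length(out) + 1L]] <- data.frame(
        image_id = va_rows$image_id, patient_id = va_rows$patient_id,
        trial = tr, fold = fd, score = as.numeric(scores),
        label = va_rows$cancer, finding = va_rows$finding,
        density = va_rows$density, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Produce a pre-initialized encoder checkpoint via a rotation pretext
#'
#' Trains the encoder to classify which of four rotations (0/90/180/270
#' degrees) was applied to a crop, then writes the weights as a
#' checkpoint. This supplies the "externally pre-initialized weights"
#' consumed by the `IN-Jig` and `IN` arms at desk scale, preserving the
#' four-arm comparison structure without any external download.
#'
#' @param images List of square matrices.
#' @param spec An [encoder_spec()] (init must be `"random"`).
#' @param path Output checkpoint path.
#' @param epochs,learning_rate,batch_size,seed Training settings.
#' @return `path`, invisibly.
#' @export
pretrain_rotation <- function(images, spec, path, epochs = 5L,
                              learning_rate = 0.001, batch_size = 32L,
                              seed = 1L) {
  stopifnot(inherits(spec, "encoder_spec"))
  params <- model_params_seeded(seed, function() init_encoder_params(spec))
  head <- model_params_seeded(seed + 1L, function() {
    h <- init_linear(spec$feature_dim, 4L)
    list(head.W = h$W, head.b = h$b)
  })
  params <- c(params, head)
  rot <- function(x, k) switch(k, x, t(x[nrow(x):1, ]),
                               x[nrow(x):1, ncol(x):1], t(x)[ncol(x):1, ])
  withr::local_seed(seed + 2L)
  opt <- adam_init(params)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(images))
    done <- 0L
    while (done < length(ord)) {
      idx <- ord[(done + 1L):min(done + batch_size, length(ord))]
      done <- done + length(idx)
      bgrads <- NULL
      for (i in idx) {
        k <- sample.int(4L, 1L)
        x <- rot(images[[i]], k)
        fw <- encoder_forward(params, spec, x, keep = TRUE)
        logits <- drop(crossprod(params$head.W, fw$features)) + params$head.b
        pr <- softmax(logits)
        gl <- pr; gl[k] <- gl[k] - 1
        g <- list(head.W = outer(fw$features, gl), head.b = gl)
        gfeat <- drop(params$head.W %*% gl)
        bw <- encoder_backward(params, spec, fw, gfeat)
        bgrads <- acc_grads(bgrads, c(g, bw$grads))
      }
      st <- adam_step(params, scale_grads(bgrads, 1 / length(idx)),
                      opt, learning_rate)
      params <- st$params
      opt <- st$state
    }
  }
  save_checkpoint(structure(list(spec = spec, params = params),
                            class = "classifier_model"), path)
}
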