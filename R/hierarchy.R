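# Temporally constrained hierarchical classification: stage 1 separates
# debris from the viable classes, stage 2 differentiated from dense+spread,
# stage 3 dense from spread — mirroring the developmental ordering. Each
# stage is a small two-class CNN; class imbalance within a stage is
# corrected by adding generated minority-class images (or by resampling /
# loss weighting for the baseline comparisons).

#' Stage classifier training configuration
#'
#' Defaults follow the published recipe: 200 epochs of SGD (learning rate
#' 0.005, momentum 0.8, weight decay 1e-4, batch 64), learning rate halved
#' halfway through training, cross-entropy loss, 5 folds.
#'
#' @param epochs Training epochs.
#' @param lr Initial learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay.
#' @param batch_size Mini-batch size.
#' @param folds Cross-validation folds.
#' @param lr_halve_at Epoch after which the rate is halved (default
#'   `epochs / 2`).
#' @param input_size Side to which patches are resized before the network
#'   (default 64, the native patch size).
#' @param base_maps Feature maps of the first convolution; doubled at each
#'   of the strided convolutions.
#' @param seed Integer seed.
#' @return A `classifier_config` object.
#' @export
classifier_config <- function(epochs = 200, lr = 0.005, momentum = 0.8,
                              weight_decay = 1e-4, batch_size = 64, folds = 5,
                              lr_halve_at = NULL, input_size = 64,
                              base_maps = 8, seed = 1) {
  if (is.null(lr_halve_at)) lr_halve_at <- epochs / 2
  stopifnot(epochs >= 1, lr > 0, momentum >= 0, weight_decay >= 0,
            batch_size >= 1, lr_halve_at < epochs, input_size %% 4 == 0)
  structure(list(epochs = epochs, lr = lr, momentum = momentum,
                 weight_decay = weight_decay, batch_size = batch_size,
                 folds = folds, lr_halve_at = lr_halve_at,
                 input_size = input_size, base_maps = base_maps, seed = seed),
            class = "classifier_config")
}

#' Learning rate at a given epoch
#'
#' The initial rate up to `lr_halve_at`, half of it afterwards.
#'
#' @param config A [classifier_config()].
#' @param epoch Epoch number (1-based).
#' @return The learning rate in effect at that epoch.
#' @export
lr_at_epoch <- function(config, epoch) {
  if (epoch > config$lr_halve_at) config$lr / 2 else config$lr
}

build_classifier <- function(n_classes, input_size, base_maps) {
  nd <- max(1L, round(log2(input_size / 4)))
  layers <- list()
  s <- input_size; c_in <- 1L
  for (i in seq_len(nd)) {
    c_out <- base_maps * 2^(i - 1)
    layers <- c(layers, list(nn_conv(c_in, c_out, k = 3, stride = 2, pad = 1,
                                     init = "he"),
                             nn_act("lrelu")))
    c_in <- c_out
    s <- (s + 2L - 3L) %/% 2L + 1L
  }
  c(layers, list(nn_flatten(), nn_dense(s * s * c_in, n_classes, init = "he")))
}

# workhorse: y is integer 1..K; returns classifier_model
train_classifier <- function(x, y, config, class_weights = NULL,
                             sampler = FALSE, seed = 1, class_names = NULL) {
  stopifnot(length(dim(x)) == 3, dim(x)[3] == length(y))
  k <- max(y)
  if (dim(x)[1] != config$input_size) x <- resize_nearest(x, config$input_size)
  xn <- normalize_patches(x)
  n <- length(y)
  with_seed(seed, {
    layers <- build_classifier(k, config$input_size, config$base_maps)
    st <- sgd_init(layers)
    curves <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
    for (ep in seq_len(config$epochs)) {
      lr <- lr_at_epoch(config, ep)
      if (sampler) { # class-balanced resampling of the epoch's index stream
        tab <- tabulate(y, k)
        ord <- unlist(lapply(which(tab > 0), function(cl)
          sample(which(y == cl), max(tab), replace = TRUE)))
        ord <- sample(ord)
      } else ord <- sample.int(n)
      bsz <- min(config$batch_size, length(ord))
      nb <- length(ord) %/% bsz
      ep_loss <- 0; ep_hit <- 0; ep_n <- 0
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1) * bsz + 1):(bi * bsz)]
        fw <- nn_forward(layers, xn[, , , idx, drop = FALSE])
        cl <- ce_loss_grad(fw$out, y[idx], class_weights)
        bw <- nn_backward(layers, fw$caches, cl$dlogits)
        up <- sgd_step(layers, bw$grads, st, lr, config$momentum,
                       config$weight_decay)
        layers <- up$layers; st <- up$state
        ep_loss <- ep_loss + cl$loss * length(idx)
        ep_hit <- ep_hit + sum(apply(fw$out, 2, which.max) == y[idx])
        ep_n <- ep_n + length(idx)
      }
      curves[ep, ] <- list(ep, ep_loss / ep_n, ep_hit / ep_n)
    }
    structure(list(layers = layers, n_classes = k, config = config,
                   class_names = class_names, curves = curves),
              class = "classifier_model")
  })
}

predict_classifier <- function(model, x, batch = 256L) {
  if (inherits(x, "patch_dataset")) x <- x$images
  if (dim(x)[1] != model$config$input_size)
    x <- resize_nearest(x, model$config$input_size)
  xn <- normalize_patches(x)
  n <- dim(xn)[4]
  out <- matrix(0, model$n_classes, n)
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + batch - 1L)
    out[, idx] <- nn_forward(model$layers, xn[, , , idx, drop = FALSE])$out
    at <- at + batch
  }
  t(softmax_cols(out))
}

#' Specify one stage of the temporal hierarchy
#'
#' @param stage Stage id: 1 (debris vs. rest), 2 (differentiated vs.
#'   dense+spread), 3 (dense vs. spread).
#' @param balancing `"none"`, `"generator"` (add generated minority-class
#'   images), `"sampler"` (balanced resampling) or `"weighted"`
#'   (inverse-frequency loss weights).
#' @return A `stage_spec` with the stage's positive/negative class sets.
#' @export
stage_spec <- function(stage, balancing = c("none", "generator", "sampler",
                                            "weighted")) {
  balancing <- match.arg(balancing)
  sets <- stage_class_sets(stage)
  structure(list(stage = stage, pos = sets$pos, neg = sets$neg,
                 balancing = balancing),
            class = "stage_spec")
}

#' Train one hierarchy stage
#'
#' Relabels the training patches into the stage's binary problem (class 1 =
#' the stage's single/positive class, class 2 = the aggregate class) and
#' trains a two-class CNN. With generator balancing, exactly
#' `balancing_plan()$n_generated` generated minority-class patches are
#' added before training, so the two stage classes have equal counts; all
#' real majority-class patches are left intact.
#'
#' @param spec A [stage_spec()].
#' @param config A [classifier_config()].
#' @param train_data A labeled `patch_dataset` (real training split).
#' @param generator Patch generator `(class_label, n, seed)`; required iff
#'   `spec$balancing == "generator"`.
#' @param seed Integer seed.
#' @return A `stage_model`.
#' @export
train_stage <- function(spec, config, train_data, generator = NULL, seed = 1) {
  stopifnot(inherits(spec, "stage_spec"))
  labs <- as.character(train_data$labels)
  keep <- labs %in% c(spec$pos, spec$neg)
  ds <- subset_patches(train_data, keep)
  labs <- as.character(ds$labels)
  if (!any(labs %in% spec$pos) || !any(labs %in% spec$neg))
    stop("training data lacks one of the stage ", spec$stage, " classes")
  if (spec$balancing == "generator") {
    if (is.null(generator)) stop("generator balancing requires a generator")
    counts <- table(factor(labs, levels = morphology_classes()))
    counts[setdiff(morphology_classes(), c(spec$pos, spec$neg))] <- 0
    plan <- balancing_plan(counts, spec$stage)
    if (plan$n_generated > 0) {
      gen <- generator(plan$minority_class, plan$n_generated,
                       derive_seed(seed, 17))
      ds <- combine_patches(ds, patch_dataset(gen, labels = plan$minority_class,
                                              provenance = "generated"))
      labs <- as.character(ds$labels)
    }
  }
  y <- ifelse(labs %in% spec$pos, 1L, 2L)
  w <- if (spec$balancing == "weighted") {
    tab <- tabulate(y, 2L)
    length(y) / (2 * tab) # inverse-frequency, normalized to mean 1
  }
  model <- train_classifier(ds$images, y, config, class_weights = w,
                            sampler = spec$balancing == "sampler",
                            seed = seed,
                            class_names = c(paste(spec$pos, collapse = "+"),
                                            paste(spec$neg, collapse = "+")))
  structure(list(stage = spec$stage, spec = spec, model = model,
                 n_train = length(y), train_counts = tabulate(y, 2L),
                 provenance_table = table(provenance = ds$provenance,
                                          stage_class = y)),
            class = "stage_model")
}

#' Route patches through the trained hierarchy
#'
#' Stage 1 positive patches are labeled debris and stop; the rest go to
#' stage 2 (differentiated or onward) and finally stage 3 (dense vs.
#' spread). Exactly one of the four labels is returned per patch.
#'
#' @param stage_models List of three `stage_model`s (stages 1, 2, 3).
#' @param patches Patches (array or `patch_dataset`).
#' @return Factor of predicted class labels.
#' @export
route_hierarchy <- function(stage_models, patches) {
  if (inherits(patches, "patch_dataset")) patches <- patches$images
  n <- dim(patches)[3]
  out <- rep(NA_character_, n)
  alive <- seq_len(n)
  p1 <- predict_classifier(stage_models[[1]]$model,
                           patches[, , alive, drop = FALSE])
  is_debris <- p1[, 1] >= 0.5
  out[alive[is_debris]] <- "debris"
  alive <- alive[!is_debris]
  if (length(alive) > 0) {
    p2 <- predict_classifier(stage_models[[2]]$model,
                             patches[, , alive, drop = FALSE])
    is_diff <- p2[, 1] >= 0.5
    out[alive[is_diff]] <- "differentiated"
    alive <- alive[!is_diff]
  }
  if (length(alive) > 0) {
    p3 <- predict_classifier(stage_models[[3]]$model,
                             patches[, , alive, drop = FALSE])
    out[alive] <- ifelse(p3[, 1] >= 0.5, "dense", "spread")
  }
  factor(out, levels = morphology_classes())
}

#' Per-class TPR / F1 classification report
#'
#' Per class: TPR = TP / (TP + FN) and F1 = TP / (TP + (FP + FN) / 2),
#' plus the confusion matrix (rows = truth) and macro averages. A class
#' absent from the truth has undefined TPR/F1, reported as `NA`.
#'
#' @param predictions,truth Equal-length label vectors (factors or
#'   characters).
#' @return A `class_report`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth))
  lev <- union(levels(factor(truth)), levels(factor(predictions)))
  pr <- factor(predictions, levels = lev)
  tr <- factor(truth, levels = lev)
  cm <- table(truth = tr, predicted = pr)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tpr <- ifelse(rowSums(cm) > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(rowSums(cm) > 0, tp / (tp + 0.5 * (fp + fn)), NA_real_)
  structure(list(confusion = cm, tpr = tpr, f1 = f1,
                 macro_tpr = mean(tpr, na.rm = TRUE),
                 macro_f1 = mean(f1, na.rm = TRUE),
                 accuracy = sum(tp) / length(truth)),
            class = "class_report")
}

#' @export
print.class_report <- function(x, ...) {
  cat("<class_report>\n")
  print(round(rbind(TPR = x$tpr, F1 = x$f1), 4))
  cat(sprintf("macro TPR %.4f  macro F1 %.4f  accuracy %.4f\n",
              x$macro_tpr, x$macro_f1, x$accuracy))
  invisible(x)
}

#' Train the full three-stage hierarchy
#'
#' Stages are trained on the ground-truth-routed subsets of the training
#' split (stage 2 sees only viable classes, stage 3 only dense/spread);
#' evaluation should use [route_hierarchy()] end-to-end.
#'
#' @param train_data Labeled `patch_dataset` (training split).
#' @param config A [classifier_config()].
#' @param balancing `"none"` or `"generator"` (applied at every stage).
#' @param generator Patch generator, required for generator balancing.
#' @param seed Integer seed.
#' @return List of three `stage_model`s.
#' @export
train_hierarchy <- function(train_data, config, balancing = "none",
                            generator = NULL, seed = 1) {
  lapply(1:3, function(s)
    train_stage(stage_spec(s, balancing), config, train_data,
                generator = generator, seed = derive_seed(seed, s)))
}

#' Train a flat four-class classifier
#'
#' The baseline configurations: unbalanced, sampler-balanced,
#' inverse-frequency weighted, or generator-balanced (every class topped up
#' to the largest class's count with generated images).
#'
#' @param train_data Labeled `patch_dataset`.
#' @param config A [classifier_config()].
#' @param balancing One of `"none"`, `"sampler"`, `"weighted"`,
#'   `"generator"`.
#' @param generator Patch generator for `"generator"` balancing.
#' @param seed Integer seed.
#' @return A `classifier_model` with `class_names` set.
#' @export
train_fourclass <- function(train_data, config,
                            balancing = c("none", "sampler", "weighted",
                                          "generator"),
                            generator = NULL, seed = 1) {
  balancing <- match.arg(balancing)
  ds <- train_data
  labs <- as.character(ds$labels)
  classes <- morphology_classes()[morphology_classes() %in% labs]
  if (balancing == "generator") {
    if (is.null(generator)) stop("generator balancing requires a generator")
    tab <- table(factor(labs, levels = classes))
    for (cl in classes) {
      add <- max(tab) - tab[[cl]]
      if (add > 0) {
        gen <- generator(cl, add, derive_seed(seed, 23 + match(cl, classes)))
        ds <- combine_patches(ds, patch_dataset(gen, labels = cl,
                                                provenance = "generated"))
      }
    }
    labs <- as.character(ds$labels)
  }
  y <- match(labs, classes)
  w <- if (balancing == "weighted") {
    tab <- tabulate(y, length(classes))
    length(y) / (length(classes) * tab)
  }
  train_classifier(ds$images, y, config, class_weights = w,
                   sampler = balancing == "sampler", seed = seed,
                   class_names = classes)
}

predict_fourclass <- function(model, patches) {
  pr <- predict_classifier(model, patches)
  factor(model$class_names[apply(pr, 1, which.max)],
         levels = morphology_classes())
}

# mean/sd aggregation of per-fold class reports
aggregate_reports <- function(reports) {
  tprs <- do.call(rbind, lapply(reports, `[[`, "tpr"))
  f1s <- do.call(rbind, lapply(reports, `[[`, "f1"))
  list(tpr_mean = colMeans(tprs, na.rm = TRUE),
       tpr_sd = apply(tprs, 2, stats::sd),
       f1_mean = colMeans(f1s, na.rm = TRUE),
       f1_sd = apply(f1s, 2, stats::sd),
       tpr_folds = tprs, f1_folds = f1s)
}

#' Compare balancing configurations under identical folds
#'
#' Trains and evaluates five configurations — unbalanced, sampler-balanced,
#' weight-balanced and generator-balanced four-class CNNs, plus the
#' generator-balanced temporal hierarchy — on the same cross-validation
#' folds and seeds. Reports per-class TPR and F1 (mean and sd over folds)
#' and Welch two-sample t-tests of each configuration against the
#' unbalanced baseline, per class, on the per-fold TPR values.
#'
#' @param ds Labeled `patch_dataset` with folds (see [make_folds()]).
#' @param config A [classifier_config()].
#' @param generator Patch generator for the generator-balanced
#'   configurations.
#' @param seed Integer seed.
#' @param folds Fold ids to run (default: all).
#' @return List with `tpr` and `f1` data frames (configurations x classes +
#'   average) and `t_tests` (p-values vs. the unbalanced baseline).
#' @export
run_baselines <- function(ds, config, generator, seed = 1, folds = NULL) {
  stopifnot(!all(is.na(ds$fold)))
  if (is.null(folds)) folds <- sort(unique(ds$fold[!is.na(ds$fold)]))
  configs <- c("unbalanced", "sampler", "weighted", "generator", "temporal")
  reports <- stats::setNames(lapply(configs, function(x) list()), configs)
  for (f in folds) {
    train <- subset_patches(ds, ds$fold != f & !is.na(ds$fold))
    test <- subset_patches(ds, ds$fold == f)
    truth <- as.character(test$labels)
    sd_f <- derive_seed(seed, 1000 + f)
    for (cfg in configs) {
      pred <- if (cfg == "temporal") {
        hm <- train_hierarchy(train, config, balancing = "generator",
                              generator = generator, seed = sd_f)
        route_hierarchy(hm, test)
      } else {
        bal <- switch(cfg, unbalanced = "none", sampler = "sampler",
                      weighted = "weighted", generator = "generator")
        m <- train_fourclass(train, config, balancing = bal,
                             generator = generator, seed = sd_f)
        predict_fourclass(m, test)
      }
      reports[[cfg]] <- c(reports[[cfg]], list(evaluate_predictions(pred, truth)))
    }
  }
  aggs <- lapply(reports, aggregate_reports)
  mk_table <- function(field_mean, field_sd) {
    rows <- lapply(aggs, function(a) {
      m <- a[[field_mean]]; s <- a[[field_sd]]
      c(stats::setNames(m, names(m)), average = mean(m, na.rm = TRUE))
    })
    df <- as.data.frame(do.call(rbind, rows))
    cbind(configuration = configs, df)
  }
  t_tests <- NULL
  if (length(folds) >= 2) {
    base <- aggs$unbalanced$tpr_folds
    t_tests <- do.call(rbind, lapply(setdiff(configs, "unbalanced"), function(cfg) {
      other <- aggs[[cfg]]$tpr_folds
      p <- vapply(seq_len(ncol(base)), function(j) {
        if (stats::sd(base[, j]) == 0 && stats::sd(other[, j]) == 0)
          return(NA_real_)
        stats::t.test(other[, j], base[, j])$p.value
      }, 0)
      data.frame(configuration = cfg, class = colnames(base), p_value = p)
    }))
  }
  list(tpr = mk_table("tpr_mean", "tpr_sd"),
       f1 = mk_table("f1_mean", "f1_sd"),
       tpr_sd = do.call(rbind, lapply(aggs, `[[`, "tpr_sd")),
       t_tests = t_tests, reports = reports)
}

#' Augmentation saturation curve for the dense/spread stage
#'
#' Retrains the stage-3 classifier with `n` generated patches added to each
#' class, for each increment `n`, and records per-class TPR and accuracy —
#' the experiment used to locate the point beyond which added generated
#' images stop helping.
#'
#' @param ds Labeled `patch_dataset` containing dense and spread patches,
#'   split into train/test via its folds (fold 0 is the test fold).
#' @param generator Patch generator.
#' @param increments Non-decreasing vector of added-image counts, starting
#'   at 0.
#' @param config A [classifier_config()].
#' @param seed Integer seed.
#' @return Data frame: one row per increment with TPR per class and
#'   accuracy.
#' @export
saturation_curve <- function(ds, generator, increments, config, seed = 1) {
  if (length(increments) == 0) stop("empty increments")
  stopifnot(!is.unsorted(increments), increments[1] == 0)
  keep <- as.character(ds$labels) %in% c("dense", "spread")
  ds <- subset_patches(ds, keep)
  test <- subset_patches(ds, !is.na(ds$fold) & ds$fold == 0)
  train <- subset_patches(ds, is.na(ds$fold) | ds$fold != 0)
  rows <- lapply(increments, function(add) {
    tr <- train
    if (add > 0) {
      for (cl in c("dense", "spread")) {
        gen <- generator(cl, add, derive_seed(seed, 31 + add + match(cl, morphology_classes())))
        tr <- combine_patches(tr, patch_dataset(gen, labels = cl,
                                                provenance = "generated"))
      }
    }
    sm <- train_stage(stage_spec(3), config, tr, seed = derive_seed(seed, 3))
    pr <- predict_classifier(sm$model, test)
    pred <- ifelse(pr[, 1] >= 0.5, "dense", "spread")
    rep <- evaluate_predictions(pred, as.character(test$labels))
    data.frame(n_added = add, tpr_dense = rep$tpr[["dense"]],
               tpr_spread = rep$tpr[["spread"]], accuracy = rep$accuracy)
  })
  do.call(rbind, rows)
}
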