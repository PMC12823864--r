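# Two-backbone neural classifier: one MLP backbone embeds the vectorized
# connectome, a second embeds the joint Betti-curve vector; the embeddings
# are concatenated and a one-layer head with dropout produces 2-class
# softmax probabilities. Trained with AdamW on cross-entropy. Implemented
# directly (dense forward/backward passes) so training is exactly
# reproducible from a seed.

#' Network and training configuration
#'
#' Defaults follow the tuned full-scale configuration: 128-unit single-layer
#' backbones with ReLU, a one-layer classification head with dropout 0.5,
#' AdamW with learning rate 1e-5 and weight decay 1e-5, 50 epochs. For small
#' synthetic cohorts trained full-batch, far fewer optimizer steps are taken
#' per epoch, so a larger learning rate and more epochs are appropriate (see
#' [desk_config()]).
#'
#' @param backbone_hidden hidden width of each backbone.
#' @param dropout_head dropout probability on the head input, in `[0, 1)`.
#' @param learning_rate AdamW step size.
#' @param weight_decay decoupled weight decay.
#' @param epochs full-batch training epochs.
#' @param standardize standardize Betti inputs with training statistics
#'   (integer Betti counts and correlations live on incompatible scales).
#' @param seed seed for initialization and dropout.
#' @return object of class `bmh_net_config`.
#' @export
bmh_net_config <- function(backbone_hidden = 128L, dropout_head = 0.5,
                           learning_rate = 1e-5, weight_decay = 1e-5,
                           epochs = 50L, standardize = TRUE, seed = 1L) {
  stopifnot(backbone_hidden >= 1, dropout_head >= 0, dropout_head < 1,
            learning_rate > 0, weight_decay >= 0, epochs >= 1)
  structure(list(backbone_hidden = as.integer(backbone_hidden),
                 dropout_head = dropout_head,
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "bmh_net_config")
}

#' Desk-scale training configuration
#'
#' Same architecture as [bmh_net_config()] but with learning rate 1e-3 and
#' 300 epochs: with full-batch training on tens of subjects, total Adam
#' parameter movement is roughly `learning_rate * epochs`, so the full-scale
#' step size would leave the network effectively untrained.
#'
#' @param ... overrides passed to [bmh_net_config()].
#' @export
desk_config <- function(...) {
  args <- list(...)
  defaults <- list(learning_rate = 1e-3, epochs = 300L)
  defaults[names(args)] <- args
  do.call(bmh_net_config, defaults)
}

#' Stack feature bundles into model input matrices
#'
#' @param bundles list of [subnetwork_features()] bundles.
#' @return list with `betti` (subjects x `18 T`) and `conn`
#'   (subjects x `N (N - 1)`) matrices.
#' @export
feature_matrices <- function(bundles) {
  stopifnot(length(bundles) >= 1, inherits(bundles[[1]], "feature_bundle"))
  list(betti = do.call(rbind, lapply(bundles, `[[`, "x_betti")),
       conn = do.call(rbind, lapply(bundles, `[[`, "x_connectome")))
}

relu <- function(x) x * (x > 0)

init_params <- function(Dc, Db, H, seed) {
  set.seed(seed)
  list(
    Wc = matrix(stats::rnorm(Dc * H, sd = sqrt(2 / Dc)), Dc, H),
    bc = numeric(H),
    Wb = matrix(stats::rnorm(Db * H, sd = sqrt(2 / Db)), Db, H),
    bb = numeric(H),
    Wh = matrix(stats::rnorm(2 * H * 2, sd = sqrt(1 / (2 * H))), 2 * H, 2),
    bh = numeric(2)
  )
}

net_forward <- function(params, conn, betti_std, drop_mask = NULL) {
  hc <- sweep(conn %*% params$Wc, 2, params$bc, `+`)
  ac <- relu(hc)
  hb <- sweep(betti_std %*% params$Wb, 2, params$bb, `+`)
  ab <- relu(hb)
  e <- cbind(ac, ab)
  e_drop <- if (is.null(drop_mask)) e else e * drop_mask
  logits <- sweep(e_drop %*% params$Wh, 2, params$bh, `+`)
  m <- apply(logits, 1, max)
  ex <- exp(logits - m)
  probs <- ex / rowSums(ex)
  list(ac = ac, ab = ab, e = e, e_drop = e_drop, logits = logits,
       probs = probs)
}

#' Fit the two-backbone connectome/Betti-curve classifier
#'
#' @param x_betti subjects x D_betti matrix of joint Betti-curve features, or
#'   a list of feature bundles (then `x_connectome` and `labels` follow from
#'   `labels`).
#' @param x_connectome subjects x D_conn matrix of vectorized connectomes.
#' @param labels 0/1 integer vector (1 = positive class).
#' @param config a [bmh_net_config]; default [bmh_net_config()].
#' @return object of class `bmh_net` with the trained parameters, the
#'   Betti-input standardization statistics, and the loss trajectory.
#' @export
bmh_net <- function(x_betti, x_connectome, labels,
                    config = bmh_net_config()) {
  if (is.list(x_betti) && !is.matrix(x_betti)) {
    fm <- feature_matrices(x_betti)
    x_betti <- fm$betti
    x_connectome <- fm$conn
  }
  x_betti <- as.matrix(x_betti)
  x_connectome <- as.matrix(x_connectome)
  labels <- as.integer(labels)
  n <- nrow(x_betti)
  stopifnot(nrow(x_connectome) == n, length(labels) == n,
            all(labels %in% 0:1))
  if (length(unique(labels)) < 2L) {
    stop("training data must contain both classes")
  }
  cfg <- config
  if (cfg$standardize) {
    mu <- colMeans(x_betti)
    sdv <- apply(x_betti, 2, stats::sd)
    sdv[sdv == 0] <- 1
  } else {
    mu <- numeric(ncol(x_betti))
    sdv <- rep(1, ncol(x_betti))
  }
  Zb <- sweep(sweep(x_betti, 2, mu), 2, sdv, `/`)
  H <- cfg$backbone_hidden
  params <- init_params(ncol(x_connectome), ncol(x_betti), H, cfg$seed)
  # AdamW state
  m_st <- lapply(params, function(p) p * 0)
  v_st <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  Y <- cbind(1 - labels, labels)  # one-hot, column 2 = positive class
  losses <- numeric(cfg$epochs)
  p_drop <- cfg$dropout_head
  for (epoch in seq_len(cfg$epochs)) {
    drop_mask <- NULL
    if (p_drop > 0) {
      drop_mask <- matrix(stats::rbinom(n * 2 * H, 1, 1 - p_drop),
                          n, 2 * H) / (1 - p_drop)
    }
    fw <- net_forward(params, x_connectome, Zb, drop_mask)
    eps_p <- 1e-12
    losses[epoch] <- -mean(log(rowSums(Y * fw$probs) + eps_p))
    # backward
    dlogits <- (fw$probs - Y) / n
    g <- list(
      Wh = crossprod(fw$e_drop, dlogits),
      bh = colSums(dlogits)
    )
    de_drop <- dlogits %*% t(params$Wh)
    de <- if (is.null(drop_mask)) de_drop else de_drop * drop_mask
    dac <- de[, seq_len(H), drop = FALSE] * (fw$ac > 0)
    dab <- de[, H + seq_len(H), drop = FALSE] * (fw$ab > 0)
    g$Wc <- crossprod(x_connectome, dac)
    g$bc <- colSums(dac)
    g$Wb <- crossprod(Zb, dab)
    g$bb <- colSums(dab)
    for (nm in names(params)) {
      m_st[[nm]] <- beta1 * m_st[[nm]] + (1 - beta1) * g[[nm]]
      v_st[[nm]] <- beta2 * v_st[[nm]] + (1 - beta2) * g[[nm]]^2
      mhat <- m_st[[nm]] / (1 - beta1^epoch)
      vhat <- v_st[[nm]] / (1 - beta2^epoch)
      params[[nm]] <- params[[nm]] -
        cfg$learning_rate * (mhat / (sqrt(vhat) + adam_eps) +
                               cfg$weight_decay * params[[nm]])
    }
  }
  structure(list(params = params, config = cfg, mu = mu, sd = sdv,
                 d_betti = ncol(x_betti), d_conn = ncol(x_connectome),
                 losses = losses, n_train = n,
                 class_balance = mean(labels)),
            class = "bmh_net")
}

#' @export
print.bmh_net <- function(x, ...) {
  cat("Two-backbone connectome/Betti classifier\n")
  cat(sprintf("  inputs: %d connectome + %d Betti features; hidden %d per backbone\n",
              x$d_conn, x$d_betti, x$config$backbone_hidden))
  cat(sprintf("  trained %d epochs on %d subjects; loss %.4f -> %.4f\n",
              x$config$epochs, x$n_train, x$losses[1],
              x$losses[length(x$losses)]))
  invisible(x)
}

#' @export
summary.bmh_net <- function(object, ...) {
  print(object)
  cat(sprintf("  learning rate %g, weight decay %g, dropout %g, seed %d\n",
              object$config$learning_rate, object$config$weight_decay,
              object$config$dropout_head, object$config$seed))
  n_par <- sum(vapply(object$params, length, integer(1)))
  cat("  parameters:", n_par, "\n")
  invisible(object)
}

#' @export
coef.bmh_net <- function(object, ...) object$params

#' @export
plot.bmh_net <- function(x, ...) {
  graphics::plot(seq_along(x$losses), x$losses, type = "l",
                 xlab = "epoch", ylab = "cross-entropy loss",
                 main = "Training loss", ...)
  invisible(x)
}

# Resolve prediction inputs: bundles list or explicit matrices.
resolve_inputs <- function(object, newdata, x_connectome = NULL) {
  if (is.list(newdata) && !is.matrix(newdata) &&
      length(newdata) && inherits(newdata[[1]], "feature_bundle")) {
    fm <- feature_matrices(newdata)
    betti <- fm$betti; conn <- fm$conn
  } else if (is.list(newdata) && !is.matrix(newdata) &&
             all(c("betti", "conn") %in% names(newdata))) {
    betti <- as.matrix(newdata$betti); conn <- as.matrix(newdata$conn)
  } else {
    betti <- as.matrix(newdata); conn <- as.matrix(x_connectome)
  }
  if (ncol(betti) != object$d_betti) {
    stop("Betti feature matrix has ", ncol(betti), " columns; model expects ",
         object$d_betti)
  }
  if (ncol(conn) != object$d_conn) {
    stop("connectome feature matrix has ", ncol(conn),
         " columns; model expects ", object$d_conn)
  }
  list(betti = betti, conn = conn)
}

#' Predict positive-class probabilities
#'
#' Inference mode: dropout disabled, deterministic.
#'
#' @param object a fitted [bmh_net].
#' @param newdata list of feature bundles, or `list(betti =, conn =)`, or a
#'   Betti matrix with `x_connectome` supplied.
#' @param x_connectome optional connectome matrix when `newdata` is a bare
#'   Betti matrix.
#' @param ... unused.
#' @return numeric vector of probabilities of the positive class.
#' @export
predict.bmh_net <- function(object, newdata, x_connectome = NULL, ...) {
  inp <- resolve_inputs(object, newdata, x_connectome)
  Zb <- sweep(sweep(inp$betti, 2, object$mu), 2, object$sd, `/`)
  fw <- net_forward(object$params, inp$conn, Zb, drop_mask = NULL)
  unname(fw$probs[, 2])
}

#' Gradient of the positive-class score with respect to Betti inputs
#'
#' Returns the per-subject Jacobian rows `d p1 / d x_betti` (on the raw,
#' unstandardized input scale), evaluated in inference mode.
#'
#' @inheritParams predict.bmh_net
#' @return subjects x D_betti matrix of gradients.
#' @export
betti_input_gradient <- function(object, newdata, x_connectome = NULL) {
  inp <- resolve_inputs(object, newdata, x_connectome)
  Zb <- sweep(sweep(inp$betti, 2, object$mu), 2, object$sd, `/`)
  fw <- net_forward(object$params, inp$conn, Zb, drop_mask = NULL)
  p1 <- fw$probs[, 2]
  # d p1 / d logits = p1 (1 - p1) * (-1, +1)
  dlogits <- cbind(-p1 * (1 - p1), p1 * (1 - p1))
  de <- dlogits %*% t(object$params$Wh)
  H <- object$config$backbone_hidden
  dab <- de[, H + seq_len(H), drop = FALSE] * (fw$ab > 0)
  dz <- dab %*% t(object$params$Wb)
  sweep(dz, 2, object$sd, `/`)
}

#' Binary classification metrics at the F-score-optimal threshold
#'
#' Scans candidate thresholds (0, 1 and all midpoints of sorted unique
#' scores), predicts positive when `score >= threshold`, picks the threshold
#' maximizing the F-score (ties broken toward the lower threshold) and
#' reports F-score, accuracy, precision and sensitivity there.
#'
#' @param scores numeric vector of positive-class scores.
#' @param labels 0/1 vector aligned with `scores`.
#' @return object of class `bmh_eval` with the four metrics, the chosen
#'   `binarization_threshold` and the confusion counts. If no positive labels
#'   are present, sensitivity (and F-score) are undefined: the report carries
#'   `undefined_sensitivity = TRUE` and NA metrics rather than silent zeros.
#' @export
evaluate <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  if (sum(labels) == 0L) {
    return(structure(list(f_score = NA_real_, accuracy = NA_real_,
                          precision = NA_real_, sensitivity = NA_real_,
                          binarization_threshold = NA_real_,
                          undefined_sensitivity = TRUE),
                     class = "bmh_eval"))
  }
  u <- sort(unique(scores))
  candidates <- c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1)
  best <- NULL
  for (thr in candidates) {
    pred <- as.integer(scores >= thr)
    tp <- sum(pred == 1 & labels == 1)
    fp <- sum(pred == 1 & labels == 0)
    fn <- sum(pred == 0 & labels == 1)
    tn <- sum(pred == 0 & labels == 0)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    sensitivity <- tp / (tp + fn)
    f <- if (!is.na(precision) && precision + sensitivity > 0) {
      2 * precision * sensitivity / (precision + sensitivity)
    } else 0
    if (is.null(best) || f > best$f_score + 1e-15) {
      best <- list(f_score = f, accuracy = (tp + tn) / length(labels),
                   precision = precision, sensitivity = sensitivity,
                   binarization_threshold = thr,
                   confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
                   undefined_sensitivity = FALSE)
    }
  }
  structure(best, class = "bmh_eval")
}

#' @export
print.bmh_eval <- function(x, ...) {
  if (isTRUE(x$undefined_sensitivity)) {
    cat("Evaluation: no positive labels; sensitivity undefined\n")
    return(invisible(x))
  }
  cat(sprintf("Evaluation at threshold %.4f:\n", x$binarization_threshold))
  cat(sprintf("  F-score %.4f | accuracy %.4f | precision %.4f | sensitivity %.4f\n",
              x$f_score, x$accuracy,
              ifelse(is.na(x$precision), NaN, x$precision), x$sensitivity))
  invisible(x)
}

#' Gradient-based subnetwork importance
#'
#' For a validation set: gradients of the model output (positive-class
#' probability) with respect to every Betti-curve input value are computed
#' per subject; the importance of each input is the mean absolute gradient
#' over subjects; the importance of a subnetwork is the sum over its inputs
#' (both its degree-0 and degree-1 curve values).
#'
#' @param model a fitted [bmh_net].
#' @param bundles validation list of feature bundles (or `list(betti =,
#'   conn =)` matrices plus `feature_map`).
#' @param feature_map optional character vector mapping each Betti input
#'   position to a subnetwork label; derived from the first bundle when
#'   bundles are supplied.
#' @return named numeric vector of nonnegative importances, one per
#'   subnetwork, in canonical order.
#' @export
subnetwork_importance <- function(model, bundles, feature_map = NULL) {
  if (is.null(feature_map)) {
    stopifnot(length(bundles) >= 1, inherits(bundles[[1]], "feature_bundle"))
    feature_map <- betti_feature_map(bundles[[1]])
  }
  G <- betti_input_gradient(model, bundles)
  stopifnot(length(feature_map) == ncol(G))
  per_input <- colMeans(abs(G))
  imp <- tapply(per_input, feature_map, sum)
  labs <- unique(feature_map)
  out <- as.numeric(imp[labs])
  names(out) <- labs
  out
}

#' Per-threshold group comparison of Betti curves
#'
#' Independent two-sample t-tests of each Betti-curve value between two
#' groups, at every grid point of every curve, with Holm correction applied
#' over the whole family of tests. Grid points with zero variance in both
#' groups are flagged (`p` undefined) rather than set to an arbitrary value.
#'
#' @param features subjects x D matrix of Betti features (e.g. rows of
#'   `x_betti`), or a list of feature bundles.
#' @param groups 0/1 vector with at least 2 subjects per group.
#' @param feature_map optional subnetwork label per column (derived from
#'   bundles when given).
#' @param alpha significance level for the flags, default 0.05.
#' @return data frame with columns `feature`, `subnetwork`, `p_raw`,
#'   `p_holm`, `significant_raw`, `significant_holm`, `zero_variance`.
#' @export
group_curve_test <- function(features, groups, feature_map = NULL,
                             alpha = 0.05) {
  if (is.list(features) && !is.matrix(features) &&
      length(features) && inherits(features[[1]], "feature_bundle")) {
    if (is.null(feature_map)) feature_map <- betti_feature_map(features[[1]])
    features <- do.call(rbind, lapply(features, `[[`, "x_betti"))
  }
  features <- as.matrix(features)
  groups <- as.integer(groups)
  stopifnot(nrow(features) == length(groups), all(groups %in% 0:1),
            sum(groups == 0) >= 2, sum(groups == 1) >= 2)
  if (is.null(feature_map)) feature_map <- rep("all", ncol(features))
  a <- features[groups == 0, , drop = FALSE]
  b <- features[groups == 1, , drop = FALSE]
  p_raw <- vapply(seq_len(ncol(features)), function(j) {
    if (stats::var(a[, j]) == 0 && stats::var(b[, j]) == 0) {
      return(NA_real_)
    }
    stats::t.test(a[, j], b[, j])$p.value
  }, numeric(1))
  p_holm <- rep(NA_real_, length(p_raw))
  ok <- !is.na(p_raw)
  p_holm[ok] <- stats::p.adjust(p_raw[ok], method = "holm")
  data.frame(feature = seq_along(p_raw),
             subnetwork = feature_map,
             p_raw = p_raw,
             p_holm = p_holm,
             significant_raw = !is.na(p_raw) & p_raw < alpha,
             significant_holm = !is.na(p_holm) & p_holm < alpha,
             zero_variance = is.na(p_raw))
}
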