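label_matrices <- function(data, rows) {
  hz <- data$horizons
  y <- as.matrix(rows[, paste0("y", hz), with = FALSE])
  mask <- as.matrix(rows[, paste0("m", hz), with = FALSE])
  storage.mode(y) <- "double"
  storage.mode(mask) <- "double"
  list(y = y, mask = mask)
}

# one differentiable pass over a batch of trajectory rows:
# loss value (incl. penalty) and gradients for every parameter.
# rng_seed drives the (training-only) stochastic regularizers.
model_loss_and_grads <- function(params, config, data, rows,
                                 rng_seed = NULL) {
  batch <- make_batch(data, rows, config$max_seq_len)
  dropout_mask <- NULL
  if (!is.null(rng_seed) &&
      (config$dropout > 0 || isTRUE(config$token_dropout > 0))) {
    reg <- with_preserved_seed(rng_seed, {
      out <- list(batch = batch, dm = NULL)
      if (isTRUE(config$token_dropout > 0)) {
        hide <- matrix(stats::runif(length(batch$mask)) < config$token_dropout,
                       nrow(batch$mask)) & batch$mask == 1
        # never hide a trajectory completely (position 1 is always real)
        hide[rowSums(batch$mask == 1 & !hide) == 0, 1L] <- FALSE
        out$batch$idx[hide] <- data$vocab$pad_index
        out$batch$mask[hide] <- 0
        out$batch$lens <- pmax(rowSums(out$batch$mask), 1)
      }
      if (config$dropout > 0) {
        fp <- fingerprint_dim(config)
        out$dm <- matrix(stats::rbinom(nrow(rows) * fp, 1L,
                                       1 - config$dropout) /
                           (1 - config$dropout), nrow(rows), fp)
      }
      out
    })
    batch <- reg$batch
    dropout_mask <- reg$dm
  }
  tape <- ad_tape()
  pn <- lapply(params, function(m) ad_leaf(tape, m))
  lab <- label_matrices(data, rows)
  fw <- model_forward(tape, pn, config, batch, dropout_mask = dropout_mask)
  ln <- loss_node(tape, fw$p, lab$y, lab$mask)
  ad_backward(tape, ln)
  grads <- lapply(pn, function(n) n$grad)
  for (nm in names(grads)) {
    if (is.null(grads[[nm]])) grads[[nm]] <- matrix(0, nrow(params[[nm]]),
                                                    ncol(params[[nm]]))
  }
  loss <- ad_val(ln)[1L, 1L]
  if (config$lambda2 > 0) {
    nrm <- l2_norm(params)
    loss <- loss + config$lambda2 * nrm
    if (nrm > 0) {
      for (nm in names(grads)) {
        grads[[nm]] <- grads[[nm]] + config$lambda2 * params[[nm]] / nrm
      }
    }
  }
  # the padding embedding stays fixed at zero
  grads$E[data$vocab$pad_index, ] <- 0
  list(loss = loss, grads = grads, p = ad_val(fw$p))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# deterministic capped dev subset: every positive plus a seeded sample of
# negatives (AUPRC on it is comparable across epochs of the same run)
dev_subset <- function(trajectories, cap, seed) {
  dev <- trajectories[split == "dev"]
  if (nrow(dev) <= cap) return(dev)
  pos <- dev[is_case == TRUE]
  neg <- dev[is_case == FALSE]
  n_neg <- max(cap - nrow(pos), 0L)
  take <- with_preserved_seed(seed, sample.int(nrow(neg), min(n_neg, nrow(neg))))
  rbind(pos, neg[take])
}

#' Train a multi-horizon risk model
#'
#' Stochastic gradient training with class-balanced batches, Adam updates, a
#' per-epoch development-set evaluation and AUPRC-based model selection:
#' the returned model carries the parameters of the epoch with the highest
#' development AUPRC at `selection_horizon`, and training stops early when
#' that metric has not improved for `patience` epochs. One epoch is the
#' number of balanced batches needed to cover the negative training
#' trajectories once (optionally capped by `steps_per_epoch`). Fully
#' deterministic given `seed` on a fixed platform.
#'
#' @param data a `trajrisk_data`.
#' @param config a `trajrisk_config`.
#' @param lr Adam learning rate.
#' @param batch_size balanced-batch size.
#' @param epochs maximum epochs (0 = no training; the initial model is
#'   evaluated once and returned).
#' @param steps_per_epoch optional cap on batches per epoch.
#' @param patience early-stopping patience in epochs.
#' @param selection_horizon horizon (months) whose dev AUPRC drives model
#'   selection, or `"mean"` to select on the mean dev AUPRC over every
#'   horizon (more stable when the dev split holds few case patients);
#'   default 36.
#' @param dev_cap maximum dev trajectories scored per epoch (all positives
#'   are always kept; negatives are subsampled deterministically).
#' @param seed integer seed for batch sampling and dev subsampling.
#' @param verbose print per-epoch progress.
#' @return a `trajrisk_run`: list with `model` (best checkpoint), `history`
#'   (per-epoch `data.table`: epoch, train_loss, dev_auprc, dev_auroc),
#'   `best_epoch`, `seed`.
#' @export
train_model <- function(data, config, lr = 1e-3, batch_size = 64L,
                        epochs = 10L, steps_per_epoch = NULL, patience = 5L,
                        selection_horizon = 36L, dev_cap = 4000L, seed = 1L,
                        verbose = FALSE) {
  stopifnot(inherits(data, "trajrisk_data"), inherits(config, "trajrisk_config"))
  sel_mean <- identical(selection_horizon, "mean")
  if (!sel_mean && !selection_horizon %in% config$horizons) {
    stop("selection_horizon must be one of the model horizons or \"mean\"")
  }
  sel_h <- if (sel_mean) config$horizons else selection_horizon
  hcol <- paste0("p", sel_h)
  ycol <- paste0("y", sel_h)
  train <- data$trajectories[split == "train"]
  dev <- dev_subset(data$trajectories, dev_cap, seed)
  if (nrow(train) == 0L || nrow(dev) == 0L) {
    stop("train_model: empty train or dev split")
  }
  if (!any(train$is_case) || !any(!train$is_case)) {
    stop("train_model: training split needs both classes")
  }
  model <- init_risk_model(config, data$vocab)
  state <- adam_init(model$params)

  eval_dev <- function(params) {
    m <- model
    m$params <- params
    p <- predict_risk(m, data, dev)
    # a dev split may hold a single class at a selection horizon (e.g.
    # after a wide exclusion window); such horizons are unavailable
    pr <- vapply(seq_along(hcol), function(j) {
      tryCatch(compute_auprc(p[, hcol[j]], dev[[ycol[j]]]),
               error = function(e) NA_real_)
    }, numeric(1))
    ro <- vapply(seq_along(hcol), function(j) {
      tryCatch(compute_auroc(p[, hcol[j]], dev[[ycol[j]]]),
               error = function(e) NA_real_)
    }, numeric(1))
    list(auprc = if (all(is.na(pr))) NA_real_ else mean(pr, na.rm = TRUE),
         auroc = if (all(is.na(ro))) NA_real_ else mean(ro, na.rm = TRUE))
  }

  # selection score: dev AUPRC when the dev split has positives at the
  # selection horizon; otherwise fall back to (negated) training loss
  has_dev_pos <- any(vapply(ycol, function(cc) any(dev[[cc]] == 1L),
                            logical(1)))
  history <- list()
  d0 <- eval_dev(model$params)
  history[[1L]] <- data.table(epoch = 0L, train_loss = NA_real_,
                              dev_auprc = d0$auprc, dev_auroc = d0$auroc)
  # the untrained initial model is a selection candidate only when no
  # training is requested; with epochs > 0 selection is among trained
  # checkpoints
  best <- list(params = model$params, score = -Inf, auprc = d0$auprc,
               epoch = 0L)
  since_best <- 0L

  if (epochs > 0L) {
    for (e in seq_len(epochs)) {
      batches <- balanced_batch_sampler(train$is_case, batch_size,
                                        seed = seed * 1000L + e,
                                        n_batches = steps_per_epoch)
      losses <- numeric(length(batches))
      for (b in seq_along(batches)) {
        rows <- train[batches[[b]]]
        lg <- model_loss_and_grads(model$params, config, data, rows,
                                   rng_seed = (seed * 99991L + e * 1009L + b) %%
                                     2000000000L)
        if (!is.finite(lg$loss)) {
          stop(sprintf("train_model: non-finite loss at epoch %d batch %d (loss=%g)",
                       e, b, lg$loss))
        }
        upd <- adam_step(model$params, lg$grads, state, lr)
        model$params <- upd$params
        state <- upd$state
        losses[b] <- lg$loss
      }
      dm <- eval_dev(model$params)
      history[[e + 1L]] <- data.table(epoch = e, train_loss = mean(losses),
                                      dev_auprc = dm$auprc,
                                      dev_auroc = dm$auroc)
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f dev AUPRC %.4f AUROC %.4f",
                        e, mean(losses), dm$auprc, dm$auroc))
      }
      score <- if (has_dev_pos) {
        if (is.na(dm$auprc)) -Inf else dm$auprc
      } else {
        -mean(losses)
      }
      if (score > best$score) {
        best <- list(params = model$params, score = score, auprc = dm$auprc,
                     epoch = e)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= patience) break
      }
    }
  }
  model$params <- best$params
  structure(list(model = model, history = rbindlist(history),
                 best_epoch = best$epoch, best_dev_auprc = best$auprc,
                 selection_horizon = selection_horizon, seed = seed),
            class = "trajrisk_run")
}

#' @export
print.trajrisk_run <- function(x, ...) {
  cat("<trajrisk_run> ", x$model$config$architecture, ", ",
      nrow(x$history) - 1L, " epochs, best dev AUPRC ",
      signif(x$best_dev_auprc, 4), " at epoch ", x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' Grid search over model configurations
#'
#' Trains one model per configuration and ranks them by best development-set
#' AUPRC. Individual failures are caught and ranked last rather than
#' aborting the sweep.
#'
#' @param grid list of `trajrisk_config` objects.
#' @param data a `trajrisk_data`.
#' @param ... passed to [train_model()].
#' @return list with `ranking` (a `data.table`: grid index, architecture,
#'   dev AUPRC, error message if any, rank), `runs` (per-config
#'   `trajrisk_run` or the error condition) and `best` (the winning run).
#' @export
hyperparameter_search <- function(grid, data, ...) {
  if (length(grid) == 0L) stop("hyperparameter_search: empty grid")
  runs <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    runs[[i]] <- tryCatch(train_model(data, grid[[i]], ...),
                          error = function(e) e)
    failed <- inherits(runs[[i]], "error")
    rows[[i]] <- data.table(
      grid_index = i,
      architecture = grid[[i]]$architecture,
      dev_auprc = if (failed) NA_real_ else runs[[i]]$best_dev_auprc,
      error = if (failed) conditionMessage(runs[[i]]) else NA_character_)
  }
  ranking <- rbindlist(rows)
  ranking[, rank := frank(-dev_auprc, na.last = TRUE, ties.method = "first")]
  setorder(ranking, rank)
  best_i <- ranking$grid_index[1L]
  if (is.na(ranking$dev_auprc[1L])) stop("hyperparameter_search: every run failed")
  list(ranking = ranking[], runs = runs, best = runs[[best_i]])
}

utils::globalVariables(c("dev_auprc", "grid_index"))
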