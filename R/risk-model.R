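#' Risk model configuration
#'
#' Bundles every architectural choice of a multi-horizon risk model. The
#' encoders share an embedding of level-3 diagnosis codes and a time-aware
#' positional weighting built from cosine waveforms evaluated at the age at
#' each diagnosis and the gap since the previous diagnosis, at
#' `n_frequencies` geometrically spaced periods between `t_min_days` and
#' `t_max_days` (1 day to a century by default, spanning clinically relevant
#' scales from acute episodes to lifetime history).
#'
#' @param architecture one of `"bag_of_codes"` (order-invariant pooling of
#'   raw code embeddings, linear head), `"mlp"` (pooling plus feed-forward
#'   layers), `"gru"` (gated recurrent encoder over the dated sequence) or
#'   `"transformer"` (self-attention encoder).
#' @param embedding_dim dimension of the code embedding space.
#' @param hidden_dim encoder/head hidden width (GRU state size, MLP width,
#'   transformer feed-forward width).
#' @param n_layers encoder depth (MLP layers / GRU layers / attention blocks).
#' @param n_attention_heads attention heads (transformer only; must divide
#'   `embedding_dim`).
#' @param n_frequencies cosine frequencies per time channel (default 128).
#' @param dropout dropout fraction applied to the fingerprint during training.
#' @param token_dropout fraction of input events randomly hidden (treated as
#'   padding) per training batch. With few distinct case patients this is the
#'   regularizer that matters: it stops the encoder from memorizing exact
#'   code combinations of individual training patients, while codes that
#'   recur across patients keep their effect.
#' @param lambda2 L2 regularization strength (coefficient of the Euclidean
#'   norm of all parameters in the loss).
#' @param horizons prediction horizons in months.
#' @param monotone_head if `TRUE`, horizon logits are cumulative sums of
#'   non-negative increments, guaranteeing risk non-decreasing over horizons.
#' @param temporal_mode how positional weights combine with token embeddings:
#'   `"multiplicative"` (default; embeddings are gated elementwise by
#'   `1 + projection`) or `"additive"`.
#' @param gru_pooling how the GRU turns its state sequence into the
#'   fingerprint: `"last"` (default: the final hidden state) or `"max"`
#'   (elementwise maximum over the per-step states). Max pooling keeps the
#'   trace of a single informative code regardless of how many later events
#'   follow it; a plain final state attenuates it multiplicatively at every
#'   step, which at this package's training scales loses rare early codes in
#'   long histories.
#' @param max_seq_len trajectories longer than this keep their most recent
#'   events (default 300).
#' @param t_min_days,t_max_days period range of the cosine schedule.
#' @param seed parameter-initialization seed.
#' @return a `trajrisk_config` list.
#' @export
risk_model_config <- function(architecture = c("gru", "transformer", "mlp",
                                               "bag_of_codes"),
                              embedding_dim = 16L, hidden_dim = 16L,
                              n_layers = 1L, n_attention_heads = 1L,
                              n_frequencies = 128L, dropout = 0,
                              token_dropout = 0,
                              lambda2 = 0, horizons = c(3L, 6L, 12L, 36L, 60L),
                              monotone_head = FALSE,
                              temporal_mode = c("multiplicative", "additive"),
                              gru_pooling = c("last", "max"),
                              max_seq_len = 300L, t_min_days = 1,
                              t_max_days = 36500, seed = 1L) {
  architecture <- match.arg(architecture)
  temporal_mode <- match.arg(temporal_mode)
  gru_pooling <- match.arg(gru_pooling)
  stopifnot(lambda2 >= 0, n_frequencies >= 1, dropout >= 0, dropout < 1,
            token_dropout >= 0, token_dropout < 1,
            embedding_dim >= 1, hidden_dim >= 1, n_layers >= 1,
            t_min_days > 0, t_max_days > t_min_days)
  if (architecture == "transformer" &&
      embedding_dim %% n_attention_heads != 0L) {
    stop("embedding_dim must be a multiple of n_attention_heads")
  }
  structure(list(architecture = architecture, embedding_dim = embedding_dim,
                 hidden_dim = hidden_dim, n_layers = n_layers,
                 n_attention_heads = n_attention_heads,
                 n_frequencies = n_frequencies, dropout = dropout,
                 token_dropout = token_dropout,
                 lambda2 = lambda2, horizons = horizons,
                 monotone_head = monotone_head, temporal_mode = temporal_mode,
                 gru_pooling = gru_pooling,
                 max_seq_len = max_seq_len, t_min_days = t_min_days,
                 t_max_days = t_max_days, seed = seed),
            class = "trajrisk_config")
}

cosine_periods <- function(config) {
  k <- seq_len(config$n_frequencies) - 1L
  config$t_min_days * (config$t_max_days / config$t_min_days)^
    (k / max(1L, config$n_frequencies - 1L))
}

#' Time-aware cosine features for diagnosis events
#'
#' Each event time is encoded by cosine waveforms observed at the patient's
#' age at diagnosis and at the time elapsed since the previous diagnosis:
#' `cos(u / T_k)` for geometrically spaced periods `T_k` (both channels are
#' measured in days before entering the waveforms). The two channels are
#' concatenated; a learned projection inside the model turns them into
#' per-dimension weights for the code embedding, letting the model
#' distinguish the same diagnosis given at different ages or spacings.
#'
#' @param age_years age at the event, in (fractional) years; non-negative.
#' @param delta_days days since the previous event (0 for the first event).
#' @param n_frequencies number of cosine periods per channel.
#' @param t_min_days,t_max_days period range in days.
#' @return a numeric matrix with `length(age_years)` rows and
#'   `2 * n_frequencies` columns (age channel first).
#' @export
temporal_encoding <- function(age_years, delta_days, n_frequencies = 128L,
                              t_min_days = 1, t_max_days = 36500) {
  if (any(age_years < 0) || any(delta_days < 0)) {
    stop("temporal_encoding: negative times")
  }
  k <- seq_len(n_frequencies) - 1L
  periods <- t_min_days * (t_max_days / t_min_days)^
    (k / max(1L, n_frequencies - 1L))
  age_days <- age_years * 365.25
  cbind(cos(outer(age_days, 1 / periods)),
        cos(outer(as.numeric(delta_days), 1 / periods)))
}

rand_mat <- function(nr, nc, fan_in = nr) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(1 / fan_in)), nr, nc)
}

fingerprint_dim <- function(config) {
  switch(config$architecture,
         bag_of_codes = config$embedding_dim,
         mlp = config$hidden_dim,
         gru = config$hidden_dim,
         transformer = config$embedding_dim)
}

#' Initialize a risk model
#'
#' Allocates all trainable parameters (code embeddings, temporal projection,
#' encoder and prediction head) with seeded fan-in-scaled random values. The
#' padding token embeds to a fixed zero vector.
#'
#' @param config a `trajrisk_config`.
#' @param vocab a `trajrisk_vocab`.
#' @return a `trajrisk_model`: list with `config`, `vocab` and `params`
#'   (named list of matrices).
#' @export
init_risk_model <- function(config, vocab) {
  stopifnot(inherits(config, "trajrisk_config"),
            inherits(vocab, "trajrisk_vocab"))
  d <- config$embedding_dim
  h <- config$hidden_dim
  nh <- length(config$horizons)
  with_preserved_seed(config$seed, {
    p <- list()
    p$E <- rand_mat(vocab$pad_index, d, fan_in = d)
    p$E[vocab$pad_index, ] <- 0
    if (config$architecture != "bag_of_codes") {
      # small init => temporal gate starts near identity in multiplicative mode
      p$Wt <- rand_mat(2L * config$n_frequencies, d,
                       fan_in = 2L * config$n_frequencies) * 0.1
    }
    if (config$architecture == "gru") {
      for (l in seq_len(config$n_layers)) {
        din <- if (l == 1L) d else h
        for (gate in c("r", "z", "n")) {
          p[[paste0("Wx", gate, l)]] <- rand_mat(din, h)
          p[[paste0("Wh", gate, l)]] <- rand_mat(h, h)
          p[[paste0("b", gate, l)]] <- matrix(0, 1L, h)
        }
        # positive update-gate bias biases the state toward retention, so a
        # single informative code early in a long history survives to the
        # final state (the recurrent analogue of the LSTM forget-gate-bias
        # convention)
        p[[paste0("bz", l)]][] <- 1.5
      }
    } else if (config$architecture == "mlp") {
      for (l in seq_len(config$n_layers)) {
        din <- if (l == 1L) d else h
        p[[paste0("Wm", l)]] <- rand_mat(din, h)
        p[[paste0("bm", l)]] <- matrix(0, 1L, h)
      }
    } else if (config$architecture == "transformer") {
      for (l in seq_len(config$n_layers)) {
        p[[paste0("Wq", l)]] <- rand_mat(d, d)
        p[[paste0("Wk", l)]] <- rand_mat(d, d)
        p[[paste0("Wv", l)]] <- rand_mat(d, d)
        p[[paste0("Wo", l)]] <- rand_mat(d, d)
        p[[paste0("Wf1", l)]] <- rand_mat(d, h)
        p[[paste0("bf1", l)]] <- matrix(0, 1L, h)
        p[[paste0("Wf2", l)]] <- rand_mat(h, d)
        p[[paste0("bf2", l)]] <- matrix(0, 1L, d)
      }
    }
    fp <- fingerprint_dim(config)
    if (config$architecture == "bag_of_codes") {
      p$Wl <- rand_mat(fp + 1L, nh) # single linear layer head (+ age input)
      p$bl <- matrix(0, 1L, nh)
    } else {
      p$W1 <- rand_mat(fp + 1L, h)
      p$b1 <- matrix(0, 1L, h)
      p$W2 <- rand_mat(h, nh)
      p$b2 <- matrix(0, 1L, nh)
    }
    structure(list(config = config, vocab = vocab, params = p),
              class = "trajrisk_model")
  })
}

#' @export
print.trajrisk_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<trajrisk_model> ", x$config$architecture, " encoder, ",
      length(x$vocab$tokens), " tokens, ", np, " parameters\n", sep = "")
  invisible(x)
}

#' Look up code embeddings
#'
#' @param model a `trajrisk_model`.
#' @param token_indices integer vocabulary indices (the padding index embeds
#'   to the zero vector).
#' @return matrix `length(token_indices) x embedding_dim`.
#' @export
embed_tokens <- function(model, token_indices) {
  V <- model$vocab$pad_index
  if (any(token_indices < 1L | token_indices > V)) {
    stop("embed_tokens: index outside vocabulary [1, ", V, "]")
  }
  model$params$E[token_indices, , drop = FALSE]
}

l2_norm <- function(params) {
  sqrt(sum(vapply(params, function(m) sum(m^2), numeric(1))))
}

#' Masked multi-horizon cross-entropy loss
#'
#' The training objective: the mean over trajectories of the mean masked
#' binary cross-entropy over that trajectory's informative horizons (its
#' `N_T` unmasked horizons), plus `lambda2` times the Euclidean norm of all
#' model parameters. Predicted risks are clipped to
#' `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param p_hat numeric matrix `n x n_horizons` of predicted risks.
#' @param y,mask binary matrices of the same shape (`mask` selects the
#'   horizons contributing to the loss; a batch with an all-masked row is
#'   rejected).
#' @param lambda2 regularization strength.
#' @param params optional parameter list for the penalty term.
#' @return scalar loss.
#' @export
multi_horizon_loss <- function(p_hat, y, mask, lambda2 = 0, params = NULL) {
  stopifnot(all(dim(p_hat) == dim(y)), all(dim(y) == dim(mask)))
  nt <- rowSums(mask)
  if (any(nt == 0)) stop("multi_horizon_loss: trajectory with all horizons masked")
  p <- pmin(pmax(p_hat, .eps_prob), 1 - .eps_prob)
  ce <- -(y * log(p) + (1 - y) * log(1 - p))
  data_term <- mean(rowSums(ce * mask) / nt)
  pen <- if (lambda2 > 0 && !is.null(params)) lambda2 * l2_norm(params) else 0
  data_term + pen
}

## ------------------------------------------------------------------------
## batched forward pass (autodiff)

# batch: list(idx, mask, agemat, deltamat [B x L], age_assess [B], lens [B])
make_batch <- function(data, rows, max_seq_len) {
  B <- nrow(rows)
  lens <- pmin(rows$end_idx, max_seq_len)
  L <- max(lens)
  pad <- data$vocab$pad_index
  idx <- matrix(pad, B, L)
  msk <- matrix(0, B, L)
  agemat <- matrix(0, B, L)
  deltamat <- matrix(0, B, L)
  seqs <- data$sequences[rows$patient_id]
  for (i in seq_len(B)) {
    s <- seqs[[i]]
    take <- seq.int(rows$end_idx[i] - lens[i] + 1L, rows$end_idx[i])
    li <- lens[i]
    idx[i, seq_len(li)] <- s$idx[take]
    msk[i, seq_len(li)] <- 1
    agemat[i, seq_len(li)] <- s$ages[take]
    deltamat[i, seq_len(li)] <- s$deltas[take]
  }
  list(idx = idx, mask = msk, agemat = agemat, deltamat = deltamat,
       age_assess = rows$age_at_assessment, lens = lens)
}

# embedding + temporal weighting for timestep t -> B x d node
embedded_step <- function(tape, pn, config, batch, periods, t,
                          emb_override = NULL) {
  X <- if (is.null(emb_override)) {
    ad_rows(tape, pn$E, batch$idx[, t])
  } else {
    emb_override[[t]]
  }
  if (config$architecture == "bag_of_codes") return(X)
  tf <- cbind(cos(outer(batch$agemat[, t] * 365.25, 1 / periods)),
              cos(outer(batch$deltamat[, t], 1 / periods)))
  P <- ad_matmul(tape, tf, pn$Wt)
  if (config$temporal_mode == "multiplicative") {
    ad_emul(tape, X, ad_addconst(tape, P, 1))
  } else {
    ad_add(tape, X, P)
  }
}

encode_gru <- function(tape, pn, config, steps, batch) {
  B <- nrow(batch$idx)
  h <- config$hidden_dim
  inputs <- steps
  for (l in seq_len(config$n_layers)) {
    H <- matrix(0, B, h)
    outputs <- vector("list", length(inputs))
    Wxr <- pn[[paste0("Wxr", l)]]; Whr <- pn[[paste0("Whr", l)]]
    Wxz <- pn[[paste0("Wxz", l)]]; Whz <- pn[[paste0("Whz", l)]]
    Wxn <- pn[[paste0("Wxn", l)]]; Whn <- pn[[paste0("Whn", l)]]
    br <- pn[[paste0("br", l)]]; bz <- pn[[paste0("bz", l)]]
    bn <- pn[[paste0("bn", l)]]
    for (t in seq_along(inputs)) {
      Xt <- inputs[[t]]
      r <- ad_sigmoid(tape, ad_add_bias(tape, ad_add(
        tape, ad_matmul(tape, Xt, Wxr), ad_matmul(tape, H, Whr)), br))
      z <- ad_sigmoid(tape, ad_add_bias(tape, ad_add(
        tape, ad_matmul(tape, Xt, Wxz), ad_matmul(tape, H, Whz)), bz))
      n <- ad_tanh(tape, ad_add_bias(tape, ad_add(
        tape, ad_matmul(tape, Xt, Wxn),
        ad_emul(tape, r, ad_matmul(tape, H, Whn))), bn))
      one_minus_z <- ad_addconst(tape, ad_scale(tape, z, -1), 1)
      Hcand <- ad_add(tape, ad_emul(tape, one_minus_z, n), ad_emul(tape, z, H))
      m <- batch$mask[, t]
      # padded positions carry the previous state forward
      H <- ad_add(tape, ad_rowscale(tape, Hcand, m), ad_rowscale(tape, H, 1 - m))
      outputs[[t]] <- H
    }
    inputs <- outputs
  }
  if (identical(config$gru_pooling, "max")) {
    # padded steps repeat the previous state, so they never win the max
    fp <- inputs[[1L]]
    if (length(inputs) > 1L) {
      for (t in 2:length(inputs)) fp <- ad_pairmax(tape, fp, inputs[[t]])
    }
    fp
  } else {
    inputs[[length(inputs)]]
  }
}

encode_pool <- function(tape, config, steps, batch) {
  acc <- NULL
  for (t in seq_along(steps)) {
    term <- ad_rowscale(tape, steps[[t]], batch$mask[, t])
    acc <- if (is.null(acc)) term else ad_add(tape, acc, term)
  }
  ad_rowscale(tape, acc, 1 / batch$lens)
}

encode_mlp <- function(tape, pn, config, steps, batch) {
  Hc <- encode_pool(tape, config, steps, batch)
  for (l in seq_len(config$n_layers)) {
    Hc <- ad_tanh(tape, ad_add_bias(
      tape, ad_matmul(tape, Hc, pn[[paste0("Wm", l)]]),
      pn[[paste0("bm", l)]]))
  }
  Hc
}

# single-sequence attention stack (steps are 1 x d rows of one sequence)
encode_transformer_one <- function(tape, pn, config, X, li) {
  d <- config$embedding_dim
  nh <- config$n_attention_heads
  dk <- d %/% nh
  for (l in seq_len(config$n_layers)) {
    Q <- ad_matmul(tape, X, pn[[paste0("Wq", l)]])
    K <- ad_matmul(tape, X, pn[[paste0("Wk", l)]])
    V <- ad_matmul(tape, X, pn[[paste0("Wv", l)]])
    heads <- vector("list", nh)
    for (hh in seq_len(nh)) {
      cols <- ((hh - 1L) * dk + 1L):(hh * dk)
      Qh <- ad_cols(tape, Q, cols)
      Kh <- ad_cols(tape, K, cols)
      Vh <- ad_cols(tape, V, cols)
      A <- ad_softmax_rows(tape, ad_scale(
        tape, ad_matmul(tape, Qh, ad_transpose(tape, Kh)), 1 / sqrt(dk)))
      heads[[hh]] <- ad_matmul(tape, A, Vh)
    }
    Z <- heads[[1L]]
    if (nh > 1L) for (hh in 2:nh) Z <- ad_cbind(tape, Z, heads[[hh]])
    X <- ad_add(tape, X, ad_matmul(tape, Z, pn[[paste0("Wo", l)]]))
    FF <- ad_tanh(tape, ad_add_bias(
      tape, ad_matmul(tape, X, pn[[paste0("Wf1", l)]]),
      pn[[paste0("bf1", l)]]))
    X <- ad_add(tape, X, ad_add_bias(
      tape, ad_matmul(tape, FF, pn[[paste0("Wf2", l)]]),
      pn[[paste0("bf2", l)]]))
  }
  ad_colmeans(tape, X)
}

head_forward <- function(tape, pn, config, fp, age_node, dropout_mask = NULL) {
  if (!is.null(dropout_mask)) fp <- ad_emul(tape, fp, dropout_mask)
  inp <- ad_cbind(tape, fp, age_node)
  logits <- if (config$architecture == "bag_of_codes") {
    ad_add_bias(tape, ad_matmul(tape, inp, pn$Wl), pn$bl)
  } else {
    Hh <- ad_tanh(tape, ad_add_bias(tape, ad_matmul(tape, inp, pn$W1), pn$b1))
    ad_add_bias(tape, ad_matmul(tape, Hh, pn$W2), pn$b2)
  }
  if (config$monotone_head) {
    nhz <- length(config$horizons)
    base <- ad_cols(tape, logits, 1L)
    cols <- vector("list", nhz)
    cols[[1L]] <- base
    acc <- base
    for (j in 2:nhz) {
      acc <- ad_add(tape, acc, ad_softplus(tape, ad_cols(tape, logits, j)))
      cols[[j]] <- acc
    }
    logits <- cols[[1L]]
    for (j in 2:nhz) logits <- ad_cbind(tape, logits, cols[[j]])
  }
  ad_sigmoid(tape, logits)
}

# full forward pass: returns list(p, fingerprint) of ad nodes
model_forward <- function(tape, pn, config, batch, emb_override = NULL,
                          age_override = NULL, dropout_mask = NULL) {
  periods <- cosine_periods(config)
  B <- nrow(batch$idx)
  L <- ncol(batch$idx)
  age_node <- if (is.null(age_override)) {
    matrix(pmin(batch$age_assess, 110) / 110, B, 1L)
  } else {
    age_override
  }
  if (config$architecture == "transformer") {
    rows <- vector("list", B)
    for (i in seq_len(B)) {
      li <- batch$lens[i]
      sub <- list(idx = batch$idx[i, seq_len(li), drop = FALSE],
                  mask = batch$mask[i, seq_len(li), drop = FALSE],
                  agemat = batch$agemat[i, seq_len(li), drop = FALSE],
                  deltamat = batch$deltamat[i, seq_len(li), drop = FALSE])
      over <- if (!is.null(emb_override)) emb_override[[i]] else NULL
      steps <- lapply(seq_len(li), function(t) {
        embedded_step(tape, pn, config, sub, periods, t,
                      emb_override = over)
      })
      Xn <- ad_stack_seq(tape, steps)
      rows[[i]] <- encode_transformer_one(tape, pn, config, Xn, li)
    }
    fp <- ad_stack_rows(tape, rows)
  } else {
    steps <- lapply(seq_len(L), function(t) {
      embedded_step(tape, pn, config, batch, periods, t, emb_override)
    })
    fp <- switch(config$architecture,
                 gru = encode_gru(tape, pn, config, steps, batch),
                 mlp = encode_mlp(tape, pn, config, steps, batch),
                 bag_of_codes = encode_pool(tape, config, steps, batch))
  }
  p <- head_forward(tape, pn, config, fp, age_node, dropout_mask)
  list(p = p, fingerprint = fp)
}

# stack 1-row (or k-row) step nodes vertically into one sequence matrix
ad_stack_seq <- function(tape, steps) {
  out <- steps[[1L]]
  if (length(steps) > 1L) {
    for (t in 2:length(steps)) out <- ad_rbind2(tape, out, steps[[t]])
  }
  out
}

# loss node (data term only; the L2 penalty and its gradient are analytic)
loss_node <- function(tape, p, y, mask) {
  nt <- rowSums(mask)
  if (any(nt == 0)) stop("loss_node: trajectory with all horizons masked")
  w <- mask / nt / nrow(y)
  pc <- ad_clamp(tape, p, .eps_prob, 1 - .eps_prob)
  pos <- ad_emul(tape, ad_log(tape, pc), y * w)
  neg <- ad_emul(tape, ad_log(tape, ad_addconst(
    tape, ad_scale(tape, pc, -1), 1)), (1 - y) * w)
  ad_scale(tape, ad_sum(tape, ad_add(tape, pos, neg)), -1)
}

#' Score trajectories with a risk model
#'
#' @param model a `trajrisk_model`.
#' @param data a `trajrisk_data`.
#' @param rows optional subset of `data$trajectories` (default: all rows).
#' @param batch_size forward-pass chunk size.
#' @return numeric matrix `nrow(rows) x n_horizons` of risks in (0, 1),
#'   columns named by horizon.
#' @export
predict_risk <- function(model, data, rows = NULL, batch_size = 512L) {
  if (is.null(rows)) rows <- data$trajectories
  if (nrow(rows) == 0L) {
    out <- matrix(numeric(0), 0L, length(model$config$horizons))
    colnames(out) <- paste0("p", model$config$horizons)
    return(out)
  }
  # process in length order so padded batches stay dense
  ord <- order(pmin(rows$end_idx, model$config$max_seq_len))
  out <- matrix(NA_real_, nrow(rows), length(model$config$horizons))
  for (start in seq(1L, length(ord), by = batch_size)) {
    take <- ord[start:min(start + batch_size - 1L, length(ord))]
    tape <- ad_tape()
    batch <- make_batch(data, rows[take], model$config$max_seq_len)
    fw <- model_forward(tape, model$params, model$config, batch)
    out[take, ] <- ad_val(fw$p)
  }
  colnames(out) <- paste0("p", model$config$horizons)
  out
}
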