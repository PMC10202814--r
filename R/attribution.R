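ig_alphas <- function(n_steps) (seq_len(n_steps) - 0.5) / n_steps # midpoint rule

# forward value of the selected horizon risk for one trajectory, with the
# embedding-layer output (and scaled age) replaced by given constants
ig_forward_value <- function(model, batch, emb_rows, age_val, h_col) {
  tape <- ad_tape()
  L <- ncol(batch$idx)
  override <- lapply(seq_len(L), function(t) emb_rows[t, , drop = FALSE])
  if (model$config$architecture == "transformer") override <- list(override)
  fw <- model_forward(tape, model$params, model$config, batch,
                      emb_override = override,
                      age_override = matrix(age_val, 1L, 1L))
  ad_val(fw$p)[1L, h_col]
}

#' Integrated-gradients attribution for one trajectory
#'
#' Attributes a model's risk output (the 36-month horizon by default) to the
#' individual diagnosis events of one trajectory and to the age input.
#' Because gradients cannot flow into categorical code indices, attribution
#' is taken at the output of the embedding layer: the path integral of the
#' output gradient is accumulated from a baseline (the zero embedding, by
#' default) to the trajectory's embedding output, approximated by a midpoint
#' Riemann sum over `n_steps` interpolation points. Per-event scores sum the
#' integrand over embedding dimensions; positive scores mark events pushing
#' the predicted risk up. The completeness identity
#' `sum(attributions) + age_attribution ~ F(input) - F(baseline)` is
#' returned for diagnostics.
#'
#' @param model a trained `trajrisk_model`.
#' @param data a `trajrisk_data`.
#' @param traj_id trajectory id (row of `data$trajectories`).
#' @param n_steps Riemann steps (>= 16; default 128).
#' @param output_horizon horizon in months whose risk output is attributed.
#' @param baseline `"zero"` (the zero embedding and age 0) is the reference
#'   input against which contributions are measured.
#' @return list with `events` (a `data.table`: position, token_index, token,
#'   attribution), `age_attribution`, `f_input`, `f_baseline` and
#'   `completeness_gap`.
#' @export
integrated_gradients <- function(model, data, traj_id, n_steps = 128L,
                                 output_horizon = 36L, baseline = "zero") {
  stopifnot(n_steps >= 16L)
  baseline <- match.arg(baseline, "zero")
  if (!output_horizon %in% model$config$horizons) {
    stop("integrated_gradients: horizon not in model horizons")
  }
  h_col <- match(output_horizon, model$config$horizons)
  row_idx <- which(data$trajectories[["traj_id"]] == traj_id) # plain vector op
  row <- data$trajectories[row_idx]
  if (nrow(row) != 1L) stop("integrated_gradients: unknown traj_id ", traj_id)
  batch <- make_batch(data, row, model$config$max_seq_len)
  L <- ncol(batch$idx)
  tok_idx <- batch$idx[1L, ]
  emb <- model$params$E[tok_idx, , drop = FALSE] # embedding-layer output
  age_val <- min(batch$age_assess[1L], 110) / 110
  alphas <- ig_alphas(n_steps)

  if (model$config$architecture == "transformer") {
    # sequential path: one forward/backward per interpolation point
    grad_sum <- matrix(0, L, ncol(emb))
    age_grad_sum <- 0
    for (a in alphas) {
      tape <- ad_tape()
      leaves <- lapply(seq_len(L), function(t) {
        ad_leaf(tape, emb[t, , drop = FALSE] * a)
      })
      age_leaf <- ad_leaf(tape, matrix(age_val * a, 1L, 1L))
      fw <- model_forward(tape, model$params, model$config, batch,
                          emb_override = list(leaves),
                          age_override = age_leaf)
      seed <- matrix(0, 1L, length(model$config$horizons))
      seed[1L, h_col] <- 1
      ad_backward(tape, fw$p, seed)
      for (t in seq_len(L)) {
        if (!is.null(leaves[[t]]$grad)) {
          grad_sum[t, ] <- grad_sum[t, ] + leaves[[t]]$grad
        }
      }
      if (!is.null(age_leaf$grad)) age_grad_sum <- age_grad_sum + age_leaf$grad[1L, 1L]
      if (!all(is.finite(grad_sum))) stop("integrated_gradients: non-finite gradients")
    }
    mean_grad <- grad_sum / n_steps
    age_attr <- age_val * age_grad_sum / n_steps
  } else {
    # batched path: the n_steps interpolation points form one batch
    m <- n_steps
    rep_rows <- function(x) x[rep(1L, m), , drop = FALSE]
    bigb <- list(idx = rep_rows(batch$idx), mask = rep_rows(batch$mask),
                 agemat = rep_rows(batch$agemat),
                 deltamat = rep_rows(batch$deltamat),
                 age_assess = rep(batch$age_assess[1L], m),
                 lens = rep(batch$lens[1L], m))
    tape <- ad_tape()
    leaves <- lapply(seq_len(L), function(t) {
      ad_leaf(tape, outer(alphas, emb[t, ]))
    })
    age_leaf <- ad_leaf(tape, matrix(alphas * age_val, m, 1L))
    fw <- model_forward(tape, model$params, model$config, bigb,
                        emb_override = leaves, age_override = age_leaf)
    seed <- matrix(0, m, length(model$config$horizons))
    seed[, h_col] <- 1
    ad_backward(tape, fw$p, seed)
    mean_grad <- t(vapply(leaves, function(l) {
      if (is.null(l$grad)) numeric(ncol(emb)) else colMeans(l$grad)
    }, numeric(ncol(emb))))
    if (!all(is.finite(mean_grad))) stop("integrated_gradients: non-finite gradients")
    age_attr <- age_val *
      (if (is.null(age_leaf$grad)) 0 else mean(age_leaf$grad))
  }

  event_attr <- rowSums(emb * mean_grad)
  f_in <- ig_forward_value(model, batch, emb, age_val, h_col)
  f_base <- ig_forward_value(model, batch, emb * 0, 0, h_col)
  tokens <- c(model$vocab$tokens, "<pad>")[tok_idx]
  list(events = data.table(position = seq_len(L), token_index = tok_idx,
                           token = tokens, attribution = event_attr),
       age_attribution = age_attr, f_input = f_in, f_baseline = f_base,
       completeness_gap = (sum(event_attr) + age_attr) - (f_in - f_base))
}

#' @rdname integrated_gradients
#' @export
age_attribution <- function(model, data, traj_id, n_steps = 128L,
                            output_horizon = 36L) {
  integrated_gradients(model, data, traj_id, n_steps,
                       output_horizon)$age_attribution
}

#' Aggregate attributions over cancer trajectories by time-to-cancer bin
#'
#' Runs integrated gradients on cancer trajectories and sums the per-event
#' contribution of each diagnosis code within time-to-cancer bins (months
#' between assessment and diagnosis). This separates codes that drive risk
#' shortly before diagnosis (symptoms) from early risk factors whose
#' contribution persists years ahead. Raw signed sums are reported alongside
#' a per-occurrence normalized view; the padding token never appears.
#'
#' @param model a trained `trajrisk_model`.
#' @param data a `trajrisk_data`.
#' @param rows cancer trajectory rows to attribute (default: all cancer
#'   trajectories of the test split with `time_to_cancer` inside the bins).
#' @param bin_edges time-to-cancer bin edges in months (default
#'   `c(0, 6, 12, 24, 36)`).
#' @param n_steps Riemann steps per trajectory.
#' @param max_per_bin optional cap on trajectories attributed per bin (the
#'   earliest `traj_id`s are kept; deterministic).
#' @inheritParams integrated_gradients
#' @return a `data.table` with columns `bin`, `token`, `contribution`,
#'   `n_occurrences`, `contribution_per_occurrence` and `rank_in_bin`
#'   (1 = largest contribution), sorted within bin.
#' @export
aggregate_attributions <- function(model, data, rows = NULL,
                                   bin_edges = c(0, 6, 12, 24, 36),
                                   n_steps = 128L, output_horizon = 36L,
                                   max_per_bin = NULL) {
  if (is.null(rows)) {
    rows <- data$trajectories[data$trajectories$split == "test" &
                                data$trajectories$is_case]
  }
  rows <- rows[!is.na(time_to_cancer) &
                 time_to_cancer >= bin_edges[1L] &
                 time_to_cancer < bin_edges[length(bin_edges)]]
  if (nrow(rows) == 0L) {
    return(data.table(bin = character(0), token = character(0),
                      contribution = numeric(0), n_occurrences = integer(0),
                      contribution_per_occurrence = numeric(0),
                      rank_in_bin = integer(0)))
  }
  rows <- copy(rows)
  rows[, bin := as.character(cut(time_to_cancer, bin_edges, right = FALSE))]
  if (!is.null(max_per_bin)) {
    setorder(rows, bin, traj_id)
    rows <- rows[, utils::head(.SD, max_per_bin), by = bin]
  }
  pieces <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    ig <- integrated_gradients(model, data, rows$traj_id[i], n_steps,
                               output_horizon)
    ev <- ig$events[token != "<pad>"]
    ev[, bin := rows$bin[i]]
    pieces[[i]] <- ev
  }
  all_ev <- rbindlist(pieces)
  out <- all_ev[, .(contribution = sum(attribution), n_occurrences = .N),
                by = .(bin, token)]
  out[, contribution_per_occurrence := contribution / n_occurrences]
  setorder(out, bin, -contribution)
  out[, rank_in_bin := seq_len(.N), by = bin]
  out[]
}

utils::globalVariables(c("attribution", "position"))
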