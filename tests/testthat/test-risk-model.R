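test_that("token embeddings are deterministic lookups with a zero pad row", {
  d <- small_gen_data()
  m <- init_risk_model(tiny_model_config(), d$vocab)
  E <- embed_tokens(m, c(1L, 2L, 1L, m$vocab$pad_index))
  expect_equal(E[1, ], E[3, ]) # same token, same row
  expect_false(isTRUE(all.equal(E[1, ], E[2, ]))) # distinct tokens differ
  expect_equal(E[4, ], rep(0, ncol(E))) # padding embeds to zero
  expect_error(embed_tokens(m, m$vocab$pad_index + 1L), "outside vocabulary")
})

test_that("temporal cosine features behave at the origin and reject bad input", {
  f0 <- temporal_encoding(0, 0, n_frequencies = 16)
  expect_equal(as.numeric(f0), rep(1, 32)) # cos(0) = 1 in every channel
  f1 <- temporal_encoding(40, 10, n_frequencies = 16)
  expect_identical(f1, temporal_encoding(40, 10, n_frequencies = 16))
  expect_false(isTRUE(all.equal(f1, temporal_encoding(70, 10,
                                                      n_frequencies = 16))))
  expect_error(temporal_encoding(-1, 0), "negative")
  expect_equal(dim(temporal_encoding(c(1, 2), c(0, 3), n_frequencies = 8)),
               c(2, 16))
})

# two cohorts with identical same-day events in different input order:
# stable sorting preserves the input order, so sequence encoders see
# genuinely permuted sequences while pooling encoders must not care
permuted_pair <- function() {
  day <- d_("2005-06-01")
  patients <- data.frame(patient_id = c("p", "q", "r"),
                         birth_date = d_("1950-01-01"), sex = NA,
                         end_of_data = d_("2018-01-01"), cancer_date = d_(NA))
  codes <- c("A10", "B20", "C30", "D40", "E50", "F60")
  mk <- function(ord) {
    ev <- rbind(
      data.frame(patient_id = "p", date = day, code = codes[ord],
                 system = "icd10"),
      data.frame(patient_id = rep(c("q", "r"), each = 5),
                 date = d_("2001-01-01") + rep(1:5, 2) * 30,
                 code = "Z99", system = "icd10"))
    as_cohort(patients, ev)
  }
  list(mk(1:6), mk(c(4, 2, 6, 1, 5, 3)))
}

test_that("bag-of-codes is order invariant; the GRU is order sensitive", {
  pair <- permuted_pair()
  d1 <- prepare_trajectories(pair[[1]], seed = 1)
  d2 <- prepare_trajectories(pair[[2]], seed = 1)
  expect_identical(d1$vocab$tokens, d2$vocab$tokens)
  last1 <- d1$trajectories[patient_id == "p"][which.max(end_idx)]
  last2 <- d2$trajectories[patient_id == "p"][which.max(end_idx)]

  mb <- init_risk_model(tiny_model_config("bag_of_codes"), d1$vocab)
  expect_equal(predict_risk(mb, d1, last1), predict_risk(mb, d2, last2),
               tolerance = 1e-12)
  mg <- init_risk_model(tiny_model_config("gru"), d1$vocab)
  expect_false(isTRUE(all.equal(predict_risk(mg, d1, last1),
                                predict_risk(mg, d2, last2))))
})

test_that("padding positions contribute nothing in any architecture", {
  d <- small_gen_data()
  rows <- d$trajectories[order(end_idx)][c(1, .N - 1, .N)]
  for (arch in c("bag_of_codes", "mlp", "gru", "transformer")) {
    m <- init_risk_model(tiny_model_config(arch), d$vocab)
    # scoring one-by-one (no padding) must match the padded batch
    batched <- predict_risk(m, d, rows)
    for (i in seq_len(nrow(rows))) {
      expect_equal(predict_risk(m, d, rows[i])[1, ], batched[i, ],
                   tolerance = 1e-10, info = arch)
    }
  }
})

test_that("a zeroed head yields risk one half; the monotone head sorts scores", {
  d <- small_gen_data()
  m <- init_risk_model(tiny_model_config("gru"), d$vocab)
  m$params$W2[] <- 0
  m$params$b2[] <- 0
  p <- predict_risk(m, d, d$trajectories[1:4])
  expect_equal(as.numeric(p), rep(0.5, length(p)))

  for (s in 1:10) {
    mm <- init_risk_model(tiny_model_config("gru", monotone_head = TRUE,
                                            seed = s), d$vocab)
    pm <- predict_risk(mm, d, d$trajectories[seq(1, 200, by = 17)])
    expect_true(all(t(apply(pm, 1, diff)) >= 0))
    expect_true(all(pm > 0 & pm < 1))
  }
})

test_that("the batched loss equals a scalar oracle, including masks and the L2 term", {
  set.seed(31)
  d <- small_gen_data()
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    p_hat <- matrix(runif(n * 5, 0.01, 0.99), n, 5)
    y <- matrix(rbinom(n * 5, 1, 0.4), n, 5)
    mask <- matrix(1, n, 5)
    mask[sample(n * 5, 4)] <- 0
    mask[rowSums(mask) == 0, 1] <- 1 # keep every row informative
    params <- list(a = matrix(rnorm(4), 2), b = matrix(rnorm(2), 1))
    lam <- runif(1, 0, 0.1)
    expect_equal(multi_horizon_loss(p_hat, y, mask, lam, params),
                 oracle_loss(p_hat, y, mask, lam, params),
                 tolerance = 1e-6)
  }
  # the differentiable graph computes the same data term
  mc <- tiny_model_config("gru", lambda2 = 0.03)
  m <- init_risk_model(mc, d$vocab)
  rows <- d$trajectories[c(1:3, which(d$trajectories$is_case)[1])]
  lg <- trajrisk:::model_loss_and_grads(m$params, mc, d, rows)
  lab <- trajrisk:::label_matrices(d, rows)
  p <- predict_risk(m, d, rows)
  expect_equal(lg$loss, oracle_loss(p, lab$y, lab$mask, mc$lambda2, m$params),
               tolerance = 1e-6)

  # single sample, single unmasked horizon at p = 0.5 gives ln 2
  expect_equal(multi_horizon_loss(matrix(0.5, 1, 5),
                                  matrix(0, 1, 5),
                                  matrix(c(1, 0, 0, 0, 0), 1, 5)),
               log(2), tolerance = 1e-12)
  # perfect prediction: loss vanishes (up to the clipping epsilon)
  y1 <- matrix(c(0, 0, 1, 1, 1), 1, 5)
  expect_lt(multi_horizon_loss(y1, y1, matrix(1, 1, 5)), 1e-5)
  expect_error(multi_horizon_loss(matrix(0.5, 1, 5), matrix(0, 1, 5),
                                  matrix(0, 1, 5)), "masked")
})

test_that("backpropagated gradients match finite differences", {
  d <- small_gen_data()
  rows <- d$trajectories[c(1, 2, which(d$trajectories$is_case)[1])]
  eps <- 1e-5
  for (arch in c("gru", "transformer")) {
    mc <- tiny_model_config(arch, lambda2 = 0.01)
    m <- init_risk_model(mc, d$vocab)
    lg <- trajrisk:::model_loss_and_grads(m$params, mc, d, rows)
    set.seed(5)
    for (nm in names(m$params)) {
      for (ii in sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))) {
        up <- m$params; up[[nm]][ii] <- up[[nm]][ii] + eps
        dn <- m$params; dn[[nm]][ii] <- dn[[nm]][ii] - eps
        fd <- (trajrisk:::model_loss_and_grads(up, mc, d, rows)$loss -
                 trajrisk:::model_loss_and_grads(dn, mc, d, rows)$loss) / (2 * eps)
        an <- lg$grads[[nm]][ii]
        if (nm == "E" && (ii - 1) %% nrow(m$params$E) + 1 == d$vocab$pad_index) next
        expect_equal(an, fd, tolerance = 1e-4,
                     info = sprintf("%s %s[%d]", arch, nm, ii))
      }
    }
  }
})

test_that("the L2 penalty decomposes additively from the data term", {
  d <- small_gen_data()
  rows <- d$trajectories[1:4]
  mc0 <- tiny_model_config("mlp", lambda2 = 0)
  mc1 <- tiny_model_config("mlp", lambda2 = 0.25)
  m <- init_risk_model(mc0, d$vocab)
  l0 <- trajrisk:::model_loss_and_grads(m$params, mc0, d, rows)$loss
  l1 <- trajrisk:::model_loss_and_grads(m$params, mc1, d, rows)$loss
  expect_equal(l1 - l0, 0.25 * trajrisk:::l2_norm(m$params), tolerance = 1e-10)
})

test_that("model checkpoints round-trip and refuse mismatched vocabularies", {
  d <- small_gen_data()
  m <- init_risk_model(tiny_model_config("mlp"), d$vocab)
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f, vocab = d$vocab)
  expect_equal(m2$params, m$params)
  expect_equal(predict_risk(m2, d, d$trajectories[1:2]),
               predict_risk(m, d, d$trajectories[1:2]))
  other <- build_vocabulary(data.frame(code = c("Z00", "Z01"),
                                       system = "icd10"))
  expect_error(load_model(f, vocab = other), "mismatch")
})
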