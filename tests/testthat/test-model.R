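test_that("encoder and decoder follow the tanh closed forms", {
  p <- manual_params(diag(2), c(0, 0), diag(2), c(0, 0), matrix(0, 2, 2))
  expect_equal(encode_rows(c(0.5, -0.5), p),
               matrix(tanh(c(0.5, -0.5)), 1), ignore_attr = TRUE)
  # zero input, zero parameters -> zero output at any depth
  pz <- init_params(10, c(6, 4), 2, 10, seed = 1)
  for (nm in names(pz$arr)) pz$arr[[nm]][] <- 0
  expect_equal(encode_rows(matrix(0, 3, 10), pz), matrix(0, 3, 2))
  expect_equal(decode_codes(matrix(0, 3, 2), pz), matrix(0, 3, 10))
  # outputs bounded in (-1, 1), shapes mirror
  pr <- init_params(10, c(6, 4), 2, 10, seed = 2)
  Y <- encode_rows(matrix(rnorm(30) * 10, 3, 10), pr)
  expect_true(all(abs(Y) < 1))
  Rhat <- decode_codes(Y, pr)
  expect_equal(dim(Rhat), c(3, 10))
  expect_true(all(abs(Rhat) < 1))
  expect_error(encode_rows(matrix(0, 2, 9), pr), "input width")
  expect_error(decode_codes(matrix(0, 2, 3), pr), "code width")
  expect_error(init_params(5, c(8), 2, 5), "strictly decrease")
})

test_that("autoencoder loss applies the elementwise penalty", {
  expect_equal(autoencoder_loss(matrix(1, 2, 2), matrix(1, 2, 2)), 0)
  # error on a zero entry weighs 1
  expect_equal(autoencoder_loss(matrix(c(0, 1), 1), matrix(c(1, 1), 1),
                                matrix(c(1, 2), 1)), 1)
  # error on a nonzero entry weighs chi = 2
  expect_equal(autoencoder_loss(matrix(c(1, 0), 1), matrix(c(0, 0), 1),
                                matrix(c(2, 1), 1)), 4)
  # chi -> 1 collapses to the unweighted squared error
  set.seed(1)
  R <- matrix(runif(20), 4, 5)
  Rh <- matrix(runif(20), 4, 5)
  expect_equal(autoencoder_loss(R, Rh, matrix(1, 4, 5)), sum((Rh - R)^2))
  expect_equal(autoencoder_loss(R, Rh), sum((Rh - R)^2))
})

test_that("skip-gram loss matches analytic values", {
  # all parameters zero: every score is 0, sigma(0) = 1/2
  H <- matrix(0, 5, 3)
  codes <- matrix(0, 1, 3)
  expect_equal(sgns_loss(codes, 2L, matrix(rep(3L, 10), 1), H), 11 * log(2))
  # score +1 for the positive, -1 for a single negative
  p1 <- manual_params(diag(1), 0, diag(1), 0, matrix(c(1, -1), 2, 1))
  y <- matrix(1, 1, 1)
  expect_equal(sgns_loss(y, 1L, matrix(2L, 1, 1), p1$arr$H),
               2 * (-log(1 / (1 + exp(-1)))))
  expect_equal(sgns_loss(y, 1L, matrix(2L, 1, 1), p1$arr$H), 0.62652338,
               tolerance = 1e-7)
  # saturated scores drive the loss to zero
  Hbig <- matrix(c(50, -50), 2, 1)
  expect_lt(sgns_loss(y, 1L, matrix(2L, 1, 1), Hbig), 1e-10)
})

test_that("regularizer covers weights only and is quadratic", {
  p <- init_params(8, c(4), 2, 8, seed = 3)
  for (nm in names(p$arr)) p$arr[[nm]][] <- 0
  expect_equal(reg_loss(p), 0)
  p$arr$enc_W1[1, 1] <- 2
  expect_equal(reg_loss(p), 2)
  # biases and H do not contribute
  p$arr$enc_b1[] <- 5; p$arr$H[] <- 5
  expect_equal(reg_loss(p), 2)
  # doubling every weight quadruples the value
  p2 <- init_params(8, c(4), 2, 8, seed = 4)
  r1 <- reg_loss(p2)
  for (k in 1:2) {
    p2$arr[[paste0("enc_W", k)]] <- 2 * p2$arr[[paste0("enc_W", k)]]
    p2$arr[[paste0("dec_W", k)]] <- 2 * p2$arr[[paste0("dec_W", k)]]
  }
  expect_equal(reg_loss(p2), 4 * r1)
})

test_that("joint objective is the stated linear combination", {
  expect_equal(total_loss(1, 2, 3, alpha = 0.5, gamma = 0.1), 2.3)
  expect_equal(total_loss(7, 99, 5, alpha = 0, gamma = 0), 7)
  expect_equal(total_loss(0, 0, 0), 0)
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  g <- tiny_attributed_graph()
  rec <- build_reconstruction(g, community_assignment(g$labels), "csm", chi = 2)
  R <- rec$R / max(rec$R)
  B <- rec$B
  params <- init_params(6, c(4), 2, 6, seed = 1)
  params$arr$H <- matrix(rnorm(12) * 0.3, 6, 2)
  centers <- c(1L, 2L, 3L, 4L)
  ctx <- c(2L, 3L, 1L, 5L)
  negs <- cbind(c(6L, 5L, 4L, 1L), c(3L, 2L, 6L, 6L))
  alpha <- 0.7; gamma <- 0.3
  loss_fn <- function(vec) {
    p <- caembed:::vector_to_params(vec, params)
    sg <- sgns_loss(encode_rows(R[centers, ], p), ctx, negs, p$arr$H)
    ae <- autoencoder_loss(R, decode_codes(encode_rows(R, p), p), B)
    total_loss(sg, ae, reg_loss(p), alpha, gamma)
  }
  sg <- caembed:::sg_loss_grad(params, R, centers, ctx, negs)
  ae <- caembed:::ae_loss_grad(params, R, B, weight = alpha)
  gr <- sg$grads
  for (nm in names(ae$grads)) {
    gr[[nm]] <- (if (is.null(gr[[nm]])) 0 else gr[[nm]]) + ae$grads[[nm]]
  }
  gr <- caembed:::add_reg_grad(gr, params, gamma)
  ganal <- unlist(gr[names(params$arr)], use.names = FALSE)
  v0 <- caembed:::params_to_vector(params)
  h <- 1e-5
  gnum <- vapply(seq_along(v0), function(i) {
    e1 <- v0; e1[i] <- e1[i] + h
    e2 <- v0; e2[i] <- e2[i] - h
    (loss_fn(e1) - loss_fn(e2)) / (2 * h)
  }, 0)
  rel <- abs(ganal - gnum) / pmax(abs(gnum), 1e-6)
  expect_lt(max(rel), 1e-4)
})

test_that("skip-gram loss decreases over full-batch gradient steps", {
  set.seed(5)
  g <- tiny_attributed_graph()
  rec <- build_reconstruction(g, community_assignment(g$labels), "csm", chi = 2)
  R <- rec$R / max(rec$R)
  params <- init_params(6, c(4), 2, 6, seed = 6)
  params$arr$H <- matrix(rnorm(12) * 0.1, 6, 2)
  walks <- generate_walks(g, walk_config(walks_per_node = 2, walk_length = 10,
                                         num_negatives = 2, seed = 7))
  pairs <- context_pairs(walks, 2)
  negs <- matrix(negative_sample(degrees(g), nrow(pairs) * 2, seed = 8),
                 nrow(pairs), 2)
  losses <- numeric(6)
  for (step in 1:6) {
    sg <- caembed:::sg_loss_grad(params, R, pairs[, 1], pairs[, 2], negs)
    losses[step] <- sg$loss
    for (nm in names(sg$grads)) {
      params$arr[[nm]] <- params$arr[[nm]] - 0.005 * sg$grads[[nm]]
    }
  }
  expect_true(all(diff(losses) < 0))
})

test_that("training descends, is reproducible, and groups automorphic nodes", {
  g <- toy_fixture("barbell")
  comm <- multilevel(g, seed = 1)
  cfg <- train_config(d = 2, hidden = 5, variant = "csm", epochs = 15,
                      batch_size = 256, ae_batch_size = 5,
                      walk = walk_config(walks_per_node = 3, walk_length = 10,
                                         window = 3, num_negatives = 3),
                      seed = 21)
  emb <- train_embedding(g, comm, cfg)
  expect_lt(emb$final_loss[["total"]], emb$initial_loss[["total"]])
  expect_true(all(is.finite(emb$Y)))
  expect_equal(dim(emb$Y), c(10, 2))
  emb2 <- train_embedding(g, comm, cfg)
  expect_equal(emb$Y, emb2$Y, tolerance = 1e-12)
  # nodes 1-4 are automorphic (clique members off the bridge), as are 7-10;
  # their codes should sit closer together than the average pair
  D <- as.matrix(dist(emb$Y))
  auto_pairs <- rbind(t(combn(1:4, 2)), t(combn(7:10, 2)))
  mean_auto <- mean(D[auto_pairs])
  expect_lt(mean_auto, mean(D[upper.tri(D)]))
})

test_that("structure-only and no-community modes train end to end", {
  g <- toy_fixture("barbell")  # no attributes
  cfg <- train_config(d = 2, hidden = 5, variant = "csm", epochs = 3,
                      batch_size = 128, ae_batch_size = 5,
                      walk = walk_config(walks_per_node = 2, walk_length = 8,
                                         window = 2, num_negatives = 2),
                      seed = 3)
  emb <- train_embedding(g, assignment = NULL, config = cfg)
  expect_equal(dim(emb$Y), c(10, 2))
  # am variant with communities but no attributes
  cfg_am <- train_config(d = 2, hidden = 5, variant = "am", epochs = 3,
                         batch_size = 128, ae_batch_size = 5,
                         walk = walk_config(walks_per_node = 2, walk_length = 8,
                                            window = 2, num_negatives = 2),
                         seed = 3)
  emb_am <- train_embedding(g, multilevel(g, seed = 1), cfg_am)
  expect_equal(dim(emb_am$Y), c(10, 2))
})
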