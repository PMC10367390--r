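test_that("joint loss and self-training loss obey their algebra", {
  expect_equal(joint_loss(2.0, 0.5, 1, 0), 2.0)
  expect_equal(joint_loss(2.0, 0.5, 1, 1), 2.5)
  expect_equal(joint_loss(2.0, 0.5, 2, 2), 2 * joint_loss(2.0, 0.5, 1, 1))
  expect_error(joint_loss(1, 1, -1, 1), "non-negative")
  expect_error(joint_loss(1, 1, 0, 0), "positive")

  expect_identical(selftrain_loss(3.2, 9.9, 0), 3.2)
  set.seed(1)
  for (rep in 1:50) {
    a <- runif(1, 0, 5); b <- runif(1, 0, 5); th <- runif(1, 0, 0.999)
    l <- selftrain_loss(a, b, th)
    expect_gte(l, min(a, b) - 1e-12)
    expect_lte(l, max(a, b) + 1e-12)
  }
  expect_error(selftrain_loss(1, 1, 1), "theta")
})

test_that("fgm_step perturbs by epsilon, restores embeddings, and is identity at 0", {
  cfg <- tiny_config()
  params <- tiny_params(cfg, vocab = 12L, ents = 4L, rads = 5L, types = 2L)
  tcfg <- train_config(alpha = 1, beta = 1)
  es <- list(char_ids = c(2L, 3L, 4L), ent_ids = c(0L, 1L, 0L),
             rad_ids = c(2L, 3L, 2L),
             boundary_idx = c(3L, 1L, 3L), type_idx = c(3L, 1L, 3L))
  before <- params$enc$E_c
  z <- fgm_step(params, cfg, list(es), 1, tcfg, epsilon = 0)
  expect_identical(z$loss, z$clean$loss)
  expect_identical(params$enc$E_c, before)
  expect_equal(sum(z$perturbation^2), 0)

  a <- fgm_step(params, cfg, list(es), 1, tcfg, epsilon = 0.25)
  expect_equal(sqrt(sum(a$perturbation^2)), 0.25, tolerance = 1e-12)
  expect_identical(params$enc$E_c, before)   # restoration contract
  expect_false(identical(a$loss, a$clean$loss))
})

test_that("training reduces the loss and is reproducible under a fixed seed", {
  d <- tiny_world()
  tc <- train_config(epochs = 3L, seed = 5L, dev_fraction = 0)
  m1 <- lexner(d$train, d$dictionary, d$radicals, control = tc)
  expect_lt(tail(m1$metrics$loss, 1), m1$metrics$loss[1])
  m2 <- lexner(d$train, d$dictionary, d$radicals, control = tc)
  expect_identical(m1$metrics, m2$metrics)
  expect_identical(m1$params$enc$E_c, m2$params$enc$E_c)
  # prediction is deterministic and shape-preserving
  p1 <- predict(m1, d$test)
  p2 <- predict(m1, d$test)
  expect_identical(lapply(p1, `[[`, "labels"), lapply(p2, `[[`, "labels"))
  expect_equal(lengths(lapply(p1, `[[`, "labels")),
               lengths(lapply(d$test, `[[`, "chars")))
  expect_error(lexner(list(), d$dictionary, d$radicals, control = tc),
               "empty")
})

test_that("pseudo_label honors the confidence threshold", {
  d <- tiny_world(n_unlabeled = 10L)
  tc <- train_config(epochs = 2L, seed = 3L, dev_fraction = 0)
  m <- lexner(d$train, d$dictionary, d$radicals, control = tc,
              unlabeled = d$unlabeled)
  all_sel <- pseudo_label(m, d$unlabeled, tau = 0)
  expect_length(all_sel$sentences, 10L)
  expect_true(all(all_sel$confidence >= 0 & all_sel$confidence <= 1))
  # duplicate sentences get identical labels and confidence
  dup <- c(d$unlabeled[1], d$unlabeled[1])
  sd <- pseudo_label(m, dup, tau = 0)
  expect_identical(sd$sentences[[1]]$labels, sd$sentences[[2]]$labels)
  expect_identical(sd$confidence[1], sd$confidence[2])
  # threshold filters
  mid <- pseudo_label(m, d$unlabeled, tau = stats::median(all_sel$confidence))
  expect_lte(length(mid$sentences), 10L)
  none <- pseudo_label(m, d$unlabeled, tau = 1 + 1e-9)
  expect_length(none$sentences, 0L)
})

test_that("self-training conserves sentences and grows the pool monotonically", {
  d <- tiny_world(seed = 22L, n_train = 40L, n_unlabeled = 0L)
  sp <- degrade_labels(d$train, 0.4, seed = 2L)
  tc <- train_config(epochs = 2L, seed = 4L, dev_fraction = 0)
  st <- selftrain_config(tau = 0.3, rounds = 2L, round_epochs = 1L,
                         round_cap = 0.25)
  m <- suppressWarnings(
    self_train(sp$labeled, sp$unlabeled, d$dictionary, d$radicals,
               control = tc, selftrain = st))
  log <- m$rounds
  expect_gt(nrow(log), 0L)
  expect_true(all(diff(log$pool_size) >= 0))
  expect_true(all(diff(log$unlabeled_left) <= 0))
  expect_true(all(log$pool_size + log$unlabeled_left == length(sp$unlabeled)))
  # tau = 1 + uncertainty: no rounds fire, model equals plain supervised fit
  st1 <- selftrain_config(tau = 1, rounds = 2L, round_epochs = 1L)
  m_sup <- lexner(sp$labeled, d$dictionary, d$radicals, control = tc,
                  unlabeled = sp$unlabeled)
  m_st1 <- suppressWarnings(
    self_train(sp$labeled, sp$unlabeled, d$dictionary, d$radicals,
               control = tc, selftrain = st1))
  expect_identical(m_sup$params, m_st1$params)
  # no unlabeled data degenerates to supervised training with a warning
  expect_warning(
    m0 <- self_train(sp$labeled, list(), d$dictionary, d$radicals,
                     control = tc),
    "no unlabeled")
  expect_s3_class(m0, "lexner")
})

test_that("model methods print, summarize, plot and expose coefficients", {
  d <- tiny_world()
  tc <- train_config(epochs = 1L, seed = 6L)
  m <- lexner(d$train, d$dictionary, d$radicals, control = tc)
  expect_output(print(m), "entity F1|epochs")
  expect_output(summary(m), "Ablation flags")
  expect_silent({
    pdf(NULL)
    plot(m)
    dev.off()
  })
  expect_named(coef(m), c("enc", "crf", "type"))
})
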