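test_that("training computes hand-countable smoothed likelihoods", {
  ts <- training_set("P1",
                     rbind(c("F", "A"), c("F", "C"), c("L", "A"),
                           c("L", "A")),
                     c("F", "F", "L", "L"))
  m <- nb_train(ts, alpha = 1)
  expect_equal(unname(m$priors), c(0.5, 0.5))
  # class F, position 1: 2 of 2 are F; 21 categories, alpha 1
  expect_equal(m$likelihoods[1L, "F", "F"], (2 + 1) / (2 + 21))
  expect_equal(m$likelihoods[1L, "F", "L"], 1 / 23)
  expect_equal(sum(m$likelihoods[1L, "F", ]), 1)
  # single-class training predicts that class with posterior 1
  one <- nb_train(training_set("P1", rbind(c("A", "A")), "W"))
  p <- nb_predict(one, c("C", "C"))
  expect_equal(p$label, "W")
  expect_equal(p$posterior, 1.0)
})

test_that("posteriors equal the brute-force Bayes oracle", {
  set.seed(21)
  for (trial in 1:15) {
    ncls <- sample(2:3, 1L)
    npos <- sample(1:3, 1L)
    n <- sample(4:9, 1L)
    labs <- sample(AA20[1:ncls], n, replace = TRUE)
    labs[1:ncls] <- AA20[1:ncls]          # every class present
    vecs <- matrix(sample(c("A", "C", "D", "-"), n * npos, replace = TRUE),
                   n, npos)
    m <- nb_train(training_set("P1", vecs, labs), alpha = 0.7)
    v <- sample(c("A", "C", "D", "-"), npos, replace = TRUE)
    pred <- nb_predict(m, v)
    orc <- oracle_nb_posterior(m, v)
    expect_equal(pred$ranking$posterior,
                 unname(sort(orc, decreasing = TRUE)), tolerance = 1e-12)
    expect_equal(pred$label, names(which.max(orc)))
  }
})

test_that("degenerate inputs behave: all-gap vector, big alpha, ties", {
  tr <- w_training()$P1
  m <- nb_train(tr)
  # an all-gap vector gives (near) prior-driven posteriors: with equal
  # class sizes the ranking posteriors are all equal
  p <- nb_predict(m, rep("-", m$n_positions))
  expect_equal(stats::sd(p$ranking$posterior), 0, tolerance = 1e-9)
  # alphabetical tie-break: equal posteriors pick the first label
  expect_equal(p$label, sort(m$classes)[1L])
  # alpha -> large washes out the likelihoods entirely
  m_flat <- nb_train(tr, alpha = 1e7)
  p2 <- nb_predict(m_flat, tr$vectors[1L, ])
  expect_equal(max(p2$ranking$posterior) - min(p2$ranking$posterior), 0,
               tolerance = 1e-4)
  # a duplicated unique training example comes back with its own label
  sep <- gen_training(list(F = "FFFF", L = "LLLL"), n_per_class = 3L,
                      jitter = 0, seed = 4L)
  ms <- nb_train(sep)
  expect_equal(nb_predict(ms, c("F", "F", "F", "F"))$label, "F")
})

test_that("relaxed matching follows the physicochemical partition", {
  cl <- default_physchem_clusters()
  expect_true(relaxed_match("L", "L", cl))
  expect_true(relaxed_match("L", "I", cl))   # both aliphatic
  expect_false(relaxed_match("L", "D", cl))
  expect_true(relaxed_match("F", "W", cl))
  expect_false(relaxed_match("C", "S", cl))  # C is a singleton group
  expect_error(validate_physchem(list(a = AA20[1:10])), "partition")
})

test_that("LOOCV: separable data scores 1.0 and relaxed >= strict", {
  tr <- w_training()
  cv1 <- nb_loocv(tr$P1)
  expect_equal(cv1$strict_accuracy, 1.0)
  expect_gte(cv1$relaxed_accuracy, cv1$strict_accuracy)
  cv2 <- nb_loocv(tr$P2)
  expect_gte(cv2$relaxed_accuracy, cv2$strict_accuracy)
})

test_that("LOOCV on label-permuted data sits at chance (12 classes)", {
  tr <- demo_training(seed = 777L, n_per_class = 5L, label_noise = 1.0)
  cv <- nb_loocv(tr$P1)
  # chance for 12 balanced classes is 1/12; allow generous Monte-Carlo slack
  expect_lt(cv$strict_accuracy, 3 / 12)
})

test_that("10% label noise still leaves strict accuracy high", {
  tr <- demo_training(seed = 88L, n_per_class = 5L, label_noise = 0.10)
  cv <- nb_loocv(tr$P1)
  expect_gte(cv$strict_accuracy, 0.85)
})

test_that("signature degradation degrades accuracy monotonically", {
  acc_at <- function(jit) {
    mean(vapply(1:20, function(s)
      nb_loocv(demo_training(seed = 5000L + s, n_per_class = 3L,
                             jitter = jit)$P1)$strict_accuracy, 0))
  }
  a0 <- acc_at(0.0); a4 <- acc_at(0.4); a8 <- acc_at(0.8)
  expect_equal(a0, 1.0)
  expect_gt(a0, a4)
  expect_gt(a4, a8)
})

test_that("overall accuracy is the mean of the two sites", {
  expect_equal(overall_accuracy(74.1, 66.7), 70.4)  # the printed metric
  expect_equal(overall_accuracy(100, 100), 100)
  expect_equal(overall_accuracy(0, 100), 50.0)
  expect_error(overall_accuracy(-1, 50))
})

test_that("enrichment over random expectation, both baseline policies", {
  expect_equal(enrichment(0.5, baseline = 0.5), 1.0)
  expect_equal(enrichment(0.672, baseline = 1 / 12), 8.064)
  labs <- rep(AA20[1:12], each = 5L)
  expect_equal(enrichment(0.672, labels = labs, policy = "uniform"),
               0.672 * 12)
  expect_equal(enrichment(0.5, labels = labs, policy = "prior_matched"),
               0.5 / sum(rep(1 / 12, 12)^2))
  expect_error(enrichment(0.5, baseline = 0), "positive")
  # uniform random predictions on balanced data enrich ~1x
  set.seed(31)
  labs12 <- rep(AA20[1:12], each = 200L)
  pred <- sample(AA20[1:12], length(labs12), replace = TRUE)
  expect_equal(enrichment(mean(pred == labs12), labels = labs12,
                          policy = "uniform"), 1.0, tolerance = 0.25)
})

test_that("ranking is stable under likelihood rescaling (log-space)", {
  tr <- w_training()$P1
  m <- nb_train(tr)
  m2 <- m
  m2$likelihoods <- m$likelihoods * 1e-250   # would underflow naive products
  for (i in c(1L, 25L, 60L)) {
    p1 <- nb_predict(m, tr$vectors[i, ])
    p2 <- nb_predict(m2, tr$vectors[i, ])
    expect_equal(p1$label, p2$label)
    # posteriors agree per label; ordering among numerically tied tail
    # classes is not part of the contract
    o <- match(p1$ranking$label, p2$ranking$label)
    expect_equal(p1$ranking$posterior, p2$ranking$posterior[o],
                 tolerance = 1e-9)
  }
})

test_that("training TSV round-trips through read/write", {
  tr <- w_training()$P2
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_training_tsv(tr, tmp)
  back <- read_training_tsv(tmp, "P2")
  expect_equal(back$vectors, tr$vectors)
  expect_equal(back$labels, tr$labels)
})
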