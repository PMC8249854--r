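test_that("coefficient distance is the Euclidean norm of the difference", {
  expect_equal(coefficient_distance(1:5, 1:5), 0)
  expect_equal(coefficient_distance(c(3, 4, 0), c(0, 0, 0)), 5)
  set.seed(2)
  K <- rnorm(101); C <- rnorm(101)
  expect_equal(coefficient_distance(K, C),
               sqrt(sum(vapply(seq_along(K), function(l) (K[l] - C[l])^2, 0))),
               tolerance = 1e-12)
  expect_error(coefficient_distance(1:3, 1:4), "length")
})

test_that("instances go to the nearest class, ties to the first label", {
  set.seed(5)
  cc <- matrix(rnorm(4 * 21), 4, 21, dimnames = list(c("A", "B", "C", "D")))
  model <- structure(list(class_coefficients = cc), class = "rc_classifier")
  expect_equal(as.character(classify_instance(cc["B", ], model)), "B")
  d <- vapply(rownames(cc), function(b)
    coefficient_distance(cc["D", ] + 0.01, cc[b, ]), 0)
  expect_equal(as.character(classify_instance(cc["D", ] + 0.01, model)),
               names(which.min(d)))
  tied <- structure(list(class_coefficients = matrix(
    rep(1:21, each = 4), 4, 21, dimnames = list(c("A", "B", "C", "D")))),
    class = "rc_classifier")
  expect_equal(as.character(classify_instance(rep(0, 21), tied)), "A")
})

test_that("classification reports are row-stochastic with E_C = 1 - mean diagonal", {
  truth <- rep(c("A", "B", "C", "D"), each = 25)
  perfect <- classification_report(truth, truth)
  expect_equal(perfect$error_fraction, 0)
  expect_equal(unname(perfect$confusion), diag(4))
  set.seed(1)
  rand <- classification_report(truth, sample(c("A", "B", "C", "D"), 100,
                                              replace = TRUE))
  expect_equal(unname(rowSums(rand$confusion)), rep(1, 4), tolerance = 1e-12)
  expect_equal(rand$error_fraction, 1 - mean(diag(rand$confusion)))
})

test_that("relabeling permutes the confusion matrix consistently", {
  set.seed(8)
  truth <- sample(c("A", "B", "C", "D"), 400, replace = TRUE,
                  prob = c(0.3, 0.3, 0.2, 0.2))
  truth <- c(truth, "A", "B", "C", "D")
  pred <- sample(c("A", "B", "C", "D"), length(truth), replace = TRUE)
  base <- classification_report(truth, pred)
  perm <- c(A = "C", B = "A", C = "D", D = "B")
  swapped <- classification_report(unname(perm[truth]), unname(perm[pred]))
  reord <- swapped$confusion[perm, perm]
  expect_equal(unname(reord), unname(base$confusion))
})

test_that("training yields one labeled coefficient vector per class, deterministically", {
  spec <- tiny_spiking_spec(seed = 4)
  model <- reservoir_classifier(spec, train_length = 4000, seed = 6,
                                transient = 500)
  expect_equal(rownames(coef(model)), c("A", "B", "C", "D"))
  expect_equal(ncol(coef(model)), 21)
  expect_true(all(model$training_errors > 0 & model$training_errors < 1))
  model2 <- reservoir_classifier(spec, train_length = 4000, seed = 6,
                                 transient = 500)
  expect_identical(coef(model), coef(model2))
})

test_that("evaluation processes fresh realizations end to end", {
  spec <- tiny_poly_spec(seed = 4)
  model <- reservoir_classifier(spec, train_length = 4000, seed = 6,
                                transient = 500)
  rep1 <- evaluate_classification(model, n_instances = 3, test_length = 1500,
                                  seed = 11)
  expect_equal(unname(rowSums(rep1$confusion)), rep(1, 4))
  expect_gte(rep1$error_fraction, 0)
  expect_lte(rep1$error_fraction, 1)
  rep2 <- evaluate_classification(model, n_instances = 3, test_length = 1500,
                                  seed = 11)
  expect_identical(rep1$confusion, rep2$confusion)
  # predict() agrees with the evaluation pipeline on a fresh trajectory
  tr <- integrate_sprott("B", NULL, 0.1, 1500, 10000, seed = 99)
  expect_true(predict(model, tr) %in% c("A", "B", "C", "D"))
})
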