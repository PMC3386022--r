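# Pearson k-NN target prediction: self-match exclusion, neighbour
# ranking, the set-intersection accuracy and precision, and the shuffled
# baseline.

test_that("pearson matches the closed form and rejects degenerate input", {
  x <- c(1, 2, 3)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(pearson(x, c(1, 2, 4)), 9 / sqrt(84))
  expect_error(pearson(x, c(1, 2)), "length mismatch")
  expect_error(pearson(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson(x, c(5, 5, 5)), "constant")
})

test_that("instances of the query compound are never neighbours", {
  # i2 is a replicate of the query compound; i3 the only other compound
  v <- rbind(i1 = c(0, 1, 2), i2 = c(0, 1, 2), i3 = c(5, 1, 0))
  colnames(v) <- paste0("p", 1:3)
  m <- make_em(v, compounds = c("cA", "cA", "cB"))
  ann <- annotation_table(list(cA = "t1", cB = "t2"))
  nb <- nearest_neighbors(m, gene_signature(colnames(v)), "i1",
                          prediction_config(1), ann)
  expect_equal(nb$instance_id, "i3")

  # an exact duplicate from another compound ranks first with r = 1
  v2 <- rbind(i1 = c(0, 1, 2), i2 = c(0, 1, 2), i3 = c(5, 1, 0))
  colnames(v2) <- paste0("p", 1:3)
  m2 <- make_em(v2, compounds = c("cA", "cB", "cC"))
  ann2 <- annotation_table(list(cA = "t1", cB = "t2", cC = "t3"))
  nb2 <- nearest_neighbors(m2, gene_signature(colnames(v2)), "i1",
                           prediction_config(2), ann2)
  expect_equal(nb2$instance_id[1], "i2")
  expect_equal(nb2$correlation[1], 1)
  expect_error(nearest_neighbors(m2, gene_signature(colnames(v2)), "i1",
                                 prediction_config(3), ann2),
               "fewer than k")
})

test_that("the five-instance fixture reproduces hand-computed metrics", {
  fx <- make_hand_fixture()
  # neighbour ranking from i1: r(i3)=9/sqrt(84), r(i4)=0.5, r(i5)=-0.5
  nb <- nearest_neighbors(fx$m, fx$sig, "i1", prediction_config(3),
                          fx$annotations)
  expect_equal(nb$instance_id, c("i3", "i4", "i5"))
  expect_equal(nb$correlation, c(9 / sqrt(84), 0.5, -0.5))

  # hand-traced 1-NN score: i1,i2 -> i3 (hit); i3 -> i1 by id-tie (hit);
  # i4 -> i1 (miss); i5 -> i3 (miss)
  r <- predict_and_score(fx$m, fx$sig, fx$annotations, prediction_config(1))
  expect_equal(r$accuracy, 3 / 5)
  expect_equal(r$precision, 0.3)
  expect_equal(r$n_queries, 5L)
  pq <- r$per_query
  expect_equal(pq$neighbor_instances[pq$query_instance == "i3"], "i1")
  expect_equal(pq$success, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # success flag and precision contribution agree per query
  expect_equal(pq$success, pq$precision > 0)
})

test_that("query target {A,B} against neighbour {B,C} scores success with precision 1/2", {
  v <- rbind(i1 = c(0, 1, 2), i2 = c(0, 1.1, 2.2))
  colnames(v) <- paste0("p", 1:3)
  m <- make_em(v, compounds = c("cA", "cB"))
  ann <- annotation_table(list(cA = c("A", "B"), cB = c("B", "C")))
  r <- predict_and_score(m, gene_signature(colnames(v)), ann,
                         prediction_config(1))
  expect_true(all(r$per_query$success))
  expect_equal(r$per_query$precision, c(0.5, 0.5))
})

test_that("accuracy is non-decreasing in the number of neighbours", {
  b <- small_bundle()
  m <- suppressMessages(batch_mean_center(b$expression, min_batch_size = 2))
  sig <- random_signature(probesets(m), 12, seed = 4)
  accs <- vapply(1:3, function(k) {
    predict_and_score(m, sig, b$annotations, prediction_config(k))$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("accuracy is invariant to signature order and per-instance affine maps", {
  fx <- make_hand_fixture()
  cfg <- prediction_config(1)
  base <- predict_and_score(fx$m, fx$sig, fx$annotations, cfg)$accuracy
  flipped <- gene_signature(rev(fx$sig$probeset_ids))
  expect_equal(predict_and_score(fx$m, flipped, fx$annotations, cfg)$accuracy,
               base)
  # y = 2x + 7 applied to every instance leaves Pearson untouched
  m2 <- expression_matrix(2 * fx$m$values + 7, fx$m$instances)
  expect_equal(predict_and_score(m2, fx$sig, fx$annotations, cfg)$accuracy,
               base)
})

test_that("the fast evaluator agrees with predict_and_score", {
  b <- small_bundle()
  m <- suppressMessages(batch_mean_center(b$expression, min_batch_size = 2))
  for (k in 1:2) {
    ev <- sigmin:::accuracy_evaluator(m, b$annotations, k = k)
    for (seed in c(2, 9)) {
      sig <- random_signature(probesets(m), 10, seed = seed)
      expect_equal(ev(sig$probeset_ids),
                   predict_and_score(m, sig, b$annotations,
                                     prediction_config(k))$accuracy)
    }
  }
})

test_that("shuffled-annotation baseline matches exhaustive permutation expectations", {
  # all compounds share one target set: any shuffle scores accuracy 1
  v <- rbind(i1 = c(0, 1, 2), i2 = c(2, 1, 0), i3 = c(1, 0, 2))
  colnames(v) <- paste0("p", 1:3)
  m <- make_em(v, compounds = c("cA", "cB", "cC"))
  shared <- annotation_table(list(cA = "t1", cB = "t1", cC = "t1"))
  bl <- random_baseline(m, gene_signature(colnames(v)), shared,
                        prediction_config(1), n_shuffles = 4, seed = 2)
  expect_equal(bl$mean, 1)
  expect_equal(bl$sd, 0)

  # two compounds with disjoint singleton targets: accuracy 0 under both
  # permutations of S2
  m2 <- make_em(v[1:2, ], compounds = c("cA", "cB"))
  disjoint2 <- annotation_table(list(cA = "t1", cB = "t2"))
  bl2 <- random_baseline(m2, gene_signature(colnames(v)), disjoint2,
                         prediction_config(1), n_shuffles = 6, seed = 3)
  expect_equal(bl2$mean, 0)

  # four compounds, disjoint singletons: under any permutation of the sets
  # a query hits iff its compound's set landed on its neighbour; exact
  # mean over all 24 permutations is 1/3 for every neighbour structure
  v4 <- rbind(i1 = c(0, 1, 2), i2 = c(2, 1, 0), i3 = c(1, 0, 2),
              i4 = c(0, 2, 1))
  colnames(v4) <- paste0("p", 1:3)
  m4 <- make_em(v4, compounds = paste0("c", 1:4))
  disjoint4 <- annotation_table(list(c1 = "t1", c2 = "t2", c3 = "t3",
                                     c4 = "t4"))
  # exact enumeration oracle over S4: for each permutation, re-run scoring
  perms <- rbind(1:4) # filled below
  perms <- do.call(rbind, lapply(1:4, function(a)
    do.call(rbind, lapply(setdiff(1:4, a), function(b)
      do.call(rbind, lapply(setdiff(1:4, c(a, b)), function(c)
        c(a, b, c, setdiff(1:4, c(a, b, c)))))))))
  sets <- list("t1", "t2", "t3", "t4")
  exact <- mean(vapply(seq_len(nrow(perms)), function(i) {
    t_perm <- annotation_table(stats::setNames(sets[perms[i, ]],
                                               paste0("c", 1:4)))
    predict_and_score(m4, gene_signature(colnames(v4)), t_perm,
                      prediction_config(1))$accuracy
  }, numeric(1)))
  n_shuffles <- 60
  bl4 <- random_baseline(m4, gene_signature(colnames(v4)), disjoint4,
                         prediction_config(1), n_shuffles = n_shuffles,
                         seed = 5)
  # Monte-Carlo mean within 3 standard errors of the exact permutation mean
  se <- stats::sd(bl4$accuracies) / sqrt(n_shuffles)
  expect_lt(abs(bl4$mean - exact), 3 * se + 1e-9)
})
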