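test_that("per-bin t tests match the closed-form and t.test oracles", {
  m <- rbind(c(0.6, 0.5), c(0.7, 0.5), c(0.8, 0.5))
  tc <- tc_from_matrix(m)
  bt <- bin_ttests(tc, perm_config())
  # mean 0.7, sd 0.1, n 3 against 0.5 -> t = 0.2 / (0.1/sqrt(3)) = 3.464
  expect_equal(bt$t[1], 0.2 / (0.1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(round(bt$t[1], 3), 3.464)
  expect_equal(bt$df[1], 2)
  # a zero-variance bin (all subjects exactly at chance) is untestable
  expect_true(is.na(bt$t[2]))
  expect_true(is.na(bt$significant[2]))

  set.seed(8)
  m2 <- matrix(runif(60, 0.2, 0.9), nrow = 6)
  m2[sample(60, 6)] <- NA
  bt2 <- bin_ttests(tc_from_matrix(m2), perm_config())
  for (b in seq_len(ncol(m2))) {
    v <- m2[, b][!is.na(m2[, b])]
    tt <- stats::t.test(v, mu = 0.5)
    expect_equal(bt2$t[b], unname(tt$statistic))
    expect_equal(bt2$p[b], tt$p.value)
    expect_equal(bt2$n[b], length(v))
  }
})

test_that("clusters are same-signed maximal runs with summed-t masses", {
  mk_tests <- function(tval, sig) {
    tibble::tibble(
      bin_index = seq_along(tval) - 1L,
      bin_onset_ms = (seq_along(tval) - 1) * 250,
      bin_offset_ms = seq_along(tval) * 250,
      t = tval, significant = sig
    )
  }
  # no significant bins -> no clusters
  expect_equal(nrow(find_clusters(mk_tests(c(1, 0.5, -1), rep(FALSE, 3)))), 0)

  # flags [T,T,F,T] -> masses 4.8 and 2.2
  cl <- find_clusters(mk_tests(c(2.5, 2.3, 1.0, 2.2),
                               c(TRUE, TRUE, FALSE, TRUE)))
  expect_equal(cl$mass, c(4.8, 2.2))
  expect_equal(cl$onset_ms, c(0, 750))
  expect_equal(cl$offset_ms, c(500, 1000))

  # a single significant bin at index 0 spans 0-250 ms
  cl1 <- find_clusters(mk_tests(c(3.1, 0.2), c(TRUE, FALSE)))
  expect_equal(cl1$n_bins, 1L)
  expect_equal(cl1$onset_ms, 0)
  expect_equal(cl1$offset_ms, 250)

  # adjacent significant bins of opposite sign form separate clusters
  cl2 <- find_clusters(mk_tests(c(3, -3, -2.5), rep(TRUE, 3)))
  expect_equal(cl2$mass, c(3, -5.5))

  # untestable (NA) bins break runs
  cl3 <- find_clusters(mk_tests(c(3, NA, 2.5), c(TRUE, NA, TRUE)))
  expect_equal(cl3$mass, c(3, 2.5))
  # |mass| always at least the largest member |t|
  expect_true(all(abs(cl2$mass) >= c(3, 2.5)))
})

test_that("permutation null is deterministic and zero for constant chance", {
  m_const <- matrix(0.5, nrow = 4, ncol = 6)
  tc <- tc_from_matrix(m_const)
  null <- permutation_null(tc, perm_config(n_permutations = 50, seed = 3))
  expect_equal(null$max_abs_masses, rep(0, 50))

  set.seed(14)
  m <- matrix(runif(40, 0.3, 0.8), nrow = 4)
  tc2 <- tc_from_matrix(m)
  n1 <- permutation_null(tc2, perm_config(n_permutations = 40, seed = 9))
  n2 <- permutation_null(tc2, perm_config(n_permutations = 40, seed = 9))
  expect_identical(n1$max_abs_masses, n2$max_abs_masses)
  expect_true(all(n1$max_abs_masses >= 0))
  expect_error(permutation_null(tc_from_matrix(m[1, , drop = FALSE])),
               class = "gazecourse_data_error")
})

test_that("null threshold equals the sorting-oracle 95th percentile", {
  set.seed(15)
  m <- matrix(runif(80, 0.2, 0.9), nrow = 8)
  null <- permutation_null(tc_from_matrix(m),
                           perm_config(n_permutations = 200, seed = 5))
  sorted <- sort(null$max_abs_masses)
  expect_equal(null$threshold, sorted[ceiling(0.95 * 201)])
})

test_that("cluster evaluation converts null exceedances to p-values", {
  clusters <- tibble::tibble(mass = c(2, 10))
  null <- structure(list(max_abs_masses = c(3, 4, 5, 6), threshold = 5.95,
                         n_permutations = 4L), class = "perm_null")
  ev <- evaluate_clusters(clusters, null, perm_config())
  expect_equal(ev$p_value, c(1, 0)) # below all -> 1; above all -> 0.000
  expect_equal(ev$significant, c(FALSE, TRUE))
  ev1 <- evaluate_clusters(clusters, null, perm_config(plus_one = TRUE))
  expect_equal(ev1$p_value, c(5 / 5, 1 / 5))
})

test_that("sampled permutation p-values match exhaustive enumeration", {
  # tiny case first: 2 subjects x 2 bins has only 4 sign assignments
  set.seed(16)
  m_tiny <- matrix(c(0.9, 0.8, 0.85, 0.75), nrow = 2)
  exact_tiny <- oracle_null_enum(m_tiny)
  null_tiny <- permutation_null(
    tc_from_matrix(m_tiny),
    perm_config(n_permutations = 2000, seed = 21)
  )
  for (v in unique(round(exact_tiny, 10))) {
    expect_lt(abs(mean(abs(null_tiny$max_abs_masses - v) < 1e-9) -
                    mean(abs(exact_tiny - v) < 1e-9)), 0.04)
  }

  # n = 6 subjects, 8 bins, with missingness
  m <- matrix(runif(48, 0.35, 0.95), nrow = 6)
  m[cbind(c(2, 5), c(3, 7))] <- NA
  exact <- oracle_null_enum(m)
  cfg <- perm_config(n_permutations = 2000, seed = 22)
  tc <- tc_from_matrix(m)
  res <- cluster_permutation_test(tc, cfg)
  for (i in seq_len(nrow(res$clusters))) {
    exact_p <- mean(exact >= abs(res$clusters$mass[i]))
    expect_lt(abs(res$clusters$p_value[i] - exact_p), 0.04)
  }
  # the sampled null mean matches the enumeration mean
  expect_lt(abs(mean(res$null$max_abs_masses) - mean(exact)), 0.2)
})

test_that("the full test object prints, tidies, and glances", {
  set.seed(17)
  m <- matrix(runif(50, 0.55, 0.95), nrow = 5)
  tc <- tc_from_matrix(m)
  res <- cluster_permutation_test(tc, perm_config(n_permutations = 99,
                                                  seed = 2))
  td <- tidy(res)
  expect_true(all(c("cluster_index", "sum_t", "onset_ms", "offset_ms",
                    "p_value", "significant") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_subjects, 5)
  expect_equal(gl$n_permutations, 99L)
  expect_output(print(res), "gaze_cluster_test")
  # subject order does not affect the observed clusters
  tc_shuffled <- tc[sample(nrow(tc)), ]
  res2 <- cluster_permutation_test(tc_shuffled,
                                   perm_config(n_permutations = 99, seed = 2))
  expect_equal(res$clusters, res2$clusters)
})

test_that("multi-condition input must be filtered to one scope", {
  tc <- tc_from_matrix(matrix(runif(20), nrow = 2))
  tc$face_race <- rep(c("White", "Asian American"), each = 10)
  tc$speech_type <- "infant-directed"
  expect_error(bin_ttests(tc, perm_config()),
               class = "gazecourse_data_error")
})
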