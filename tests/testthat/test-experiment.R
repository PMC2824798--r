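test_that("length distributions pool significant group counts and normalize", {
  fake_report <- function(lens, sig) {
    structure(data.frame(length = lens, group = seq_along(lens),
                         n_members = 3L, mean_similarity = 0.5,
                         shuffle_max = 0.4, significant = sig),
              class = c("significance_report", "data.frame"))
  }
  # counts (4,2,1,1,0,...) over L = 2..9
  r1 <- fake_report(c(2, 2, 2, 3, 4), rep(TRUE, 5))
  r2 <- fake_report(c(2, 3, 5, 6), c(TRUE, TRUE, TRUE, FALSE))
  d <- length_distribution(list(r1, r2))
  expect_equal(as.numeric(d), c(0.5, 0.25, 0.125, 0.125, 0, 0, 0, 0))
  expect_equal(sum(d), 1)
  expect_equal(attr(d, "n_groups"), 8)
  # zero significant groups: all-zero with empty flag
  d0 <- length_distribution(list(fake_report(c(2, 3), c(FALSE, FALSE))))
  expect_true(attr(d0, "empty"))
  expect_equal(sum(d0), 0)
})

test_that("sum-of-squares error is a symmetric non-negative discrepancy", {
  p <- group_length_distribution(c(1, 0, 0, 0, 0, 0, 0, 0))
  q <- group_length_distribution(c(0, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(sse(p, p), 0)
  expect_equal(sse(p, q), 2)
  expect_equal(sse(p, q), sse(q, p))
  a <- group_length_distribution(c(0.5, 0.5, 0, 0, 0, 0, 0, 0))
  b <- group_length_distribution(c(0.25, 0.75, 0, 0, 0, 0, 0, 0))
  expect_equal(sse(a, b), 0.125)
  expect_error(sse(as.numeric(p), c(0.5, 0.5)))
})

test_that("run_condition produces reproducible per-run reports at protocol lengths", {
  cfg <- model_config(n_steps = 6000, seed = 1)
  res <- run_condition(1.2, n_runs = 2, config = cfg,
                       shuffle_cfg = shuffle_config(5), cap = 60, seed = 7)
  expect_length(res, 2L)
  for (r in res) {
    expect_s3_class(r, "significance_report")
    if (nrow(r)) expect_true(all(r$length %in% 2:9))
  }
  # distinct run seeds give distinct rasters, same master seed reproduces
  expect_false(identical(attr(res, "seeds")[1, ], attr(res, "seeds")[2, ]))
  res2 <- run_condition(1.2, n_runs = 2, config = cfg,
                        shuffle_cfg = shuffle_config(5), cap = 60, seed = 7)
  expect_identical(as.data.frame(res[[1]]), as.data.frame(res2[[1]]))
  expect_identical(as.data.frame(res[[2]]), as.data.frame(res2[[2]]))
})

test_that("the sweep reports per-B fits, the good-fit set, and a deterministic optimum", {
  ref <- gen_reference_distribution(log(2))
  cfg <- model_config(n_steps = 6000, seed = 2)
  sw <- sweep_exponent(B_values = c(0.4, 1.6, 3.6), reference = ref,
                       config = cfg, n_runs = 1,
                       shuffle_cfg = shuffle_config(5), cap = 60, seed = 9)
  expect_equal(sw$B, c(0.4, 1.6, 3.6))
  expect_true(all(sw$n_groups >= 0))
  expect_true(all(sw$sse >= 0))
  expect_equal(attr(sw, "optimal_B"),
               min(sw$B[sw$n_groups == max(sw$n_groups)]))
  expect_equal(attr(sw, "best_fit_B"), sw$B[which.min(sw$sse)])
  expect_identical(sw$good_fit, sw$sse <= 0.016)
  # bit-reproducible given the master seed
  sw2 <- sweep_exponent(B_values = c(0.4, 1.6, 3.6), reference = ref,
                        config = cfg, n_runs = 1,
                        shuffle_cfg = shuffle_config(5), cap = 60, seed = 9)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))
  expect_error(sweep_exponent(B_values = c(0.4, 1.6), reference = NULL))
})

test_that("self-fit: a condition's own pooled distribution minimizes its SSE", {
  cfg <- model_config(n_steps = 15000, seed = 3)
  Bs <- c(0.4, 1.6, 3.2)
  dists <- lapply(Bs, function(B) {
    res <- run_condition(B, n_runs = 2, config = cfg,
                         shuffle_cfg = shuffle_config(10), cap = 100,
                         seed = 100 + round(10 * B))
    length_distribution(res)
  })
  # reference := the B = 1.6 condition's own distribution
  ref <- dists[[2]]
  errs <- vapply(dists, function(d) sse(d, ref), numeric(1))
  expect_equal(which.min(errs), 2L)
})

test_that("sweep results serialize to a table plus a reproducibility manifest", {
  ref <- gen_reference_distribution(log(2))
  cfg <- model_config(n_steps = 4000, seed = 4)
  sw <- sweep_exponent(B_values = c(0.8, 2.0), reference = ref, config = cfg,
                       n_runs = 1, shuffle_cfg = shuffle_config(3), cap = 40,
                       seed = 13)
  dir <- withr::local_tempdir()
  files <- write_sweep_result(sw, dir)
  expect_true(all(file.exists(file.path(dir, c("sweep.csv", "sweep_manifest.json")))))
  tab <- utils::read.csv(file.path(dir, "sweep.csv"))
  expect_equal(tab$B, sw$B)
  man <- jsonlite::read_json(file.path(dir, "sweep_manifest.json"))
  expect_equal(man$n_steps, 4000L)
  expect_equal(unlist(man$seeds), attr(sw, "seeds"))
})
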