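make_toy_patterns <- function(n_classes, m_images, h = 12, w = 12, seed = 1) {
  set.seed(seed)
  out <- list()
  for (g in seq_len(n_classes)) {
    base <- random_pattern(h, w, 0.3)
    imgs <- list()
    for (j in seq_len(m_images)) {
      p <- base
      flip <- sample(length(p), 6)
      p[flip] <- 1L - p[flip]
      imgs[[sprintf("img_%02d", j)]] <- p
    }
    out[[sprintf("class_%03d", g)]] <- imgs
  }
  out
}

test_that("the protocol produces the expected attempt counts", {
  pats <- make_toy_patterns(3, 4)
  tbl <- build_score_table(pats, match_config(cw = 1, ch = 1))
  expect_s3_class(tbl, "fv_scores")
  expect_equal(attr(tbl, "n_genuine"), 9)      # 3 classes x 3 non-templates
  expect_equal(attr(tbl, "n_impostor"), 24)    # 3 templates x 2 x 4 images
  expect_true(all(tbl$rm >= 0 & tbl$rm <= 0.5))

  # deterministic: same inputs, identical table
  tbl2 <- build_score_table(pats, match_config(cw = 1, ch = 1))
  expect_equal(as.data.frame(tbl), as.data.frame(tbl2))
})

test_that("classes with fewer than two images are skipped with a warning", {
  pats <- make_toy_patterns(3, 3)
  pats$class_002 <- pats$class_002[1]
  expect_warning(tbl <- build_score_table(pats, match_config(1, 1)),
                 "fewer than 2")
  expect_equal(length(unique(tbl$gallery_class)), 2L)
  expect_error(build_score_table(pats[1], match_config(1, 1)), "at least 2")
})

test_that("far_frr implements the accept-iff-rm>=t rule in percent", {
  tbl <- tibble::tibble(
    rm = c(0.4, 0.3, 0.2, 0.35, 0.15, 0.1),
    is_genuine = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  expect_equal(far_frr(tbl, 0), c(far = 100, frr = 0))
  expect_equal(far_frr(tbl, 0.5), c(far = 0, frr = 100))
  expect_equal(far_frr(tbl, 0.25), c(far = 100 / 3, frr = 100 / 3))
  # NFA = 5 of NIRA = 100 -> FAR 5%
  tbl2 <- tibble::tibble(rm = c(rep(0.4, 5), rep(0.1, 95), 0.45),
                         is_genuine = c(rep(FALSE, 100), TRUE))
  expect_equal(far_frr(tbl2, 0.3)[["far"]], 5)
})

test_that("the default threshold sweep has exactly 5001 points", {
  tbl <- tibble::tibble(rm = c(0.4, 0.1), is_genuine = c(TRUE, FALSE))
  res <- eer(tbl)
  expect_equal(nrow(res$curve), 5001L)
  expect_equal(res$curve$threshold[1], 0)
  expect_equal(res$curve$threshold[5001], 0.5)
})

test_that("perfectly separated scores give EER 0", {
  tbl <- tibble::tibble(rm = c(0.45, 0.4, 0.35, 0.2, 0.1),
                        is_genuine = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(eer(tbl)$eer, 0)
})

test_that("eer matches the brute-force sweep oracle on a toy table", {
  gen <- c(0.40, 0.30, 0.20)
  imp <- c(0.35, 0.15, 0.10)
  tbl <- tibble::tibble(rm = c(gen, imp),
                        is_genuine = rep(c(TRUE, FALSE), each = 3))
  res <- eer(tbl)
  o <- oracle_eer(gen, imp)
  expect_equal(res$eer, o$eer)
  expect_equal(res$threshold, o$threshold)
  expect_equal(res$curve$far, o$far)
  expect_equal(res$curve$frr, o$frr)
})

test_that("FAR is non-increasing and FRR non-decreasing in the threshold", {
  set.seed(8)
  tbl <- tibble::tibble(
    rm = round(c(rbeta(200, 4, 2), rbeta(400, 1, 4)) / 2, 4),
    is_genuine = rep(c(TRUE, FALSE), c(200, 400))
  )
  res <- eer(tbl)
  expect_true(all(diff(res$curve$far) <= 0))
  expect_true(all(diff(res$curve$frr) >= 0))
  expect_gte(res$eer, 0)
  expect_lte(res$eer, 100)
  # the curve agrees with far_frr at a handful of grid thresholds
  for (t in c(0, 0.1234, 0.25, 0.5)) {
    i <- which.min(abs(res$curve$threshold - t))
    expect_equal(unname(far_frr(tbl, res$curve$threshold[i])),
                 c(res$curve$far[i], res$curve$frr[i]))
  }
})

test_that("EER is invariant to duplicating every attempt", {
  set.seed(12)
  tbl <- tibble::tibble(rm = round(runif(60, 0, 0.5), 3),
                        is_genuine = rep(c(TRUE, FALSE), 30))
  doubled <- dplyr::bind_rows(tbl, tbl)
  expect_equal(eer(tbl)$eer, eer(doubled)$eer)
})

test_that("degenerate tables are rejected", {
  only_gen <- tibble::tibble(rm = c(0.2, 0.3), is_genuine = c(TRUE, TRUE))
  expect_error(eer(only_gen), "genuine and impostor")
  expect_error(far_frr(only_gen, 0.1), "genuine and impostor")
})

test_that("tidiers and report writer expose the result faithfully", {
  tbl <- tibble::tibble(rm = c(0.45, 0.4, 0.2, 0.1),
                        is_genuine = c(TRUE, TRUE, FALSE, FALSE))
  res <- eer(tbl)
  expect_equal(nrow(tidy(res)), 5001L)
  g <- glance(res)
  expect_equal(g$eer, res$eer)
  expect_equal(g$n_genuine, 2L)
  f <- withr::local_tempfile(fileext = ".json")
  write_eer_report(res, f, settings = list(cw = 30))
  rpt <- jsonlite::read_json(f)
  expect_equal(rpt$eer_percent, res$eer)
  expect_equal(rpt$settings$cw, 30)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
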