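# Golden-file enumeration of the two packaged whole-pelvis protocols.

row_sig <- function(ob) {
  p <- ob$params
  paste(ob$priority, ob$structure, ob$kind,
        if (is.numeric(ob$goal)) ob$goal else
          paste0(ob$goal$percent, "%", ob$goal$of),
        if (!is.null(p$D_p)) paste0(p$D_p$percent, "%", p$D_p$of) else "",
        if (!is.null(p$alpha)) p$alpha else "",
        if (!is.null(p$k)) p$k else "")
}

con_sig <- function(cn)
  paste(cn$structure, cn$type,
        paste0(cn$limit$percent, "%", cn$limit$of))

test_that("the packaged phase-1 wishlist reproduces every protocol row", {
  w <- builtin_wishlist(1)
  expect_length(w$constraints, 7)
  expect_length(w$objectives, 14)
  expect_equal(
    vapply(w$constraints, con_sig, character(1)),
    c("PTV-P MAX 105%D_high",
      "PTV-P MEAN 101%D_high",
      "PTV-LN - PTV-P+5mm MAX 105%D_low",
      "PTV-LN - PTV-P+5mm MEAN 101%D_low",
      "femoral_heads MAX 70%D_high",
      "PTV-LN shell 50 mm MAX 50%D_high",
      "Unspecified tissues MAX 105%D_high"))
  expect_equal(
    vapply(w$objectives, row_sig, character(1)),
    c("1 PTV-P LTCP 0.65 100%D_high 0.7 ",
      "2 PTV-LN LTCP 0.5 100%D_low 0.9 ",
      "3 PTV-LN shell 5 mm MAX 90%D_low   ",
      "4 rectum EUD 70%D_high   12",
      "4 rectum EUD 30%D_high   4",
      "5 bladder EUD 30%D_high   4",
      "6 PTV-LN shell 15 mm MAX 60%D_low   ",
      "6 PTV-LN shell 25 mm MAX 40%D_low   ",
      "7 bowel_bag EUD 30%D_high   8",
      "8 Skin ring 20 mm MAX 30%D_high   ",
      "9 rectum MEAN 20%D_low   ",
      "10 bladder MEAN 20%D_low   ",
      "11 bowel_bag MEAN 20%D_low   ",
      "12 femoral_heads EUD 10%D_high   5"))
  # priorities 4 and 6 carry two rows each
  pr <- vapply(w$objectives, `[[`, numeric(1), "priority")
  expect_equal(sum(pr == 4), 2)
  expect_equal(sum(pr == 6), 2)
})

test_that("the packaged phase-2 wishlist reproduces every protocol row", {
  w <- builtin_wishlist(2)
  expect_length(w$constraints, 5)
  expect_length(w$objectives, 10)
  expect_equal(
    vapply(w$constraints, con_sig, character(1)),
    c("PTV-P MAX 105%D_p",
      "PTV-P MEAN 101%D_p",
      "femoral_heads MAX 70%D_p",
      "PTV-P shell 50 mm MAX 50%D_p",
      "Unspecified tissues MAX 105%D_p"))
  expect_equal(
    vapply(w$objectives, row_sig, character(1)),
    c("1 PTV-P LTCP 0.5 100%D_p 0.95 ",
      "2 PTV-P shell 5 mm MAX 90%D_p   ",
      "3 rectum EUD 70%D_p   16",
      "4 bladder EUD 60%D_p   12",
      "5 PTV-P shell 15 mm MAX 50%D_p   ",
      "5 PTV-P shell 25 mm MAX 30%D_p   ",
      "5 Skin ring 20 mm MAX 30%D_p   ",
      "6 rectum MEAN 10%D_p   ",
      "7 bladder MEAN 10%D_p   ",
      "8 femoral_heads EUD 10%D_p   5"))
  pr <- vapply(w$objectives, `[[`, numeric(1), "priority")
  expect_equal(sum(pr == 5), 3)
  expect_error(builtin_wishlist(3), "phase")
})

test_that("wishlists round-trip through YAML and reject malformed input", {
  for (ph in 1:2) {
    w <- builtin_wishlist(ph)
    f <- withr::local_tempfile(fileext = ".yaml")
    save_wishlist(w, f)
    expect_equal(load_wishlist(f), w, ignore_attr = FALSE)
  }
  # hand-edited goal overrides survive the round-trip
  w <- builtin_wishlist(1)
  w$objectives[[4]]$goal$percent <- 55
  f <- withr::local_tempfile(fileext = ".yaml")
  save_wishlist(w, f)
  expect_equal(load_wishlist(f)$objectives[[4]]$goal$percent, 55)
  # schema violations are rejected with a path
  bad <- unclass(builtin_wishlist(1))
  bad$objectives[[1]]$priority <- 0
  fb <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, fb)
  expect_error(load_wishlist(fb), "objectives\\[1\\].*priority")
  bad2 <- unclass(builtin_wishlist(1))
  bad2$objectives[[1]]$kind <- "NTCP"
  yaml::write_yaml(bad2, fb)
  expect_error(load_wishlist(fb), "cost kind")
})

test_that("resolution converts every percent limit and goal to Gy", {
  tp <- tiny_phantom()
  ctx <- prescription_context()
  p1 <- resolve_wishlist(builtin_wishlist(1), ctx, tp$ss)
  lim <- vapply(p1$constraints, `[[`, numeric(1), "limit_gy")
  names(lim) <- vapply(p1$constraints, `[[`, character(1), "structure")
  expect_equal(unname(lim["PTV-P"]), 1.05 * 60)            # 63 Gy
  expect_equal(unname(lim[names(lim) == "PTV-P"]), c(63, 60.6))
  expect_equal(unname(lim["femoral_heads"]), 42)
  expect_equal(unname(lim["PTV-LN shell 50 mm"]), 30)
  expect_equal(unname(lim["Unspecified tissues"]), 63)
  expect_equal(unname(lim[names(lim) == "PTV-LN - PTV-P+5mm"]),
               c(52.5, 50.5))
  goals <- vapply(p1$objectives, `[[`, numeric(1), "goal")
  expect_equal(goals[1:2], c(0.65, 0.5))                   # LTCP unitless
  expect_equal(goals[3], 45)                               # 90% of 50
  expect_equal(goals[4:5], c(42, 18))
  p2 <- resolve_wishlist(builtin_wishlist(2), ctx, tp$ss)
  g2 <- vapply(p2$objectives, `[[`, numeric(1), "goal")
  expect_equal(g2[3], 9.1)                                 # 70% of 13
  expect_equal(g2[4], 7.8)                                 # 60% of 13
  l2 <- vapply(p2$constraints, `[[`, numeric(1), "limit_gy")
  expect_equal(l2[1], 13.65)                               # 105% of 13
})

test_that("auxiliary structures are materialized with the stated recipes", {
  tp <- tiny_phantom()
  g <- tp$grid
  prob <- resolve_wishlist(builtin_wishlist(1), prescription_context(),
                           tp$ss)
  m <- prob$masks
  trans <- expand_mask(tp$ss$masks[["PTV-P"]], g, 5)
  expect_identical(m[["PTV-P+5mm"]], trans)
  # the nodal ring excludes the whole transition region
  expect_equal(sum(m[["PTV-LN - PTV-P+5mm"]] & trans), 0)
  expect_identical(m[["PTV-LN - PTV-P+5mm"]],
                   mask_subtract(tp$ss$masks[["PTV-LN"]], trans, g))
  # shells exclude the phase PTV and stay inside the body
  for (nm in c("PTV-LN shell 5 mm", "PTV-LN shell 15 mm",
               "PTV-LN shell 25 mm", "PTV-LN shell 50 mm")) {
    expect_equal(sum(m[[nm]] & tp$ss$masks[["PTV-LN"]]), 0)
    expect_true(all(m[[nm]] <= tp$ss$masks$external))
  }
  # unspecified tissue is disjoint from every named/auxiliary structure
  un <- m[["Unspecified tissues"]]
  others <- m[setdiff(names(m), c("external", "Unspecified tissues"))]
  expect_equal(sum(un & Reduce(`|`, others)), 0)
  # resolution is pure: same inputs give identical output
  prob2 <- resolve_wishlist(builtin_wishlist(1), prescription_context(),
                            tp$ss)
  expect_identical(prob$constraints, prob2$constraints)
  expect_identical(lapply(prob$objectives, `[`, c("priority", "goal")),
                   lapply(prob2$objectives, `[`, c("priority", "goal")))
})

test_that("resolving against a missing structure names the culprit", {
  tp <- tiny_phantom()
  ss2 <- tp$ss
  ss2$masks$rectum <- NULL
  expect_error(resolve_wishlist(builtin_wishlist(1),
                                prescription_context(), ss2),
               "rectum")
})
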