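mk_profile <- function(label, F_by_len, F_native = NA_real_) {
  stability_profile(label, as.integer(names(F_by_len)), unname(F_by_len),
                    F_native)
}

test_that("the three metrics vanish for the control against itself", {
  ctrl <- mk_profile("control", c(`1` = -10, `2` = -22, `4` = -40),
                     F_native = -10)
  expect_identical(delta_g(ctrl), 0)
  expect_identical(delta_n(ctrl), 0)
  expect_identical(delta_f_tilde(ctrl, ctrl), 0)
})

test_that("dG sign semantics follow the endothermic/exothermic convention", {
  expect_equal(delta_g(mk_profile("m", c(`1` = -10), F_native = -30)), 20)
  expect_equal(delta_g(mk_profile("m", c(`1` = -30), F_native = -10)), -20)
  expect_error(delta_g(mk_profile("m", c(`1` = -30))), "native")
  expect_error(delta_g(mk_profile("m", c(`2` = -30), F_native = 0)),
               "length 1")
})

test_that("dN measures nucleation relative to four free monomers", {
  expect_equal(delta_n(mk_profile("m", c(`1` = -10, `4` = -40))), 0)
  expect_equal(delta_n(mk_profile("m", c(`1` = -10, `4` = -50))), -10)
  expect_equal(delta_n(mk_profile("m", c(`1` = -10, `4` = -30))), 10)
  expect_error(delta_n(mk_profile("m", c(`1` = -10, `2` = -20))), "length 4")
})

test_that("dF~ is the length-weighted sum of energy differences", {
  ctrl <- mk_profile("control", c(`1` = 0, `2` = 0, `5` = 0))
  # +10 at lengths 1, 2, 5: 10/1 + 10/2 + 10/5 = 17
  mut <- mk_profile("m", c(`1` = 10, `2` = 10, `5` = 10))
  expect_equal(delta_f_tilde(mut, ctrl), 17)
  # difference +j at each of n lengths gives n
  ctrl3 <- mk_profile("control", c(`1` = -5, `2` = -9, `3` = -14))
  mut3 <- mk_profile("m", c(`1` = -4, `2` = -7, `3` = -11))
  expect_equal(delta_f_tilde(mut3, ctrl3), 3)
  # linearity in the differences
  mut_s <- mk_profile("m", c(`1` = 30, `2` = 30, `5` = 30))
  expect_equal(delta_f_tilde(mut_s, ctrl), 3 * 17)
  # mismatched length sets are rejected with the missing lengths named
  expect_error(delta_f_tilde(mk_profile("m", c(`1` = 0, `3` = 0)), ctrl),
               "missing lengths")
})

test_that("filter stages drop mutations in the stated order", {
  lens <- c(1, 2, 4)
  ctrl <- stability_profile("control", lens, c(-10, -25, -55), F_native = -12)
  # control dN = -55 - 4*(-10) = -15
  neg_dg <- stability_profile("negG", lens, c(-30, -60, -130),
                              F_native = -10)  # dG = -20 < 0, huge dF~
  weak_dn <- stability_profile("weakN", lens, c(-8, -20, -52),
                               F_native = -10) # dG = 2; dN = -20 <= -15
  surv_a <- stability_profile("survA", lens, c(-8, -20, -40),
                              F_native = -10)  # dN = -8 survives
  surv_b <- stability_profile("survB", lens, c(-6, -15, -30),
                              F_native = -10)  # larger dF~
  rep <- filter_and_rank(list(neg_dg, weak_dn, surv_a, surv_b), ctrl)
  expect_equal(rep$stage_dropped[rep$label == "negG"], 1L)
  expect_equal(rep$stage_dropped[rep$label == "weakN"], 2L)
  expect_true(all(is.na(rep$stage_dropped[rep$label %in% c("survA", "survB")])))
  # larger dF~ ranks first
  expect_equal(rep$label[which(rep$rank == 1)], "survB")
  expect_equal(rep$label[which(rep$rank == 2)], "survA")
  # input order invariance
  rep2 <- filter_and_rank(list(surv_b, surv_a, weak_dn, neg_dg), ctrl)
  expect_equal(rep2[order(rep2$label), ], rep[order(rep$label), ],
               ignore_attr = TRUE)
  # control-only input: empty ranking, no error
  rep0 <- filter_and_rank(list(), ctrl)
  expect_equal(nrow(rep0), 0L)
})

test_that("a constructed dF~ ordering is reproduced end to end", {
  set.seed(11)
  lens <- 1:6
  ctrl <- stability_profile("control", lens, -10 * lens, F_native = -12)
  labels <- paste0("M", 1:5)
  bumps <- c(5, 40, 12, 25, 1)  # uplift at lengths >= 2; bigger = weaker
  profs <- lapply(seq_along(labels), function(i)
    stability_profile(labels[i], lens,
                      -10 * lens + ifelse(lens >= 2, bumps[i], 0),
                      F_native = -13))
  rep <- filter_and_rank(profs, ctrl)
  expect_true(all(is.na(rep$stage_dropped)))
  ranked <- rep$label[order(rep$rank)][seq_along(labels)]
  expect_equal(ranked, labels[order(-bumps)])
})

test_that("profiles round-trip through TSV and the report through JSON", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(mutation = rep(c("control", "A1B"), each = 3),
                    j = rep(c(1, 2, 4), 2),
                    F = c(-10, -20, -45, -8, -15, -33),
                    F_native = rep(c(-11, -10), each = 3))
  utils::write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
  profs <- read_profiles(f)
  expect_named(profs, c("A1B", "control"), ignore.order = TRUE)
  rep <- filter_and_rank(profs["A1B"], profs$control)
  fj <- withr::local_tempfile(fileext = ".json")
  write_report(rep, fj)
  js <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(js$mutations$label, "A1B")
  expect_equal(js$mutations$dG, delta_g(profs$A1B))
})
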