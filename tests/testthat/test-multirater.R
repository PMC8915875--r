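panel_evaluations <- function(n, seed = 1, study = "Study A") {
  lapply(seq_len(n), function(k) {
    generate_evaluation(test_catalog(), "mixed", seed = seed * 1000 + k,
                        study_label = study, evaluator = sprintf("ex%02d", k))
  })
}

test_that("consolidation builds the rater-by-criterion matrix with NA for removals", {
  evs <- panel_evaluations(31)
  evs[[5]] <- suppressWarnings(remove_criterion(evs[[5]], "RQ09"))
  mat <- consolidate(evs, "RQ")
  expect_identical(dim(mat), c(31L, 24L))
  expect_identical(rownames(mat)[5], "ex05")
  expect_true(is.na(mat["ex05", "RQ09"]))
  expect_false(anyNA(mat[-5, ]))

  rel <- consolidate(evs, "REL")
  expect_identical(dim(rel), c(31L, 4L))
  expect_false(anyNA(rel))
})

test_that("consolidation rejects incompatible panels", {
  evs <- panel_evaluations(3)
  other <- evs[[2]]
  other$catalog_ref <- "scirap-invitro@1.0"
  expect_error(consolidate(c(evs[1], list(other)), "RQ"),
               class = "scirap_incompatibility_error")

  dup <- evs
  dup[[2]]$evaluator <- "ex01"
  expect_error(consolidate(dup, "RQ"), class = "scirap_incompatibility_error")

  mixed_study <- evs
  mixed_study[[3]]$study_label <- "Study B"
  expect_error(consolidate(mixed_study, "RQ"),
               class = "scirap_incompatibility_error")
})

test_that("agreement tallies retained ratings; removals leave the denominator", {
  cells <- matrix("F", nrow = 31, ncol = 2,
                  dimnames = list(NULL, c("RQ01", "RQ02")))
  mat <- rating_matrix(cells, "RQ")
  s <- agreement(mat, "RQ01")
  expect_identical(s$n_retained, 31L)
  expect_identical(s$k_observed, 1L)
  expect_equal(s$p_max, 1)

  # one removal, then 24 F + 6 PF of 30 retained -> p_max 0.8
  cells[1, "RQ02"] <- NA
  cells[2:7, "RQ02"] <- "PF"
  mat <- rating_matrix(cells, "RQ")
  s <- agreement(mat, "RQ02")
  expect_identical(s$n_retained, 30L)
  expect_equal(s$p_max, 0.8)
  expect_identical(s$modal_category, "F")

  # 10 F / 10 PF / 11 NF of 31
  cells[, "RQ01"] <- c(rep("F", 10), rep("PF", 10), rep("NF", 11))
  mat <- rating_matrix(cells, "RQ")
  s <- agreement(mat, "RQ01")
  expect_equal(s$p_max, 11 / 31)
  expect_identical(s$k_observed, 3L)
  expect_identical(s$modal_category, "NF")
  expect_equal(sum(s$proportions), 1, tolerance = 1e-9)

  # all cells NA -> degenerate marker
  cells[, "RQ01"] <- NA
  s <- agreement(rating_matrix(cells, "RQ"), "RQ01")
  expect_identical(s$n_retained, 0L)
  expect_true(is.na(s$p_max))
})

test_that("modal ties break by the fixed category order, never moving p_max", {
  cells <- matrix(c(rep("PF", 3), rep("ND", 3)), ncol = 1,
                  dimnames = list(NULL, "RQ01"))
  s <- agreement(rating_matrix(cells, "RQ"), "RQ01")
  expect_equal(s$p_max, 0.5)
  expect_identical(s$modal_category, "PF")
})

test_that("decision rules classify the published bands", {
  rules <- decision_rules()
  mk <- function(tokens) {
    agreement(rating_matrix(matrix(tokens, ncol = 1,
                                   dimnames = list(NULL, "RQ01")), "RQ"),
              "RQ01")
  }
  expect_identical(classify_variability(mk(rep("F", 31)), rules)$class,
                   "consensus")
  # 25 of 31 -> p_max 0.806, low band [0.8, 1)
  expect_identical(
    classify_variability(mk(c(rep("F", 25), rep("PF", 6))), rules)$class,
    "low")
  # 11/31 with three categories observed -> high
  cl <- classify_variability(
    mk(c(rep("F", 10), rep("PF", 10), rep("NF", 11))), rules)
  expect_identical(cl$class, "high")
  expect_match(cl$triggering_rule, "p_max < 0.6")
  # 0.7 agreement with two categories -> moderate (band left open by the
  # consensus/low/high rules)
  expect_identical(
    classify_variability(mk(c(rep("F", 7), rep("PF", 3))), rules)$class,
    "moderate")
  # k >= 3 branch: p_max 0.75 with three categories -> high
  expect_identical(
    classify_variability(mk(c(rep("F", 6), "PF", "NF")), rules)$class,
    "high")
  # below min_raters -> unclassifiable
  expect_identical(classify_variability(mk("F"), rules)$class,
                   "unclassifiable")
})

test_that("rule thresholds are validated and configurable", {
  expect_error(decision_rules(low_lower = 0.5, high_k_pmax = 0.8),
               class = "scirap_domain_error")
  strict <- decision_rules(high_pmax = 0.7, high_k_pmax = 0.7)
  cells <- matrix(c(rep("F", 13), rep("PF", 7)), ncol = 1,
                  dimnames = list(NULL, "RQ01"))
  s <- agreement(rating_matrix(cells, "RQ"), "RQ01")
  expect_identical(classify_variability(s)$class, "moderate")
  expect_identical(classify_variability(s, strict)$class, "high")
})

test_that("agreement and classification match the exhaustive oracle", {
  tokens <- c("F", "PF", "NF", "ND", NA)
  rules <- decision_rules()

  # every 3-rater combination over one criterion (125 matrices)
  grid <- expand.grid(a = tokens, b = tokens, c = tokens,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    col <- unlist(grid[i, ], use.names = FALSE)
    mat <- rating_matrix(matrix(col, ncol = 1, dimnames = list(NULL, "X1")),
                         "RQ")
    s <- agreement(mat, "X1")
    o <- oracle_agreement(col)
    expect_identical(s$n_retained, o$n)
    if (o$n > 0) {
      expect_identical(s$k_observed, o$k)
      expect_equal(s$p_max, o$p_max)
      cl <- classify_variability(s, rules)
      if (o$n >= rules$min_raters) {
        expect_identical(cl$class, oracle_class(o$p_max, o$k))
      } else {
        expect_identical(cl$class, "unclassifiable")
      }
    }
  }

  # seeded random 8-rater x 5-criterion matrices
  set.seed(2024)
  for (rep in 1:200) {
    cells <- matrix(sample(tokens, 40, replace = TRUE,
                           prob = c(.3, .25, .2, .15, .1)),
                    nrow = 8, dimnames = list(NULL, paste0("C", 1:5)))
    mat <- rating_matrix(cells, "RQ")
    for (id in colnames(mat)) {
      s <- agreement(mat, id)
      o <- oracle_agreement(cells[, id])
      expect_identical(s$n_retained, o$n)
      if (o$n == 0) next
      expect_equal(s$p_max, o$p_max)
      expect_identical(s$k_observed, o$k)
      cl <- classify_variability(s, rules)$class
      expected <- if (o$n < rules$min_raters) "unclassifiable"
                  else oracle_class(o$p_max, o$k)
      expect_identical(cl, expected)
    }
  }
})

test_that("classification is total and exclusive over classifiable criteria", {
  set.seed(77)
  sp <- panel_spec(12, c(F = .4, PF = .3, NF = .2, ND = .1),
                   removal_probability = 0.05, seed = 313)
  mat <- generate_panel(test_catalog(), "RQ", sp)
  classes <- classify_matrix(mat)
  expect_identical(nrow(classes), 24L)
  classifiable <- classes[classes$n_retained >= 2, ]
  expect_true(all(classifiable$class %in%
                    c("consensus", "low", "moderate", "high")))
  expect_true(all(classes$class[classes$n_retained < 2] == "unclassifiable"))
})

test_that("prioritization flags criteria high in at least one study", {
  mk_classes <- function(classes) {
    data.frame(criterion_id = paste0("RQ", seq_along(classes)),
               class = classes, stringsAsFactors = FALSE)
  }
  out <- prioritize(list(
    s1 = mk_classes(c("high", "low", "consensus")),
    s2 = mk_classes(c("low", "low", "consensus")),
    s3 = mk_classes(c("moderate", "low", "consensus"))))
  expect_identical(out$prioritized,
                   c(TRUE, FALSE, FALSE))  # high once / low always / consensus
  expect_identical(out$s1, c("high", "low", "consensus"))
  expect_error(prioritize(list()), class = "scirap_degenerate_input_error")
})

test_that("percent_summary rounds half away from zero on exact integers", {
  expect_identical(percent_summary(26, 30), 87L)
  expect_identical(percent_summary(30, 31), 97L)
  expect_identical(percent_summary(0, 30), 0L)
  expect_identical(percent_summary(1, 8), 13L)   # 12.5 rounds up
  expect_identical(percent_summary(1, 40), 3L)   # 2.5 rounds up
  expect_error(percent_summary(1, 0), class = "scirap_domain_error")
  expect_error(percent_summary(5, 3), class = "scirap_domain_error")
})

test_that("rating matrices round-trip through the CSV dialect", {
  sp <- panel_spec(9, c(F = .5, PF = .2, NF = .2, ND = .1),
                   removal_probability = 0.1, seed = 21)
  mat <- generate_panel(test_catalog(), "MQ", sp)
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix(mat, path)
  # removed cells appear as the literal token NA
  expect_true(any(grepl(",NA", readLines(path)[-(1:2)], fixed = TRUE)))
  back <- read_matrix(path)
  expect_identical(unclass(back)[, ], unclass(mat)[, ])
  expect_identical(attr(back, "section"), "MQ")
  expect_identical(attr(back, "study_label"), attr(mat, "study_label"))
})

test_that("relevance matrices refuse NA cells and foreign tokens", {
  cells <- matrix(c("DR", "IR", "NR", "ND"), nrow = 2,
                  dimnames = list(NULL, c("REL1", "REL2")))
  expect_s3_class(rating_matrix(cells, "REL"), "scirap_rating_matrix")
  cells[1, 1] <- NA
  expect_error(rating_matrix(cells, "REL"), class = "scirap_format_error")
  cells[1, 1] <- "F"
  expect_error(rating_matrix(cells, "REL"), class = "scirap_format_error")
})
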