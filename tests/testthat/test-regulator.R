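test_that("regulator keywords match case-insensitively as substrings", {
  expect_true(is_regulator_annotation("LysR family transcriptional regulator"))
  expect_true(is_regulator_annotation("Transcriptional ACTIVATOR of xyz"))
  expect_true(is_regulator_annotation("putative repressor"))
  expect_false(is_regulator_annotation("benzaldehyde dehydrogenase"))
  # custom keyword lists are honoured
  expect_true(is_regulator_annotation("sigma factor", keywords = "sigma"))
  expect_false(is_regulator_annotation("LysR regulator", keywords = "sigma"))
  # vectorised over annotations
  expect_equal(is_regulator_annotation(c("a regulator", "a kinase")),
               c(TRUE, FALSE))
})

# layout helper: operon members at fixed indices on a given strand, the rest
# configurable per test
operon_at <- function(ft, tags) {
  m <- ft[ft$locus_tag %in% tags, ]
  detect_operon(dplyr::mutate(m, step = seq_len(nrow(m))))
}

test_that("the nearest divergent regulator is found on the promoter side only", {
  # layout (indices 0..5): regulator(-) operon(+ + +) decoy decoy
  ft <- make_features(
    c("-", "+", "+", "+", "+", "+"),
    annotations = c("LysR family transcriptional regulator",
                    rep("catabolic enzyme", 3),
                    "hypothetical protein", "transcriptional regulator")
  )
  op <- operon_at(ft, c("TST_0002", "TST_0003", "TST_0004"))
  reg <- find_nearest_divergent_regulator(ft, op)
  expect_equal(reg$locus_tag, "TST_0001")
  expect_equal(reg$distance_genes, 0)
  expect_equal(reg$matched_keyword, "regulator")
})

test_that("non-matching opposite-strand genes are passed over, not returned", {
  # upstream of the operon: a dehydrogenase on the opposite strand, then the
  # true regulator one gene further
  ft <- make_features(
    c("-", "-", "+", "+", "+"),
    annotations = c("LysR family transcriptional regulator",
                    "benzaldehyde dehydrogenase",
                    rep("catabolic enzyme", 3))
  )
  op <- operon_at(ft, c("TST_0003", "TST_0004", "TST_0005"))
  reg <- find_nearest_divergent_regulator(ft, op)
  expect_equal(reg$locus_tag, "TST_0001")
  expect_equal(reg$distance_genes, 1)
})

test_that("a regulator on the 3' side is invisible unless both sides are searched", {
  ft <- make_features(
    c("+", "+", "+", "-"),
    annotations = c(rep("catabolic enzyme", 3),
                    "transcriptional regulator")
  )
  op <- operon_at(ft, c("TST_0001", "TST_0002", "TST_0003"))
  expect_null(find_nearest_divergent_regulator(ft, op))
  reg <- find_nearest_divergent_regulator(ft, op, search_both_sides = TRUE)
  expect_equal(reg$locus_tag, "TST_0004")
  expect_equal(reg$side, "downstream")
})

test_that("minus-strand operons are scanned toward increasing indices", {
  ft <- make_features(
    c("-", "-", "-", "+"),
    annotations = c(rep("catabolic enzyme", 3),
                    "transcriptional regulator")
  )
  op <- operon_at(ft, c("TST_0001", "TST_0002", "TST_0003"))
  expect_equal(op$upstream_index, 2)
  reg <- find_nearest_divergent_regulator(ft, op)
  expect_equal(reg$locus_tag, "TST_0004")
  expect_equal(reg$distance_genes, 0)
})

test_that("proximity scoring follows the strand-weighted deduction rule", {
  mk <- function(between_strands) {
    n_b <- length(between_strands)
    strands <- c("-", between_strands, "+", "+", "+")
    annots <- c("transcriptional regulator",
                rep("hypothetical protein", n_b),
                rep("catabolic enzyme", 3))
    ft <- make_features(strands, annotations = annots)
    member_tags <- ft$locus_tag[(n_b + 2):(n_b + 4)]
    op <- operon_at(ft, member_tags)
    reg <- find_nearest_divergent_regulator(ft, op)
    list(ft = ft, op = op, reg = reg)
  }
  # adjacent: 0
  x <- mk(character())
  expect_equal(score_pair(x$ft, x$op, x$reg), 0)
  # one intervening gene on the operon strand: -1
  x <- mk("+")
  expect_equal(score_pair(x$ft, x$op, x$reg), -1)
  # one intervening gene on the regulator strand: -2
  x <- mk("-")
  expect_equal(score_pair(x$ft, x$op, x$reg), -2)
  # two operon-strand + one regulator-strand: -4
  x <- mk(c("+", "-", "+"))
  expect_equal(score_pair(x$ft, x$op, x$reg), -4)
})

test_that("the score clamps at -500 for very distant regulators", {
  strands <- c("-", rep("+", 600), "+", "+", "+")
  annots <- c("transcriptional regulator",
              rep("hypothetical protein", 600),
              rep("catabolic enzyme", 3))
  ft <- make_features(strands, annotations = annots)
  op <- operon_at(ft, ft$locus_tag[602:604])
  reg <- find_nearest_divergent_regulator(ft, op)
  expect_equal(reg$distance_genes, 600)
  expect_equal(score_pair(ft, op, reg), -500)
})

test_that("scores equal a naive recount on random arrangements", {
  set.seed(404)
  for (rep in 1:200) {
    n_between <- sample(0:20, 1)
    between <- if (n_between > 0) sample(c("+", "-"), n_between, TRUE) else character()
    op_strand <- sample(c("+", "-"), 1)
    reg_strand <- if (op_strand == "+") "-" else "+"
    if (op_strand == "+") {
      strands <- c(reg_strand, between, rep("+", 3))
      reg_pos <- 1L
      member_pos <- (n_between + 2):(n_between + 4)
    } else {
      strands <- c(rep("-", 3), rev(between), reg_strand)
      member_pos <- 1:3
      reg_pos <- n_between + 4L
    }
    annots <- rep("hypothetical protein", length(strands))
    annots[reg_pos] <- "transcriptional regulator"
    ft <- make_features(strands, annotations = annots)
    op <- operon_at(ft, ft$locus_tag[member_pos])
    reg <- find_nearest_divergent_regulator(ft, op)
    expect_false(is.null(reg))
    got <- score_pair(ft, op, reg)
    want <- oracle_score(ft, op_strand, op$upstream_index, reg$index,
                         op$members[[1]]$index)
    expect_identical(got, want)
    expect_lte(got, 0)
    expect_gte(got, -500)
    expect_equal(got == 0, reg$distance_genes == 0)
  }
})

test_that("adding an intervening gene never raises the score", {
  base_between <- c("+", "-")
  score_for <- function(between) {
    strands <- c("-", between, rep("+", 3))
    annots <- c("transcriptional regulator",
                rep("hypothetical protein", length(between)),
                rep("catabolic enzyme", 3))
    ft <- make_features(strands, annotations = annots)
    op <- operon_at(ft, ft$locus_tag[(length(between) + 2):(length(between) + 4)])
    reg <- find_nearest_divergent_regulator(ft, op)
    score_pair(ft, op, reg)
  }
  s0 <- score_for(base_between)
  expect_lte(score_for(c(base_between, "+")), s0)
  expect_lte(score_for(c(base_between, "-")), s0)
})
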