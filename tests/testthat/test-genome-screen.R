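test_that("feature tables round-trip through the file dialect with dense indices", {
  ft <- make_features(c("+", "-", "+"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_feature_table(ft, path)
  expect_match(readLines(path, n = 1), "^# feature")
  ft2 <- read_feature_table(path)
  expect_equal(ft2$index, 0:2)
  expect_equal(ft2$locus_tag, ft$locus_tag)
  expect_equal(ft2$strand, ft$strand)
  expect_equal(ft2$start, ft$start)
})

test_that("interleaved replicons get independent index sequences", {
  raw <- tibble::tibble(
    genomic_accession = c("CHR1", "PLAS1", "CHR1", "PLAS1"),
    start = c(100L, 50L, 2000L, 900L),
    end = c(900L, 700L, 2800L, 1500L),
    strand = c("+", "-", "+", "+"),
    locus_tag = c("G1", "P1", "G2", "P2"),
    annotation = rep("hypothetical protein", 4)
  )
  ft <- new_feature_table(raw)
  expect_equal(ft$index[ft$genomic_accession == "CHR1"], 0:1)
  expect_equal(ft$index[ft$genomic_accession == "PLAS1"], 0:1)
  # sorted by start within replicon
  expect_equal(ft$locus_tag[ft$genomic_accession == "PLAS1"], c("P1", "P2"))
})

test_that("broken tables are rejected with informative errors", {
  raw <- make_features(c("+", "+"))
  raw$locus_tag <- c("DUP_1", "DUP_1")
  expect_error(new_feature_table(raw), "duplicate locus_tag.*DUP_1")

  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("feature\tstart\tend", "CDS\t1\t10"), path)
  expect_error(read_feature_table(path), "missing column")
})

test_that("non-CDS rows and rows lacking locus tags are dropped", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "# feature\tclass\tgenomic_accession\tstart\tend\tstrand\tlocus_tag\tname",
    "gene\t\tCHR1\t1\t900\t+\tX_0001\tsome gene",
    "CDS\twith_protein\tCHR1\t1\t900\t+\tX_0001\tisomerase",
    "CDS\twith_protein\tCHR1\t1000\t1900\t-\t\tno tag here",
    "CDS\twith_protein\tCHR1\t2000\t2900\t+\tX_0002\tkinase"
  ), path)
  expect_message(ft <- read_feature_table(path), "dropped 1")
  expect_equal(ft$locus_tag, c("X_0001", "X_0002"))
  expect_equal(ft$index, 0:1)
})

test_that("locus-tag matching is case-insensitive and enumerates copies", {
  ft <- make_features(rep("+", 6))
  # tags TST_0001..TST_0006; step2 has two copies
  asg <- locate_chain_genes(ft, list("tst_0002", c("TST_0003", "TST_0006")))
  expect_equal(nrow(asg), 2)
  # the tighter span (genes 2-3) sorts first
  expect_equal(sort(asg$members[[1]]$locus_tag), c("TST_0002", "TST_0003"))
  expect_lt(asg$span[1], asg$span[2])

  # a step with no matching tag kills the assignment list
  expect_equal(nrow(locate_chain_genes(ft, list("TST_0002", "NOPE_1"))), 0)
})

test_that("assignments spanning replicons sort after single-replicon ones", {
  raw <- rbind(
    make_features(rep("+", 3), replicon = "CHR1", tag_prefix = "A"),
    make_features(rep("+", 3), replicon = "CHR2", tag_prefix = "B")
  )
  ft <- new_feature_table(raw[, setdiff(names(raw), "index")])
  asg <- locate_chain_genes(ft, list("A_0001", c("A_0002", "B_0002")))
  expect_equal(nrow(asg), 2)
  expect_true(is.finite(asg$span[1]))
  expect_equal(asg$span[2], Inf)
})

test_that("the combination cap keeps the tightest assignments and warns", {
  ft <- make_features(rep("+", 12))
  tags <- ft$locus_tag
  expect_warning(
    asg <- locate_chain_genes(ft, list(tags[1:4], tags[5:8], tags[9:12]),
                              combination_cap = 10),
    "cap"
  )
  expect_equal(nrow(asg), 10)
  expect_true(all(diff(asg$span) >= 0))
})

test_that("operon detection enforces strand, replicon and the gap rule", {
  ft <- make_features(c(rep("+", 16)))
  pick <- function(tags) {
    m <- ft[ft$locus_tag %in% tags, ]
    dplyr::mutate(m, step = seq_len(nrow(m)))
  }
  # indices 10,11,12 (tags are index+1)
  op <- detect_operon(pick(c("TST_0011", "TST_0012", "TST_0013")))
  expect_false(is.null(op))
  expect_equal(op$upstream_index, 10)
  expect_equal(op$strand, "+")

  # indices 10,11,15: three intervening genes exceed gap_tolerance 2
  expect_null(detect_operon(pick(c("TST_0011", "TST_0012", "TST_0016")),
                            gap_tolerance = 2))
  # but pass at gap_tolerance 3
  expect_false(is.null(detect_operon(pick(c("TST_0011", "TST_0012", "TST_0016")),
                                     gap_tolerance = 3)))

  # mixed strands never form an operon
  ft2 <- make_features(c("+", "-", "+"))
  mixed <- dplyr::mutate(ft2, step = seq_len(nrow(ft2)))
  expect_null(detect_operon(mixed))
})

test_that("operon detection is invariant to member input order", {
  ft <- make_features(rep("-", 8))
  members <- dplyr::mutate(ft[3:5, ], step = 1:3)
  shuffled <- members[c(3, 1, 2), ]
  shuffled$step <- 1:3
  a <- detect_operon(members)
  b <- detect_operon(shuffled)
  expect_equal(a$member_tags, b$member_tags)
  expect_equal(a$upstream_index, b$upstream_index)
  # minus-strand operon: the 5' member is the highest-index one
  expect_equal(a$upstream_index, 4)
})

test_that("collinearity can be required", {
  ft <- make_features(rep("+", 6))
  fwd <- dplyr::mutate(ft[2:4, ], step = 1:3)
  scrambled <- fwd
  scrambled$step <- c(2L, 1L, 3L)
  expect_false(is.null(detect_operon(fwd, require_collinear = TRUE)))
  expect_null(detect_operon(scrambled, require_collinear = TRUE))
  # on the minus strand, step order runs against the index order
  ftm <- make_features(rep("-", 6))
  rev_steps <- dplyr::mutate(ftm[2:4, ], step = 3:1)
  expect_false(is.null(detect_operon(rev_steps, require_collinear = TRUE)))
})

test_that("planted operons are recalled and strand-scrambles are rejected", {
  set.seed(11)
  ecs <- c("5.3.1.4", "2.7.1.16", "5.1.3.4")
  for (seed in 1:5) {
    spec <- genome_spec(paste0("go", seed), n_genes = 50, seed = seed,
      operons = list(list(ecs = ecs, start_index = 20, strand = "+",
                          gaps = c(sample(0:2, 1), sample(0:2, 1)))))
    sim <- simulate_genome(spec)
    asg <- locate_chain_genes(sim$features,
                              as.list(sim$gene_map$genes))
    op <- detect_operon(asg$members[[1]], gap_tolerance = 2)
    expect_false(is.null(op))
    expect_equal(op$member_tags, sim$truth$member_tags)

    scrambled <- sim$features
    member_rows <- scrambled$locus_tag %in% sim$gene_map$genes
    flip <- which(member_rows)[1]
    scrambled$strand[flip] <- "-"
    asg2 <- locate_chain_genes(scrambled, as.list(sim$gene_map$genes))
    expect_null(detect_operon(asg2$members[[1]], gap_tolerance = 2))
  }
})
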