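# Independent oracles: deliberately naive re-implementations used only to
# cross-check the package's outputs. They share no code with the paths they
# verify (equations are split by hand, intersections and score recounts are
# plain loops).

# brute-force enumeration of EC-sequence paths in a reaction table
oracle_enumerate_ec_paths <- function(reactions, seed, max_len, min_len = 2) {
  # hand-parse equations: left/right of "<=>", terms split on " + ",
  # optional leading integer coefficient
  edges <- list()
  for (i in seq_len(nrow(reactions))) {
    sides <- strsplit(reactions$equation[i], "<=>", fixed = TRUE)[[1]]
    terms <- function(s) {
      ts <- strsplit(trimws(s), " + ", fixed = TRUE)[[1]]
      vapply(ts, function(t) {
        parts <- strsplit(trimws(t), " +")[[1]]
        parts[length(parts)]
      }, character(1), USE.NAMES = FALSE)
    }
    subs <- terms(sides[1])
    prods <- terms(sides[2])
    ecs <- strsplit(reactions$ec_numbers[i], ";", fixed = TRUE)[[1]]
    ecs <- ecs[!grepl("-", ecs, fixed = TRUE)]
    for (s in subs) {
      for (p in prods) {
        for (e in ecs) {
          edges[[length(edges) + 1]] <- list(
            from = s, to = p, ec = e, rid = reactions$reaction_id[i]
          )
        }
      }
    }
  }
  results <- character()
  recurse <- function(compound, visited, ecs_so_far) {
    if (length(ecs_so_far) >= min_len) {
      results[length(results) + 1] <<- paste(ecs_so_far, collapse = ";")
    }
    if (length(ecs_so_far) >= max_len) return(invisible(NULL))
    # deterministic expansion order: reaction id, ec, product
    keys <- vapply(edges, function(e) paste(e$rid, e$ec, e$to), character(1))
    for (e in edges[order(keys)]) {
      if (e$from == compound && !(e$to %in% visited)) {
        recurse(e$to, c(visited, e$to), c(ecs_so_far, e$ec))
      }
    }
    invisible(NULL)
  }
  recurse(seed, seed, character())
  unique(results)
}

# naive proximity-score recount: walk every gene row between the two anchors
oracle_score <- function(features, operon_strand, upstream_index,
                         regulator_index, member_indices, floor = -500) {
  lo <- min(upstream_index, regulator_index)
  hi <- max(upstream_index, regulator_index)
  total <- 0
  for (i in seq_len(nrow(features))) {
    idx <- features$index[i]
    if (idx > lo && idx < hi && !(idx %in% member_indices)) {
      total <- total + if (features$strand[i] == operon_strand) 1 else 2
    }
  }
  max(floor, -total)
}

# compact builder for synthetic single-replicon feature tables
make_features <- function(strands, annotations = NULL, replicon = "TEST_1",
                          tag_prefix = "TST") {
  n <- length(strands)
  if (is.null(annotations)) annotations <- rep("hypothetical protein", n)
  starts <- seq(1L, by = 1000L, length.out = n)
  new_feature_table(tibble::tibble(
    genomic_accession = replicon,
    start = starts,
    end = starts + 800L,
    strand = strands,
    locus_tag = sprintf("%s_%04d", tag_prefix, seq_len(n)),
    annotation = annotations
  ))
}

# random knowledge base over a small compound universe, for property tests
random_kb <- function(n_compounds = 8, n_reactions = 12) {
  compounds <- sprintf("C9%04d", seq_len(n_compounds))
  rxn <- lapply(seq_len(n_reactions), function(i) {
    sub <- sample(compounds, 1)
    prods <- sample(setdiff(compounds, sub), sample(1:2, 1))
    tibble::tibble(
      reaction_id = sprintf("R9%04d", i),
      equation = paste(sub, "<=>", paste(prods, collapse = " + ")),
      ec_numbers = sprintf("%d.%d.%d.%d", sample(1:6, 1), sample(1:9, 1),
                           sample(1:9, 1), sample(1:99, 1))
    )
  })
  reactions <- do.call(rbind, rxn)
  kb_new(
    compounds = tibble::tibble(compound_id = compounds, name = compounds),
    reactions = reactions
  )
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
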