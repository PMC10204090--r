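#' Enumerate enzymatic chains degrading a seed compound
#'
#' Depth-first expansion of the reaction graph: starting from the seed
#' compound, every reaction that consumes the current compound is expanded
#' once per full EC number it carries and once per product (each product is an
#' independent continuation). Expansion stops at `max_len` steps; all chains
#' with length in `[min_len, max_len]` are returned. A chain never revisits a
#' compound already on its own consumed path (seed included). Chains are
#' deduplicated by their ordered EC sequence, keeping the first found in
#' lexicographic (reaction id, EC, product id) traversal order, so output is
#' reproducible.
#'
#' @param kb a `tfb_kb`.
#' @param seed seed compound id.
#' @param max_len maximum chain length (number of catalytic steps), >= 2.
#' @param min_len minimum chain length, >= 2 (default 2).
#' @param treat_reversible also traverse reactions right-to-left (default
#'   `FALSE`: the written direction only).
#' @param include_partial_ec include partial EC numbers (e.g. `1.1.1.-`) as
#'   chain steps (default `FALSE`: they carry no reliable gene linkage).
#' @param exclude_compounds compound ids never traversed through (e.g. a
#'   currency-metabolite list). Default empty: cofactor-regeneration
#'   continuations are enumerated and left to downstream triage.
#' @param chain_cap stop after this many chains with a warning (default
#'   10000), guarding against combinatorial explosion.
#'
#' @return tibble with one row per unique chain: `chain_id`, `seed`,
#'   `length`, `ec_seq` (ECs joined by `";"`) and `steps`, a list-column of
#'   per-step tibbles (`step`, `ec`, `reaction_id`, `consumed`, `produced`).
#' @examples
#' kb <- arabinose_kb()
#' enumerate_chains(kb, "C02479", max_len = 3)
#' @export
enumerate_chains <- function(kb, seed, max_len, min_len = 2,
                             treat_reversible = FALSE,
                             include_partial_ec = FALSE,
                             exclude_compounds = character(),
                             chain_cap = 10000) {
  stopifnot(inherits(kb, "tfb_kb"))
  if (!is.numeric(max_len) || max_len < 2) {
    abort("max_len must be an integer >= 2")
  }
  if (!is.numeric(min_len) || min_len < 2 || min_len > max_len) {
    abort("min_len must satisfy 2 <= min_len <= max_len")
  }

  found <- list()
  n_found <- 0L
  capped <- FALSE

  expand <- function(compound, path_compounds, steps_so_far) {
    if (capped) return(invisible(NULL))
    depth <- nrow(steps_so_far)
    if (depth >= max_len) return(invisible(NULL))
    rxns <- withCallingHandlers(
      reactions_consuming(kb, compound, treat_reversible = treat_reversible),
      message = function(m) invokeRestart("muffleMessage")
    )
    if (nrow(rxns) == 0) return(invisible(NULL))
    for (i in seq_len(nrow(rxns))) {
      ecs <- sort(rxns$ec_numbers[[i]])
      if (!include_partial_ec) ecs <- ecs[!grepl("-", ecs, fixed = TRUE)]
      if (length(ecs) == 0) next
      prods <- sort(unique(rxns$products[[i]]$compound_id))
      prods <- setdiff(prods, c(path_compounds, exclude_compounds))
      for (ec_i in ecs) {
        for (prod in prods) {
          if (capped) return(invisible(NULL))
          step_row <- tibble(
            step = depth + 1L, ec = ec_i,
            reaction_id = rxns$reaction_id[[i]],
            consumed = compound, produced = prod
          )
          steps <- bind_rows(steps_so_far, step_row)
          if (nrow(steps) >= min_len) {
            if (n_found >= chain_cap) {
              capped <<- TRUE
              return(invisible(NULL))
            }
            n_found <<- n_found + 1L
            found[[n_found]] <<- steps
          }
          expand(prod, c(path_compounds, prod), steps)
        }
      }
    }
    invisible(NULL)
  }

  expand(seed, seed, tibble())
  if (capped) {
    warn(sprintf("chain enumeration capped at %d chains; results are truncated",
                 chain_cap))
  }
  if (length(found) == 0) {
    return(tibble(chain_id = character(), seed = character(),
                  length = integer(), ec_seq = character(), steps = list()))
  }
  out <- tibble(
    seed = seed,
    length = map_int(found, nrow),
    ec_seq = map_chr(found, function(s) paste(s$ec, collapse = ";")),
    steps = found
  ) |>
    distinct(ec_seq, .keep_all = TRUE) |>
    mutate(chain_id = sprintf("%s_len%d_%s", seed, length,
                              gsub(";", "_", ec_seq, fixed = TRUE))) |>
    select(chain_id, seed, length, ec_seq, steps)
  out
}

#' Organisms encoding every step of a chain
#'
#' Intersects, over the chain's steps, the sets of organisms whose genomes
#' are annotated with the step's EC number; only organisms that carry genes
#' for every step are kept, with the candidate gene lists preserved per step.
#'
#' @param kb a `tfb_kb`.
#' @param chain one row of the tibble returned by [enumerate_chains()], or
#'   its `steps` tibble.
#' @return tibble with one row per retained organism-step: `organism`,
#'   `step`, `ec`, `genes` (list-column). Zero rows when no organism encodes
#'   the full chain or when a step's EC is absent from the knowledge base
#'   (logged, since such a chain cannot be screened).
#' @export
organisms_with_chain <- function(kb, chain) {
  steps <- chain_steps(chain)
  empty <- tibble(organism = character(), step = integer(),
                  ec = character(), genes = list())
  per_step <- purrr::map(seq_len(nrow(steps)), function(i) {
    g <- genes_for_ec(kb, steps$ec[i])
    mutate(g, step = steps$step[i], ec = steps$ec[i])
  })
  missing <- steps$ec[map_int(per_step, nrow) == 0]
  if (length(missing) > 0) {
    inform(paste0("chain skipped: no gene links for EC ",
                  paste(missing, collapse = ", ")))
    return(empty)
  }
  shared <- Reduce(intersect, purrr::map(per_step, "organism"))
  if (length(shared) == 0) return(empty)
  list_rbind(per_step) |>
    filter(organism %in% shared) |>
    select(organism, step, ec, genes) |>
    arrange(organism, step)
}

chain_steps <- function(chain) {
  if (is_tibble(chain) && "steps" %in% names(chain)) {
    stopifnot(nrow(chain) == 1)
    chain$steps[[1]]
  } else if (is_tibble(chain) && all(c("step", "ec") %in% names(chain))) {
    chain
  } else {
    abort("chain must be a one-row chain tibble or a steps tibble")
  }
}
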