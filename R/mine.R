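#' Read an organism-to-assembly map
#'
#' TSV with header and columns `organism_code`, `assembly_accession`, `path`
#' (feature-table file, absolute or relative to the map's directory). Stands
#' in for the internal database linking organism codes to downloaded genome
#' assemblies.
#'
#' @param path path to the map file.
#' @return tibble with the three columns; relative feature-table paths are
#'   resolved against the map file's directory.
#' @export
read_org_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing <- setdiff(c("organism_code", "assembly_accession", "path"), names(df))
  if (length(missing) > 0) {
    abort(paste0("organism map ", path, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  base <- dirname(path)
  df |>
    mutate(path = ifelse(grepl("^/", path), path, file.path(base, path))) |>
    select(organism_code, assembly_accession, path)
}

#' Mine candidate transcription-factor biosensors for a compound
#'
#' End-to-end run: enumerate the enzymatic chains that sequentially degrade
#' the seed compound, find the organisms encoding every chain step, map the
#' step genes onto each organism's genome feature table, keep arrangements
#' that form a plausible operon, attach the nearest divergently oriented
#' regulator and score the pair by proximity. One ranked CSV per chain with
#' at least one candidate is written to `out_dir` (if given), named
#' `<seed>_len<k>_<EC1>_<EC2>[...].csv`. The run is deterministic for fixed
#' inputs: reruns produce byte-identical outputs.
#'
#' @param kb a `tfb_kb`.
#' @param compound seed compound id.
#' @param org_map tibble from [read_org_map()] (or a path to the map file).
#' @param max_len,min_len chain length window (see [enumerate_chains()]).
#' @param gap_tolerance operon gap rule (see [detect_operon()]).
#' @param keywords regulator keyword list.
#' @param score_floor candidates scoring below this are dropped; scores are
#'   clamped at -500 regardless (default -500).
#' @param combination_cap per organism-chain cap on gene-copy assignments.
#' @param chain_cap enumeration cap (see [enumerate_chains()]).
#' @param out_dir output directory for per-chain CSVs; `NULL` writes nothing.
#' @param treat_reversible,require_collinear,search_both_sides relaxation
#'   flags forwarded to the respective stages.
#' @return list with `summary` (one-row tibble: `chains_enumerated`,
#'   `chains_with_output`, `candidates_total`), `candidates` (ranked tibble,
#'   all chains pooled) and `files` (paths written).
#' @export
mine <- function(kb, compound, org_map, max_len, min_len = 2,
                 gap_tolerance = 2, keywords = default_regulator_keywords(),
                 score_floor = -500, combination_cap = 50, chain_cap = 10000,
                 out_dir = NULL, treat_reversible = FALSE,
                 require_collinear = FALSE, search_both_sides = FALSE) {
  stopifnot(inherits(kb, "tfb_kb"))
  if (is.character(org_map) && length(org_map) == 1) {
    org_map <- read_org_map(org_map)
  }
  chains <- enumerate_chains(kb, compound, max_len = max_len, min_len = min_len,
                             treat_reversible = treat_reversible,
                             chain_cap = chain_cap)
  inform(sprintf("enumerated %d chain(s) for %s (max_len %d)",
                 nrow(chains), compound, max_len))

  table_cache <- new.env(parent = emptyenv())
  load_table <- function(row) {
    key <- row$path
    if (!is.null(table_cache[[key]])) return(table_cache[[key]])
    ft <- tryCatch(
      read_feature_table(row$path, organism_code = row$organism_code,
                         assembly_accession = row$assembly_accession),
      error = function(e) e
    )
    if (inherits(ft, "error")) {
      inform(sprintf("skipping organism %s: cannot read %s (%s)",
                     row$organism_code, row$path, conditionMessage(ft)))
      ft <- NULL
    }
    table_cache[[key]] <- ft
    ft
  }

  all_candidates <- list()
  files <- character()
  chains_with_output <- 0L

  for (ci in seq_len(nrow(chains))) {
    chain <- chains[ci, ]
    org_genes <- organisms_with_chain(kb, chain)
    if (nrow(org_genes) == 0) next
    chain_candidates <- list()
    for (org in intersect(sort(unique(org_genes$organism)), org_map$organism_code)) {
      map_row <- org_map[org_map$organism_code == org, ][1, ]
      ft <- load_table(map_row)
      if (is.null(ft)) next
      per_step <- org_genes |>
        filter(organism == org) |>
        arrange(step) |>
        pull(genes)
      assignments <- locate_chain_genes(ft, per_step,
                                        combination_cap = combination_cap)
      for (ai in seq_len(nrow(assignments))) {
        op <- detect_operon(assignments$members[[ai]],
                            gap_tolerance = gap_tolerance,
                            require_collinear = require_collinear)
        if (is.null(op)) next
        reg <- find_nearest_divergent_regulator(ft, op, keywords = keywords,
                                                search_both_sides = search_both_sides)
        if (is.null(reg)) next
        sc <- score_pair(ft, op, reg)
        if (sc < score_floor) next
        chain_candidates[[length(chain_candidates) + 1]] <- tibble(
          chain_id = chain$chain_id, ec_seq = chain$ec_seq,
          organism_code = org,
          assembly_accession = map_row$assembly_accession,
          replicon = op$replicon,
          enzyme_locus_tags = op$member_tags,
          regulator_locus_tag = reg$locus_tag,
          regulator_annotation = reg$annotation,
          score = sc
        )
      }
    }
    if (length(chain_candidates) == 0) next
    cand <- list_rbind(chain_candidates) |>
      distinct(organism_code, replicon, enzyme_locus_tags,
               regulator_locus_tag, .keep_all = TRUE) |>
      rank_candidates()
    chains_with_output <- chains_with_output + 1L
    all_candidates[[length(all_candidates) + 1]] <- cand
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      f <- file.path(out_dir, paste0(chain$chain_id, ".csv"))
      readr::write_csv(select(cand, -chain_id, -ec_seq) |>
                         mutate(ec_seq = chain$ec_seq, .before = 1),
                       f, progress = FALSE)
      files <- c(files, f)
    }
  }

  candidates <- if (length(all_candidates) > 0) {
    list_rbind(all_candidates)
  } else {
    tibble(chain_id = character(), ec_seq = character(),
           organism_code = character(), assembly_accession = character(),
           replicon = character(), enzyme_locus_tags = character(),
           regulator_locus_tag = character(), regulator_annotation = character(),
           score = integer())
  }
  summary <- tibble(
    chains_enumerated = nrow(chains),
    chains_with_output = chains_with_output,
    candidates_total = nrow(candidates)
  )
  inform(sprintf("%d chain(s) with candidates; %d candidate(s) total",
                 chains_with_output, nrow(candidates)))
  list(summary = summary, candidates = candidates, files = files)
}

#' Rank biosensor candidates
#'
#' Descending proximity score (0 is best); ties broken by organism code then
#' regulator locus tag, lexicographically, so output order is reproducible.
#'
#' @param candidates candidate tibble with columns `score`, `organism_code`,
#'   `regulator_locus_tag`.
#' @return the tibble, ranked.
#' @export
rank_candidates <- function(candidates) {
  arrange(candidates, desc(score), organism_code, regulator_locus_tag)
}

#' Plot the gene neighborhood of a biosensor candidate
#'
#' Draws the operon members, the regulator and the surrounding genes as
#' strand-aware arrows around the shared divergent promoter region.
#'
#' @param features indexed feature tibble.
#' @param operon one-row operon tibble from [detect_operon()].
#' @param regulator one-row regulator tibble, or `NULL`.
#' @param flank extra genes to show on each side (default 3).
#' @return a ggplot object.
#' @export
plot_neighborhood <- function(features, operon, regulator = NULL, flank = 3) {
  member_idx <- operon$members[[1]]$index
  regulator_idx <- if (is.null(regulator)) integer() else regulator$index
  idx_all <- c(member_idx, regulator_idx)
  window <- features |>
    filter(genomic_accession == operon$replicon,
           index >= min(idx_all) - flank, index <= max(idx_all) + flank) |>
    mutate(
      role = dplyr::case_when(
        index %in% member_idx ~ "operon member",
        index %in% regulator_idx ~ "regulator",
        TRUE ~ "other"
      ),
      xstart = ifelse(strand == "+", start, end),
      xend = ifelse(strand == "+", end, start)
    )
  ggplot2::ggplot(window) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$xstart, xend = .data$xend, y = 0, yend = 0,
                   colour = .data$role),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "inches")),
      linewidth = 3, lineend = "butt"
    ) +
    ggplot2::geom_text(ggplot2::aes(x = (start + end) / 2, y = 0.1,
                                    label = .data$locus_tag),
                       angle = 45, hjust = 0, size = 2.8) +
    ggplot2::scale_y_continuous(limits = c(-0.3, 0.6), breaks = NULL) +
    ggplot2::labs(x = paste0(operon$replicon, " (bp)"), y = NULL, colour = NULL)
}
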