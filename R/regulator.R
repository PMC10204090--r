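#' Default regulator keyword list
#'
#' Annotation terms denoting a regulatory function. Matching is
#' case-insensitive substring matching, so e.g. "antirepressor" also matches
#' "repressor" -- a documented limitation of keyword screening.
#' @export
default_regulator_keywords <- function() c("regulator", "activator", "repressor")

#' Does an annotation denote a transcriptional regulator?
#'
#' @param text annotation string(s) from the feature table's product column.
#' @param keywords keyword list (default [default_regulator_keywords()]).
#' @return logical vector: `TRUE` where any keyword is a case-insensitive
#'   substring of the annotation.
#' @examples
#' is_regulator_annotation("LysR family transcriptional regulator")
#' is_regulator_annotation("benzaldehyde dehydrogenase")
#' @export
is_regulator_annotation <- function(text, keywords = default_regulator_keywords()) {
  low <- stringr::str_to_lower(text)
  hits <- purrr::map(keywords, function(kw) {
    stringr::str_detect(low, stringr::fixed(stringr::str_to_lower(kw)))
  })
  Reduce(`|`, hits)
}

matched_keyword <- function(text, keywords) {
  low <- stringr::str_to_lower(text)
  for (kw in keywords) {
    if (stringr::str_detect(low, stringr::fixed(stringr::str_to_lower(kw)))) return(kw)
  }
  NA_character_
}

#' Find the nearest divergently oriented transcriptional regulator
#'
#' Walks the genes upstream of the operon's 5' member -- decreasing gene
#' index for a plus-strand operon, increasing index for a minus-strand one,
#' i.e. the shared divergent-promoter side -- and returns the first gene that
#' lies on the opposite strand and whose annotation matches a regulator
#' keyword. Genes passed over on the way (either strand, any annotation)
#' become the intervening genes that [score_pair()] penalises. The scan runs
#' to the end of the replicon; distant hits are not discarded here but their
#' score is clamped at the floor by [score_pair()].
#'
#' @param features an indexed feature tibble.
#' @param operon a one-row operon tibble from [detect_operon()].
#' @param keywords regulator keyword list.
#' @param search_both_sides also scan downstream of the operon's 3' member;
#'   ties between equidistant hits prefer the upstream side, then the lower
#'   start coordinate (default `FALSE`).
#' @return one-row tibble (`locus_tag`, `annotation`, `strand`, `index`,
#'   `start`, `end`, `matched_keyword`, `distance_genes`, `side`) or `NULL`
#'   when no divergent regulator exists on the searched side(s).
#' @export
find_nearest_divergent_regulator <- function(features, operon,
                                             keywords = default_regulator_keywords(),
                                             search_both_sides = FALSE) {
  repl <- features |>
    filter(genomic_accession == operon$replicon) |>
    arrange(index)
  member_idx <- operon$members[[1]]$index

  scan <- function(from_index, direction, side) {
    idx <- from_index + direction
    max_idx <- max(repl$index)
    while (idx >= 0 && idx <= max_idx) {
      gene <- repl[repl$index == idx, ]
      if (nrow(gene) == 1 && gene$strand != operon$strand &&
          is_regulator_annotation(gene$annotation, keywords)) {
        between <- setdiff(seq(from_index, idx), c(from_index, idx, member_idx))
        return(mutate(
          gene,
          matched_keyword = matched_keyword(gene$annotation, keywords),
          distance_genes = length(between),
          side = side
        ))
      }
      idx <- idx + direction
    }
    NULL
  }

  upstream_dir <- if (operon$strand == "+") -1L else 1L
  up <- scan(operon$upstream_index, upstream_dir, "upstream")
  if (!search_both_sides) {
    return(up)
  }
  downstream_from <- if (operon$strand == "+") max(member_idx) else min(member_idx)
  down <- scan(downstream_from, -upstream_dir, "downstream")
  candidates <- bind_rows(up, down)
  if (nrow(candidates) == 0) return(NULL)
  candidates |>
    mutate(side_rank = ifelse(side == "upstream", 0L, 1L)) |>
    arrange(distance_genes, side_rank, start) |>
    select(-side_rank) |>
    head(1)
}

#' Proximity score for a regulator-operon pair
#'
#' The score starts at 0 -- a regulator directly adjacent to the operon's 5'
#' member -- and is reduced by the genes lying strictly between the regulator
#' and that member: one point for each intervening gene on the operon's
#' strand (such genes may simply be unrecognised operon members), two points
#' for each intervening gene on the regulator's strand. The score is clamped
#' at the floor, so it always lies in `[score_floor, 0]`.
#'
#' @param features an indexed feature tibble.
#' @param operon one-row operon tibble from [detect_operon()].
#' @param regulator one-row regulator tibble from
#'   [find_nearest_divergent_regulator()].
#' @param score_floor lower clamp (default -500).
#' @return integer score in `[score_floor, 0]`.
#' @export
score_pair <- function(features, operon, regulator, score_floor = -500) {
  repl <- filter(features, genomic_accession == operon$replicon)
  member_idx <- operon$members[[1]]$index
  anchor <- if (identical(regulator$side, "downstream")) {
    if (operon$strand == "+") max(member_idx) else min(member_idx)
  } else {
    operon$upstream_index
  }
  lo <- min(anchor, regulator$index)
  hi <- max(anchor, regulator$index)
  between <- repl |>
    filter(index > lo, index < hi, !(index %in% member_idx))
  deduction <- sum(ifelse(between$strand == operon$strand, 1L, 2L))
  max(score_floor, -deduction)
}
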